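#' Build an ORF corpus
#'
#' An `orf_corpus` is a data frame with one row per coding sequence and
#' columns `id`, `cds`, `upstream` and `downstream` (flanking nucleotides,
#' possibly empty strings). Sequences are stored uppercase on the DNA
#' alphabet; U is mapped to T on construction. No validation beyond alphabet
#' normalisation is applied here — see [filter_orfs()].
#'
#' @param id character vector of unique sequence identifiers.
#' @param cds character vector of coding sequences.
#' @param upstream,downstream optional flanking nucleotide strings, recycled
#'   to length of `id`; default empty.
#' @return a data frame of class `orf_corpus`.
#' @examples
#' orf_corpus("g1", "atggaagagtaa")
#' @export
orf_corpus <- function(id, cds, upstream = "", downstream = "") {
  stopifnot(length(id) == length(cds))
  if (anyDuplicated(id)) stop("duplicated sequence ids")
  norm <- function(x) chartr("U", "T", toupper(x))
  out <- data.frame(id = as.character(id), cds = norm(cds),
                    upstream = rep_len(norm(upstream), length(id)),
                    downstream = rep_len(norm(downstream), length(id)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("orf_corpus", "data.frame")
  out
}

#' @export
print.orf_corpus <- function(x, ...) {
  cat("ORF corpus:", nrow(x), "sequences,",
      sum(nchar(x$cds)) %/% 3L, "codons\n")
  if (nrow(x)) {
    show <- utils::head(x, 4L)
    cat(sprintf("  %-12s %6d bp\n", show$id, nchar(show$cds)), sep = "")
    if (nrow(x) > 4L) cat("  ...\n")
  }
  invisible(x)
}

#' Read candidate ORFs from a FASTA file
#'
#' Reads plain or gzipped FASTA. Sequences are uppercased and U is mapped to
#' T, so RNA input is accepted. No structural validation is performed —
#' records are candidates for [filter_orfs()].
#'
#' @param path path to a FASTA file.
#' @param flanks optional flank table as returned by [read_flanks()]; matched
#'   by id, missing ids get empty flanks.
#' @return an [orf_corpus()].
#' @export
read_orf_fasta <- function(path, flanks = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && !startsWith(first, ">"))
    stop("malformed FASTA (", path, " line 1): expected '>' header, got: ",
         substr(first, 1, 40))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(orf_corpus(character(), character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  corp <- orf_corpus(ids, as.character(set))
  if (!is.null(flanks)) {
    i <- match(corp$id, flanks$id)
    hit <- !is.na(i)
    corp$upstream[hit] <- chartr("U", "T", toupper(flanks$upstream[i[hit]]))
    corp$downstream[hit] <- chartr("U", "T", toupper(flanks$downstream[i[hit]]))
  }
  corp
}

#' Read flanking sequences
#'
#' Two layouts are accepted: a FASTA file whose entries are named
#' `<id>|up` / `<id>|down`, or a headerless 3-column TSV
#' (id, upstream, downstream; `-` or empty for absent).
#'
#' @param path path to the flank file.
#' @param format `"auto"` (sniff the first byte), `"fasta"` or `"tsv"`.
#' @return data frame with columns `id`, `upstream`, `downstream`.
#' @export
read_flanks <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(first, ">")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    nm <- sub("\\s.*$", "", names(set))
    side <- sub("^.*\\|", "", nm)
    id <- sub("\\|(up|down)$", "", nm)
    if (!all(side %in% c("up", "down")))
      stop("flank FASTA entries must be named <id>|up or <id>|down")
    ids <- unique(id)
    out <- data.frame(id = ids, upstream = "", downstream = "",
                      stringsAsFactors = FALSE)
    up <- side == "up"
    out$upstream[match(id[up], ids)] <- as.character(set[up])
    out$downstream[match(id[!up], ids)] <- as.character(set[!up])
  } else {
    out <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("id", "upstream", "downstream"))
    out$upstream[is.na(out$upstream) | out$upstream == "-"] <- ""
    out$downstream[is.na(out$downstream) | out$downstream == "-"] <- ""
  }
  out
}

#' Read a homolog reference-length table
#'
#' Headerless two-column TSV: sequence id and the length (bp) of its best
#' homolog, standing in for a BLAST top-hit length.
#'
#' @param path path to the TSV.
#' @return named integer vector of lengths.
#' @export
read_homolog_lengths <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "length_bp"))
  stats::setNames(as.integer(tab$length_bp), tab$id)
}

#' Write a corpus to FASTA (with optional flank sidecar)
#'
#' @param corpus an [orf_corpus()].
#' @param path output FASTA path.
#' @param flank_path optional path for a 3-column flank TSV
#'   (id, upstream, downstream).
#' @return `path`, invisibly.
#' @export
write_corpus_fasta <- function(corpus, path, flank_path = NULL) {
  lines <- character(2L * nrow(corpus))
  lines[c(TRUE, FALSE)] <- paste0(">", corpus$id)
  lines[c(FALSE, TRUE)] <- corpus$cds
  writeLines(lines, path)
  if (!is.null(flank_path)) {
    utils::write.table(corpus[, c("id", "upstream", "downstream")],
                       flank_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
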