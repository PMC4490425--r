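# ORF structural validation, length/homology filtering, positional bin and
# start/stop context extraction.

REJECT_REASONS <- c("not-multiple-of-3", "no-start", "no-stop", "internal-stop",
                    "ambiguous-base", "too-short", "homolog-length-ratio")

# first failing rule in the fixed REJECT_REASONS order, or NA if valid
.orf_reject_reason <- function(cds, min_len_bp, homolog_len, ratio_bounds) {
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) return("not-multiple-of-3")
  if (substr(cds, 1L, 3L) != "ATG") return("no-start")
  if (!substr(cds, n - 2L, n) %in% STOP_CODONS) return("no-stop")
  codons <- .codon_split(cds)
  k <- length(codons)
  if (k > 2L && any(codons[2:(k - 1L)] %in% STOP_CODONS))
    return("internal-stop")
  if (grepl("[^ACGT]", cds)) return("ambiguous-base")
  if (n <= min_len_bp) return("too-short")
  if (!is.na(homolog_len)) {
    r <- n / homolog_len
    if (r < ratio_bounds[1L] || r > ratio_bounds[2L])
      return("homolog-length-ratio")
  }
  NA_character_
}

#' Validate and filter candidate ORFs
#'
#' A record is kept when its CDS length is a positive multiple of 3, it
#' begins with ATG and ends with a stop codon (TAA/TAG/TGA), carries no
#' in-frame internal stop and no character outside A/C/G/T, its length is
#' strictly greater than `min_len_bp`, and — when a homolog reference length
#' is supplied for its id — the length ratio lies within `ratio_bounds`
#' (inclusive). Each rejected record carries the first failing rule, checked
#' in the fixed order: not-multiple-of-3, no-start, no-stop, internal-stop,
#' ambiguous-base, too-short, homolog-length-ratio.
#'
#' @param corpus an [orf_corpus()] of candidates.
#' @param min_len_bp minimum CDS length in bp, exclusive (default 300:
#'   sequences of no more than 300 bp are dropped).
#' @param homolog_lengths optional named vector of reference lengths (bp),
#'   as from [read_homolog_lengths()]; ids without an entry skip the ratio
#'   rule.
#' @param ratio_bounds inclusive lower/upper bounds on length/homolog-length.
#' @return an object of class `orf_filter` with elements `kept`
#'   (an `orf_corpus`) and `rejected` (data frame of id, reason).
#' @examples
#' co <- orf_corpus(c("ok", "short"),
#'                  c(paste0("ATG", strrep("GAA", 100), "TAA"), "ATGTAA"))
#' filter_orfs(co)
#' @export
filter_orfs <- function(corpus, min_len_bp = 300,
                        homolog_lengths = NULL,
                        ratio_bounds = c(0.95, 1.05)) {
  stopifnot(inherits(corpus, "orf_corpus"), length(ratio_bounds) == 2L)
  hl <- rep(NA_real_, nrow(corpus))
  if (!is.null(homolog_lengths)) {
    i <- match(corpus$id, names(homolog_lengths))
    hl[!is.na(i)] <- as.numeric(homolog_lengths[i[!is.na(i)]])
  }
  reason <- vapply(seq_len(nrow(corpus)), function(i)
    .orf_reject_reason(corpus$cds[i], min_len_bp, hl[i], ratio_bounds),
    character(1))
  keep <- is.na(reason)
  kept <- corpus[keep, , drop = FALSE]
  class(kept) <- c("orf_corpus", "data.frame")
  rownames(kept) <- NULL
  out <- list(kept = kept,
              rejected = data.frame(id = corpus$id[!keep],
                                    reason = reason[!keep],
                                    stringsAsFactors = FALSE),
              params = list(min_len_bp = min_len_bp,
                            ratio_bounds = ratio_bounds))
  class(out) <- "orf_filter"
  out
}

#' @export
print.orf_filter <- function(x, ...) {
  cat("ORF filter:", nrow(x$kept), "kept,", nrow(x$rejected), "rejected\n")
  if (nrow(x$rejected)) {
    tab <- table(factor(x$rejected$reason, levels = REJECT_REASONS))
    tab <- tab[tab > 0]
    cat(sprintf("  %-22s %d\n", names(tab), as.integer(tab)), sep = "")
  }
  invisible(x)
}

#' Write a filter report as TSV
#'
#' One row per input record: id, verdict (`kept`/`rejected`) and reason.
#'
#' @param report an `orf_filter` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "orf_filter"))
  nk <- nrow(report$kept); nr <- nrow(report$rejected)
  df <- data.frame(id = c(report$kept$id, report$rejected$id),
                   verdict = rep(c("kept", "rejected"), c(nk, nr)),
                   reason = c(rep("", nk), report$rejected$reason),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

BIN_LABELS <- function(n_bins = 5L)
  c(paste0("bin_", seq_len(n_bins)), paste0("bin_-", rev(seq_len(n_bins))))

# 1-based codon indices (start codon = 1) covered by each bin of a gene with
# L codons including start and stop; NULL when the gene is too short for
# disjoint 5' and 3' bins
.bin_indices <- function(L, bin_size = 10L, n_bins = 5L) {
  need <- 2L + 2L * bin_size * n_bins
  if (L < need) return(NULL)
  five <- lapply(seq_len(n_bins), function(k)
    (2L + bin_size * (k - 1L)):(1L + bin_size * k))
  three <- lapply(rev(seq_len(n_bins)), function(k)
    (L - bin_size * k):(L - 1L - bin_size * (k - 1L)))
  stats::setNames(c(five, three), BIN_LABELS(n_bins))
}

#' Extract positional codon bins
#'
#' Slices each sufficiently long gene into `n_bins` bins of `bin_size` codons
#' following the start codon (bin_1 ... bin_5, start codon excluded) and
#' `n_bins` bins counting back from the codon before the stop
#' (bin_-5 ... bin_-1, stop excluded), and pools the codons of each bin over
#' the corpus. Genes shorter than `2 + 2 * bin_size * n_bins` codons
#' (including start and stop) would have overlapping 5' and 3' bins and are
#' excluded.
#'
#' @param corpus a validated [orf_corpus()].
#' @param bin_size codons per bin (default 10).
#' @param n_bins bins per end (default 5).
#' @return list with `bins` (named list of pooled codon vectors in the order
#'   bin_1..bin_n, bin_-n..bin_-1), `admitted` and `excluded` (id vectors).
#' @export
extract_bins <- function(corpus, bin_size = 10, n_bins = 5) {
  stopifnot(inherits(corpus, "orf_corpus"))
  codons <- .corpus_codons(corpus)
  L <- lengths(codons)
  labels <- BIN_LABELS(n_bins)
  ok <- L >= 2L + 2L * bin_size * n_bins
  bins <- stats::setNames(vector("list", length(labels)), labels)
  for (lab in labels) bins[[lab]] <- vector("list", sum(ok))
  j <- 0L
  for (g in which(ok)) {
    j <- j + 1L
    gi <- .bin_indices(L[g], bin_size, n_bins)
    for (lab in labels) bins[[lab]][[j]] <- codons[[g]][gi[[lab]]]
  }
  bins <- lapply(bins, function(x) unlist(x, use.names = FALSE))
  if (any(!ok))
    message(sum(!ok), " gene(s) too short for positional bins; excluded")
  list(bins = bins, admitted = corpus$id[ok], excluded = corpus$id[!ok],
       bin_size = bin_size, n_bins = n_bins)
}

#' Extract 18-nt start/stop context windows
#'
#' For the start anchor the window is the last 9 upstream-flank nucleotides,
#' the ATG, and the first 6 CDS nucleotides after it. For the stop anchor it
#' is the last 9 coding nucleotides before the stop codon, the stop codon,
#' and the first 6 downstream-flank nucleotides. Positions 10-12 therefore
#' always hold the anchor codon. Records with insufficient flank (or, for
#' the stop anchor, fewer than 4 codons) are skipped and counted.
#'
#' @param corpus a validated [orf_corpus()] with flanks.
#' @param anchor `"start"` or `"stop"`.
#' @return data frame (gene_id, anchor, window) with attribute `n_skipped`.
#' @export
extract_context <- function(corpus, anchor = c("start", "stop")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(corpus, "orf_corpus"))
  n <- nchar(corpus$cds)
  if (anchor == "start") {
    ok <- nchar(corpus$upstream) >= 9L & n >= 9L
    win <- paste0(substr(corpus$upstream, nchar(corpus$upstream) - 8L,
                         nchar(corpus$upstream)),
                  substr(corpus$cds, 1L, 9L))
  } else {
    ok <- nchar(corpus$downstream) >= 6L & n >= 12L
    win <- paste0(substr(corpus$cds, n - 11L, n),
                  substr(corpus$downstream, 1L, 6L))
  }
  out <- data.frame(gene_id = corpus$id[ok],
                    anchor = rep_len(anchor, sum(ok)),
                    window = win[ok], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!ok)
  out
}
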