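# Corpus- and gene-level codon usage: counts, per-mille frequencies, RSCU,
# within-family shares q, GC partition, SCUO and codon classification.

# named integer vector over the 64 codons
.tabulate_codons <- function(codons) {
  tab <- tabulate(match(codons, ALL_CODONS), nbins = 64L)
  stats::setNames(tab, ALL_CODONS)
}

# RSCU over degenerate sense families plus the stop family; NA for Met/Trp.
# q: within-family share for every sense family and the stop family.
.rscu_from_counts <- function(counts) {
  rscu <- q <- stats::setNames(rep(NA_real_, 64L), ALL_CODONS)
  fams <- c(AA_FAMILIES, list(`*` = STOP_CODONS))
  for (fam in fams) {
    tot <- sum(counts[fam])
    if (tot == 0) next
    q[fam] <- counts[fam] / tot
    if (length(fam) >= 2L) rscu[fam] <- counts[fam] / (tot / length(fam))
  }
  q[c("ATG", "TGG")] <- ifelse(counts[c("ATG", "TGG")] > 0, 1, NA_real_)
  list(rscu = rscu, q = q)
}

#' Count codons and derive usage statistics
#'
#' Counts every in-frame codon of every gene. Start-ATG and stop positions
#' are included by default (corpus-level accounting covers the whole ORF);
#' RSCU is reported for the 59 degenerate sense codons and, separately, for
#' the 3-codon stop family, and is `NA` for ATG (Met) and TGG (Trp).
#' Per-mille frequencies are over all counted codons.
#'
#' @param corpus a validated [orf_corpus()].
#' @param include_start,include_stop count the first/last codon of each gene?
#' @return object of class `codon_usage`: list with `counts` (named integer,
#'   64), `total_codons`, `freq_permille`, `rscu`, `q` (within-family
#'   share), `n_orfs`.
#' @examples
#' cu <- count_codons(orf_corpus("g", "ATGGAGGAGGAGGAATAA"))
#' cu$rscu[c("GAG", "GAA")]   # 1.5, 0.5
#' @export
count_codons <- function(corpus, include_start = TRUE, include_stop = TRUE) {
  stopifnot(inherits(corpus, "orf_corpus"), nrow(corpus) > 0L)
  genes <- .corpus_codons(corpus)
  if (!include_start) genes <- lapply(genes, function(v) v[-1L])
  if (!include_stop) genes <- lapply(genes, function(v) v[-length(v)])
  counts <- .tabulate_codons(unlist(genes, use.names = FALSE))
  total <- sum(counts)
  der <- .rscu_from_counts(counts)
  out <- list(counts = counts, total_codons = total,
              freq_permille = 1000 * counts / total,
              rscu = der$rscu, q = der$q, n_orfs = nrow(corpus),
              include_start = include_start, include_stop = include_stop)
  class(out) <- "codon_usage"
  out
}

#' @export
print.codon_usage <- function(x, digits = 3, ...) {
  cat("Codon usage:", x$n_orfs, "ORFs,", x$total_codons, "codons\n")
  top <- sort(x$freq_permille[SENSE_CODONS], decreasing = TRUE)[1:5]
  cat("  top codons (permille):",
      paste(sprintf("%s=%.1f", as_rna(names(top)), top), collapse = " "), "\n")
  hi <- classify_high_frequency(x)
  if (length(hi)) cat("  high-frequency:", paste(as_rna(hi), collapse = " "), "\n")
  invisible(x)
}

#' GC content by codon position
#'
#' Fractions of G+C overall and at codon positions 1-3, plus the A+T
#' fraction at position 3, computed over the same codon set as `usage`.
#'
#' @param x a `codon_usage` object or an [orf_corpus()].
#' @param ... passed to [count_codons()] when `x` is a corpus.
#' @return named list `gc`, `gc1`, `gc2`, `gc3`, `au3`, each in `[0, 1]`.
#' @export
gc_partition <- function(x, ...) {
  cu <- if (inherits(x, "codon_usage")) x else count_codons(x, ...)
  counts <- cu$counts
  posfrac <- function(p, bases) {
    sum(counts[substr(ALL_CODONS, p, p) %in% bases]) / cu$total_codons
  }
  gc1 <- posfrac(1L, c("G", "C")); gc2 <- posfrac(2L, c("G", "C"))
  gc3 <- posfrac(3L, c("G", "C"))
  list(gc = (gc1 + gc2 + gc3) / 3, gc1 = gc1, gc2 = gc2, gc3 = gc3,
       au3 = posfrac(3L, c("A", "T")))
}

#' Per-gene GC3 values
#'
#' @param corpus a validated [orf_corpus()].
#' @return named numeric vector, fraction of G/C at codon position 3 of each
#'   gene (whole ORF including start and stop codons).
#' @export
gene_gc3 <- function(corpus) {
  stopifnot(inherits(corpus, "orf_corpus"))
  v <- vapply(corpus$cds, function(s) {
    n <- nchar(s)
    ch <- substring(s, seq.int(3L, n, 3L), seq.int(3L, n, 3L))
    mean(ch %in% c("G", "C"))
  }, numeric(1))
  stats::setNames(v, corpus$id)
}

# SCUO from a 64-codon count vector; NA when no degenerate family occurs
.scuo_from_counts <- function(counts) {
  fams <- AA_FAMILIES[FAMILY_SIZE >= 2L]
  ftot <- vapply(fams, function(f) sum(counts[f]), numeric(1))
  occ <- ftot > 0
  if (!any(occ)) return(NA_real_)
  o <- vapply(fams[occ], function(f) {
    q <- counts[f] / sum(counts[f])
    q <- q[q > 0]
    h <- -sum(q * log2(q))
    (log2(length(f)) - h) / log2(length(f))
  }, numeric(1))
  sum(ftot[occ] / sum(ftot[occ]) * o)
}

#' Synonymous codon usage order (SCUO)
#'
#' Entropy-based bias index in `[0, 1]`: 0 for uniform synonymous usage, 1
#' when every degenerate family uses a single codon. For each occurring
#' degenerate family i with degeneracy S_i and within-family shares q_ij,
#' O_i = (log2 S_i - H_i)/log2 S_i with H_i the Shannon entropy, and SCUO is
#' the codon-count-weighted mean of O_i over degenerate families. Met, Trp
#' and stop codons do not contribute.
#'
#' @param x a `codon_usage` object, an [orf_corpus()], or a single CDS
#'   string.
#' @return SCUO value, or `NA` (with a warning) if no degenerate amino acid
#'   occurs.
#' @export
scuo <- function(x) {
  counts <- if (inherits(x, "codon_usage")) x$counts
  else if (inherits(x, "orf_corpus")) count_codons(x)$counts
  else if (is.character(x) && length(x) == 1L) .tabulate_codons(.codon_split(x))
  else stop("cannot compute SCUO from ", class(x)[1])
  out <- .scuo_from_counts(counts)
  if (is.na(out)) warning("no degenerate amino acid observed; SCUO undefined")
  out
}

#' Per-gene SCUO values
#'
#' @param corpus a validated [orf_corpus()].
#' @return named numeric vector (NA for genes without degenerate families).
#' @export
gene_scuo <- function(corpus) {
  stopifnot(inherits(corpus, "orf_corpus"))
  v <- vapply(corpus$cds,
              function(s) .scuo_from_counts(.tabulate_codons(.codon_split(s))),
              numeric(1))
  stats::setNames(v, corpus$id)
}

#' High-frequency codons
#'
#' Degenerate sense codons with RSCU above `rscu_cutoff` or within-family
#' relative frequency above `share_cutoff`.
#'
#' @param usage a `codon_usage` object.
#' @param rscu_cutoff RSCU threshold (default 1.5).
#' @param share_cutoff within-family share threshold (default 0.60).
#' @return character vector of codons (DNA alphabet), sorted.
#' @export
classify_high_frequency <- function(usage, rscu_cutoff = 1.5,
                                    share_cutoff = 0.60) {
  stopifnot(inherits(usage, "codon_usage"))
  cand <- DEGENERATE_CODONS
  hit <- (!is.na(usage$rscu[cand]) & usage$rscu[cand] > rscu_cutoff) |
    (!is.na(usage$q[cand]) & usage$q[cand] > share_cutoff)
  sort(cand[hit])
}

#' Most abundant and most rare sense codons
#'
#' Top-k and bottom-k sense codons by per-mille frequency; stop codons are
#' excluded; ties are broken lexicographically so the split is deterministic.
#'
#' @param usage a `codon_usage` object.
#' @param k set size (default 15).
#' @return list with character vectors `abundant` and `rare`.
#' @export
abundant_rare_sets <- function(usage, k = 15) {
  stopifnot(inherits(usage, "codon_usage"), 2 * k <= length(SENSE_CODONS))
  f <- usage$freq_permille[SENSE_CODONS]
  # at a frequency tie on the set boundary the lexicographically smaller
  # codon is included, in both sets
  list(abundant = names(f)[order(-f, names(f))][seq_len(k)],
       rare = names(f)[order(f, names(f))][seq_len(k)])
}

#' NCG:NCC ratio (CpG suppression index)
#'
#' Total count of ACG/CCG/GCG/TCG codons over that of ACC/CCC/GCC/TCC; low
#' values indicate CpG suppression as expected under cytosine methylation.
#'
#' @param usage a `codon_usage` object.
#' @return the ratio, or an error when no NCC codon was observed.
#' @export
ncg_ncc_ratio <- function(usage) {
  stopifnot(inherits(usage, "codon_usage"))
  ncg <- sum(usage$counts[paste0(DNA_BASES, "CG")])
  ncc <- sum(usage$counts[paste0(DNA_BASES, "CC")])
  if (ncc == 0) stop("NCG:NCC undefined: no NCC codons observed")
  ncg / ncc
}

#' Write a codon usage table as TSV
#'
#' Columns: codon (RNA alphabet), amino acid, count, permille frequency,
#' RSCU (empty for Met/Trp).
#'
#' @param usage a `codon_usage` object.
#' @param path output path.
#' @param header optional comment lines to prepend (each prefixed `#`).
#' @return `path`, invisibly.
#' @export
write_usage_table <- function(usage, path, header = NULL) {
  df <- data.frame(codon = as_rna(ALL_CODONS),
                   aa = unname(CODON_AA),
                   count = unname(usage$counts),
                   permille = round(unname(usage$freq_permille), 4),
                   rscu = round(unname(usage$rscu), 4))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
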