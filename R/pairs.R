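# Codon-pair counting at junction distances 0-5, RSCPU, high-frequency pair
# classification and junction-dinucleotide profiles. The pair universe is the
# 61 x 61 ordered sense-codon pairs; pairs are taken within the interior
# codons of each gene (start and stop excluded), never across genes.

#' Count ordered codon pairs at a junction distance
#'
#' Counts pairs `(c_i, c_{i+1+d})` over the interior codons (start and stop
#' codons excluded) of each gene; `d` is the number of intervening codons
#' (0 = neighboring). Expected pair frequencies are the products of the
#' single-codon frequencies estimated from the same interior codons over the
#' 61 sense codons.
#'
#' @param corpus a validated [orf_corpus()].
#' @param distance number of intervening codons, 0 to 5.
#' @return object of class `pair_table`: list with `distance`, `counts`
#'   (61 x 61 integer matrix, rows = first codon), `total_pairs`,
#'   `obs_freq`, `exp_freq`, `codon_freq` (interior single-codon
#'   frequencies), `n_interior_codons`.
#' @export
count_pairs <- function(corpus, distance = 0) {
  stopifnot(inherits(corpus, "orf_corpus"))
  d <- as.integer(distance)
  if (d < 0L || d > 5L) stop("distance must be in 0..5")
  genes <- .corpus_codons(corpus)
  interior <- lapply(genes, function(v) v[-c(1L, length(v))])
  single <- .tabulate_codons(unlist(interior, use.names = FALSE))[SENSE_CODONS]
  idx <- lapply(interior, function(v) {
    n <- length(v)
    if (n < 2L + d) return(integer())
    i <- match(v, SENSE_CODONS)
    first <- i[seq_len(n - 1L - d)]
    second <- i[seq.int(2L + d, n)]
    keep <- !is.na(first) & !is.na(second)
    (first[keep] - 1L) * 61L + second[keep]
  })
  tab <- tabulate(unlist(idx, use.names = FALSE), nbins = 61L * 61L)
  counts <- matrix(as.integer(tab), nrow = 61L, byrow = TRUE,
                   dimnames = list(SENSE_CODONS, SENSE_CODONS))
  total <- sum(counts)
  cf <- single / sum(single)
  out <- list(distance = d, counts = counts, total_pairs = total,
              obs_freq = counts / total, exp_freq = outer(cf, cf),
              codon_freq = cf,
              n_interior_codons = sum(lengths(interior)))
  class(out) <- "pair_table"
  out
}

#' @export
print.pair_table <- function(x, ...) {
  cat("Codon-pair table: distance", x$distance, "(",
      x$total_pairs, "pairs from", x$n_interior_codons, "interior codons )\n")
  invisible(x)
}

# the 4 ordered pairs of single-codon (Met/Trp) families
MET_TRP_PAIRS <- as.vector(outer(c("ATG", "TGG"), c("ATG", "TGG"), paste0))

#' Relative synonymous codon pair usage (RSCPU)
#'
#' For a neighboring-pair (`distance = 0`) table: every ordered codon pair
#' belongs to an amino-acid-pair family; the expected count of a pair in
#' family F with first/second degeneracies S_a, S_b is `N(F) / (S_a * S_b)`
#' and RSCPU is observed over expected. The four pairs whose two codons both
#' come from single-codon families (MetMet, MetTrp, TrpMet, TrpTrp) carry no
#' synonymous choice and are excluded; families never observed are absent
#' from the result.
#'
#' @param pair_table a `pair_table` with `distance == 0`.
#' @return data frame: pair (12-letter codon pair), aa_pair, obs, expected,
#'   rscpu, family_share (pair count over its aa-pair family count).
#' @export
rscpu <- function(pair_table) {
  stopifnot(inherits(pair_table, "pair_table"))
  if (pair_table$distance != 0L)
    stop("RSCPU is defined for neighboring pairs (distance 0)")
  cn <- SENSE_CODONS
  pair <- as.vector(outer(cn, cn, function(a, b) paste0(a, b)))
  first <- rep(cn, times = 61L); second <- rep(cn, each = 61L)
  obs <- pair_table$counts[cbind(first, second)]
  aa_pair <- paste0(CODON_AA[first], CODON_AA[second])
  keep <- !pair %in% MET_TRP_PAIRS
  df <- data.frame(pair = pair[keep], aa_pair = aa_pair[keep],
                   first = first[keep], second = second[keep],
                   obs = obs[keep], stringsAsFactors = FALSE)
  fam_tot <- tapply(df$obs, df$aa_pair, sum)
  df <- df[fam_tot[df$aa_pair] > 0, , drop = FALSE]
  deg <- FAMILY_SIZE[CODON_AA[df$first]] * FAMILY_SIZE[CODON_AA[df$second]]
  df$expected <- as.numeric(fam_tot[df$aa_pair]) / deg
  df$rscpu <- df$obs / df$expected
  df$family_share <- df$obs / as.numeric(fam_tot[df$aa_pair])
  df$first <- df$second <- NULL
  rownames(df) <- NULL
  df
}

#' High-frequency codon pairs
#'
#' Pairs with RSCPU above `rscpu_cutoff` or within-family share above
#' `share_cutoff`.
#'
#' @param rscpu_table result of [rscpu()].
#' @param rscpu_cutoff RSCPU threshold (default 1.5).
#' @param share_cutoff family-share threshold (default 0.60).
#' @return subset of `rscpu_table`, ordered by decreasing RSCPU.
#' @export
classify_high_frequency_pairs <- function(rscpu_table, rscpu_cutoff = 1.5,
                                          share_cutoff = 0.60) {
  hit <- rscpu_table$rscpu > rscpu_cutoff |
    rscpu_table$family_share > share_cutoff
  out <- rscpu_table[hit, , drop = FALSE]
  out[order(-out$rscpu, out$pair), , drop = FALSE]
}

#' Preferred/avoided codon-pair calls
#'
#' Applies [call_bias()] to the 3721 pair counts against the product-of-
#' frequencies expectation of the table.
#'
#' @param pair_table a `pair_table`.
#' @param ... thresholds passed to [call_bias()].
#' @return a `bias_calls` data frame (items are 12-letter codon pairs).
#' @export
call_pair_bias <- function(pair_table, ...) {
  stopifnot(inherits(pair_table, "pair_table"))
  obs <- as.vector(pair_table$counts)
  ef <- as.vector(pair_table$exp_freq)
  nm <- as.vector(outer(rownames(pair_table$counts),
                        colnames(pair_table$counts),
                        function(a, b) paste0(a, b)))
  call_bias(stats::setNames(obs, nm), stats::setNames(ef, nm),
            n = pair_table$total_pairs, ...)
}

#' Junction-dinucleotide profile of neighboring pairs
#'
#' Groups the 61 x 61 pairs by the dinucleotide spanning the junction (third
#' nucleotide of the first codon, first nucleotide of the second) and
#' summarises the observed/expected frequency ratios per group.
#'
#' @param pair_table a `pair_table` with `distance == 0`.
#' @return data frame: junction (16 dinucleotides), n_pairs, q1, median, q3
#'   of the obs/exp ratio (pairs with zero expectation are skipped).
#' @export
junction_profile <- function(pair_table) {
  stopifnot(inherits(pair_table, "pair_table"))
  if (pair_table$distance != 0L)
    stop("junction profile is defined for neighboring pairs (distance 0)")
  first <- rep(SENSE_CODONS, times = 61L)
  second <- rep(SENSE_CODONS, each = 61L)
  junction <- paste0(substr(first, 3L, 3L), substr(second, 1L, 1L))
  ratio <- pair_table$obs_freq[cbind(first, second)] /
    pair_table$exp_freq[cbind(first, second)]
  ok <- is.finite(ratio)
  qs <- tapply(ratio[ok], junction[ok], stats::quantile,
               probs = c(0.25, 0.5, 0.75), names = FALSE)
  jn <- sort(names(qs))
  data.frame(junction = jn,
             n_pairs = as.integer(table(junction[ok])[jn]),
             q1 = vapply(qs[jn], `[`, numeric(1), 1L),
             median = vapply(qs[jn], `[`, numeric(1), 2L),
             q3 = vapply(qs[jn], `[`, numeric(1), 3L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write pair bias calls as TSV
#'
#' @param calls a `bias_calls` data frame from [call_pair_bias()].
#' @param path output path.
#' @param header optional comment lines (prefixed `#`).
#' @return `path`, invisibly.
#' @export
write_pair_calls <- function(calls, path, header = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
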