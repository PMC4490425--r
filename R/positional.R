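# Position-dependent codon bias: binned Kullback-Leibler divergence against
# the corpus-wide within-family usage, with a synonymous-shuffle (SSC) null
# baseline; post-AUG codon bias; start/stop context information matrices;
# AU3 profiles over the first codons.

#' Kullback-Leibler divergence of a codon sample from background usage
#'
#' Natural-log KL divergence of the within-family codon frequencies of a
#' codon sample from background within-family frequencies `q`, summed over
#' amino-acid families present in the sample:
#' `sum_i sum_j p_ij log(p_ij / q_ij)`. Codons with `p_ij = 0` contribute 0
#' (the limit x log x -> 0); families absent from the sample contribute 0.
#'
#' @param codons character vector of codons, or a named 64-count vector.
#' @param q named within-family background frequencies over codons, as in
#'   the `q` element of [count_codons()].
#' @return non-negative KLD value (nats).
#' @examples
#' q <- c(GAA = 0.5, GAG = 0.5)
#' codon_kld(rep("GAA", 5), q)   # log(2)
#' @export
codon_kld <- function(codons, q) {
  counts <- if (is.character(codons)) .tabulate_codons(codons) else codons
  kld <- 0
  for (fam in AA_FAMILIES) {
    tot <- sum(counts[fam])
    if (tot == 0) next
    p <- counts[fam] / tot
    j <- p > 0
    if (any(is.na(q[fam][j])) || any(q[fam][j] == 0))
      stop("background q is zero for a codon observed in the sample")
    kld <- kld + sum(p[j] * log(p[j] / q[fam][j]))
  }
  kld
}

#' Positional KLD profile with SSC null baseline
#'
#' Computes the per-bin KLD of positional codon usage from the corpus-wide
#' within-family usage q, then estimates the finite-sample bias of the
#' statistic by recomputing it on `ssc_replicates` synonymous-codon-shuffled
#' (SSC) corpora, which preserve every protein sequence and the corpus codon
#' counts while destroying positional structure. The corrected KLD is the
#' raw value minus the null mean.
#'
#' @param corpus a validated [orf_corpus()].
#' @param bin_size,n_bins bin layout passed to [extract_bins()].
#' @param ssc_replicates number of SSC shuffles for the null baseline
#'   (default 100).
#' @param seed optional RNG seed for the shuffles.
#' @return object of class `kld_profile`: data frame with columns `bin`,
#'   `kld_raw`, `null_mean`, `null_sd`, `kld_corrected`; attributes
#'   `n_genes` (admitted to positional analysis) and `ssc_replicates`.
#' @export
kld_profile <- function(corpus, bin_size = 10, n_bins = 5,
                        ssc_replicates = 100, seed = NULL) {
  stopifnot(inherits(corpus, "orf_corpus"))
  if (!is.null(seed)) set.seed(seed)
  q <- count_codons(corpus, include_start = FALSE, include_stop = FALSE)$q
  bins <- extract_bins(corpus, bin_size = bin_size, n_bins = n_bins)
  if (length(bins$admitted) == 0L) stop("no gene long enough for positional bins")
  raw <- vapply(bins$bins, codon_kld, numeric(1), q = q)
  null <- matrix(NA_real_, nrow = ssc_replicates, ncol = length(raw),
                 dimnames = list(NULL, names(raw)))
  for (r in seq_len(ssc_replicates)) {
    shuf <- ssc_shuffle(corpus)
    sb <- suppressMessages(extract_bins(shuf, bin_size = bin_size,
                                        n_bins = n_bins))
    null[r, ] <- vapply(sb$bins, codon_kld, numeric(1), q = q)
  }
  out <- data.frame(bin = names(raw), kld_raw = unname(raw),
                    null_mean = colMeans(null),
                    null_sd = apply(null, 2L, stats::sd),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$kld_corrected <- out$kld_raw - out$null_mean
  class(out) <- c("kld_profile", "data.frame")
  attr(out, "n_genes") <- length(bins$admitted)
  attr(out, "ssc_replicates") <- ssc_replicates
  out
}

#' @export
print.kld_profile <- function(x, ...) {
  cat("Positional KLD profile (", attr(x, "n_genes"), "genes,",
      attr(x, "ssc_replicates"), "SSC replicates )\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# the 12 positional-nucleotide masks: base at codon position 1, 2 or 3
.codon_masks <- function() {
  m <- expand.grid(base = DNA_BASES, pos = 1:3, stringsAsFactors = FALSE)
  m$label <- vapply(seq_len(nrow(m)), function(i) {
    s <- c("n", "n", "n"); s[m$pos[i]] <- m$base[i]; paste(s, collapse = "")
  }, character(1))
  m
}

#' Codon bias at the position following start or internal AUG codons
#'
#' Tallies the sense codon immediately following the start codon
#' (`anchor = "start"`) or each internal (non-start) ATG whose following
#' codon is not the gene's stop (`anchor = "internal"`), tests each codon
#' against the corpus-wide interior frequencies with [call_bias()], and
#' aggregates observed/expected counts over the 12 positional-nucleotide
#' masks (base at codon position 1, 2 or 3: `Ann`, `nAn`, `nnA`, ...).
#'
#' @param corpus a validated [orf_corpus()].
#' @param anchor `"start"` or `"internal"`.
#' @param ... thresholds passed to [call_bias()].
#' @return list with `calls` (a `bias_calls` data frame over the 61 sense
#'   codons, DNA alphabet) and `masks` (data frame: mask, obs, exp, ratio).
#' @export
post_aug_bias <- function(corpus, anchor = c("start", "internal"), ...) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(corpus, "orf_corpus"))
  genes <- .corpus_codons(corpus)
  following <- unlist(lapply(genes, function(v) {
    n <- length(v)
    if (anchor == "start") {
      if (n >= 3L) v[2L] else character()
    } else {
      at <- which(v == "ATG")
      at <- at[at > 1L & at < n - 1L]   # internal, and not followed by stop
      v[at + 1L]
    }
  }), use.names = FALSE)
  following <- following[following %in% SENSE_CODONS]
  if (length(following) == 0L) stop("no qualifying anchor position in corpus")
  obs <- .tabulate_codons(following)[SENSE_CODONS]
  interior <- unlist(lapply(genes, function(v) v[-c(1L, length(v))]),
                     use.names = FALSE)
  ef <- .tabulate_codons(interior)[SENSE_CODONS]
  ef <- ef / sum(ef)
  calls <- call_bias(obs, ef, n = sum(obs), ...)
  masks <- .codon_masks()
  exp_counts <- sum(obs) * ef
  mobs <- mexp <- numeric(nrow(masks))
  for (i in seq_len(nrow(masks))) {
    hit <- substr(SENSE_CODONS, masks$pos[i], masks$pos[i]) == masks$base[i]
    mobs[i] <- sum(obs[hit]); mexp[i] <- sum(exp_counts[hit])
  }
  list(calls = calls,
       masks = data.frame(mask = chartr("T", "U", masks$label),
                          obs = mobs, exp = mexp, ratio = mobs / mexp,
                          stringsAsFactors = FALSE))
}

#' Sequence-logo information matrix for context windows
#'
#' Per-position Shannon information content in bits with the WebLogo-style
#' small-sample correction: `R = 2 - (H + e_n)` where H is the entropy of
#' the A/C/G/T frequencies at the position and `e_n = 3 / (2 ln2 n)`;
#' negative corrected values are clamped to 0. Letter heights are the
#' nucleotide frequencies scaled by R. The anchor-codon positions (10-12 of
#' the 18-nt window) are dropped from the output.
#'
#' @param windows character vector of equal-length windows, or the data
#'   frame returned by [extract_context()].
#' @param anchor_positions positions to drop (default 10:12; `NULL` keeps
#'   all).
#' @return object of class `logo_matrix`: data frame with `position`,
#'   letter-height columns `A`, `C`, `G`, `U`, and `info_bits`.
#' @export
logo_matrix <- function(windows, anchor_positions = 10:12) {
  if (is.data.frame(windows)) windows <- windows$window
  if (length(windows) == 0L) stop("no context windows supplied")
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1L) stop("windows must have equal length")
  n <- length(windows)
  en <- 3 / (2 * log(2) * n)
  keep <- setdiff(seq_len(wlen), anchor_positions)
  rows <- lapply(keep, function(p) {
    ch <- substring(windows, p, p)
    f <- tabulate(match(ch, DNA_BASES), nbins = 4L) / n
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    r <- max(0, 2 - h - en)
    data.frame(position = p, A = f[1] * r, C = f[2] * r, G = f[3] * r,
               U = f[4] * r, info_bits = r)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("logo_matrix", "data.frame")
  attr(out, "n_windows") <- n
  out
}

#' AU3 fraction over the first codons
#'
#' Fraction of codons with A or T at the third position, per codon index
#' (2 .. `first_k_codons` + 1, the codons following the start), with the
#' corpus-wide AU3 fraction as baseline.
#'
#' @param corpus a validated [orf_corpus()].
#' @param first_k_codons how many post-start codons to profile (default 10).
#' @return data frame (codon_index, au3, n) with attribute `baseline`.
#' @export
au3_profile <- function(corpus, first_k_codons = 10) {
  stopifnot(inherits(corpus, "orf_corpus"))
  genes <- .corpus_codons(corpus)
  baseline <- gc_partition(count_codons(corpus))$au3
  rows <- lapply(seq.int(2L, first_k_codons + 1L), function(j) {
    cods <- unlist(lapply(genes, function(v)
      if (length(v) - 1L >= j) v[j] else character()), use.names = FALSE)
    data.frame(codon_index = j,
               au3 = mean(substr(cods, 3L, 3L) %in% c("A", "T")),
               n = length(cods))
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- baseline
  out
}
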