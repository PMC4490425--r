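# Mono-, di- and tri-nucleotide composition, CpG/CWG relative abundance,
# GC3 stratification and the SCUO ~ GC3 polynomial fit.

.window_freq <- function(seqs, width) {
  counts <- integer(0)
  words <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < width) return(character())
    substring(s, seq_len(n - width + 1L), seq.int(width, n))
  }), use.names = FALSE)
  alphabet <- DNA_BASES
  for (w in seq_len(width - 1L))
    alphabet <- as.vector(outer(alphabet, DNA_BASES, paste0))
  alphabet <- sort(alphabet)
  f <- tabulate(match(words, alphabet), nbins = length(alphabet))
  stats::setNames(f / sum(f), alphabet)
}

#' Dinucleotide and trinucleotide relative abundance
#'
#' Mono-, di- and tri-nucleotide frequencies from overlapping windows within
#' each sequence (windows never span sequence boundaries), and the
#' methylation-related odds ratios
#' `rho_CG = f_CG / (f_C f_G)` and
#' `rho_CWG = f_CWG f_C f_W f_G / (f_CW f_WG f_CNG)`
#' with `W` = A or T, `f_W = f_A + f_T`, `f_CW = f_CA + f_CT`,
#' `f_WG = f_AG + f_TG`, `f_CWG = f_CAG + f_CTG` and `f_CNG` the sum of
#' `f_CAG, f_CCG, f_CGG, f_CTG`. A rho is `NA` (with a warning) when its
#' denominator is zero.
#'
#' @param seqs character vector of DNA sequences, or an [orf_corpus()]
#'   (its CDS strings are used).
#' @return object of class `composition_stats`: list with `f_nt`, `f_di`,
#'   `f_tri`, `rho_cg`, `rho_cwg`.
#' @examples
#' relative_abundance("CGCGCG")$rho_cg   # 2.4
#' @export
relative_abundance <- function(seqs) {
  if (inherits(seqs, "orf_corpus")) seqs <- seqs$cds
  stopifnot(is.character(seqs))
  if (sum(nchar(seqs)) < 3L) stop("need at least 3 nucleotides")
  f1 <- .window_freq(seqs, 1L)
  f2 <- .window_freq(seqs, 2L)
  f3 <- .window_freq(seqs, 3L)
  den_cg <- f1[["C"]] * f1[["G"]]
  rho_cg <- if (den_cg > 0) f2[["CG"]] / den_cg else {
    warning("rho_CG undefined: zero C or G frequency"); NA_real_
  }
  f_w <- f1[["A"]] + f1[["T"]]
  f_cw <- f2[["CA"]] + f2[["CT"]]
  f_wg <- f2[["AG"]] + f2[["TG"]]
  f_cwg <- f3[["CAG"]] + f3[["CTG"]]
  f_cng <- sum(f3[paste0("C", DNA_BASES, "G")])
  den_cwg <- f_cw * f_wg * f_cng
  rho_cwg <- if (den_cwg > 0)
    f_cwg * f1[["C"]] * f_w * f1[["G"]] / den_cwg else {
      warning("rho_CWG undefined: zero denominator (no CNG/CW/WG windows)")
      NA_real_
    }
  out <- list(f_nt = f1, f_di = f2, f_tri = f3,
              rho_cg = unname(rho_cg), rho_cwg = unname(rho_cwg))
  class(out) <- "composition_stats"
  out
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("Composition: GC %.3f, rho_CG %.3f, rho_CWG %.3f\n",
              x$f_nt[["C"]] + x$f_nt[["G"]], x$rho_cg, x$rho_cwg))
  invisible(x)
}

#' Split genes into GC3 terciles (or other strata)
#'
#' Sorts genes by GC3 (ties broken by id for determinism) and splits them
#' into `n_strata` contiguous groups of near-equal size (sizes differ by at
#' most 1; remainders go to the middle stratum first, then outward from the
#' low end).
#'
#' @param gc3 named numeric vector of per-gene GC3 values (see
#'   [gene_gc3()]).
#' @param n_strata number of strata (default 3).
#' @return a list of id vectors, lowest to highest GC3; for the default 3
#'   strata the names are `low`, `mid`, `high`.
#' @export
gc3_strata <- function(gc3, n_strata = 3) {
  n <- length(gc3)
  if (n < n_strata) stop("need at least ", n_strata, " genes")
  if (is.null(names(gc3))) names(gc3) <- as.character(seq_along(gc3))
  ord <- order(gc3, names(gc3))
  sizes <- rep(n %/% n_strata, n_strata)
  extra <- n %% n_strata
  if (extra > 0) {
    pri <- order(abs(seq_len(n_strata) - (n_strata + 1) / 2),
                 seq_len(n_strata))       # middle first, then low side
    sizes[pri[seq_len(extra)]] <- sizes[pri[seq_len(extra)]] + 1L
  }
  idx <- split(names(gc3)[ord], rep(seq_len(n_strata), times = sizes))
  names(idx) <- if (n_strata == 3) c("low", "mid", "high")
  else paste0("stratum_", seq_len(n_strata))
  idx
}

#' Per-stratum relative abundance with bootstrap intervals
#'
#' Pools the sequences of each GC3 stratum, computes `rho_CG` and `rho_CWG`,
#' and attaches percentile bootstrap confidence intervals from gene-level
#' resampling.
#'
#' @param corpus a validated [orf_corpus()].
#' @param groups list of id vectors from [gc3_strata()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed optional RNG seed.
#' @return data frame: group, n_genes, rho_cg with CI, rho_cwg with CI.
#' @export
strata_composition_contrast <- function(corpus, groups, n_boot = 1000,
                                        conf = 0.95, seed = NULL) {
  stopifnot(inherits(corpus, "orf_corpus"))
  if (!is.null(seed)) set.seed(seed)
  a <- (1 - conf) / 2
  rows <- lapply(names(groups), function(g) {
    seqs <- corpus$cds[match(groups[[g]], corpus$id)]
    if (anyNA(seqs)) stop("group ids missing from corpus: ", g)
    if (length(seqs) < 2L)
      warning("stratum '", g, "' has a single gene; interval is degenerate")
    point <- relative_abundance(seqs)
    boot <- replicate(n_boot, {
      cs <- suppressWarnings(
        relative_abundance(sample(seqs, replace = TRUE)))
      c(cs$rho_cg, cs$rho_cwg)
    })
    ci <- apply(boot, 1L, stats::quantile, probs = c(a, 1 - a),
                na.rm = TRUE, names = FALSE)
    data.frame(group = g, n_genes = length(seqs),
               rho_cg = point$rho_cg, rho_cg_lo = ci[1, 1], rho_cg_hi = ci[2, 1],
               rho_cwg = point$rho_cwg, rho_cwg_lo = ci[1, 2],
               rho_cwg_hi = ci[2, 2], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Polynomial fit of SCUO against GC3
#'
#' Least-squares polynomial (default quadratic, capturing the "U"-shaped
#' dependence of codon bias on wobble-position GC) of per-gene SCUO on
#' per-gene GC3.
#'
#' @param scuo_values per-gene SCUO (see [gene_scuo()]); NA pairs dropped.
#' @param gc3_values per-gene GC3, same order.
#' @param degree polynomial degree (default 2).
#' @return object of class `scuo_gc3_fit`: list with `coefficients`
#'   (ascending powers), `r_squared`, `minimum` (GC3 of the fitted minimum
#'   over the observed range), and the underlying `lm` fit.
#' @export
scuo_gc3_fit <- function(scuo_values, gc3_values, degree = 2) {
  stopifnot(length(scuo_values) == length(gc3_values))
  ok <- is.finite(scuo_values) & is.finite(gc3_values)
  y <- scuo_values[ok]; x <- gc3_values[ok]
  if (length(x) < degree + 2) stop("need at least degree + 2 genes")
  if (stats::sd(x) == 0) stop("degenerate design: constant GC3")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  beta <- unname(stats::coef(fit))
  minimum <- if (degree == 2 && beta[3] > 0) -beta[2] / (2 * beta[3]) else {
    grid <- seq(min(x), max(x), length.out = 1001L)
    grid[which.min(outer(grid, 0:degree, "^") %*% beta)]
  }
  out <- list(coefficients = beta, r_squared = summary(fit)$r.squared,
              minimum = minimum, fit = fit)
  class(out) <- "scuo_gc3_fit"
  out
}

#' @export
print.scuo_gc3_fit <- function(x, ...) {
  cat("SCUO ~ GC3 polynomial fit (degree",
      length(x$coefficients) - 1, ")\n")
  cat("  coefficients:", paste(signif(x$coefficients, 4), collapse = ", "),
      "\n  R-squared:", signif(x$r_squared, 4),
      "\n  fitted minimum at GC3 =", signif(x$minimum, 4), "\n")
  invisible(x)
}
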