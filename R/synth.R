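# Synthetic ORF corpora with known codon-usage structure, plus the SSC
# (synonymous-codon) and SC (full-codon) shuffling null models. The
# generator is the ground-truth source for parameter-recovery and null-
# calibration testing of every downstream statistic.

#' Specify a synthetic ORF corpus
#'
#' Validates and assembles the parameters of the generator. Gene lengths are
#' in codons and include the start and stop codons. Amino acids of the
#' interior positions are drawn i.i.d. (uniform over the 20 amino acids by
#' default); the codon for each amino acid is drawn from its family weight
#' vector, optionally modulated by first-order pair coupling against the
#' previous codon and by per-bin positional overrides.
#'
#' @param n_genes number of genes (>= 1).
#' @param min_codons,max_codons inclusive gene length bounds in codons
#'   (including start and stop; `min_codons >= 3`).
#' @param length_law `"uniform"` (default) or `"lognormal"`; lognormal
#'   lengths use `length_meanlog`/`length_sdlog` and are clamped to the
#'   bounds.
#' @param length_meanlog,length_sdlog lognormal parameters (log-codons).
#' @param codon_weights named list: amino-acid one-letter code -> named
#'   probability vector over that family's codons. Unlisted families are
#'   uniform. Weights are normalised; all must be positive.
#' @param pair_coupling data frame with columns `first`, `second`, `weight`
#'   (> 0): when the previous codon is `first`, the sampling weight of
#'   `second` is multiplied by `weight`. Default: no coupling.
#' @param positional_overrides named list: bin label (`"bin_1"` ...
#'   `"bin_-1"`, as in [extract_bins()]) -> `codon_weights`-style list of
#'   multiplicative factors applied on top of the base family weights within
#'   that bin. Applied only to genes long enough for disjoint bins.
#' @param stop_weights named probability vector over TAA/TAG/TGA (default
#'   uniform).
#' @param aa_weights optional named probability vector over the 20 amino
#'   acids (default uniform).
#' @param upstream_profile,downstream_profile 4 x L probability matrices
#'   (rows A/C/G/T) giving per-position nucleotide profiles for the flanks;
#'   default uniform with lengths 9 and 6.
#' @param seed RNG seed stored with the spec (default 1).
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_genes, min_codons = 103, max_codons = 203,
                           length_law = c("uniform", "lognormal"),
                           length_meanlog = 5, length_sdlog = 0.3,
                           codon_weights = NULL, pair_coupling = NULL,
                           positional_overrides = NULL,
                           stop_weights = NULL, aa_weights = NULL,
                           upstream_profile = NULL, downstream_profile = NULL,
                           seed = 1) {
  length_law <- match.arg(length_law)
  problems <- character()
  if (length(n_genes) != 1L || n_genes < 1) problems <- c(problems, "n_genes must be >= 1")
  if (min_codons < 3) problems <- c(problems, "min_codons must be >= 3")
  if (max_codons < min_codons) problems <- c(problems, "max_codons < min_codons")
  aa20 <- names(AA_FAMILIES)
  norm_weights <- function(wl, field) {
    if (is.null(wl)) return(list())
    for (aa in names(wl)) {
      fam <- AA_FAMILIES[[aa]]
      if (is.null(fam)) { problems <<- c(problems, paste0(field, ": unknown amino acid '", aa, "'")); next }
      w <- wl[[aa]]
      if (is.null(names(w)) || !all(names(w) %in% fam))
        problems <<- c(problems, paste0(field, "[", aa, "]: names must be codons of the family"))
      if (any(w <= 0) || any(!is.finite(w)))
        problems <<- c(problems, paste0(field, "[", aa, "]: weights must be positive"))
    }
    wl
  }
  codon_weights <- norm_weights(codon_weights, "codon_weights")
  if (!is.null(positional_overrides)) {
    bad <- setdiff(names(positional_overrides), BIN_LABELS(5L))
    if (length(bad)) problems <- c(problems,
      paste0("positional_overrides: unknown bin(s) ", paste(bad, collapse = ", ")))
    for (b in names(positional_overrides))
      positional_overrides[[b]] <- norm_weights(positional_overrides[[b]],
                                                paste0("positional_overrides$", b))
  }
  if (is.null(stop_weights))
    stop_weights <- stats::setNames(rep(1 / 3, 3), STOP_CODONS)
  if (!all(names(stop_weights) %in% STOP_CODONS) || length(stop_weights) != 3L ||
      any(stop_weights <= 0))
    problems <- c(problems, "stop_weights must be positive and named TAA/TAG/TGA")
  if (is.null(aa_weights))
    aa_weights <- stats::setNames(rep(1 / length(aa20), length(aa20)), aa20)
  if (!all(names(aa_weights) %in% aa20) || any(aa_weights <= 0))
    problems <- c(problems, "aa_weights must be positive and named by amino acid")
  if (!is.null(pair_coupling)) {
    pc <- as.data.frame(pair_coupling)
    if (!all(c("first", "second", "weight") %in% names(pc)) ||
        !all(pc$first %in% SENSE_CODONS) || !all(pc$second %in% SENSE_CODONS) ||
        any(pc$weight <= 0))
      problems <- c(problems,
        "pair_coupling needs columns first/second (sense codons) and weight > 0")
  }
  chk_profile <- function(p, len, field) {
    if (is.null(p)) return(matrix(0.25, nrow = 4, ncol = len,
                                  dimnames = list(DNA_BASES, NULL)))
    p <- as.matrix(p)
    if (nrow(p) != 4L || any(p < 0) ||
        any(abs(colSums(p) - 1) > 1e-8))
      problems <<- c(problems, paste0(field, " must be a 4 x L column-stochastic matrix"))
    rownames(p) <- DNA_BASES
    p
  }
  upstream_profile <- chk_profile(upstream_profile, 9L, "upstream_profile")
  downstream_profile <- chk_profile(downstream_profile, 6L, "downstream_profile")
  if (length(problems))
    stop("invalid generator spec:\n  ", paste(problems, collapse = "\n  "))
  out <- list(n_genes = as.integer(n_genes), min_codons = as.integer(min_codons),
              max_codons = as.integer(max_codons), length_law = length_law,
              length_meanlog = length_meanlog, length_sdlog = length_sdlog,
              codon_weights = codon_weights, pair_coupling = pair_coupling,
              positional_overrides = positional_overrides,
              stop_weights = stop_weights[STOP_CODONS],
              aa_weights = aa_weights[aa20],
              upstream_profile = upstream_profile,
              downstream_profile = downstream_profile,
              seed = as.integer(seed))
  class(out) <- "generator_spec"
  out
}

# base (normalised) weight vectors per family, spec overrides applied
.family_weights <- function(spec) {
  w <- lapply(AA_FAMILIES, function(fam)
    stats::setNames(rep(1 / length(fam), length(fam)), fam))
  for (aa in names(spec$codon_weights)) {
    v <- spec$codon_weights[[aa]]
    full <- stats::setNames(rep(0, length(AA_FAMILIES[[aa]])), AA_FAMILIES[[aa]])
    full[names(v)] <- v
    w[[aa]] <- full / sum(full)
  }
  w
}

# family weights with a bin's multiplicative override applied
.bin_weights <- function(base, override) {
  for (aa in names(override)) {
    v <- base[[aa]]
    v[names(override[[aa]])] <- v[names(override[[aa]])] * override[[aa]]
    base[[aa]] <- v / sum(v)
  }
  base
}

#' Generate a synthetic ORF corpus with known ground truth
#'
#' Draws gene lengths, interior amino-acid sequences and codons according to
#' the spec (see [generator_spec()]), prepends ATG, appends a stop drawn
#' from `stop_weights`, and samples flanking nucleotides from the
#' per-position profiles. Reproducible: the same spec (including its seed)
#' yields a byte-identical corpus.
#'
#' @param spec a `generator_spec`.
#' @return list with `corpus` (an [orf_corpus()] with flanks) and `truth`
#'   (list: the spec, `target_rscu` — the expected RSCU of every degenerate
#'   codon implied by the family weights — and `coupled_pairs`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  len <- if (spec$length_law == "uniform") {
    sample.int(spec$max_codons - spec$min_codons + 1L, n, replace = TRUE) +
      spec$min_codons - 1L
  } else {
    pmin(pmax(round(stats::rlnorm(n, spec$length_meanlog, spec$length_sdlog)),
              spec$min_codons), spec$max_codons)
  }
  base_w <- .family_weights(spec)
  has_overrides <- length(spec$positional_overrides) > 0L
  bin_w <- if (has_overrides)
    lapply(spec$positional_overrides, .bin_weights, base = base_w)
  coupling <- spec$pair_coupling
  n_int <- len - 2L
  aa_all <- sample(names(spec$aa_weights), sum(n_int), replace = TRUE,
                   prob = spec$aa_weights)
  gene_of <- rep.int(seq_len(n), n_int)
  # bin label of each interior position (codon index = position within
  # interior + 1), NA outside bins or for genes too short for disjoint bins
  bin_lab <- rep(NA_character_, length(aa_all))
  if (has_overrides) {
    pos_in_gene <- sequence(n_int) + 1L
    L_of <- len[gene_of]
    ok <- L_of >= 102L
    for (b in names(bin_w)) {
      k <- as.integer(sub("bin_", "", b))
      hit <- if (k > 0) {
        ok & pos_in_gene >= 2L + 10L * (k - 1L) & pos_in_gene <= 1L + 10L * k
      } else {
        kk <- -k
        ok & pos_in_gene >= L_of - 10L * kk & pos_in_gene <= L_of - 1L - 10L * (kk - 1L)
      }
      bin_lab[hit] <- b
    }
  }
  codons <- character(length(aa_all))
  if (is.null(coupling)) {
    # fully vectorised: sample per (family, bin) group
    grp <- paste(aa_all, ifelse(is.na(bin_lab), ".", bin_lab))
    for (g in unique(grp)) {
      i <- which(grp == g)
      aa <- aa_all[i[1L]]
      b <- bin_lab[i[1L]]
      w <- if (is.na(b)) base_w[[aa]] else bin_w[[b]][[aa]]
      codons[i] <- if (length(w) == 1L) names(w) else
        sample(names(w), length(i), replace = TRUE, prob = w)
    }
  } else {
    cmap <- split(stats::setNames(coupling$weight, coupling$second),
                  coupling$first)
    offset <- c(0L, cumsum(n_int))
    for (g in seq_len(n)) {
      prev <- "ATG"
      for (j in seq_len(n_int[g])) {
        i <- offset[g] + j
        aa <- aa_all[i]
        w <- if (is.na(bin_lab[i])) base_w[[aa]] else bin_w[[bin_lab[i]]][[aa]]
        cm <- cmap[[prev]]
        if (!is.null(cm)) {
          hit <- intersect(names(w), names(cm))
          if (length(hit)) { w[hit] <- w[hit] * cm[hit]; w <- w / sum(w) }
        }
        codons[i] <- if (length(w) == 1L) names(w) else
          sample(names(w), 1L, prob = w)
        prev <- codons[i]
      }
    }
  }
  stops <- sample(STOP_CODONS, n, replace = TRUE, prob = spec$stop_weights)
  cds <- vapply(seq_len(n), function(g)
    paste0("ATG", paste(codons[gene_of == g], collapse = ""), stops[g]),
    character(1))
  sample_flank <- function(profile, n) {
    apply(profile, 2L, function(p) sample(DNA_BASES, n, replace = TRUE, prob = p))
  }
  up <- sample_flank(spec$upstream_profile, n)
  down <- sample_flank(spec$downstream_profile, n)
  collapse_rows <- function(m) if (is.null(dim(m)))
    paste(m, collapse = "") else apply(m, 1L, paste, collapse = "")
  corpus <- orf_corpus(sprintf("synth_%05d", seq_len(n)), cds,
                       upstream = collapse_rows(up),
                       downstream = collapse_rows(down))
  target_rscu <- unlist(lapply(names(base_w), function(aa) {
    w <- base_w[[aa]]
    if (length(w) < 2L) return(NULL)
    w * length(w)
  }))
  truth <- list(spec = spec, target_rscu = target_rscu[DEGENERATE_CODONS],
                coupled_pairs = coupling)
  list(corpus = corpus, truth = truth)
}

#' Synonymous-codon (SSC) shuffle
#'
#' Permutes codons among all corpus positions encoding the same amino acid
#' (stop codons among stop positions). Every gene's protein sequence and
#' the corpus-wide codon counts are exactly preserved; positional and
#' pair structure within synonymous families is destroyed.
#'
#' @param corpus a validated [orf_corpus()].
#' @param seed optional RNG seed.
#' @return a shuffled [orf_corpus()] (flanks carried through).
#' @export
ssc_shuffle <- function(corpus, seed = NULL) {
  stopifnot(inherits(corpus, "orf_corpus"))
  if (!is.null(seed)) set.seed(seed)
  genes <- .corpus_codons(corpus)
  lens <- lengths(genes)
  flat <- unlist(genes, use.names = FALSE)
  aa <- CODON_AA[flat]
  for (a in unique(aa)) {
    i <- which(aa == a)
    if (length(i) > 1L) flat[i] <- flat[sample(i)]
  }
  out <- corpus
  gene_id <- factor(rep.int(seq_along(lens), lens), levels = seq_along(lens))
  out$cds <- vapply(split(flat, gene_id), paste, character(1), collapse = "")
  out
}

#' Full-codon (SC) shuffle
#'
#' Permutes all interior codons across the corpus (start and stop codons
#' stay in place). Gene lengths and corpus-wide codon counts are preserved;
#' amino-acid sequences generally are not. Interior codons of validated
#' ORFs are sense codons, so no internal stop can be introduced.
#'
#' @inheritParams ssc_shuffle
#' @return a shuffled [orf_corpus()].
#' @export
sc_shuffle <- function(corpus, seed = NULL) {
  stopifnot(inherits(corpus, "orf_corpus"))
  if (!is.null(seed)) set.seed(seed)
  genes <- .corpus_codons(corpus)
  interior <- lapply(genes, function(v) v[-c(1L, length(v))])
  lens <- lengths(interior)
  flat <- unlist(interior, use.names = FALSE)
  flat <- flat[sample.int(length(flat))]
  shuffled <- split(flat, factor(rep.int(seq_along(lens), lens),
                                 levels = seq_along(lens)))
  out <- corpus
  out$cds <- vapply(seq_along(genes), function(g) {
    v <- genes[[g]]
    paste0(v[1L], paste(shuffled[[g]], collapse = ""), v[length(v)])
  }, character(1))
  out
}
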