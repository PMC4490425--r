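# Cross-species comparison: per-species RSCU profiles, hierarchical
# clustering of the species x codon RSCU matrix, PCA, codon-context
# adjusted-residual matrices and context-based similarity trees.

#' Adjusted (standardized) residuals of a contingency table
#'
#' Pearson residuals divided by their marginal correction:
#' `r_ij = (o_ij - e_ij) / sqrt(e_ij (1 - row_i/N)(1 - col_j/N))` with
#' `e_ij = row_i col_j / N`. Approximately standard normal under
#' independence. Cells in a zero row or column marginal get residual 0.
#'
#' @param tab a numeric contingency matrix.
#' @return matrix of adjusted residuals, same dimensions.
#' @examples
#' adjusted_residuals(matrix(c(10, 0, 0, 10), 2))  # +/- 4.4721
#' @export
adjusted_residuals <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n <= 0) stop("empty contingency table")
  rs <- rowSums(tab); cs <- colSums(tab)
  e <- outer(rs, cs) / n
  denom <- sqrt(e * outer(1 - rs / n, 1 - cs / n))
  r <- (tab - e) / denom
  r[!is.finite(r)] <- 0
  r
}

#' Codon-context adjusted residuals
#'
#' Treats the neighboring-pair counts as a 61 x 61 contingency table (rows:
#' first codon, columns: second codon) and returns the adjusted residual of
#' every cell — the chi-square association between the two codons of each
#' pair.
#'
#' @param pair_table a `pair_table` with `distance == 0`.
#' @return 61 x 61 matrix of adjusted residuals.
#' @export
context_residuals <- function(pair_table) {
  stopifnot(inherits(pair_table, "pair_table"))
  if (pair_table$total_pairs <= 0) stop("pair table is empty")
  adjusted_residuals(pair_table$counts)
}

#' Build per-species codon usage profiles
#'
#' Runs the codon and pair statistics on each corpus and assembles one
#' profile per species: ORF and codon totals, GC partition, the
#' 59-dimensional RSCU vector (fixed codon order) and the 61 x 61 codon-
#' context adjusted-residual matrix. Species with an empty corpus are
#' excluded with a warning.
#'
#' @param corpora named list of validated [orf_corpus()] objects.
#' @return list of `species_profile` objects (name, n_orfs, n_codons, gc,
#'   rscu_vector, residual_matrix).
#' @export
build_profiles <- function(corpora) {
  stopifnot(is.list(corpora), length(names(corpora)) == length(corpora))
  out <- list()
  for (nm in names(corpora)) {
    corp <- corpora[[nm]]
    if (!inherits(corp, "orf_corpus") || nrow(corp) == 0L) {
      warning("species '", nm, "' has no kept ORFs; excluded")
      next
    }
    cu <- count_codons(corp)
    prof <- list(name = nm, n_orfs = nrow(corp), n_codons = cu$total_codons,
                 gc = gc_partition(cu),
                 rscu_vector = cu$rscu[DEGENERATE_CODONS],
                 residual_matrix = context_residuals(count_pairs(corp, 0)))
    class(prof) <- "species_profile"
    out[[nm]] <- prof
  }
  out
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("Species profile '%s': %d ORFs, %d codons, GC3 %.3f\n",
              x$name, x$n_orfs, x$n_codons, x$gc$gc3))
  invisible(x)
}

.rscu_matrix <- function(profiles) {
  m <- t(vapply(profiles, function(p) p$rscu_vector,
                numeric(length(DEGENERATE_CODONS))))
  rownames(m) <- vapply(profiles, function(p) p$name, character(1))
  colnames(m) <- DEGENERATE_CODONS
  m
}

.hclust_newick <- function(hc) {
  phy <- ape::as.phylo(hc)
  phy$tip.label <- gsub("\\s+", "_", phy$tip.label)
  ape::write.tree(phy)
}

#' Cluster species and codons by RSCU
#'
#' Hierarchically clusters the species x codon RSCU matrix on both axes.
#' Each codon column is standardized to zero mean and unit variance across
#' species first ("adjusted RSCU"; constant columns are set to 0). Species
#' distance is Euclidean by default; `metric = "spearman"` uses
#' 1 - rank-order correlation instead. Average linkage throughout;
#' `hclust` ties resolve by input order, so results are deterministic.
#'
#' @param profiles list of `species_profile` objects (>= 2).
#' @param metric `"euclidean"` or `"spearman"` (species axis).
#' @param standardize z-score each codon column first? (default TRUE)
#' @return object of class `rscu_clustering`: list with `matrix` (the
#'   standardized matrix), `species_hclust`, `codon_hclust`, `leaf_order`,
#'   `newick`.
#' @export
cluster_species_rscu <- function(profiles, metric = c("euclidean", "spearman"),
                                 standardize = TRUE) {
  metric <- match.arg(metric)
  if (length(profiles) < 2L) stop("need at least 2 species")
  m <- .rscu_matrix(profiles)
  if (standardize) {
    m <- apply(m, 2L, function(v) {
      s <- stats::sd(v)
      if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
    rownames(m) <- vapply(profiles, function(p) p$name, character(1))
  }
  d <- if (metric == "euclidean") stats::dist(m) else
    stats::as.dist(1 - stats::cor(t(m), method = "spearman"))
  hc_sp <- stats::hclust(d, method = "average")
  hc_cod <- stats::hclust(stats::dist(t(m)), method = "average")
  out <- list(matrix = m[hc_sp$order, hc_cod$order, drop = FALSE],
              species_hclust = hc_sp, codon_hclust = hc_cod,
              leaf_order = rownames(m)[hc_sp$order],
              newick = .hclust_newick(hc_sp))
  class(out) <- "rscu_clustering"
  out
}

#' @export
print.rscu_clustering <- function(x, ...) {
  cat("RSCU clustering of", nrow(x$matrix), "species x", ncol(x$matrix),
      "codons\n  leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' PCA of RSCU vectors
#'
#' Centered (unscaled) principal component analysis of RSCU vectors, either
#' one per species (a list of profiles) or one per gene (a numeric matrix,
#' rows = genes, columns = the 59 degenerate codons). The sign of each
#' component is fixed so its largest-magnitude loading is positive.
#'
#' @param x list of `species_profile` objects (>= 3) or a numeric matrix.
#' @return list with `scores`, `loadings`, `variance_ratio` (sums to 1).
#' @export
pca_rscu <- function(x) {
  m <- if (is.matrix(x)) x else .rscu_matrix(x)
  if (nrow(m) < 3L) stop("need at least 3 observations for PCA")
  m[is.na(m)] <- 0
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  list(scores = scores, loadings = loadings,
       variance_ratio = pc$sdev^2 / sum(pc$sdev^2))
}

#' Species tree from codon-context patterns
#'
#' Average-linkage dendrogram of species from their codon-context
#' adjusted-residual matrices; the distance between two species is
#' 1 - Pearson correlation of the flattened matrices (0 for identical
#' context patterns, 2 for perfectly anti-correlated ones).
#'
#' @param profiles list of `species_profile` objects (>= 2), or a named
#'   list of residual matrices.
#' @return object of class `rscu_clustering` (without a codon axis).
#' @export
species_context_tree <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 species")
  mats <- lapply(profiles, function(p)
    if (inherits(p, "species_profile")) p$residual_matrix else as.matrix(p))
  nm <- if (!is.null(names(profiles)) && all(nzchar(names(profiles))))
    names(profiles) else vapply(profiles, function(p) p$name, character(1))
  flat <- vapply(mats, as.vector, numeric(length(mats[[1]])))
  colnames(flat) <- nm
  d <- stats::as.dist(1 - stats::cor(flat))
  hc <- stats::hclust(d, method = "average")
  out <- list(matrix = NULL, species_hclust = hc, codon_hclust = NULL,
              leaf_order = nm[hc$order], newick = .hclust_newick(hc))
  class(out) <- "rscu_clustering"
  out
}
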