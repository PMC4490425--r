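test_that("adjusted residuals match the hand formula and chisq.test", {
  m <- matrix(c(10, 0, 0, 10), 2)
  r <- adjusted_residuals(m)
  expect_equal(r[1, 1], (10 - 5) / sqrt(5 * 0.5 * 0.5))   # +4.4721
  expect_equal(unname(diag(r)), rep(4.472136, 2), tolerance = 1e-6)
  expect_equal(r[1, 2], -4.472136, tolerance = 1e-6)
  # independent oracle on an asymmetric table
  set.seed(3)
  tab <- matrix(rpois(12, 30), 3, 4)
  ref <- suppressWarnings(stats::chisq.test(tab))$stdres
  expect_equal(adjusted_residuals(tab), ref, ignore_attr = TRUE,
               tolerance = 1e-12)
  # zero marginal -> residual 0 by convention
  z <- matrix(c(5, 0, 3, 0), 2)
  expect_equal(adjusted_residuals(z)[, 2], c(0, 0), ignore_attr = TRUE)
})

test_that("null residuals are standard-normal scaled; injected pairs stand out", {
  corp <- uniform_corpus(800, seed = 41, min_codons = 128, max_codons = 132)
  res <- context_residuals(count_pairs(corp, 0))
  expect_equal(dim(res), c(61L, 61L))
  expect_gt(count_pairs(corp, 0)$total_pairs, 1e5)
  sdres <- sd(as.vector(res))
  expect_gt(sdres, 0.9); expect_lt(sdres, 1.1)
  expect_gt(mean(abs(as.vector(res)) < 2), 0.93)

  pc <- data.frame(first = "GCC", second = "GCC", weight = 12)
  g <- generate_corpus(generator_spec(600, 103, 123, pair_coupling = pc,
                                      seed = 43))
  res2 <- context_residuals(count_pairs(g$corpus, 0))
  expect_gt(res2["GCC", "GCC"], 3)
})

test_that("profiles are reproducible and reflect generator GC3 ordering", {
  a <- uniform_corpus(40, seed = 51)
  profs <- build_profiles(list(s1 = a, s2 = a))
  expect_equal(profs$s1$rscu_vector, profs$s2$rscu_vector)
  expect_equal(profs$s1$residual_matrix, profs$s2$residual_matrix)
  expect_equal(profs$s1$n_orfs, 40L)
  expect_length(profs$s1$rscu_vector, 59L)

  # GC3-shifted species recover their ordering
  lowgc <- generate_corpus(generator_spec(
    80, 103, 123, codon_weights = list(A = c(GCA = 0.4, GCT = 0.4,
                                             GCC = 0.1, GCG = 0.1),
                                       E = c(GAA = 0.8, GAG = 0.2)),
    seed = 52))$corpus
  higc <- generate_corpus(generator_spec(
    80, 103, 123, codon_weights = list(A = c(GCA = 0.1, GCT = 0.1,
                                             GCC = 0.4, GCG = 0.4),
                                       E = c(GAA = 0.2, GAG = 0.8)),
    seed = 53))$corpus
  p2 <- build_profiles(list(lo = lowgc, hi = higc))
  expect_lt(p2$lo$gc$gc3, p2$hi$gc$gc3)

  # empty corpus excluded with warning
  empty <- orf_corpus(character(), character())
  expect_warning(p3 <- build_profiles(list(ok = a, none = empty)), "excluded")
  expect_named(p3, "ok")
})

test_that("RSCU clustering merges identical species first and is deterministic", {
  a <- uniform_corpus(40, seed = 61)
  b <- a; b$id <- paste0(b$id, "_b")
  class(b) <- c("orf_corpus", "data.frame")
  c_corp <- generate_corpus(generator_spec(
    40, 103, 153, codon_weights = list(L = c(CTG = 0.75, CTA = 0.05,
                                             CTC = 0.05, CTT = 0.05,
                                             TTA = 0.05, TTG = 0.05)),
    seed = 62))$corpus
  profs <- build_profiles(list(A = a, B = b, C = c_corp))
  cl <- cluster_species_rscu(profs)
  hc <- cl$species_hclust
  # first merge joins the two identical profiles at height ~0
  expect_setequal(hc$labels[-hc$merge[1, ]], c("A", "B"))
  expect_lt(hc$height[1], 1e-8)
  expect_lt(hc$height[1], hc$height[2])
  # determinism and newick round-trip topology
  cl2 <- cluster_species_rscu(profs)
  expect_equal(cl$newick, cl2$newick)
  phy <- ape::read.tree(text = cl$newick)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  # spearman metric also supported
  cls <- cluster_species_rscu(profs, metric = "spearman")
  expect_s3_class(cls$species_hclust, "hclust")
})

test_that("synthetic clades are recovered by cutting the RSCU dendrogram", {
  # opposite skews in every 2-fold family: clades differ in many codons,
  # within-clade variation is sampling noise only
  twofold <- list(N = c("AAT", "AAC"), D = c("GAT", "GAC"),
                  C = c("TGT", "TGC"), Q = c("CAA", "CAG"),
                  E = c("GAA", "GAG"), H = c("CAT", "CAC"),
                  K = c("AAA", "AAG"), F = c("TTT", "TTC"),
                  Y = c("TAT", "TAC"))
  skew <- function(p) lapply(twofold, function(f) setNames(c(p, 1 - p), f))
  centro <- list(skew(0.8), skew(0.2))
  ok <- vapply(1:10, function(s) {
    corpora <- list()
    for (i in 1:2) for (j in 1:3) {
      corpora[[paste0("clade", i, "_sp", j)]] <- generate_corpus(
        generator_spec(25, 103, 123, codon_weights = centro[[i]],
                       seed = 1000 * s + 10 * i + j))$corpus
    }
    cl <- cluster_species_rscu(build_profiles(corpora))
    grp <- stats::cutree(cl$species_hclust, k = 2)
    length(unique(grp[1:3])) == 1 && length(unique(grp[4:6])) == 1 &&
      grp[1] != grp[4]
  }, logical(1))
  expect_true(all(ok))
})

test_that("PCA conventions: ratios sum to 1, rank-1 data, group separation", {
  a <- uniform_corpus(30, seed = 71)
  profs <- build_profiles(list(A = a,
                               B = uniform_corpus(30, seed = 72),
                               C = uniform_corpus(30, seed = 73),
                               D = uniform_corpus(30, seed = 74)))
  pca <- pca_rscu(profs)
  expect_equal(sum(pca$variance_ratio), 1, tolerance = 1e-9)
  # species order invariance (up to nothing: scores identical by name)
  pca_rev <- pca_rscu(profs[c(3, 1, 4, 2)])
  expect_equal(pca$scores[rownames(pca_rev$scores), 1], pca_rev$scores[, 1],
               tolerance = 1e-9)
  # collinear points in 59-D -> PC1 carries all variance
  base <- rnorm(59)
  m <- outer(seq(0, 3, length.out = 6), base)
  rownames(m) <- paste0("s", 1:6)
  expect_equal(pca_rscu(m)$variance_ratio[1], 1, tolerance = 1e-9)
  # two well-separated groups split on PC1
  m2 <- rbind(matrix(rnorm(5 * 59, 0, 0.05), 5),
              matrix(rnorm(5 * 59, 1.5, 0.05), 5))
  rownames(m2) <- paste0("s", 1:10)
  p2 <- pca_rscu(m2)
  expect_gt(p2$variance_ratio[1], 0.8)
  expect_lt(max(p2$scores[1:5, 1]), min(p2$scores[6:10, 1]))
})

test_that("context trees collapse identical species and bound anti-correlation", {
  m <- matrix(rnorm(61 * 61), 61)
  tr <- species_context_tree(list(a = m, b = m, c = -m))
  hc <- tr$species_hclust
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("a", "b"))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_equal(max(hc$height), 2, tolerance = 1e-9)   # 1 - (-1)
  expect_match(tr$newick, "^\\(")
})
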