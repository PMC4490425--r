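test_that("codon KLD matches closed forms and zero cases", {
  q <- c(GAA = 0.5, GAG = 0.5)
  expect_equal(codon_kld(rep("GAA", 7), q), log(2), tolerance = 1e-12)
  # p == q -> 0 exactly
  expect_equal(codon_kld(c(rep("GAA", 3), rep("GAG", 3)), q), 0)
  # families absent from the sample contribute nothing
  q2 <- c(GAA = 0.5, GAG = 0.5, CTG = 1 / 6, CTA = 5 / 6)
  expect_equal(codon_kld(c("GAA", "GAG"), q2), 0)
  # p > 0 where q = 0 is a hard error, not silent infinity
  expect_error(codon_kld("GAA", c(GAA = 0, GAG = 1)), "zero")
})

test_that("KLD is invariant to gene order and corpus duplication", {
  corp <- uniform_corpus(20, seed = 61)
  q <- count_codons(corp, include_start = FALSE, include_stop = FALSE)$q
  bins <- extract_bins(corp)
  rev_corp <- corp[rev(seq_len(nrow(corp))), ]
  class(rev_corp) <- c("orf_corpus", "data.frame")
  bins_rev <- extract_bins(rev_corp)
  dup <- rbind_corpus(corp, within(as.data.frame(corp), id <- paste0(id, "b")))
  bins_dup <- extract_bins(dup)
  for (b in names(bins$bins)) {
    k <- codon_kld(bins$bins[[b]], q)
    expect_equal(codon_kld(bins_rev$bins[[b]], q), k, tolerance = 1e-12)
    expect_equal(codon_kld(bins_dup$bins[[b]], q), k, tolerance = 1e-12)
  }
})

test_that("SSC-shuffled corpora sit inside the null band in every bin", {
  corp <- uniform_corpus(120, seed = 71)
  shuf <- ssc_shuffle(corp, seed = 5)
  prof <- kld_profile(shuf, ssc_replicates = 40, seed = 6)
  expect_true(all(prof$kld_raw >= 0))
  expect_equal(prof$kld_corrected, prof$kld_raw - prof$null_mean)
  expect_true(all(abs(prof$kld_corrected) <= 3 * prof$null_sd))
})

test_that("an injected bin_1 bias is detected in bin_1 only", {
  ov <- list(bin_1 = list(L = c(CTA = 12), E = c(GAA = 6)))
  g <- generate_corpus(generator_spec(300, 103, 143,
                                      positional_overrides = ov, seed = 23))
  prof <- kld_profile(g$corpus, ssc_replicates = 40, seed = 9)
  z <- prof$kld_corrected / prof$null_sd
  expect_gt(z[prof$bin == "bin_1"], 2)
  expect_true(all(abs(z[prof$bin %in% c("bin_3", "bin_4", "bin_5")]) < 3))
})

test_that("post-AUG bias flags a forced codon after the start", {
  # every gene starts ATG GCT ...
  set.seed(2)
  body <- vapply(1:60, function(i)
    paste0("ATGGCT", paste(sample(c("GAA", "GAG", "CTG", "GCC", "AAA", "TTT"),
                                  110, replace = TRUE), collapse = ""), "TAA"),
    character(1))
  corp <- orf_corpus(paste0("g", 1:60), body)
  pa <- post_aug_bias(corp, "start")
  gct <- pa$calls[pa$calls$item == "GCT", ]
  expect_equal(gct$verdict, "preferred")
  # mask membership: GCT contributes to Gnn, nCn, nnU
  m <- setNames(pa$masks$obs, pa$masks$mask)
  expect_gte(m[["Gnn"]], 60)
  expect_gte(m[["nCn"]], 60)
  expect_gte(m[["nnU"]], 60)
  expect_equal(nrow(pa$masks), 12L)
})

test_that("internal-AUG anchor on unbiased corpora stays quiet", {
  sig <- vapply(1:4, function(s) {
    corp <- uniform_corpus(150, seed = 300 + s)
    pa <- post_aug_bias(corp, "internal")
    mean(pa$calls$verdict != "unbiased")
  }, numeric(1))
  expect_lte(mean(sig), 0.01)
})

test_that("logo information spans its entropy anchors", {
  # identical windows, large n -> info ~ 2 bits at every kept position
  lm1 <- logo_matrix(rep(strrep("ACGTACGTACGTACGTAC", 1), 4000))
  expect_true(all(lm1$info_bits > 1.99))
  expect_equal(nrow(lm1), 15L)                 # anchor 10-12 dropped
  expect_false(any(lm1$position %in% 10:12))
  # letter heights sum to the information content
  expect_equal(rowSums(lm1[, c("A", "C", "G", "U")]), lm1$info_bits,
               tolerance = 1e-12, ignore_attr = TRUE)
  # uniform composition -> ~0 bits
  set.seed(4)
  rand <- vapply(1:4000, function(i)
    paste(sample(c("A", "C", "G", "T"), 18, replace = TRUE), collapse = ""),
    character(1))
  expect_true(all(logo_matrix(rand)$info_bits < 0.05))
  # two equiprobable letters -> ~1 bit
  half <- c(rep(strrep("A", 18), 2000), rep(strrep("C", 18), 2000))
  expect_true(all(abs(logo_matrix(half)$info_bits - 1) < 0.01))
})

test_that("injected flank motifs raise logo bits at their positions only", {
  up <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  up[, 7] <- c(0.97, 0.01, 0.01, 0.01)          # Kozak A at -3
  down <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  down[, 1] <- c(0.01, 0.01, 0.97, 0.01)        # G right after the stop
  g <- generate_corpus(generator_spec(400, 103, 123, upstream_profile = up,
                                      downstream_profile = down, seed = 31))
  lm_start <- logo_matrix(extract_context(g$corpus, "start"))
  # upstream flank occupies window positions 1-9; only -3 (position 7) is hot
  expect_gt(lm_start$info_bits[lm_start$position == 7], 0.5)
  expect_true(all(lm_start[lm_start$position %in% c(1:6, 8, 9),
                           "info_bits"] < 0.1))
  lm_stop <- logo_matrix(extract_context(g$corpus, "stop"))
  # downstream flank occupies window positions 13-18; only its first
  # position carries the injected motif
  expect_gt(lm_stop$info_bits[lm_stop$position == 13], 0.5)
  expect_true(all(lm_stop[lm_stop$position %in% 14:18, "info_bits"] < 0.1))
})

test_that("AU3 profile tracks injected early AU3 enrichment", {
  ov <- list(bin_1 = list(E = c(GAA = 20), K = c(AAA = 20),
                          L = c(CTA = 20, TTA = 20)))
  g <- generate_corpus(generator_spec(250, 103, 123,
                                      positional_overrides = ov, seed = 37))
  prof <- au3_profile(g$corpus, first_k_codons = 15)
  base <- attr(prof, "baseline")
  early <- prof$au3[prof$codon_index <= 11]
  late <- prof$au3[prof$codon_index > 11]
  expect_gt(mean(early), base + 0.05)
  expect_lt(mean(abs(late - base)), 0.05)
  # all-GCC corpus: AU3 identically zero
  gcc <- orf_corpus("g", paste0("ATG", strrep("GCC", 120), "TAA"))
  expect_true(all(au3_profile(gcc)$au3 == 0))
})
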