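test_that("pair counting slides over interior codons only", {
  # body CTG CTG CTG: d=0 -> 2 neighboring CTG|CTG, d=1 -> 1
  orf <- orf_corpus("t3", paste0("ATG", strrep("CTG", 3), "TAA"))
  p0 <- count_pairs(orf, 0)
  expect_equal(p0$counts["CTG", "CTG"], 2L)
  expect_equal(p0$total_pairs, 2L)
  p1 <- count_pairs(orf, 1)
  expect_equal(p1$counts["CTG", "CTG"], 1L)
  # no pair crosses a gene junction
  two <- rbind_corpus(orf_corpus("a", paste0("ATG", strrep("CTG", 3), "TAA")),
                      orf_corpus("b", paste0("ATG", strrep("GAA", 3), "TAA")))
  pt <- count_pairs(two, 0)
  expect_equal(pt$counts["CTG", "CTG"], 2L)
  expect_equal(pt$counts["GAA", "GAA"], 2L)
  expect_equal(pt$counts["CTG", "GAA"], 0L)
})

test_that("pair totals and counts match the brute-force oracle at all distances", {
  corp <- uniform_corpus(15, seed = 8, min_codons = 10, max_codons = 40)
  for (d in c(0L, 2L, 5L)) {
    pt <- count_pairs(corp, d)
    interior <- nchar(corp$cds) / 3 - 2
    expect_equal(pt$total_pairs, sum(pmax(0, interior - 1 - d)))
    ref <- oracle_pair_counts(corp$cds, d)
    for (key in names(ref)) {
      a <- substr(key, 1, 3); b <- substr(key, 4, 6)
      expect_equal(unname(pt$counts[a, b]), ref[[key]], label = key)
    }
    expect_equal(sum(pt$counts), sum(unlist(ref)))
    expect_equal(sum(pt$obs_freq), 1, tolerance = 1e-9)
    expect_equal(sum(pt$exp_freq), 1, tolerance = 1e-9)
  }
})

test_that("RSCPU reproduces the single-family hand computation", {
  # GluGlu family: only GAGGAG observed 4 times -> expected each 4/4 = 1
  orf <- orf_corpus("g", paste0("ATG", strrep("GAG", 5), "TAA"))
  rp <- rscpu(count_pairs(orf, 0))
  ee <- rp[rp$pair == "GAGGAG", ]
  expect_equal(ee$obs, 4L)
  expect_equal(ee$expected, 1)
  expect_equal(ee$rscpu, 4)
  expect_equal(ee$family_share, 1)
  # Met/Trp-only pairs are excluded from the synonymous universe
  expect_false(any(c("ATGATG", "ATGTGG", "TGGATG", "TGGTGG") %in% rp$pair))
})

test_that("RSCPU family means are 1 and uniform usage gives RSCPU near 1", {
  corp <- uniform_corpus(60, seed = 13)
  rp <- rscpu(count_pairs(corp, 0))
  means <- tapply(rp$rscpu, rp$aa_pair, mean)
  expect_true(all(abs(means - 1) < 1e-9))
  shares <- tapply(rp$family_share, rp$aa_pair, sum)
  expect_true(all(abs(shares - 1) < 1e-9))
})

test_that("RSCPU recovers an injected pair weight and flags high pairs", {
  pc <- data.frame(first = "CTG", second = "CTG", weight = 8)
  g <- generate_corpus(generator_spec(250, 103, 123, pair_coupling = pc,
                                      seed = 99))
  rp <- rscpu(count_pairs(g$corpus, 0))
  top <- classify_high_frequency_pairs(rp)
  expect_true("CTGCTG" %in% top$pair)
  expect_gt(rp$rscpu[rp$pair == "CTGCTG"], 1.5)
  # the 60%-share rule fires even when RSCPU is modest
  fake <- data.frame(pair = c("p1", "p2", "p3", "p4"), aa_pair = "XY",
                     obs = c(62, 20, 10, 8), expected = 25,
                     rscpu = c(62, 20, 10, 8) / 25,
                     family_share = c(0.62, 0.20, 0.10, 0.08))
  expect_true("p1" %in% classify_high_frequency_pairs(fake)$pair)
})

test_that("Audic-Claverie probabilities hit their closed forms", {
  expect_equal(audic_claverie_p(0, 0, 50, 50, two_sided = FALSE), 0.5)
  expect_equal(audic_claverie_p(0, 0, 50, 50), 1)
  expect_equal(audic_claverie_p(5, 0, 100, 100, two_sided = FALSE), 1 / 64)
  # symmetric case is never significant
  for (x in c(0L, 3L, 17L, 240L))
    expect_equal(audic_claverie_p(x, x, 1000, 1000), 1)
  expect_error(audic_claverie_p(-1, 0, 10, 10), "non-negative")
  expect_error(audic_claverie_p(1, 0, 0, 10), "positive")
})

test_that("Audic-Claverie matches direct log-space summation", {
  cases <- expand.grid(x = c(0, 2, 9, 40), y = c(0, 3, 25),
                       n2 = c(1000, 2500))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    expect_equal(audic_claverie_p(cs$x, cs$y, 1000, cs$n2),
                 oracle_ac_p(cs$x, cs$y, 1000, cs$n2), tolerance = 1e-10,
                 label = paste(cs, collapse = "/"))
  }
})

test_that("bias calls require both significance and fold change", {
  ef <- c(a = 0.5, b = 0.25, c = 0.25)
  # large N: 8-fold excess on 'a' -> preferred
  obs <- c(a = 4000, b = 500, c = 500)
  ef2 <- c(a = 0.1, b = 0.45, c = 0.45)
  calls <- call_bias(obs, ef2)
  expect_equal(calls$verdict[calls$item == "a"], "preferred")
  # same ratio at tiny N: significance gate blocks the call
  tiny <- call_bias(c(a = 4, b = 3, c = 3), ef2, n = 10)
  expect_equal(tiny$verdict[tiny$item == "a"], "unbiased")
  # p floored at 1e-10
  expect_true(all(calls$p >= 1e-10))
  # zero-count continuity correction keeps the ratio finite
  z <- call_bias(c(a = 0, b = 50, c = 50), c(a = 0.3, b = 0.35, c = 0.35),
                 n = 100)
  expect_true(is.finite(z$log2_ratio[z$item == "a"]))
  expect_equal(z$verdict[z$item == "a"], "avoided")
})

test_that("an injected preferred pair is called and the null is quiet", {
  # coupling acts within the family of the second codon, so the attainable
  # enrichment is e = w / (1 + (w - 1) q) with q the baseline within-family
  # share; for CTG (6-fold Leu) at w = 10 that is 4-fold (log2 = 2)
  pc <- data.frame(first = "GAA", second = "CTG", weight = 10)
  g <- generate_corpus(generator_spec(400, 103, 123, pair_coupling = pc,
                                      seed = 17))
  calls <- call_pair_bias(count_pairs(g$corpus, 0))
  pref <- calls$item[calls$verdict == "preferred"]
  expect_true("GAACTG" %in% pref)
  expect_lte(length(pref), 2L)
  truth_log2 <- log2(10 / (1 + 9 / 6))
  expect_lt(abs(calls$log2_ratio[calls$item == "GAACTG"] - truth_log2),
            0.15 * truth_log2)
  # distance decay: neighboring coupling leaves spaced distances quiet
  n_sig <- vapply(0:3, function(d) {
    cd <- call_pair_bias(count_pairs(g$corpus, d))
    sum(cd$verdict != "unbiased")
  }, numeric(1))
  expect_true(all(n_sig[-1] <= n_sig[1]))
})

test_that("SC-shuffled corpora stay below 1% significant calls", {
  rates <- vapply(1:5, function(s) {
    corp <- uniform_corpus(150, seed = 100 + s, min_codons = 103,
                           max_codons = 143)
    shuf <- sc_shuffle(corp, seed = 200 + s)
    calls <- call_pair_bias(count_pairs(shuf, 0))
    mean(calls$p < 0.01)
  }, numeric(1))
  expect_lte(mean(rates), 0.01)
})

test_that("junction profile groups pairs by the junction dinucleotide", {
  corp <- uniform_corpus(80, seed = 55)
  jp <- junction_profile(count_pairs(corp, 0))
  expect_equal(nrow(jp), 16L)
  expect_equal(sum(jp$n_pairs), 61L * 61L)
  # GAG|GAA -> junction GG lives in the GG group median's support
  expect_true("GG" %in% jp$junction)
  # null corpus: all group medians near 1
  expect_true(all(abs(jp$median - 1) < 0.35))
})
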