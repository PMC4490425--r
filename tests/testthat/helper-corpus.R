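# Shared fixtures and independent oracles. Everything is built in code; the
# oracles deliberately take the dumbest possible route (string chopping,
# explicit loops, log-space summation) so they stay independent of the
# package's vectorised implementations.

toy1 <- function() orf_corpus("t1", "ATGGAAGAGGAAGAGTAA")
toy2 <- function() orf_corpus("t2", "ATGGAGGAGGAGGAATAA")

# a valid ORF of n_codons total (including start and stop) built from a
# recycled body alphabet
make_orf <- function(id, n_codons, body = c("GAA", "GAG", "CTG", "GCC"),
                     stop = "TAA", upstream = "", downstream = "") {
  interior <- rep_len(body, n_codons - 2L)
  orf_corpus(id, paste0("ATG", paste(interior, collapse = ""), stop),
             upstream = upstream, downstream = downstream)
}

rbind_corpus <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("orf_corpus", "data.frame")
  out
}

# brute-force ordered pair counter over interior codons of one cds string
oracle_pair_counts <- function(cds_vec, d) {
  out <- new.env()
  for (cds in cds_vec) {
    cod <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
    cod <- cod[-c(1, length(cod))]
    if (length(cod) >= 2 + d) {
      for (i in seq_len(length(cod) - 1 - d)) {
        key <- paste0(cod[i], cod[i + 1 + d])
        out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + 1
      }
    }
  }
  as.list(out)
}

# direct log-space summation of the Audic-Claverie two-sided tail
oracle_ac_p <- function(x, y, n1, n2) {
  logp <- function(k) k * log(n2 / n1) + lchoose(x + k, k) -
    (x + k + 1) * log(1 + n2 / n1)
  lower <- sum(exp(vapply(0:y, logp, numeric(1))))
  upper <- 1 - lower + exp(logp(y))
  min(1, 2 * min(lower, upper))
}

# uniform random valid corpus via the generator with default (uniform) weights
uniform_corpus <- function(n_genes, seed, min_codons = 103, max_codons = 153) {
  generate_corpus(generator_spec(n_genes, min_codons, max_codons,
                                 seed = seed))$corpus
}
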