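# End-to-end orchestration: filter -> usage -> pairs -> positional ->
# composition (-> comparative for >= 2 corpora), writing a report bundle of
# TSV/JSON/newick files with a run manifest.

#' Assemble a pipeline configuration
#'
#' Thresholds default to the analysis conventions used throughout the
#' package: significance at p < 0.01, |log2| ratio cutoff 1.5 (3-fold),
#' high-frequency cutoffs RSCU/RSCPU > 1.5 or family share > 60%, minimum
#' ORF length > 300 bp, homolog length ratio within [0.95, 1.05], 5 bins of
#' 10 codons per gene end, 100 SSC replicates, 1000 bootstrap resamples.
#'
#' @param p_thresh,log2_cutoff,rscu_high,share_high,min_len,ratio_bounds
#'   analysis thresholds (see above).
#' @param bin_size,n_bins positional bin layout.
#' @param ssc_reps,bootstrap_reps replicate counts.
#' @param pair_distances junction distances for pair tables.
#' @param seed RNG seed recorded in every output header.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(p_thresh = 0.01, log2_cutoff = 1.5, rscu_high = 1.5,
                       share_high = 0.60, min_len = 300,
                       ratio_bounds = c(0.95, 1.05), bin_size = 10,
                       n_bins = 5, ssc_reps = 100, bootstrap_reps = 1000,
                       pair_distances = 0:5, seed = 1) {
  stopifnot(p_thresh > 0, log2_cutoff > 0, rscu_high > 0, share_high > 0,
            min_len > 0)
  out <- as.list(environment())
  class(out) <- "run_config"
  out
}

.config_hash <- function(config) {
  s <- paste(vapply(config, function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = ";")
  # small deterministic polynomial hash; enough to fingerprint a config
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 4294967296
  sprintf("%010.0f", h)
}

.bundle_header <- function(config) {
  c(paste0("codonbias ", as.character(utils::packageVersion("codonbias"))),
    paste0("config_hash=", .config_hash(config)),
    paste0("seed=", config$seed))
}

.write_tsv <- function(df, path, header) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Filters each corpus, computes codon usage, pair statistics at all
#' configured distances, the positional KLD profile, post-AUG bias, context
#' logos (when flanks are present), composition statistics with GC3 strata,
#' and — when two or more corpora are supplied — the comparative RSCU
#' clustering, PCA and context trees. All tables are written under
#' `out_dir` with a header (package version, config hash, seed) and a JSON
#' manifest reconciling per-stage record counts.
#'
#' @param corpora a single [orf_corpus()] or a named list of them
#'   (unvalidated candidates; filtering is the first stage).
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @param homolog_lengths optional named vector for the length-ratio filter.
#' @return invisibly, a list with the per-species results and the manifest.
#' @export
run_pipeline <- function(corpora, out_dir, config = run_config(),
                         homolog_lengths = NULL) {
  if (inherits(corpora, "orf_corpus")) corpora <- list(corpus = corpora)
  stopifnot(length(corpora) >= 1L, !is.null(names(corpora)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- .bundle_header(config)
  set.seed(config$seed)
  manifest <- list(version = as.character(utils::packageVersion("codonbias")),
                   config_hash = .config_hash(config), seed = config$seed,
                   species = list())
  results <- list()
  kept_corpora <- list()
  for (nm in names(corpora)) {
    stage <- function(s) file.path(out_dir, paste0(nm, ".", s))
    filt <- filter_orfs(corpora[[nm]], min_len_bp = config$min_len,
                        homolog_lengths = homolog_lengths,
                        ratio_bounds = config$ratio_bounds)
    write_filter_report(filt, stage("filter.tsv"))
    corp <- filt$kept
    if (nrow(corp) == 0L) {
      warning("no ORF of '", nm, "' passed filtering; skipped")
      next
    }
    usage <- count_codons(corp)
    write_usage_table(usage, stage("usage.tsv"), header = hdr)
    pair_tabs <- lapply(config$pair_distances, function(d) count_pairs(corp, d))
    names(pair_tabs) <- paste0("d", config$pair_distances)
    calls <- lapply(pair_tabs, call_pair_bias, p_thresh = config$p_thresh,
                    log2_cutoff = config$log2_cutoff)
    for (d in names(calls))
      write_pair_calls(calls[[d]], stage(paste0("pairs_", d, ".tsv")),
                       header = hdr)
    rp <- rscpu(pair_tabs[["d0"]])
    hi_pairs <- classify_high_frequency_pairs(rp, config$rscu_high,
                                              config$share_high)
    .write_tsv(hi_pairs, stage("high_freq_pairs.tsv"), hdr)
    kld <- tryCatch(kld_profile(corp, bin_size = config$bin_size,
                                n_bins = config$n_bins,
                                ssc_replicates = config$ssc_reps,
                                seed = config$seed),
                    error = function(e) NULL)
    if (!is.null(kld)) .write_tsv(as.data.frame(kld), stage("kld.tsv"), hdr)
    post_aug <- post_aug_bias(corp, "start", p_thresh = config$p_thresh,
                              log2_cutoff = config$log2_cutoff)
    .write_tsv(post_aug$calls, stage("post_aug.tsv"), hdr)
    for (anchor in c("start", "stop")) {
      win <- extract_context(corp, anchor)
      if (nrow(win) > 0L)
        .write_tsv(as.data.frame(logo_matrix(win)),
                   stage(paste0("logo_", anchor, ".tsv")), hdr)
    }
    comp <- relative_abundance(corp)
    strata <- gc3_strata(gene_gc3(corp))
    contrast <- strata_composition_contrast(corp, strata,
                                            n_boot = config$bootstrap_reps,
                                            seed = config$seed)
    .write_tsv(contrast, stage("composition_strata.tsv"), hdr)
    fit <- tryCatch(scuo_gc3_fit(gene_scuo(corp), gene_gc3(corp)),
                    error = function(e) NULL)
    jsonlite::write_json(
      list(gc = gc_partition(usage), scuo = scuo(usage),
           ncg_ncc = tryCatch(ncg_ncc_ratio(usage), error = function(e) NULL),
           rho_cg = comp$rho_cg, rho_cwg = comp$rho_cwg,
           scuo_gc3 = if (!is.null(fit))
             fit[c("coefficients", "r_squared", "minimum")]),
      stage("summary.json"), auto_unbox = TRUE, digits = NA)
    manifest$species[[nm]] <- list(input = nrow(corpora[[nm]]),
                                   kept = nrow(corp),
                                   rejected = nrow(filt$rejected),
                                   codons = usage$total_codons)
    kept_corpora[[nm]] <- corp
    results[[nm]] <- list(filter = filt, usage = usage, pairs = pair_tabs,
                          calls = calls, kld = kld, composition = comp)
  }
  if (length(kept_corpora) >= 2L) {
    profiles <- build_profiles(kept_corpora)
    clus <- cluster_species_rscu(profiles)
    writeLines(clus$newick, file.path(out_dir, "rscu_tree.nwk"))
    .write_tsv(data.frame(species = rownames(clus$matrix), clus$matrix,
                          check.names = FALSE),
               file.path(out_dir, "rscu_heatmap.tsv"), hdr)
    if (length(profiles) >= 3L) {
      pca <- pca_rscu(profiles)
      .write_tsv(data.frame(species = rownames(pca$scores),
                            round(pca$scores, 6), check.names = FALSE),
                 file.path(out_dir, "rscu_pca_scores.tsv"), hdr)
      results$pca <- pca
    }
    tree <- species_context_tree(profiles)
    writeLines(tree$newick, file.path(out_dir, "context_tree.nwk"))
    results$clustering <- clus
    results$context_tree <- tree
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}
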