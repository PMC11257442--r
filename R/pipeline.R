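#' Analysis configuration
#'
#' The single home of the workflow's thresholds and settings: bin sizes
#' (1-kb profile and 10-kb segmentation resolution), the spike-in constant
#' (30,000), HMM settings (4 states), the consensus support rule, the
#' 5-TPM expressed threshold, the 2-fold / 0.05 gene significance rule,
#' and the 10-fold TE derepression threshold.
#'
#' @param profile_bin_bp Fine resolution for density profiles (1 kb).
#' @param hmm_bin_bp Segmentation resolution (10 kb).
#' @param spike_constant Spike-in scale numerator (30,000).
#' @param n_states HMM states (4).
#' @param hmm_seed,hmm_restarts,hmm_max_iter,hmm_tol HMM fitting controls.
#' @param min_support Consensus replicate support (2 of 3 by default).
#' @param tpm_threshold Expressed threshold in TPM (5).
#' @param gene_fold,alpha Gene differential-expression classification rule
#'   (2-fold, adjusted p < 0.05).
#' @param te_fold TE derepression fold threshold (10).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(profile_bin_bp = 1000,
                            hmm_bin_bp = 10000,
                            spike_constant = 30000,
                            n_states = 4L,
                            hmm_seed = 1L,
                            hmm_restarts = 3L,
                            hmm_max_iter = 100L,
                            hmm_tol = 1e-6,
                            min_support = 2L,
                            tpm_threshold = 5,
                            gene_fold = 2,
                            alpha = 0.05,
                            te_fold = 10) {
  cfg <- list(profile_bin_bp = profile_bin_bp, hmm_bin_bp = hmm_bin_bp,
              spike_constant = spike_constant, n_states = as.integer(n_states),
              hmm_seed = as.integer(hmm_seed),
              hmm_restarts = as.integer(hmm_restarts),
              hmm_max_iter = as.integer(hmm_max_iter), hmm_tol = hmm_tol,
              min_support = as.integer(min_support),
              tpm_threshold = tpm_threshold, gene_fold = gene_fold,
              alpha = alpha, te_fold = te_fold)
  num <- unlist(cfg[c("profile_bin_bp", "hmm_bin_bp", "spike_constant",
                      "n_states", "min_support", "tpm_threshold",
                      "gene_fold", "alpha", "te_fold")])
  if (any(num <= 0)) stop("all thresholds must be positive")
  structure(cfg, class = "analysis_config")
}

#' Call consensus domains for one condition from raw replicate tracks
#'
#' Spike-in-normalizes each replicate track, fits a per-replicate HMM at
#' the segmentation bin size, Viterbi-decodes, labels states by emission
#' mean, segments class1/class2 domains, and merges replicates into a
#' consensus with the configured support rule.
#'
#' @param libs List of `list(track, spike_reads)` pairs (one per
#'   replicate), as produced by [simulate_tracks()] or assembled from
#'   bedGraph input.
#' @param analysis An [analysis_config()].
#' @return List with `consensus` (domain set), `replicate_domains`,
#'   `models`, `partition`, `normalized` (tracks) and `averaged` (track).
#' @export
call_condition_domains <- function(libs, analysis = analysis_config()) {
  norm <- lapply(libs, function(lib)
    normalize_track(lib$track,
                    compute_scale_factor(lib$spike_reads,
                                         analysis$spike_constant)))
  norm10 <- lapply(norm, function(t)
    if (t$bin_size == analysis$hmm_bin_bp) t else rebin(t, analysis$hmm_bin_bp))
  models <- list()
  doms <- list()
  for (j in seq_along(norm10)) {
    m <- fit_hmm(norm10[[j]], n_states = analysis$n_states,
                 seed = analysis$hmm_seed + j,
                 max_iter = analysis$hmm_max_iter, tol = analysis$hmm_tol,
                 n_restarts = analysis$hmm_restarts)
    path <- decode_states(m, norm10[[j]])
    doms[[j]] <- segment_domains(path, label_states(m))
    models[[j]] <- m
  }
  part <- multi_intersect(doms)
  list(consensus = consensus_filter(part, analysis$min_support),
       replicate_domains = doms, models = models, partition = part,
       normalized = norm, averaged = average_replicates(norm))
}

#' Run the full synthetic-data pipeline
#'
#' Generates planted truth, simulates spike-in-controlled replicate tracks
#' for both conditions, calls per-condition consensus domains, computes
#' domain statistics and cross-condition sharing, simulates count tables,
#' computes TPM, gene assignment, expressed fractions and gene flow
#' between conditions, calls derepressed TE copies, and contrasts H3K9me2
#' on affected versus unaffected copies. Deterministic given the seeds in
#' `synth` and `analysis`.
#'
#' @param synth A [synth_config()].
#' @param analysis An [analysis_config()].
#' @param out_dir Optional directory; when given, stage outputs (domain
#'   BEDs, stats TSVs, the truth manifest and a run manifest) are written
#'   there.
#' @param depth Optional per-sample RNA depth multipliers, passed to
#'   [simulate_counts()].
#' @return A list of stage results (see Details in the package vignette).
#' @export
run_pipeline <- function(synth = synth_config(), analysis = analysis_config(),
                         out_dir = NULL, depth = NULL) {
  truth <- generate_truth(synth)
  conditions <- truth$conditions

  domain_calls <- list()
  for (cond in conditions) {
    libs <- simulate_tracks(truth, cond,
                            spike_constant = analysis$spike_constant)
    domain_calls[[cond]] <- call_condition_domains(libs, analysis)
  }
  stats <- lapply(domain_calls, function(dc)
    domain_stats(dc$consensus, truth$layout))
  sharing <- condition_sharing(lapply(domain_calls, `[[`, "consensus"))
  jaccard <- vapply(domain_calls, function(dc)
    interval_jaccard(dc$consensus, truth$domains), numeric(1))

  counts <- simulate_counts(truth, depth = depth)
  tpm_mat <- tpm(counts$genes, truth$genes)
  assignments <- lapply(domain_calls, function(dc)
    assign_genes(truth$genes, dc$consensus))
  expressed <- lapply(conditions, function(cond)
    expressed_fraction(assignments[[cond]], tpm_mat, counts$genes,
                       if (cond == "wild-type") "wild-type" else "mutant",
                       threshold = analysis$tpm_threshold))
  names(expressed) <- conditions
  flow <- domain_flow(assignments[[1]], assignments[[2]])

  te_calls <- call_derepressed(truth$te, counts$te, "wild-type", "mutant",
                               fold_threshold = analysis$te_fold,
                               alpha = analysis$alpha)
  k9 <- simulate_te_k9_counts(truth, "wild-type")
  k9_cmp <- if (all(c("up", "unchanged") %in% te_calls$called))
    k9_on_copy_sets(k9, te_calls, "wild-type") else NULL

  res <- list(truth = truth, domain_calls = domain_calls, stats = stats,
              sharing = sharing, jaccard = jaccard, counts = counts,
              tpm = tpm_mat, assignments = assignments,
              expressed = expressed, flow = flow, te_calls = te_calls,
              k9_comparison = k9_cmp,
              manifest = list(package_version =
                                as.character(utils::packageVersion("perichrom")),
                              seed = synth$seed,
                              analysis = unclass(analysis),
                              synth = unclass(synth),
                              timestamp = format(Sys.time(), tz = "UTC")))
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

#' @keywords internal
.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_chrom_sizes(res$truth$layout, file.path(out_dir, "chrom.sizes"))
  write_truth_manifest(res$truth, file.path(out_dir, "truth.json"))
  write_domain_bed(res$truth$domains,
                   file.path(out_dir, "planted_domains.bed"))
  for (cond in names(res$domain_calls)) {
    dc <- res$domain_calls[[cond]]
    safe <- gsub("[^A-Za-z0-9]+", "_", cond)
    write_domain_bed(dc$consensus,
                     file.path(out_dir, paste0(safe, "_consensus.bed")))
    write_support_table(dc$partition,
                        file.path(out_dir, paste0(safe, "_support.tsv")))
    write_bedgraph(dc$averaged,
                   file.path(out_dir, paste0(safe, "_averaged.bedgraph")))
    for (j in seq_along(dc$models))
      write_hmm_json(dc$models[[j]],
                     file.path(out_dir, sprintf("%s_rep%d_hmm.json", safe, j)))
  }
  write_sharing_table(res$sharing, file.path(out_dir, "sharing.tsv"))
  utils::write.table(res$te_calls, file.path(out_dir, "te_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_counts_tsv(res$counts$genes, file.path(out_dir, "gene_counts.tsv"))
  write_counts_tsv(res$counts$te, file.path(out_dir, "te_counts.tsv"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
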