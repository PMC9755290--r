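#' Configuration for an end-to-end testbed run
#'
#' Bundles the cohort configurations, feature options, selection method,
#' classifier specification and seeds of one reproducible run. Stage seeds
#' are derived deterministically from the master seed.
#'
#' @param train_config \code{cohort_config} of the training regime.
#' @param val_configs list of validation \code{cohort_config}s.
#' @param opts a \code{feature_opts}.
#' @param selection \code{"lmm"}, \code{"pca"}, or both.
#' @param spec an \code{rlr_spec}.
#' @param n_boot bootstrap resamples for AUC CIs (0 disables).
#' @param decompose logical; run the PermEn surrogate decomposition on the
#'   training cohort.
#' @param decomp_surrogates,decomp_segments,decomp_channel decomposition
#'   settings (surrogates per term, segments per condition, channel index).
#' @param seed master seed.
#' @param out_dir optional output directory for CSV tables.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(train_config, val_configs, opts = feature_opts(),
                       selection = c("lmm", "pca"), spec = rlr_spec(),
                       n_boot = 0, decompose = FALSE,
                       decomp_surrogates = 200, decomp_segments = 20,
                       decomp_channel = 10, seed = 1, out_dir = NULL) {
  structure(list(train_config = train_config, val_configs = val_configs,
                 opts = opts, selection = match.arg(selection, several.ok = TRUE),
                 spec = spec, n_boot = n_boot, decompose = decompose,
                 decomp_surrogates = decomp_surrogates,
                 decomp_segments = decomp_segments,
                 decomp_channel = decomp_channel,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# matched entropy-vs-spectral comparisons of the head-to-head design
matched_comparisons <- function() {
  list(c(entropy = "fcEntropy", spectral = "fcSpectral"),
       c(entropy = "scEntropy", spectral = "scSpectralA"),
       c(entropy = "scEntropy", spectral = "scSpectralR"))
}

#' Run the full testbed pipeline
#'
#' Synthesize (or accept) recordings, preprocess, extract features, z-score
#' pooled across cohorts, select features on the training cohort, train one
#' regularized classifier per feature category, evaluate on the training and
#' validation cohorts, compare matched entropy-versus-spectral AUCs with the
#' Mann-Whitney z machinery under FDR control, and optionally decompose the
#' training cohort's PermEn changes into amplitude and non-amplitude parts.
#'
#' @param config a \code{run_config}.
#' @param records optional pre-generated list of \code{eeg_record}s (skips
#'   synthesis).
#' @param progress print stage messages.
#' @return list with \code{manifest}, \code{features} (z-scored table),
#'   \code{selection}, \code{models}, \code{performance} (data.frame),
#'   \code{comparisons} (data.frame), and optionally \code{decomposition} and
#'   \code{decomposition_stats}.
#' @export
run_pipeline <- function(config, records = NULL, progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  set.seed(config$seed %% 2000000011)
  stage_seeds <- sample.int(2000000000L, 8)
  tryCatch({
    if (is.null(records)) {
      say("stage synth: generating %d + %d cohorts",
          1, length(config$val_configs))
      ds <- generate_dataset(config$train_config, config$val_configs,
                             seed = stage_seeds[1])
      records <- ds$records
      manifest <- ds$manifest
    } else {
      manifest <- data.frame(
        recording_id = paste(vapply(records, `[[`, "", "participant_id"),
                             vapply(records, `[[`, "", "state"), sep = "_"),
        participant_id = vapply(records, `[[`, "", "participant_id"),
        cohort = vapply(records, `[[`, "", "cohort"),
        state = vapply(records, `[[`, "", "state"),
        seed = NA_integer_, stringsAsFactors = FALSE)
    }
  }, error = function(e) stop("pipeline stage 'synth' failed: ",
                              conditionMessage(e)))
  say("stage preprocess+features: %d records", length(records))
  feats <- tryCatch(
    feature_table(records, config$opts, preprocess = TRUE,
                  progress = progress),
    error = function(e) stop("pipeline stage 'features' failed: ",
                             conditionMessage(e)))
  feats <- tryCatch(zscore_pooled(feats),
                    error = function(e) stop("pipeline stage 'zscore' failed: ",
                                             conditionMessage(e)))
  train_cohort <- config$train_config$regime
  cohorts <- unique(feats$cohort)
  selections <- tryCatch({
    sl <- list()
    if ("lmm" %in% config$selection)
      sl$LMM <- lmm_select(feats, train_cohort)
    if ("pca" %in% config$selection)
      sl$PCA <- suppressWarnings(pca_select(feats, train_cohort))
    sl
  }, error = function(e) stop("pipeline stage 'select' failed: ",
                              conditionMessage(e)))
  cats <- intersect(unique(canonical_features()$category),
                    config$opts$categories)
  perf <- list(); models <- list(); comps <- list()
  tr_rows <- feats$cohort == train_cohort
  for (sel_name in names(selections)) {
    sel <- selections[[sel_name]]
    for (cat in cats) {
      X <- tryCatch(apply_selection(sel, feats, cat), error = function(e) NULL)
      if (is.null(X) || ncol(X) == 0) next
      model <- tryCatch(
        fit_rlr(X[tr_rows, , drop = FALSE], feats$state[tr_rows],
                feats$participant_id[tr_rows], config$spec,
                seed = stage_seeds[2]),
        error = function(e) stop("pipeline stage 'classify' failed (", cat,
                                 "): ", conditionMessage(e)))
      models[[paste(sel_name, cat, sep = ".")]] <- model
      for (ch in cohorts) {
        rows <- feats$cohort == ch
        sc <- rlr_scores(model, X[rows, , drop = FALSE])
        r <- evaluate(sc, feats$state[rows])
        N <- sum(feats$state[rows] == "wake")
        zz <- auc_to_z(r$auc, N)
        ci <- c(NA_real_, NA_real_)
        if (config$n_boot > 0) {
          bb <- bootstrap_auc(sc, feats$state[rows],
                              feats$participant_id[rows],
                              n_boot = config$n_boot, seed = stage_seeds[3])
          ci <- bb$ci
        }
        perf[[length(perf) + 1]] <- data.frame(
          selection = sel_name, category = cat, cohort = ch,
          role = if (ch == train_cohort) "train" else "validation",
          auc = r$auc, accuracy = r$accuracy, precision = r$precision,
          recall = r$recall, specificity = r$specificity, N = N,
          z = zz$z, p_vs_chance = zz$p_one_tailed,
          ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
      }
    }
  }
  performance <- do.call(rbind, perf)
  for (sel_name in names(selections)) {
    for (cmp in matched_comparisons()) {
      for (ch in cohorts) {
        p1 <- performance[performance$selection == sel_name &
                          performance$category == cmp["entropy"] &
                          performance$cohort == ch, ]
        p2 <- performance[performance$selection == sel_name &
                          performance$category == cmp["spectral"] &
                          performance$cohort == ch, ]
        if (!nrow(p1) || !nrow(p2)) next
        if (p1$N <= 3 || p2$N <= 3) next  # z' undefined at N <= 3
        cc <- compare_aucs(p1$z, p1$N, p2$z, p2$N)
        comps[[length(comps) + 1]] <- data.frame(
          selection = sel_name, cohort = ch,
          comparison = paste(cmp["entropy"], "vs", cmp["spectral"]),
          auc_entropy = p1$auc, auc_spectral = p2$auc,
          z_prime = cc$z_prime, p = cc$p_two_tailed, stringsAsFactors = FALSE)
      }
    }
  }
  comparisons <- if (length(comps)) do.call(rbind, comps) else NULL
  if (!is.null(comparisons)) {
    fdr <- fdr_bh(comparisons$p)
    comparisons$p_fdr <- fdr$p_adjusted
    comparisons$significant <- fdr$rejected
  }
  out <- list(manifest = manifest, features = feats, selection = selections,
              models = models, performance = performance,
              comparisons = comparisons)
  if (config$decompose) {
    say("stage decompose: training cohort")
    out$decomposition <- tryCatch(
      pipeline_decomposition(records, train_cohort, config, stage_seeds[4]),
      error = function(e) stop("pipeline stage 'decompose' failed: ",
                               conditionMessage(e)))
    out$decomposition_stats <- component_stats(out$decomposition)
  }
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

pipeline_decomposition <- function(records, train_cohort, config, seed) {
  set.seed(seed %% 2000000011)
  res <- list()
  for (rec_pair in split(records, vapply(records, `[[`, "", "participant_id"))) {
    coh <- rec_pair[[1]]$cohort
    if (coh != train_cohort) next
    states <- vapply(rec_pair, `[[`, "", "state")
    wk <- rec_pair[[which(states == "wake")]]
    sl <- rec_pair[[which(states == "nrem")]]
    wk <- downsample(average_reference(bandpass(wk)), 125)
    sl <- downsample(average_reference(bandpass(sl)), 125)
    ws <- draw_segments(wk, config$decomp_channel, config$decomp_segments)
    ss <- draw_segments(sl, config$decomp_channel, config$decomp_segments)
    dc <- decompose_permen(ws, ss, taus_ms = config$opts$taus_ms,
                           n_surrogates = config$decomp_surrogates,
                           seed = sample.int(2000000000L, 1))
    dc$participant_id <- wk$participant_id
    res[[length(res) + 1]] <- dc
  }
  do.call(rbind, res)
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines("# eegstates table schema v1", con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wr(out$manifest, "manifest.csv")
  wr(out$features, "features.csv")
  wr(out$performance, "performance.csv")
  if (!is.null(out$comparisons)) wr(out$comparisons, "comparisons.csv")
  if (!is.null(out$decomposition)) wr(out$decomposition, "decomposition.csv")
  if (!is.null(out$decomposition_stats))
    wr(out$decomposition_stats, "decomposition_stats.csv")
  invisible(dir)
}
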