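#' Pooled z-scoring of a feature table
#'
#' Column-wise standardization (SD with denominator n-1) over all rows, i.e.
#' pooled across cohorts and states.
#'
#' @param table a \code{feature_table}.
#' @return the table with standardized feature columns.
#' @export
zscore_pooled <- function(table) {
  if (nrow(table) < 2) stop("zscore_pooled: need at least 2 rows")
  for (cn in feature_columns(table)) {
    v <- table[[cn]]
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("zscore_pooled: zero-variance feature column '", cn, "'")
    table[[cn]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  table
}

#' Mixed-model feature selection
#'
#' For each feature (z-scored) in the training cohort, fits the linear mixed
#' model \code{feature ~ state + (1 | participant)} (REML) with NREM sleep
#' coded 1 and wakefulness 0, and selects features with |beta_state| strictly
#' greater than the threshold, within each category. Singular fits fall back
#' to the paired within-participant mean difference (flagged).
#'
#' @param table a z-scored \code{feature_table}.
#' @param training_cohort cohort label used for fitting.
#' @param threshold selection threshold on |beta|.
#' @return list of class \code{selection_result} with \code{method = "LMM"},
#'   \code{betas} (named), \code{selected} (names by category), and
#'   \code{fallback} flags.
#' @export
lmm_select <- function(table, training_cohort, threshold = 0.5) {
  tr <- table[table$cohort == training_cohort, , drop = FALSE]
  if (!nrow(tr)) stop("lmm_select: no rows for cohort ", training_cohort)
  feats <- feature_columns(tr)
  state01 <- as.numeric(tr$state == "nrem")
  betas <- stats::setNames(rep(NA_real_, length(feats)), feats)
  fallback <- stats::setNames(rep(FALSE, length(feats)), feats)
  for (fn in feats) {
    df <- data.frame(y = tr[[fn]], state01 = state01,
                     participant = tr$participant_id)
    df <- df[is.finite(df$y), , drop = FALSE]
    b <- tryCatch({
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(y ~ state01 + (1 | participant), data = df, REML = TRUE)))
      if (lme4::isSingular(fit)) stop("singular")
      unname(lme4::fixef(fit)["state01"])
    }, error = function(e) NA_real_)
    if (is.na(b)) {
      # paired-difference fallback: mean within-participant (nrem - wake)
      wk <- tapply(df$y[df$state01 == 0], df$participant[df$state01 == 0], mean)
      sl <- tapply(df$y[df$state01 == 1], df$participant[df$state01 == 1], mean)
      common <- intersect(names(wk), names(sl))
      b <- mean(sl[common] - wk[common])
      fallback[fn] <- TRUE
    }
    betas[fn] <- b
  }
  catmap <- canonical_features()
  selected <- lapply(split(catmap$name, catmap$category), function(nm) {
    nm <- intersect(nm, feats)
    nm[abs(betas[nm]) > threshold & !is.na(betas[nm])]
  })
  structure(list(method = "LMM", betas = betas, selected = selected,
                 threshold = threshold, fallback = fallback,
                 training_cohort = training_cohort),
            class = "selection_result")
}

#' Principal-component feature selection on the wake-sleep contrast
#'
#' Per category: participant-level wake minus sleep difference vectors from
#' the training cohort are decomposed by PCA (covariance of mean-centred
#' differences; features are already z-scored); the smallest number of
#' components explaining at least \code{var_threshold} of the variance is
#' retained. State-level feature vectors are later projected onto the
#' loadings via \code{\link{apply_selection}}.
#'
#' @param table a z-scored \code{feature_table}.
#' @param training_cohort cohort label used for fitting.
#' @param var_threshold cumulative explained-variance target.
#' @return list of class \code{selection_result} with \code{method = "PCA"}
#'   and per-category loadings, normalized eigenvalues and \code{k}.
#' @export
pca_select <- function(table, training_cohort, var_threshold = 0.90) {
  tr <- table[table$cohort == training_cohort, , drop = FALSE]
  if (!nrow(tr)) stop("pca_select: no rows for cohort ", training_cohort)
  feats <- feature_columns(tr)
  catmap <- canonical_features()
  cats <- split(intersect(catmap$name, feats),
                catmap$category[catmap$name %in% feats])
  wk <- tr[tr$state == "wake", , drop = FALSE]
  sl <- tr[tr$state == "nrem", , drop = FALSE]
  common <- intersect(wk$participant_id, sl$participant_id)
  if (length(common) < 2)
    stop("pca_select: need wake and sleep rows for at least 2 participants")
  per_cat <- list()
  for (cat in names(cats)) {
    nm <- cats[[cat]]
    dmat <- sapply(nm, function(fn) {
      w <- tapply(wk[[fn]], wk$participant_id, mean)[common]
      s <- tapply(sl[[fn]], sl$participant_id, mean)[common]
      w - s
    })
    dmat <- as.matrix(dmat)
    dmat <- dmat[stats::complete.cases(dmat), , drop = FALSE]
    pc <- stats::prcomp(dmat, center = TRUE, scale. = FALSE)
    ev <- pc$sdev ^ 2
    evn <- ev / sum(ev)
    k <- which(cumsum(evn) >= var_threshold)[1]
    flag_all <- FALSE
    if (is.na(k)) { k <- length(evn); flag_all <- TRUE }
    if (k < 2 || k > 5)
      warning(sprintf("pca_select: %d component(s) for %s (2-5 expected)",
                      k, cat))
    per_cat[[cat]] <- list(loadings = pc$rotation[, seq_len(k), drop = FALSE],
                           eigenvalues = evn, k = k, features = nm,
                           flag_all = flag_all)
  }
  structure(list(method = "PCA", per_category = per_cat,
                 var_threshold = var_threshold,
                 training_cohort = training_cohort),
            class = "selection_result")
}

#' Build a classifier design matrix from a selection result
#'
#' LMM path: the selected feature columns of the category. PCA path: the
#' category's z-scored features projected onto the stored loadings.
#'
#' @param selection a \code{selection_result}.
#' @param table a z-scored \code{feature_table}.
#' @param category feature category.
#' @return numeric matrix with one row per table row (possibly 0 columns when
#'   nothing was selected).
#' @export
apply_selection <- function(selection, table, category) {
  if (selection$method == "LMM") {
    nm <- selection$selected[[category]]
    as.matrix(table[, nm, drop = FALSE])
  } else {
    pc <- selection$per_category[[category]]
    X <- as.matrix(table[, pc$features, drop = FALSE])
    X %*% pc$loadings
  }
}

#' Influence of usable data length on features
#'
#' Per feature, fits \code{feature ~ cohort + state + length + (1 |
#' participant)} and reports the usable-length coefficient with a
#' likelihood-ratio p-value and a Benjamini-Hochberg FDR flag.
#'
#' @param table a \code{feature_table} (z-scored or raw).
#' @param q FDR level.
#' @return data.frame: feature, beta_length, p, p_fdr, significant.
#' @export
length_robustness <- function(table, q = 0.05) {
  feats <- feature_columns(table)
  res <- data.frame(feature = feats, beta_length = NA_real_, p = NA_real_)
  for (i in seq_along(feats)) {
    df <- data.frame(y = table[[feats[i]]],
                     cohort = factor(table$cohort),
                     state01 = as.numeric(table$state == "nrem"),
                     len = as.numeric(scale(table$usable_length_s)),
                     participant = table$participant_id)
    df <- df[is.finite(df$y), , drop = FALSE]
    f1 <- if (nlevels(df$cohort) > 1)
      y ~ cohort + state01 + len + (1 | participant)
    else y ~ state01 + len + (1 | participant)
    f0 <- if (nlevels(df$cohort) > 1)
      y ~ cohort + state01 + (1 | participant)
    else y ~ state01 + (1 | participant)
    fit <- tryCatch({
      m1 <- suppressWarnings(suppressMessages(
        lme4::lmer(f1, data = df, REML = FALSE)))
      m0 <- suppressWarnings(suppressMessages(
        lme4::lmer(f0, data = df, REML = FALSE)))
      an <- stats::anova(m0, m1)
      list(beta = unname(lme4::fixef(m1)["len"]),
           p = an[["Pr(>Chisq)"]][2])
    }, error = function(e) list(beta = NA_real_, p = NA_real_))
    res$beta_length[i] <- fit$beta
    res$p[i] <- fit$p
  }
  ok <- is.finite(res$p)
  res$p_fdr <- NA_real_
  res$p_fdr[ok] <- fdr_bh(res$p[ok], q)$p_adjusted
  res$significant <- !is.na(res$p_fdr) & res$p_fdr < q
  res
}
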