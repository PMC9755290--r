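#' Regularized logistic regression specification
#'
#' 100 logarithmically spaced penalty values between 4.4e-5 and 0.44, chosen
#' by grouped k-fold cross-validation (both state rows of a participant stay
#' on the same side of every partition). The penalty type defaults to L1;
#' set \code{alpha = 0} for L2.
#'
#' @param lambda_grid penalty grid.
#' @param cv_folds number of folds (10 conventional, 5 optional).
#' @param alpha glmnet elastic-net mixing (1 = lasso, 0 = ridge).
#' @return list of class \code{rlr_spec}.
#' @export
rlr_spec <- function(lambda_grid = exp(seq(log(4.4e-5), log(0.44),
                                           length.out = 100)),
                     cv_folds = 10, alpha = 1) {
  structure(list(lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 cv_folds = as.integer(cv_folds), alpha = alpha),
            class = "rlr_spec")
}

#' Fit a regularized logistic-regression classifier
#'
#' Chooses lambda by grouped cross-validated binomial deviance on the
#' training rows, then refits on all training rows at the chosen lambda.
#' Wakefulness is the positive class. With a single predictor column the
#' model falls back to an unpenalized logistic fit (flagged).
#'
#' @param x numeric design matrix (training rows).
#' @param y state labels ("wake"/"nrem") or 0/1 with wake = 1.
#' @param participants grouping vector for the folds.
#' @param spec an \code{rlr_spec}.
#' @param seed integer seed for the fold assignment.
#' @return list of class \code{rlr_model}.
#' @export
fit_rlr <- function(x, y, participants, spec = rlr_spec(), seed = 1) {
  x <- as.matrix(x)
  if (is.character(y) || is.factor(y)) y <- as.numeric(as.character(y) == "wake")
  if (length(unique(y)) < 2) stop("fit_rlr: training data contain one class")
  keep <- stats::complete.cases(x) & is.finite(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  participants <- participants[keep]
  if (ncol(x) == 1) {
    fit <- stats::glm.fit(cbind(1, x), y, family = stats::binomial())
    return(structure(list(kind = "glm", coef = fit$coefficients,
                          lambda = NA_real_, flag_unpenalized = TRUE),
                     class = "rlr_model"))
  }
  set.seed(seed %% 2000000011)
  ids <- unique(participants)
  fold_of_id <- stats::setNames(
    rep_len(sample(spec$cv_folds), length(ids)), sample(ids))
  foldid <- as.integer(fold_of_id[as.character(participants)])
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = spec$alpha,
                          lambda = spec$lambda_grid, foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  lam <- cv$lambda.min
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = spec$alpha,
                        lambda = spec$lambda_grid, standardize = FALSE)
  structure(list(kind = "glmnet", fit = fit, lambda = lam, cv = cv,
                 flag_unpenalized = FALSE),
            class = "rlr_model")
}

#' Classifier scores (log-odds of wakefulness)
#' @param model an \code{rlr_model} or \code{univariate} model.
#' @param x design matrix.
#' @return numeric vector of linear-predictor scores.
#' @export
rlr_scores <- function(model, x) {
  x <- as.matrix(x)
  if (model$kind == "glm") {
    as.numeric(cbind(1, x) %*% model$coef)
  } else {
    as.numeric(stats::predict(model$fit, x, s = model$lambda, type = "link"))
  }
}

#' ROC curve, AUC, and operating-point metrics
#'
#' ROC from continuous scores with wakefulness as the positive class; AUC by
#' the trapezoid rule (equivalently the Mann-Whitney statistic); accuracy,
#' precision, recall and specificity at the Youden-J-optimal operating point.
#'
#' @param scores numeric scores (higher = more wake-like), or an
#'   \code{rlr_model} together with \code{x}.
#' @param y labels ("wake"/"nrem" or 1/0 with wake = 1).
#' @param x design matrix when \code{scores} is a model.
#' @return list of class \code{roc_result}.
#' @export
evaluate <- function(scores, y, x = NULL) {
  if (inherits(scores, "rlr_model")) scores <- rlr_scores(scores, x)
  if (is.character(y) || is.factor(y)) y <- as.numeric(as.character(y) == "wake")
  ok <- is.finite(scores) & is.finite(y)
  scores <- scores[ok]; y <- y[ok]
  if (length(unique(y)) < 2) stop("evaluate: need both classes")
  np <- sum(y == 1); nn <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys == 1); fp <- cumsum(ys == 0)
  # collapse tied thresholds
  last <- c(diff(ss) != 0, TRUE)
  tpr <- c(0, tp[last] / np); fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- tpr - fpr
  jbest <- which.max(j)
  thr_idx <- which(last)[max(1, jbest - 1)]
  thr <- if (jbest == 1) Inf else ss[thr_idx]
  pred <- as.numeric(scores >= thr)
  tp1 <- sum(pred == 1 & y == 1); fp1 <- sum(pred == 1 & y == 0)
  tn1 <- sum(pred == 0 & y == 0); fn1 <- sum(pred == 0 & y == 1)
  structure(list(fpr = fpr, tpr = tpr, auc = auc, threshold = thr,
                 accuracy = (tp1 + tn1) / length(y),
                 precision = if (tp1 + fp1 > 0) tp1 / (tp1 + fp1) else NA_real_,
                 recall = tp1 / (tp1 + fn1),
                 specificity = tn1 / (tn1 + fp1),
                 n_per_class = c(wake = np, nrem = nn)),
            class = "roc_result")
}

#' Participant-level BCa bootstrap confidence interval for the AUC
#'
#' Resamples participants with replacement (a participant's wake and sleep
#' rows move together), recomputes the AUC of fixed scores per resample, and
#' forms a bias-corrected and accelerated percentile interval (acceleration
#' from a participant-level jackknife). Degenerate resamples with one class
#' are redrawn and counted.
#'
#' @param scores numeric scores (fixed model; the model is not refit).
#' @param y labels (wake positive).
#' @param participants participant ids aligned with rows.
#' @param n_boot number of resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with \code{auc}, \code{ci} (lo, hi), \code{boot} (resampled
#'   AUCs), \code{n_redrawn}.
#' @export
bootstrap_auc <- function(scores, y, participants, n_boot = 10000,
                          level = 0.95, seed = 1) {
  if (is.character(y) || is.factor(y)) y <- as.numeric(as.character(y) == "wake")
  set.seed(seed %% 2000000011)
  ids <- unique(participants)
  if (length(ids) < 5) stop("bootstrap_auc: need >= 5 participants")
  rows_of <- split(seq_along(participants), participants)
  obs <- fast_auc(scores, y)
  boot <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      take <- sample(ids, length(ids), replace = TRUE)
      idx <- unlist(rows_of[take], use.names = FALSE)
      if (length(unique(y[idx])) == 2) break
      n_redrawn <- n_redrawn + 1L
    }
    boot[b] <- fast_auc(scores[idx], y[idx])
  }
  alpha <- (1 - level) / 2
  if (stats::sd(boot) == 0) {
    ci <- c(boot[1], boot[1])
  } else {
    z0 <- stats::qnorm((sum(boot < obs) + 0.5 * sum(boot == obs)) / n_boot)
    jack <- vapply(ids, function(id) {
      idx <- unlist(rows_of[setdiff(ids, id)], use.names = FALSE)
      if (length(unique(y[idx])) < 2) return(NA_real_)
      fast_auc(scores[idx], y[idx])
    }, numeric(1))
    jack <- jack[is.finite(jack)]
    jm <- mean(jack)
    num <- sum((jm - jack) ^ 3)
    den <- 6 * (sum((jm - jack) ^ 2)) ^ 1.5
    a <- if (den > 0) num / den else 0
    zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
    p1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
    p2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
    ci <- unname(stats::quantile(boot, c(p1, p2), na.rm = TRUE, type = 6))
  }
  list(auc = obs, ci = ci, boot = boot, n_redrawn = n_redrawn)
}

# rank-based AUC (Mann-Whitney form)
fast_auc <- function(scores, y) {
  r <- rank(scores)
  np <- sum(y == 1); nn <- sum(y == 0)
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' AUC to Mann-Whitney z-score (balanced design)
#'
#' Uses the printed convention U = AUC * N^2 and
#' z = (U - N^2/2) / sqrt(N^2 (N^2 + 1) / 12) for N observations per class.
#' Note this variance differs from the classical Mann-Whitney normal
#' approximation N^2 (2N + 1) / 12, which is available via
#' \code{variance = "classical"}; the two are not asserted equivalent.
#'
#' @param auc area under the ROC curve.
#' @param N per-class sample size (balanced design).
#' @param variance \code{"printed"} (default) or \code{"classical"}.
#' @return list with \code{U}, \code{z}, \code{p_one_tailed}.
#' @export
auc_to_z <- function(auc, N, variance = c("printed", "classical")) {
  variance <- match.arg(variance)
  if (N < 2) stop("auc_to_z: N must be >= 2")
  U <- auc * N ^ 2
  v <- switch(variance,
              printed = N ^ 2 * (N ^ 2 + 1) / 12,
              classical = N ^ 2 * (2 * N + 1) / 12)
  z <- (U - N ^ 2 / 2) / sqrt(v)
  list(U = U, z = z, p_one_tailed = stats::pnorm(z, lower.tail = FALSE))
}

#' Compare two AUC-derived z-scores
#'
#' z' = (z1 - z2) / sqrt(1/(N1 - 3) + 1/(N2 - 3)) with a two-tailed normal
#' p-value; valid as a significance test when N1 = N2.
#'
#' @param z1,z2 z-scores from \code{\link{auc_to_z}}.
#' @param N1,N2 per-class sample sizes.
#' @return list of class \code{auc_comparison}.
#' @export
compare_aucs <- function(z1, N1, z2, N2) {
  if (N1 <= 3 || N2 <= 3) stop("compare_aucs: N must exceed 3")
  if (N1 != N2)
    warning("compare_aucs: the z' test is only calibrated for N1 = N2")
  zp <- (z1 - z2) / sqrt(1 / (N1 - 3) + 1 / (N2 - 3))
  structure(list(z1 = z1, z2 = z2, z_prime = zp,
                 p_two_tailed = 2 * stats::pnorm(-abs(zp))),
            class = "auc_comparison")
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' The linear step-up procedure: adjusted p-values are p * m / rank with a
#' running minimum from the largest rank down, and hypotheses with adjusted
#' p below \code{q} are rejected.
#'
#' @param p_values vector of p-values in [0, 1].
#' @param q FDR level.
#' @return list with \code{p_adjusted} and logical \code{rejected}.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("fdr_bh: p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  adj <- p_values[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  list(p_adjusted = out, rejected = out < q)
}

#' Univariate (unregularized) per-feature classifiers
#'
#' One unpenalized logistic model per feature, fitted on the training cohort
#' and evaluated on every cohort in the table. Complete separation is handled
#' with a tiny ridge penalty (flagged).
#'
#' @param table a z-scored \code{feature_table}.
#' @param training_cohort cohort label for fitting.
#' @return data.frame: feature, cohort, auc, accuracy, precision, recall,
#'   specificity, flag_ridge.
#' @export
univariate_models <- function(table, training_cohort) {
  feats <- feature_columns(table)
  tr <- table[table$cohort == training_cohort, , drop = FALSE]
  cohorts <- unique(table$cohort)
  out <- list()
  for (fn in feats) {
    xtr <- tr[[fn]]; ytr <- as.numeric(tr$state == "wake")
    ok <- is.finite(xtr)
    flag <- FALSE
    fit <- suppressWarnings(stats::glm(ytr[ok] ~ xtr[ok],
                                       family = stats::binomial()))
    co <- stats::coef(fit)
    if (!all(is.finite(co)) || abs(co[2]) > 50) {
      # separation: refit with a whisper of ridge
      flag <- TRUE
      xm <- cbind(xtr[ok], 0)
      g <- glmnet::glmnet(xm, ytr[ok], family = "binomial", alpha = 0,
                          lambda = 1e-4, standardize = FALSE)
      co <- c(g$a0, as.numeric(g$beta)[1])
    }
    for (ch in cohorts) {
      ev <- table[table$cohort == ch, , drop = FALSE]
      sc <- co[1] + co[2] * ev[[fn]]
      r <- evaluate(sc, ev$state)
      out[[length(out) + 1]] <- data.frame(
        feature = fn, cohort = ch, auc = r$auc, accuracy = r$accuracy,
        precision = r$precision, recall = r$recall,
        specificity = r$specificity, flag_ridge = flag,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Features exceeding an AUC threshold in every cohort
#'
#' The set-intersection summary over univariate classifier results.
#'
#' @param uni data.frame from \code{\link{univariate_models}}.
#' @param threshold AUC threshold.
#' @return character vector of feature names.
#' @export
auc_intersection <- function(uni, threshold = 0.9) {
  byf <- split(uni$auc, uni$feature)
  names(byf)[vapply(byf, function(a) all(a >= threshold), logical(1))]
}
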