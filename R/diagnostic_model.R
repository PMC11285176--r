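.as_malignant_indicator <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("benign", "malignant"))
    if (length(bad) > 0)
      stop("labels must be 'benign'/'malignant' (or 0/1); got: ",
           paste(bad, collapse = ", "))
    y <- as.integer(labels == "malignant")
  } else y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  y
}

#' ROC analysis with Youden cutoff
#'
#' Empirical ROC of a score against benign/malignant labels (malignant is
#' the positive class), AUC with DeLong 95\% CI, and the Youden-optimal
#' cutoff reported on the original parameter scale together with
#' sensitivity, specificity and accuracy (percent) at that cutoff.
#'
#' Orientation: `direction = "lower"` declares that lower values indicate
#' malignancy (the behaviour of diffusion coefficients and beta, whose
#' group means are lower in malignant lesions); scores are negated
#' internally and the cutoff mapped back with the "<= cutoff predicts
#' malignant" convention. `"higher"` is the ">= cutoff" convention (mu).
#' `"auto"` (default) picks the direction giving AUC >= 0.5.
#'
#' Cutoffs are evaluated at midpoints between consecutive distinct score
#' values; Youden ties are broken toward the higher specificity.
#'
#' @param scores numeric score vector.
#' @param labels benign/malignant (or 0/1) labels.
#' @param direction "auto", "lower" or "higher".
#' @return object of class `roc_result` with fields auc, auc_ci, cutoff,
#'   sensitivity, specificity, accuracy, direction, n.
#' @export
roc_analysis <- function(scores, labels, direction = c("auto", "lower",
                                                       "higher")) {
  direction <- match.arg(direction)
  y <- .as_malignant_indicator(labels)
  ok <- is.finite(scores)
  scores <- scores[ok]; y <- y[ok]
  if (direction == "auto") {
    # pick the orientation whose AUC is >= 0.5
    auc_higher <- .empirical_auc(scores, y)
    direction <- if (auc_higher >= 0.5) "higher" else "lower"
  }
  s <- if (direction == "lower") -scores else scores
  r <- pROC::roc(response = y, predictor = s, direction = "<",
                 levels = c(0, 1), quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- tryCatch(suppressWarnings(
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]),
    error = function(e) c(NA_real_, NA_real_))
  # Youden scan over midpoints of distinct internal-scale scores
  su <- sort(unique(s))
  cand <- if (length(su) > 1L) (su[-1] + su[-length(su)]) / 2 else su
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  best <- NULL
  for (cth in cand) {
    pred <- s >= cth
    sens <- sum(pred & y == 1L) / n_pos
    spec <- sum(!pred & y == 0L) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(cut = cth, j = j, sens = sens, spec = spec)
    }
  }
  acc <- (best$sens * n_pos + best$spec * n_neg) / (n_pos + n_neg)
  structure(list(
    auc = auc, auc_ci = ci,
    cutoff = if (direction == "lower") -best$cut else best$cut,
    sensitivity = 100 * best$sens, specificity = 100 * best$spec,
    accuracy = 100 * acc, youden = best$j, direction = direction,
    rule = if (direction == "lower") "<= cutoff predicts malignant"
           else ">= cutoff predicts malignant",
    n = length(y)), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (95%% CI %.3f-%.3f), cutoff %.3g (%s)\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$cutoff, x$rule))
  cat(sprintf("  sens %.2f%%, spec %.2f%%, accuracy %.2f%% (n = %d)\n",
              x$sensitivity, x$specificity, x$accuracy, x$n))
  invisible(x)
}

# Mann-Whitney form of the empirical AUC (ties counted 1/2)
.empirical_auc <- function(scores, y) {
  rk <- rank(scores)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(rk[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Operating point at a fixed cutoff
#'
#' Sensitivity, specificity and accuracy (percent) of a score dichotomised
#' at a given cutoff with an explicit decision rule.
#'
#' @param scores numeric scores; @param labels benign/malignant labels.
#' @param cutoff decision threshold on the original scale.
#' @param direction "lower" (`<=` cutoff predicts malignant) or "higher".
#' @return list with sensitivity, specificity, accuracy (percent).
#' @export
operating_point <- function(scores, labels, cutoff,
                            direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  y <- .as_malignant_indicator(labels)
  pred <- if (direction == "lower") scores <= cutoff else scores >= cutoff
  sens <- sum(pred & y == 1L) / sum(y == 1L)
  spec <- sum(!pred & y == 0L) / sum(y == 0L)
  list(sensitivity = 100 * sens, specificity = 100 * spec,
       accuracy = 100 * mean((pred & y == 1L) | (!pred & y == 0L)))
}

#' DeLong test for paired AUC difference
#'
#' Two-sided comparison of the AUCs of two scores measured on the same
#' subjects, using the paired DeLong structural-component covariance.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels benign/malignant labels shared by both scores.
#' @return list with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- .as_malignant_indicator(labels)
  a <- .empirical_auc(scores_a, y)
  b <- .empirical_auc(scores_b, y)
  ra <- pROC::roc(y, scores_a, direction = "auto", levels = c(0, 1),
                  quiet = TRUE)
  rb <- pROC::roc(y, scores_b, direction = "auto", levels = c(0, 1),
                  quiet = TRUE)
  if (isTRUE(all.equal(scores_a, scores_b)))
    return(list(auc_a = a, auc_b = b, z = 0, p = 1))
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  z <- unname(tt$statistic)
  if (!is.finite(z)) stop("degenerate scores: zero DeLong variance")
  list(auc_a = a, auc_b = b, z = z, p = tt$p.value)
}

#' Multivariate logistic model with single-pass selection
#'
#' Maximum-likelihood logistic regression of malignancy on the given
#' features, followed by one exclusion pass: features whose Wald p >= 0.05
#' are dropped and the model refit on the survivors (mirroring the usual
#' one-step exclusion of non-significant diffusion parameters). Perfect
#' separation or collinearity triggers a weakly ridge-penalised fit
#' (lambda = 1e-4, intercept unpenalised) with Wald p from the penalised
#' information matrix, and a warning.
#'
#' @param data data frame holding the feature columns and a `group`
#'   column (benign/malignant) unless `labels` is given.
#' @param features character vector of feature column names.
#' @param labels optional explicit labels overriding `data$group`.
#' @param alpha Wald threshold for retention (default 0.05).
#' @return object of class `logistic_model` with coefficients, wald_p,
#'   retained features, fitted probabilities and the training data.
#' @export
fit_logistic_with_selection <- function(data, features = c("D", "beta", "mu"),
                                        labels = NULL, alpha = 0.05) {
  stopifnot(all(features %in% names(data)))
  y <- .as_malignant_indicator(if (is.null(labels)) data$group else labels)
  X <- as.matrix(data[, features, drop = FALSE])
  full <- .logistic_fit(X, y)
  keep <- features[full$wald_p[features] < alpha]
  final <- if (length(keep) == length(features)) full
           else .logistic_fit(X[, keep, drop = FALSE], y)
  structure(list(
    coefficients = final$coef, wald_p = final$wald_p,
    retained = keep, dropped = setdiff(features, keep),
    full_wald_p = full$wald_p,
    fitted = final$fitted, penalized = final$penalized,
    features = features, data = data[, features, drop = FALSE], y = y),
    class = "logistic_model")
}

# ML fit with ridge fallback on separation/collinearity
.logistic_fit <- function(X, y) {
  nm <- colnames(X)
  fallback <- FALSE
  fit <- NULL
  if (ncol(X) > 0) {
    df <- data.frame(y = y, X)
    wrn <- character()
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        wrn <<- c(wrn, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    sep <- any(grepl("fitted probabilities numerically 0 or 1", wrn)) ||
      !fit$converged || any(is.na(stats::coef(fit))) ||
      any(abs(stats::coef(fit)) > 1e3)
    if (sep) fallback <- TRUE
  }
  if (!fallback && !is.null(fit)) {
    sm <- summary(fit)$coefficients
    co <- stats::coef(fit)
    wp <- sm[, "Pr(>|z|)"]
    names(co) <- names(wp) <- c("(Intercept)", nm)
    return(list(coef = co, wald_p = wp[-1], fitted = stats::fitted(fit),
                penalized = FALSE))
  }
  if (ncol(X) > 0)
    warning("separation or collinearity detected: using a weakly ",
            "ridge-penalised fit (lambda = 1e-4)")
  rf <- .ridge_logistic(X, y, lambda = 1e-4)
  list(coef = rf$coef, wald_p = rf$wald_p, fitted = rf$fitted,
       penalized = TRUE)
}

# ridge-penalised logistic regression by Newton iterations;
# the intercept is not penalised
.ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 200, tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (i in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, Xd * w) + pen
    g <- crossprod(Xd, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(Xd %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(Xd, Xd * w) + pen
  se <- sqrt(diag(solve(H)))
  z <- beta / se
  wald <- 2 * stats::pnorm(-abs(z))
  names(beta) <- names(wald) <- colnames(Xd)
  list(coef = beta, wald_p = wald[-1], fitted = mu)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic model (malignant = 1)\n")
  cat("  retained:", if (length(x$retained)) paste(x$retained,
      collapse = ", ") else "(intercept only)", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.logistic_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- cbind(1, as.matrix(newdata[, object$retained, drop = FALSE]))
  stats::plogis(drop(X %*% object$coefficients))
}

#' ROC of a fitted logistic model
#'
#' ROC analysis on the model's predicted malignancy probabilities; the
#' cutoff is reported on the probability scale (higher probability
#' predicts malignant).
#'
#' @param model a [fit_logistic_with_selection()] fit.
#' @param data optional data frame to predict on (default: training data,
#'   with the training labels).
#' @param labels labels for `data` when supplied.
#' @return a `roc_result`.
#' @export
combined_roc <- function(model, data = NULL, labels = NULL) {
  stopifnot(inherits(model, "logistic_model"))
  if (is.null(data)) {
    p <- model$fitted; y <- model$y
  } else {
    p <- predict(model, data)
    y <- .as_malignant_indicator(labels)
  }
  roc_analysis(p, y, direction = "higher")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Chi-square comparison of observed and predicted event counts over g
#' risk bins (deciles of predicted probability by default), with g - 2
#' degrees of freedom. Bins left empty by tied probabilities are merged
#' with their neighbour, with a warning.
#'
#' @param probabilities predicted probabilities (or a `logistic_model`).
#' @param labels benign/malignant labels (ignored when a model carrying
#'   its training labels is passed).
#' @param g number of bins, >= 3 (default 10).
#' @return list with `chi2`, `df`, `p`, `g` (bins actually used).
#' @export
hosmer_lemeshow <- function(probabilities, labels = NULL, g = 10) {
  if (inherits(probabilities, "logistic_model")) {
    labels <- probabilities$y
    probabilities <- probabilities$fitted
  }
  if (g < 3) stop("need at least 3 bins")
  y <- .as_malignant_indicator(labels)
  br <- unique(stats::quantile(probabilities, probs = seq(0, 1, length.out =
                                                            g + 1)))
  if (length(br) < 4)
    stop("fewer than 3 distinct risk bins: probabilities are too discrete")
  if (length(br) < g + 1)
    warning("tied probabilities: merged ", g + 1 - length(br), " bin(s)")
  bins <- cut(probabilities, breaks = br, include.lowest = TRUE)
  obs1 <- tapply(y, bins, sum)
  exp1 <- tapply(probabilities, bins, sum)
  nbin <- tapply(y, bins, length)
  keep <- !is.na(nbin) & nbin > 0
  obs1 <- obs1[keep]; exp1 <- exp1[keep]; nbin <- nbin[keep]
  chi2 <- sum((obs1 - exp1)^2 / exp1 +
                ((nbin - obs1) - (nbin - exp1))^2 / (nbin - exp1))
  df <- length(nbin) - 2L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       g = length(nbin))
}

#' Bootstrap-corrected calibration curve
#'
#' Per-decile observed malignancy frequency against mean predicted
#' probability, with a bootstrap optimism correction: the model is refit
#' on B resamples, the difference between each refit's calibration on its
#' own resample and on the original data estimates the optimism, and the
#' apparent per-bin calibration is shrunk by its mean.
#'
#' @param model a `logistic_model`.
#' @param B bootstrap replicates, >= 100.
#' @param g number of probability bins (default 10).
#' @param seed integer seed for the resampling.
#' @return data frame with columns bin, predicted, observed,
#'   observed_corrected, n.
#' @export
bootstrap_calibration <- function(model, B = 200, g = 10, seed = 1L) {
  stopifnot(inherits(model, "logistic_model"))
  if (B < 100) stop("need at least 100 bootstrap replicates")
  set.seed(seed)
  data <- model$data; y <- model$y
  n <- length(y)
  calib <- function(p, yy, breaks) {
    bins <- cut(p, breaks = breaks, include.lowest = TRUE)
    data.frame(predicted = as.numeric(tapply(p, bins, mean)),
               observed = as.numeric(tapply(yy, bins, mean)),
               n = as.numeric(tapply(yy, bins, length)))
  }
  breaks <- unique(stats::quantile(model$fitted,
                                   probs = seq(0, 1, length.out = g + 1)))
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  apparent <- calib(model$fitted, y, breaks)
  optimism <- matrix(0, nrow(apparent), B)
  for (b in seq_len(B)) {
    ii <- sample.int(n, n, replace = TRUE)
    mb <- tryCatch(suppressWarnings(
      fit_logistic_with_selection(
        cbind(data[ii, , drop = FALSE]),
        features = model$retained, labels = y[ii], alpha = 1)),
      error = function(e) NULL)
    if (is.null(mb)) next
    cb_boot <- calib(mb$fitted, y[ii], breaks)
    p_orig <- predict(mb, data)
    cb_orig <- calib(p_orig, y, breaks)
    optimism[, b] <- (cb_boot$observed - cb_boot$predicted) -
      (cb_orig$observed - cb_orig$predicted)
  }
  opt <- rowMeans(optimism, na.rm = TRUE)
  apparent$observed_corrected <- apparent$observed - opt
  apparent$bin <- seq_len(nrow(apparent))
  apparent[, c("bin", "predicted", "observed", "observed_corrected", "n")]
}

#' Decision-curve analysis
#'
#' Net benefit of treating on the model across threshold probabilities,
#' against the treat-all and treat-none strategies:
#' NB(pt) = TP/n - FP/n * pt/(1-pt).
#'
#' @param probabilities predicted malignancy probabilities.
#' @param labels benign/malignant labels.
#' @param thresholds threshold probability grid in (0,1)
#'   (default 0.01-0.99 step 0.01).
#' @return data frame of class `net_benefit_curve` with columns threshold,
#'   net_benefit, treat_all, treat_none.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  y <- .as_malignant_indicator(labels)
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    pred <- probabilities >= pt
    tp <- sum(pred & y == 1L) / n
    fp <- sum(pred & y == 0L) / n
    tp - fp * pt / (1 - pt)
  }, numeric(1))
  ta <- prev - (1 - prev) * thresholds / (1 - thresholds)
  out <- data.frame(threshold = thresholds, net_benefit = nb,
                    treat_all = ta, treat_none = 0)
  class(out) <- c("net_benefit_curve", "data.frame")
  out
}

#' Nomogram scale of a logistic model
#'
#' Standard point-scale construction: the retained feature with the
#' largest |coefficient| x observed range spans 0-100 points, the others
#' are scaled proportionally, and total points map to predicted
#' probability through the inverse logit of the reassembled linear
#' predictor.
#'
#' @param model a `logistic_model` with at least one retained feature.
#' @param n_knots number of tick values tabulated per feature axis.
#' @return object of class `nomogram_spec`: per-feature point tables, a
#'   total-points-to-probability table, and `points_for()` /
#'   `probability_for()` closures.
#' @export
build_nomogram <- function(model, n_knots = 7) {
  stopifnot(inherits(model, "logistic_model"))
  feats <- model$retained
  if (length(feats) == 0L) stop("nomogram needs at least one feature")
  co <- model$coefficients[feats]
  rng <- lapply(feats, function(f) range(model$data[[f]]))
  names(rng) <- feats
  # per-feature linear-predictor contribution minima and spans
  lo_contrib <- vapply(feats, function(f) min(co[f] * rng[[f]]), numeric(1))
  span <- vapply(feats, function(f) abs(co[f]) * diff(rng[[f]]), numeric(1))
  K <- max(span)
  axes <- lapply(feats, function(f) {
    vals <- seq(rng[[f]][1], rng[[f]][2], length.out = n_knots)
    data.frame(value = vals,
               points = (co[f] * vals - lo_contrib[f]) / K * 100)
  })
  names(axes) <- feats
  points_for <- function(newdata) {
    pts <- rep(0, nrow(newdata))
    for (f in feats)
      pts <- pts + (co[f] * newdata[[f]] - lo_contrib[f]) / K * 100
    pts
  }
  probability_for <- function(total_points) {
    lp <- model$coefficients[["(Intercept)"]] + sum(lo_contrib) +
      total_points * K / 100
    stats::plogis(lp)
  }
  total_grid <- seq(0, sum(vapply(axes, function(a) max(a$points),
                                  numeric(1))), length.out = 21)
  structure(list(axes = axes, scale = K, features = feats,
                 points_for = points_for, probability_for = probability_for,
                 probability_table = data.frame(
                   total_points = total_grid,
                   probability = vapply(total_grid, probability_for,
                                        numeric(1)))),
            class = "nomogram_spec")
}

#' @export
print.nomogram_spec <- function(x, ...) {
  cat("Nomogram over:", paste(x$features, collapse = ", "), "\n")
  print(x$probability_table[c(1, 11, 21), ], row.names = FALSE)
  invisible(x)
}
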