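test_that("ROC handles separation, null scores and orientation", {
  y <- rep(c("benign", "malignant"), each = 20)
  sep <- c(rnorm(20, 10, 0.1), rnorm(20, 0, 0.1))
  rr <- roc_analysis(sep, y, direction = "lower")
  expect_equal(rr$auc, 1)
  expect_equal(rr$sensitivity, 100)
  expect_equal(rr$specificity, 100)
  expect_true(rr$cutoff > min(sep) && rr$cutoff < max(sep))
  set.seed(41)
  null <- roc_analysis(rnorm(2000), rep(c(0, 1), 1000))
  expect_equal(null$auc, 0.5, tolerance = 0.05)
  expect_error(roc_analysis(rnorm(5), rep("malignant", 5)), "both classes")
})

test_that("AUC equals the normalised Mann-Whitney U statistic", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- rnorm(n) + y * runif(1, 0, 2)
    rr <- roc_analysis(s, y, direction = "higher")
    expect_equal(rr$auc, oracle_auc(s, y), tolerance = 1e-12)
    # wilcox.test's U as a second, independent route
    u <- unname(wilcox.test(s[y == 1], s[y == 0], exact = FALSE)$statistic)
    expect_equal(rr$auc, u / (sum(y == 1) * sum(y == 0)), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(43)
  y <- rbinom(100, 1, 0.5); s <- rnorm(100) + y
  a0 <- roc_analysis(s, y, direction = "higher")$auc
  expect_equal(roc_analysis(exp(s), y, direction = "higher")$auc, a0)
  expect_equal(roc_analysis(qlogis(plogis(s)), y, "higher")$auc, a0,
               tolerance = 1e-9)
})

test_that("Youden cutoff matches an exhaustive scan with spec-tiebreak", {
  set.seed(44)
  for (i in 1:8) {
    n <- sample(20:50, 1)
    y <- rbinom(n, 1, 0.5); if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(n) + 1.2 * y, 1)   # rounding forces ties
    rr <- roc_analysis(s, y, direction = "higher")
    su <- sort(unique(s))
    cand <- (su[-1] + su[-length(su)]) / 2
    stats <- t(vapply(cand, function(cth) {
      sens <- mean(s[y == 1] >= cth); spec <- mean(s[y == 0] < cth)
      c(j = sens + spec - 1, sens = sens, spec = spec)
    }, numeric(3)))
    jmax <- max(stats[, "j"])
    ties <- which(abs(stats[, "j"] - jmax) <= 1e-12)
    pick <- ties[which.max(stats[ties, "spec"])]
    expect_equal(rr$youden, jmax, tolerance = 1e-12)
    expect_equal(rr$cutoff, cand[pick], tolerance = 1e-12)
  }
})

test_that("reported operating point is reproducible from the cutoff rule", {
  set.seed(45)
  y <- rep(c("benign", "malignant"), c(40, 60))
  s <- c(rnorm(40, 1.17, 0.34), rnorm(60, 0.73, 0.18))
  rr <- roc_analysis(s, y, direction = "lower")
  op <- operating_point(s, y, rr$cutoff, "lower")
  expect_equal(op$sensitivity, rr$sensitivity)
  expect_equal(op$specificity, rr$specificity)
  expect_equal(op$accuracy, rr$accuracy)
})

test_that("empirical AUC converges to the binormal closed form", {
  set.seed(46)
  n <- 2e4
  x <- c(rnorm(n, 1.17, 0.34), rnorm(n, 0.73, 0.18))
  y <- rep(c(0, 1), each = n)
  expect_equal(oracle_auc(-x, y),
               pnorm(0.44 / sqrt(0.34^2 + 0.18^2)), tolerance = 0.01)
})

test_that("DeLong test flags informative differences and not noise", {
  set.seed(7)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  a <- y * 0.8 + rnorm(n)
  expect_identical(delong_test(a, a, y)$p, 1)
  set.seed(9)
  s1 <- y + rnorm(n); s2 <- s1 + rnorm(n, sd = 0.05)
  expect_gt(delong_test(s1, s2, y)$p, 0.5)
  set.seed(10)
  n2 <- 500; y2 <- rep(c(0, 1), each = n2 / 2)
  informative <- y2 * 1.2 + rnorm(n2)
  noise <- rnorm(n2)
  expect_lt(delong_test(informative, noise, y2)$p, 0.01)
})

test_that("DeLong p agrees with a paired bootstrap on a small fixture", {
  set.seed(7)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  a <- y * 0.8 + rnorm(n)
  b <- 0.6 * a + 0.4 * (y * 0.8 + rnorm(n))
  dl <- delong_test(a, b, y)
  set.seed(8)
  B <- 1e4
  idx0 <- which(y == 0); idx1 <- which(y == 1)
  d <- replicate(B, {
    ii <- c(sample(idx0, length(idx0), TRUE),
            sample(idx1, length(idx1), TRUE))
    oracle_auc(a[ii], y[ii]) - oracle_auc(b[ii], y[ii])
  })
  p_boot <- 2 * min(mean(d <= 0), mean(d >= 0))
  expect_lt(abs(dl$p - p_boot), 0.02)
})

test_that("single-pass selection drops noise and keeps the signal", {
  set.seed(51)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  noise_only <- data.frame(D = rnorm(n))
  m0 <- fit_logistic_with_selection(noise_only, features = "D", labels = y)
  expect_identical(m0$retained, character(0))
  expect_identical(unname(m0$coefficients["D"]), NA_real_)
  keepD <- vapply(1:20, function(s) {
    co <- simulate_cohort(cohort_spec(seed = 1000 + s))
    cs <- co[co$sequence == "SSEPI", ]
    m <- suppressWarnings(fit_logistic_with_selection(cs))
    "D" %in% m$retained
  }, logical(1))
  expect_gte(mean(keepD), 0.95)
})

test_that("collinear features fall back to the penalised fit with warning", {
  set.seed(52)
  n <- 150
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  df <- data.frame(a = x, b = x, group = ifelse(y == 1, "malignant",
                                                "benign"))
  expect_warning(m <- fit_logistic_with_selection(df, features = c("a", "b"),
                                                  alpha = 1),
                 "ridge")
  expect_true(m$penalized)
  expect_true(all(is.finite(m$coefficients)))
  expect_true(all(m$fitted > 0 & m$fitted < 1))
  # perfect separation also routes to the penalised fit
  sep <- data.frame(a = c(rnorm(30, -5), rnorm(30, 5)),
                    group = rep(c("benign", "malignant"), each = 30))
  expect_warning(ms <- fit_logistic_with_selection(sep, features = "a",
                                                   alpha = 1), "ridge")
  expect_true(ms$penalized)
})

test_that("combined model score inherits and improves single-score ROC", {
  set.seed(53)
  co <- simulate_cohort(cohort_spec(seed = 53L))
  cs <- co[co$sequence == "SSEPI", ]
  one <- fit_logistic_with_selection(cs, features = "D", alpha = 1)
  rr1 <- combined_roc(one)
  rrD <- roc_analysis(cs$D, cs$group, direction = "lower")
  expect_equal(rr1$auc, rrD$auc, tolerance = 1e-12)  # monotone transform
  # independent second signal raises (or at least never lowers) the AUC
  n <- 400
  y <- rep(c("benign", "malignant"), each = n / 2)
  d <- rnorm(n) + (y == "malignant") * 1
  b <- rnorm(n) + (y == "malignant") * 1
  df <- data.frame(D = d, beta = b, group = y)
  both <- fit_logistic_with_selection(df, features = c("D", "beta"),
                                      alpha = 1)
  auc_both <- combined_roc(both)$auc
  auc_single <- max(roc_analysis(d, y, "higher")$auc,
                    roc_analysis(b, y, "higher")$auc)
  expect_gte(auc_both, auc_single - 0.02)
  # degenerate constant second feature adds nothing
  dfc <- data.frame(D = d, beta = 1, group = y)
  mc <- suppressWarnings(fit_logistic_with_selection(dfc,
                                                     features = c("D", "beta"),
                                                     alpha = 1))
  expect_equal(combined_roc(mc)$auc, roc_analysis(d, y, "higher")$auc,
               tolerance = 1e-9)
})

test_that("Hosmer-Lemeshow holds its size and detects miscalibration", {
  set.seed(54)
  pv <- replicate(200, {
    n <- 500
    x <- rnorm(n)
    p <- plogis(-0.5 + x)
    yy <- rbinom(n, 1, p)
    m <- suppressWarnings(glm(yy ~ x, family = binomial))
    hosmer_lemeshow(fitted(m), yy)$p
  })
  expect_gt(mean(pv < 0.05), 0.01)
  expect_lt(mean(pv < 0.05), 0.11)
  set.seed(55)
  n <- 5000
  x <- rnorm(n); p <- plogis(x)
  yy <- rbinom(n, 1, p)
  expect_lt(hosmer_lemeshow(p^3, yy)$p, 0.01)
  g3 <- hosmer_lemeshow(p, yy, g = 3)
  expect_identical(g3$df, 1L + 0L)
  expect_error(hosmer_lemeshow(p, yy, g = 2), "3 bins")
})

test_that("bootstrap calibration recovers the identity on good models", {
  set.seed(56)
  n <- 5000
  d <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 1.1 * d))
  df <- data.frame(D = d)
  m <- fit_logistic_with_selection(df, features = "D", labels = y)
  cal <- bootstrap_calibration(m, B = 200, seed = 99L)
  expect_lt(max(abs(cal$observed_corrected - cal$predicted)), 0.05)
  cal2 <- bootstrap_calibration(m, B = 200, seed = 99L)
  expect_identical(cal, cal2)          # deterministic given seed
  expect_error(bootstrap_calibration(m, B = 50), "100")
  expect_silent(bootstrap_calibration(m, B = 100, seed = 1L))
})

test_that("net benefit matches the closed forms of reference strategies", {
  y <- rep(c(0, 1), c(60, 40))          # prevalence 0.4
  perfect <- c(rep(0.01, 60), rep(0.99, 40))
  dc <- decision_curve(perfect, y, thresholds = c(0.1, 0.4, 0.9))
  expect_equal(dc$net_benefit, rep(0.4, 3))
  expect_equal(dc$treat_none, rep(0, 3))
  # treat-all crosses zero exactly at the prevalence
  expect_equal(dc$treat_all[2], 0)
  expect_equal(dc$treat_all[1], 0.4 - 0.6 * 0.1 / 0.9)
  expect_error(decision_curve(perfect, y, thresholds = c(0, 0.5)), "inside")
})

test_that("nomogram points reassemble the model probabilities", {
  set.seed(57)
  co <- simulate_cohort(cohort_spec(seed = 57L))
  cs <- co[co$sequence == "SSEPI", ]
  m <- fit_logistic_with_selection(cs, features = c("D", "beta"), alpha = 1)
  nom <- build_nomogram(m)
  # the widest axis spans exactly 0-100 points, all axes are monotone
  tops <- vapply(nom$axes, function(a) max(a$points), numeric(1))
  expect_equal(max(tops), 100)
  for (a in nom$axes) {
    expect_gte(min(a$points), 0)
    expect_true(all(diff(a$points) > 0) || all(diff(a$points) < 0))
  }
  pts <- nom$points_for(cs)
  probs <- vapply(pts, nom$probability_for, numeric(1))
  expect_lt(max(abs(probs - predict(m))), 1e-12)
  expect_error(build_nomogram(fit_logistic_with_selection(
    data.frame(D = rnorm(100)), features = "D",
    labels = rbinom(100, 1, 0.5))), "at least one")
})
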