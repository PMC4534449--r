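test_that("collinearity screen reports correlations and VIFs without dropping", {
  set.seed(2)
  A <- rnorm(100); B <- rnorm(100)
  X <- cbind(A = A, B = B, C = A)
  sc <- collinearity_screen(X)
  expect_equal(abs(sc$correlations["A", "C"]), 1)
  expect_identical(sc$vif[["C"]], Inf)
  expect_true(all(c("A", "C") %in% sc$flagged))

  # orthogonal columns: nothing flagged
  X2 <- qr.Q(qr(matrix(rnorm(300), 100, 3)))
  colnames(X2) <- c("a", "b", "c")
  expect_length(collinearity_screen(X2)$flagged, 0)

  # near-collinear sum: VIF blows past 10
  C <- A + B + rnorm(100, 0, 0.01)
  sc3 <- collinearity_screen(cbind(A = A, B = B, C = C))
  expect_gt(sc3$vif[["C"]], 10)
  expect_true("C" %in% sc3$flagged)

  expect_error(collinearity_screen(cbind(A = A)), "two columns")
  expect_error(collinearity_screen(cbind(A = A, B = rep(1, 100))), "constant")
})

test_that("logistic fit matches closed forms and a likelihood grid", {
  # intercept-only, 100 presences vs 200 background -> log(1/2)
  X <- matrix(1, 300, 1, dimnames = list(NULL, "(Intercept)"))
  y <- rep(c(1, 0), c(100, 200))
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$coef), log(0.5), tolerance = 1e-10)
  expect_true(fit$converged)
  expect_equal(fit$logLik, 100 * log(1 / 3) + 200 * log(2 / 3),
               tolerance = 1e-10)

  # one-covariate toy: MLE equals the brute-force likelihood grid optimum
  set.seed(6)
  x <- rnorm(40)
  yy <- rbinom(40, 1, plogis(-0.4 + 1.1 * x))
  X2 <- cbind(`(Intercept)` = 1, x = x)
  fit2 <- fit_logistic(X2, yy)
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(yy * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0)
  for (step in c(0.5, 0.05, 5e-3, 5e-4, 5e-5, 2e-5)) {
    b0s <- centre[1] + step * (-12:12)
    b1s <- centre[2] + step * (-12:12)
    grid <- outer(b0s, b1s, Vectorize(loglik))
    best <- which(grid == max(grid), arr.ind = TRUE)[1, ]
    centre <- c(b0s[best[1]], b1s[best[2]])
  }
  expect_equal(unname(fit2$coef), centre, tolerance = 1e-4)

  # perfect separation is reported as a warning state, not an error
  xs <- c(rep(0, 10), rep(1, 10))
  fit3 <- fit_logistic(cbind(1, xs), xs)
  expect_true(any(grepl("separation", fit3$warnings)))

  expect_error(fit_logistic(X, rep(1, 300)), "both classes")
})

test_that("AICc follows its definition and limits", {
  expect_equal(aicc(-100, 3, 100), 206.25)
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)
  expect_equal(aicc(-100, 0, 50), 200)
  expect_error(aicc(-100, 10, 11), "n > k")
})

test_that("subset enumeration respects marginality", {
  spec <- global_model_spec()
  expect_length(enumerate_subsets(spec), 192)
  spec_free <- global_model_spec(marginality = FALSE)
  expect_length(enumerate_subsets(spec_free), 256)
  spec_null <- global_model_spec(terms = character(0))
  expect_length(enumerate_subsets(spec_null), 1)
  # every marginal subset containing the quadratic contains the linear term
  subs <- enumerate_subsets(spec)
  for (s in subs)
    if ("days_above_35_sq" %in% s) expect_true("days_above_35" %in% s)
  expect_error(global_model_spec(terms = c("days_above_35_sq", "snow_depth")),
               "lacks its linear term")
})

test_that("averaging formulas reproduce hand-computed two-model cases", {
  # synthetic two-model ledger: delta = {0, 2}, term x only in model 1
  ledger <- structure(list(
    table = data.frame(model = 1:2, terms = c("x", ""), k = c(2, 1),
                       logLik = c(-10, -12), AICc = c(24, 26),
                       delta = c(0, 2),
                       weight = c(1, exp(-1)) / (1 + exp(-1)),
                       warnings = ""),
    coef = matrix(c(0.5, 0.2, 1.0, NA), 2, 2,
                  dimnames = list(NULL, c("(Intercept)", "x"))),
    se = matrix(c(0.1, 0.1, 0.3, NA), 2, 2,
                dimnames = list(NULL, c("(Intercept)", "x"))),
    terms = c("(Intercept)", "x"), n = 100), class = "subset_ledger")
  avg <- model_average(ledger)
  w1 <- 1 / (1 + exp(-1))
  expect_equal(w1, 0.7311, tolerance = 1e-4)
  row_x <- avg$table[avg$table$term == "x", ]
  expect_equal(row_x$estimate, w1 * 1.0, tolerance = 1e-12)
  expect_equal(row_x$importance, w1, tolerance = 1e-12)
  # unconditional SE: shrinkage spread counts for the absent model too
  w2 <- 1 - w1
  expect_equal(row_x$se,
               w1 * sqrt(0.3^2 + (1 - w1)^2) + w2 * sqrt(0 + (0 - w1)^2),
               tolerance = 1e-12)
  # single-model ledger: averaging is the identity
  l1 <- ledger
  l1$table <- l1$table[1, ]; l1$table$weight <- 1; l1$table$model <- 1L
  l1$coef <- l1$coef[1, , drop = FALSE]; l1$se <- l1$se[1, , drop = FALSE]
  avg1 <- model_average(l1)
  expect_equal(avg1$table$estimate, c(0.5, 1.0))
  expect_equal(avg1$table$se, c(0.1, 0.3))
})

test_that("ledger weights are normalized and estimates are convex", {
  set.seed(9)
  dat <- toy_std_table(n = 120)
  for (tm in covariate_terms()) dat[[tm]] <- rnorm(120)
  dat$y <- rbinom(120, 1, plogis(0.5 * dat$dist_water - 0.7))
  spec <- global_model_spec(terms = c("dist_water", "snow_depth",
                                      "forest_pct"))
  ledger <- fit_all_subsets(dat, spec)
  expect_equal(sum(ledger$table$weight), 1, tolerance = 1e-10)
  expect_true(all(ledger$table$delta >= 0))
  expect_equal(ledger$table$delta[1], 0)
  avg <- model_average(ledger)
  for (j in seq_along(ledger$terms)) {
    bmax <- max(abs(ledger$coef[, j]), na.rm = TRUE)
    expect_lte(abs(avg$table$estimate[j]), bmax + 1e-12)
  }
  expect_true(all(avg$table$importance >= 0 & avg$table$importance <= 1))
  expect_true(all(avg$table$ci_low <= avg$table$estimate &
                    avg$table$estimate <= avg$table$ci_high))
})

test_that("relative-occurrence prediction follows the RSF conventions", {
  est <- c(`(Intercept)` = -1.2, days_above_35 = 0.638,
           days_above_35_sq = -0.120, days_below_minus4 = -2.749,
           snow_depth = -0.006, dist_water = -0.529, forest_pct = -0.035,
           forage_pct = 0.009, heterogeneity = 0.197)
  model <- toy_averaged_model(est)

  z0 <- toy_std_table(n = 3, z = 0)
  pe <- predict_relative_occurrence(model, z0, "exponential")
  expect_equal(pe$score, rep(1, 3))  # exp(0), intercept excluded
  pl <- predict_relative_occurrence(model, z0, "logistic")
  expect_equal(pl$score, rep(plogis(-1.2), 3))

  # score increases with heterogeneity (positive coefficient), all else fixed
  zh <- toy_std_table(n = 5, z = 0)
  zh$heterogeneity <- seq(-1, 1, length.out = 5)
  expect_true(all(diff(predict_relative_occurrence(model, zh,
                                                   "exponential")$score) > 0))

  # both forms rank watersheds identically
  set.seed(14)
  zr <- toy_std_table(n = 50)
  for (tm in covariate_terms()) zr[[tm]] <- rnorm(50)
  re <- predict_relative_occurrence(model, zr, "exponential")$score
  rl <- predict_relative_occurrence(model, zr, "logistic")$score
  expect_equal(cor(re, rl, method = "spearman"), 1)

  # quadratic optimum on standardized and natural scales
  opt <- attr(predict_relative_occurrence(model, z0, "exponential"),
              "optimum")
  expect_equal(opt$z_star, 0.638 / (2 * 0.120), tolerance = 1e-12)
  expect_equal(opt$z_star, 2.6583, tolerance = 1e-4)
  expect_equal(opt$x_star, 14 + 22 * opt$z_star, tolerance = 1e-12)

  # unstandardized input is a scale error
  raw <- z0
  attr(raw, "standardization") <- NULL
  expect_error(predict_relative_occurrence(model, raw, "exponential"),
               "not standardized")
})

test_that("confidence intervals use the exact normal multiplier", {
  ci <- ci_wald(c(0.638, -2.749), c(0.044, 0.106))
  expect_equal(unname(round(ci[1, ], 4)), c(0.5518, 0.7242))
  expect_equal(unname(round(ci[2, ], 4)), c(-2.9568, -2.5412))
})
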