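#' Collinearity screen
#'
#' Reports pairwise Pearson correlations and variance inflation factors for a
#' covariate matrix and flags terms exceeding either cutoff. Nothing is
#' dropped: exclusion is a caller decision. A singular design yields an
#' infinite VIF rather than an error.
#'
#' @param X numeric covariate matrix (named columns, no constant column).
#' @param r_cut pairwise |r| cutoff.
#' @param vif_cut VIF cutoff.
#' @return list with `correlations` (matrix), `vif` (named vector),
#'   `flagged` (character vector of offending terms), and the cutoffs.
#' @export
collinearity_screen <- function(X, r_cut = 0.7, vif_cut = 10) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least two columns", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column: ", paste(colnames(X)[sds == 0], collapse = ", "),
         call. = FALSE)
  r <- stats::cor(X)
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  rr <- r; diag(rr) <- 0
  flagged <- colnames(X)[apply(abs(rr) > r_cut, 1, any) | vif > vif_cut]
  list(correlations = r, vif = vif, flagged = flagged,
       r_cut = r_cut, vif_cut = vif_cut)
}

#' Maximum-likelihood logistic regression fit
#'
#' Fits presence (1) versus background (0) labels by iteratively reweighted
#' least squares, with standard errors from the observed information and the
#' maximized log-likelihood. Convergence is checked against the score
#' equations (gradient max-norm below `tol`); non-convergence or apparent
#' separation is recorded in a `warnings` field on the returned fit rather
#' than raised, so degenerate subsets keep their ledger entry.
#'
#' @param X design matrix including the intercept column.
#' @param y 0/1 response.
#' @param tol gradient max-norm defining convergence.
#' @return list of class `logistic_fit`: `coef`, `se`, `vcov`, `logLik`,
#'   `k` (parameter count), `n`, `converged`, `warnings`, `fitted`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = 100)))
  p <- fit$fitted.values
  beta <- fit$coefficients
  warn <- character()
  grad <- drop(crossprod(X, y - p))
  converged <- max(abs(grad)) < tol
  if (!converged) warn <- c(warn, "IRLS did not reach the score tolerance")
  if (any(p > 1 - 1e-10) || any(p < 1e-10))
    warn <- c(warn, "possible complete or quasi-complete separation")
  w <- p * (1 - p)
  info <- crossprod(X * sqrt(w))
  vcov <- tryCatch(chol2inv(chol(info)), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(pmax(diag(vcov), 0))
  names(beta) <- names(se) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  structure(list(coef = beta, se = se, vcov = vcov, logLik = ll,
                 k = ncol(X), n = nrow(X), converged = converged,
                 warnings = warn, fitted = p),
            class = "logistic_fit")
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `-2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param logLik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size; must exceed `k + 1`.
#' @return AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1", call. = FALSE)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Global model specification
#'
#' The global logistic discrimination model: the seven covariate linear terms
#' plus a quadratic term for days above 35 degC (warm climates favour
#' occurrence up to a threshold of hot days). Under marginality the quadratic
#' term enters a subset only together with its linear term.
#'
#' @param terms model term names; default the seven linear terms plus
#'   `days_above_35_sq`.
#' @param marginality must the quadratic term be accompanied by its linear
#'   term?
#' @param r_cut,vif_cut collinearity cutoffs carried for the screen.
#' @return list of class `global_model_spec`.
#' @export
global_model_spec <- function(terms = covariate_terms(quadratic = TRUE),
                              marginality = TRUE, r_cut = 0.7,
                              vif_cut = 10) {
  quad <- grep("_sq$", terms, value = TRUE)
  for (q in quad)
    if (!sub("_sq$", "", q) %in% terms)
      stop(sprintf("quadratic term `%s` lacks its linear term", q),
           call. = FALSE)
  structure(list(terms = terms, quadratic = quad, marginality = marginality,
                 r_cut = r_cut, vif_cut = vif_cut),
            class = "global_model_spec")
}

#' Enumerate all additive subsets of the global model
#'
#' Every subset of the model terms, including the intercept-only null model.
#' With marginality on, subsets containing a quadratic term without its
#' linear term are removed.
#'
#' @param spec a [global_model_spec()].
#' @return list of character vectors of term names (empty vector = null
#'   model).
#' @export
enumerate_subsets <- function(spec) {
  stopifnot(inherits(spec, "global_model_spec"))
  terms <- spec$terms
  n <- length(terms)
  subsets <- lapply(seq_len(2^n) - 1L, function(mask) {
    terms[bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L]
  })
  if (spec$marginality && length(spec$quadratic)) {
    ok <- vapply(subsets, function(s) {
      all(sub("_sq$", "", intersect(s, spec$quadratic)) %in% s)
    }, logical(1))
    subsets <- subsets[ok]
  }
  subsets
}

#' Build a design matrix for model terms
#'
#' Maps term names onto columns of a standardized covariate table; a
#' quadratic term `<x>_sq` is the square of the standardized column `<x>`.
#'
#' @param covariates covariate table (or estimation data frame).
#' @param terms character vector of term names.
#' @return numeric matrix with one named column per term (no intercept).
#' @export
build_design <- function(covariates, terms) {
  cols <- lapply(terms, function(tm) {
    if (grepl("_sq$", tm)) covariates[[sub("_sq$", "", tm)]]^2
    else covariates[[tm]]
  })
  bad <- vapply(cols, is.null, logical(1))
  if (any(bad))
    stop("unknown model terms: ", paste(terms[bad], collapse = ", "),
         call. = FALSE)
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

#' Fit every subset of the global model
#'
#' Fits each enumerated subset by maximum likelihood and assembles the subset
#' ledger: per-model terms, parameter count, log-likelihood, AICc, delta
#' AICc, and Akaike weight, plus the per-model coefficient and SE matrices
#' used for averaging. The intercept is included in every subset.
#'
#' @param data estimation data (standardized covariates plus a `y` column).
#' @param spec a [global_model_spec()].
#' @return list of class `subset_ledger`: `table` (data frame), `coef`, `se`
#'   (models x terms matrices, NA where a term is absent), `terms`, `n`.
#' @export
fit_all_subsets <- function(data, spec) {
  subsets <- enumerate_subsets(spec)
  Xfull <- cbind(`(Intercept)` = 1, build_design(data, spec$terms))
  y <- data$y
  n <- length(y)
  all_terms <- c("(Intercept)", spec$terms)
  m <- length(subsets)
  coefm <- sem <- matrix(NA_real_, m, length(all_terms),
                         dimnames = list(NULL, all_terms))
  ll <- kk <- numeric(m)
  warns <- character(m)
  for (i in seq_len(m)) {
    keep <- c("(Intercept)", subsets[[i]])
    fit <- fit_logistic(Xfull[, keep, drop = FALSE], y)
    coefm[i, keep] <- fit$coef
    sem[i, keep] <- fit$se
    ll[i] <- fit$logLik
    kk[i] <- fit$k
    warns[i] <- paste(fit$warnings, collapse = "; ")
  }
  aic <- vapply(seq_len(m), function(i) aicc(ll[i], kk[i], n), numeric(1))
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab <- data.frame(
    model = seq_len(m),
    terms = vapply(subsets, paste, character(1), collapse = "+"),
    k = kk, logLik = ll, AICc = aic, delta = delta, weight = w,
    warnings = warns, stringsAsFactors = FALSE)
  tab <- tab[order(tab$delta), ]
  structure(list(table = tab, coef = coefm, se = sem, terms = all_terms,
                 n = n, spec = spec), class = "subset_ledger")
}

#' Shrinkage model averaging over a subset ledger
#'
#' Averages coefficients over all subset fits with Akaike weights
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)`. Terms absent from a model
#' contribute zero (shrinkage), the unconditional SE combines within-model
#' variance and between-model spread,
#' `SE_j = sum_i w_i sqrt(se_ij^2 + (b_ij - bbar_j)^2)` (absent terms enter
#' with se 0), the 95% CI is `bbar +/- 1.959964 SE`, and the importance of a
#' term is the cumulative weight of the models containing it.
#'
#' @param ledger a [fit_all_subsets()] ledger.
#' @param standardization optional standardization metadata to carry along
#'   for natural-scale reporting.
#' @return list of class `averaged_model`: `table` (data frame `term`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `importance`), `z` (CI
#'   multiplier), `n`, `standardization`.
#' @export
model_average <- function(ledger, standardization = NULL) {
  stopifnot(inherits(ledger, "subset_ledger"))
  if (!nrow(ledger$table)) stop("empty subset ledger", call. = FALSE)
  w <- ledger$table$weight[order(ledger$table$model)]
  z <- 1.959964
  coefm <- ledger$coef; sem <- ledger$se
  est <- se <- imp <- stats::setNames(numeric(length(ledger$terms)),
                                      ledger$terms)
  for (j in seq_along(ledger$terms)) {
    b <- coefm[, j]; s <- sem[, j]
    present <- !is.na(b)
    b[!present] <- 0; s[!present] <- 0
    est[j] <- sum(w * b)
    se[j] <- sum(w * sqrt(s^2 + (b - est[j])^2))
    imp[j] <- sum(w[present])
  }
  tab <- data.frame(term = ledger$terms, estimate = unname(est),
                    se = unname(se), ci_low = unname(est - z * se),
                    ci_high = unname(est + z * se),
                    importance = unname(imp), stringsAsFactors = FALSE)
  structure(list(table = tab, z = z, n = ledger$n,
                 standardization = standardization),
            class = "averaged_model")
}

#' Wald confidence interval
#'
#' @param estimate point estimate.
#' @param se standard error.
#' @param z normal quantile multiplier (default the 97.5% point, 1.959964).
#' @return two-column matrix of lower and upper bounds.
#' @export
ci_wald <- function(estimate, se, z = 1.959964) {
  cbind(low = estimate - z * se, high = estimate + z * se)
}

#' Predict relative occurrence probability
#'
#' Evaluates the averaged model over a standardized covariate table. The
#' exponential form returns `exp(eta)` with the intercept excluded (the
#' resource-selection convention: only relative values are mapped); the
#' logistic form returns `plogis(eta)` with the intercept included. When both
#' hot-days terms are in the model with a negative quadratic coefficient, the
#' natural-scale optimum of the hot-days response,
#' `x* = mean + SD * (-b1 / (2 b2))`, is reported from the standardization
#' metadata.
#'
#' @param model an [model_average()] result.
#' @param covariates standardized covariate table (its standardization
#'   metadata must be present).
#' @param form `"exponential"` or `"logistic"`.
#' @return data frame `watershed_id`, `eta`, `score`, with attribute
#'   `optimum` = list(`z_star`, `x_star`) when defined.
#' @export
predict_relative_occurrence <- function(model, covariates,
                                        form = c("exponential", "logistic")) {
  form <- match.arg(form)
  stopifnot(inherits(model, "averaged_model"))
  if (is.null(attr(covariates, "standardization")))
    stop("covariates are not standardized; fit and prediction scales differ",
         call. = FALSE)
  tab <- model$table
  terms <- setdiff(tab$term, "(Intercept)")
  beta <- stats::setNames(tab$estimate, tab$term)
  X <- build_design(covariates, terms)
  eta <- drop(X %*% beta[terms])
  if (form == "logistic") eta <- eta + beta[["(Intercept)"]]
  score <- if (form == "exponential") exp(eta) else stats::plogis(eta)
  out <- data.frame(watershed_id = covariates$watershed_id, eta = eta,
                    score = score)
  has_quad <- all(c("days_above_35", "days_above_35_sq") %in% tab$term)
  if (has_quad && is.finite(beta[["days_above_35_sq"]]) &&
      beta[["days_above_35_sq"]] < 0) {
    b1 <- beta[["days_above_35"]]; b2 <- beta[["days_above_35_sq"]]
    z_star <- -b1 / (2 * b2)
    meta <- attr(covariates, "standardization")
    x_star <- meta$center[["days_above_35"]] +
      meta$scale[["days_above_35"]] * z_star
    attr(out, "optimum") <- list(z_star = z_star, x_star = x_star)
  }
  attr(out, "form") <- form
  out
}
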