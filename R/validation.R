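#' Random k-fold partition
#'
#' Seeded uniform random partition of ids into `k` folds whose sizes differ
#' by at most one.
#'
#' @param ids vector of unit identifiers (or row indices).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold assignment (1..k) aligned with `ids`.
#' @export
kfold_split <- function(ids, k = 4, seed = 1L) {
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  n <- length(ids)
  if (n < k) stop("fewer units than folds", call. = FALSE)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' RSF plot index
#'
#' Presence-only calibration statistic: withheld predicted scores are binned
#' (quantile bins with equal counts, or equal-interval bins over the score
#' range), and the Pearson correlation is computed between the bin midpoints
#' of the predicted values and the proportion of records in each bin that are
#' presences. For equal-interval bins the midpoint is the interval centre;
#' for quantile bins it is the median predicted score in the bin (interval
#' centres of quantile bins are artifacts of the score distribution). Empty
#' bins are dropped; fewer than two non-empty bins, or constant predictions,
#' are reported as a degenerate-binning error.
#'
#' @param pred predicted scores of the withheld records.
#' @param labels presence (1/TRUE) vs background (0/FALSE) labels.
#' @param n_bins number of bins.
#' @param method `"quantile"` or `"equal_interval"`.
#' @return list with `r` (Pearson correlation) and `bins` (data frame `bin`,
#'   `midpoint`, `prop_presence`, `n`).
#' @export
rsf_plot_index <- function(pred, labels, n_bins = 10,
                           method = c("quantile", "equal_interval")) {
  method <- match.arg(method)
  labels <- as.numeric(labels)
  stopifnot(length(pred) == length(labels))
  if (diff(range(pred)) == 0)
    stop("degenerate binning: all predictions identical", call. = FALSE)
  if (method == "quantile") {
    br <- unique(stats::quantile(pred, probs = seq(0, 1, length.out =
                                                     n_bins + 1)))
    if (length(br) < 3)
      stop("degenerate binning: fewer than 2 non-empty bins", call. = FALSE)
    bin <- cut(pred, br, include.lowest = TRUE, labels = FALSE)
  } else {
    br <- seq(min(pred), max(pred), length.out = n_bins + 1)
    bin <- cut(pred, br, include.lowest = TRUE, labels = FALSE)
  }
  used <- sort(unique(bin))
  if (length(used) < 2)
    stop("degenerate binning: fewer than 2 non-empty bins", call. = FALSE)
  mid <- vapply(used, function(b) {
    if (method == "quantile") stats::median(pred[bin == b])
    else (br[b] + br[b + 1]) / 2
  }, numeric(1))
  prop <- vapply(used, function(b) mean(labels[bin == b]), numeric(1))
  nrec <- vapply(used, function(b) sum(bin == b), numeric(1))
  list(r = stats::cor(mid, prop),
       bins = data.frame(bin = used, midpoint = mid, prop_presence = prop,
                         n = nrec))
}

#' RSF-plot-index k-fold cross-validation
#'
#' Repeats, `iterations` times: draw a fresh random `k`-fold allocation of
#' the estimation records; for each fold, run the full all-subsets
#' model-averaging procedure on the other `k - 1` folds and predict the
#' withheld fold; pool the withheld predictions of the iteration and compute
#' the RSF plot index under each binning method. Folds are drawn over the
#' union of presence and background records with labels preserved.
#'
#' @param data estimation data (standardized covariates plus `y`).
#' @param spec a [global_model_spec()].
#' @param k number of folds.
#' @param iterations number of random re-allocations.
#' @param n_bins number of bins for the RSF plot index.
#' @param seed integer root seed (per-iteration folds are derived from it).
#' @param methods binning methods to evaluate.
#' @param form prediction form used for the withheld scores.
#' @return list of class `validation_report`: `results` (data frame
#'   `iteration`, `method`, `r`), `bins` (last iteration's bin tables),
#'   `summary` (mean r per method), and the settings.
#' @export
cross_validate <- function(data, spec, k = 4, iterations = 100, n_bins = 10,
                           seed = 1L,
                           methods = c("quantile", "equal_interval"),
                           form = "logistic") {
  methods <- match.arg(methods, several.ok = TRUE)
  n <- nrow(data)
  res <- list(); last_bins <- list()
  for (it in seq_len(iterations)) {
    fold <- kfold_split(seq_len(n), k,
                        seed = derive_seed(seed, paste0("cv-fold-", it)))
    pooled_pred <- numeric(n)
    for (f in seq_len(k)) {
      train <- data[fold != f, , drop = FALSE]
      test <- data[fold == f, , drop = FALSE]
      attr(train, "standardization") <- attr(data, "standardization")
      attr(test, "standardization") <- attr(data, "standardization")
      ledger <- fit_all_subsets(train, spec)
      avg <- model_average(ledger, attr(data, "standardization"))
      pooled_pred[fold == f] <-
        predict_relative_occurrence(avg, test, form = form)$score
    }
    for (m in methods) {
      rp <- rsf_plot_index(pooled_pred, data$y, n_bins, m)
      res[[length(res) + 1L]] <-
        data.frame(iteration = it, method = m, r = rp$r)
      if (it == iterations) last_bins[[m]] <- rp$bins
    }
  }
  results <- do.call(rbind, res)
  summary <- stats::aggregate(r ~ method, results, mean)
  structure(list(results = results, bins = last_bins, summary = summary,
                 k = k, iterations = iterations, n_bins = n_bins,
                 seed = seed, form = form),
            class = "validation_report")
}

#' RSF calibration plot
#'
#' Scatter of bin midpoints against observed presence proportions with a
#' least-squares reference line, mirroring the standard RSF-plot display.
#'
#' @param bins bin table from [rsf_plot_index()].
#' @param ... passed to [plot()].
#' @return invisibly, `bins`.
#' @export
plot_rsf_bins <- function(bins, ...) {
  graphics::plot(bins$midpoint, bins$prop_presence,
                 xlab = "predicted score (bin midpoint)",
                 ylab = "observed proportion of presences", pch = 19, ...)
  graphics::abline(stats::lm(prop_presence ~ midpoint, data = bins), lty = 2)
  invisible(bins)
}
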