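#' Sample labelled calls from positive/negative control pools
#'
#' Draws `n` calls without replacement from the union of the two control
#' pools, preserving labels. If the union holds fewer than `n` calls the whole
#' union is returned with a warning and the shortfall recorded in attribute
#' `shortfall`.
#'
#' @param pc_llr Numeric LLRs from the positive (fully methylated) control.
#' @param nc_llr Numeric LLRs from the negative (unmethylated) control.
#' @param n Sample size (default 50,000).
#' @param seed Integer seed.
#' @return data.frame with columns `llr` and `label`
#'   (`"positive_control"`/`"negative_control"`).
#' @export
sample_labelled_calls <- function(pc_llr, nc_llr, n = 50000L, seed = NULL) {
  if (!length(pc_llr) && !length(nc_llr)) stop("both control pools are empty")
  if (!is.null(seed)) set.seed(seed)
  pool <- data.frame(
    llr = c(pc_llr, nc_llr),
    label = rep(c("positive_control", "negative_control"),
                c(length(pc_llr), length(nc_llr))),
    stringsAsFactors = FALSE
  )
  if (nrow(pool) <= n) {
    if (nrow(pool) < n) {
      warning(sprintf("only %d calls available; requested %d", nrow(pool), n))
      attr(pool, "shortfall") <- n - nrow(pool)
    }
    return(pool)
  }
  out <- pool[sample.int(nrow(pool), n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ROC curve over an LLR threshold grid
#'
#' At each threshold T a call is predicted methylated iff `llr >= T`. The
#' true-positive rate is the fraction of positive-control calls predicted
#' methylated; the false-positive rate the same fraction among
#' negative-control calls. `tpr`/`fpr` are reported on the requested grid; the
#' AUC is integrated trapezoidally over the full empirical ROC (thresholds at
#' every distinct LLR, endpoints (0,0) and (1,1) appended), which equals the
#' normalized Mann-Whitney U statistic with half credit for ties.
#'
#' @param calls data.frame from [sample_labelled_calls()] (columns `llr`,
#'   `label`).
#' @param grid_min,grid_max,step Threshold grid (defaults -20 to 20 by 0.25).
#' @return Object of class `roc_result`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(calls, grid_min = -20, grid_max = 20, step = 0.25) {
  pos <- calls$llr[calls$label == "positive_control"]
  neg <- calls$llr[calls$label == "negative_control"]
  if (!length(pos) || !length(neg)) {
    stop("both labels must be present to compute rates")
  }
  thresholds <- seq(grid_min, grid_max, by = step)
  tpr <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(neg >= t), numeric(1))

  cuts <- sort(unique(c(pos, neg)))
  e_tpr <- c(1, vapply(cuts, function(t) mean(pos > t), numeric(1)), 0)
  e_fpr <- c(1, vapply(cuts, function(t) mean(neg > t), numeric(1)), 0)
  xy <- cbind(fpr = e_fpr, tpr = e_tpr)
  xy <- xy[order(xy[, "fpr"], xy[, "tpr"]), , drop = FALSE]
  auc <- sum(diff(xy[, "fpr"]) * (utils::head(xy[, "tpr"], -1) +
                                    utils::tail(xy[, "tpr"], -1)) / 2)

  structure(
    list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc,
         n_pos = length(pos), n_neg = length(neg)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.4f over %d thresholds (%d PC / %d NC calls)\n",
    x$auc, length(x$thresholds), x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Accuracy scan over an LLR threshold grid
#'
#' Accuracy at threshold T is `(TP + TN) / n`: positive-control calls with
#' `llr >= T` plus negative-control calls with `llr < T`, over all calls. The
#' reported best threshold is the grid argmax, taking the smallest threshold
#' on ties.
#'
#' @param calls data.frame with columns `llr`, `label`.
#' @param grid_min,grid_max,step Threshold grid (defaults 0 to 10 by 0.25).
#' @return List with `thresholds`, `accuracy` and `best_threshold`.
#' @export
accuracy_curve <- function(calls, grid_min = 0, grid_max = 10, step = 0.25) {
  pos <- calls$llr[calls$label == "positive_control"]
  neg <- calls$llr[calls$label == "negative_control"]
  if (!length(pos) || !length(neg)) {
    stop("both labels must be present to compute accuracy")
  }
  thresholds <- seq(grid_min, grid_max, by = step)
  n <- length(pos) + length(neg)
  accuracy <- vapply(thresholds, function(t) {
    (sum(pos >= t) + sum(neg < t)) / n
  }, numeric(1))
  list(
    thresholds = thresholds,
    accuracy = accuracy,
    best_threshold = thresholds[which.max(accuracy)]
  )
}
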