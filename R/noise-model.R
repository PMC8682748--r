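#' Subsample a call table by read and measure depth/methylation pairs
#'
#' Emulates subsampling of an alignment file: for each fraction f, every read
#' (with all of its calls) is retained independently with probability f, the
#' standard frequency pipeline is run on the thinned table, and the realized
#' mean depth (mean called reads per site) and the genome-wide mean
#' methylation (percent) are recorded. Applied to an unmethylated control this
#' traces the background-noise curve as a function of depth.
#'
#' @param calls Call table (grouped rows, as consumed by
#'   [call_table_frequencies()]).
#' @param genome A [circular_genome()].
#' @param fractions Read-retention fractions in (0, 1]; default 30 log-spaced
#'   values from 1/30 to 1.
#' @param seed Integer seed (one stream drives all fractions; fixed seed gives
#'   identical points).
#' @param threshold Calling threshold (default 5).
#' @return data.frame with columns `fraction`, `depth`, `meth_pct`.
#' @export
subsample_calls <- function(calls, genome, fractions = NULL, seed = NULL,
                            threshold = 5) {
  if (is.null(fractions)) {
    fractions <- exp(seq(log(1 / 30), 0, length.out = 30L))
  }
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  read_names <- unique(calls$read_name)
  out <- data.frame(fraction = fractions, depth = NA_real_,
                    meth_pct = NA_real_)
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    keep_reads <- if (f >= 1) read_names else
      read_names[stats::runif(length(read_names)) < f]
    sub <- calls[calls$read_name %in% keep_reads, , drop = FALSE]
    if (!nrow(sub)) next
    sites <- call_table_frequencies(sub, genome, threshold)
    if (!nrow(sites)) next
    out$depth[i] <- attr(sites, "mean_depth")
    out$meth_pct[i] <- genome_mean_methylation(sites)
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Generate (depth, methylation) points from the exponential decay law
#'
#' Draws noise points directly from `Y = m * exp(-t * x) + b` with optional
#' multiplicative Gaussian noise, emulating the depth-versus-apparent-
#' methylation relation of unmethylated control data. Used to validate
#' parameter recovery of [fit_noise_model()] against a known truth.
#'
#' @param m,t,b True decay parameters (percent scale).
#' @param depths Depth grid; default 30 log-spaced values from 2 to 150.
#' @param rel_noise Relative (multiplicative) noise standard deviation.
#' @param seed Integer seed.
#' @return data.frame with columns `depth` and `meth_pct`.
#' @export
simulate_noise_points <- function(m = 2, t = 0.05, b = 0.3,
                                  depths = exp(seq(log(2), log(150),
                                                   length.out = 30L)),
                                  rel_noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- m * exp(-t * depths) + b
  if (rel_noise > 0) {
    y <- y * (1 + stats::rnorm(length(y), 0, rel_noise))
  }
  data.frame(depth = depths, meth_pct = pmax(y, 0))
}

#' Fit the exponential background-noise model
#'
#' Fits `Y = m * exp(-t * x) + b` by bounded nonlinear least squares
#' (Levenberg-Marquardt, all three parameters constrained non-negative),
#' where x is mean read depth and Y the apparent genome-wide methylation of
#' unmethylated data, in percent. Initial values are
#' `m0 = max(y) - min(y)`, `t0 = 1 / median(x)`, `b0 = min(y)`.
#' `r_squared = 1 - SS_res / SS_tot` (may be negative for a poor fit). A
#' constant-y input is flagged degenerate (`m = t = 0`, `b = mean(y)`,
#' `r_squared = NA`); fit failures raise an error rather than returning
#' silently.
#'
#' @param points data.frame with columns `depth` (or `x`) and `meth_pct`
#'   (or `y`); at least 4 points spanning at least a 2-fold depth range.
#' @return Object of class `noise_model` with elements `m`, `t`, `b`,
#'   `r_squared`, `degenerate` and `data`.
#' @export
fit_noise_model <- function(points) {
  x <- if ("depth" %in% names(points)) points$depth else points$x
  y <- if ("meth_pct" %in% names(points)) points$meth_pct else points$y
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 points")
  if (min(x) <= 0) stop("depths must be positive")
  if (max(x) / min(x) < 2) stop("points must span at least a 2-fold depth range")
  dat <- data.frame(x = x, y = y)

  if (stats::sd(y) < 1e-12) {
    return(new_noise_model(0, 0, mean(y), NA_real_, TRUE, dat))
  }
  start <- list(m = max(max(y) - min(y), 1e-6),
                t = 1 / stats::median(x),
                b = max(min(y), 0))
  try_fit <- function(t0) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ m * exp(-t * x) + b,
        data = dat, start = list(m = start$m, t = t0, b = start$b),
        lower = c(m = 0, t = 0, b = 0),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
  }
  fit <- NULL
  for (t0 in start$t * c(1, 0.1, 10, 0.01)) {
    fit <- try_fit(t0)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # optimisation cannot improve on a flat model (typical for near-constant
    # response); return the flat fallback, explicitly flagged
    b0 <- mean(y)
    r2 <- 1 - sum((y - b0)^2) / sum((y - mean(y))^2)
    return(new_noise_model(0, 0, b0, r2, TRUE, dat))
  }
  p <- stats::coef(fit)
  resid <- y - (p[["m"]] * exp(-p[["t"]] * x) + p[["b"]])
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  new_noise_model(p[["m"]], p[["t"]], p[["b"]], r2, FALSE, dat)
}

new_noise_model <- function(m, t, b, r_squared, degenerate, data) {
  structure(
    list(m = m, t = t, b = b, r_squared = r_squared,
         degenerate = degenerate, data = data),
    class = "noise_model"
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat("Background-noise model: Y = m * exp(-t * x) + b\n")
  cat(sprintf("  m = %.6g  t = %.6g  b = %.6g\n", x$m, x$t, x$b))
  cat(sprintf("  R^2 = %s on %d points%s\n",
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              nrow(x$data),
              if (x$degenerate) " (degenerate: constant response)" else ""))
  invisible(x)
}

#' @export
coef.noise_model <- function(object, ...) {
  c(m = object$m, t = object$t, b = object$b)
}

#' @export
fitted.noise_model <- function(object, ...) {
  object$m * exp(-object$t * object$data$x) + object$b
}

#' @export
residuals.noise_model <- function(object, ...) {
  object$data$y - fitted(object)
}

#' Predict background noise at a given read depth
#' @param object A [fit_noise_model()] result.
#' @param depth Positive read depth(s).
#' @param ... Unused.
#' @return Predicted apparent methylation in percent.
#' @export
predict.noise_model <- function(object, depth, ...) {
  if (any(depth <= 0)) stop("depth must be positive")
  object$m * exp(-object$t * depth) + object$b
}

#' @export
summary.noise_model <- function(object, ...) {
  cat(sprintf(
    "Exponential background-noise fit on %d (depth, methylation%%) points\n",
    nrow(object$data)
  ))
  print(object)
  cat(sprintf("  residual sd: %.4g\n", stats::sd(residuals(object))))
  invisible(object)
}

#' @export
plot.noise_model <- function(x, ...) {
  graphics::plot(x$data$x, x$data$y, xlab = "Mean read depth",
                 ylab = "Apparent methylation (%)",
                 main = "Background-noise model", ...)
  xs <- seq(min(x$data$x), max(x$data$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Functional form of [predict.noise_model()]
#' @param model A `noise_model`.
#' @param depth Positive depth(s).
#' @return Predicted noise in percent.
#' @export
predict_noise <- function(model, depth) {
  predict(model, depth)
}

#' Judge an observed sample against the predicted background noise
#'
#' A sample is `above_noise` iff its observed genome-wide mean methylation is
#' strictly greater than the noise predicted at the sample's own mean depth.
#'
#' @param observed_mean Observed genome-wide mean methylation (%).
#' @param observed_depth Sample mean read depth.
#' @param model A `noise_model`.
#' @return List with `observed_mean`, `predicted_noise`, `above_noise` and
#'   `margin` (observed minus predicted, percentage points).
#' @export
noise_verdict <- function(observed_mean, observed_depth, model) {
  predicted <- predict_noise(model, observed_depth)
  list(
    observed_mean = observed_mean,
    predicted_noise = predicted,
    above_noise = observed_mean > predicted,
    margin = observed_mean - predicted
  )
}
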