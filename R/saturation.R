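# Saturation curves over the ladder, plateau detection and the recommended
# cell number.

#' Build a saturation curve
#'
#' Aggregates a metric measured per ladder size (possibly over replicate
#' seeds) into a curve: per size the median value and the inter-replicate
#' IQR as dispersion, annotated with the plateau size at the default
#' tolerance.
#'
#' @param metric_values named list (names = sizes) of numeric values
#'   (length > 1 means replicates), or a data.frame with columns `size`
#'   and `value`.
#' @param metric metric name (for reports).
#' @param epsilon relative plateau tolerance used for the annotation
#'   (default 0.05).
#' @return an object of class `saturation_curve`: data.frame `data`
#'   (size, value, dispersion), `metric`, `plateau` (see
#'   [detect_plateau()]).
#' @export
build_curve <- function(metric_values, metric = "metric", epsilon = 0.05) {
  if (is.data.frame(metric_values)) {
    metric_values <- split(metric_values$value, metric_values$size)
  }
  sizes <- as.integer(names(metric_values))
  if (length(sizes) < 3) stopf("need at least 3 sizes, got %d", length(sizes))
  o <- order(sizes)
  dat <- data.frame(
    size = sizes[o],
    value = vapply(metric_values[o], function(v)
      stats::median(as.numeric(v), na.rm = TRUE), numeric(1)),
    dispersion = vapply(metric_values[o], function(v)
      if (length(v) > 1) stats::IQR(as.numeric(v), na.rm = TRUE) else 0,
      numeric(1)),
    row.names = NULL)
  curve <- structure(list(data = dat, metric = metric), class = "saturation_curve")
  curve$plateau <- detect_plateau(curve, epsilon = epsilon)
  curve
}

#' Plateau of a saturation curve
#'
#' For a metric increasing toward an asymptote, the plateau is the
#' smallest size whose value is at least `(1 - epsilon)` times the value
#' at the largest size; if only the largest size qualifies the plateau is
#' "not reached". When the curve decreases beyond its replicate
#' dispersion, isotonic regression is applied first and the result is
#' flagged `smoothed`.
#'
#' @param curve a `saturation_curve` (or data.frame size/value).
#' @param epsilon relative tolerance in `[0, 1]`; larger epsilon never
#'   yields a larger plateau size.
#' @return list with `size` (integer, `NA` when not reached), `reached`,
#'   `smoothed`.
#' @export
detect_plateau <- function(curve, epsilon = 0.05) {
  dat <- if (inherits(curve, "saturation_curve")) curve$data else
    as.data.frame(curve)
  v <- dat$value
  disp <- dat$dispersion %||% rep(0, length(v))
  if (epsilon < 0 || epsilon > 1) stopf("epsilon must be in [0, 1]")
  tol <- pmax(disp[-length(disp)], disp[-1])
  smoothed <- any(diff(v) < -tol - 1e-12)
  if (smoothed) v <- stats::isoreg(dat$size, v)$yf
  target <- (1 - epsilon) * v[length(v)]
  idx <- which(v >= target)[1]
  if (is.na(idx) || idx == length(v) && epsilon > 0)
    return(list(size = NA_integer_, reached = FALSE, smoothed = smoothed))
  list(size = as.integer(dat$size[idx]), reached = TRUE, smoothed = smoothed)
}

#' Recommend a cell number from several saturation curves
#'
#' Default policy: the maximum plateau size over the supplied curves
#' (typically cluster agreement, discovered types and DEG recovery).
#' Curves whose plateau is not reached are flagged; if no curve reaches a
#' plateau the recommendation is to enlarge the pool rather than a number.
#'
#' @param curves a `saturation_curve` or list of them.
#' @param policy `"max_plateau"` (only policy currently).
#' @return an object of class `sc_recommendation`: `size` (`NA` when no
#'   curve saturates), `per_metric` (named plateau sizes), `unreached`
#'   (metric names), `action` (`"use_size"` or `"increase_pool"`).
#' @export
recommend <- function(curves, policy = "max_plateau") {
  if (inherits(curves, "saturation_curve")) curves <- list(curves)
  if (!length(curves)) stopf("need at least one curve")
  plateaus <- vapply(curves, function(cu) {
    p <- cu$plateau %||% detect_plateau(cu)
    if (p$reached) as.integer(p$size) else NA_integer_
  }, integer(1))
  names(plateaus) <- vapply(curves, function(cu) cu$metric, character(1))
  unreached <- names(plateaus)[is.na(plateaus)]
  size <- if (all(is.na(plateaus))) NA_integer_ else
    max(plateaus, na.rm = TRUE)
  structure(
    list(size = size, per_metric = plateaus, unreached = unreached,
         action = if (is.na(size)) "increase_pool" else "use_size",
         policy = policy),
    class = "sc_recommendation")
}

#' @export
print.sc_recommendation <- function(x, ...) {
  if (x$action == "increase_pool") {
    cat("<sc_recommendation> no metric saturated: increase the pool\n")
  } else {
    cat(sprintf("<sc_recommendation> recommended cell number: %d\n", x$size))
  }
  for (m in names(x$per_metric))
    cat(sprintf("  %-20s plateau %s\n", m,
                if (is.na(x$per_metric[m])) "not reached"
                else format(x$per_metric[m])))
  invisible(x)
}

#' @export
plot.saturation_curve <- function(x, ...) {
  dat <- x$data
  graphics::plot(dat$size, dat$value, type = "b", log = "x",
                 xlab = "cells sampled", ylab = x$metric,
                 main = sprintf("%s vs sample size", x$metric), ...)
  if (isTRUE(x$plateau$reached))
    graphics::abline(v = x$plateau$size, lty = 2, col = "grey40")
  invisible(x)
}
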