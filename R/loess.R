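# Local tricube-weighted polynomial regression (classic LOESS), computed
# exactly at every point: no interpolation surface, so predictions equal a
# per-point weighted-least-squares fit by construction. Used to remove the
# RLuc-on-FLuc trend in screen scoring; residuals feed the z-scores.

#' Fit a local tricube-weighted polynomial regression
#'
#' For each evaluation point the `ceiling(span * n)` nearest neighbours in `x`
#' receive tricube weights `w = (1 - (d/dmax)^3)^3` (with `dmax` the largest
#' neighbour distance); a polynomial of degree `degree` is fitted by weighted
#' least squares and evaluated at the point. If all neighbour distances are 0
#' the fit degenerates to a weighted mean (with a warning).
#'
#' @param x,y Numeric vectors of equal length.
#' @param span Fraction of points in each local neighbourhood, in (0, 1]
#'   (default 0.9).
#' @param degree Local polynomial degree (default 2, classic LOESS; 1 gives
#'   local lines).
#' @return An object of class `loess_local` with elements `x`, `y`, `fitted`,
#'   `residuals`, `span`, `degree`, `n`.
#' @examples
#' x <- runif(50); y <- x^2 + rnorm(50, sd = 0.01)
#' fit <- loess_local(x, y, span = 0.9, degree = 2)
#' glance(fit)
#' @export
loess_local <- function(x, y, span = 0.9, degree = 2L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) abort("`x` and `y` must be finite")
  span <- assert_number(span, "span", min = 1e-6, max = 1)
  degree <- assert_count(degree, "degree", 0L)
  n <- length(x)
  q <- ceiling(span * n)
  if (n < degree + 2L || q < degree + 2L) {
    abort("need at least degree + 2 points in each neighbourhood")
  }
  fitted <- vapply(x, function(x0) loess_point(x0, x, y, q, degree), numeric(1))
  structure(
    list(x = x, y = y, fitted = fitted, residuals = y - fitted,
         span = span, degree = degree, n = n),
    class = "loess_local"
  )
}

# local WLS prediction at a single point x0
loess_point <- function(x0, x, y, q, degree) {
  d <- abs(x - x0)
  dmax <- sort(d, partial = q)[q]
  if (dmax == 0) {
    warn("degenerate neighbourhood (all x identical); using weighted mean")
    return(mean(y[d == 0]))
  }
  w <- (1 - pmin(d / dmax, 1)^3)^3
  use <- w > 0
  # centred basis keeps the design well-conditioned; prediction = intercept
  X <- outer(x[use] - x0, 0:degree, `^`)
  fit <- stats::lm.wfit(X, y[use], w[use])
  unname(fit$coefficients[1L])
}

#' Predict from a `loess_local` fit at new x values
#'
#' Runs the same local regression (neighbourhood, tricube weights, polynomial)
#' against the training data at each new point, so control wells can be scored
#' against a curve fitted on sample wells only.
#'
#' @param object A [loess_local()] fit.
#' @param newdata Numeric vector of x values (default: training x).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.loess_local <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  q <- ceiling(object$span * object$n)
  vapply(as.numeric(newdata),
         function(x0) loess_point(x0, object$x, object$y, q, object$degree),
         numeric(1))
}

#' @export
print.loess_local <- function(x, ...) {
  cat(sprintf(
    "<loess_local> n = %d, span = %.3g, degree = %d, residual SD = %.4g\n",
    x$n, x$span, x$degree, sd(x$residuals)
  ))
  invisible(x)
}

#' @rdname loess_local
#' @param x A `loess_local` object (for `tidy`/`glance`/`augment`).
#' @param ... Unused.
#' @export
tidy.loess_local <- function(x, ...) {
  obj <- x
  tibble(x = obj$x, y = obj$y, .fitted = obj$fitted, .resid = obj$residuals)
}

#' @rdname loess_local
#' @export
glance.loess_local <- function(x, ...) {
  tibble(n = x$n, span = x$span, degree = x$degree,
         sigma = sd(x$residuals), r_squared = 1 - stats::var(x$residuals) / stats::var(x$y))
}

#' @rdname loess_local
#' @param data Optional data frame to bind the fit columns to.
#' @export
augment.loess_local <- function(x, data = NULL, ...) {
  obj <- x
  cols <- tibble(.fitted = obj$fitted, .resid = obj$residuals)
  if (is.null(data)) bind_cols(tibble(x = obj$x, y = obj$y), cols)
  else bind_cols(data, cols)
}
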