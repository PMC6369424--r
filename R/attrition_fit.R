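# Three-parameter exponential engagement-decay model for weekly-active
# curves:  p_w = p_inf + (p0 - p_inf) * exp(-lambda * w),  w = 1, 2, ...
# p0 is the initial weekly-active probability, p_inf the long-run floor,
# lambda the weekly decay rate.

#' Fit the exponential engagement-decay model to a weekly-active curve
#'
#' Least-squares fit of `p_inf + (p0 - p_inf) exp(-lambda w)` to a
#' weekly-active series (fractions in `[0, 1]`, weeks `1..length(curve)`),
#' via bounded quasi-Newton optimization from a small deterministic set of
#' starting values.  A constant curve is the degenerate case: `lambda = 0`
#' with `p0 = p_inf = mean(curve)`.
#'
#' @param curve Numeric vector of weekly-active fractions.
#' @return An object of class `"attrition_fit"` with `coefficients`
#'   (`p0`, `p_inf`, `lambda`), `fitted`, `residuals`, `curve`, `sse`.
#' @export
#' @examples
#' w <- 1:52
#' y <- 0.4 + 0.5 * exp(-0.08 * w)
#' coef(fit_attrition_decay(y))
fit_attrition_decay <- function(curve) {
  y <- as.numeric(curve)
  if (length(y) < 3L) stop("need at least 3 weeks of curve")
  if (any(!is.finite(y)) || any(y < 0 | y > 1))
    stop("curve values must be fractions in [0, 1]")
  w <- seq_along(y)

  mk <- function(par, sse) {
    fitted <- par[2L] + (par[1L] - par[2L]) * exp(-par[3L] * w)
    structure(list(coefficients = c(p0 = par[1L], p_inf = par[2L],
                                    lambda = par[3L]),
                   fitted = fitted, residuals = y - fitted,
                   curve = y, sse = sse),
              class = "attrition_fit")
  }

  if (diff(range(y)) < 1e-9) {
    m <- mean(y)
    return(mk(c(m, m, 0), 0))
  }

  sse <- function(par) {
    p0 <- par[1L]; pinf <- par[2L]; lam <- par[3L]
    sum((pinf + (p0 - pinf) * exp(-lam * w) - y)^2)
  }

  p0_start <- min(max(y[1L], 1e-3), 1)
  tail_n <- max(5L, length(y) %/% 5L)
  pinf_start <- min(max(mean(utils::tail(y, tail_n)), 0), 1)
  best <- NULL
  for (lam0 in c(0.02, 0.05, 0.1, 0.3, 1)) {
    fit <- tryCatch(
      stats::optim(c(p0_start, pinf_start, lam0), sse, method = "L-BFGS-B",
                   lower = c(0, 0, 0), upper = c(1, 1, 20),
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("decay fit failed to converge")
  mk(best$par, best$value)
}

#' @export
print.attrition_fit <- function(x, ...) {
  cat("Exponential engagement-decay fit: p_inf + (p0 - p_inf) exp(-lambda w)\n")
  cat(sprintf("  p0 = %.4f, p_inf = %.4f, lambda = %.4f /week  (SSE %.3g, %d weeks)\n",
              x$coefficients["p0"], x$coefficients["p_inf"],
              x$coefficients["lambda"], x$sse, length(x$curve)))
  invisible(x)
}

#' @export
coef.attrition_fit <- function(object, ...) object$coefficients

#' @export
fitted.attrition_fit <- function(object, ...) object$fitted

#' @export
residuals.attrition_fit <- function(object, ...) object$residuals

#' Predicted weekly-active fraction from a decay fit
#' @param object An `"attrition_fit"`.
#' @param week Week indexes (default the fitted weeks).
#' @param ... Unused.
#' @export
predict.attrition_fit <- function(object, week = seq_along(object$curve), ...) {
  cf <- object$coefficients
  unname(cf["p_inf"] + (cf["p0"] - cf["p_inf"]) * exp(-cf["lambda"] * week))
}

#' Plot a weekly-active curve and its decay fit
#' @param x An `"attrition_fit"`.
#' @param ... Passed to [plot()].
#' @export
plot.attrition_fit <- function(x, ...) {
  w <- seq_along(x$curve)
  plot(w, x$curve, xlab = "week since enrollment",
       ylab = "fraction of cohort active", ylim = c(0, 1), pch = 16, ...)
  graphics::lines(w, x$fitted, lwd = 2)
  invisible(x)
}
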