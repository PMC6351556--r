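# Saturating logarithmic growth-curve fitting for clonal-expansion series,
# plus the exponential-saturation alternative used for model comparison.
#
# The working model for the expansion of the labelled population is
#   y = a * ln(t + b)
# with y the GFP% statistic and t the chase time in days. In constrained
# mode b is fixed to 1 and the fit has the closed form of a no-intercept
# regression of y on ln(t + 1); in free mode (a, b) are fitted by nonlinear
# least squares. Both models pass through y(0) = 0: a freshly labelled
# population occupies no measurable area.

as_growth_xy <- function(series) {
  if (is.data.frame(series)) {
    if (!all(c("time_days", "gfp_percent") %in% names(series)))
      stop("growth series needs columns time_days and gfp_percent",
           call. = FALSE)
    list(x = as.numeric(series$time_days), y = as.numeric(series$gfp_percent))
  } else if (is.list(series) && all(c("x", "y") %in% names(series))) {
    list(x = as.numeric(series$x), y = as.numeric(series$y))
  } else stop("unsupported growth series object", call. = FALSE)
}

new_growth_fit <- function(coeffs, x, y, fitted, model_tag, formula_text,
                           call) {
  res <- y - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) (if (ss_res == 0) 1 else -Inf) else 1 - ss_res / ss_tot
  structure(list(coefficients = coeffs,
                 r_squared = r2,
                 residuals = res,
                 fitted.values = fitted,
                 data = data.frame(time_days = x, gfp_percent = y),
                 model_tag = model_tag,
                 formula_text = formula_text,
                 call = call),
            class = "growth_fit")
}

#' Fit the saturating logarithmic growth law
#'
#' Least-squares fit of `y = a * ln(t + b)` to (chase time, GFP%)
#' observations. The default constrained mode fixes `b = 1` and uses the
#' closed-form no-intercept solution
#' `a = sum(y * l) / sum(l^2)`, `l = ln(t + 1)`; with `free_offset = TRUE`
#' both parameters are estimated by nonlinear least squares (start
#' `a = 1, b = 1`, convergence tolerance 1e-10, at most 500 iterations).
#'
#' @param series a `growth_series` data frame (columns `time_days`,
#'   `gfp_percent`) or a list with `x` and `y`.
#' @param free_offset fit the offset `b` instead of fixing it to 1.
#' @return An object of class `growth_fit` with `coefficients` (`a`, `b`),
#'   `r_squared` (`1 - SS_res/SS_tot`), `residuals`, `fitted.values`,
#'   the observations and a `model_tag` (`log_constrained` or `log_free`).
#' @examples
#' s <- simulate_growth_series(growth_config(obs_noise_sd = 0))
#' fit <- fit_log_growth(s)
#' coef(fit)
#' @export
fit_log_growth <- function(series, free_offset = FALSE) {
  d <- as_growth_xy(series)
  x <- d$x
  y <- d$y
  if (length(unique(x)) < 2L)
    stop("at least 2 distinct time points are required", call. = FALSE)
  if (free_offset && length(unique(x)) < 3L)
    stop("free-offset fit needs at least 3 distinct time points",
         call. = FALSE)
  if (any(x + 1 <= 0))
    stop("x + b must be positive over the observations", call. = FALSE)
  if (var(y) == 0 && all(y != 0) )
    stop("degenerate series: all responses identical", call. = FALSE)

  if (!free_offset) {
    l <- log(x + 1)
    if (sum(l^2) == 0)
      stop("degenerate series: no variation in ln(t + 1)", call. = FALSE)
    a <- sum(y * l) / sum(l^2)
    return(new_growth_fit(c(a = a, b = 1), x, y, a * l, "log_constrained",
                          "y = a * ln(t + 1)", match.call()))
  }
  dat <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(y ~ a * log(x + b), data = dat,
                           start = list(a = 1, b = 1),
                           lower = c(a = -Inf, b = max(1e-9, -min(x) + 1e-9)),
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-10, ptol = 1e-10, maxiter = 500))
  cf <- coef(fit)
  new_growth_fit(c(a = unname(cf["a"]), b = unname(cf["b"])), x, y,
                 unname(predict(fit)), "log_free", "y = a * ln(t + b)",
                 match.call())
}

#' Fit the exponential-saturation alternative model
#'
#' Least-squares fit of the saturating form `y = c * (1 - exp(-t / tau))`,
#' the alternative growth law against which the logarithmic model is
#' compared. R-squared is computed on the same observations so the two
#' models are directly comparable via [compare_models()].
#'
#' @param series as in [fit_log_growth()]; at least 3 observations.
#' @return A `growth_fit` with coefficients `c` and `tau` and
#'   `model_tag = "exp_decay"`.
#' @export
fit_exp_decay_alternative <- function(series) {
  d <- as_growth_xy(series)
  x <- d$x
  y <- d$y
  if (length(x) < 3L)
    stop("at least 3 observations are required", call. = FALSE)
  if (var(y) == 0)
    stop("saturation time is unidentifiable on a constant series (non-convergence)",
         call. = FALSE)
  dat <- data.frame(x = x, y = y)
  c0 <- max(y)
  if (c0 <= 0) c0 <- 1
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ cc * (1 - exp(-x / tau)), data = dat,
                      start = list(cc = c0, tau = max(median(x), 1e-3)),
                      lower = c(cc = -Inf, tau = 1e-9),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
    error = function(e) stop("exponential-saturation fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  new_growth_fit(c(c = unname(cf["cc"]), tau = unname(cf["tau"])), x, y,
                 unname(predict(fit)), "exp_decay",
                 "y = c * (1 - exp(-t / tau))", match.call())
}

#' Rank competing growth fits
#'
#' Orders fits of the same observations by R-squared (higher first), with
#' residual root-mean-square as tie-break (lower first); ties beyond that
#' keep input order. Residual summaries replace visual inspection of fit
#' quality.
#'
#' @param fits a list of `growth_fit` objects over identical observations.
#' @return A data frame (best first) with `model_tag`, `r_squared`,
#'   `residual_rms`, `max_abs_residual`, `rank`.
#' @export
compare_models <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L ||
      !all(vapply(fits, inherits, TRUE, "growth_fit")))
    stop("need at least two growth_fit objects", call. = FALSE)
  ref <- fits[[1]]$data
  for (f in fits[-1])
    if (!isTRUE(all.equal(ref, f$data)))
      stop("fits were computed on different observation sets", call. = FALSE)
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  rms <- vapply(fits, function(f) sqrt(mean(f$residuals^2)), numeric(1))
  ord <- order(-r2, rms, seq_along(fits))
  out <- data.frame(model_tag = vapply(fits, `[[`, "", "model_tag")[ord],
                    r_squared = r2[ord], residual_rms = rms[ord],
                    max_abs_residual = vapply(
                      fits, function(f) max(abs(f$residuals)), numeric(1))[ord],
                    rank = seq_along(fits))
  rownames(out) <- NULL
  out
}

# ---- growth_fit methods ----------------------------------------------------

growth_curve_fun <- function(object) {
  cf <- object$coefficients
  switch(object$model_tag,
         log_constrained = ,
         log_free = function(t) cf[["a"]] * log(t + cf[["b"]]),
         exp_decay = function(t) cf[["c"]] * (1 - exp(-t / cf[["tau"]])),
         stop("unknown model_tag"))
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth fit [%s]: %s\n", x$model_tag, x$formula_text))
  cat("  coefficients:",
      paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  R-squared = %.4f on %d observations\n", x$r_squared,
              nrow(x$data)))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
fitted.growth_fit <- function(object, ...) object$fitted.values

#' @export
residuals.growth_fit <- function(object, ...) object$residuals

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  f <- growth_curve_fun(object)
  if (is.null(newdata)) return(object$fitted.values)
  t <- if (is.data.frame(newdata)) newdata$time_days else as.numeric(newdata)
  f(t)
}

#' @export
summary.growth_fit <- function(object, ...) {
  structure(list(fit = object,
                 residual_rms = sqrt(mean(object$residuals^2)),
                 residual_summary = summary(object$residuals)),
            class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual RMS = %.6g\n", x$residual_rms))
  cat("  residuals:\n")
  print(x$residual_summary)
  invisible(x)
}

#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$data)
  s <- sd(object$residuals)
  out <- as.data.frame(replicate(nsim, object$fitted.values + rnorm(n, 0, s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(object$data["time_days"], out)
}

#' Plot a growth fit
#'
#' Observations with the fitted curve overlaid.
#'
#' @param x a `growth_fit`.
#' @param ... passed to [plot()].
#' @export
plot.growth_fit <- function(x, ...) {
  d <- x$data
  plot(d$time_days, d$gfp_percent, xlab = "chase time (days)",
       ylab = "GFP (%)", pch = 19, col = "grey30", ...)
  f <- growth_curve_fun(x)
  tt <- seq(min(d$time_days), max(d$time_days), length.out = 200)
  graphics::lines(tt, f(tt), col = "firebrick", lwd = 2)
  legend("bottomright", bty = "n",
         legend = sprintf("%s, R2 = %.3f", x$formula_text, x$r_squared))
  invisible(x)
}
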