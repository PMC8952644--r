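#' Single-exponential decay fit
#'
#' Weighted least-squares fit of \eqn{A e^{-t/\tau}} to a decay curve.
#' Count curves use Neyman weights \eqn{1/\max(n_k, 1)} (standard TCSPC
#' practice); model curves are fitted unweighted. Starting values come from a
#' log-linear regression on the positive channels.
#'
#' @param curve A [decay_curve] (or data frame with `time_ns` plus a value
#'   column).
#' @param fit_range Optional `c(t_min, t_max)` window, ns.
#' @param value Name of the value column (default: auto-detect).
#' @param weighting Residual weighting for count curves: `"neyman"`
#'   (\eqn{1/\max(n_k,1)}, the TCSPC default), `"pearson"` (iteratively
#'   reweighted \eqn{1/\max(\hat\mu_k,1)}; unbiased on sparse histograms,
#'   where Neyman weights pull the lifetime down), or `"none"`. Model curves
#'   are always fitted unweighted.
#' @return A `fret_fit` object; see [tidy.fret_fit()].
#' @examples
#' tt <- seq(0.01, 20, length.out = 256)
#' curve <- decay_curve(tibble::tibble(time_ns = tt,
#'                                     intensity = 0.5 * exp(-tt / 1)),
#'                      kind = "model")
#' coef(fit_monoexponential(curve))
#' @export
fit_monoexponential <- function(curve, fit_range = NULL, value = NULL,
                                weighting = c("neyman", "pearson", "none")) {
  weighting <- match.arg(weighting)
  value <- value %||% value_column(curve)
  df <- tibble(t = curve$time_ns, y = curve[[value]])
  if (!is.null(fit_range)) {
    df <- dplyr::filter(df, .data$t >= fit_range[1], .data$t <= fit_range[2])
  }
  if (sum(df$y > 0) < 3) {
    abort("need at least 3 channels with positive content in the fit range.",
          class = "fretsphere_fit_error")
  }
  counts_like <- identical(attr(curve, "kind"), "counts")
  if (!counts_like) weighting <- "none"
  w <- if (weighting == "none") rep(1, nrow(df)) else 1 / pmax(df$y, 1)
  pos <- df$y > 0
  ll <- lm(log(y) ~ t, data = df[pos, ])
  start <- list(A = exp(coef(ll)[[1]]), tau = max(-1 / coef(ll)[[2]], 1e-3))
  n_pass <- if (weighting == "pearson") 4L else 1L
  for (pass in seq_len(n_pass)) {
    fit <- minpack.lm::nlsLM(
      y ~ A * exp(-t / tau), data = df, start = start, weights = w,
      lower = c(A = 0, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    start <- as.list(coef(fit))
    if (weighting == "pearson") w <- 1 / pmax(stats::fitted(fit), 1e-3)
  }
  new_fret_fit(fit, model = "monoexponential", data = df,
               free = c("A", "tau"), n_starts = 1L)
}

#' Fit the analytic size-dispersed decay model
#'
#' Least-squares estimation of single-step FRET model parameters (acceptor
#' number, mean radius, size spread, amplitude) from a decay curve, using the
#' analytic model [donor_decay()], optionally convolved with a Gaussian
#' instrument response. Count curves are weighted by \eqn{1/\max(n_k, 1)}.
#' The optimizer (Levenberg--Marquardt with box bounds) is restarted from
#' `n_starts` randomly perturbed starting points (+-`perturb` relative) and
#' the best converged objective is kept; start perturbations use the current
#' RNG state, so seed the session for reproducibility.
#'
#' The acceptor number enters the model as a continuous exponent; it is
#' optimized as a real number and reported both raw and rounded. The size
#' spread `sigma` is only weakly identifiable from the decay shape alone: if
#' you free it, quote its confidence interval (see [tidy.fret_fit()] with
#' `conf.int = TRUE`), not the bare point estimate.
#'
#' @param curve A [decay_curve] with `time_ns` and a counts/intensity column.
#' @param params A [photophysics_params()] (fixed photophysical constants).
#' @param dist A [size_distribution()]: initial / fixed values of `mean_R`
#'   and `sigma`.
#' @param n_acceptors Initial / fixed acceptor number.
#' @param free Character subset of `c("n_acceptors", "mean_R", "sigma",
#'   "amplitude")` to optimize.
#' @param amplitude Initial / fixed amplitude (default: scales the model to
#'   the data).
#' @param lower,upper Named bound overrides for free parameters.
#' @param n_starts Number of perturbed restarts (>= 1).
#' @param perturb Relative perturbation of starting values.
#' @param irf_fwhm Gaussian instrument-response FWHM, ns; 0 disables
#'   convolution (default: decays are analyzed as recorded).
#' @param weighting Count-curve weighting as in [fit_monoexponential()].
#' @param value Value column name (default auto-detect).
#' @param n_nodes Radius-quadrature order passed to [donor_decay()].
#' @return A `fret_fit` object.
#' @export
fit_decay_model <- function(curve, params, dist, n_acceptors,
                            free = c("n_acceptors", "mean_R", "amplitude"),
                            amplitude = NULL, lower = NULL, upper = NULL,
                            n_starts = 5L, perturb = 0.2, irf_fwhm = 0,
                            value = NULL, n_nodes = 64L,
                            weighting = c("neyman", "pearson", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(params, "photophysics_params"),
            inherits(dist, "size_distribution"), n_starts >= 1)
  allowed <- c("n_acceptors", "mean_R", "sigma", "amplitude")
  free <- match.arg(free, allowed, several.ok = TRUE)
  value <- value %||% value_column(curve)
  df <- tibble(t = curve$time_ns, y = curve[[value]])
  counts_like <- identical(attr(curve, "kind"), "counts")
  if (!counts_like) weighting <- "none"
  w <- if (weighting == "none") rep(1, nrow(df)) else 1 / pmax(df$y, 1)

  model0 <- donor_decay(df$t, params, dist, n_acceptors, n_nodes = n_nodes)
  amplitude <- amplitude %||% (sum(df$y * model0) / sum(model0^2))
  base <- c(n_acceptors = n_acceptors, mean_R = dist$mean_R,
            sigma = dist$sigma, amplitude = amplitude)
  lo <- c(n_acceptors = 0, mean_R = 1, sigma = 1e-4, amplitude = 0)
  hi <- c(n_acceptors = Inf, mean_R = Inf, sigma = Inf, amplitude = Inf)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  dt <- if (nrow(df) > 1) df$t[2] - df$t[1] else NA_real_
  model_fun <- function(t, n_acceptors, mean_R, sigma, amplitude) {
    m <- amplitude * donor_decay(t, params, size_distribution(mean_R, sigma),
                                 n_acceptors, n_nodes = n_nodes)
    if (irf_fwhm > 0) m <- gaussian_convolve(m, dt, irf_fwhm)
    m
  }

  best <- NULL
  for (k in seq_len(n_starts)) {
    st <- base[free]
    if (k > 1) st <- st * runif(length(st), 1 - perturb, 1 + perturb)
    st <- pmin(pmax(st, lo[free] + 1e-9), hi[free])
    fml <- stats::as.formula(paste(
      "y ~ model_fun(t,",
      paste(vapply(allowed, function(p) {
        if (p %in% free) p else format(base[[p]], digits = 17)
      }, character(1)), collapse = ", "), ")"))
    wk <- w
    n_pass <- if (weighting == "pearson") 3L else 1L
    fit <- NULL
    for (pass in seq_len(n_pass)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(fml, data = df, start = as.list(st), weights = wk,
                          lower = unname(lo[free]), upper = unname(hi[free]),
                          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(fit)) break
      st <- setNames(coef(fit), free)
      if (weighting == "pearson") wk <- 1 / pmax(stats::fitted(fit), 1e-3)
    }
    if (is.null(fit)) next
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  if (is.null(best)) {
    abort("model fit failed to converge from any starting point.",
          class = "fretsphere_fit_error")
  }
  new_fret_fit(best, model = "single_step_analytic", data = df, free = free,
               n_starts = n_starts,
               fixed = c(base[setdiff(allowed, free)],
                         irf_fwhm = irf_fwhm),
               bounds = list(lower = lo[free], upper = hi[free]))
}

new_fret_fit <- function(fit, model, data, free, n_starts, fixed = NULL,
                         bounds = NULL) {
  sm <- summary(fit)
  est <- coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  at_bound <- if (!is.null(bounds)) {
    abs(est - bounds$lower) < 1e-8 | abs(est - bounds$upper) < 1e-8
  } else rep(FALSE, length(est))
  if (any(at_bound)) {
    warn(paste("estimate(s) at bound:", paste(names(est)[at_bound],
                                              collapse = ", ")))
  }
  structure(
    list(fit = fit, model = model,
         estimates = tibble(term = names(est), estimate = unname(est),
                            std.error = unname(se)),
         objective = deviance(fit),
         convergence = fit$convInfo$isConv %||% TRUE,
         at_bound = at_bound, free = free, fixed = fixed,
         n_starts = n_starts, data = data,
         fitted = stats::fitted(fit)),
    class = "fret_fit")
}

#' @export
coef.fret_fit <- function(object, ...) {
  setNames(object$estimates$estimate, object$estimates$term)
}

#' @export
print.fret_fit <- function(x, ...) {
  cat(sprintf("<fret_fit: %s> %s\n", x$model,
              if (isTRUE(x$convergence)) "converged" else "NOT converged"))
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    extra <- if (est$term[i] == "n_acceptors")
      sprintf("  (rounded: %d)", round(est$estimate[i])) else ""
    cat(sprintf("  %-12s %12.6g +- %.3g%s\n", est$term[i], est$estimate[i],
                est$std.error[i], extra))
  }
  cat(sprintf("  weighted RSS: %g over %d channels (%d start%s)\n",
              x$objective, nrow(x$data), x$n_starts,
              if (x$n_starts > 1) "s" else ""))
  invisible(x)
}

#' Tidy a decay fit
#'
#' @param x A `fret_fit`.
#' @param conf.int Add Wald confidence intervals.
#' @param conf.level Confidence level.
#' @param ... Ignored.
#' @return A tibble with one row per estimated parameter (`term`, `estimate`,
#'   `std.error`, optionally `conf.low`/`conf.high`).
#' @export
tidy.fret_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- x$estimates
  if (conf.int) {
    dfree <- nrow(x$data) - nrow(out)
    q <- qt(1 - (1 - conf.level) / 2, dfree)
    out <- dplyr::mutate(out, conf.low = .data$estimate - q * .data$std.error,
                         conf.high = .data$estimate + q * .data$std.error)
  }
  out
}

#' One-line fit summary
#'
#' @param x A `fret_fit`.
#' @param ... Ignored.
#' @return One-row tibble: `objective` (weighted RSS), `converged`, `nobs`,
#'   `n_starts`, `any_at_bound`.
#' @export
glance.fret_fit <- function(x, ...) {
  tibble(objective = x$objective, converged = isTRUE(x$convergence),
         nobs = nrow(x$data), n_starts = x$n_starts,
         any_at_bound = any(x$at_bound))
}

#' Plot a fit with residuals
#'
#' @param object A `fret_fit`.
#' @param ... Ignored.
#' @return A ggplot object (log-scale data + model overlay).
#' @export
autoplot.fret_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, fitted = object$fitted)
  ggplot2::ggplot(dplyr::filter(df, .data$y > 0),
                  ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "signal",
                  title = sprintf("%s fit", object$model)) +
    ggplot2::theme_minimal()
}

# discrete Gaussian convolution on a uniform grid, kernel normalized to unit
# sum; open convolution truncated back to the original window
gaussian_convolve <- function(v, dt, fwhm) {
  sdk <- fwhm / (2 * sqrt(2 * log(2)))
  h <- ceiling(4 * sdk / dt)
  if (2 * h + 1 > length(v)) {
    abort("IRF kernel is wider than the decay window.",
          class = "fretsphere_domain_error")
  }
  kern <- dnorm(seq(-h, h) * dt, sd = sdk)
  kern <- kern / sum(kern)
  full <- convolve(v, rev(kern), type = "open")
  full[(h + 1):(h + length(v))]
}

#' Convolve a model decay with a Gaussian instrument response
#'
#' Discrete convolution of a uniformly channelized decay with a normalized
#' Gaussian kernel of the given full width at half maximum (e.g. the 0.28 ns
#' width of a ps pulsed-diode excitation system). The kernel sums to one, so
#' the curve integral is preserved up to edge truncation; `fwhm = 0` returns
#' the input unchanged.
#'
#' @param curve A [decay_curve].
#' @param fwhm Kernel full width at half maximum, ns.
#' @param value Value column to convolve (default auto-detect).
#' @return A [decay_curve] of kind `"model"` on the same time grid.
#' @export
convolve_irf <- function(curve, fwhm, value = NULL) {
  stopifnot(fwhm >= 0)
  value <- value %||% value_column(curve)
  if (fwhm == 0) return(curve)
  dt <- curve$time_ns[2] - curve$time_ns[1]
  out <- as_tibble(curve)
  out[[value]] <- gaussian_convolve(curve[[value]], dt, fwhm)
  new_decay_curve(out, kind = "model",
                  meta = c(attr(curve, "meta"), list(irf_fwhm = fwhm)))
}
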