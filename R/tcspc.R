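#' Synthetic TCSPC measurement of a model decay
#'
#' Emulates a time-correlated single-photon counting histogram: per-channel
#' counts are drawn independently Poisson with mean proportional to the
#' (optionally IRF-convolved) model curve plus a flat background, scaled so
#' the expected total equals `total_counts`. Channel independence ignores
#' pile-up and dead time (single-photon regime). Uses the session RNG; call
#' `set.seed()` for reproducible fixtures.
#'
#' @param model A [decay_curve] of model intensities (non-negative, not all
#'   zero).
#' @param total_counts Expected total photon count (> 0).
#' @param background Expected background counts per channel (>= 0).
#' @param irf_fwhm Gaussian instrument-response FWHM, ns; 0 disables.
#' @param value Value column of `model` (default auto-detect).
#' @return A [decay_curve] of kind `"counts"` with columns `time_ns`,
#'   `counts`; `meta` records the generation settings.
#' @examples
#' set.seed(42)
#' m <- analytic_decay_curve(photophysics_params(), size_distribution(75, 5),
#'                           n_acceptors = 335, k_max = 256)
#' d <- generate_tcspc(m, total_counts = 1e5)
#' sum(d$counts)
#' @export
generate_tcspc <- function(model, total_counts, background = 0, irf_fwhm = 0,
                           value = NULL) {
  stopifnot(total_counts > 0, background >= 0)
  value <- value %||% value_column(model, prefer = c("intensity", "counts",
                                                     "value"))
  v <- model[[value]]
  if (any(v < 0)) {
    abort("model curve must be non-negative.", class = "fretsphere_domain_error")
  }
  if (all(v == 0)) {
    abort("model curve is identically zero: nothing to measure.",
          class = "fretsphere_domain_error")
  }
  k <- length(v)
  if (irf_fwhm > 0) {
    dt <- model$time_ns[2] - model$time_ns[1]
    v <- gaussian_convolve(v, dt, irf_fwhm)
  }
  signal <- total_counts - background * k
  if (signal < 0) {
    abort("`background` exceeds the total count budget.",
          class = "fretsphere_domain_error")
  }
  lambda <- background + v / sum(v) * signal
  new_decay_curve(
    tibble(time_ns = model$time_ns, counts = rpois(k, lambda)),
    kind = "counts",
    meta = c(attr(model, "meta"),
             list(tcspc = list(total_counts = total_counts,
                               background = background,
                               irf_fwhm = irf_fwhm))))
}
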