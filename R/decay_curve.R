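#' Decay-curve container
#'
#' A `decay_curve` is a tibble with a uniformly spaced `time_ns` column plus
#' one or more value columns (`counts`, `intensity`, `survival`), carrying
#' `kind` ("counts", "model" or "survival") and a `meta` provenance list as
#' attributes. All package functions that consume decays accept it (or any
#' data frame with compatible columns).
#'
#' @param x A data frame with a `time_ns` column and at least one value
#'   column.
#' @param kind One of `"counts"`, `"model"`, `"survival"`.
#' @param meta Named list of provenance (parameters, seed, counts, ...).
#' @return A tibble of class `decay_curve`.
#' @export
decay_curve <- function(x, kind = c("counts", "model", "survival"),
                        meta = list()) {
  kind <- match.arg(kind)
  x <- as_tibble(x)
  if (!"time_ns" %in% names(x) || ncol(x) < 2) {
    abort("a decay curve needs a `time_ns` column and at least one value column.",
          class = "fretsphere_parse_error")
  }
  validate_time_axis(x$time_ns)
  new_decay_curve(x, kind, meta)
}

new_decay_curve <- function(x, kind, meta = list()) {
  structure(as_tibble(x), kind = kind, meta = meta,
            class = c("decay_curve", class(as_tibble(x))))
}

validate_time_axis <- function(t, rel_tol = 1e-6) {
  if (length(t) < 2) return(invisible(t))
  dt <- diff(t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    abort(sprintf("time axis is not strictly increasing (row %d).", bad),
          class = "fretsphere_parse_error")
  }
  if (max(abs(dt - dt[1])) > rel_tol * abs(dt[1])) {
    abort("time axis is not uniformly spaced.",
          class = "fretsphere_parse_error")
  }
  invisible(t)
}

value_column <- function(curve, prefer = c("counts", "intensity", "survival",
                                           "value")) {
  nm <- intersect(prefer, names(curve))
  if (!length(nm)) {
    nm <- setdiff(names(curve), "time_ns")[1]
    if (is.na(nm)) abort("no value column found.",
                         class = "fretsphere_parse_error")
  } else nm <- nm[1]
  nm
}

#' Normalized survival curve from a count histogram
#'
#' Converts per-channel termination counts \eqn{n_k} into the normalized
#' decay histogram \eqn{I(t_k) = 1 - \sum_{j\le k} n_j / \sum_j n_j}: the
#' empirical complementary CDF of termination times, i.e. the excitation
#' survival probability. It is nonincreasing, starts at \eqn{\le 1} and ends
#' at 0.
#'
#' @param counts Non-negative per-channel counts.
#' @return Numeric vector, same length.
#' @examples
#' eq_survival(c(5, 3, 2))  # 0.5, 0.2, 0
#' @export
eq_survival <- function(counts) {
  if (any(counts < 0)) {
    abort("counts must be non-negative.", class = "fretsphere_domain_error")
  }
  tot <- sum(counts)
  if (tot == 0) {
    abort("no recorded events: cannot normalize an empty histogram.",
          class = "fretsphere_empty_result")
  }
  1 - cumsum(counts) / tot
}

#' @export
print.decay_curve <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<decay_curve: %s> %d channels", attr(x, "kind"), nrow(x)))
  if (!is.null(meta$n_traj)) cat(sprintf(", %s trajectories", meta$n_traj))
  cat("\n")
  NextMethod()
}

#' Plot a decay curve
#'
#' Log-intensity decay plot in the usual TCSPC presentation.
#'
#' @param object A [decay_curve].
#' @param value Value column to plot (default: first of counts, intensity,
#'   survival).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.decay_curve <- function(object, value = NULL, ...) {
  value <- value %||% value_column(object)
  df <- as_tibble(object)[, c("time_ns", value)]
  names(df) <- c("time_ns", "value")
  df <- dplyr::filter(df, .data$value > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ns, .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = value) +
    ggplot2::theme_minimal()
}
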