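#' Pairwise transfer-rate table of a realization
#'
#' Computes Foerster rates \eqn{w_{ij} = (1/\tau_{0D})(R_{0XY}/r_{ij})^6} for
#' every ordered donor-to-fluorophore pair of one particle realization
#' (donor--donor homotransfer uses `R0DD`, donor-to-acceptor transfer uses
#' `R0DA`). Acceptors are perfect traps: they have no outgoing rates. In
#' `"explicit_static"` orientation mode each rate is additionally scaled by
#' the pair's frozen \eqn{\kappa^2 / \kappa^2_{\mathrm{ref}}}. The table is
#' built once per realization and reused across all excitations of it.
#'
#' @param realization A [sample_configuration()] result (donors first).
#' @param params A [photophysics_params()].
#' @return An object of class `rate_table`: `pair_rates` (n x n, 1/ns, zero
#'   diagonal and zero acceptor rows), `decay_rate` (1/ns), `row_totals`
#'   (per-fluorophore total exit rate; `decay_rate + sum_j w_ij` for donors,
#'   0 for acceptors), `n_donors`, `chord2` (squared pairwise chords, nm^2).
#' @export
build_rate_table <- function(realization, params) {
  stopifnot(inherits(realization, "nanoparticle_realization"),
            inherits(params, "photophysics_params"))
  sp <- realization$species
  n <- length(sp)
  n_d <- sum(sp == "donor")
  if (n_d > 0 && any(sp[seq_len(n_d)] != "donor")) {
    abort("realization must list donors before acceptors.",
          class = "fretsphere_domain_error")
  }
  P <- realization$positions
  D2 <- unname(as.matrix(stats::dist(P)))^2
  if (n > 1) {
    off <- D2[upper.tri(D2)]
    if (any(off <= 0)) {
      abort("coincident fluorophores: transfer rate diverges.",
            class = "fretsphere_domain_error")
    }
  }
  R06 <- matrix(params$R0DA^6, n, n)
  if (n_d > 1) R06[seq_len(n_d), seq_len(n_d)] <- params$R0DD^6
  W <- matrix(0, n, n)
  if (n > 1) {
    W <- (1 / params$tau0D) * R06 / pmax(D2, .Machine$double.xmin)^3
    diag(W) <- 0
    if (params$kappa2_mode == "explicit_static") {
      W <- W * pair_kappa2(P, realization$dipoles) / params$kappa2_ref
    }
    if (n_d < n) W[(n_d + 1L):n, ] <- 0   # acceptors are absorbing
  }
  diag(W) <- 0
  row_totals <- rowSums(W)
  row_totals[seq_len(n_d)] <- row_totals[seq_len(n_d)] + 1 / params$tau0D
  if (n_d < n) row_totals[(n_d + 1L):n] <- 0
  structure(list(pair_rates = W, decay_rate = 1 / params$tau0D,
                 row_totals = row_totals, n_donors = n_d, chord2 = D2),
            class = "rate_table")
}

# per-pair kappa^2 matrix from positions and frozen dipoles
pair_kappa2 <- function(P, Dp) {
  n <- nrow(P)
  D2 <- unname(as.matrix(stats::dist(P)))^2
  r <- sqrt(pmax(D2, .Machine$double.xmin))
  cosDD <- Dp %*% t(Dp)
  X <- Dp %*% t(P)               # X[i, j] = d_i . p_j
  ds <- rowSums(Dp * P)          # d_i . p_i
  A <- (X - ds) / r              # d_i . (p_j - p_i) / r_ij
  B <- t(A)                      # flips r-hat sign; product A*B is invariant
  B <- -B                        # d_j . (p_j - p_i)/r = -(d_j . (p_i - p_j))/r
  k <- cosDD - 3 * A * B
  k2 <- k^2
  diag(k2) <- 0
  k2
}

#' Simulate one excitation trajectory (reference implementation)
#'
#' Pure-R Gillespie loop over one excitation: starting from a uniformly chosen
#' donor, draw the exponential waiting time from the current total exit rate,
#' then select intrinsic decay, a donor-to-donor hop, or trapping by an
#' acceptor with probabilities proportional to their rates. Donor-to-donor
#' hops move the excitation and increment the jump count; trapping and
#' intrinsic decay terminate it. The compiled engine behind [simulate_decay()]
#' implements the identical process; this function exists for inspection and
#' event-level diagnostics.
#'
#' @param table A [build_rate_table()] result.
#' @param record_events If `TRUE`, attach the per-event log (site, waiting
#'   time) as attribute `"events"`.
#' @return One-row tibble: `event_time` (ns), `termination`
#'   (`"donor_decay"`/`"acceptor_trap"`), `n_jumps`, `sq_displacement`
#'   (nm^2, chord squared from the initially excited donor to the site
#'   occupied at termination).
#' @export
run_trajectory <- function(table, record_events = FALSE) {
  stopifnot(inherits(table, "rate_table"))
  n_d <- table$n_donors
  if (n_d < 1) abort("at least one donor is required.",
                     class = "fretsphere_domain_error")
  n <- nrow(table$pair_rates)
  start <- sample.int(n_d, 1L)
  cur <- start; t <- 0; nj <- 0L
  log_site <- integer(); log_dt <- numeric()
  repeat {
    w_row <- table$pair_rates[cur, ]
    W <- table$decay_rate + sum(w_row)
    dt <- stats::rexp(1L, W)
    t <- t + dt
    if (record_events) { log_site <- c(log_site, cur); log_dt <- c(log_dt, dt) }
    u <- runif(1L) * W
    if (u <= table$decay_rate) { term <- "donor_decay"; fin <- cur; break }
    j <- findInterval(u - table$decay_rate, cumsum(w_row), left.open = TRUE) + 1L
    j <- min(j, n)
    if (j <= n_d) { cur <- j; nj <- nj + 1L } else {
      term <- "acceptor_trap"; fin <- j; break
    }
  }
  out <- tibble(event_time = t, termination = term, n_jumps = nj,
                sq_displacement = table$chord2[start, fin])
  if (record_events) attr(out, "events") <- tibble(site = log_site,
                                                   waiting_time = log_dt)
  out
}

# transfer-rate row and squared chords of a lone donor (avoids the full
# n x n table; same rates as build_rate_table)
donor_row <- function(np, params) {
  P <- np$positions
  n <- nrow(P)
  d2 <- (P[, 1] - P[1, 1])^2 + (P[, 2] - P[1, 2])^2 + (P[, 3] - P[1, 3])^2
  w <- numeric(n)
  if (n > 1) {
    if (any(d2[-1] <= 0)) {
      abort("coincident fluorophores: transfer rate diverges.",
            class = "fretsphere_domain_error")
    }
    w[-1] <- (1 / params$tau0D) * params$R0DA^6 / d2[-1]^3
    if (params$kappa2_mode == "explicit_static") {
      r <- sqrt(d2[-1])
      rhat <- sweep(P[-1, , drop = FALSE], 2, P[1, ]) / r
      k2 <- orientation_factor(
        matrix(np$dipoles[1, ], n - 1, 3, byrow = TRUE),
        np$dipoles[-1, , drop = FALSE], rhat)
      w[-1] <- w[-1] * k2 / params$kappa2_ref
    }
  }
  list(rates = matrix(w, 1), chord2 = matrix(d2, 1))
}

# shared driver: run n_configs fresh realizations x n_traj trajectories
kmc_ensemble <- function(spec, dist, params, n_configs, n_traj_per_config) {
  stopifnot(inherits(spec, "labeling_spec"), n_configs >= 1,
            n_traj_per_config >= 1)
  if (spec$n_donors < 1) {
    abort("at least one donor is required.", class = "fretsphere_domain_error")
  }
  radii <- sample_radius(n_configs, dist)
  single_donor <- spec$n_donors == 1L
  out <- vector("list", n_configs)
  for (cfg in seq_len(n_configs)) {
    np <- sample_configuration(spec, radii[cfg])
    if (single_donor) {
      row <- donor_row(np, params)
      res <- run_kmc_cpp(row$rates, 1 / params$tau0D, row$chord2,
                         as.integer(n_traj_per_config))
    } else {
      tab <- build_rate_table(np, params)
      n_d <- tab$n_donors
      res <- run_kmc_cpp(tab$pair_rates[seq_len(n_d), , drop = FALSE],
                         tab$decay_rate,
                         tab$chord2[seq_len(n_d), , drop = FALSE],
                         as.integer(n_traj_per_config))
    }
    res$config <- cfg
    res$radius <- radii[cfg]
    out[[cfg]] <- res
  }
  as_tibble(dplyr::bind_rows(out))
}

#' Kinetic Monte-Carlo donor decay histogram
#'
#' Simulates `n_configs` independent particle realizations (each with a fresh
#' radius drawn from the size distribution) times `n_traj_per_config`
#' excitations, and bins the excitation termination times into `k_max` equal
#' channels on `[0, T_ns]`. Both the raw count histogram and the normalized
#' survival curve ([eq_survival()]) are returned. By default all terminations
#' (intrinsic donor decay and acceptor trapping) are binned, so the survival
#' column estimates the excitation survival probability -- the quantity the
#' analytic model's \eqn{I(t)/I_0} predicts; with
#' `termination = "donor_decay"` only donor emission events are histogrammed
#' (a TCSPC photon histogram). Events beyond `T_ns` are dropped from both the
#' numerator and the denominator; choose `T_ns` large enough that the tail
#' loss is negligible (default 10 donor lifetimes).
#'
#' @param spec A [labeling_spec()].
#' @param dist A [size_distribution()].
#' @param params A [photophysics_params()].
#' @param n_configs Number of particle realizations.
#' @param n_traj_per_config Excitations per realization.
#' @param k_max Number of channels (default 4096, a typical TCSPC depth).
#' @param T_ns Observation window, ns.
#' @param termination Which termination events to bin.
#' @return A [decay_curve] tibble: `time_ns` (right channel edges `t_k =
#'   kT/k_max`), `counts`, `survival`; attribute `meta` records parameters,
#'   trajectory counts and the number of dropped late events.
#' @examples
#' set.seed(7)
#' d <- simulate_decay(labeling_spec(1, 20), size_distribution(75, 0),
#'                     photophysics_params(), n_configs = 20,
#'                     n_traj_per_config = 50, k_max = 128)
#' @export
simulate_decay <- function(spec, dist, params, n_configs = 100L,
                           n_traj_per_config = 100L, k_max = 4096L,
                           T_ns = 10 * params$tau0D,
                           termination = c("all", "donor_decay")) {
  termination <- match.arg(termination)
  stopifnot(k_max >= 1, T_ns > 0)
  ev <- kmc_ensemble(spec, dist, params, n_configs, n_traj_per_config)
  if (termination == "donor_decay") ev <- dplyr::filter(ev, .data$termination == 1L)
  keep <- ev$event_time <= T_ns
  n_dropped <- sum(!keep)
  tt <- ev$event_time[keep]
  if (!length(tt)) {
    abort("no events recorded inside the observation window.",
          class = "fretsphere_empty_result")
  }
  edges <- seq(0, T_ns, length.out = k_max + 1L)
  ch <- pmin(pmax(ceiling(tt / (T_ns / k_max)), 1L), k_max)
  counts <- tabulate(ch, nbins = k_max)
  new_decay_curve(
    tibble(time_ns = edges[-1L], counts = counts,
           survival = eq_survival(counts)),
    kind = "counts",
    meta = list(model = "kmc", spec = unclass(spec), dist = unclass(dist),
                params = unclass(params), n_configs = n_configs,
                n_traj = n_configs * n_traj_per_config, k_max = k_max,
                T_ns = T_ns, termination = termination,
                n_dropped_late = n_dropped))
}

#' Energy-migration observables
#'
#' Ensemble statistics of donor-to-donor excitation hopping: the mean number
#' of jumps per excitation and the mean squared displacement (squared chord
#' distance from the initially excited donor to the site occupied at
#' termination), also reported relative to \eqn{R_{0DD}^2}. Standard errors
#' are computed across configuration means (realizations are the independent
#' replicates; trajectories within one realization share its geometry).
#' Jump counts average over all trajectories; displacement averages over
#' donor-decay terminations (the excitation's position when it decays).
#'
#' @inheritParams simulate_decay
#' @return One-row tibble: `mean_jumps`, `se_jumps`, `mean_sq_displacement`
#'   (nm^2), `se_sq_displacement`, `rel_msd` (\eqn{\langle r^2\rangle /
#'   R_{0DD}^2}), `se_rel_msd`, `rel_rms` (\eqn{\sqrt{\langle r^2\rangle} /
#'   R_{0DD}}, the relative root-mean-square displacement; delta-method SE),
#'   `se_rel_rms`, `n_traj`, `n_configs`, `min_separation`.
#' @examples
#' set.seed(7)
#' migration_stats(labeling_spec(2, 0), size_distribution(75, 0),
#'                 photophysics_params(), n_configs = 5,
#'                 n_traj_per_config = 20)
#' @export
migration_stats <- function(spec, dist, params, n_configs = 100L,
                            n_traj_per_config = 100L) {
  ev <- kmc_ensemble(spec, dist, params, n_configs, n_traj_per_config)
  per_cfg <- ev |>
    dplyr::group_by(.data$config) |>
    dplyr::summarise(
      jumps = mean(.data$n_jumps),
      msd = mean(.data$sq_displacement[.data$termination == 1L]),
      .groups = "drop")
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  tibble(
    mean_jumps = mean(per_cfg$jumps),
    se_jumps = se(per_cfg$jumps),
    mean_sq_displacement = mean(per_cfg$msd),
    se_sq_displacement = se(per_cfg$msd),
    rel_msd = mean(per_cfg$msd) / params$R0DD^2,
    se_rel_msd = se(per_cfg$msd) / params$R0DD^2,
    rel_rms = sqrt(mean(per_cfg$msd)) / params$R0DD,
    se_rel_rms = se(per_cfg$msd) / params$R0DD^2 /
      (2 * sqrt(mean(per_cfg$msd)) / params$R0DD),
    n_traj = nrow(ev),
    n_configs = n_configs,
    min_separation = spec$min_separation)
}
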