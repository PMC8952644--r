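test_that("rate table matches direct summation and closed forms", {
  p <- photophysics_params()
  # lone donor: exit rate is the intrinsic decay rate exactly
  set.seed(301)
  np1 <- sample_configuration(labeling_spec(1, 0), R = 75)
  tab1 <- build_rate_table(np1, p)
  expect_identical(tab1$row_totals, 1 / p$tau0D)
  # two donors at exactly R0DD: each row total is 2/tau0D
  tab2 <- build_rate_table(two_donor_realization(p$R0DD), p)
  expect_equal(tab2$row_totals, rep(2 / p$tau0D, 2), tolerance = 1e-12)
  # random mixed realization vs brute-force recomputation
  set.seed(302)
  np <- sample_configuration(labeling_spec(3, 4), R = 30)
  tab <- build_rate_table(np, p)
  for (i in 1:3) {
    manual <- 1 / p$tau0D
    for (j in seq_len(7)) {
      if (j == i) next
      r <- chord_distance(np$positions[i, ], np$positions[j, ])
      kind <- if (np$species[j] == "donor") "DD" else "DA"
      manual <- manual + transfer_rate(r, kind, p)
    }
    expect_equal(tab$row_totals[i], manual, tolerance = 1e-12)
  }
  # acceptors are absorbing
  expect_equal(tab$row_totals[4:7], rep(0, 4))
  expect_equal(tab$pair_rates[4:7, ], matrix(0, 4, 7))
  expect_equal(diag(tab$pair_rates), rep(0, 7))
})

test_that("explicit-static rates are the effective rates scaled by kappa^2", {
  set.seed(303)
  eff <- photophysics_params()
  exp_mode <- photophysics_params(kappa2_mode = "explicit_static")
  np <- sample_configuration(labeling_spec(3, 2, min_separation = 2), R = 15)
  w_eff <- build_rate_table(np, eff)$pair_rates
  w_exp <- build_rate_table(np, exp_mode)$pair_rates
  for (i in 1:3) {
    for (j in 1:5) {
      if (i == j) next
      rh <- np$positions[j, ] - np$positions[i, ]
      rh <- rh / sqrt(sum(rh^2))
      k2 <- orientation_factor(np$dipoles[i, ], np$dipoles[j, ], rh)
      expect_equal(w_exp[i, j], w_eff[i, j] * k2 / 0.476, tolerance = 1e-12)
    }
  }
})

test_that("single-donor trajectories are a pure exponential decay", {
  p <- photophysics_params()
  set.seed(304)
  np <- sample_configuration(labeling_spec(1, 0), R = 75)
  tab <- build_rate_table(np, p)
  tr <- dplyr::bind_rows(lapply(1:2000, function(i) run_trajectory(tab)))
  expect_true(all(tr$n_jumps == 0))
  expect_true(all(tr$sq_displacement == 0))
  expect_true(all(tr$termination == "donor_decay"))
  expect_lt(abs(mean(tr$event_time) - p$tau0D),
            3 * p$tau0D / sqrt(2000))
  ks <- stats::ks.test(tr$event_time, "pexp", rate = 1 / p$tau0D)
  expect_gt(ks$p.value, 0.01)
})

test_that("waiting times are exponential in the total exit rate", {
  p <- photophysics_params()
  set.seed(305)
  tab <- build_rate_table(two_donor_realization(p$R0DD), p)
  W <- 2 / p$tau0D   # same total exit rate in both states by symmetry
  dts <- unlist(lapply(1:4000, function(i) {
    attr(run_trajectory(tab, record_events = TRUE), "events")$waiting_time
  }))
  expect_gt(length(dts), 1e4 * 0.7)
  ks <- stats::ks.test(dts, "pexp", rate = W)
  expect_gt(ks$p.value, 0.01)
})

test_that("event selection matches rate ratios (two-state closed form)", {
  # donors at exactly R0DD: hop and decay are equally likely, so the jump
  # count is geometric with mean 1 and variance 2
  p <- photophysics_params()
  set.seed(306)
  tab <- build_rate_table(two_donor_realization(p$R0DD), p)
  res <- fretsphere:::run_kmc_cpp(tab$pair_rates, tab$decay_rate,
                                  tab$chord2, 30000L)
  expect_lt(abs(mean(res$n_jumps) - 1), 3 * sqrt(2 / 30000))
  expect_lt(abs(mean(res$event_time) - p$tau0D),
            3 * p$tau0D / sqrt(30000))
})

test_that("engine reproduces first-passage linear algebra on a dense cluster", {
  p <- photophysics_params()
  set.seed(307)
  np <- sample_configuration(labeling_spec(5, 1, min_separation = 1.5),
                             R = 8)
  tab <- build_rate_table(np, p)
  or <- first_passage_oracle(tab)
  res <- fretsphere:::run_kmc_cpp(tab$pair_rates[1:5, ], tab$decay_rate,
                                  tab$chord2[1:5, ], 100000L)
  n <- nrow(res)
  expect_lt(abs(mean(res$n_jumps) - or$mean_jumps),
            4 * sd(res$n_jumps) / sqrt(n))
  dd <- res$termination == 1
  expect_lt(abs(mean(res$sq_displacement[dd]) - or$msd_donor_decay),
            4 * sd(res$sq_displacement[dd]) / sqrt(sum(dd)))
  tf <- mean(res$termination == 2)
  expect_lt(abs(tf - or$trap_fraction),
            4 * sqrt(max(tf * (1 - tf), 1 / n) / n))
})

test_that("R-level and compiled trajectory paths agree in distribution", {
  p <- photophysics_params()
  set.seed(308)
  np <- sample_configuration(labeling_spec(4, 1, min_separation = 1.5),
                             R = 8)
  tab <- build_rate_table(np, p)
  or <- first_passage_oracle(tab)
  tr <- dplyr::bind_rows(lapply(1:4000, function(i) run_trajectory(tab)))
  expect_lt(abs(mean(tr$n_jumps) - or$mean_jumps),
            4 * sd(tr$n_jumps) / sqrt(4000))
  expect_lt(abs(mean(tr$termination == "acceptor_trap") - or$trap_fraction),
            4 * sqrt(max(or$trap_fraction / 4000, 1e-6)))
})

test_that("normalized histogram follows the cumulative formula", {
  expect_equal(eq_survival(c(5, 3, 2)), c(0.5, 0.2, 0))
  # all events in channel 1: curve reaches 0 immediately
  expect_equal(eq_survival(c(7, 0, 0, 0)), c(0, 0, 0, 0))
  # uniform event times: linear decay 1 - k/k_max
  k <- 50
  expect_equal(eq_survival(rep(3, k)), 1 - (1:k) / k)
  s <- eq_survival(rpois(64, 10) + 1)
  expect_true(all(diff(s) <= 0))
  expect_lte(s[1], 1)
  expect_equal(s[64], 0)
  expect_error(eq_survival(numeric(64) * 0),
               class = "fretsphere_empty_result")
  expect_error(eq_survival(c(3, -1)), class = "fretsphere_domain_error")
})

test_that("simulated decay histograms are seed-reproducible", {
  p <- photophysics_params()
  d <- size_distribution(75, 5)
  spec <- labeling_spec(2, 2)
  set.seed(309)
  a <- simulate_decay(spec, d, p, n_configs = 5, n_traj_per_config = 50,
                      k_max = 64)
  set.seed(309)
  b <- simulate_decay(spec, d, p, n_configs = 5, n_traj_per_config = 50,
                      k_max = 64)
  expect_identical(a$counts, b$counts)
  expect_identical(a$survival, b$survival)
  expect_error(
    simulate_decay(spec, d, p, n_configs = 2, n_traj_per_config = 5,
                   k_max = 8, T_ns = 1e-9),
    class = "fretsphere_empty_result")
})

test_that("migration among identical donors leaves the decay exponential", {
  p <- photophysics_params()
  d <- size_distribution(75, 0)
  set.seed(310)
  sim <- simulate_decay(labeling_spec(50, 0, min_separation = 1), d, p,
                        n_configs = 25, n_traj_per_config = 2000,
                        k_max = 1024, T_ns = 20)
  f <- fit_monoexponential(sim, weighting = "pearson")
  expect_equal(coef(f)[["tau"]], p$tau0D, tolerance = 0.02)
})

test_that("migration statistics handle degenerate systems", {
  p <- photophysics_params()
  d <- size_distribution(75, 0)
  set.seed(311)
  st <- migration_stats(labeling_spec(1, 0), d, p, n_configs = 3,
                        n_traj_per_config = 30)
  expect_equal(st$mean_jumps, 0)
  expect_equal(st$mean_sq_displacement, 0)
  expect_equal(st$rel_msd, 0)
  expect_identical(st$min_separation, 1.0)
})
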