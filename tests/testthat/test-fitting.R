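test_that("monoexponential fit is exact on noiseless curves", {
  tt <- seq(20 / 4096, 20, length.out = 4096)
  cv <- decay_curve(tibble::tibble(time_ns = tt,
                                   intensity = exp(-tt / 3.82)),
                    kind = "model")
  f <- fit_monoexponential(cv)
  expect_equal(coef(f)[["tau"]], 3.82, tolerance = 5e-5)
  cv2 <- decay_curve(tibble::tibble(time_ns = tt,
                                    intensity = 0.5 * exp(-tt)),
                     kind = "model")
  f2 <- fit_monoexponential(cv2)
  expect_equal(coef(f2)[["A"]], 0.5, tolerance = 1e-6)
  expect_equal(coef(f2)[["tau"]], 1, tolerance = 1e-6)
  expect_true(glance(f2)$converged)
})

test_that("lifetime is recovered within reported errors across replicates", {
  tt <- seq(20 / 1024, 20, length.out = 1024)
  m <- exp(-tt / 3.82)
  lam <- m / sum(m) * 1e6
  hits <- 0L
  for (i in 1:100) {
    set.seed(400 + i)
    cv <- decay_curve(tibble::tibble(time_ns = tt,
                                     counts = rpois(1024, lam)),
                      kind = "counts")
    f <- fit_monoexponential(cv, weighting = "pearson")
    est <- tidy(f)
    tau <- est$estimate[est$term == "tau"]
    se <- est$std.error[est$term == "tau"]
    if (abs(tau - 3.82) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("reported uncertainties scale as one over root counts", {
  tt <- seq(20 / 512, 20, length.out = 512)
  m <- exp(-tt / 3.82)
  ses <- vapply(c(1e4, 1e5, 1e6), function(N) {
    set.seed(round(N))
    cv <- decay_curve(tibble::tibble(time_ns = tt,
                                     counts = rpois(512, m / sum(m) * N)),
                      kind = "counts")
    est <- tidy(fit_monoexponential(cv, weighting = "pearson"))
    est$std.error[est$term == "tau"]
  }, numeric(1))
  slope <- coef(lm(log(ses) ~ log(c(1e4, 1e5, 1e6))))[[2]]
  expect_equal(slope, -0.5, tolerance = 0.2)
})

test_that("decay-model fit is idempotent on noiseless data", {
  p <- photophysics_params()
  d <- size_distribution(75, 5)
  cv <- analytic_decay_curve(p, d, 335, k_max = 512, T_ns = 20)
  set.seed(410)
  # transverse directions are strongly identified; fit each with the other
  # anchored (the joint (N_A, R) direction is a known flat ridge)
  f1 <- fit_decay_model(cv, p, d, n_acceptors = 335 * 1.15,
                        free = c("n_acceptors", "amplitude"),
                        n_starts = 3, n_nodes = 48L)
  expect_equal(coef(f1)[["n_acceptors"]], 335, tolerance = 1e-3)
  expect_equal(coef(f1)[["amplitude"]], 1, tolerance = 1e-3)
  f2 <- fit_decay_model(cv, p, size_distribution(75 * 0.85, 5),
                        n_acceptors = 335,
                        free = c("mean_R", "amplitude"),
                        n_starts = 3, n_nodes = 48L)
  expect_equal(coef(f2)[["mean_R"]], 75, tolerance = 1e-3)
})

test_that("an unquenched curve yields a zero acceptor estimate", {
  p <- photophysics_params()
  d <- size_distribution(75, 5)
  cv <- analytic_decay_curve(p, d, 0, k_max = 256, T_ns = 20)
  set.seed(411)
  f <- suppressWarnings(
    fit_decay_model(cv, p, d, n_acceptors = 5,
                    free = c("n_acceptors", "amplitude"),
                    n_starts = 3, n_nodes = 32L))
  expect_lte(coef(f)[["n_acceptors"]], 0.01)
})

test_that("freed sigma comes with a confidence interval", {
  p <- photophysics_params()
  d <- size_distribution(75, 5)
  cv <- analytic_decay_curve(p, d, 335, k_max = 256, T_ns = 20)
  set.seed(412)
  f <- fit_decay_model(cv, p, size_distribution(75, 4), n_acceptors = 335,
                       free = c("sigma", "amplitude"), n_starts = 2,
                       n_nodes = 32L)
  ti <- tidy(f, conf.int = TRUE)
  expect_true(all(c("conf.low", "conf.high") %in% names(ti)))
  row <- ti[ti$term == "sigma", ]
  expect_true(is.finite(row$conf.low) && is.finite(row$conf.high))
  expect_lt(row$conf.low, row$conf.high)
})

test_that("IRF convolution preserves mass and widens a delta correctly", {
  k <- 512
  tt <- seq(20 / k, 20, length.out = k)
  v <- numeric(k); v[200] <- 1
  cv <- decay_curve(tibble::tibble(time_ns = tt, intensity = v),
                    kind = "model")
  expect_identical(convolve_irf(cv, 0), cv)
  out <- convolve_irf(cv, 0.28)
  expect_equal(sum(out$intensity), 1, tolerance = 1e-9)
  expect_equal(which.max(out$intensity), 200)
  # measured FWHM of the smeared delta
  half <- max(out$intensity) / 2
  above <- range(which(out$intensity >= half))
  fwhm <- (diff(above) + 1) * (tt[2] - tt[1])
  expect_equal(fwhm, 0.28, tolerance = 0.2)
  expect_error(convolve_irf(decay_curve(
    tibble::tibble(time_ns = tt[1:8], intensity = rep(1, 8)),
    kind = "model"), 5), class = "fretsphere_domain_error")
})

test_that("tail fitting an IRF-convolved exponential recovers the lifetime", {
  k <- 4096
  tt <- seq(20 / k, 20, length.out = k)
  cv <- decay_curve(tibble::tibble(time_ns = tt,
                                   intensity = exp(-tt / 3.82)),
                    kind = "model")
  sm <- convolve_irf(cv, 0.28)
  f <- fit_monoexponential(sm, fit_range = c(2, 19))
  expect_equal(coef(f)[["tau"]], 3.82, tolerance = 0.01)
})

test_that("fit objects expose tidy, glance and plotting methods", {
  tt <- seq(0.05, 20, length.out = 128)
  cv <- decay_curve(tibble::tibble(time_ns = tt,
                                   intensity = 2 * exp(-tt / 3)),
                    kind = "model")
  f <- fit_monoexponential(cv)
  expect_named(tidy(f), c("term", "estimate", "std.error"))
  g <- glance(f)
  expect_true(g$converged)
  expect_identical(g$nobs, 128L)
  expect_gte(g$objective, 0)
  expect_s3_class(autoplot(f), "ggplot")
  expect_output(print(f), "monoexponential")
})
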