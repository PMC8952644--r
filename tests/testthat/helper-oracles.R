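# Independent oracles used across the suite.  These deliberately avoid the
# package's own fast paths: adaptive quadrature instead of the fixed-panel
# integral, direct summation instead of the vectorized rate table, and
# first-passage linear algebra instead of the stochastic engine.

paper_params <- function(...) photophysics_params(...)

# q(a) = 1 - (1/2) int_0^2 exp(-a u^-3) du via stats::integrate on
# geometrically split intervals (the integrand has a boundary layer at
# u ~ a^(1/3))
q_oracle <- function(a) {
  vapply(a, function(ai) {
    if (ai <= 0) return(0)
    us <- ai^(1 / 3)
    f <- function(u) -expm1(-ai / u^3)
    br <- us / 4 * 2^(0:300)
    br <- unique(pmin(c(0, br[br < 2], 2), 2))
    tot <- 0
    for (i in seq_len(length(br) - 1)) {
      tot <- tot + stats::integrate(f, br[i], br[i + 1], rel.tol = 1e-12,
                                    abs.tol = 1e-16,
                                    subdivisions = 400L)$value
    }
    tot / 2
  }, numeric(1))
}

# Monte-Carlo oracle for the single-acceptor survival: average exp(-t w(r))
# over uniform acceptor placements (u = 1 - cos(theta) uniform on [0, 2])
s_mc_oracle <- function(t, R, params, n = 1e6) {
  u <- runif(n, 0, 2)
  r2 <- 2 * R^2 * u
  w <- (1 / params$tau0D) * (params$R0DA^2 / r2)^3
  x <- exp(-t * w)
  c(mean = mean(x), se = sd(x) / sqrt(n))
}

# First-passage oracle for a frozen realization: expected jump count,
# termination-site distribution and donor-decay MSD by linear algebra
first_passage_oracle <- function(tab) {
  n_d <- tab$n_donors
  n <- nrow(tab$pair_rates)
  W <- tab$pair_rates
  tot <- rowSums(W)[seq_len(n_d)] + tab$decay_rate
  Pdd <- sweep(W[seq_len(n_d), seq_len(n_d), drop = FALSE], 1, tot, "/")
  jumps <- solve(diag(n_d) - Pdd, rowSums(Pdd))
  rho_dd <- solve(diag(n_d) - Pdd, diag(tab$decay_rate / tot, n_d))
  trap <- if (n > n_d) {
    Pda <- sweep(W[seq_len(n_d), (n_d + 1):n, drop = FALSE], 1, tot, "/")
    rowSums(solve(diag(n_d) - Pdd, Pda))
  } else rep(0, n_d)
  msd <- vapply(seq_len(n_d), function(i) {
    sum(rho_dd[i, ] * tab$chord2[i, seq_len(n_d)]) / sum(rho_dd[i, ])
  }, numeric(1))
  list(mean_jumps = mean(jumps), msd_donor_decay = mean(msd),
       trap_fraction = mean(trap))
}

# hand-built realization with fluorophores at given positions
fixed_realization <- function(positions, species, R,
                              dipoles = NULL, min_separation = 0) {
  n <- nrow(positions)
  if (is.null(dipoles)) {
    dipoles <- matrix(rnorm(3 * n), ncol = 3)
    dipoles <- dipoles / sqrt(rowSums(dipoles^2))
  }
  structure(list(radius = R, positions = positions, dipoles = dipoles,
                 species = species, min_separation = min_separation),
            class = "nanoparticle_realization")
}

# two donors separated by a given chord on a sphere of radius R
two_donor_realization <- function(chord, R = 75) {
  th <- 2 * asin(chord / (2 * R))
  fixed_realization(rbind(c(R, 0, 0),
                          c(R * cos(th), R * sin(th), 0)),
                    c("donor", "donor"), R)
}
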