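#' Draw particle radii from the size distribution
#'
#' Samples radii from the positive-truncated Gaussian size law by rejection.
#' With the default batches (mean 15 sigma above zero) the rejection step is
#' essentially free. `sigma = 0` returns `mean_R` deterministically.
#'
#' @param n Number of radii to draw.
#' @param dist A [size_distribution()].
#' @return Numeric vector of `n` radii, nm; all strictly positive.
#' @examples
#' set.seed(1)
#' mean(sample_radius(1e4, size_distribution(75, 5)))
#' @export
sample_radius <- function(n, dist) {
  stopifnot(inherits(dist, "size_distribution"))
  if (dist$sigma == 0) return(rep(dist$mean_R, n))
  out <- rnorm(n, dist$mean_R, dist$sigma)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), dist$mean_R, dist$sigma)
    bad <- bad[out[bad] <= 0]
  }
  out
}

# uniform unit vectors in R^3 (rows)
runif_sphere <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Generate one labelled-particle realization
#'
#' Places `n_donors + n_acceptors` fluorophores i.i.d. uniformly on the sphere
#' of radius `R` subject to the hard-core constraint that every pairwise
#' (chord) distance is at least `spec$min_separation`, by rejection sampling.
#' Each fluorophore also receives a frozen, isotropically random transition
#' dipole orientation (the static case: orientations do not rotate within the
#' excited-state lifetime). Donors occupy the leading rows.
#'
#' @param spec A [labeling_spec()].
#' @param R Particle radius, nm.
#' @param max_attempts Rejection budget per fluorophore before the
#'   configuration is declared unpackable.
#' @return An object of class `nanoparticle_realization`: list with `radius`,
#'   `positions` (n x 3, nm), `dipoles` (n x 3, unit rows), `species`
#'   (character, `"donor"`/`"acceptor"`), `min_separation`.
#' @examples
#' set.seed(1)
#' np <- sample_configuration(labeling_spec(5, 10), R = 75)
#' sqrt(rowSums(np$positions^2))  # all equal to the radius
#' @export
sample_configuration <- function(spec, R, max_attempts = 10000L) {
  stopifnot(inherits(spec, "labeling_spec"), R > 0)
  n <- spec$n_donors + spec$n_acceptors
  if (spec$min_separation > 2 * R && n > 1) {
    abort(sprintf(
      "cannot place %d fluorophores with min separation %g nm on a sphere of radius %g nm (max chord %g nm)",
      n, spec$min_separation, R, 2 * R), class = "fretsphere_packing_error")
  }
  pos <- matrix(NA_real_, n, 3)
  ms2 <- spec$min_separation^2
  if (ms2 == 0) {
    pos <- R * runif_sphere(n)
    return(structure(
      list(radius = R, positions = pos, dipoles = runif_sphere(n),
           species = rep(c("donor", "acceptor"),
                         c(spec$n_donors, spec$n_acceptors)),
           min_separation = spec$min_separation),
      class = "nanoparticle_realization"))
  }
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- R * runif_sphere(1L)
      if (i == 1L || ms2 == 0) { pos[i, ] <- p; placed <- TRUE; break }
      prev <- pos[seq_len(i - 1L), , drop = FALSE]
      d2 <- (prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 + (prev[, 3] - p[3])^2
      if (all(d2 >= ms2)) { pos[i, ] <- p; placed <- TRUE; break }
    }
    if (!placed) {
      abort(sprintf(
        "failed to place fluorophore %d of %d after %d attempts (min separation %g nm, R = %g nm): labelling density too high",
        i, n, max_attempts, spec$min_separation, R),
        class = "fretsphere_packing_error")
    }
  }
  structure(
    list(radius = R, positions = pos, dipoles = runif_sphere(n),
         species = rep(c("donor", "acceptor"),
                       c(spec$n_donors, spec$n_acceptors)),
         min_separation = spec$min_separation),
    class = "nanoparticle_realization"
  )
}

#' @export
print.nanoparticle_realization <- function(x, ...) {
  cat(sprintf("<nanoparticle_realization> R = %g nm, %d donors + %d acceptors\n",
              x$radius, sum(x$species == "donor"),
              sum(x$species == "acceptor")))
  invisible(x)
}

#' Chord distance between two points on a sphere
#'
#' Straight-line (through-space) distance \eqn{r(\theta) = \sqrt{2R^2(1 -
#' \cos\theta)} = 2R\sin(\theta/2)} between surface points; dipole--dipole
#' coupling acts through space, not along the surface.
#'
#' @param p_i,p_j Numeric 3-vectors (or n x 3 matrices, rowwise), nm.
#' @return Chord distance(s), nm.
#' @examples
#' chord_distance(c(75, 0, 0), c(-75, 0, 0))  # antipodal: 2R
#' @export
chord_distance <- function(p_i, p_j) {
  if (is.null(dim(p_i))) p_i <- matrix(p_i, ncol = 3)
  if (is.null(dim(p_j))) p_j <- matrix(p_j, ncol = 3)
  sqrt(rowSums((p_i - p_j)^2))
}

#' Orientation factor of a dipole pair
#'
#' \eqn{\kappa = \hat d_i \cdot \hat d_j - 3(\hat d_i \cdot \hat r)(\hat d_j
#' \cdot \hat r)}; returns \eqn{\kappa^2 \in [0, 4]}. Over isotropic random
#' orientations \eqn{\langle\kappa^2\rangle = 2/3} (dynamic average) while the
#' static-ensemble effective value \eqn{\langle|\kappa|\rangle^2 \approx
#' 0.476}.
#'
#' @param d_i,d_j Unit dipole vectors (3-vectors or n x 3 matrices).
#' @param r_hat Unit separation vector(s), same shape convention.
#' @return \eqn{\kappa^2}, numeric vector.
#' @examples
#' orientation_factor(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))  # head-to-tail: 4
#' orientation_factor(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))  # orthogonal: 0
#' @export
orientation_factor <- function(d_i, d_j, r_hat) {
  if (is.null(dim(d_i))) d_i <- matrix(d_i, ncol = 3)
  if (is.null(dim(d_j))) d_j <- matrix(d_j, ncol = 3)
  if (is.null(dim(r_hat))) r_hat <- matrix(r_hat, ncol = 3)
  k <- rowSums(d_i * d_j) - 3 * rowSums(d_i * r_hat) * rowSums(d_j * r_hat)
  k^2
}

#' Pairwise Foerster transfer rate
#'
#' \eqn{w = (1/\tau_{0X}) (R_{0XY}/r)^6} for a donor-sourced transfer over
#' distance `r`. In `"effective"` mode (orientation averaged into the critical
#' radius) the rate is used as-is; in `"explicit_static"` mode it is scaled by
#' \eqn{\kappa^2/\kappa^2_{\mathrm{ref}}} using the supplied per-pair
#' orientation factor.
#'
#' @param r Donor--target distance(s), nm; must be positive.
#' @param pair_kind `"DD"` (donor to donor) or `"DA"` (donor to acceptor).
#' @param params A [photophysics_params()].
#' @param kappa2 Per-pair \eqn{\kappa^2}, required in `"explicit_static"`
#'   mode; ignored in `"effective"` mode.
#' @return Transfer rate(s), 1/ns.
#' @examples
#' p <- photophysics_params()
#' transfer_rate(p$R0DA, "DA", p)  # equals 1/tau0D at the critical radius
#' @export
transfer_rate <- function(r, pair_kind = c("DD", "DA"), params,
                          kappa2 = NULL) {
  pair_kind <- match.arg(pair_kind)
  stopifnot(inherits(params, "photophysics_params"))
  if (any(r <= 0)) {
    abort("transfer rate undefined at zero separation (degenerate configuration).",
          class = "fretsphere_domain_error")
  }
  R0 <- if (pair_kind == "DD") params$R0DD else params$R0DA
  w <- (1 / params$tau0D) * (R0 / r)^6
  if (params$kappa2_mode == "explicit_static") {
    if (is.null(kappa2)) {
      abort("`kappa2` is required in explicit_static mode.",
            class = "fretsphere_domain_error")
    }
    w <- w * kappa2 / params$kappa2_ref
  }
  w
}
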