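#' WCA pair interaction
#'
#' Purely repulsive shifted-truncated Lennard-Jones (Weeks-Chandler-Andersen)
#' potential: for `r < 2^(1/6) sigma`,
#' `U = 4 eps [ (sigma/r)^12 - (sigma/r)^6 ] + eps`, zero beyond the cutoff.
#' The `+eps` shift makes the energy continuous (zero) at the cutoff, where
#' the unshifted Lennard-Jones minimum equals `-eps`.
#'
#' @param r_vec displacement vector from the second particle to the first
#'   (`r_i - r_j`), length 2.
#' @param sigma particle diameter.
#' @param eps energy scale (k_B T).
#' @return list with `energy` and `force`, the force acting on the first
#'   particle (directed along `r_vec`: repulsive).
#' @export
#' @examples
#' wca_pair(c(1, 0))$force   # magnitude 24 at contact r = sigma
wca_pair <- function(r_vec, sigma = 1.0, eps = 1.0) {
  r2 <- sum(r_vec^2)
  if (r2 == 0) stop("overlapping particles: zero pair distance")
  rc2 <- 2^(1 / 3) * sigma^2
  if (r2 >= rc2) return(list(energy = 0.0, force = c(0.0, 0.0)))
  s2 <- sigma^2 / r2
  s6 <- s2^3
  u <- 4 * eps * (s6^2 - s6) + eps
  fr <- 24 * eps * (2 * s6^2 - s6) / r2
  list(energy = u, force = fr * r_vec)
}

#' Harmonic bond pair interaction
#'
#' `U = (ks / 2) (|r_vec| - r0)^2`, acting between consecutive ring
#' monomers (including the closure bond `L -> 1`).
#'
#' @param r_vec displacement vector from the second monomer to the first.
#' @param ks spring constant.
#' @param r0 equilibrium bond length.
#' @return list with `energy` and `force` on the first monomer.
#' @export
bond_pair <- function(r_vec, ks = 4000, r0 = 1.0) {
  r <- sqrt(sum(r_vec^2))
  if (r == 0) stop("overlapping bonded monomers: zero pair distance")
  u <- 0.5 * ks * (r - r0)^2
  f <- -ks * (r - r0) / r * r_vec
  list(energy = u, force = f)
}

#' Total forces and potential energy of a configuration
#'
#' Sums WCA interactions over all particle pairs (active-active,
#' active-membrane, membrane-membrane; bonded neighbours included unless
#' `params$wca_bonded_neighbors` is `FALSE`) plus harmonic bonds along the
#' ring, using the minimum-image convention in the periodic box.  The
#' cell-list path and the brute-force all-pairs path are exactly
#' equivalent; the latter exists as an internal cross-check.
#'
#' @param state a `cav_state` (see [init_configuration()]).
#' @param params a [sim_params()] object.
#' @param method `"cell"` (cell-list neighbour search, default) or
#'   `"brute"` (all pairs).
#' @return An object of class `cav_forces`: list with `mem_force` (L x 2),
#'   `act_force` (N x 2), `mem_force_from_active` (L x 2, the pairwise sum
#'   restricted to active-membrane pairs), `potential_energy`, `min_dist`
#'   and `n_close` (pairs closer than `0.3 sigma`, a sign the timestep is
#'   too large).
#' @export
compute_forces <- function(state, params, method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "cav_params"))
  pos <- rbind(state$mem_pos, state$act_pos)
  res <- cav_forces_cpp(pos, .cpp_par(params), brute = identical(method, "brute"))
  if (res$n_close > 0)
    warning(sprintf("%d pair(s) closer than 0.3 sigma: timestep too large?",
                    as.integer(res$n_close)))
  class(res) <- "cav_forces"
  res
}
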