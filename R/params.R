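#' Simulation parameters for a vesicle filled with chiral active particles
#'
#' Collects every physical and numerical constant of the model in simulation
#' units (particle diameter `sigma` = unit length, thermal energy `eps` =
#' k_B T = unit energy, time in units of `sigma^2 / D0 / 100`, i.e. the
#' default timestep `dt = 0.01` equals `1e-4` of the diffusive time
#' `tau0 = sigma^2 / D0`).
#'
#' The membrane is a closed ring of `L` monomers with harmonic bonds
#' (spring constant `ks`, rest length `r0`) and purely repulsive WCA
#' excluded volume; the interior holds `N` chiral active Brownian particles
#' that self-propel at speed `V0` along an internal orientation and
#' self-rotate at angular velocity `omega` (counterclockwise positive).
#' Either `rho` (target area fraction, `rho = N sigma^2 / (4 R0^2)` with
#' `R0 = sigma / (2 sin(pi/L))`) or `N` may be given; the other is derived.
#'
#' @param L integer >= 3, number of membrane monomers (vesicle perimeter).
#' @param rho target area fraction of active particles in `[0, 1)`;
#'   ignored when `N` is given.
#' @param N number of active particles; derived from `rho` when `NULL`.
#' @param V0 self-propulsion speed.
#' @param omega intrinsic angular velocity of the active particles
#'   (rad/time, counterclockwise positive).
#' @param D0 translational diffusion coefficient.
#' @param Dtheta rotational diffusion coefficient (default `3 * D0 / sigma^2`).
#' @param gamma friction coefficient; must satisfy `gamma * D0 = eps`.
#' @param ks bond spring constant.
#' @param r0 equilibrium bond length.
#' @param sigma particle diameter (unit of length).
#' @param eps interaction energy scale, equal to k_B T.
#' @param dt integration timestep.
#' @param box periodic box side length.
#' @param seed RNG seed for the run.
#' @param n_steps number of integration steps.
#' @param sample_every record a frame every this many steps.
#' @param burn_in fraction of each run discarded before averaging.
#' @param wca_bonded_neighbors apply WCA also between bonded ring
#'   neighbours (harmless at `r ~ sigma`, where it only adds a constant-ish
#'   repulsion on top of the stiff bond).
#' @param translational_noise include the translational Gaussian noise in
#'   the position updates; switch off for direct comparisons with the
#'   noise-free mean-square-displacement theory.
#'
#' @return An object of class `cav_params`: a validated list with all the
#'   above fields plus the derived circumradius `R0` and, when `rho` was
#'   given, the derived particle count `N` (and vice versa).
#' @export
#' @examples
#' p <- sim_params(L = 50, rho = 0.3)
#' p$N    # 76
#' p$R0   # about 7.963
sim_params <- function(L = 50L, rho = NULL, N = NULL,
                       V0 = 0.5, omega = 0.0,
                       D0 = 0.01, Dtheta = 3 * D0 / sigma^2, gamma = eps / D0,
                       ks = 4000, r0 = sigma,
                       sigma = 1.0, eps = 1.0,
                       dt = 0.01, box = 200, seed = 1L,
                       n_steps = 2e6, sample_every = 1000L,
                       burn_in = 0.5,
                       wca_bonded_neighbors = TRUE,
                       translational_noise = TRUE) {
  L <- as.integer(L)
  if (is.na(L) || L < 3L) stop("invalid geometry: L must be an integer >= 3")
  if (is.null(rho) && is.null(N)) rho <- 0
  if (is.null(N)) {
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
    geom <- derive_geometry(L, rho, sigma)
    N <- geom$N
  } else {
    # explicit N: rho becomes a derived diagnostic, not a constraint
    N <- as.integer(N)
    if (is.na(N) || N < 0L) stop("N must be a non-negative integer")
    geom <- derive_geometry(L, 0, sigma)
    rho <- N * sigma^2 / (4 * geom$R0^2)
  }
  if (dt <= 0) stop("dt must be positive")
  if (abs(gamma * D0 - eps) > 1e-9 * eps)
    stop("parameters must satisfy gamma * D0 = eps (gamma = k_B T / D0)")
  if (2 * geom$R0 + 2 * sigma >= box)
    stop("box too small: need 2 * R0 + 2 * sigma < box")
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must lie in [0, 1)")
  if (n_steps < 0) stop("n_steps must be >= 0")
  sample_every <- as.integer(sample_every)
  if (sample_every < 1L) stop("sample_every must be >= 1")

  p <- list(
    L = L, N = N, rho = rho, R0 = geom$R0,
    V0 = V0, omega = omega, D0 = D0, Dtheta = Dtheta, gamma = gamma,
    ks = ks, r0 = r0, sigma = sigma, eps = eps,
    dt = dt, box = box, seed = as.integer(seed),
    n_steps = as.double(n_steps), sample_every = sample_every,
    burn_in = burn_in,
    wca_bonded_neighbors = isTRUE(wca_bonded_neighbors),
    translational_noise = isTRUE(translational_noise)
  )
  class(p) <- "cav_params"
  p
}

#' @export
print.cav_params <- function(x, ...) {
  cat(sprintf(
    "vesicle parameters: L = %d, N = %d (rho = %.4g), R0 = %.4g\n",
    x$L, x$N, x$rho, x$R0))
  cat(sprintf("  V0 = %g, omega = %g, D0 = %g, Dtheta = %g, gamma = %g\n",
              x$V0, x$omega, x$D0, x$Dtheta, x$gamma))
  cat(sprintf("  ks = %g, r0 = %g, dt = %g, box = %g, seed = %d\n",
              x$ks, x$r0, x$dt, x$box, x$seed))
  cat(sprintf("  n_steps = %g, sample_every = %d, burn_in = %g\n",
              x$n_steps, x$sample_every, x$burn_in))
  invisible(x)
}

#' Derive vesicle circumradius and active-particle count
#'
#' The vesicle's initial configuration is a circle of radius
#' `R0 = sigma / (2 sin(pi / L))`, the circumradius of the regular `L`-gon
#' with side `sigma`.  The number of enclosed active particles follows from
#' the target area fraction via `rho = N sigma^2 / (4 R0^2)`, rounded to the
#' nearest integer.
#'
#' @param L integer >= 3, number of membrane monomers.
#' @param rho area fraction in `[0, 1)`.
#' @param sigma particle diameter.
#' @return list with elements `R0` and `N`.
#' @export
#' @examples
#' derive_geometry(150, 0.7)$N  # 1596
derive_geometry <- function(L, rho, sigma = 1.0) {
  L <- as.integer(L)
  if (is.na(L) || L < 3L) stop("invalid geometry: L must be an integer >= 3")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  R0 <- sigma / (2 * sin(pi / L))
  N <- as.integer(round(rho * 4 * R0^2 / sigma^2))
  list(R0 = R0, N = N)
}

# triangular lattice sites within radius r_in of the origin, spacing s,
# ordered deterministically (distance, then angle)
.tri_lattice <- function(s, r_in) {
  if (r_in < 0) return(matrix(numeric(0), 0, 2))
  dy <- s * sqrt(3) / 2
  jmax <- floor(r_in / dy)
  pts <- list()
  for (j in (-jmax):jmax) {
    y <- j * dy
    half <- sqrt(max(r_in^2 - y^2, 0))
    xoff <- if (j %% 2 == 0) 0 else s / 2
    imin <- ceiling((-half - xoff) / s)
    imax <- floor((half - xoff) / s)
    if (imax < imin) next
    xs <- (imin:imax) * s + xoff
    pts[[length(pts) + 1L]] <- cbind(xs, y)
  }
  if (!length(pts)) return(matrix(numeric(0), 0, 2))
  m <- unname(do.call(rbind, pts))
  d <- sqrt(m[, 1]^2 + m[, 2]^2)
  a <- atan2(m[, 2], m[, 1])
  m[order(d, a), , drop = FALSE]
}

#' Build the initial configuration
#'
#' Places the `L` membrane monomers on a regular polygon of circumradius
#' `R0` centred in the box (so every bond has length exactly `sigma` for
#' the default `r0 = sigma`), and the `N` active particles on a triangular
#' lattice clipped to the disc of radius `R0 - sigma`, with the largest
#' lattice spacing >= `sigma` that still fits all `N` particles.
#' Orientations are drawn uniformly on `[0, 2 pi)` after seeding R's RNG
#' with `params$seed`, so the whole configuration is a deterministic
#' function of the parameters.
#'
#' @param params a [sim_params()] object.
#' @return An object of class `cav_state`: list with `mem_pos`, `act_pos`
#'   (wrapped coordinates), `act_theta`, `mem_pos_unwrapped`,
#'   `act_pos_unwrapped` and `time = 0`.
#' @export
init_configuration <- function(params) {
  stopifnot(inherits(params, "cav_params"))
  L <- params$L; N <- params$N
  R0 <- params$R0; sigma <- params$sigma
  cx <- params$box / 2; cy <- params$box / 2

  ang <- 2 * pi * (seq_len(L) - 1) / L
  mem <- cbind(cx + R0 * cos(ang), cy + R0 * sin(ang))

  r_in <- R0 - sigma
  if (N > 0) {
    base <- .tri_lattice(sigma, r_in)
    n_max <- nrow(base)
    if (n_max < N)
      stop(sprintf(
        "cannot place %d active particles at spacing >= sigma inside radius R0 - sigma; maximum feasible N is %d",
        N, n_max))
    # widest spacing (on a small deterministic grid) that still fits N
    spacings <- sigma * seq(1, 3, by = 0.02)
    s_use <- sigma
    for (s in spacings) {
      sites <- .tri_lattice(s, r_in)
      if (nrow(sites) >= N) s_use <- s else break
    }
    sites <- .tri_lattice(s_use, r_in)
    act <- sites[seq_len(N), , drop = FALSE]
    act[, 1] <- act[, 1] + cx
    act[, 2] <- act[, 2] + cy
  } else {
    act <- matrix(numeric(0), 0, 2)
  }

  set.seed(params$seed)
  theta <- if (N > 0) stats::runif(N, 0, 2 * pi) else numeric(0)

  st <- list(
    mem_pos = mem, act_pos = act, act_theta = theta,
    mem_pos_unwrapped = mem, act_pos_unwrapped = act,
    time = 0.0
  )
  class(st) <- "cav_state"
  st
}

#' @export
print.cav_state <- function(x, ...) {
  cat(sprintf("vesicle state: %d membrane monomers, %d active particles, t = %g\n",
              nrow(x$mem_pos), nrow(x$act_pos), x$time))
  invisible(x)
}

# flat parameter list handed to the compiled core
.cpp_par <- function(params) {
  list(L = params$L, N = params$N, sigma = params$sigma, eps = params$eps,
       V0 = params$V0, omega = params$omega, D0 = params$D0,
       Dtheta = params$Dtheta, gamma = params$gamma, ks = params$ks,
       r0 = params$r0, box = params$box, dt = params$dt,
       wca_bonded_neighbors = params$wca_bonded_neighbors,
       translational_noise = params$translational_noise)
}
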