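#' Deterministic fixtures with analytically known observables
#'
#' Builds small configurations or trajectories whose observables are known
#' in closed form, for testing and calibration:
#' \describe{
#'   \item{`regular_ring`}{a regular `L`-gon membrane (asphericity 0,
#'     interior angles `pi (L-2)/L`, curvature `1/R0`); params: `L`,
#'     optional `R0`, `box`.  Returns a `cav_state`.}
#'   \item{`ellipse_ring`}{`L` monomers on an ellipse sampled uniformly in
#'     the angle parameter; params: `L`, `a`, `b`, `box`.  Returns a
#'     `cav_state`.}
#'   \item{`rigid_rotation`}{a trajectory of a regular polygon rotating
#'     rigidly by `rate` radians per frame for `n_frames` frames
#'     (exactly linear cumulative rotation); params: `L`, `rate`,
#'     `n_frames`, `dt_frame`.  Returns a `cav_trajectory`.}
#'   \item{`single_swimmer`}{a trajectory of `n_swimmers` independent
#'     non-interacting chiral swimmers (no membrane, `eps = 0`), the
#'     free chiral active Brownian particle whose ensemble MSD has the
#'     closed form of [theory_msd()] with `N = 1`, `L = 0`; params:
#'     `V0`, `omega`, `D0`, `Dtheta`, `n_swimmers`, `n_steps`,
#'     `sample_every`, `dt`, `seed`, `translational_noise`.  Returns a
#'     `cav_trajectory` with an empty membrane.}
#' }
#'
#' @param kind fixture name.
#' @param params named list of fixture parameters (see above).
#' @return a `cav_state` or `cav_trajectory` depending on `kind`.
#' @export
make_fixture <- function(kind = c("regular_ring", "ellipse_ring",
                                  "rigid_rotation", "single_swimmer"),
                         params = list()) {
  kind <- match.arg(kind)
  g <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  switch(kind,
    regular_ring = {
      L <- g("L", 50L)
      R0 <- g("R0", 1 / (2 * sin(pi / L)))
      box <- g("box", 200)
      ang <- 2 * pi * (seq_len(L) - 1) / L
      mem <- cbind(box / 2 + R0 * cos(ang), box / 2 + R0 * sin(ang))
      structure(list(mem_pos = mem, act_pos = matrix(numeric(0), 0, 2),
                     act_theta = numeric(0), mem_pos_unwrapped = mem,
                     act_pos_unwrapped = matrix(numeric(0), 0, 2),
                     time = 0), class = "cav_state")
    },
    ellipse_ring = {
      L <- g("L", 50L); a <- g("a", 2); b <- g("b", 1); box <- g("box", 200)
      ang <- 2 * pi * (seq_len(L) - 1) / L
      mem <- cbind(box / 2 + a * cos(ang), box / 2 + b * sin(ang))
      structure(list(mem_pos = mem, act_pos = matrix(numeric(0), 0, 2),
                     act_theta = numeric(0), mem_pos_unwrapped = mem,
                     act_pos_unwrapped = matrix(numeric(0), 0, 2),
                     time = 0), class = "cav_state")
    },
    rigid_rotation = {
      L <- g("L", 50L)
      rate <- g("rate", 0.05)
      nf <- g("n_frames", 11L)
      dtf <- g("dt_frame", 1)
      box <- g("box", 200)
      R0 <- 1 / (2 * sin(pi / L))
      mem <- array(0, dim = c(L, 2, nf))
      base <- 2 * pi * (seq_len(L) - 1) / L
      for (k in seq_len(nf)) {
        ang <- base + (k - 1) * rate
        mem[, , k] <- cbind(box / 2 + R0 * cos(ang), box / 2 + R0 * sin(ang))
      }
      p <- sim_params(L = L, rho = 0, box = box, n_steps = 0)
      structure(list(
        times = (seq_len(nf) - 1) * dtf,
        mem = mem, act = array(0, c(0, 2, nf)),
        mem_unwrapped = mem, act_unwrapped = array(0, c(0, 2, nf)),
        theta = matrix(numeric(0), 0, nf),
        fmem_act = array(0, c(L, 2, nf)),
        U = rep(0, nf), min_dist = rep(NA_real_, nf),
        params = p, seed = p$seed), class = "cav_trajectory")
    },
    single_swimmer = {
      n_sw <- g("n_swimmers", 1L)
      V0 <- g("V0", 0.5); omega <- g("omega", 0)
      D0 <- g("D0", 0.01); Dtheta <- g("Dtheta", 0.03)
      dt <- g("dt", 0.01); n_steps <- g("n_steps", 1000L)
      sample_every <- g("sample_every", 10L); seed <- g("seed", 1L)
      box <- g("box", 200)  # periodic images are irrelevant at eps = 0
      trn <- g("translational_noise", TRUE)
      par <- list(L = 0L, N = as.integer(n_sw), sigma = 1, eps = 0,
                  V0 = V0, omega = omega, D0 = D0, Dtheta = Dtheta,
                  gamma = 1 / D0, ks = 0, r0 = 1, box = box, dt = dt,
                  wca_bonded_neighbors = TRUE, translational_noise = trn)
      # spread starting points on a coarse grid (non-interacting anyway,
      # but identical positions would trip the overlap guard)
      side <- ceiling(sqrt(n_sw))
      ij <- cbind((seq_len(n_sw) - 1) %% side, (seq_len(n_sw) - 1) %/% side)
      pos0 <- (ij + 0.5) * (box / side)
      set.seed(as.integer(seed))
      theta0 <- stats::runif(n_sw, 0, 2 * pi)
      res <- cav_run_cpp(pos0, theta0, par, as.integer(n_steps),
                         as.integer(sample_every), as.double(seed), FALSE)
      p <- list(L = 0L, N = as.integer(n_sw), rho = 0, R0 = NA_real_,
                V0 = V0, omega = omega, D0 = D0, Dtheta = Dtheta,
                gamma = 1 / D0, ks = 0, r0 = 1, sigma = 1, eps = 0,
                dt = dt, box = box, seed = as.integer(seed),
                n_steps = as.double(n_steps),
                sample_every = as.integer(sample_every), burn_in = 0,
                wca_bonded_neighbors = TRUE, translational_noise = trn)
      class(p) <- "cav_params"
      structure(list(
        times = res$times,
        mem = array(0, c(0, 2, res$n_frames)),
        act = res$pos, mem_unwrapped = array(0, c(0, 2, res$n_frames)),
        act_unwrapped = res$pos_unwrapped, theta = res$theta,
        fmem_act = array(0, c(0, 2, res$n_frames)),
        U = res$potential_energy, min_dist = res$min_dist,
        params = p, seed = as.integer(seed)), class = "cav_trajectory")
    }
  )
}

#' Per-particle ensemble mean squared displacement
#'
#' MSD averaged over the particles of a trajectory (each particle treated
#' as an independent realisation, displacement from the first frame):
#' the estimator for ensembles of non-interacting swimmers produced by
#' `make_fixture("single_swimmer", ...)`.
#'
#' @param traj a `cav_trajectory` (active particles are used).
#' @return list with `times`, `msd`, `se` (over particles).
#' @export
swimmer_msd <- function(traj) {
  N <- dim(traj$act)[1]
  stopifnot(N >= 1)
  f <- n_frames(traj)
  x <- matrix(traj$act_unwrapped[, 1, ], nrow = N)
  y <- matrix(traj$act_unwrapped[, 2, ], nrow = N)
  d2 <- (x - x[, 1])^2 + (y - y[, 1])^2
  list(times = traj$times - traj$times[1],
       msd = colMeans(d2),
       se = apply(d2, 2, stats::sd) / sqrt(N))
}
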