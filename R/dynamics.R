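#' Gaussian noise stream for the reference integrator
#'
#' A thin wrapper around R's global RNG: constructing the stream seeds the
#' generator, and [step_state()] consumes draws from it in a documented
#' order (active translations x/y per particle, then active rotations, then
#' membrane translations).  The compiled integrator used by
#' [run_simulation()] carries its own generator with the same draw order.
#'
#' @param seed integer seed.
#' @return object of class `cav_noise`.
#' @export
noise_stream <- function(seed) {
  set.seed(as.integer(seed))
  structure(list(seed = as.integer(seed)), class = "cav_noise")
}

#' Advance the system by one Euler-Maruyama step
#'
#' Reference (pure R) implementation of the overdamped update: active
#' particles move by `[V0 (cos theta, sin theta) + F / gamma] dt +
#' sqrt(2 D0 dt) eta` and rotate by `omega dt + sqrt(2 Dtheta dt) eta_R`;
#' membrane monomers follow the same translational rule with `V0 = 0`.
#' Wrapped coordinates are re-imaged into `[0, box)`, unwrapped mirrors
#' advance by the raw displacement.  The compiled loop in
#' [run_simulation()] integrates the same equations; this function is the
#' transparent single-step reference used in tests and prototyping.
#'
#' @param state a `cav_state`.
#' @param params a [sim_params()] object.
#' @param noise a [noise_stream()]; pass `NULL` to reuse the current global
#'   RNG state.
#' @return the advanced `cav_state`.
#' @export
step_state <- function(state, params, noise = NULL) {
  stopifnot(inherits(params, "cav_params"))
  if (!is.null(noise)) stopifnot(inherits(noise, "cav_noise"))
  L <- params$L; N <- nrow(state$act_pos)
  dt <- params$dt
  f <- compute_forces(state, params)
  trn <- if (params$translational_noise) sqrt(2 * params$D0 * dt) else 0
  rot <- sqrt(2 * params$Dtheta * dt)

  if (N > 0) {
    eta <- if (trn > 0) matrix(stats::rnorm(2 * N), N, 2, byrow = TRUE) else matrix(0, N, 2)
    u <- cbind(cos(state$act_theta), sin(state$act_theta))
    d_act <- (params$V0 * u + f$act_force / params$gamma) * dt + trn * eta
    eta_r <- stats::rnorm(N)
    theta <- state$act_theta + params$omega * dt + rot * eta_r
  } else {
    d_act <- matrix(numeric(0), 0, 2)
    theta <- state$act_theta
  }
  eta_m <- if (trn > 0) matrix(stats::rnorm(2 * L), L, 2, byrow = TRUE) else matrix(0, L, 2)
  d_mem <- f$mem_force / params$gamma * dt + trn * eta_m

  wrap <- function(x) x - params$box * floor(x / params$box)
  st <- state
  st$mem_pos_unwrapped <- state$mem_pos_unwrapped + d_mem
  st$act_pos_unwrapped <- state$act_pos_unwrapped + d_act
  st$mem_pos <- wrap(state$mem_pos + d_mem)
  st$act_pos <- wrap(state$act_pos + d_act)
  st$act_theta <- theta
  st$time <- state$time + dt
  if (any(!is.finite(st$mem_pos)) || any(!is.finite(st$act_pos)))
    stop("non-finite coordinate after step; dumping frame", call. = FALSE)
  st
}

#' Run a full simulation
#'
#' Builds the initial configuration (regular polygon membrane, lattice of
#' active particles, seeded orientations), then integrates `n_steps`
#' Euler-Maruyama steps in compiled code with a cell-list neighbour
#' search, recording every `sample_every`-th frame together with the
#' active-on-membrane pair-force snapshot of that frame.  Deterministic
#' given `params` (which include the seed).
#'
#' @param params a [sim_params()] object.
#' @param state optional starting `cav_state`; defaults to
#'   [init_configuration()].
#' @param verbose log progress (time, potential energy, minimum pair
#'   distance) to stderr every 1e5 steps.
#' @return An object of class `cav_trajectory`: list with `times` (frame
#'   times), `mem`, `act` (wrapped coordinates, dims `L x 2 x F` and
#'   `N x 2 x F`), `mem_unwrapped`, `act_unwrapped`, `theta` (`N x F`),
#'   `fmem_act` (`L x 2 x F`, per-frame force on each monomer from active
#'   particles), `U`, `min_dist`, `params`, `seed`.
#' @export
#' @examples
#' p <- sim_params(L = 20, rho = 0.2, n_steps = 1000, sample_every = 100)
#' traj <- run_simulation(p)
#' n_frames(traj)
run_simulation <- function(params, state = init_configuration(params),
                           verbose = FALSE) {
  stopifnot(inherits(params, "cav_params"), inherits(state, "cav_state"))
  L <- params$L
  N <- nrow(state$act_pos)
  pos0 <- rbind(state$mem_pos, state$act_pos)
  par <- .cpp_par(params)
  par$N <- N
  res <- cav_run_cpp(pos0, state$act_theta, par,
                     as.integer(params$n_steps), params$sample_every,
                     as.double(params$seed), isTRUE(verbose))
  if (res$n_close > 0)
    warning(sprintf("%g pair events closer than 0.3 sigma during run: timestep too large?",
                    res$n_close))
  # overshoot cascades at high density leave finite but absurd coordinates;
  # flag a ruptured ring loudly (dense systems need a smaller dt)
  if (L >= 3) {
    mlast <- matrix(res$pos_unwrapped[seq_len(L), , res$n_frames], ncol = 2)
    blmax <- max(sqrt(rowSums((mlast[c(2:L, 1), , drop = FALSE] - mlast)^2)))
    if (blmax > 3 * params$sigma)
      warning(sprintf("membrane ruptured (max bond %.3g sigma): reduce dt", blmax),
              call. = FALSE)
  }
  mem_idx <- seq_len(L)
  act_idx <- if (N > 0) L + seq_len(N) else integer(0)
  traj <- list(
    times = res$times + state$time,
    mem = res$pos[mem_idx, , , drop = FALSE],
    act = res$pos[act_idx, , , drop = FALSE],
    mem_unwrapped = res$pos_unwrapped[mem_idx, , , drop = FALSE],
    act_unwrapped = res$pos_unwrapped[act_idx, , , drop = FALSE],
    theta = if (N > 0) res$theta else matrix(numeric(0), 0, res$n_frames),
    fmem_act = res$mem_force_from_active,
    U = res$potential_energy,
    min_dist = res$min_dist,
    params = params,
    seed = params$seed
  )
  class(traj) <- "cav_trajectory"
  traj
}

#' Number of frames in a trajectory
#' @param traj a `cav_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one frame of a trajectory as a state
#' @param traj a `cav_trajectory`.
#' @param k frame index (1-based).
#' @return a `cav_state` with an extra `fmem_act` element.
#' @export
get_frame <- function(traj, k) {
  stopifnot(k >= 1, k <= n_frames(traj))
  slab <- function(a) matrix(a[, , k], ncol = 2)
  st <- list(
    mem_pos = slab(traj$mem),
    act_pos = slab(traj$act),
    act_theta = traj$theta[, k],
    mem_pos_unwrapped = slab(traj$mem_unwrapped),
    act_pos_unwrapped = slab(traj$act_unwrapped),
    time = traj$times[k],
    fmem_act = slab(traj$fmem_act)
  )
  class(st) <- "cav_state"
  st
}

#' @export
print.cav_trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d frames, t in [%g, %g], L = %d, N = %d, seed = %d\n",
    n_frames(x), x$times[1], x$times[n_frames(x)],
    dim(x$mem)[1], dim(x$act)[1], x$seed))
  invisible(x)
}

# frame indices surviving the burn-in fraction (always keeps >= 1 frame)
.after_burn_in <- function(traj, burn_in = traj$params$burn_in) {
  f <- n_frames(traj)
  first <- min(f, floor(burn_in * f) + 1L)
  first:f
}
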