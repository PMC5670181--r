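#' Cumulative rotation angle of the vesicle
#'
#' For each membrane monomer the polar angle of its position relative to
#' the instantaneous membrane centroid (unwrapped coordinates) is tracked
#' frame to frame and the per-frame increments, wrapped into `(-pi, pi]`,
#' are accumulated without 2 pi jumps.  The vesicle angle `beta(t)` is the
#' monomer mean of the cumulative angles, counterclockwise positive, with
#' `beta(0) = 0`.  Measuring about the centroid (not the box centre) keeps
#' net translation of the vesicle from aliasing into rotation.
#'
#' @param traj a `cav_trajectory`.
#' @return object of class `cav_rotation`: list with `times`, `beta`
#'   (frame means), and `beta_i` (`L x F` per-monomer cumulative angles).
#' @export
cumulative_rotation <- function(traj) {
  L <- dim(traj$mem)[1]
  f <- n_frames(traj)
  beta_i <- matrix(0, L, f)
  prev <- NULL
  acc <- rep(0, L)
  for (k in seq_len(f)) {
    m <- matrix(traj$mem_unwrapped[, , k], ncol = 2)
    c0 <- colMeans(m)
    ang <- atan2(m[, 2] - c0[2], m[, 1] - c0[1])
    if (!is.null(prev)) {
      d <- ang - prev
      d <- d - 2 * pi * round(d / (2 * pi))
      if (any(abs(d) >= 0.95 * pi))
        stop("per-frame angular increment close to pi: trajectory undersampled for rotation analysis")
      acc <- acc + d
    }
    beta_i[, k] <- acc
    prev <- ang
  }
  out <- list(times = traj$times, beta = colMeans(beta_i), beta_i = beta_i)
  class(out) <- "cav_rotation"
  out
}

#' Mean angular velocity of the vesicle
#'
#' Least-squares slope of `beta(t)` over the fit window of each run
#' (default: the second half, i.e. after a 50% burn-in), averaged over
#' runs, with the standard error across runs (or the slope's own standard
#' error for a single run).
#'
#' @param runs a `cav_rotation` or a list of them.
#' @param burn_in fraction of each series discarded before fitting.
#' @param window optional explicit `c(t_start, t_end)` fit window
#'   overriding `burn_in`.
#' @return list with `omega_prime`, `se`, `fit_window`, `per_run` slopes.
#' @export
mean_angular_velocity <- function(runs, burn_in = 0.5, window = NULL) {
  if (inherits(runs, "cav_rotation")) runs <- list(runs)
  stopifnot(length(runs) >= 1)
  slopes <- numeric(length(runs))
  se1 <- NA_real_
  win_used <- NULL
  for (j in seq_along(runs)) {
    r <- runs[[j]]
    if (is.null(window)) {
      f <- length(r$times)
      idx <- (floor(burn_in * f) + 1L):f
    } else {
      idx <- which(r$times >= window[1] & r$times <= window[2])
    }
    if (length(idx) < 2) stop("fewer than 2 frames in fit window")
    fit <- stats::lm.fit(cbind(1, r$times[idx]), r$beta[idx])
    slopes[j] <- fit$coefficients[2]
    if (length(runs) == 1) {
      res <- fit$residuals
      dfree <- length(idx) - 2L
      if (dfree > 0) {
        s2 <- sum(res^2) / dfree
        xc <- r$times[idx] - mean(r$times[idx])
        se1 <- sqrt(s2 / sum(xc^2))
      }
    }
    win_used <- range(r$times[idx])
  }
  se <- if (length(runs) > 1) stats::sd(slopes) / sqrt(length(slopes)) else se1
  list(omega_prime = mean(slopes), se = se, fit_window = win_used,
       per_run = slopes)
}

#' Number of active particles stacked to the membrane
#'
#' Counts active particles whose minimum-image distance to the nearest
#' membrane monomer is at most `stack_cutoff` (default the WCA interaction
#' range `2^(1/6) sigma`; the criterion is a modelling choice, so the
#' cutoff is exposed).
#'
#' @param frame a `cav_state` (e.g. from [get_frame()]).
#' @param stack_cutoff contact distance threshold.
#' @param box box side for minimum-image distances; `NULL` disables
#'   periodic wrapping.
#' @return integer count.
#' @export
stacked_count <- function(frame, stack_cutoff = 2^(1 / 6), box = NULL) {
  N <- nrow(frame$act_pos)
  if (N == 0) return(0L)
  L <- nrow(frame$mem_pos)
  dx <- outer(frame$act_pos[, 1], frame$mem_pos[, 1], "-")
  dy <- outer(frame$act_pos[, 2], frame$mem_pos[, 2], "-")
  if (!is.null(box)) {
    dx <- dx - box * round(dx / box)
    dy <- dy - box * round(dy / box)
  }
  dmin <- sqrt(apply(dx^2 + dy^2, 1, min))
  sum(dmin <= stack_cutoff)
}

# per-monomer unit tangents (CCW) and outward normals for one membrane frame
.frame_tangents <- function(mem) {
  L <- nrow(mem)
  nxt <- c(2:L, 1)
  prv <- c(L, 1:(L - 1))
  # ring orientation from the signed area (shoelace)
  a2 <- sum(mem[, 1] * mem[nxt, 2] - mem[nxt, 1] * mem[, 2])
  s <- if (a2 >= 0) 1 else -1
  tv <- (mem[nxt, , drop = FALSE] - mem[prv, , drop = FALSE]) * s
  len <- sqrt(rowSums(tv^2))
  if (any(len == 0)) stop("degenerate tangent: coincident neighbour monomers")
  tv <- tv / len
  nv <- cbind(tv[, 2], -tv[, 1])  # tangent rotated -pi/2: outward for CCW
  list(tangent = tv, normal = nv)
}

#' Membrane contact-force statistics
#'
#' Projects the per-frame force exerted by active particles on each
#' membrane monomer onto the local unit tangent (counterclockwise
#' positive) and the outward unit normal, averaging over monomers and the
#' post-burn-in frames.  Also reports the mean contact pressure `P_n`:
#' the monomer-mean positive outward normal force divided by the mean
#' bond length (force per unit contour length), and the mean stacked
#' count `N_s`.
#'
#' @param traj a `cav_trajectory` (must carry per-frame active-on-membrane
#'   forces, as produced by [run_simulation()]).
#' @param burn_in fraction of frames discarded.
#' @param stack_cutoff contact threshold for `N_s` (see [stacked_count()]).
#' @return object of class `cav_memforce`: list with `N_s`, `F_tau`,
#'   `F_n`, `P_n`, their standard errors over frames, and `stack_cutoff`.
#' @export
membrane_force_stats <- function(traj, burn_in = traj$params$burn_in,
                                 stack_cutoff = 2^(1 / 6) * traj$params$sigma) {
  idx <- .after_burn_in(traj, burn_in)
  L <- dim(traj$mem)[1]
  box <- traj$params$box
  ftau <- fn <- pn <- ns <- numeric(length(idx))
  for (j in seq_along(idx)) {
    k <- idx[j]
    mem <- matrix(traj$mem_unwrapped[, , k], ncol = 2)
    fr <- matrix(traj$fmem_act[, , k], ncol = 2)
    tn <- .frame_tangents(mem)
    ftau[j] <- mean(rowSums(fr * tn$tangent))
    proj_n <- rowSums(fr * tn$normal)
    fn[j] <- mean(proj_n)
    nxt <- c(2:L, 1)
    bond_len <- mean(sqrt(rowSums((mem[nxt, ] - mem) ^ 2)))
    pn[j] <- mean(pmax(proj_n, 0)) / bond_len
    ns[j] <- stacked_count(get_frame(traj, k), stack_cutoff, box = box)
  }
  nse <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  out <- list(
    N_s = mean(ns), N_s_se = nse(ns),
    F_tau = mean(ftau), F_tau_se = nse(ftau),
    F_n = mean(fn), F_n_se = nse(fn),
    P_n = mean(pn), P_n_se = nse(pn),
    stack_cutoff = stack_cutoff, n_frames = length(idx)
  )
  class(out) <- "cav_memforce"
  out
}
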