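#' Centre-of-mass mean squared displacement
#'
#' `g3(t) = < (x_cm(t) - x_cm(0))^2 + (y_cm(t) - y_cm(0))^2 >` where the
#' centre of mass runs over all `N + L` particles (equal masses) using
#' unwrapped coordinates.  Averaged over multiple time origins on a set of
#' (by default log-spaced) frame lags.
#'
#' @param traj a `cav_trajectory`.
#' @param lags integer frame lags; default about `n_lags` log-spaced lags.
#' @param n_lags number of default lags.
#' @param origin_stride spacing between time origins in frames (default
#'   chosen so origins are at least one rotational correlation time
#'   `1/Dtheta` apart, which limits correlation between origins).
#' @return object of class `cav_msd`: list with `lag_times`, `g3`,
#'   `n_origins`, `se`.
#' @export
com_msd <- function(traj, lags = NULL, n_lags = 40, origin_stride = NULL) {
  f <- n_frames(traj)
  if (f < 2) stop("need at least 2 frames")
  L <- dim(traj$mem)[1]
  N <- dim(traj$act)[1]
  # frame-by-frame COM over all particles
  cx <- (colSums(matrix(traj$mem_unwrapped[, 1, ], nrow = L)) +
         (if (N > 0) colSums(matrix(traj$act_unwrapped[, 1, ], nrow = N)) else 0)) / (N + L)
  cy <- (colSums(matrix(traj$mem_unwrapped[, 2, ], nrow = L)) +
         (if (N > 0) colSums(matrix(traj$act_unwrapped[, 2, ], nrow = N)) else 0)) / (N + L)
  dt_frame <- traj$times[2] - traj$times[1]
  if (is.null(lags)) {
    lags <- unique(round(exp(seq(log(1), log(f - 1), length.out = n_lags))))
  }
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1) || any(lags > f - 1)) stop("lag beyond trajectory length")
  if (is.null(origin_stride)) {
    tau_rot <- 1 / traj$params$Dtheta
    origin_stride <- max(1L, as.integer(round(tau_rot / dt_frame)))
    # keep a sane number of origins for short trajectories
    if (f %/% origin_stride < 8L) origin_stride <- max(1L, f %/% 8L)
  }
  g3 <- se <- numeric(length(lags))
  n_or <- integer(length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    origins <- seq(1L, f - k, by = origin_stride)
    d2 <- (cx[origins + k] - cx[origins])^2 + (cy[origins + k] - cy[origins])^2
    g3[j] <- mean(d2)
    n_or[j] <- length(d2)
    se[j] <- if (length(d2) > 1) stats::sd(d2) / sqrt(length(d2)) else NA_real_
  }
  out <- list(lag_times = lags * dt_frame, g3 = g3, n_origins = n_or, se = se,
              params = traj$params)
  class(out) <- "cav_msd"
  out
}

#' Closed-form constants of the chiral-swimmer MSD theory
#'
#' For `N` non-interacting chiral active particles dragging a composite of
#' `N + L` equal-mobility particles, the centre-of-mass MSD takes the form
#' `g3(t) = 4 D t + A [ exp(-Dtheta t) cos(omega t + phi0) - cos(phi0) ]`
#' with
#' `A = 2 N V0^2 / ((Dtheta^2 + omega^2) (N + L)^2)`,
#' `D = A Dtheta / 4`, and
#' `cos(phi0) = (Dtheta^2 - omega^2) / (Dtheta^2 + omega^2)`.
#' The phase branch with `sin(phi0) >= 0` is the one for which
#' `g3(0) = 0` and `g3'(0) = 0`.
#'
#' @param N active particle count.
#' @param L membrane monomer count.
#' @param V0 self-propulsion speed.
#' @param Dtheta rotational diffusion coefficient.
#' @param omega chiral angular velocity.
#' @return list with `A`, `D`, `cos_phi0`, `phi0`.
#' @export
#' @examples
#' theory_constants(N = 76, L = 50, V0 = 0.5, Dtheta = 0.03, omega = 0)$D
theory_constants <- function(N, L, V0, Dtheta, omega) {
  A <- 2 * N * V0^2 / ((Dtheta^2 + omega^2) * (N + L)^2)
  D <- A * Dtheta / 4
  cos_phi0 <- (Dtheta^2 - omega^2) / (Dtheta^2 + omega^2)
  phi0 <- atan2(2 * Dtheta * omega, Dtheta^2 - omega^2)  # sin(phi0) >= 0
  list(A = A, D = D, cos_phi0 = cos_phi0, phi0 = phi0)
}

#' Evaluate the closed-form chiral MSD
#'
#' `g3(t) = 4 D t + A [ exp(-Dtheta t) cos(omega t + phi0) - cos(phi0) ]`,
#' which at `omega = 0` reduces exactly to
#' `g3(t) = 4 D t + A (exp(-Dtheta t) - 1)`.
#' Optionally `D` can be overridden (e.g. by a fitted effective diffusion
#' coefficient), keeping `A` and `phi0` at their theoretical values.
#'
#' @param t times (vector).
#' @param N,L,V0,Dtheta,omega model constants (see [theory_constants()]).
#' @param D diffusion coefficient of the linear term; defaults to the
#'   theoretical `A Dtheta / 4`.
#' @param extra_D0 additional plain diffusion added as `4 extra_D0 t`
#'   (use the translational diffusion coefficient of the composite,
#'   `D0 / (N + L)`, when translational noise is on).
#' @return numeric vector `g3(t)`.
#' @export
theory_msd <- function(t, N, L, V0, Dtheta, omega, D = NULL, extra_D0 = 0) {
  stopifnot(Dtheta > 0)
  th <- theory_constants(N, L, V0, Dtheta, omega)
  if (is.null(D)) D <- th$D
  4 * (D + extra_D0) * t +
    th$A * (exp(-Dtheta * t) * cos(omega * t + th$phi0) - th$cos_phi0)
}

#' Fit the effective diffusion coefficient
#'
#' With the amplitude `A` and phase `phi0` fixed at their closed-form
#' values, the MSD model is linear in the single free parameter `D_eff`:
#' `g3(t) - A [exp(-Dtheta t) cos(omega t + phi0) - cos(phi0)] = 4 D_eff t`.
#' The least-squares solution is computed in closed form.
#'
#' @param msd a `cav_msd`, or a list with `lag_times` and `g3`.
#' @param N,L,V0,Dtheta,omega model constants.
#' @param lag_range optional `c(t_min, t_max)` restricting the fit; the
#'   default window `[0.1/Dtheta, min(10/Dtheta, max lag)]` spans the
#'   damped-oscillation and diffusive regimes.
#' @return object of class `cav_msd_fit`: list with `Deff`, `A`, `D`
#'   (theory), `phi0`, `cos_phi0`, `residual_rms`, `n_points`, inputs.
#' @export
fit_deff <- function(msd, N, L, V0, Dtheta, omega, lag_range = NULL) {
  t <- msd$lag_times
  g3 <- msd$g3
  if (is.null(lag_range))
    lag_range <- c(0.1 / Dtheta, min(10 / Dtheta, max(t)))
  keep <- t >= lag_range[1] & t <= lag_range[2]
  if (sum(keep) < 1) keep <- rep(TRUE, length(t))
  t <- t[keep]; g3 <- g3[keep]
  if (length(t) < 1 || all(t == 0)) stop("degenerate fit design: no usable lags")
  th <- theory_constants(N, L, V0, Dtheta, omega)
  y <- g3 - th$A * (exp(-Dtheta * t) * cos(omega * t + th$phi0) - th$cos_phi0)
  Deff <- sum(t * y) / (4 * sum(t^2))
  resid <- y - 4 * Deff * t
  out <- list(Deff = Deff, A = th$A, D = th$D, phi0 = th$phi0,
              cos_phi0 = th$cos_phi0,
              residual_rms = sqrt(mean(resid^2)), n_points = length(t),
              inputs = list(N = N, L = L, V0 = V0, Dtheta = Dtheta,
                            omega = omega, lag_range = lag_range))
  class(out) <- "cav_msd_fit"
  out
}

#' @export
print.cav_msd_fit <- function(x, ...) {
  cat(sprintf("Deff = %.6g (theory D = %.6g, A = %.6g, phi0 = %.4g rad)\n",
              x$Deff, x$D, x$A, x$phi0))
  cat(sprintf("  fit on %d lags in [%.3g, %.3g], residual rms %.3g\n",
              x$n_points, x$inputs$lag_range[1], x$inputs$lag_range[2],
              x$residual_rms))
  invisible(x)
}

#' Oscillation period of the short-time MSD
#'
#' Removes the fitted linear part `4 D_eff t` (plus the constant offset)
#' from `g3(t)` and estimates the dominant period of the remaining damped
#' oscillation from the mean spacing of its local maxima.  Flags (rather
#' than fails) when no oscillation is detectable.
#'
#' @param msd a `cav_msd` with lags resolving the expected period.
#' @param N,L,V0,Dtheta,omega model constants for the detrending fit.
#' @param lag_range optional fit window passed to [fit_deff()].
#' @return list with `period` (NA when flagged), `se` (half a lag
#'   spacing, the resolution limit), `n_peaks`, `detected`.
#' @export
oscillation_period <- function(msd, N, L, V0, Dtheta, omega,
                               lag_range = NULL) {
  fit <- fit_deff(msd, N, L, V0, Dtheta, omega, lag_range = lag_range)
  t <- msd$lag_times
  th <- theory_constants(N, L, V0, Dtheta, omega)
  resid <- msd$g3 - 4 * fit$Deff * t + th$A * th$cos_phi0
  # local maxima of the detrended signal
  n <- length(resid)
  if (n < 5) return(list(period = NA_real_, se = NA_real_, n_peaks = 0L,
                         detected = FALSE))
  pk <- which(resid[2:(n - 1)] > resid[1:(n - 2)] &
              resid[2:(n - 1)] >= resid[3:n]) + 1L
  # require a meaningful amplitude compared to the residual scale
  amp <- stats::sd(resid)
  pk <- pk[resid[pk] > 0.05 * amp]
  if (length(pk) < 2)
    return(list(period = NA_real_, se = NA_real_, n_peaks = length(pk),
                detected = FALSE))
  gaps <- diff(t[pk])
  list(period = mean(gaps),
       se = max(stats::sd(gaps) / sqrt(length(gaps)), max(diff(t)) / 2,
                na.rm = TRUE),
       n_peaks = length(pk), detected = TRUE)
}
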