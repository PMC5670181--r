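#' Gyration-tensor asphericity of the membrane
#'
#' From the 2 x 2 gyration tensor of the membrane monomers (unwrapped,
#' centroid-referenced), `S_ab = (1/L) sum (x_a - xbar_a)(x_b - xbar_b)`,
#' the asphericity is `Delta = (lambda1 - lambda2)^2 / (lambda1 +
#' lambda2)^2` with eigenvalues `lambda1 >= lambda2`: 0 for a circle, 1
#' for a rod.  The gyration radius is `Rg = sqrt(lambda1 + lambda2)`.
#'
#' @param frame a `cav_state`, or an `L x 2` coordinate matrix.
#' @return list with `lambda1`, `lambda2`, `Delta`, `Rg`.
#' @export
#' @examples
#' ring <- make_fixture("regular_ring", list(L = 100))
#' asphericity(ring)$Delta  # 0
asphericity <- function(frame) {
  m <- if (is.matrix(frame)) frame else frame$mem_pos_unwrapped
  if (nrow(m) < 3) stop("need at least 3 membrane monomers")
  c0 <- colMeans(m)
  xc <- m[, 1] - c0[1]
  yc <- m[, 2] - c0[2]
  sxx <- mean(xc^2); syy <- mean(yc^2); sxy <- mean(xc * yc)
  tr <- sxx + syy
  if (tr == 0) stop("all monomers coincident")
  disc <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  list(lambda1 = l1, lambda2 = l2,
       Delta = (l1 - l2)^2 / (l1 + l2)^2, Rg = sqrt(tr))
}

#' Interior angles of the membrane ring
#'
#' The interior angle at monomer `i` is measured between the edges to its
#' ring neighbours, on the interior side of the (assumed simple) polygon:
#' `phi_i = pi - turn_i`, where `turn_i` is the signed turning (exterior)
#' angle oriented so that the polygon winds counterclockwise.  Reflex
#' vertices give `phi_i > pi`.  The per-frame spread is the standard
#' deviation with `1/L` normalisation.
#'
#' @param frame a `cav_state` or an `L x 2` coordinate matrix.
#' @return list with `phi` (length L, radians in `(0, 2 pi)`) and
#'   `DeltaPhi_frame`, the per-frame standard deviation.
#' @export
interior_angles <- function(frame) {
  m <- if (is.matrix(frame)) frame else frame$mem_pos_unwrapped
  L <- nrow(m)
  if (L < 3) stop("need at least 3 monomers")
  nxt <- c(2:L, 1)
  prv <- c(L, 1:(L - 1))
  e_in <- m - m[prv, , drop = FALSE]    # edge arriving at vertex i
  e_out <- m[nxt, , drop = FALSE] - m   # edge leaving vertex i
  if (any(rowSums(e_in^2) == 0) || any(rowSums(e_out^2) == 0))
    stop("coincident neighbour monomers")
  a2 <- sum(m[, 1] * m[nxt, 2] - m[nxt, 1] * m[, 2])
  s <- if (a2 >= 0) 1 else -1
  turn <- s * atan2(e_in[, 1] * e_out[, 2] - e_in[, 2] * e_out[, 1],
                    rowSums(e_in * e_out))
  phi <- pi - turn
  list(phi = phi, DeltaPhi_frame = sqrt(mean((phi - mean(phi))^2)))
}

#' Mean interior-angle fluctuation over a trajectory
#'
#' `DeltaPhi` is the mean over post-burn-in frames of the per-frame
#' standard deviation of the interior angles (see [interior_angles()]).
#'
#' @param traj a `cav_trajectory`.
#' @param burn_in fraction of frames discarded.
#' @return list with `DeltaPhi`, `se` (over frames) and `per_frame`.
#' @export
interior_angle_fluctuation <- function(traj, burn_in = traj$params$burn_in) {
  idx <- .after_burn_in(traj, burn_in)
  v <- vapply(idx, function(k)
    interior_angles(matrix(traj$mem_unwrapped[, , k], ncol = 2))$DeltaPhi_frame,
    numeric(1))
  list(DeltaPhi = mean(v),
       se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
       per_frame = v)
}

#' Local curvature along the membrane
#'
#' Discrete curvature at monomer `i` as the reciprocal circumradius of the
#' triplet `(i-1, i, i+1)`:
#' `kappa = 2 |cross(b - a, c - a)| / (|b-a| |c-a| |c-b|)`.
#' Collinear triplets give 0.  With `signed = TRUE` the sign of the cross
#' product relative to the counterclockwise ring orientation is kept
#' (convex positive).
#'
#' @param frame a `cav_state` or an `L x 2` coordinate matrix.
#' @param signed keep the orientation sign.
#' @return numeric vector of length L.
#' @export
local_curvature <- function(frame, signed = FALSE) {
  m <- if (is.matrix(frame)) frame else frame$mem_pos_unwrapped
  L <- nrow(m)
  if (L < 3) stop("need at least 3 monomers")
  nxt <- c(2:L, 1)
  prv <- c(L, 1:(L - 1))
  a <- m[prv, , drop = FALSE]
  b <- m
  c_ <- m[nxt, , drop = FALSE]
  ab <- b - a; ac <- c_ - a; bc <- c_ - b
  cr <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  den <- sqrt(rowSums(ab^2) * rowSums(ac^2) * rowSums(bc^2))
  if (any(den == 0)) stop("coincident monomers in curvature triplet")
  kappa <- 2 * abs(cr) / den
  if (signed) {
    a2 <- sum(m[, 1] * m[nxt, 2] - m[nxt, 1] * m[, 2])
    s <- if (a2 >= 0) 1 else -1
    kappa <- kappa * sign(cr) * s
  }
  kappa
}

#' Distribution of reduced local curvature
#'
#' Pools `kappa_i / kappa0` (with `kappa0 = 1 / R0`, the curvature of the
#' initial circular configuration) over monomers and post-burn-in frames
#' and bins it into a probability density (the histogram integrates to 1).
#'
#' @param traj a `cav_trajectory`.
#' @param n_bins number of bins (default 61 over `[0, 3]`, widened if the
#'   data exceed that range).
#' @param burn_in fraction of frames discarded.
#' @return list with `bin_center`, `prob` (density), `bin_width`,
#'   `values` (the pooled reduced curvatures), `mean`, `sd`.
#' @export
curvature_distribution <- function(traj, n_bins = 61,
                                   burn_in = traj$params$burn_in) {
  idx <- .after_burn_in(traj, burn_in)
  kappa0 <- 1 / traj$params$R0
  vals <- unlist(lapply(idx, function(k)
    local_curvature(matrix(traj$mem_unwrapped[, , k], ncol = 2)) / kappa0))
  hi <- max(3, max(vals))
  breaks <- seq(0, hi, length.out = n_bins + 1)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  list(bin_center = h$mids, prob = h$density,
       bin_width = diff(breaks)[1], values = vals,
       mean = mean(vals), sd = stats::sd(vals))
}

#' Swelling ratio of the vesicle
#'
#' Time-averaged gyration radius after burn-in plugged into the pair of
#' coordinates `((Rg - R0)/Rg, rho R0^2 / Rg^2)`: the relative swelling of
#' the membrane versus the actual area fraction of the enclosed particles.
#' Negative swelling indicates a vesicle compressed below its relaxed
#' circular size.
#'
#' @param traj a `cav_trajectory`.
#' @param params parameters (defaults to those of the trajectory).
#' @param burn_in fraction of frames discarded.
#' @return list with `swelling` (`(Rg - R0)/Rg`), `actual_fraction`
#'   (`rho R0^2 / Rg^2`), and `Rg`.
#' @export
swelling_ratio <- function(traj, params = traj$params,
                           burn_in = params$burn_in) {
  idx <- .after_burn_in(traj, burn_in)
  rg <- vapply(idx, function(k)
    asphericity(matrix(traj$mem_unwrapped[, , k], ncol = 2))$Rg, numeric(1))
  Rg <- mean(rg)
  if (Rg <= 0) stop("non-positive gyration radius")
  list(swelling = (Rg - params$R0) / Rg,
       actual_fraction = params$rho * params$R0^2 / Rg^2,
       Rg = Rg)
}
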