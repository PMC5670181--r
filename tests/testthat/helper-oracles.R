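# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: plain R loops, closed forms, and generic numerics.

# all-pairs force/energy reference built from the scalar pair formulas
brute_forces_R <- function(state, params) {
  pos <- rbind(state$mem_pos, state$act_pos)
  n <- nrow(pos)
  L <- nrow(state$mem_pos)
  box <- params$box
  f <- matrix(0, n, 2)
  fa <- matrix(0, L, 2)
  U <- 0
  mi <- function(d) d - box * round(d / box)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- c(mi(pos[i, 1] - pos[j, 1]), mi(pos[i, 2] - pos[j, 2]))
      bonded <- i <= L && j <= L && (abs(i - j) == 1 || abs(i - j) == L - 1)
      if (!bonded || params$wca_bonded_neighbors) {
        w <- wca_pair(d, params$sigma, params$eps)
        U <- U + w$energy
        f[i, ] <- f[i, ] + w$force
        f[j, ] <- f[j, ] - w$force
        if (i <= L && j > L) fa[i, ] <- fa[i, ] + w$force
        if (j <= L && i > L) fa[j, ] <- fa[j, ] - w$force
      }
    }
  }
  if (L > 0) {
    for (i in seq_len(L)) {
      j <- if (i == L) 1L else i + 1L
      d <- c(mi(pos[i, 1] - pos[j, 1]), mi(pos[i, 2] - pos[j, 2]))
      b <- bond_pair(d, params$ks, params$r0)
      U <- U + b$energy
      f[i, ] <- f[i, ] + b$force
      f[j, ] <- f[j, ] - b$force
    }
  }
  list(mem_force = f[seq_len(L), , drop = FALSE],
       act_force = f[setdiff(seq_len(n), seq_len(L)), , drop = FALSE],
       mem_force_from_active = fa, potential_energy = U)
}

# random non-overlapping configuration inside the box (seeded)
random_config <- function(n_mem, n_act, box = 30, min_dist = 0.8, seed = 1) {
  set.seed(seed)
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n_mem + n_act) {
    cand <- runif(2, 0.1 * box, 0.9 * box)
    ok <- TRUE
    if (nrow(pts) > 0) {
      d <- sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)
      ok <- all(d > min_dist)
    }
    if (ok) pts <- rbind(pts, cand)
  }
  st <- list(mem_pos = pts[seq_len(n_mem), , drop = FALSE],
             act_pos = pts[n_mem + seq_len(n_act), , drop = FALSE],
             act_theta = runif(n_act, 0, 2 * pi),
             mem_pos_unwrapped = pts[seq_len(n_mem), , drop = FALSE],
             act_pos_unwrapped = pts[n_mem + seq_len(n_act), , drop = FALSE],
             time = 0)
  class(st) <- "cav_state"
  st
}

# params object for force tests on arbitrary small configurations
config_params <- function(n_mem, n_act, box = 30, ...) {
  # L is the membrane ring size; rho irrelevant here (N set explicitly)
  sim_params(L = max(n_mem, 3L), N = n_act, box = box, ...)
}

# point-in-polygon via the winding number (angle sum), independent of any
# package geometry code
in_polygon <- function(pts, poly) {
  apply(pts, 1, function(p) {
    dx <- poly[, 1] - p[1]
    dy <- poly[, 2] - p[2]
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- d - 2 * pi * round(d / (2 * pi))
    abs(sum(d)) > pi
  })
}

# random star-shaped simple polygon (seeded)
random_simple_polygon <- function(L, seed) {
  set.seed(seed)
  ang <- sort(runif(L, 0, 2 * pi))
  r <- runif(L, 0.5, 2)
  cbind(r * cos(ang), r * sin(ang))
}

# circumcircle radius via perpendicular-bisector intersection
circumradius_bisector <- function(a, b, c) {
  m1 <- (a + b) / 2; m2 <- (b + c) / 2
  d1 <- c(-(b - a)[2], (b - a)[1])
  d2 <- c(-(c - b)[2], (c - b)[1])
  A <- cbind(d1, -d2)
  if (abs(det(A)) < 1e-14) return(Inf)  # collinear
  t <- solve(A, m2 - m1)
  ctr <- m1 + t[1] * d1
  sqrt(sum((a - ctr)^2))
}

# closed-form chiral MSD by direct numerical quadrature of the
# force-correlation double integral (reduced to a single integral)
g3_quadrature <- function(t, N, L, V0, Dtheta, omega) {
  pref <- N * V0^2 / (N + L)^2
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    # integrate period by period so the oscillatory integrand stays easy
    brk <- if (omega > 0) unique(c(seq(0, tt, by = 2 * pi / omega), tt)) else c(0, tt)
    pieces <- vapply(seq_len(length(brk) - 1), function(i)
      stats::integrate(function(s) (tt - s) * exp(-Dtheta * s) * cos(omega * s),
                       brk[i], brk[i + 1], rel.tol = 1e-12,
                       subdivisions = 500L, stop.on.error = FALSE)$value,
      numeric(1))
    2 * pref * sum(pieces)
  }, numeric(1))
}

# central-difference gradient of the potential energy of a configuration
numerical_forces <- function(state, params, h = 1e-6) {
  energy <- function(st) compute_forces(st, params, method = "brute")$potential_energy
  grad_of <- function(which) {
    m <- state[[which]]
    g <- matrix(0, nrow(m), 2)
    for (i in seq_len(nrow(m))) for (k in 1:2) {
      sp <- state; sm <- state
      sp[[which]][i, k] <- sp[[which]][i, k] + h
      sm[[which]][i, k] <- sm[[which]][i, k] - h
      g[i, k] <- -(energy(sp) - energy(sm)) / (2 * h)
    }
    g
  }
  list(mem = grad_of("mem_pos"), act = grad_of("act_pos"))
}
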