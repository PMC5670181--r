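test_that("geometry derivation matches the closed forms", {
  g <- derive_geometry(150, 0.7)
  expect_identical(g$N, 1596L)

  g4 <- derive_geometry(4, 0)
  expect_equal(g4$R0, 1 / sqrt(2), tolerance = 1e-15)
  expect_identical(g4$N, 0L)

  g50 <- derive_geometry(50, 0.3)
  expect_equal(g50$R0, 7.9629855549543276, tolerance = 1e-15)
  expect_identical(g50$N, 76L)  # round(76.0909...)

  expect_error(derive_geometry(2, 0.3), "invalid geometry")
  expect_error(derive_geometry(50, 1.2), "rho")
})

test_that("parameter validation enforces the model invariants", {
  expect_error(sim_params(L = 50, rho = 0.3, gamma = 50), "gamma")
  expect_error(sim_params(L = 50, rho = 0.3, dt = 0), "dt")
  expect_error(sim_params(L = 500, rho = 0.3, box = 100), "box")
  p <- sim_params(L = 50, rho = 0.3)
  expect_equal(p$gamma * p$D0, p$eps)
  expect_equal(p$Dtheta, 3 * p$D0 / p$sigma^2)
  expect_equal(p$N, 76L)
  # N given instead of rho
  p2 <- sim_params(L = 50, N = 76)
  expect_equal(p2$rho, 76 / (4 * p2$R0^2), tolerance = 1e-12)
})

test_that("initial configuration is a regular ring with lattice-filled interior", {
  p <- sim_params(L = 50, rho = 0)
  st <- init_configuration(p)
  expect_equal(nrow(st$mem_pos), 50L)
  bl <- sqrt(rowSums((st$mem_pos[c(2:50, 1), ] - st$mem_pos)^2))
  expect_equal(bl, rep(p$sigma, 50), tolerance = 1e-12)

  p <- sim_params(L = 150, rho = 0.7)
  st <- init_configuration(p)
  expect_equal(nrow(st$act_pos), 1596L)
  ctr <- c(p$box / 2, p$box / 2)
  r <- sqrt(rowSums((st$act_pos - matrix(ctr, 1596, 2, byrow = TRUE))^2))
  expect_true(all(r <= p$R0 - p$sigma + 1e-12))

  # stated placement constraint: min pairwise distance >= sigma (1 - 1e-9)
  for (pp in list(sim_params(L = 50, rho = 0.5), sim_params(L = 100, rho = 0.2))) {
    s <- init_configuration(pp)
    all_pos <- rbind(s$mem_pos, s$act_pos)
    dmin <- min(dist(all_pos))
    expect_gte(dmin, pp$sigma * (1 - 1e-9))
  }

  expect_equal(init_configuration(p), init_configuration(p))  # deterministic
  expect_error(init_configuration(sim_params(L = 50, rho = 0.95)),
               "maximum feasible N")
})

test_that("WCA pair potential follows the shifted-truncated form", {
  rc <- 2^(1 / 6)
  at_cut <- wca_pair(c(rc, 0))
  expect_equal(at_cut$energy, 0)
  expect_equal(at_cut$force, c(0, 0))
  expect_equal(wca_pair(c(0, 2))$energy, 0)          # beyond cutoff
  # just inside the cutoff the energy is continuous (tends to 0)
  expect_lt(abs(wca_pair(c(rc - 1e-8, 0))$energy), 1e-6)

  at_contact <- wca_pair(c(1, 0))
  expect_equal(at_contact$energy, 1)                  # U(sigma) = eps
  expect_equal(at_contact$force, c(24, 0))            # |F(sigma)| = 24 eps/sigma

  # force is the negative radial derivative of the energy
  for (r in c(0.85, 0.95, 1.05, 1.11)) {
    h <- 1e-7
    dU <- (wca_pair(c(r + h, 0))$energy - wca_pair(c(r - h, 0))$energy) / (2 * h)
    expect_equal(wca_pair(c(r, 0))$force[1], -dU, tolerance = 1e-5)
  }
  expect_error(wca_pair(c(0, 0)), "overlap")
})

test_that("harmonic bond matches its closed form and symmetry", {
  eq <- bond_pair(c(1, 0), ks = 4000, r0 = 1)
  expect_equal(eq$energy, 0)
  expect_equal(eq$force, c(0, 0))

  st <- bond_pair(c(1.01, 0), ks = 4000, r0 = 1)
  expect_equal(st$energy, 0.2, tolerance = 1e-12)
  expect_equal(sqrt(sum(st$force^2)), 40, tolerance = 1e-12)
  expect_lt(st$force[1], 0)   # stretched bond pulls the first monomer back

  # even in the stretch
  d <- 0.037
  expect_equal(bond_pair(c(1 + d, 0))$energy, bond_pair(c(1 - d, 0))$energy,
               tolerance = 1e-12)
})

test_that("total forces match the R all-pairs oracle on random configurations", {
  for (seed in 1:5) {
    n_mem <- 8L; n_act <- 12L
    st <- random_config(n_mem, n_act, seed = seed)
    p <- config_params(n_mem, n_act)
    got <- suppressWarnings(compute_forces(st, p))
    want <- brute_forces_R(st, p)
    expect_equal(got$mem_force, want$mem_force, tolerance = 1e-10)
    expect_equal(got$act_force, want$act_force, tolerance = 1e-10)
    expect_equal(got$mem_force_from_active, want$mem_force_from_active,
                 tolerance = 1e-10)
    expect_equal(got$potential_energy, want$potential_energy, tolerance = 1e-10)
  }
})

test_that("equilibrium ring has zero bond forces and no WCA between distant monomers", {
  p <- sim_params(L = 50, rho = 0, wca_bonded_neighbors = FALSE)
  st <- init_configuration(p)
  f <- compute_forces(st, p)
  # non-bonded distances on the 50-gon all exceed the WCA cutoff, and every
  # bond is at its rest length
  expect_equal(max(abs(f$mem_force)), 0, tolerance = 1e-10)
  expect_equal(f$potential_energy, 0, tolerance = 1e-10)
})

test_that("two isolated particles at contact push each other apart symmetrically", {
  st <- random_config(3, 2, seed = 99)
  st$mem_pos <- st$mem_pos_unwrapped <- cbind(c(20, 21, 20.5), c(20, 20, 20.9))
  st$act_pos <- st$act_pos_unwrapped <- cbind(c(5, 6), c(5, 5))
  p <- config_params(3, 2)
  f <- suppressWarnings(compute_forces(st, p))
  expect_equal(f$act_force[1, ], -f$act_force[2, ], tolerance = 1e-12)
  expect_equal(sqrt(sum(f$act_force[1, ]^2)), 24, tolerance = 1e-10)
  expect_equal(f$act_force[1, 1], -24, tolerance = 1e-10)  # pushed in -x
})

test_that("forces sum to zero and equal the negative energy gradient", {
  for (seed in 1:3) {
    st <- random_config(6, 10, seed = 100 + seed)
    p <- config_params(6, 10)
    f <- suppressWarnings(compute_forces(st, p))
    tot <- colSums(f$mem_force) + colSums(f$act_force)
    expect_lt(sqrt(sum(tot^2)), 1e-9)
    ng <- suppressWarnings(numerical_forces(st, p))
    expect_equal(f$mem_force, ng$mem, tolerance = 1e-5)
    expect_equal(f$act_force, ng$act, tolerance = 1e-5)
  }
  # larger system: Newton's third law at n = 2000
  p <- sim_params(L = 150, rho = 0.7)
  st <- init_configuration(p)
  f <- compute_forces(st, p)
  tot <- colSums(f$mem_force) + colSums(f$act_force)
  expect_lt(sqrt(sum(tot^2)), 1e-9)
})

test_that("cell-list and brute-force paths are equivalent", {
  for (seed in 1:50) {
    n_mem <- sample(3:20, 1)
    n_act <- sample(0:25, 1)
    st <- random_config(n_mem, n_act, seed = 2000 + seed)
    p <- config_params(n_mem, n_act)
    a <- suppressWarnings(compute_forces(st, p, method = "cell"))
    b <- suppressWarnings(compute_forces(st, p, method = "brute"))
    expect_equal(a$mem_force, b$mem_force, tolerance = 1e-12)
    expect_equal(a$act_force, b$act_force, tolerance = 1e-12)
    expect_equal(a$potential_energy, b$potential_energy, tolerance = 1e-12)
  }
})
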