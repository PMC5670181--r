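test_that("a force-free noise-free state does not move", {
  p <- sim_params(L = 50, rho = 0, V0 = 0, omega = 0,
                  translational_noise = FALSE, wca_bonded_neighbors = FALSE)
  st <- init_configuration(p)
  st2 <- step_state(st, p, noise_stream(1))
  expect_equal(st2$mem_pos, st$mem_pos, tolerance = 1e-14)
  expect_equal(st2$time, p$dt)
})

test_that("deterministic self-propulsion advances by exactly V0 u dt", {
  p <- sim_params(L = 50, N = 1, V0 = 0.5, omega = 0,
                  translational_noise = FALSE, Dtheta = 0, gamma = 100, D0 = 0.01)
  st <- init_configuration(p)
  # the single active particle sits at the centre, far from the membrane
  st$act_pos <- st$act_pos_unwrapped <- matrix(c(100, 100), 1, 2)
  st$act_theta <- 0.7
  st2 <- step_state(st, p)
  expect_equal(st2$act_pos[1, ] - st$act_pos[1, ],
               0.5 * 0.01 * c(cos(0.7), sin(0.7)), tolerance = 1e-10)
  expect_equal(st2$act_theta, 0.7)  # omega = 0, Dtheta = 0
})

test_that("reference step and compiled loop integrate identically without noise", {
  p <- sim_params(L = 20, rho = 0.2, omega = 0.3, translational_noise = FALSE,
                  Dtheta = 0, n_steps = 25, sample_every = 25)
  st <- init_configuration(p)
  traj <- run_simulation(p, state = st)
  st_r <- st
  for (i in 1:25) st_r <- step_state(st_r, p)
  expect_equal(matrix(traj$mem[, , 2], ncol = 2), st_r$mem_pos, tolerance = 1e-9)
  expect_equal(matrix(traj$act[, , 2], ncol = 2), st_r$act_pos, tolerance = 1e-9)
  expect_equal(traj$theta[, 2], st_r$act_theta, tolerance = 1e-9)
})

test_that("free translational diffusion recovers MSD = 4 D0 t", {
  # ensemble of passive tracers (V0 = 0): displacement variance 2 D0 t per axis
  tr <- make_fixture("single_swimmer",
                     list(n_swimmers = 600, V0 = 0, D0 = 0.01, Dtheta = 0.03,
                          n_steps = 2000, sample_every = 2000, seed = 42))
  m <- swimmer_msd(tr)
  t_end <- m$times[2]
  expect_lt(abs(m$msd[2] - 4 * 0.01 * t_end), 3 * m$se[2])
})

test_that("runs are deterministic and n_steps = 0 yields only the initial frame", {
  p <- sim_params(L = 30, rho = 0.3, omega = 0.5, n_steps = 500,
                  sample_every = 100, seed = 77)
  t1 <- run_simulation(p)
  t2 <- run_simulation(p)
  expect_identical(t1$mem, t2$mem)
  expect_identical(t1$act, t2$act)
  expect_identical(t1$theta, t2$theta)

  p0 <- sim_params(L = 30, rho = 0.3, n_steps = 0, seed = 77)
  t0 <- run_simulation(p0)
  expect_equal(n_frames(t0), 1L)
  expect_equal(t0$times, 0)
})

test_that("frames satisfy the state invariants", {
  p <- sim_params(L = 30, rho = 0.3, omega = 0.1, n_steps = 2000,
                  sample_every = 200, seed = 3)
  traj <- run_simulation(p)
  expect_equal(diff(traj$times), rep(p$sample_every * p$dt, n_frames(traj) - 1),
               tolerance = 1e-12)
  for (k in seq_len(n_frames(traj))) {
    fr <- get_frame(traj, k)
    expect_true(all(fr$mem_pos >= 0 & fr$mem_pos < p$box))
    expect_true(all(fr$act_pos >= 0 & fr$act_pos < p$box))
    # unwrapped minus wrapped is an integer multiple of the box
    shift <- (fr$mem_pos_unwrapped - fr$mem_pos) / p$box
    expect_equal(shift, round(shift), tolerance = 1e-9)
  }
})

test_that("active particles stay inside the membrane and bonds stay stiff", {
  p <- sim_params(L = 50, rho = 0.3, omega = 0.04, n_steps = 3e5,
                  sample_every = 5000, seed = 5)
  traj <- run_simulation(p)
  L <- p$L
  ok_in <- TRUE
  ok_bond <- TRUE
  for (k in seq_len(n_frames(traj))) {
    mem <- matrix(traj$mem_unwrapped[, , k], ncol = 2)
    act_w <- matrix(traj$act[, , k], ncol = 2)
    # containment is checked in unwrapped membrane coordinates; map the
    # actives into the same image as the membrane centroid
    ctr <- colMeans(mem)
    act <- act_w
    act[, 1] <- act[, 1] - p$box * round((act[, 1] - ctr[1]) / p$box)
    act[, 2] <- act[, 2] - p$box * round((act[, 2] - ctr[2]) / p$box)
    ok_in <- ok_in && all(in_polygon(act, mem))
    bl <- sqrt(rowSums((mem[c(2:L, 1), ] - mem)^2))
    # the active pressure stretches the ring systematically (the vesicle
    # swells); the stiff spring bounds the *fluctuations* about that mean
    ok_bond <- ok_bond && all(abs(bl - mean(bl)) < 0.1 * p$sigma)
  }
  expect_true(ok_in)
  expect_true(ok_bond)

  # passive ring: bonds hold the literal r0 +/- 0.1 sigma window
  p0 <- sim_params(L = 50, rho = 0, n_steps = 1e5, sample_every = 5000, seed = 6)
  tr0 <- run_simulation(p0)
  bl0 <- unlist(lapply(seq_len(n_frames(tr0)), function(k) {
    mem <- matrix(tr0$mem_unwrapped[, , k], ncol = 2)
    sqrt(rowSums((mem[c(2:L, 1), ] - mem)^2))
  }))
  expect_true(all(abs(bl0 - p0$r0) < 0.1 * p0$sigma))
})

test_that("halving the timestep leaves the swimmer MSD unchanged within error", {
  msd_at <- function(dt) {
    tr <- make_fixture("single_swimmer",
                       list(n_swimmers = 400, V0 = 0.5, omega = 0.5,
                            dt = dt, n_steps = round(20 / dt),
                            sample_every = round(20 / dt), seed = 9))
    m <- swimmer_msd(tr)
    c(m$msd[2], m$se[2])
  }
  a <- msd_at(0.01)
  b <- msd_at(0.005)
  expect_lt(abs(a[1] - b[1]), 3 * sqrt(a[2]^2 + b[2]^2))
})
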