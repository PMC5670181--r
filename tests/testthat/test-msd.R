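test_that("closed-form theory constants match the model formulas", {
  th <- theory_constants(N = 10, L = 50, V0 = 0.5, Dtheta = 0.03, omega = 0)
  expect_equal(th$cos_phi0, 1)
  expect_equal(th$phi0, 0)
  th <- theory_constants(10, 50, 0.5, 0.03, 0.03)
  expect_equal(th$cos_phi0, 0)
  expect_equal(th$phi0, pi / 2, tolerance = 1e-12)
  # reference parameter set used for the L = 50, rho = 0.3 vesicle
  th <- theory_constants(76, 50, 0.5, 0.03, 0)
  expect_equal(th$D, 2 * 76 * 0.25 * 0.03 / (4 * 0.03^2 * 126^2), tolerance = 1e-14)
  expect_equal(round(th$D, 3), 0.020)
  expect_equal(th$D, th$A * 0.03 / 4)
})

test_that("theory MSD matches direct quadrature of the force correlation", {
  for (omega in c(0, 0.04, 0.5, 1.0)) {
    t <- c(0.1, 1, 10, 100, 1000)
    got <- theory_msd(t, N = 76, L = 50, V0 = 0.5, Dtheta = 0.03, omega = omega)
    want <- g3_quadrature(t, 76, 50, 0.5, 0.03, omega)
    expect_equal(got, want, tolerance = 1e-8)
    expect_equal(theory_msd(0, 76, 50, 0.5, 0.03, omega), 0, tolerance = 1e-14)
  }
})

test_that("omega = 0 reduces to the exponential-relaxation form", {
  t <- exp(seq(log(0.01), log(2000), length.out = 60))
  th <- theory_constants(76, 50, 0.5, 0.03, 0)
  eq19 <- 4 * th$D * t + th$A * (exp(-0.03 * t) - 1)
  expect_equal(theory_msd(t, 76, 50, 0.5, 0.03, 0), eq19, tolerance = 1e-14)
})

test_that("short-time expansion is ballistic with the composite prefactor", {
  # g3''(0+) = 2 N V0^2 / (N + L)^2
  h <- 1e-5
  for (omega in c(0, 0.7)) {
    g <- theory_msd(c(h, 2 * h), 76, 50, 0.5, 0.03, omega)
    second <- (g[2] - 2 * g[1]) / h^2   # g3(0) = 0
    expect_equal(second, 2 * 76 * 0.25 / 126^2, tolerance = 1e-3)
  }
})

test_that("COM MSD handles static, ballistic and diffusive references", {
  tr <- make_fixture("rigid_rotation", list(L = 40, rate = 0.01, n_frames = 20))
  m <- com_msd(tr, lags = 1:10)
  expect_equal(max(abs(m$g3)), 0, tolerance = 1e-16)

  # uniform rigid drift: g3(t) = v^2 t^2 exactly
  v <- c(0.3, -0.4)
  nf <- 30L
  mem <- array(0, c(40, 2, nf))
  base <- tr$mem[, , 1]
  for (k in seq_len(nf)) mem[, , k] <- base + matrix((k - 1) * v, 40, 2, byrow = TRUE)
  tr2 <- tr
  tr2$times <- seq_len(nf) - 1
  tr2$mem <- tr2$mem_unwrapped <- mem
  tr2$act <- tr2$act_unwrapped <- array(0, c(0, 2, nf))
  tr2$theta <- matrix(0, 0, nf)
  tr2$U <- rep(0, nf)
  m <- com_msd(tr2, lags = c(1, 3, 7))
  expect_equal(m$g3, sum(v^2) * c(1, 3, 7)^2, tolerance = 1e-12)
  expect_error(com_msd(tr2, lags = 50), "lag beyond")

  # seeded random-walk COM: fitted slope / 4 recovers D within 3 SE
  set.seed(31)
  D <- 0.05; dtf <- 0.5; nf <- 4000L
  steps <- matrix(rnorm(2 * (nf - 1), sd = sqrt(2 * D * dtf)), nf - 1, 2)
  path <- rbind(c(0, 0), apply(steps, 2, cumsum))
  mem <- array(0, c(3, 2, nf))
  tri <- make_fixture("regular_ring", list(L = 3))$mem_pos
  for (k in seq_len(nf)) mem[, , k] <- tri + matrix(path[k, ], 3, 2, byrow = TRUE)
  tr3 <- tr
  tr3$times <- (seq_len(nf) - 1) * dtf
  tr3$mem <- tr3$mem_unwrapped <- mem
  tr3$act <- tr3$act_unwrapped <- array(0, c(0, 2, nf))
  tr3$theta <- matrix(0, 0, nf)
  tr3$U <- rep(0, nf)
  m <- com_msd(tr3, lags = c(2, 5, 10, 20), origin_stride = 25)
  slope <- sum(m$lag_times * m$g3) / sum(m$lag_times^2)
  se_slope <- sqrt(sum((m$lag_times * m$se)^2)) / sum(m$lag_times^2)
  expect_lt(abs(slope / 4 - D), 3 * se_slope / 4)
})

test_that("Deff fitting is exact on clean data and unbiased under noise", {
  t <- exp(seq(log(1), log(500), length.out = 60))
  pars <- list(N = 76, L = 50, V0 = 0.5, Dtheta = 0.03, omega = 0.5)
  truth <- 3.7e-4
  g3 <- theory_msd(t, pars$N, pars$L, pars$V0, pars$Dtheta, pars$omega, D = truth)
  fit <- fit_deff(list(lag_times = t, g3 = g3), pars$N, pars$L, pars$V0,
                  pars$Dtheta, pars$omega)
  expect_equal(fit$Deff, truth, tolerance = 1e-12)

  set.seed(17)
  rec <- replicate(100, {
    noisy <- g3 * (1 + 0.01 * rnorm(length(g3)))
    fit_deff(list(lag_times = t, g3 = noisy), pars$N, pars$L, pars$V0,
             pars$Dtheta, pars$omega)$Deff
  })
  expect_lt(abs(mean(rec) - truth), 3 * sd(rec) / sqrt(length(rec)))

  # omega = 0 fit agrees with fitting the exponential-relaxation form directly
  g0 <- theory_msd(t, 76, 50, 0.5, 0.03, 0, D = 2.2e-3)
  fit0 <- fit_deff(list(lag_times = t, g3 = g0), 76, 50, 0.5, 0.03, 0)
  th <- theory_constants(76, 50, 0.5, 0.03, 0)
  keep <- t >= 0.1 / 0.03 & t <= min(10 / 0.03, max(t))
  y <- (g0 - th$A * (exp(-0.03 * t) - 1))[keep]
  expect_equal(fit0$Deff, sum(t[keep] * y) / (4 * sum(t[keep]^2)), tolerance = 1e-12)
  expect_equal(fit0$Deff, 2.2e-3, tolerance = 1e-10)
})

test_that("oscillation period is recovered from synthetic oscillatory MSD", {
  t <- seq(0.5, 80, by = 0.5)
  pars <- list(N = 76, L = 50, V0 = 0.5, Dtheta = 0.03, omega = 0.5)
  g3 <- theory_msd(t, pars$N, pars$L, pars$V0, pars$Dtheta, pars$omega, D = 2e-4)
  os <- oscillation_period(list(lag_times = t, g3 = g3), pars$N, pars$L,
                           pars$V0, pars$Dtheta, pars$omega)
  expect_true(os$detected)
  expect_lt(abs(os$period - 2 * pi / 0.5), 0.5)  # one lag spacing

  g0 <- theory_msd(t, 76, 50, 0.5, 0.03, 0, D = 2e-4)
  os0 <- oscillation_period(list(lag_times = t, g3 = g0), 76, 50, 0.5, 0.03, 0)
  expect_false(os0$detected)
})
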