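# Membrane module: pore-discovery resistance, flux, RK4 exchange,
# mirror-and-recycle bookkeeping.

test_that("membrane resistance matches an independent three-term evaluation", {
  # frozen from a one-line evaluation: A=1e-6 m^2, r=0.5 um, phi=0.1,
  # th=10 um, D=1e-9 m^2/s
  expect_equal(as.numeric(membrane_resistance(1e-6, 0.5e-6, 0.1, 10e-6, 1e-9)),
               13926990816.98724, tolerance = 1e-12)
})

test_that("membrane resistance limits behave physically", {
  # transparent limit: high porosity, vanishing thickness, fine pores (the
  # pore-discovery term scales as pi*r/(4*A*phi*D), so many small pores beat
  # few large ones)
  r_open <- as.numeric(membrane_resistance(1e-6, 1e-9, 0.99, 1e-9, 1e-9))
  expect_lt(r_open, 1e7)
  # impermeable limit
  r0 <- membrane_resistance(1e-6, 0.5e-6, 0, 10e-6, 1e-9)
  expect_identical(as.numeric(r0), Inf)
  expect_true(attr(r0, "impermeable"))
  # doubling the thickness adds exactly th/(A D)
  r1 <- as.numeric(membrane_resistance(1e-6, 0.5e-6, 0.1, 10e-6, 1e-9))
  r2 <- as.numeric(membrane_resistance(1e-6, 0.5e-6, 0.1, 20e-6, 1e-9))
  expect_equal(r2 - r1, 10e-6 / (1e-6 * 1e-9))
})

test_that("the flux law is linear and antisymmetric", {
  expect_equal(membrane_flux(0, 1e9), 0)
  expect_equal(membrane_flux(1, 1e9), 1e-9)
  expect_equal(membrane_flux(-0.37, 2e9), -membrane_flux(0.37, 2e9))
  expect_equal(membrane_flux(5, Inf), 0)
})

test_that("RK4 reproduces the exponential to classic accuracy", {
  y <- rk4_step(function(t, y) -y, 1, 0, 0.1)
  expect_equal(y, exp(-0.1), tolerance = 1e-6)
  expect_equal(rk4_step(function(t, y) 0 * y, c(1, 2), 0, 5), c(1, 2))
  expect_error(rk4_step(function(t, y) 1 / (y - y), 1, 0, 0.1), "finite")
})

test_that("RK4 converges with order >= 3.8 against the closed form", {
  horizon <- 1
  errs <- vapply(c(0.1, 0.05, 0.025, 0.0125, 0.00625), function(h) {
    y <- 1; t <- 0
    for (i in seq_len(round(horizon / h))) {
      y <- rk4_step(function(t, y) -y, y, t, h)
      t <- t + h
    }
    abs(y - exp(-horizon))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  fit <- stats::lm(log(errs) ~ log(c(0.1, 0.05, 0.025, 0.0125, 0.00625)))
  expect_gte(unname(stats::coef(fit)[2]), 3.8)
  expect_true(all(orders > 3.5))
})

test_that("exchange with equal concentrations changes nothing", {
  ch <- uniform_slug_set(c(A = 0.4))
  tk <- uniform_slug_set(c(A = 0.4))
  out <- exchange_step(ch, tk, c(A = 1e10), 1, 1e-10, 1e-9)
  expect_equal(out$channel$C, ch$C)
  expect_equal(out$tank$C, tk$C)
})

test_that("a large channel reservoir drives the tank to the closed form", {
  R_M <- c(A = 1e10); V_t <- 1e-9; V_c <- 1e6 * V_t
  tau <- V_t * R_M[["A"]]
  ch <- uniform_slug_set(c(A = 1)); tk <- uniform_slug_set(c(A = 0))
  dt <- tau / 20; t <- 0
  for (i in 1:60) {
    out <- exchange_step(ch, tk, R_M, dt, V_c, V_t)
    ch <- out$channel; tk <- out$tank; t <- t + dt
  }
  expect_equal(unname(tk$C[1, "A"]), 1 - exp(-t / tau), tolerance = 1e-5)
})

test_that("a closed pair equilibrates to the mole-weighted mean", {
  R_M <- c(A = 5e9); V_c <- 4e-10; V_t <- 1e-9
  ch <- uniform_slug_set(c(A = 1)); tk <- uniform_slug_set(c(A = 0.1))
  target <- (V_c * 1 + V_t * 0.1) / (V_c + V_t)
  dt <- 1
  for (i in 1:400) {
    out <- exchange_step(ch, tk, R_M, dt, V_c, V_t)
    ch <- out$channel; tk <- out$tank
  }
  expect_equal(unname(ch$C[1, "A"]), target, tolerance = 1e-6)
  expect_equal(unname(tk$C[1, "A"]), target, tolerance = 1e-6)
})

test_that("exchange conserves total moles per species over many steps", {
  R_M <- c(A = 1e9, B = 4e9); V_c <- 2e-10; V_t <- 1.3e-9
  ch <- slug_set(c(0, 0.5, 1), rbind(c(A = 1, B = 0), c(A = 0.2, B = 0.7)))
  tk <- slug_set(c(0, 0.5, 1), rbind(c(A = 0, B = 0.1), c(A = 0.9, B = 0)))
  moles <- function(ch, tk) slug_moles_pair(ch, tk, V_c, V_t)
  m0 <- moles(ch, tk)
  for (i in 1:200) {
    out <- exchange_step(ch, tk, R_M, 0.5, V_c, V_t)
    ch <- out$channel; tk <- out$tank
  }
  expect_equal(moles(ch, tk), m0, tolerance = 1e-12)
})

test_that("misaligned profiles are rejected", {
  ch <- slug_set(c(0, 0.5, 1), rbind(c(A = 1), c(A = 0)))
  tk <- uniform_slug_set(c(A = 0))
  expect_error(exchange_step(ch, tk, c(A = 1e9), 1, 1e-10, 1e-9),
               "misaligned")
})

test_that("mirror-and-recycle rotates in order and leaves uniforms alone", {
  u <- uniform_slug_set(c(A = 0.5))
  expect_equal(mirror_and_recycle(u, 0.37)$C, u$C)

  tk <- slug_set(c(0, 0.5, 1), rbind(c(A = 1), c(A = 0)))
  rot <- mirror_and_recycle(tk, 0.5)   # the exiting half re-enters in front
  expect_equal(rot$b, c(0, 0.5, 1))
  expect_equal(unname(rot$C[, "A"]), c(0, 1))
})

test_that("mirror-and-recycle conserves tank moles for arbitrary patterns", {
  set.seed(77)
  for (i in 1:25) {
    k <- sample(1:6, 1)
    b <- c(0, sort(runif(k - 1)), 1)
    conc <- matrix(runif(k), ncol = 1, dimnames = list(NULL, "A"))
    tk <- slug_set(b, conc)
    m0 <- sum(diff(tk$b) * tk$C[, "A"])
    rot <- mirror_and_recycle(tk, runif(1))
    expect_equal(sum(diff(rot$b) * rot$C[, "A"]), m0, tolerance = 1e-12)
  }
})

test_that("an impermeable membrane leaves the tank untouched in a full run", {
  mb <- make_membrane_channel(porosity = 0.01)
  mb$network$membranes$porosity <- 0
  cfg <- sim_config(max_time = 1, fixed_step = 0.1)
  rs <- run_simulation(mb$network, cfg)
  tp <- tank_concentration_profile(rs, "m1")
  expect_true(all(tp$concentration == 0))
})

test_that("aligned splitting preserves both profiles", {
  x <- slug_set(c(0, 0.3, 1), rbind(c(A = 1), c(A = 0)))
  y <- slug_set(c(0, 0.6, 1), rbind(c(A = 0.2), c(A = 0.9)))
  al <- align_slug_sets(x, y)
  expect_equal(al$x$b, al$y$b)
  expect_equal(al$x$b, c(0, 0.3, 0.6, 1))
  expect_equal(unname(al$x$C[, "A"]), c(1, 0, 0))
  expect_equal(unname(al$y$C[, "A"]), c(0.2, 0.2, 0.9))
})
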