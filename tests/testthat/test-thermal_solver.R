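# ADI scheme against analytic diffusion oracles, then the simulation driver.

adiabatic_cfg <- function() {
  solver_config(surface_bc = "adiabatic", far_bc = "adiabatic")
}

test_that("uniform field with no source is an exact equilibrium", {
  m <- uniform_medium(50)
  T0 <- matrix(37, 50, 50)
  T1 <- adi_step(T0, 0, m$k, m$rhoc, dt = 1e-3, cell_size = 5e-6,
                 cfg = adiabatic_cfg())
  expect_equal(T1, T0, tolerance = 1e-14)
})

test_that("a Gaussian hot spot spreads per the 2-D Green's function", {
  # infinite-medium solution: a Gaussian of variance s0^2 evolves to
  # variance s0^2 + 2 alpha t with amplitude scaled by s0^2 / (s0^2 + 2 a t)
  n <- 120; d <- 5e-6
  m <- uniform_medium(n)
  xc <- (seq_len(n) - 0.5) * d - n * d / 2
  r2 <- outer(xc^2, xc^2, "+")
  s0 <- 30e-6; A <- 10
  T0 <- A * exp(-r2 / (2 * s0^2))
  t_end <- 2e-3
  nstep <- 40
  Tn <- T0
  for (i in seq_len(nstep)) {
    Tn <- adi_step(Tn, 0, m$k, m$rhoc, dt = t_end / nstep, cell_size = d,
                   cfg = adiabatic_cfg())
  }
  s2 <- s0^2 + 2 * m$alpha * t_end
  Texact <- A * (s0^2 / s2) * exp(-r2 / (2 * s2))
  l2 <- sqrt(sum((Tn - Texact)^2) / sum(Texact^2))
  expect_lt(l2, 0.01)
})

test_that("uniform steady heating raises the mean at H / (rho c) per second", {
  n <- 40
  m <- uniform_medium(n)
  H <- 2e8                      # W/m^3
  T0 <- matrix(35, n, n)
  dt <- 1e-4
  Tn <- T0
  for (i in 1:20) {
    Tn <- adi_step(Tn, H, m$k, m$rhoc, dt = dt, cell_size = 5e-6,
                   cfg = adiabatic_cfg())
  }
  expect_equal(mean(Tn) - 35, H / (1200 * 3600) * 20 * dt, tolerance = 1e-9)
})

test_that("adiabatic energy balance holds on the heterogeneous tissue grid", {
  grid <- tiny_grid()
  ab <- tiny_absorption()
  maps <- iplheat:::thermal_maps(grid)
  d <- grid$geometry$cell_size
  H <- ab$deposited * 1e5       # 10 J/cm^2 delivered in one step set
  dt <- 1e-4; nstep <- 30
  Tn <- matrix(35, nrow(H), ncol(H))
  for (i in seq_len(nstep)) {
    Tn <- adi_step(Tn, H, maps$k, maps$rhoc, dt = dt, cell_size = d,
                   cfg = adiabatic_cfg())
  }
  added <- sum(H) * d^2 * nstep * dt            # J per unit out-of-plane length
  stored <- sum(maps$rhoc * (Tn - 35)) * d^2
  expect_lt(abs(stored - added) / added, 0.005)
})

test_that("maximum principle: no undershoot below baseline for H >= 0", {
  grid <- tiny_grid()
  ab <- tiny_absorption()
  cfg <- solver_config(dt = 1e-4, t_extra = 0.01, surface_bc = "adiabatic",
                       far_bc = "fixed", far_T = 35)
  h <- run_simulation(ab, standard_train("SQUARE_PULSE"), grid, cfg = cfg,
                      probes = locate_probes(grid, follicle_depth = 250e-6))
  expect_true(all(h$T_final >= 35 - 1e-9))
  expect_true(all(h$epidermal_trace >= 35 - 1e-9))
  expect_true(all(h$follicle_trace >= 35 - 1e-9))
})

test_that("volumetric source follows the pulse envelope and integrates exactly", {
  ab <- tiny_absorption()
  tr <- standard_train("SPACED_PULSE_STACK")
  # inside the first off interval: no emission anywhere
  t_off <- 2.2e-3 + 7e-3
  expect_true(all(volumetric_source(ab, tr, 10, t_off) == 0))
  # linear in fluence
  H1 <- volumetric_source(ab, tr, 10, 1e-3)
  H2 <- volumetric_source(ab, tr, 20, 1e-3)
  expect_equal(H2, 2 * H1)
  # midpoint quadrature at the solver step returns the deposited map exactly
  # (segment breakpoints are multiples of the 50 us step)
  dt <- 5e-5
  tm <- seq(dt / 2, envelope_duration(tr) + 0.01, by = dt)
  wsum <- sum(power_fraction(tr, tm)) * dt
  expect_equal(wsum, 1, tolerance = 1e-12)
  total <- Reduce(`+`, lapply(tm, function(t) volumetric_source(ab, tr, 10, t))) * dt
  nz <- ab$deposited > 0
  expect_equal(total[nz], ab$deposited[nz] * 1e5, tolerance = 1e-6)
})

test_that("probe traces: zero fluence stays at baseline, rises scale linearly", {
  grid <- tiny_grid()
  ab <- tiny_absorption()
  pr <- locate_probes(grid, follicle_depth = 250e-6)
  # baseline-equilibrium boundaries so the unforced solution is constant
  cfg <- solver_config(dt = 1e-4, t_extra = 5e-3, surface_bc = "adiabatic")
  tr <- standard_train("FREE_DISCHARGE")
  h0 <- run_simulation(ab, tr, grid, cfg = cfg, probes = pr, fluence = 1e-12)
  expect_equal(max(abs(h0$epidermal_trace - 35)), 0, tolerance = 1e-6)
  h1 <- run_simulation(ab, tr, grid, cfg = cfg, probes = pr, fluence = 5)
  h2 <- run_simulation(ab, tr, grid, cfg = cfg, probes = pr, fluence = 10)
  expect_equal(h2$epidermal_trace - 35, 2 * (h1$epidermal_trace - 35),
               tolerance = 1e-6)
  expect_equal(h2$peak_follicle - 35, 2 * (h1$peak_follicle - 35),
               tolerance = 1e-6)
})

test_that("halving the time step moves probe peaks by less than 0.1 C", {
  grid <- tiny_grid()
  ab <- tiny_absorption()
  pr <- locate_probes(grid, follicle_depth = 250e-6)
  tr <- standard_train("FREE_DISCHARGE")
  ha <- run_simulation(ab, tr, grid, probes = pr,
                       cfg = solver_config(dt = 1e-4, t_extra = 0.01))
  hb <- run_simulation(ab, tr, grid, probes = pr,
                       cfg = solver_config(dt = 5e-5, t_extra = 0.01))
  expect_lt(abs(ha$peak_epidermal - hb$peak_epidermal), 0.1)
  expect_lt(abs(ha$peak_follicle - hb$peak_follicle), 0.1)
})

test_that("simulation driver validates its inputs", {
  grid <- tiny_grid()
  ab <- tiny_absorption()
  pr <- locate_probes(grid, follicle_depth = 250e-6)
  tr <- standard_train("SQUARE_PULSE")
  expect_error(run_simulation(ab, tr, grid, probes = pr,
                              cfg = solver_config(t_end = 5e-3)),
               "envelope")
  other <- build_grid(geometry_config(domain_width = 400e-6,
                                      domain_depth = 400e-6,
                                      follicle_top_depth = 150e-6,
                                      follicle_diameter = 100e-6,
                                      follicle_length = 200e-6))
  expect_error(run_simulation(ab, tr, other), "does not match")
})

test_that("peak metrics summarise and flag thresholds", {
  grid <- tiny_grid()
  ab <- tiny_absorption()
  pr <- locate_probes(grid, follicle_depth = 250e-6)
  cfg <- solver_config(dt = 1e-4, t_extra = 5e-3)
  h <- run_simulation(ab, standard_train("FREE_DISCHARGE"), grid,
                      cfg = cfg, probes = pr)
  # identical histories in every slot -> all excesses exactly zero
  hs <- list(h,
             structure(modifyList(unclass(h), list(category = "SQUARE_PULSE")),
                       class = "thermal_history"),
             structure(modifyList(unclass(h),
                                  list(category = "CLOSE_PULSE_STACK")),
                       class = "thermal_history"))
  pm <- peak_metrics(hs)
  expect_equal(unname(pm$excess_rise_pct), c(0, 0))
  # threshold above every peak -> nothing flagged
  pm_hi <- peak_metrics(hs, threshold = 1000)
  expect_false(any(pm_hi$table$exceeds_threshold))
  expect_error(peak_metrics(list()), "length")
})
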