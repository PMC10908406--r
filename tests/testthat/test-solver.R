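test_that("rhs_interior vanishes at rest and reduces to pure friction decay", {
  fluid <- fluid_properties()
  seg <- hw_vessel(n = 41L)
  n <- seg$n_nodes
  Ad <- segment_Ad(seg, segment_x(seg))
  ## uniform rest state: both derivatives identically zero
  r <- rhs_interior(Ad, rep(0, n), seg, fluid)
  expect_equal(max(abs(r$dA_dt)), 0)
  expect_equal(max(abs(r$dU_dt)), 0)
  ## uniform A and constant U in a uniform vessel: only friction acts on U
  U0 <- 0.3
  r <- rhs_interior(Ad, rep(U0, n), seg, fluid)
  fr <- 2 * (fluid$xi + 2) * pi * fluid$mu * U0 / (fluid$rho * Ad)
  expect_equal(r$dU_dt, -fr, tolerance = 1e-12)
  expect_equal(max(abs(r$dA_dt[2:(n - 1)])), 0)  # centred interior flux
  expect_error(rhs_interior(c(-1, Ad[-1]), rep(0, n), seg, fluid),
               "nonpositive")
})

test_that("the R-level junction solve enforces both coupling conditions", {
  fluid <- fluid_properties()
  p <- hw_vessel("p", d = 0.012, c0 = 5)
  d1 <- hw_vessel("d1", d = 0.008, c0 = 6)
  d2 <- hw_vessel("d2", d = 0.007, c0 = 6)
  ends <- list(list(seg = p, end = "dist", A = p$Ad_dist * 1.1, U = 0.4),
               list(seg = d1, end = "prox", A = d1$Ad_prox * 1.05, U = 0.5),
               list(seg = d2, end = "prox", A = d2$Ad_prox * 0.98, U = 0.3))
  sol <- solve_junction(ends, fluid)
  TP <- vapply(sol, function(s) s$P + 0.5 * fluid$rho * s$U^2, numeric(1))
  Q <- c(sol[[1]]$A * sol[[1]]$U, -sol[[2]]$A * sol[[2]]$U,
         -sol[[3]]$A * sol[[3]]$U)
  expect_lt(max(abs(TP - TP[1])), 1e-8 * max(abs(TP)))
  expect_lt(abs(sum(Q)), 1e-12 * max(abs(Q)))
  ## identical segments in series with a uniform state: nothing changes
  a <- hw_vessel("a"); b <- hw_vessel("b")
  u0 <- list(list(seg = a, end = "dist", A = a$Ad_dist * 1.2, U = 0.6),
             list(seg = b, end = "prox", A = a$Ad_dist * 1.2, U = 0.6))
  s0 <- solve_junction(u0, fluid)
  expect_equal(s0[[1]]$A, a$Ad_dist * 1.2, tolerance = 1e-12)
  expect_equal(s0[[2]]$U, 0.6, tolerance = 1e-12)
  expect_error(solve_junction(u0[1], fluid), "at least two")
})

test_that("a network at rest stays at rest to machine precision", {
  net <- hw_sealed_net(n = 51L)
  Ad <- pi * 0.01^2 / 4
  sim <- advance_cycle(net, T = 0.05,
                       config = solver_config(dt = 2e-4, min_steps = 1,
                                              tol = 1e-9),
                       sites = list(list(segment = "v", pos = 0.5, name = "m")),
                       init = list(segs = list(list(A = rep(Ad, 51),
                                                    U = rep(0, 51)))))
  st <- sim$state$segs[[1]]
  expect_lt(max(abs(st$A - Ad)) / Ad, 1e-13)
  expect_lt(max(abs(st$U)), 1e-12)
})

test_that("a small pulse propagates at the diastolic wave speed", {
  ## well-resolved Gaussian (sigma = 8 dx) in a long inviscid vessel
  net <- hw_sealed_net(n = 201L, L = 2.0, mu = 1e-6)
  g <- hw_gauss_state(201L, L = 2.0, x0 = 0.4, w = 0.08)
  dt <- 0.8 * (2 / 200) / 5
  sim <- advance_cycle(net, T = 0.24,
                       config = solver_config(dt = dt, min_steps = 1,
                                              tol = 1e-12, n_out = 12000),
                       sites = list(list(segment = "v", pos = 0.3, name = "a"),
                                    list(segment = "v", pos = 0.8, name = "b")),
                       init = g$moving)
  ta <- sim$records$a$t[which.max(sim$records$a$P)]
  tb <- sim$records$b$t[which.max(sim$records$b$P)]
  expect_equal(1.0 / (tb - ta), 5, tolerance = 0.01)
})

test_that("grid refinement shows convergence order of at least two", {
  run_at <- function(n) {
    dx <- 0.5 / (n - 1)
    dt0 <- 0.4 * dx / 6
    nst <- round(0.03 / dt0)
    dt <- 0.03 / nst                       # identical end time on all grids
    g <- hw_gauss_state(n)
    sim <- advance_cycle(hw_sealed_net(n = n), T = 0.03,
                         config = solver_config(dt = dt, min_steps = 1,
                                                tol = 1e-12),
                         sites = list(list(segment = "v", pos = 0.5,
                                           name = "m")),
                         init = g$standing)
    sim$state$segs[[1]]$A
  }
  ns <- c(101L, 201L, 401L)
  ref <- run_at(801L)
  err <- vapply(ns, function(n) {
    A <- run_at(n)
    stride <- (801L - 1L) / (n - 1L)
    sqrt(mean((A - ref[seq(1L, 801L, by = stride)])^2))
  }, numeric(1))
  orders <- log2(err[-length(err)] / err[-1])
  expect_gte(min(orders), 2)
})

test_that("junction reflections match the linear admittance oracle", {
  cases <- list(
    list(daughters = list(list(d = 0.009, c0 = 5), list(d = 0.009, c0 = 5))),
    list(daughters = list(list(d = 0.006, c0 = 6), list(d = 0.006, c0 = 6))),
    list(daughters = list(list(d = 0.012, c0 = 5), list(d = 0.012, c0 = 5))))
  for (cs in cases) {
    r <- hw_measure_reflection(cs$daughters)
    expect_equal(r$measured, r$theory, tolerance = 0.02,
                 info = sprintf("theory R = %.3f", r$theory))
    expect_lt(abs(r$measured - r$theory), 0.02)   # absolute, incident units
  }
  ## identical series junction: transmitted pulse unchanged, |R| tiny
  r0 <- hw_measure_reflection(list(list(d = 0.012, c0 = 5)))
  expect_lt(abs(r0$measured), 1e-3)
})

test_that("a sealed network conserves volume to the stated tolerance", {
  d <- 0.012; Ad <- pi * d^2 / 4
  a <- hw_vessel("a"); b <- hw_vessel("b")
  jn <- junction(list(list(segment = "a", end = "dist")),
                 list(list(segment = "b", end = "prox")))
  net <- network_spec(list(a, b), list(jn),
                      list(terminal("a", "prox", "closed"),
                           terminal("b", "dist", "closed")),
                      fluid = fluid_properties())
  n <- 81L; x <- seq(0, 0.4, length.out = n)
  dA <- 0.05 * Ad * exp(-(x - 0.2)^2 / (2 * 0.04^2))   # finite amplitude
  init <- list(segs = list(list(A = Ad + dA, U = rep(0, n)),
                           list(A = rep(Ad, n), U = rep(0, n))))
  sim <- advance_cycle(net, T = 0.5,
                       config = solver_config(dt = 1e-4, min_steps = 1,
                                              tol = 1e-12),
                       sites = list(list(segment = "a", pos = 0.5,
                                         name = "m")),
                       init = init)
  v0 <- sum(0.5 * (init$segs[[1]]$A[-1] + init$segs[[1]]$A[-n])) *
    0.4 / (n - 1) + Ad * 0.4
  expect_lt(abs(sim$arterial_volume[[1]] - v0) / v0, 1e-4)   # < 0.01 %
})

test_that("run_to_periodic satisfies the DC Windkessel oracle and restarts", {
  sv <- make_single_vessel_case()
  sim <- run_to_periodic(sv$net, inflow = sv$inflow, T = sv$T,
                         config = solver_config(tol = 1e-4, cycles_max = 60),
                         sites = list(list(segment = "vessel", pos = 1,
                                           name = "out")))
  expect_true(sim$converged)
  expect_equal(mean(sim$records$out$P), sv$oracle$P_mean_out,
               tolerance = 0.01)
  ## restarting from the converged state is already periodic after 1 cycle
  sim2 <- simulate_circulation(sv$net, inflow = sv$inflow, T = sv$T,
                               config = solver_config(tol = 1e-4,
                                                      cycles_max = 5),
                               sites = list(list(segment = "vessel", pos = 1,
                                                 name = "out")),
                               init = sim)
  expect_lt(sim2$residuals[[1]], 1e-4)
  expect_lte(sim2$cycles, 2L)
  ## non-convergence raises a descriptive error
  expect_error(
    run_to_periodic(sv$net, inflow = sv$inflow, T = sv$T,
                    config = solver_config(tol = 1e-12, cycles_max = 2),
                    sites = list(list(segment = "vessel", pos = 1,
                                      name = "out"))),
    "no periodic limit cycle")
})

test_that("the limit cycle is independent of the initial condition", {
  sv <- make_single_vessel_case()
  sites <- list(list(segment = "vessel", pos = 0.5, name = "m"))
  cfg <- solver_config(tol = 1e-5, cycles_max = 80)
  s1 <- simulate_circulation(sv$net, inflow = sv$inflow, T = sv$T,
                             sites = sites, config = cfg)
  ## start from a strongly perturbed state: +20 mmHg everywhere
  n <- sv$net$segments$vessel$n_nodes
  seg <- sv$net$segments$vessel
  Pex <- seg$Pext + 20 * MMHG_PA
  sq <- sqrt(seg$Ad_prox) + (Pex - seg$Pext) * seg$Ad_prox / seg$beta_prox
  init <- list(segs = list(list(A = rep(sq^2, n), U = rep(0, n))),
               bedPc = c(0, Pex))
  s2 <- simulate_circulation(sv$net, inflow = sv$inflow, T = sv$T,
                             sites = sites, config = cfg, init = init)
  rel <- sqrt(mean((s1$records$m$P - s2$records$m$P)^2)) /
    sqrt(mean((s1$records$m$P - mean(s1$records$m$P))^2))
  expect_lt(rel, 2e-4)
})

test_that("solver failure paths are diagnostic", {
  ## an unresolvable time step blows the CFL limit and is caught
  net <- hw_sealed_net(n = 51L)
  g <- hw_gauss_state(51L, amp = 0.3)
  expect_error(
    advance_cycle(net, T = 0.5,
                  config = solver_config(dt = 5e-3, min_steps = 1,
                                         tol = 1e-9),
                  sites = list(list(segment = "v", pos = 0.5, name = "m")),
                  init = g$standing),
    "diverged")
})
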