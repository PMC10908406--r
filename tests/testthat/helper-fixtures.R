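## shared fixtures and memoised expensive simulations

hw_cache <- new.env(parent = emptyenv())

hw_memo <- function(key, expr) {
  if (is.null(hw_cache[[key]])) hw_cache[[key]] <- force(expr)
  hw_cache[[key]]
}

## uniform test vessel with prescribed diastolic wave speed
hw_vessel <- function(id = "v", L = 0.4, d = 0.012, c0 = 5, n = 81L,
                      Pext = 0, rho = 1050) {
  Ad <- pi * d^2 / 4
  vessel_segment(id, id, L = L, d_prox = d, d_dist = d,
                 beta_prox = beta_for_wave_speed(c0, Ad, rho),
                 Pext = Pext, n_nodes = as.integer(n))
}

## sealed single-vessel network (both ends closed)
hw_sealed_net <- function(n = 101L, L = 0.5, d = 0.01, c0 = 5, mu = 4e-3) {
  vs <- hw_vessel("v", L = L, d = d, c0 = c0, n = n)
  network_spec(list(vs), list(),
               list(terminal("v", "prox", "closed"),
                    terminal("v", "dist", "closed")),
               fluid = fluid_properties(mu = mu))
}

## small Gaussian area pulse as a raw initial state; moving = waterhammer
## forward wave, otherwise a standing pulse that splits symmetrically
hw_gauss_state <- function(n, L = 0.5, d = 0.01, c0 = 5, amp = 1e-3,
                           x0 = 0.25 * L, w = 0.03) {
  Ad <- pi * d^2 / 4
  x <- seq(0, L, length.out = n)
  dA <- amp * Ad * exp(-(x - x0)^2 / (2 * w^2))
  list(standing = list(segs = list(list(A = Ad + dA, U = rep(0, n)))),
       moving = list(segs = list(list(A = Ad + dA, U = c0 * dA / Ad))),
       Ad = Ad, x = x)
}

## parent->daughters junction network for reflection studies (inviscid)
hw_junction_net <- function(daughters, n = 161L, L = 0.4) {
  p <- hw_vessel("p", L = L, d = 0.012, c0 = 5, n = n)
  ds <- lapply(seq_along(daughters), function(i)
    hw_vessel(paste0("d", i), L = L, d = daughters[[i]]$d,
              c0 = daughters[[i]]$c0, n = n))
  jn <- junction(list(list(segment = "p", end = "dist")),
                 lapply(seq_along(ds), function(i)
                   list(segment = paste0("d", i), end = "prox")))
  terms <- c(list(terminal("p", "prox", "closed")),
             lapply(seq_along(ds), function(i)
               terminal(paste0("d", i), "dist", "closed")))
  network_spec(c(list(p), ds), list(jn), terms,
               fluid = fluid_properties(mu = 1e-6))
}

## launch a forward pulse at the parent, return reflection coefficient
## measured from the backward characteristic at a mid-parent monitor,
## plus the linear admittance-oracle value
hw_measure_reflection <- function(daughters, n = 161L) {
  net <- hw_junction_net(daughters, n = n)
  p <- net$segments$p
  Adp <- pi * 0.012^2 / 4
  x <- seq(0, 0.4, length.out = n)
  amp <- 5e-4
  dA <- amp * Adp * exp(-(x - 0.12)^2 / (2 * 0.03^2))
  init <- list(segs = c(
    list(list(A = Adp + dA, U = 5 * dA / Adp)),
    lapply(net$segments[-1], function(s)
      list(A = rep(s$Ad_prox, n), U = rep(0, n)))))
  dt <- 0.4 * (0.4 / (n - 1)) / 6
  nst <- round(0.1 / dt)
  sim <- advance_cycle(net, T = nst * dt,
                       config = solver_config(dt = dt, min_steps = 1,
                                              tol = 1e-12, n_out = 4000),
                       sites = list(list(segment = "p", pos = 0.625,
                                         name = "m")),
                       init = init)
  r <- sim$records$m
  cA <- wave_speed(r$A, 0.25, p, net$fluid)
  c0v <- wave_speed(Adp, 0.25, p, net$fluid)
  Wp <- r$U + 4 * (cA - c0v)
  Wm <- r$U - 4 * (cA - c0v)
  Y <- function(d, c0) (pi * d^2 / 4) / (1050 * c0)
  theory <- (Y(0.012, 5) - sum(vapply(daughters, function(s)
    Y(s$d, s$c0), numeric(1)))) /
    (Y(0.012, 5) + sum(vapply(daughters, function(s)
      Y(s$d, s$c0), numeric(1))))
  ## pressure reflection coefficient = -W-/W+ (waterhammer sign convention)
  list(measured = -Wm[which.max(abs(Wm))] / max(Wp), theory = theory)
}

## converged baseline reduced-tree run, shared across test files
hw_baseline <- function() hw_memo("baseline", {
  net <- make_reduced_tree()
  sim <- simulate_circulation(net, heart = heart_params(),
                              config = solver_config(tol = 2e-4))
  list(net = net, sim = sim)
})

## synthetic sinusoidal record: P = Pm + a sin(wt), Q = Qm + b sin(wt + phi)
hw_sine_record <- function(Pm = 1e4, a = 2e3, Qm = 1e-5, b = 4e-6,
                           phi = 0, T = 0.8, n = 1000L) {
  t <- (seq_len(n) - 1L) * T / n
  w <- 2 * pi / T
  waveform_record(t = t, P = Pm + a * sin(w * t),
                  Q = Qm + b * sin(w * t + phi),
                  U = (Qm + b * sin(w * t + phi)) / 3e-5,
                  A = rep(3e-5, n), site = "sine")
}
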