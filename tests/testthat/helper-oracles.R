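# Independent numerical oracles and small fixture builders used across the
# suite.

# Emitted mass per area (mg/cm^2) from a 1-D diffusion PDE with a
# perfect-sink surface, solved by method of lines on cell centers with a
# ghost-node Dirichlet face. Independent of the closed-form model.
pde_flux_emitted <- function(C0, D, t_end, L, nx = 200) {
  dx <- L / nx
  rhs <- function(t, C, p) {
    left <- c(-C[1], C[-nx])        # sink face at x = 0
    right <- c(C[-1], C[nx])        # no-flux at x = L
    list(D * (left - 2 * C + right) / dx^2)
  }
  out <- deSolve::ode.1D(y = rep(C0, nx), times = c(0, t_end), func = rhs,
                         parms = NULL, nspec = 1, dimens = nx,
                         method = "lsoda", rtol = 1e-9, atol = 1e-14)
  C_end <- out[2, -1]
  (C0 * L - sum(C_end) * dx) * 1000
}

# Fixed-step RK4 integration of the film/air/vent system; independent of
# the adaptive solver used by the package. Assumes the film is not
# exhausted within the event (true for the parameter ranges tested).
rk4_release_fraction <- function(substance, spec, box, nstep = 5000) {
  svc <- saturated_vapor_concentration(substance, spec$temperature)
  kA <- spec$mass_transfer_coefficient * spec$applied_film_area / 1e4
  V <- box$room_volume
  q <- box$air_exchange_rate
  h <- box$event_duration / nstep
  deriv <- function(y) {
    drive <- if (y[1] > 0) kA * (svc - y[2]) else 0
    c(-drive, drive / V - q * y[2], q * V * y[2])
  }
  y <- c(spec$film_mass, 0, 0)
  for (i in seq_len(nstep)) {
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  min(max((spec$film_mass - y[1]) / spec$film_mass, 0), 1)
}

# Scenario shortcut with screening defaults and explicit overrides.
make_scenario <- function(code = "TEST", class = "product", ...) {
  exposure_scenario(code, class, ...)
}

# A substance whose saturated vapor concentration is far above any
# concentration the tests produce, so the cap never binds.
uncapped_substance <- function(vp = 5000, mw = 100) {
  substance("uncapped", molecular_weight = mw, vapor_pressure = vp)
}
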