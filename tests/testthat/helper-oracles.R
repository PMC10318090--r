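# Independent numerical oracles used to check the closed forms. They share
# no code with the package internals: the toxicant subsystem is integrated
# by plain RK4 with event handling at the pulses, and the periodic orbit is
# found by iterating the impulsive period map to a fixed point.

# RK4 integration of dc_o/dt = f c_e - (g+m) c_o, dc_e/dt = -h c_e between
# pulses, pulse +b applied at multiples of gamma (not at t = 0).
rk4_toxicant <- function(params, t_end, c_o0, c_e0, n_sub = 400L) {
  f <- params$f; k <- params$g + params$m; h <- params$h
  rhs <- function(y) c(f * y[2] - k * y[1], -h * y[2])
  gam <- params$gamma
  y <- c(c_o0, c_e0)
  t <- 0
  n_pulses <- floor(t_end / gam + 1e-9)
  seg_ends <- c(seq_len(n_pulses) * gam, t_end)
  seg_ends <- seg_ends[seg_ends > 1e-12]
  for (te in unique(seg_ends)) {
    hstep <- (te - t) / n_sub
    for (i in seq_len(n_sub)) {
      k1 <- rhs(y)
      k2 <- rhs(y + hstep / 2 * k1)
      k3 <- rhs(y + hstep / 2 * k2)
      k4 <- rhs(y + hstep * k3)
      y <- y + hstep / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    t <- te
    at_pulse <- abs(te / gam - round(te / gam)) < 1e-9 && te < t_end + 1e-12
    if (at_pulse && te <= n_pulses * gam + 1e-12 && te != t_end) {
      y[2] <- y[2] + params$b
    }
  }
  y # state at t_end, pre-pulse if t_end is a pulse instant
}

# fixed point of the exact one-period map, found by iteration, then extrema
# on a dense grid. Uses only the textbook between-pulse solution formulas.
orbit_oracle <- function(params, n_grid = 100000L, n_iter = 400L) {
  f <- params$f; k <- params$g + params$m; h <- params$h
  b <- params$b; gam <- params$gamma
  prop <- function(co, ce, s) {
    ce_s <- ce * exp(-h * s)
    co_s <- if (abs(h - k) > 1e-10) {
      co * exp(-k * s) + f * ce * (exp(-k * s) - exp(-h * s)) / (h - k)
    } else {
      co * exp(-k * s) + f * ce * s * exp(-h * s)
    }
    cbind(co_s, ce_s, deparse.level = 0)
  }
  co <- 0.5; ce <- 0.5
  for (i in seq_len(n_iter)) {
    st <- prop(co, ce, gam)
    co <- st[1]; ce <- st[2] + b
  }
  s <- seq(0, gam, length.out = n_grid)
  st <- prop(co, ce, s)
  list(co0 = co, ce0 = ce,
       co_min = min(st[, 1]), co_max = max(st[, 1]),
       ce_min = min(st[, 2]), ce_max = max(st[, 2]),
       s = s, co = st[, 1], ce = st[, 2])
}

# random toxicant parameter sets satisfying the boundedness constraints
random_tox_params <- function(n, seed = 1) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- runif(1, 0.05, 0.6)
    m <- runif(1, 0.05, 0.6)
    f <- runif(1, 0, g + m)
    h <- runif(1, 0.1, 1)
    gam <- runif(1, 0.4, 2)
    b <- runif(1, 0, 1 - exp(-h * gam))
    out[[i]] <- toxicant_params(f, g, m, h, b, gam)
  }
  out
}

fixture_model <- function(name) fixture(name)$model

# textbook between-pulse solution for the periodic body burden, written out
# independently of the package internals
periodic_co_at_oracle <- function(params, co0, ce0, s) {
  k <- params$g + params$m; h <- params$h
  if (abs(h - k) > 1e-10) {
    co0 * exp(-k * s) + params$f * ce0 * (exp(-k * s) - exp(-h * s)) / (h - k)
  } else {
    co0 * exp(-k * s) + params$f * ce0 * s * exp(-h * s)
  }
}

# RK4 reference for the noiseless population ODE with exact toxicant
# forcing; dt must divide gamma so stages never cross a pulse
rk4_population <- function(model, t_end, dt, x0, tox0) {
  tox <- solve_toxicant(model$toxicant, seq(0, t_end, by = dt / 2),
                        tox0[1], tox0[2])
  gam <- model$toxicant$gamma
  idx <- which(abs(tox$t / gam - round(tox$t / gam)) < 1e-9 & tox$t > 0)
  tox$c_e[idx] <- tox$c_e[idx] + model$toxicant$b
  a1 <- model$patch1$a; a2 <- model$patch2$a
  d21 <- model$migration$d21
  rhs <- function(j, x) {
    r1 <- mean_growth(model$patch1, tox$t[j]) - model$delta * tox$c_o[j]
    r2 <- mean_growth(model$patch2, tox$t[j])
    d12t <- migration_rate(model$migration, tox$c_e[j])
    c(x[1] * (r1 - a1 * x[1]) + d21 * x[2] - d12t * x[1],
      x[2] * (r2 - a2 * x[2]) + d12t * x[1] - d21 * x[2])
  }
  x <- x0
  for (s in seq_len(round(t_end / dt))) {
    j <- 2 * s - 1
    k1 <- rhs(j, x)
    k2 <- rhs(j + 1, x + dt / 2 * k1)
    k3 <- rhs(j + 1, x + dt / 2 * k2)
    k4 <- rhs(j + 2, x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}
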