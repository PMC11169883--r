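# Independent oracles used across the suite.

# Capacitance by direct evaluation of the volume-fraction mixing rule:
# reconstruct the three phase volume fractions from the wet-basis moisture
# fraction and the pore ratio, then apply C = (S*eps0/d) * sum(v_i * eps_i).
oracle_capacitance <- function(w, geom, mat) {
  e <- geom$pore_ratio
  # Vw/Vc from W = rho_w Vw / (rho_c Vc + rho_w Vw)
  u <- (w / (1 - w)) * mat$rho_cereal / mat$rho_water
  v_cereal <- (1 - e) / (1 + u)
  v_water <- (1 - e) * u / (1 + u)
  geom$plate_area * mat$eps0 / geom$plate_spacing *
    (v_cereal * mat$eps_cereal + v_water * mat$eps_water + e * mat$eps_air)
}

random_geometry <- function() {
  sensor_geometry(plate_area = runif(1, 0.001, 0.1),
                  plate_spacing = runif(1, 0.01, 0.5),
                  pore_ratio = runif(1, 0, 0.9))
}

random_materials <- function() {
  eps_air <- runif(1, 1, 1.01)
  eps_cereal <- runif(1, 2, 6)
  material_constants(eps_cereal = eps_cereal,
                     eps_water = runif(1, 60, 90),
                     eps_air = eps_air,
                     rho_cereal = runif(1, 400, 900),
                     rho_water = 1000)
}

# Straight-line scalar reimplementations of the three sparrow update rules,
# written independently of the vectorised package code. They consume the
# same pre-drawn random quantities.
oracle_update_finders <- function(X, rows, cfg, R, alpha, Q) {
  for (i in seq_along(rows)) {
    for (j in seq_len(ncol(X))) {
      x <- X[rows[i], j]
      x <- if (R < cfg$safety_value) {
        x * exp(-i / (alpha[i] * cfg$max_iters))
      } else {
        x + Q[i, j]
      }
      X[rows[i], j] <- min(max(x, cfg$lower[j]), cfg$upper[j])
    }
  }
  X
}

oracle_update_joiners <- function(X, rows, n_finders, cfg, x_p, x_l, Q, Asign) {
  n <- cfg$pop_size
  d <- cfg$dims
  for (k in seq_along(rows)) {
    i <- n_finders + k
    old <- X[rows[k], ]
    if (i > n / 2) {
      newx <- sapply(seq_len(d), function(j) {
        Q[k, j] * exp((x_l[j] - old[j]) / i^2)
      })
    } else {
      s <- 0
      for (j in seq_len(d)) s <- s + abs(old[j] - x_p[j]) * Asign[k, j]
      newx <- x_p + s / d
    }
    X[rows[k], ] <- pmin(pmax(newx, cfg$lower), cfg$upper)
  }
  X
}

oracle_update_scouts <- function(X, rows, fitness, x_b, f_g, x_l, f_w, cfg,
                                 beta, K, eps = 1e-50) {
  for (k in seq_along(rows)) {
    old <- X[rows[k], ]
    newx <- if (fitness[rows[k]] > f_g) {
      x_b + beta[k] * abs(old - x_b)
    } else {
      old + K[k] * (abs(old - x_l) / ((fitness[rows[k]] - f_w) + eps))
    }
    X[rows[k], ] <- pmin(pmax(newx, cfg$lower), cfg$upper)
  }
  X
}

# feature matrix used throughout the regression tests
campaign_features <- function(df) {
  as.matrix(df[, c("temperature_C", "duty_cycle", "capacitance_pF")])
}
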