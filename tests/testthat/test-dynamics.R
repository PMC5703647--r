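# dynamics: parameters, energy/forces, OU tension process, stepping,
# T1 handling, relaxation, simulation driver

test_that("model_params validates its invariants", {
  p <- model_params()
  expect_equal(p$alpha, p$tau_p * p$gamma_mean / p$l_char)
  expect_error(model_params(dt = 1), "dt must be below")
  expect_error(model_params(l_new = 0.01, l_T1 = 0.05), "l_new must exceed")
  expect_error(model_params(K = -1), "positive")
  expect_error(model_params(bogus = 1), "unknown parameter")
  expect_error(model_params(alpha = 99), "alpha inconsistent")
})

test_that("tissue energy matches a brute-force re-summation", {
  p <- model_params()
  v <- build_voronoi(20, seed = 3)
  set.seed(1)
  g <- stats::runif(nrow(v$edges), 0.5, 1.5)
  # independent oracle: explicit loops over elements
  E_oracle <- 0
  for (r in seq_len(nrow(v$edges))) {
    d <- v$pos[v$edges[r, 2], ] - v$pos[v$edges[r, 1], ]
    d <- d - v$box * round(d / v$box)
    E_oracle <- E_oracle + g[r] * sqrt(sum(d^2))
  }
  for (ci in seq_along(v$cells)) {
    E_oracle <- E_oracle + p$K / 2 * (cell_area(v, ci) - v$A0[ci])^2
  }
  expect_equal(tissue_energy(v, g, p), E_oracle, tolerance = 1e-12)
  # zero tension at preferred areas -> zero energy
  expect_equal(tissue_energy(v, rep(0, nrow(v$edges)), p), 0)
  # perimeter-only check: honeycomb at its preferred area, unit tension
  h <- build_honeycomb(2, 2, side = 1)
  expect_equal(tissue_energy(h, rep(1, nrow(h$edges)), p),
               sum(edge_lengths(h)))
})

test_that("forces equal -dE/dx (central finite differences) and sum to zero", {
  p <- model_params()
  for (seed in c(3, 8)) {
    v <- build_voronoi(15, seed = seed)
    set.seed(seed)
    g <- stats::runif(nrow(v$edges), 0.5, 1.5)
    v$pos <- wrap_point(v$pos + matrix(stats::rnorm(length(v$pos), 0, 0.02),
                                       ncol = 2), v$box)
    F <- vertex_forces(v, g, p)
    expect_equal(colSums(F), c(0, 0), tolerance = 1e-10)
    h <- 1e-6
    for (vi in sample(nrow(v$pos), 6)) {
      for (dim in 1:2) {
        vp <- v; vp$pos[vi, dim] <- vp$pos[vi, dim] + h
        vm <- v; vm$pos[vi, dim] <- vm$pos[vi, dim] - h
        fd <- -(tissue_energy(vp, g, p) - tissue_energy(vm, g, p)) / (2 * h)
        expect_equal(F[vi, dim], fd,
                     tolerance = 1e-6 * max(1, abs(fd)))
      }
    }
  }
})

test_that("a uniform honeycomb is force-free by symmetry", {
  p <- model_params()
  h <- build_honeycomb(4, 4)
  F <- vertex_forces(h, rep(1, nrow(h$edges)), p)
  expect_lt(max(abs(F)), 1e-10)
})

test_that("extrinsic cell tension draws follow the truncated normal", {
  p <- model_params(sigma_e = 1.07, sigma_i = 1.07 * 0.08 / 0.13)
  set.seed(42)
  x <- draw_cell_tensions(p, 1e5)
  expect_true(all(x >= 0))
  # closed-form truncated-normal moments (truncation at 0)
  mu <- p$gamma_mean; s <- p$sigma_e
  alpha <- -mu / s
  lam <- stats::dnorm(alpha) / (1 - stats::pnorm(alpha))
  m_th <- mu + s * lam
  v_th <- s^2 * (1 + alpha * lam - lam^2)
  expect_equal(mean(x), m_th, tolerance = 4 / sqrt(1e5) * s / m_th)
  expect_equal(stats::sd(x), sqrt(v_th), tolerance = 0.02)
  # degenerate spread
  p0 <- model_params(sigma_e = 0)
  expect_equal(draw_cell_tensions(p0, 10), rep(1, 10))
})

test_that("reference tensions average the two flanking cells", {
  h <- build_honeycomb(2, 2)
  cg <- rep(1, 4)
  expect_equal(reference_tensions(h, cg), rep(1, nrow(h$edges)))
  cg2 <- c(0.8, 1.2, 1.0, 1.0)
  g0 <- reference_tensions(h, cg2)
  r <- which(h$edges[, 3] %in% 1:2 & h$edges[, 4] %in% 1:2)
  expect_true(all(abs(g0[r] - 1.0) < 1e-12))
})

test_that("OU tension updates have the exact relaxation and stationary law", {
  # deterministic relaxation: gamma(tau_m) = gamma0 + (gamma-gamma0)/e
  p <- model_params(dt = 0.001, sigma_i = 0)
  g <- 2
  for (k in seq_len(round(p$tau_m / p$dt))) g <- ou_update(g, 1, p)$gamma
  expect_equal(g, 1 + exp(-1), tolerance = 1e-3)
  # stationary moments and autocorrelation on a long run
  p2 <- model_params(dt = 0.02)
  set.seed(7)
  n <- 2e4
  g <- numeric(n); g[1] <- 1
  for (k in 2:n) g[k] <- ou_update(g[k - 1], 1, p2)$gamma
  g <- g[-(1:2000)]
  expect_equal(mean(g), 1, tolerance = 3 * p2$sigma_i / sqrt(length(g) / 110))
  expect_equal(stats::sd(g), p2$sigma_i, tolerance = 0.08)
  lag <- round(p2$tau_m / p2$dt)   # one persistence time
  ac <- stats::cor(g[-(1:lag)], g[seq_len(length(g) - lag)])
  expect_equal(ac, exp(-1), tolerance = 0.1)
})

test_that("stepping is deterministic, conservative at rest, dissipative without noise", {
  p <- model_params()
  h <- build_honeycomb(4, 4)
  st <- sim_state(h, p, list(cell_gamma = rep(1, 16),
                             gamma0 = rep(1, nrow(h$edges)),
                             gamma = rep(1, nrow(h$edges))))
  st1 <- sim_step(st, p, noise = FALSE)
  expect_equal(st1$tissue$pos, h$pos, tolerance = 1e-12)
  # noise off from a perturbed start: energy nonincreasing
  set.seed(5)
  pert <- h
  pert$pos <- wrap_point(h$pos + matrix(stats::rnorm(length(h$pos), 0, 0.05),
                                        ncol = 2), h$box)
  st <- sim_state(pert, p, list(cell_gamma = rep(1, 16),
                                gamma0 = rep(1, nrow(h$edges)),
                                gamma = rep(1, nrow(h$edges))))
  E <- tissue_energy(st$tissue, st$gamma, p)
  for (k in 1:50) {
    st <- sim_step(st, p, noise = FALSE)
    E2 <- tissue_energy(st$tissue, st$gamma, p)
    expect_lte(E2, E + 1e-12)
    E <- E2
  }
  # identical seeds give identical trajectories and event logs
  cfg <- list(init = "voronoi", n_cells = 25, duration = 3, burn_in = 2,
              seed = 9)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$frames[[length(s1$frames)]]$length,
                   s2$frames[[length(s2$frames)]]$length)
})

test_that("short edges trigger T1s with reset tension and reversal linkage", {
  p <- model_params()
  h <- build_honeycomb(4, 4)
  tension <- init_tension(h, p)
  st <- sim_state(h, p, tension)
  st$time <- 1
  # no edge below threshold: nothing happens
  st0 <- handle_short_edges(st, p)
  expect_equal(length(st0$events), 0)
  # manually contract one edge below threshold
  row <- 5L
  v1 <- st$tissue$edges[row, 1]; v2 <- st$tissue$edges[row, 2]
  mid <- st$tissue$pos[v1, ] +
    wrap_delta(st$tissue$pos[v2, ] - st$tissue$pos[v1, ], st$tissue$box) / 2
  dirv <- wrap_delta(st$tissue$pos[v2, ] - st$tissue$pos[v1, ], st$tissue$box)
  dirv <- dirv / sqrt(sum(dirv^2))
  st$tissue$pos[v1, ] <- wrap_point(mid - dirv * p$l_T1 / 4, st$tissue$box)
  st$tissue$pos[v2, ] <- wrap_point(mid + dirv * p$l_T1 / 4, st$tissue$box)
  st1 <- handle_short_edges(st, p)
  expect_equal(length(st1$events), 1)
  ev <- st1$events[[1]]
  new_row <- match(ev$edge_new, st1$tissue$eid)
  expect_equal(edge_lengths(st1$tissue)[new_row], p$l_new, tolerance = 1e-12)
  # tension reset to the new flanking cells' mean
  expect_equal(st1$gamma[new_row],
               mean(st1$cell_gamma[c(ev$gaining1, ev$gaining2)]))
  expect_true(is.na(ev$reversal_of))
  # contract the new edge: the second flip is linked as a reversal
  st1$time <- 2
  v1 <- st1$tissue$edges[new_row, 1]; v2 <- st1$tissue$edges[new_row, 2]
  mid <- st1$tissue$pos[v1, ] +
    wrap_delta(st1$tissue$pos[v2, ] - st1$tissue$pos[v1, ], st1$tissue$box) / 2
  dirv <- wrap_delta(st1$tissue$pos[v2, ] - st1$tissue$pos[v1, ], st1$tissue$box)
  dirv <- dirv / sqrt(sum(dirv^2))
  st1$tissue$pos[v1, ] <- wrap_point(mid - dirv * p$l_T1 / 4, st1$tissue$box)
  st1$tissue$pos[v2, ] <- wrap_point(mid + dirv * p$l_T1 / 4, st1$tissue$box)
  st2 <- handle_short_edges(st1, p)
  expect_equal(length(st2$events), 2)
  expect_equal(st2$events[[2]]$reversal_of, 1L)
})

test_that("relaxation converges, is idempotent, and start-dependent", {
  p <- model_params()
  h <- build_honeycomb(4, 4)
  r1 <- relax_tissue(h, p, tol = 1e-3)
  expect_equal(r1$steps, 0L)   # uniform honeycomb is already an equilibrium
  v <- build_voronoi(36, seed = 4)
  r2 <- relax_tissue(v, p, tol = 1e-3)
  expect_lt(r2$residual, 1e-3)
  r3 <- relax_tissue(r2$tissue, p, tol = 1e-3)
  expect_equal(r3$steps, 0L)
  expect_equal(r3$tissue$pos, r2$tissue$pos)
  # honeycomb and Voronoi relax to distinct packings
  h36 <- build_honeycomb(6, 6)
  expect_gt(topological_disorder(r2$tissue), topological_disorder(h36))
})

test_that("run_simulation handles the degenerate zero-duration case", {
  sim <- run_simulation(list(init = "honeycomb", n_cells = 16, duration = 0,
                             burn_in = 0, seed = 1))
  expect_equal(length(sim$frames), 1)
  expect_equal(nrow(sim$events), 0)
  expect_error(run_simulation(list(bogus = 1)), "unknown config key")
})
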