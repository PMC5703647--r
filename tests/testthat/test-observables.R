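# sim_observables: rates, order metrics, CVs, correlation machinery, fits

test_that("t1_rate is events / (junctions at t0 x minutes)", {
  expect_equal(t1_rate(0, 200, 90), 0)
  expect_equal(t1_rate(10, 200, 90), 10 / (200 * 90))
  expect_equal(t1_rate(data.frame(time_min = c(1, 2, 3)), 100, 10), 3e-3)
  expect_error(t1_rate(1, 100, 0), "duration")
})

test_that("topological disorder is the population SD of side counts", {
  expect_equal(topological_disorder(build_honeycomb(4, 4)), 0)
  expect_equal(topological_disorder(c(5L, 6L, 7L)), sqrt(2 / 3))
  # brute-force recount on a flipped tissue
  t <- build_honeycomb(4, 4)
  t <- t1_flip(t, t$eid[3], 0.2)$tissue
  sides <- vapply(t$cells, length, integer(1))
  expect_equal(topological_disorder(t),
               sqrt(mean((sides - mean(sides))^2)))
})

test_that("polygon fractions sum to one and match tallies", {
  expect_equal(polygon_fractions(build_honeycomb(4, 4)), c("6" = 1))
  f <- polygon_fractions(c(5L, 6L, 6L, 7L))
  expect_equal(unname(f), c(0.25, 0.5, 0.25))
  expect_equal(names(f), c("5", "6", "7"))
  expect_equal(sum(polygon_fractions(build_voronoi(50, seed = 2))), 1)
})

test_that("length and snapshot CVs use the population convention", {
  expect_equal(length_cv(c(2, 2, 2)), 0)
  expect_equal(length_cv(c(1, 2, 3)), sqrt(2 / 3) / 2)
  expect_equal(snapshot_tension_cv(rep(1.3, 10)), 0)
  x <- c(1, 2, 3, 4)
  expect_equal(snapshot_tension_cv(x),
               sqrt(mean((x - mean(x))^2)) / mean(x))
})

test_that("autocorrelation matches white-noise and OU closed forms", {
  set.seed(11)
  # white noise with CV c: value ~ c^2 at lag 0, ~ 0 beyond
  cv <- 0.2
  X <- matrix(1 + stats::rnorm(200 * 400, 0, cv), nrow = 200)
  ac <- junction_autocorr(X, dt = 0.5, max_lag = 3)
  expect_equal(ac$value[1], cv^2, tolerance = 0.05)
  expect_lt(max(abs(ac$value[-1])), cv^2 * 0.05)
  # lag-0 equals the mean squared temporal CoV exactly (identity)
  x <- abs(stats::rnorm(100, 1, 0.1))
  ac1 <- junction_autocorr(x, dt = 0.5, max_lag = 2)
  expect_equal(ac1$value[1],
               mean((x - mean(x))^2) / mean(x)^2, tolerance = 1e-12)
  # constant series: zero curve, counted, not NaN
  acc <- junction_autocorr(rep(2, 50), dt = 0.5, max_lag = 2)
  expect_true(all(acc$value == 0))
  expect_equal(attr(acc, "n_constant"), 1)
})

test_that("exponential fits recover exact and noisy decays", {
  lag <- seq(0, 10, by = 0.5)
  curve <- data.frame(lag_min = lag, value = 0.0064 * exp(-0.451 * lag))
  f <- fit_exp_decay(curve)
  expect_equal(f$a, 0.0064, tolerance = 1e-6)
  expect_equal(f$rate, 0.451, tolerance = 1e-6)
  expect_equal(f$decorrelation_time, 1 / 0.451, tolerance = 1e-6)
  expect_error(fit_exp_decay(data.frame(lag_min = 0:5,
                                        value = -(1:6))), "non-positive")
})

test_that("cross-correlation resolves constructed lead-lag structure", {
  set.seed(3)
  nt <- 400; dt <- 0.5
  shift <- 2L  # 1 min at 30 s sampling
  curves <- replicate(30, {
    x <- stats::rnorm(nt + shift)
    list(a = x[(1 + shift):(nt + shift)], b = -x[1:nt])  # b(t) = -a(t - 1 min)
  }, simplify = FALSE)
  A <- do.call(rbind, lapply(curves, `[[`, "a"))
  B <- do.call(rbind, lapply(curves, `[[`, "b"))
  cc <- junction_crosscorr(A, B, dt = dt, max_lag = 5)
  expect_equal(attr(cc, "lag_min_at_min"), shift * dt)
  expect_equal(min(cc$value), -1, tolerance = 0.02)
  # independent noise: flat near zero
  C <- matrix(stats::rnorm(30 * nt), 30)
  cc0 <- junction_crosscorr(A, C, dt = dt, max_lag = 5)
  expect_lt(max(abs(cc0$value)), 0.05)
  # zero-variance junctions are excluded and counted
  A2 <- rbind(A, 1); B2 <- rbind(B, stats::rnorm(nt))
  cc2 <- junction_crosscorr(A2, B2, dt = dt, max_lag = 5)
  expect_equal(attr(cc2, "n_excluded"), 1)
})

test_that("cumulative curve fits and windowed rates behave as closed forms", {
  # exact saturating exponential: a and b recovered
  tt <- seq(0.5, 60, by = 0.5)
  cum <- 2 * (1 - exp(-0.05 * tt))
  f <- fit_saturating(data.frame(time_min = tt, cum_per_junction = cum))
  expect_equal(f$a, 2, tolerance = 1e-6)
  expect_equal(f$b, 0.05, tolerance = 1e-6)
  # derivative at origin of the fitted curve is a*b
  expect_equal(f$a * f$b, 0.1, tolerance = 1e-6)
  # linear cumulative counts give a flat windowed rate r
  ev <- data.frame(time_min = seq(0.1, 50, by = 0.1))
  cc <- cumulative_t1_curve(ev, n_junctions_t0 = 100)
  expect_equal(cc$cum_per_junction[nrow(cc)], nrow(ev) / 100)
  wr <- windowed_rate(cc, window = 5, times = seq(10, 40, by = 5))
  expect_equal(wr$rate, rep(0.1, nrow(wr)), tolerance = 0.05)
})

test_that("aligned T1 profiles detect constructed length conservation", {
  # scripted event: focal loses exactly what the four neighbours gain
  dt <- 0.5
  tt <- seq(0, 20, by = dt)
  ev_t <- 10
  focal_old <- pmax(2 - 0.2 * tt, 0)
  focal_new <- pmax(0.2 * (tt - ev_t), 0)
  nb <- 3 - 0.05 * abs(tt - ev_t)  # each neighbour gains focal loss / 4
  mk <- function(id, len) data.frame(junction_id = id, time_min = tt,
                                     length = len)
  tracks <- rbind(mk(1, ifelse(tt <= ev_t, focal_old, NA)),
                  mk(2, ifelse(tt >= ev_t, focal_new, NA)),
                  mk(3, nb), mk(4, nb), mk(5, nb), mk(6, nb))
  tracks <- tracks[!is.na(tracks$length), ]
  events <- data.frame(time_min = ev_t, edge_old = 1, edge_new = 2,
                       n1 = 3, n2 = 4, n3 = 5, n4 = 6)
  pr <- aligned_t1_profiles(tracks, events, half_window = 5, dt = dt)
  expect_equal(pr$n_excluded, 0)
  # focal loss 0.2/min is offset by 4 x 0.05/min neighbour gain
  expect_equal(diff(range(pr$profile$total_mean)), 0, tolerance = 1e-9)
  expect_gt(diff(range(pr$profile$focal_mean)), 0.9)
  # window exceeding the tracks: event excluded
  pr2 <- aligned_t1_profiles(tracks, events, half_window = 15, dt = dt)
  expect_null(pr2$profile)
  expect_equal(pr2$n_excluded, 1)
})
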