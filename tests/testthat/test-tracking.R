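# tracking, T1 detection on tracks, persistence, intensity, survival

test_that("tracking assignment equals the brute-force optimum (<= 6 points)", {
  expect_equal(assign_points(rbind(c(0, 0), c(10, 0)),
                             rbind(c(0.5, 0), c(10.5, 0)), cutoff = 5),
               c(1L, 2L))
  set.seed(14)
  for (trial in 1:25) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    A <- matrix(stats::runif(2 * n, 0, 20), n)
    B <- matrix(stats::runif(2 * m, 0, 20), m)
    co <- stats::runif(1, 2, 12)
    got <- assign_points(A, B, co)
    want <- brute_assign(A, B, co)
    expect_equal(assignment_cost(A, B, got, co), want$cost, tolerance = 1e-9)
  }
})

test_that("junctions reappearing beyond the cutoff start new tracks", {
  mids <- list(rbind(c(5, 5)), rbind(c(30, 30)), rbind(c(30, 30)))
  ids <- vertexflux:::link_tracks(mids, cutoff = 10)
  expect_equal(ids[[1]], 1L)
  expect_equal(ids[[2]], 2L)   # too far: a fresh id
  expect_equal(ids[[3]], 2L)
})

test_that("persistence segments implement the hysteresis filter", {
  # strictly decreasing series: one contraction spanning it
  s <- persistence_segments(10:1)
  expect_equal(nrow(s), 1)
  expect_equal(s$sign, "contraction")
  expect_equal(s$dlength, -9)
  # worked example, filter 0
  s2 <- persistence_segments(c(5, 4, 3, 2, 3, 4), filter_amplitude = 0)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$dlength, c(-3, 2))
  expect_equal(s2$duration_min, c(3, 2))
  expect_equal(s2$velocity, c(1, 1))
  # a small wiggle below the filter amplitude is suppressed
  s3 <- persistence_segments(c(5, 4, 3, 3.05, 2, 3, 4), filter_amplitude = 0.1)
  expect_equal(s3$dlength, c(-3, 2))
  # velocity = |dlength| / duration with explicit times
  s4 <- persistence_segments(c(4, 2), times = c(0, 4))
  expect_equal(nrow(s4), 0)   # < 3 samples: no segments
  s5 <- persistence_segments(c(6, 4, 2), times = c(0, 2, 4))
  expect_equal(ballistic_velocity(s5), 1)
})

test_that("intensity measurement is normalization-invariant and unbiased", {
  img <- matrix(0L, 40, 40)
  img[20, 5:35] <- 255L
  img[5:35, 20] <- 255L
  pr <- parse_skeleton(img)
  flat <- matrix(7, 40, 40)
  v <- measure_intensity(pr, flat)
  expect_equal(v[!is.na(v)], rep(1, sum(!is.na(v))), tolerance = 1e-12)
  # doubling every pixel leaves normalized intensities unchanged
  set.seed(4)
  noisy <- matrix(stats::runif(1600, 1, 3), 40, 40)
  v1 <- measure_intensity(pr, noisy)
  v2 <- measure_intensity(pr, 2 * noisy)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("scripted event tables classify directionality and reverse pairs", {
  ev <- data.frame(frame = c(1, 10, 30), time_min = c(0.5, 5, 15),
                   junction_old = 1:3, junction_new = 1:3,
                   losing1 = c(1, 3, 1), losing2 = c(2, 4, 2),
                   gaining1 = c(3, 1, 3), gaining2 = c(4, 2, 4),
                   q1 = 1, q2 = 2, q3 = 3, q4 = 4, event_id = 1:3)
  cl <- classify_directionality(ev)
  expect_equal(cl$direction, c("uni", "multi", "multi"))
  expect_equal(cl$reversal_of, c(NA_integer_, 1L, 2L))
  expect_equal(attr(cl, "fraction_multi"), 2 / 3)
  # window cuts old reversals
  cl2 <- classify_directionality(ev, window = 6)
  expect_equal(cl2$direction, c("uni", "multi", "uni"))
  # single event: uni
  cl3 <- classify_directionality(ev[1, ])
  expect_equal(cl3$direction, "uni")
})

test_that("Kaplan-Meier reversal survival matches the hand calculation", {
  # 3 quartets: one reversal at 30 min, two censored (observation 60, 90)
  ev <- data.frame(frame = 1, time_min = c(0, 30, 0, 0),
                   junction_old = 1:4, junction_new = 1:4,
                   losing1 = c(1, 3, 11, 21), losing2 = c(2, 4, 12, 22),
                   gaining1 = c(3, 1, 13, 23), gaining2 = c(4, 2, 14, 24),
                   q1 = c(1, 1, 11, 21), q2 = c(2, 2, 12, 22),
                   q3 = c(3, 3, 13, 23), q4 = c(4, 4, 14, 24),
                   event_id = 1:4)
  # censor quartet 2 at 60, quartet 3 at 90: emulate by observation_end
  rs <- reversal_survival(ev, observation_end = 60)
  expect_equal(rs$n_reversed, 1)
  expect_equal(rs$n_censored, 2)
  s30 <- rs$table$surv[rs$table$time == 30]
  expect_equal(s30, 2 / 3)
  # no reversals: survival stays 1
  rs2 <- reversal_survival(ev[c(1, 3, 4), ], observation_end = 60)
  expect_true(all(rs2$table$surv == 1))
  expect_null(reversal_survival(ev[0, ], 60))
})

test_that("quartet aspect ratios follow symmetry and affine stretching", {
  sq <- function(cx, cy) rbind(c(cx - 0.5, cy - 0.5), c(cx + 0.5, cy - 0.5),
                               c(cx + 0.5, cy + 0.5), c(cx - 0.5, cy + 0.5))
  # CoA of a square is its centroid
  expect_equal(vertexflux:::poly_centroid(sq(0.5, 0.5)), c(0.5, 0.5))
  # four congruent cells in square symmetry: losing axis x, gaining axis y
  polys <- list(L = sq(-1, 0), R = sq(1, 0), T = sq(0, 1), B = sq(0, -1))
  r <- quartet_aspect_ratios(polys, losing = c("L", "R"), gaining = c("T", "B"))
  expect_equal(r$internal, 1, tolerance = 1e-9)
  expect_equal(r$external, 1, tolerance = 1e-9)
  # stretching the cluster 2x along the losing axis doubles the internal
  # ratio (affine construction)
  polys2 <- lapply(polys, function(P) { P[, 1] <- 2 * P[, 1]; P })
  r2 <- quartet_aspect_ratios(polys2, losing = c("L", "R"),
                              gaining = c("T", "B"))
  expect_equal(r2$internal, 2, tolerance = 1e-9)
})
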