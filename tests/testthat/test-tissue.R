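# tissue_core: constructors, geometry, topology, T1 flip

test_that("honeycomb lattice has the exact toroidal counts and geometry", {
  t <- build_honeycomb(4, 4, side = 1)
  expect_equal(length(t$cells), 16)
  expect_equal(nrow(t$pos), 32)
  expect_equal(nrow(t$edges), 48)
  expect_equal(nrow(t$pos) - nrow(t$edges) + length(t$cells), 0)
  expect_equal(unname(cell_areas(t)), rep(3 * sqrt(3) / 2, 16),
               tolerance = 1e-12)
  expect_equal(edge_lengths(t), rep(1, 48), tolerance = 1e-12)
  expect_equal(topological_disorder(t), 0)
  expect_equal(nrow(validate_topology(t)), 0)
  expect_error(build_honeycomb(1, 4), "nx >= 2")
  expect_error(build_honeycomb(4, 3), "even ny")
})

test_that("edge lengths follow the minimum-image convention", {
  fake <- list(pos = rbind(c(0, 0), c(3, 4), c(1, 0), c(99, 0)),
               edges = rbind(c(1L, 2L, 1L, 2L), c(3L, 4L, 1L, 2L),
                             c(1L, 1L, 1L, 2L)),
               eid = 1:3, box = c(100, 100))
  fake$edges[3, ] <- c(1L, 3L, 1L, 2L)
  class(fake) <- "vm_tissue"
  expect_equal(edge_length(fake, 1), 5)        # plain Euclid
  expect_equal(edge_length(fake, 2), 2)        # wraps across the seam
  fake$pos[3, ] <- fake$pos[1, ]
  expect_equal(edge_length(fake, 3), 0)        # coincident endpoints
  expect_error(edge_length(fake, 99), "unknown edge id")
})

test_that("areas are invariant under periodic translation (seam straddling)", {
  t <- build_honeycomb(4, 4, side = 1)
  a0 <- cell_areas(t)
  t2 <- t
  t2$pos <- wrap_point(sweep(t$pos, 2, t$box / 2, `+`), t$box)
  expect_equal(cell_areas(t2), a0, tolerance = 1e-9)
})

test_that("periodic Voronoi tessellations are valid, deterministic meshes", {
  v <- build_voronoi(100, seed = 7)
  expect_equal(nrow(validate_topology(v)), 0)
  expect_equal(sum(cell_areas(v)), prod(v$box), tolerance = 1e-9)
  v2 <- build_voronoi(100, seed = 7)
  expect_identical(v$pos, v2$pos)
  expect_identical(v$cells, v2$cells)
  for (s in c(1, 11, 42)) {
    expect_equal(nrow(validate_topology(build_voronoi(60, seed = s))), 0)
  }
  expect_error(build_voronoi(3), "n_cells >= 4")
})

test_that("degenerate four-fold Voronoi vertices split into degree-3 pairs", {
  pts <- as.matrix(expand.grid(c(0.5, 1.5), c(0.5, 1.5)))
  sq <- build_voronoi(4, box = c(2, 2), points = pts)
  deg <- tabulate(c(sq$edges[, 1], sq$edges[, 2]), nbins = nrow(sq$pos))
  expect_true(all(deg == 3L))
  expect_equal(nrow(sq$pos) - nrow(sq$edges) + length(sq$cells), 0)
  # one short edge per resolved four-fold vertex, length ~ 1e-3
  short <- edge_lengths(sq) < 2e-3
  expect_equal(sum(short), 4)
  expect_true(all(edge_lengths(sq)[short] > 0))
  expect_error(build_voronoi(4, box = c(2, 2), points = pts[c(1, 1, 2, 3), ]),
               "duplicate")
})

test_that("validate_topology reports violations for a broken mesh", {
  t <- build_honeycomb(4, 4)
  t$edges <- t$edges[-1, , drop = FALSE]
  t$eid <- t$eid[-1]
  rep <- validate_topology(t)
  expect_gt(nrow(rep), 0)
  expect_true(any(rep$check %in% c("euler", "degree", "incidence")))
})

test_that("t1_flip exchanges neighbours with conserved counts", {
  t <- build_honeycomb(4, 4, side = 1)
  res <- t1_flip(t, t$eid[1], new_length = 0.3)
  t2 <- res$tissue
  expect_equal(nrow(validate_topology(t2)), 0)
  expect_null(res$refused)
  # (6,6,6,6) -> (5,7,5,7): sharing cells lose, end cells gain
  sides <- lengths(t2$cells)
  expect_equal(as.vector(table(sides)), c(2, 12, 2))
  rec <- res$record
  expect_equal(sides[c(rec$losing1, rec$losing2)], c(5L, 5L))
  expect_equal(sides[c(rec$gaining1, rec$gaining2)], c(7L, 7L))
  # conservation
  expect_equal(nrow(t2$pos), nrow(t$pos))
  expect_equal(nrow(t2$edges), nrow(t$edges))
  expect_equal(length(t2$cells), length(t$cells))
  expect_equal(sum(lengths(t2$cells)), 2L * nrow(t2$edges))
  expect_equal(edge_lengths(t2, rec$edge_new), 0.3, tolerance = 1e-12)
  # involution at topology level: flipping the new edge restores all-6
  res2 <- t1_flip(t2, rec$edge_new, new_length = 1)
  expect_equal(nrow(validate_topology(res2$tissue)), 0)
  expect_true(all(lengths(res2$tissue$cells) == 6L))
  expect_setequal(
    unname(unlist(res2$record[c("gaining1", "gaining2")])),
    unname(unlist(rec[c("losing1", "losing2")])))
})

test_that("t1_flip refuses edges adjacent to a triangle", {
  t <- build_honeycomb(4, 4, side = 1)
  # shrink one chosen cell by flipping its edges until it is a triangle
  target <- 6L
  for (k in 1:3) {
    rows <- which(t$edges[, 3] == target | t$edges[, 4] == target)
    done <- FALSE
    for (r in rows) {
      res <- t1_flip(t, t$eid[r], 0.2)
      if (!is.null(res$record)) { t <- res$tissue; done <- TRUE; break }
    }
    expect_true(done)
  }
  expect_equal(length(t$cells[[target]]), 3L)
  rows <- which(t$edges[, 3] == target | t$edges[, 4] == target)
  res <- t1_flip(t, t$eid[rows[1]], 0.2)
  expect_null(res$record)
  expect_match(res$refused, "triangle")
})

test_that("tissue tables round-trip through the text serialization", {
  v <- build_voronoi(30, seed = 5)
  tf <- tempfile()
  write_tissue(v, tf, tension = seq_len(nrow(v$edges)) / 10)
  v2 <- read_tissue(tf, v$box)
  expect_equal(v2$pos, v$pos)
  expect_identical(v2$cells, v$cells)
  expect_equal(v2$edges, v$edges, ignore_attr = TRUE)
  expect_equal(v2$A0, v$A0)
  expect_equal(attr(v2, "tension"), seq_len(nrow(v$edges)) / 10)
})
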