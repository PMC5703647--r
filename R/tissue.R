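# Polygonal tissue mesh on a periodic (toroidal) box.
#
# A tissue is a list with:
#   pos   : nv x 2 matrix of vertex positions (row index = vertex id)
#   edges : ne x 4 integer matrix, columns v1, v2, cell_left, cell_right;
#           cell_left is the cell whose counterclockwise cycle traverses
#           v1 -> v2, cell_right traverses v2 -> v1
#   eid   : ne integer vector of persistent junction ids
#   cells : list of integer vertex cycles, counterclockwise
#   A0    : per-cell preferred areas
#   box   : c(width, height); all edges are interior (no tissue border)

#' Minimum-image displacement on a periodic box
#'
#' @param d matrix (n x 2) or length-2 vector of raw displacements.
#' @param box c(width, height).
#' @return Displacements wrapped into (-box/2, box/2].
#' @keywords internal
wrap_delta <- function(d, box) {
  if (is.null(dim(d))) {
    d - box * round(d / box)
  } else {
    d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
    d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
    d
  }
}

#' @keywords internal
wrap_point <- function(p, box) {
  if (is.null(dim(p))) {
    ((p %% box) + box) %% box
  } else {
    p[, 1] <- ((p[, 1] %% box[1]) + box[1]) %% box[1]
    p[, 2] <- ((p[, 2] %% box[2]) + box[2]) %% box[2]
    p
  }
}

# Cluster points on a periodic box: points closer than tol (minimum image)
# receive the same id.  Grid hash; neighbours looked up in the 3x3 block of
# grid cells around each point, with periodic wrap of the grid.
cluster_points <- function(pts, box, tol = 1e-6) {
  n <- nrow(pts)
  pts <- wrap_point(pts, box)
  h <- max(tol * 4, 1e-12)
  ngx <- max(1L, as.integer(floor(box[1] / h)))
  ngy <- max(1L, as.integer(floor(box[2] / h)))
  gx <- pmin(as.integer(floor(pts[, 1] / box[1] * ngx)), ngx - 1L)
  gy <- pmin(as.integer(floor(pts[, 2] / box[2] * ngy)), ngy - 1L)
  bucket <- new.env(hash = TRUE, parent = emptyenv())
  ids <- integer(n)
  nid <- 0L
  canon <- matrix(0, n, 2)  # representative position per id
  for (k in seq_len(n)) {
    found <- 0L
    for (dx in -1:1) {
      for (dy in -1:1) {
        key <- paste0((gx[k] + dx) %% ngx, ",", (gy[k] + dy) %% ngy)
        cand <- bucket[[key]]
        if (!is.null(cand)) {
          for (id in cand) {
            dd <- wrap_delta(pts[k, ] - canon[id, ], box)
            if (dd[1] * dd[1] + dd[2] * dd[2] <= tol * tol) { found <- id; break }
          }
        }
        if (found > 0L) break
      }
      if (found > 0L) break
    }
    if (found == 0L) {
      nid <- nid + 1L
      found <- nid
      canon[nid, ] <- pts[k, ]
      key <- paste0(gx[k], ",", gy[k])
      bucket[[key]] <- c(bucket[[key]], nid)
    }
    ids[k] <- found
  }
  list(ids = ids, pos = canon[seq_len(nid), , drop = FALSE])
}

# Signed area of a cycle of vertex ids, unwrapped by minimum-image steps.
cycle_signed_area <- function(cycle, pos, box) {
  k <- length(cycle)
  p <- pos[cycle, , drop = FALSE]
  d <- wrap_delta(p[c(2:k, 1), , drop = FALSE] - p, box)
  sx <- cumsum(c(0, d[-k, 1]))
  sy <- cumsum(c(0, d[-k, 2]))
  0.5 * sum(sx * d[, 2] - sy * d[, 1])
}

# Assemble a tissue from a list of cell polygons given in original
# (unwrapped) coordinates, arbitrary orientation.  Shared vertices are
# identified by tolerance clustering; cycles are re-oriented
# counterclockwise; edges are paired from the original coordinates (robust
# to parallel edges on small tori); degenerate vertices of degree >= 4 are
# split into degree-3 pairs.
mesh_from_cells <- function(polys, box, A0 = NULL, tol = 1e-6, .split = TRUE) {
  # orient every polygon counterclockwise in its own coordinates
  polys <- lapply(polys, function(P) {
    k <- nrow(P)
    a <- 0.5 * sum(P[, 1] * P[c(2:k, 1), 2] - P[c(2:k, 1), 1] * P[, 2])
    if (a < 0) P[k:1, , drop = FALSE] else P
  })
  if (.split) {
    polys <- split_degenerate_corners(polys, box, tol)
    return(mesh_from_cells(polys, box, A0 = A0, tol = tol, .split = FALSE))
  }
  allpts <- do.call(rbind, polys)
  cl <- cluster_points(allpts, box, tol)
  pos <- cl$pos
  lens <- vapply(polys, nrow, integer(1))
  idx <- split(cl$ids, rep(seq_along(polys), lens))
  cells <- vector("list", length(polys))
  from <- to <- cid <- integer(0)
  midl <- vector("list", length(polys))
  for (i in seq_along(polys)) {
    v <- idx[[i]]
    keep <- c(TRUE, v[-1] != v[-length(v)])
    if (sum(keep) > 1 && v[keep][1] == v[keep][sum(keep)]) {
      keep[max(which(keep))] <- FALSE
    }
    w <- v[keep]
    if (length(w) < 3L) stop("degenerate cell polygon (fewer than 3 distinct vertices)")
    P <- polys[[i]][keep, , drop = FALSE]
    k <- length(w)
    cells[[i]] <- w
    from <- c(from, w)
    to <- c(to, w[c(2:k, 1)])
    cid <- c(cid, rep(i, k))
    midl[[i]] <- wrap_point((P + P[c(2:k, 1), , drop = FALSE]) / 2, box)
  }
  mids <- do.call(rbind, midl)
  tis <- list(pos = pos, cells = cells, box = box)
  tis$A0 <- if (is.null(A0)) vapply(polys, function(P) {
    k <- nrow(P)
    0.5 * sum(P[, 1] * P[c(2:k, 1), 2] - P[c(2:k, 1), 1] * P[, 2])
  }, numeric(1)) else A0
  tis <- assemble_edges(tis, from, to, cid, mids, keep = NULL)
  deg <- tabulate(c(tis$edges[, 1], tis$edges[, 2]), nbins = nrow(tis$pos))
  if (any(deg > 3L)) stop("unresolved vertex of degree > 3 after assembly")
  class(tis) <- "vm_tissue"
  tis
}

# Pair directed edge occurrences (from, to, owning cell, segment midpoint)
# into an edge table.  Forward (v1 < v2) and reverse traversals are matched
# by midpoint proximity so parallel edges on small tori stay distinct.
assemble_edges <- function(tis, from, to, cid, mids, keep = NULL) {
  a <- pmin(from, to); b <- pmax(from, to)
  fwd <- from < to  # directed v1 -> v2 belongs to the left cell's cycle
  # group occurrences by (a, b) with locale-independent numeric ordering
  # (string keys would make the edge-table row order -- and with it the
  # per-edge RNG stream -- depend on the collation locale)
  ord <- order(a, b)
  key_num <- a * (max(b) + 1) + b
  runs <- rle(key_num[ord])
  ends <- cumsum(runs$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  groups <- lapply(seq_along(starts), function(g) ord[starts[g]:ends[g]])
  rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    occ <- groups[[g]]
    f <- occ[fwd[occ]]; r <- occ[!fwd[occ]]
    if (length(f) != length(r)) {
      stop("mesh has edges with fewer than two incident cells")
    }
    if (length(f) == 1L) {
      rows[[g]] <- c(a[f], b[f], cid[f], cid[r])
    } else {
      used <- logical(length(r))
      out <- matrix(0, length(f), 4)
      for (i in seq_along(f)) {
        dd <- wrap_delta(mids[r, , drop = FALSE] -
                           matrix(mids[f[i], ], length(r), 2, byrow = TRUE),
                         tis$box)
        d2 <- dd[, 1]^2 + dd[, 2]^2
        d2[used] <- Inf
        j <- which.min(d2)
        used[j] <- TRUE
        out[i, ] <- c(a[f[i]], b[f[i]], cid[f[i]], cid[r[j]])
      }
      rows[[g]] <- out
    }
  }
  tab <- do.call(rbind, rows)
  edges <- matrix(as.integer(tab), ncol = 4)
  colnames(edges) <- c("v1", "v2", "cell_left", "cell_right")
  tis$edges <- edges
  if (!is.null(keep)) {
    okey <- paste0(keep$edges[, 1], "_", keep$edges[, 2])
    m <- match(paste0(edges[, 1], "_", edges[, 2]), okey)
    eid <- keep$eid[m]
    nxt <- if (length(keep$eid)) max(keep$eid) else 0L
    miss <- which(is.na(eid))
    eid[miss] <- nxt + seq_along(miss)
    tis$eid <- as.integer(eid)
  } else {
    tis$eid <- seq_len(nrow(edges))
  }
  tis
}

# Derive the edge table from the cell cycles (used after a flip).  Segment
# midpoints come from each cycle's minimum-image unwrap; fine whenever no
# edge spans half the box.  Keeps existing junction ids for surviving
# vertex pairs when `keep` (the pre-flip tissue) is supplied.
rebuild_edges <- function(tis, keep = NULL) {
  cyc <- tis$cells
  from <- unlist(cyc, use.names = FALSE)
  to <- unlist(lapply(cyc, function(v) v[c(2:length(v), 1)]), use.names = FALSE)
  cid <- rep(seq_along(cyc), lengths(cyc))
  mids <- do.call(rbind, lapply(cyc, function(v) {
    k <- length(v)
    p <- tis$pos[v, , drop = FALSE]
    d <- wrap_delta(p[c(2:k, 1), , drop = FALSE] - p, tis$box)
    px <- p[1, 1] + cumsum(c(0, d[-k, 1]))
    py <- p[1, 2] + cumsum(c(0, d[-k, 2]))
    wrap_point(cbind(px + d[, 1] / 2, py + d[, 2] / 2), tis$box)
  }))
  assemble_edges(tis, from, to, cid, mids, keep = keep)
}

# Resolve Voronoi degeneracies where four cells meet at one point.  Works
# on the cell polygons (faithful local coordinates) before mesh assembly:
# the shared corner is replaced by two points a short edge apart.  Among
# the two opposite cell pairs around the corner, the pair containing the
# smallest cell id becomes adjacent to the new edge (deterministic
# tie-break); the other two cells keep a single displaced corner each.
split_degenerate_corners <- function(polys, box, tol, sep = 1e-3) {
  allpts <- do.call(rbind, polys)
  cl <- cluster_points(allpts, box, tol)
  lens <- vapply(polys, nrow, integer(1))
  pidx <- rep(seq_along(polys), lens)
  tab <- tabulate(cl$ids)
  bad <- which(tab >= 4L)
  if (!length(bad)) return(polys)
  if (any(tab > 4L)) stop("vertex where more than four cells meet cannot be resolved")
  plan <- list()
  for (v in bad) {
    occ <- which(cl$ids == v)            # one corner occurrence per cell
    cells <- pidx[occ]
    if (anyDuplicated(cells)) stop("cell polygon touches a degenerate vertex twice")
    # interior-sector midangle of each cell at the corner
    phi <- numeric(length(occ))
    corner_at <- integer(length(occ))
    for (k in seq_along(occ)) {
      ci <- cells[k]
      P <- polys[[ci]]
      i <- occ[k] - c(0L, cumsum(lens))[ci]
      corner_at[k] <- i
      kp <- nrow(P)
      d_in <- P[if (i == 1L) kp else i - 1L, ] - P[i, ]
      d_out <- P[if (i == kp) 1L else i + 1L, ] - P[i, ]
      a_in <- atan2(d_in[2], d_in[1]); a_out <- atan2(d_out[2], d_out[1])
      span <- (a_in - a_out) %% (2 * pi)
      phi[k] <- a_out + span / 2
    }
    ord <- order(phi %% (2 * pi))
    cyc <- cells[ord]                    # cells in angular order
    pairs <- list(cyc[c(1, 3)], cyc[c(2, 4)])
    adj <- pairs[[which.min(vapply(pairs, min, numeric(1)))]]
    rest <- setdiff(cyc, adj)
    u_of <- function(ci) { a <- phi[match(ci, cells)]; c(cos(a), sin(a)) }
    off1 <- 0.5 * sep * u_of(rest[1])
    off2 <- 0.5 * sep * u_of(rest[2])
    for (k in seq_along(cells)) {
      ci <- cells[k]; i <- corner_at[k]
      key <- as.character(ci)
      repl <- if (ci == rest[1]) {
        matrix(off1, 1)
      } else if (ci == rest[2]) {
        matrix(off2, 1)
      } else {
        rbind(off1, off2)   # order resolved when applied
      }
      plan[[key]] <- c(plan[[key]], list(list(i = i, off = repl)))
    }
  }
  shoelace <- function(Q) {
    k <- nrow(Q)
    0.5 * sum(Q[, 1] * Q[c(2:k, 1), 2] - Q[c(2:k, 1), 1] * Q[, 2])
  }
  for (key in names(plan)) {
    ci <- as.integer(key)
    todo <- plan[[key]]
    ord <- order(vapply(todo, function(z) z$i, integer(1)), decreasing = TRUE)
    for (z in todo[ord]) {
      P <- polys[[ci]]
      corner <- P[z$i, ]
      reps <- sweep(z$off, 2, corner, `+`)
      ins <- function(R) {
        rbind(P[seq_len(z$i - 1L), , drop = FALSE], R,
              if (z$i < nrow(P)) P[(z$i + 1L):nrow(P), , drop = FALSE])
      }
      if (nrow(reps) == 1L) {
        polys[[ci]] <- ins(reps)
      } else {
        A <- ins(reps); Bm <- ins(reps[2:1, , drop = FALSE])
        polys[[ci]] <- if (shoelace(A) >= shoelace(Bm)) A else Bm
      }
    }
  }
  polys
}

#' Build a periodic honeycomb tissue
#'
#' Regular pointy-top hexagonal packing of \code{nx} by \code{ny} cells on a
#' periodic box.  \code{ny} must be even for the lattice to close on the
#' torus.
#'
#' @param nx,ny number of cells along x and y; both >= 2, \code{ny} even.
#' @param side hexagon side length (model units).
#' @return A \code{vm_tissue}.
#' @export
build_honeycomb <- function(nx, ny, side = sqrt(2 / (3 * sqrt(3)))) {
  if (nx < 2 || ny < 2) stop("honeycomb requires nx >= 2 and ny >= 2")
  if (ny %% 2 != 0) stop("honeycomb requires even ny for periodic closure")
  if (side <= 0) stop("hexagon side must be positive")
  w <- sqrt(3) * side
  box <- c(nx * w, ny * 1.5 * side)
  th <- pi / 6 + (0:5) * pi / 3  # counterclockwise, pointy-top
  polys <- vector("list", nx * ny)
  k <- 0L
  for (j in 0:(ny - 1)) {
    for (i in 0:(nx - 1)) {
      cx <- (i + 0.5 + 0.5 * (j %% 2)) * w
      cy <- (j + 0.5) * 1.5 * side + 0.25 * side
      k <- k + 1L
      polys[[k]] <- cbind(cx + side * cos(th), cy + side * sin(th))
    }
  }
  mesh_from_cells(polys, box, tol = side * 1e-7)
}

#' Build a tissue from a periodic Voronoi tessellation of random points
#'
#' Seed points are drawn uniformly in the box; each Voronoi cell is obtained
#' by half-plane clipping against all other generators under the
#' minimum-image convention, and the cells are stitched into a mesh.
#' Degenerate vertices where four cells meet are split into two degree-3
#' vertices separated by a short edge.
#'
#' @param n_cells number of cells (>= 4).
#' @param seed RNG seed (integer) used for the point draw.
#' @param box c(width, height); default square box of area \code{n_cells}
#'   so that mean cell area is 1.
#' @param points optional n x 2 matrix of generator points overriding the
#'   random draw (used for deterministic fixtures).
#' @return A \code{vm_tissue}.
#' @export
build_voronoi <- function(n_cells, seed = 1L, box = NULL, points = NULL) {
  if (is.null(points) && n_cells < 4) stop("voronoi requires n_cells >= 4")
  if (is.null(box)) box <- rep(sqrt(n_cells), 2)
  if (is.null(points)) {
    if (!is.null(seed)) set.seed(seed)
    points <- cbind(stats::runif(n_cells) * box[1], stats::runif(n_cells) * box[2])
  } else {
    points <- wrap_point(as.matrix(points), box)
    n_cells <- nrow(points)
  }
  # reject duplicate generators
  if (anyDuplicated(round(points / 1e-9)) > 0) {
    stop("duplicate generator points")
  }
  # displacement vectors to all periodic images of all generators (the
  # generator's own nonzero images included: they bound its cell too)
  img <- as.matrix(expand.grid(x = (-1:1) * box[1], y = (-1:1) * box[2]))
  disp <- do.call(rbind, lapply(seq_len(nrow(img)), function(k) {
    cbind(points[, 1] + img[k, 1], points[, 2] + img[k, 2])
  }))
  polys <- vector("list", n_cells)
  half <- max(box)
  base <- rbind(c(-half, -half), c(half, -half), c(half, half), c(-half, half))
  for (i in seq_len(n_cells)) {
    d <- disp - matrix(points[i, ], nrow(disp), 2, byrow = TRUE)
    d2 <- d[, 1]^2 + d[, 2]^2
    ord <- order(d2)
    poly <- base
    for (j in ord) {
      if (d2[j] < 1e-18) next  # the generator itself
      # candidates farther than twice the current max vertex radius
      # cannot clip the cell any further
      rmax2 <- max(poly[, 1]^2 + poly[, 2]^2)
      if (d2[j] > 4 * rmax2) break
      poly <- clip_halfplane(poly, d[j, ] / 2, d[j, ] / sqrt(d2[j]))
      if (nrow(poly) < 3L) stop("empty Voronoi cell (degenerate point set)")
    }
    polys[[i]] <- poly + matrix(points[i, ], nrow(poly), 2, byrow = TRUE)
  }
  mesh_from_cells(polys, box, tol = min(box) * 1e-8)
}

# Sutherland-Hodgman clip of a convex polygon (local coordinates) by the
# half-plane {x : (x - m) . n <= 0}.
clip_halfplane <- function(poly, m, n) {
  s <- (poly[, 1] - m[1]) * n[1] + (poly[, 2] - m[2]) * n[2]
  k <- nrow(poly)
  out <- matrix(0, k + 4L, 2)
  cnt <- 0L
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    if (s[i] <= 0) {
      cnt <- cnt + 1L; out[cnt, ] <- poly[i, ]
    }
    if ((s[i] <= 0) != (s[j] <= 0)) {
      t <- s[i] / (s[i] - s[j])
      cnt <- cnt + 1L
      out[cnt, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(cnt), , drop = FALSE]
}

#' Edge lengths under the minimum-image convention
#'
#' @param tissue a \code{vm_tissue}.
#' @param edge_id optional junction id(s); default all edges in table order.
#' @return Numeric vector of lengths.
#' @export
edge_lengths <- function(tissue, edge_id = NULL) {
  rows <- if (is.null(edge_id)) seq_len(nrow(tissue$edges)) else {
    r <- match(edge_id, tissue$eid)
    if (anyNA(r)) stop("unknown edge id: ", paste(edge_id[is.na(r)], collapse = ", "))
    r
  }
  d <- wrap_delta(tissue$pos[tissue$edges[rows, 2], , drop = FALSE] -
                    tissue$pos[tissue$edges[rows, 1], , drop = FALSE], tissue$box)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

#' @rdname edge_lengths
#' @export
edge_length <- function(tissue, edge_id) edge_lengths(tissue, edge_id)

# areas for all cells (internal, no id checks)
cell_areas_of <- function(tis) {
  vapply(tis$cells, cycle_signed_area, numeric(1), pos = tis$pos, box = tis$box)
}

#' Cell areas by the shoelace formula on minimum-image unwrapped cycles
#'
#' @param tissue a \code{vm_tissue}.
#' @param cell_id optional cell id(s); default all.
#' @return Numeric vector of (positive) areas.
#' @export
cell_areas <- function(tissue, cell_id = NULL) {
  ids <- if (is.null(cell_id)) seq_along(tissue$cells) else cell_id
  if (any(ids < 1L | ids > length(tissue$cells))) stop("unknown cell id")
  a <- vapply(tissue$cells[ids], cycle_signed_area, numeric(1),
              pos = tissue$pos, box = tissue$box)
  if (any(a <= 0)) stop("non-positive cell area (self-intersecting polygon?)")
  a
}

#' @rdname cell_areas
#' @export
cell_area <- function(tissue, cell_id) cell_areas(tissue, cell_id)

#' Number of sides of every cell
#' @param tissue a \code{vm_tissue}.
#' @return Integer vector.
#' @export
cell_sides <- function(tissue) lengths(tissue$cells)

#' Validate the topological and geometric invariants of a tissue
#'
#' Checks the toroidal Euler characteristic, vertex degrees, edge-cell
#' incidence, cycle simplicity and orientation, and the tiling property
#' that cell areas sum to the box area.
#'
#' @param tissue a \code{vm_tissue}.
#' @return A data.frame of violations (columns \code{check}, \code{detail});
#'   zero rows for a valid tissue.
#' @export
validate_topology <- function(tissue) {
  bad <- list()
  note <- function(check, detail) bad[[length(bad) + 1L]] <<- data.frame(
    check = check, detail = detail, stringsAsFactors = FALSE)
  nv <- nrow(tissue$pos); ne <- nrow(tissue$edges); nf <- length(tissue$cells)
  if (nv - ne + nf != 0L) {
    note("euler", sprintf("V - E + F = %d (expected 0 on the torus)", nv - ne + nf))
  }
  deg <- tabulate(c(tissue$edges[, 1], tissue$edges[, 2]), nbins = nv)
  if (any(deg != 3L)) {
    note("degree", sprintf("%d vertices with degree != 3", sum(deg != 3L)))
  }
  if (any(tissue$edges[, 1] == tissue$edges[, 2])) note("loop", "edge with v1 == v2")
  if (sum(lengths(tissue$cells)) != 2L * ne) {
    note("incidence", "sum of cell side counts != 2E")
  }
  if (anyDuplicated(tissue$eid)) note("ids", "duplicate junction ids")
  simple <- vapply(tissue$cells, function(cy) !anyDuplicated(cy), logical(1))
  if (!all(simple)) note("simple", sprintf("%d non-simple cycles", sum(!simple)))
  ar <- vapply(tissue$cells, cycle_signed_area, numeric(1),
               pos = tissue$pos, box = tissue$box)
  if (any(ar <= 0)) note("orientation", sprintf("%d non-CCW cycles", sum(ar <= 0)))
  tot <- sum(ar); boxa <- prod(tissue$box)
  if (abs(tot - boxa) > 1e-9 * boxa) {
    note("tiling", sprintf("cell areas sum to %.12g, box area %.12g", tot, boxa))
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(check = character(0), detail = character(0))
}

#' Perform a T1 neighbor-exchange flip on an edge
#'
#' The edge is removed and a new edge of length \code{new_length} is created
#' at right angles through the old midpoint.  The two cells that shared the
#' edge lose one side each; the two cells at its endpoints gain one side
#' each.  Vertex, edge and cell counts are conserved.  The new junction
#' receives a fresh persistent id.
#'
#' @param tissue a \code{vm_tissue}.
#' @param edge_id persistent id of the edge to flip.
#' @param new_length length of the newly created edge.
#' @return List with \code{tissue} (flipped) and \code{record}: a one-row
#'   data.frame with old/new edge ids, the quartet of cells, and the losing
#'   and gaining pairs; or \code{record = NULL} and \code{refused} reason if
#'   the flip would create a two-sided cell.
#' @export
t1_flip <- function(tissue, edge_id, new_length) {
  row <- match(edge_id, tissue$eid)
  if (is.na(row)) stop("unknown edge id: ", edge_id)
  e <- tissue$edges[row, ]
  a <- e[1]; b <- e[2]; L <- e[3]; R <- e[4]
  # end cells: the third cell at each endpoint
  inc_a <- which(tissue$edges[, 1] == a | tissue$edges[, 2] == a)
  inc_b <- which(tissue$edges[, 1] == b | tissue$edges[, 2] == b)
  cells_a <- unique(as.vector(tissue$edges[inc_a, 3:4]))
  cells_b <- unique(as.vector(tissue$edges[inc_b, 3:4]))
  A <- setdiff(cells_a, c(L, R))
  B <- setdiff(cells_b, c(L, R))
  if (length(A) != 1L || length(B) != 1L || A == B || L == R) {
    return(list(tissue = tissue, record = NULL,
                refused = "degenerate local configuration"))
  }
  if (length(tissue$cells[[L]]) <= 3L || length(tissue$cells[[R]]) <= 3L) {
    return(list(tissue = tissue, record = NULL,
                refused = "adjacent triangle cell"))
  }
  pa <- tissue$pos[a, ]; pb <- tissue$pos[b, ]
  d <- wrap_delta(pb - pa, tissue$box)
  len <- sqrt(sum(d^2))
  mid <- pa + d / 2
  nhat <- if (len > 0) c(-d[2], d[1]) / len else c(0, 1)
  # a' stays in L (left of a->b, interior on +nhat side); b' stays in R
  tissue$pos[a, ] <- wrap_point(mid + 0.5 * new_length * nhat, tissue$box)
  tissue$pos[b, ] <- wrap_point(mid - 0.5 * new_length * nhat, tissue$box)
  drop_from <- function(cy, v) cy[cy != v]
  repl <- function(cy, v, seq2) append(cy[cy != v], seq2, after = match(v, cy) - 1L)
  tissue$cells[[L]] <- drop_from(tissue$cells[[L]], b)
  tissue$cells[[R]] <- drop_from(tissue$cells[[R]], a)
  tissue$cells[[A]] <- repl(tissue$cells[[A]], a, c(b, a))
  tissue$cells[[B]] <- repl(tissue$cells[[B]], b, c(a, b))
  old <- tissue
  tissue <- rebuild_edges(tissue, keep = old)
  new_row <- which(tissue$edges[, 1] == min(a, b) & tissue$edges[, 2] == max(a, b))
  # two spokes reattach from one flip vertex to the other, changing their
  # endpoint pair; they are still the same junctions, so restore their
  # ids by their (invariant) flanking cell pair
  fresh <- setdiff(which(!(tissue$eid %in% old$eid)), new_row)
  for (r in fresh) {
    cp <- sort(tissue$edges[r, 3:4])
    cand <- which(old$edges[, 3] %in% cp & old$edges[, 4] %in% cp &
                    (old$edges[, 1] %in% c(a, b) | old$edges[, 2] %in% c(a, b)))
    if (length(cand) == 1L) tissue$eid[r] <- old$eid[cand]
  }
  new_id <- max(c(tissue$eid, old$eid)) + 1L
  tissue$eid[new_row] <- new_id
  # the four spoke junctions (they keep their ids through the flip)
  spokes <- setdiff(which(tissue$edges[, 1] %in% c(a, b) |
                            tissue$edges[, 2] %in% c(a, b)), new_row)
  sp <- tissue$eid[spokes]
  rec <- data.frame(edge_old = edge_id, edge_new = new_id,
                    q1 = L, q2 = R, q3 = A, q4 = B,
                    losing1 = L, losing2 = R, gaining1 = A, gaining2 = B,
                    n1 = sp[1], n2 = sp[2], n3 = sp[3], n4 = sp[4])
  list(tissue = tissue, record = rec, refused = NULL)
}

#' Write / read a tissue as three delimited text tables
#'
#' Files \code{<prefix>_vertices.tsv} (id, x, y),
#' \code{<prefix>_edges.tsv} (id, v1, v2, cell_left, cell_right) and
#' \code{<prefix>_cells.tsv} (id, vertex_cycle, preferred_area; the cycle is
#' a space-separated counterclockwise vertex list).  A fourth column
#' \code{tension} is written alongside the edges when supplied.
#'
#' @param tissue a \code{vm_tissue}.
#' @param prefix path prefix for the three files.
#' @param tension optional per-edge tension column (table order).
#' @return \code{prefix}, invisibly (write) / a \code{vm_tissue} (read).
#' @export
write_tissue <- function(tissue, prefix, tension = NULL) {
  v <- data.frame(id = seq_len(nrow(tissue$pos)),
                  x = tissue$pos[, 1], y = tissue$pos[, 2])
  e <- data.frame(id = tissue$eid, v1 = tissue$edges[, 1], v2 = tissue$edges[, 2],
                  cell_left = tissue$edges[, 3], cell_right = tissue$edges[, 4])
  if (!is.null(tension)) e$tension <- tension
  cdf <- data.frame(id = seq_along(tissue$cells),
                    vertex_cycle = vapply(tissue$cells, paste, "", collapse = " "),
                    preferred_area = tissue$A0)
  utils::write.table(v, paste0(prefix, "_vertices.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(e, paste0(prefix, "_edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cdf, paste0(prefix, "_cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  attr(prefix, "box") <- tissue$box
  invisible(prefix)
}

#' @rdname write_tissue
#' @param box c(width, height) of the periodic box (not stored in the
#'   tables; recorded in the run manifest by the drivers).
#' @export
read_tissue <- function(prefix, box) {
  v <- utils::read.table(paste0(prefix, "_vertices.tsv"), header = TRUE, sep = "\t")
  e <- utils::read.table(paste0(prefix, "_edges.tsv"), header = TRUE, sep = "\t")
  cdf <- utils::read.table(paste0(prefix, "_cells.tsv"), header = TRUE, sep = "\t",
                           colClasses = c("integer", "character", "numeric"))
  tis <- list(pos = cbind(v$x, v$y)[order(v$id), , drop = FALSE],
              edges = as.matrix(e[, c("v1", "v2", "cell_left", "cell_right")]),
              eid = as.integer(e$id),
              cells = lapply(strsplit(cdf$vertex_cycle[order(cdf$id)], " "),
                             as.integer),
              A0 = cdf$preferred_area[order(cdf$id)],
              box = box)
  colnames(tis$edges) <- c("v1", "v2", "cell_left", "cell_right")
  storage.mode(tis$edges) <- "integer"
  class(tis) <- "vm_tissue"
  if (!is.null(e$tension)) attr(tis, "tension") <- e$tension
  tis
}

#' @export
print.vm_tissue <- function(x, ...) {
  cat(sprintf("vm_tissue: %d vertices, %d edges, %d cells, box %.3g x %.3g\n",
              nrow(x$pos), nrow(x$edges), length(x$cells), x$box[1], x$box[2]))
  invisible(x)
}
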