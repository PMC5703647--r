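# Parsing of skeletonized segmentation images: 1-pixel-wide junction
# curves meeting at vertices.  Images are integer matrices (row = y,
# col = x, origin top-left); skeleton pixels are > 0.

# 8-neighbourhood offsets (col, row)
.n8 <- cbind(dx = c(-1, 0, 1, -1, 1, -1, 0, 1),
             dy = c(-1, -1, -1, 0, 0, 1, 1, 1))

# neighbour count image (8-connectivity) of a logical mask
neighbor_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  m <- matrix(0L, nr + 2L, nc + 2L)
  m[2:(nr + 1), 2:(nc + 1)] <- mask
  for (k in seq_len(nrow(.n8))) {
    out <- out + m[2:(nr + 1) + .n8[k, 2], 2:(nc + 1) + .n8[k, 1]]
  }
  out
}

# connected components (8-conn) among TRUE pixels given as (col,row) matrix
pixel_components <- function(px, nr, nc) {
  if (!nrow(px)) return(integer(0))
  lab <- matrix(0L, nr, nc)
  lab[cbind(px[, 2], px[, 1])] <- -1L
  comp <- integer(nrow(px))
  cur <- 0L
  for (i in seq_len(nrow(px))) {
    if (lab[px[i, 2], px[i, 1]] != -1L) next
    cur <- cur + 1L
    queue <- matrix(px[i, ], 1)
    lab[px[i, 2], px[i, 1]] <- cur
    while (nrow(queue)) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(.n8))) {
        cc <- p[1] + .n8[k, 1]; rr <- p[2] + .n8[k, 2]
        if (cc >= 1 && cc <= nc && rr >= 1 && rr <= nr &&
            lab[rr, cc] == -1L) {
          lab[rr, cc] <- cur
          queue <- rbind(queue, c(cc, rr))
        }
      }
    }
  }
  for (i in seq_len(nrow(px))) comp[i] <- lab[px[i, 2], px[i, 1]]
  comp
}

#' Parse a skeleton frame into vertices and junction pixel chains
#'
#' Vertices are skeleton pixels with at least three skeleton neighbours
#' (adjacent vertex pixels are clustered and represented by their
#' centroid).  Junctions are 8-connected pixel chains walked from vertex
#' to vertex; chains that touch the image border or end freely are
#' flagged \code{border} and are excluded from downstream statistics.
#'
#' @param img integer/numeric matrix; skeleton pixels are > 0.
#' @return List with \code{vertices} (data.frame vertex_id, col, row,
#'   n_pixels) and \code{junctions}: list of records (junction_id, v1,
#'   v2, pixels (m x 2 col,row), border, length_px, mid (col,row),
#'   angle_deg).
#' @export
parse_skeleton <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  mask <- img > 0
  if (!any(mask)) {
    return(list(vertices = data.frame(vertex_id = integer(0), col = numeric(0),
                                      row = numeric(0), n_pixels = integer(0)),
                junctions = list()))
  }
  ncnt <- neighbor_count(mask)
  isv <- mask & ncnt >= 3L
  vpix <- which(isv, arr.ind = TRUE)          # (row, col)
  vpix <- cbind(col = vpix[, 2], row = vpix[, 1])
  comp <- pixel_components(vpix, nr, nc)
  nvert <- if (length(comp)) max(comp) else 0L
  verts <- data.frame(vertex_id = seq_len(nvert),
                      col = rep(NA_real_, nvert),
                      row = rep(NA_real_, nvert),
                      n_pixels = rep(0L, nvert))
  vmap <- matrix(0L, nr, nc)                  # pixel -> vertex id
  for (v in seq_len(nvert)) {
    sel <- comp == v
    verts$col[v] <- mean(vpix[sel, 1]); verts$row[v] <- mean(vpix[sel, 2])
    verts$n_pixels[v] <- sum(sel)
    vmap[cbind(vpix[sel, 2], vpix[sel, 1])] <- v
  }
  visited <- matrix(FALSE, nr, nc)
  visited[vmap > 0L] <- TRUE
  at_border <- function(cc, rr) cc <= 1L || cc >= nc || rr <= 1L || rr >= nr
  junctions <- list()
  add_junction <- function(v1, v2, pixels, border) {
    junctions[[length(junctions) + 1L]] <<- list(
      junction_id = length(junctions) + 1L, v1 = v1, v2 = v2,
      pixels = pixels, border = border)
  }
  nb_of <- function(cc, rr) {
    out <- matrix(0L, 0, 2)
    for (k in seq_len(nrow(.n8))) {
      c2 <- cc + .n8[k, 1]; r2 <- rr + .n8[k, 2]
      if (c2 >= 1 && c2 <= nc && r2 >= 1 && r2 <= nr && mask[r2, c2]) {
        out <- rbind(out, c(c2, r2))
      }
    }
    out
  }
  walk <- function(start, from_v) {
    chain <- matrix(start, 1)
    visited[start[2], start[1]] <<- TRUE
    prev <- NULL
    repeat {
      cur <- chain[nrow(chain), ]
      nbs <- nb_of(cur[1], cur[2])
      vhit <- nbs[vmap[cbind(nbs[, 2], nbs[, 1])] > 0L, , drop = FALSE]
      vhit_id <- unique(vmap[cbind(vhit[, 2], vhit[, 1])])
      vhit_id <- setdiff(vhit_id, if (nrow(chain) <= 1L) from_v else integer(0))
      if (length(vhit_id)) {
        return(list(chain = chain, end_v = vhit_id[1],
                    border = FALSE))
      }
      cand <- nbs[!visited[cbind(nbs[, 2], nbs[, 1])] &
                    vmap[cbind(nbs[, 2], nbs[, 1])] == 0L, , drop = FALSE]
      if (!nrow(cand)) {
        return(list(chain = chain, end_v = NA_integer_,
                    border = TRUE))
      }
      # prefer cardinal continuation for clean 1-px chains
      card <- abs(cand[, 1] - cur[1]) + abs(cand[, 2] - cur[2]) == 1L
      nxt <- if (any(card)) cand[which(card)[1], ] else cand[1, ]
      visited[nxt[2], nxt[1]] <<- TRUE
      chain <- rbind(chain, nxt)
      prev <- cur
    }
  }
  # walk out of every vertex cluster
  for (v in seq_len(nvert)) {
    members <- which(vmap == v, arr.ind = TRUE)   # (row, col)
    for (mi in seq_len(nrow(members))) {
      mcc <- members[mi, 2]; mrr <- members[mi, 1]
      nbs <- nb_of(mcc, mrr)
      for (k in seq_len(nrow(nbs))) {
        cc <- nbs[k, 1]; rr <- nbs[k, 2]
        if (visited[rr, cc] || vmap[rr, cc] > 0L) next
        res <- walk(c(cc, rr), v)
        brd <- res$border ||
          any(apply(res$chain, 1, function(p) at_border(p[1], p[2])))
        add_junction(v, res$end_v, res$chain, brd || is.na(res$end_v))
      }
    }
  }
  # direct vertex-vertex contacts (four-way vertices appear as one cluster,
  # but two distinct adjacent clusters form a zero-pixel junction)
  seen_pair <- character(0)
  for (v in seq_len(nvert)) {
    members <- which(vmap == v, arr.ind = TRUE)
    for (mi in seq_len(nrow(members))) {
      nbs <- nb_of(members[mi, 2], members[mi, 1])
      ids <- vmap[cbind(nbs[, 2], nbs[, 1])]
      for (o in unique(ids[ids > v])) {
        key <- paste0(v, "_", o)
        if (!(key %in% seen_pair)) {
          seen_pair <- c(seen_pair, key)
          add_junction(v, o, matrix(numeric(0), 0, 2), FALSE)
        }
      }
    }
  }
  # leftover chains not attached to any vertex (isolated lines/loops)
  rest <- which(mask & !visited, arr.ind = TRUE)
  while (nrow(rest)) {
    # start from an endpoint if one exists, else anywhere (loop)
    cnt <- ncnt[rest]
    st <- rest[which.min(cnt), ]
    res <- walk(c(st[2], st[1]), NA_integer_)
    add_junction(NA_integer_, res$end_v, res$chain, TRUE)
    rest <- which(mask & !visited, arr.ind = TRUE)
  }
  # derived junction properties
  for (i in seq_along(junctions)) {
    j <- junctions[[i]]
    pts <- j$pixels
    ends <- rbind(
      if (!is.na(j$v1)) c(verts$col[j$v1], verts$row[j$v1]),
      pts,
      if (!is.na(j$v2)) c(verts$col[j$v2], verts$row[j$v2]))
    # chain length plus the gaps to the two vertex centroids
    gap <- 0
    if (!is.na(j$v1)) {
      ref <- if (nrow(pts)) pts[1, ] else c(verts$col[j$v2], verts$row[j$v2])
      gap <- gap + sqrt(sum((ref - c(verts$col[j$v1], verts$row[j$v1]))^2))
    }
    if (!is.na(j$v2) && nrow(pts)) {
      gap <- gap + sqrt(sum((pts[nrow(pts), ] -
                               c(verts$col[j$v2], verts$row[j$v2]))^2))
    }
    j$length_px <- junction_length_px(pts) + gap
    j$mid <- colMeans(ends[c(1, nrow(ends)), , drop = FALSE])
    d <- ends[nrow(ends), ] - ends[1, ]
    j$angle_deg <- (atan2(-d[2], d[1]) * 180 / pi) %% 180
    junctions[[i]] <- j
  }
  list(vertices = verts, junctions = junctions)
}

#' Junction length from a pixel chain by block decomposition
#'
#' The chain is decomposed into maximal axis-aligned straight runs
#' ("blocks"); consecutive blocks share their turning pixel when the turn
#' is between two cardinal directions.  The length is the sum of the
#' within-block spans plus the Euclidean distances connecting consecutive
#' blocks (\eqn{\sqrt 2} for diagonal steps).
#'
#' @param chain m x 2 matrix of ordered pixel coordinates (col, row).
#' @return Length in pixels (0 for chains of fewer than 2 pixels).
#' @export
junction_length_px <- function(chain) {
  m <- nrow(chain)
  if (is.null(m) || m < 2L) return(0)
  st <- diff(chain)
  total <- 0
  i <- 1L
  n <- nrow(st)
  while (i <= n) {
    if (abs(st[i, 1]) + abs(st[i, 2]) == 1L) {
      j <- i
      while (j < n && st[j + 1L, 1] == st[i, 1] && st[j + 1L, 2] == st[i, 2]) {
        j <- j + 1L
      }
      total <- total + sqrt(sum((chain[j + 1L, ] - chain[i, ])^2))
      i <- j + 1L
    } else {
      total <- total + sqrt(sum(st[i, ]^2))
      i <- i + 1L
    }
  }
  total
}

#' Estimate and accumulate whole-frame drift
#'
#' Translation between consecutive frames is estimated by integer-pixel
#' phase correlation (or taken from \code{translations} when supplied);
#' cumulative offsets stabilize all downstream coordinates.
#'
#' @param frames list of image matrices (or NULL if translations given).
#' @param translations optional (n_frames-1) x 2 matrix of known per-frame
#'   (dx, dy) shifts.
#' @return List with \code{per_frame} and \code{cumulative} (n_frames x 2,
#'   first row zero); subtracting \code{cumulative} from frame-k
#'   coordinates maps them into frame-1 coordinates.
#' @export
register_drift <- function(frames = NULL, translations = NULL) {
  if (is.null(translations)) {
    if (is.null(frames) || length(frames) < 2)
      return(list(per_frame = matrix(0, max(1, length(frames)) - 1, 2),
                  cumulative = matrix(0, max(1, length(frames)), 2)))
    nfr <- length(frames)
    translations <- matrix(0, nfr - 1, 2)
    for (k in 2:nfr) {
      translations[k - 1, ] <- phase_correlate(frames[[k - 1]], frames[[k]])
      if (any(abs(translations[k - 1, ]) >
              0.2 * c(ncol(frames[[k]]), nrow(frames[[k]])))) {
        warning(sprintf("estimated drift at frame %d exceeds 20%% of the frame", k))
      }
    }
  }
  translations <- matrix(translations, ncol = 2)
  cumulative <- rbind(c(0, 0), apply(translations, 2, cumsum))
  list(per_frame = translations, cumulative = matrix(cumulative, ncol = 2))
}

# integer-pixel translation of b relative to a by phase correlation
phase_correlate <- function(a, b) {
  A <- stats::fft(a); B <- stats::fft(b)
  R <- A * Conj(B)
  den <- Mod(R); den[den == 0] <- 1
  r <- Re(stats::fft(R / den, inverse = TRUE))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  dy <- pk[1] - 1L; dx <- pk[2] - 1L
  if (dy > nrow(a) / 2) dy <- dy - nrow(a)
  if (dx > ncol(a) / 2) dx <- dx - ncol(a)
  # b shifted by (dx, dy) relative to a
  unname(c(-dx, -dy))
}

#' Detect cells (interior faces) from parsed junctions
#'
#' Traverses the planar graph of junctions: starting from a directed
#' junction, repeatedly takes the next junction around the head vertex in
#' clockwise image orientation until returning to the start.  Each
#' interior face is found once; the outer face (largest area, opposite
#' orientation) is discarded, as are faces touching border junctions.
#'
#' @param parsed output of \code{parse_skeleton}.
#' @return List of cell records (cell_id, junction_ids, vertex_ids,
#'   polygon (k x 2 col,row), area_px, perimeter_px, mid (col,row)) plus
#'   attribute \code{junction_cells}: n_junctions x 2 matrix of the cells
#'   flanking each junction (NA for border-side).
#' @export
detect_cells <- function(parsed) {
  verts <- parsed$vertices
  jl <- parsed$junctions
  usable <- which(vapply(jl, function(j) !is.na(j$v1) && !is.na(j$v2), logical(1)))
  # directed half-junctions: (junction, orientation) with tail vertex and
  # outgoing direction at the tail
  dir_tail <- dir_head <- integer(0); dir_j <- integer(0); dir_o <- integer(0)
  ang_out <- numeric(0)
  for (j in usable) {
    rec <- jl[[j]]
    p1 <- c(verts$col[rec$v1], verts$row[rec$v1])
    p2 <- c(verts$col[rec$v2], verts$row[rec$v2])
    ref1 <- if (nrow(rec$pixels)) rec$pixels[1, ] else p2
    ref2 <- if (nrow(rec$pixels)) rec$pixels[nrow(rec$pixels), ] else p1
    dir_j <- c(dir_j, j, j); dir_o <- c(dir_o, 1L, 2L)
    dir_tail <- c(dir_tail, rec$v1, rec$v2)
    dir_head <- c(dir_head, rec$v2, rec$v1)
    ang_out <- c(ang_out, atan2(ref1[2] - p1[2], ref1[1] - p1[1]),
                 atan2(ref2[2] - p2[2], ref2[1] - p2[1]))
  }
  nd <- length(dir_j)
  if (!nd) return(structure(list(), junction_cells = NULL))
  # next directed half-junction in the traversal: reverse of the current,
  # then rotate to the angularly adjacent outgoing junction at that vertex
  nxt <- integer(nd)
  for (d in seq_len(nd)) {
    rev_d <- which(dir_j == dir_j[d] & dir_o != dir_o[d])
    v <- dir_tail[rev_d]
    outs <- which(dir_tail == v)
    a0 <- ang_out[rev_d]
    rel <- (ang_out[outs] - a0) %% (2 * pi)
    rel[outs == rev_d] <- 2 * pi   # take the reverse only as a last resort
    nxt[d] <- outs[which.min(rel)]
  }
  face_of <- rep(0L, nd)
  faces <- list()
  for (d0 in seq_len(nd)) {
    if (face_of[d0]) next
    fid <- length(faces) + 1L
    path <- d0
    face_of[d0] <- fid
    d <- nxt[d0]
    guard <- 0L
    while (d != d0 && guard < nd + 1L) {
      face_of[d] <- fid
      path <- c(path, d)
      d <- nxt[d]
      guard <- guard + 1L
    }
    faces[[fid]] <- path
  }
  cells <- list()
  jcells <- matrix(NA_integer_, length(jl), 2)
  border_j <- vapply(jl, function(j) isTRUE(j$border), logical(1))
  for (fid in seq_along(faces)) {
    path <- faces[[fid]]
    vs <- dir_tail[path]
    poly <- cbind(verts$col[vs], verts$row[vs])
    k <- nrow(poly)
    if (k < 3) next
    a <- -0.5 * sum(poly[, 1] * poly[c(2:k, 1), 2] -
                      poly[c(2:k, 1), 1] * poly[, 2])
    # in image coordinates (row axis points down) interior faces come out
    # with negative shoelace area under this traversal; the outer face has
    # the opposite sign
    if (a <= 0) next
    js <- unique(dir_j[path])
    if (any(border_j[js])) next
    if (anyDuplicated(vs)) next
    cell_id <- length(cells) + 1L
    cells[[cell_id]] <- list(
      cell_id = cell_id, junction_ids = js, vertex_ids = vs,
      polygon = poly, area_px = a,
      perimeter_px = sum(vapply(jl[js], function(j) j$length_px, numeric(1))),
      mid = c(mean(poly[, 1]), mean(poly[, 2])))
    for (j in js) {
      slot <- if (is.na(jcells[j, 1])) 1L else 2L
      jcells[j, slot] <- cell_id
    }
  }
  structure(cells, junction_cells = jcells)
}
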