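# Junction and cell tracking, T1 event detection, fluctuation analysis and
# intensity measurement on parsed skeleton movies.

#' Optimal frame-to-frame point assignment
#'
#' Matches rows of \code{A} to rows of \code{B} minimizing total squared
#' displacement, with a maximum-displacement cutoff; unmatched points cost
#' \code{cutoff^2}.  Candidate pairs are split into connected components
#' and each component is solved exactly by branch and bound (components
#' larger than \code{exhaustive_cap} fall back to greedy nearest-neighbour
#' with a warning).  Ties are broken toward the lower point index.
#'
#' @param A,B n x 2 and m x 2 coordinate matrices.
#' @param cutoff maximum displacement.
#' @param exhaustive_cap largest component size solved exactly.
#' @return Integer vector of length n: matched row of B, or NA.
#' @export
assign_points <- function(A, B, cutoff, exhaustive_cap = 12L) {
  n <- nrow(A); m <- nrow(B)
  match_out <- rep(NA_integer_, n)
  if (!n || !m) return(match_out)
  c2 <- cutoff^2
  D <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2
  cand <- D < c2
  # connected components on the bipartite candidate graph
  compA <- rep(0L, n); compB <- rep(0L, m); cur <- 0L
  for (i in seq_len(n)) {
    if (compA[i] || !any(cand[i, ])) next
    cur <- cur + 1L
    qa <- i
    while (length(qa)) {
      a <- qa[1]; qa <- qa[-1]
      if (compA[a]) next
      compA[a] <- cur
      bs <- which(cand[a, ] & compB == 0L)
      for (b in bs) {
        compB[b] <- cur
        qa <- c(qa, which(cand[, b] & compA == 0L))
      }
    }
  }
  for (g in seq_len(cur)) {
    ai <- which(compA == g); bi <- which(compB == g)
    if (length(ai) > exhaustive_cap || length(bi) > exhaustive_cap) {
      warning("assignment component larger than exhaustive cap; using greedy")
      d <- D[ai, bi, drop = FALSE]
      repeat {
        k <- which.min(d)
        if (!is.finite(d[k]) || d[k] >= c2) break
        r <- (k - 1L) %% nrow(d) + 1L; cc <- (k - 1L) %/% nrow(d) + 1L
        match_out[ai[r]] <- bi[cc]
        d[r, ] <- Inf; d[, cc] <- Inf
      }
      next
    }
    # branch and bound over ai
    best_cost <- Inf; best_asgn <- rep(NA_integer_, length(ai))
    asgn <- rep(NA_integer_, length(ai))
    usedB <- rep(FALSE, length(bi))
    rec <- function(k, cost) {
      if (cost >= best_cost) return()
      if (k > length(ai)) {
        best_cost <<- cost; best_asgn <<- asgn
        return()
      }
      ds <- D[ai[k], bi]
      ord <- order(ds)
      for (j in ord) {
        if (usedB[j] || ds[j] >= c2) next
        asgn[k] <<- j; usedB[j] <<- TRUE
        rec(k + 1L, cost + ds[j])
        usedB[j] <<- FALSE; asgn[k] <<- NA_integer_
      }
      rec(k + 1L, cost + c2)  # leave ai[k] unmatched
    }
    rec(1L, 0)
    ok <- !is.na(best_asgn)
    match_out[ai[ok]] <- bi[best_asgn[ok]]
  }
  match_out
}

#' Track junctions (or cells) across frames by midpoint matching
#'
#' Links per-frame midpoint sets into persistent tracks: consecutive
#' frames are matched with \code{assign_points} (minimum total squared
#' displacement under a cutoff); unmatched midpoints start new tracks.
#'
#' @param mids list of per-frame n x 2 midpoint matrices (stabilized
#'   coordinates).
#' @param cutoff maximum midpoint displacement per frame.
#' @return List of per-frame integer vectors of persistent track ids.
#' @export
track_junctions <- function(mids, cutoff = 10) link_tracks(mids, cutoff)

#' @rdname track_junctions
#' @export
track_cells <- function(mids, cutoff = 10) link_tracks(mids, cutoff)

# generic tracker: list of per-frame midpoint matrices -> per-frame
# integer vectors of persistent track ids
link_tracks <- function(mids, cutoff) {
  nf <- length(mids)
  ids <- vector("list", nf)
  nxt <- 0L
  ids[[1]] <- seq_len(nrow(mids[[1]])) ; nxt <- nrow(mids[[1]])
  for (f in 2:nf) {
    a <- mids[[f - 1]]; b <- mids[[f]]
    mt <- assign_points(a, b, cutoff)
    cur <- rep(NA_integer_, nrow(b))
    for (i in seq_along(mt)) if (!is.na(mt[i])) cur[mt[i]] <- ids[[f - 1]][i]
    new <- which(is.na(cur))
    if (length(new)) { cur[new] <- nxt + seq_along(new); nxt <- nxt + length(new) }
    ids[[f]] <- cur
  }
  ids
}

#' Analyze a skeleton movie into tracked junctions, cells and T1 events
#'
#' Full chain: drift registration (phase correlation of the skeleton
#' frames, or known translations), per-frame skeleton parsing, cell
#' detection, junction and cell tracking by midpoint assignment, optional
#' junction intensity measurement, and T1 event detection.
#'
#' @param skeleton list of skeleton image matrices.
#' @param intensity optional list of matching intensity images.
#' @param px_size physical size of one pixel (micrometres per px; use 1
#'   to stay in pixel units).
#' @param frame_interval_s frame interval in seconds.
#' @param cutoff_px tracking cutoff (max midpoint displacement / frame).
#' @param translations optional known per-frame drift (passed to
#'   \code{register_drift}).
#' @param width_px dilation width for intensity measurement.
#' @return List with \code{tracks} (junction track table), \code{cells}
#'   (cell track table), \code{events} (T1 event table from
#'   \code{detect_t1_events}), \code{parsed}, \code{drift}.
#' @export
analyze_movie <- function(skeleton, intensity = NULL, px_size = 1,
                          frame_interval_s = 30, cutoff_px = 10,
                          translations = NULL, width_px = 7L,
                          min_new_frames = 4L, fourway_px = 6) {
  nf <- length(skeleton)
  drift <- register_drift(skeleton, translations)
  parsed <- lapply(skeleton, parse_skeleton)
  cells <- lapply(parsed, detect_cells)
  dtm <- frame_interval_s / 60
  # stabilized midpoints
  jmids <- vector("list", nf); cmids <- vector("list", nf)
  for (f in seq_len(nf)) {
    jm <- t(vapply(parsed[[f]]$junctions, function(j) j$mid, numeric(2)))
    if (!length(parsed[[f]]$junctions)) jm <- matrix(0, 0, 2)
    jmids[[f]] <- sweep(jm, 2, drift$cumulative[f, ])
    cm <- t(vapply(cells[[f]], function(cl) cl$mid, numeric(2)))
    if (!length(cells[[f]])) cm <- matrix(0, 0, 2)
    cmids[[f]] <- sweep(cm, 2, drift$cumulative[f, ])
  }
  jids <- link_tracks(jmids, cutoff_px)
  cids <- link_tracks(cmids, cutoff_px)
  # intensity measurement
  inten <- if (!is.null(intensity)) {
    lapply(seq_len(nf), function(f) {
      measure_intensity(parsed[[f]], intensity[[f]], width_px = width_px)
    })
  } else NULL
  rows <- list()
  for (f in seq_len(nf)) {
    jl <- parsed[[f]]$junctions
    if (!length(jl)) next
    jc <- attr(cells[[f]], "junction_cells")
    # map local cell ids to persistent cell track ids
    c1 <- c2 <- rep(NA_integer_, length(jl))
    if (!is.null(jc) && nrow(jc)) {
      c1 <- ifelse(is.na(jc[, 1]), NA_integer_, cids[[f]][jc[, 1]])
      c2 <- ifelse(is.na(jc[, 2]), NA_integer_, cids[[f]][jc[, 2]])
    }
    rows[[f]] <- data.frame(
      junction_id = jids[[f]],
      frame = f, time_min = (f - 1) * dtm,
      mid_col = jmids[[f]][, 1], mid_row = jmids[[f]][, 2],
      length_px = vapply(jl, function(j) j$length_px, numeric(1)),
      length_um = vapply(jl, function(j) j$length_px, numeric(1)) * px_size,
      angle_deg = vapply(jl, function(j) j$angle_deg, numeric(1)),
      border = vapply(jl, function(j) isTRUE(j$border), logical(1)),
      cell1 = pmin(c1, c2), cell2 = pmax(c1, c2),
      intensity_norm = if (!is.null(inten)) inten[[f]] else NA_real_)
  }
  tracks <- do.call(rbind, rows)
  crows <- list()
  for (f in seq_len(nf)) {
    cl <- cells[[f]]
    if (!length(cl)) next
    crows[[f]] <- data.frame(
      cell_id = cids[[f]], frame = f, time_min = (f - 1) * dtm,
      mid_col = cmids[[f]][, 1], mid_row = cmids[[f]][, 2],
      area_px = vapply(cl, function(x) x$area_px, numeric(1)),
      perimeter_px = vapply(cl, function(x) x$perimeter_px, numeric(1)),
      n_sides = vapply(cl, function(x) length(x$junction_ids), integer(1)))
  }
  cell_tracks <- do.call(rbind, crows)
  events <- detect_t1_events(tracks, min_new_frames = min_new_frames,
                             fourway_px = fourway_px)
  list(tracks = tracks, cells = cell_tracks, events = events,
       parsed = parsed, cells_by_frame = cells, drift = drift,
       frame_interval_min = dtm, px_size = px_size)
}

#' Detect T1 neighbour-exchange events from tracked junctions
#'
#' A junction qualifies when it contracts to the four-way-vertex scale
#' (length below \code{fourway_px}) or disappears, and a junction at the
#' same location subsequently re-expands with a different pair of
#' flanking cells that stays stable for at least \code{min_new_frames}
#' frames.  Contractions that re-expand with unchanged neighbours are
#' recorded as near misses.  Event time is the four-way-vertex frame.
#'
#' @param tracks junction track table from \code{analyze_movie}.
#' @param min_new_frames required stability of the new configuration.
#' @param fourway_px four-way-vertex length scale (px).
#' @param gap_frames maximum frames between loss and reappearance
#'   (four-way vertices can pause for minutes before resolving).
#' @return data.frame of events (frame, time_min, junction_old,
#'   junction_new, losing1, losing2, gaining1, gaining2, quartet columns
#'   q1..q4) with attribute \code{near_misses}.
#' @export
detect_t1_events <- function(tracks, min_new_frames = 4L, fourway_px = 6,
                             gap_frames = 10L) {
  ev <- list(); near <- 0L
  tracks <- tracks[!tracks$border & !is.na(tracks$cell1) & !is.na(tracks$cell2), ]
  if (!nrow(tracks)) {
    out <- empty_events(); attr(out, "near_misses") <- 0L; return(out)
  }
  nf <- max(tracks$frame)
  dtm <- if (nf > 1) (max(tracks$time_min) - min(tracks$time_min)) /
    (nf - 1) else 1
  # candidate "loss" records: last frame a (junction, cell-pair) is seen
  # with its pair, where the junction is short or about to vanish
  tracks$pair <- paste0(tracks$cell1, "_", tracks$cell2)
  by_j <- split(tracks, tracks$junction_id)
  pair_stable_from <- function(tj, k, pair) {
    # pair constant for min_new_frames consecutive frames starting at k
    idx <- which(tj$frame >= tj$frame[k])
    run <- tj[idx, ]
    if (nrow(run) < min_new_frames) return(FALSE)
    all(run$pair[seq_len(min_new_frames)] == pair) &&
      all(diff(run$frame[seq_len(min_new_frames)]) == 1L)
  }
  for (tj in by_j) {
    tj <- tj[order(tj$frame), ]
    ch <- which(tj$pair[-1] != tj$pair[-nrow(tj)])
    for (k in ch) {
      old_pair <- c(tj$cell1[k], tj$cell2[k])
      new_pair <- c(tj$cell1[k + 1], tj$cell2[k + 1])
      if (length(intersect(old_pair, new_pair))) next
      if (!pair_stable_from(tj, k + 1L, tj$pair[k + 1])) { near <- near + 1L; next }
      # four-way vertex: the length minimum around the change
      wnd <- tj[tj$frame >= tj$frame[k] - 2L & tj$frame <= tj$frame[k + 1] + 2L, ]
      if (min(wnd$length_px) > fourway_px) next
      fmin <- wnd$frame[which.min(wnd$length_px)]
      ev[[length(ev) + 1L]] <- data.frame(
        frame = fmin, time_min = tj$time_min[match(fmin, tj$frame)],
        junction_old = tj$junction_id[1], junction_new = tj$junction_id[1],
        losing1 = old_pair[1], losing2 = old_pair[2],
        gaining1 = new_pair[1], gaining2 = new_pair[2])
    }
  }
  # cross-track case: track ends (or stays short) and a different track
  # with a disjoint stable pair appears nearby
  ends <- do.call(rbind, lapply(by_j, function(tj) tj[which.max(tj$frame), ]))
  starts <- do.call(rbind, lapply(by_j, function(tj) tj[which.min(tj$frame), ]))
  for (i in seq_len(nrow(ends))) {
    e <- ends[i, ]
    if (e$frame >= nf) next
    cand <- starts[starts$frame > e$frame &
                     starts$frame <= e$frame + gap_frames &
                     abs(starts$mid_col - e$mid_col) <= fourway_px &
                     abs(starts$mid_row - e$mid_row) <= fourway_px, ]
    for (j in seq_len(nrow(cand))) {
      s <- cand[j, ]
      old_pair <- c(e$cell1, e$cell2); new_pair <- c(s$cell1, s$cell2)
      if (length(intersect(old_pair, new_pair))) next
      tj <- by_j[[as.character(s$junction_id)]]
      tj <- tj[order(tj$frame), ]
      if (!pair_stable_from(tj, 1L, s$pair)) { near <- near + 1L; next }
      ev[[length(ev) + 1L]] <- data.frame(
        frame = e$frame + 1L, time_min = e$time_min + dtm,
        junction_old = e$junction_id, junction_new = s$junction_id,
        losing1 = old_pair[1], losing2 = old_pair[2],
        gaining1 = new_pair[1], gaining2 = new_pair[2])
      break
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else empty_events()
  if (nrow(out)) {
    out <- out[order(out$frame), ]
    out$q1 <- out$losing1; out$q2 <- out$losing2
    out$q3 <- out$gaining1; out$q4 <- out$gaining2
    out$event_id <- seq_len(nrow(out))
  }
  attr(out, "near_misses") <- near
  out
}

empty_events <- function() {
  data.frame(frame = integer(0), time_min = numeric(0),
             junction_old = integer(0), junction_new = integer(0),
             losing1 = integer(0), losing2 = integer(0),
             gaining1 = integer(0), gaining2 = integer(0),
             q1 = integer(0), q2 = integer(0), q3 = integer(0),
             q4 = integer(0), event_id = integer(0))
}

#' Classify events as uni- or multi-directional
#'
#' Within each quartet of cells, an event whose losing pair equals the
#' gaining pair of an earlier event within \code{window} minutes marks the
#' quartet's exchange as multi-directional (a reversal).
#'
#' @param events event table (needs losing/gaining pairs and time_min).
#' @param window time window (min), default Inf.
#' @return The events with columns \code{direction}
#'   ("uni"/"multi") and \code{reversal_of}, plus attribute
#'   \code{fraction_multi}.
#' @export
classify_directionality <- function(events, window = Inf) {
  if (!nrow(events)) {
    events$direction <- character(0); events$reversal_of <- integer(0)
    attr(events, "fraction_multi") <- NA_real_
    return(events)
  }
  key <- apply(events[, c("q1", "q2", "q3", "q4")], 1,
               function(x) paste(sort(x), collapse = "_"))
  events$direction <- "uni"
  events$reversal_of <- NA_integer_
  for (qk in unique(key)) {
    idx <- which(key == qk)
    idx <- idx[order(events$time_min[idx])]
    for (a in seq_along(idx)[-1]) {
      i <- idx[a]
      for (b in seq_len(a - 1)) {
        j <- idx[b]
        if (events$time_min[i] - events$time_min[j] <= window &&
            setequal(c(events$losing1[i], events$losing2[i]),
                     c(events$gaining1[j], events$gaining2[j]))) {
          events$direction[i] <- "multi"
          events$reversal_of[i] <- if ("event_id" %in% names(events))
            events$event_id[j] else j
          break
        }
      }
    }
  }
  attr(events, "fraction_multi") <- mean(events$direction == "multi")
  events
}

#' Persistence segments of a junction length series
#'
#' Turning points are found after suppressing reversals whose
#' peak-to-trough amplitude is below \code{filter_amplitude} (hysteresis
#' filter); maximal monotone stretches between surviving turning points
#' are the segments.  The ballistic velocity of a segment is
#' |change in length| / duration.
#'
#' @param lengths numeric series (regular sampling).
#' @param times matching times (min); default 0, 1, 2, ... frames.
#' @param filter_amplitude hysteresis amplitude in length units.
#' @return data.frame (start, end, dlength, duration_min, sign,
#'   velocity); zero rows for series shorter than 3 samples.
#' @export
persistence_segments <- function(lengths, times = seq_along(lengths) - 1,
                                 filter_amplitude = 0) {
  n <- length(lengths)
  empty <- data.frame(start = integer(0), end = integer(0),
                      dlength = numeric(0), duration_min = numeric(0),
                      sign = character(0), velocity = numeric(0))
  if (n < 3) return(empty)
  x <- lengths
  turns <- integer(0)
  d <- 0L
  runmin <- 1L; runmax <- 1L; m <- 1L
  for (i in 2:n) {
    if (d == 0L) {
      if (x[i] < x[runmin]) runmin <- i
      if (x[i] > x[runmax]) runmax <- i
      if (x[i] >= x[runmin] + filter_amplitude && runmin < i) {
        turns <- c(turns, runmin); d <- 1L; m <- i
      } else if (x[i] <= x[runmax] - filter_amplitude && runmax < i) {
        turns <- c(turns, runmax); d <- -1L; m <- i
      }
    } else if (d == 1L) {
      if (x[i] >= x[m]) m <- i
      else if (x[i] <= x[m] - filter_amplitude) {
        turns <- c(turns, m); d <- -1L; m <- i
      }
    } else {
      if (x[i] <= x[m]) m <- i
      else if (x[i] >= x[m] + filter_amplitude) {
        turns <- c(turns, m); d <- 1L; m <- i
      }
    }
  }
  pts <- unique(c(1L, turns, n))
  pts <- sort(pts)
  if (length(pts) < 2) return(empty)
  seg <- data.frame(start = pts[-length(pts)], end = pts[-1])
  seg$dlength <- x[seg$end] - x[seg$start]
  seg$duration_min <- times[seg$end] - times[seg$start]
  seg <- seg[seg$dlength != 0 & seg$duration_min > 0, ]
  if (!nrow(seg)) return(empty)
  seg$sign <- ifelse(seg$dlength < 0, "contraction", "expansion")
  seg$velocity <- abs(seg$dlength) / seg$duration_min
  rownames(seg) <- NULL
  seg
}

#' @rdname persistence_segments
#' @param segments data.frame from \code{persistence_segments}.
#' @return \code{ballistic_velocity}: numeric vector of velocities.
#' @export
ballistic_velocity <- function(segments) segments$velocity

#' Normalized junction intensity in one frame
#'
#' Each junction's pixel chain is dilated to an average width of
#' \code{width_px}; disks of radius \code{width_px/2} around every vertex
#' are excluded; pixel intensities are summed per junction.  The frame is
#' normalized so the mean per-pixel intensity over all dilated junction
#' pixels equals 1 (bleaching correction), and each junction's total is
#' divided by its pixel count ("normalized average intensity").
#'
#' @param parsed one \code{parse_skeleton} result.
#' @param img matching intensity image.
#' @param width_px dilated width (default 7).
#' @return Numeric vector (one value per junction; NA when a junction is
#'   fully inside vertex-exclusion zones).
#' @export
measure_intensity <- function(parsed, img, width_px = 7L) {
  nr <- nrow(img); nc <- ncol(img)
  jl <- parsed$junctions
  if (!length(jl)) return(numeric(0))
  rad <- floor(width_px / 2)
  off <- as.matrix(expand.grid(dx = -rad:rad, dy = -rad:rad))
  off <- off[off[, 1]^2 + off[, 2]^2 <= rad^2 + 1e-9, , drop = FALSE]
  vrad <- width_px / 2
  voff <- as.matrix(expand.grid(dx = -ceiling(vrad):ceiling(vrad),
                                dy = -ceiling(vrad):ceiling(vrad)))
  voff <- voff[voff[, 1]^2 + voff[, 2]^2 <= vrad^2, , drop = FALSE]
  excl <- matrix(FALSE, nr, nc)
  for (v in seq_len(nrow(parsed$vertices))) {
    cc <- round(parsed$vertices$col[v]) + voff[, 1]
    rr <- round(parsed$vertices$row[v]) + voff[, 2]
    ok <- cc >= 1 & cc <= nc & rr >= 1 & rr <= nr
    excl[cbind(rr[ok], cc[ok])] <- TRUE
  }
  jpx <- vector("list", length(jl))
  for (i in seq_along(jl)) {
    ch <- jl[[i]]$pixels
    if (!nrow(ch)) { jpx[[i]] <- matrix(0L, 0, 2); next }
    cc <- rep(ch[, 1], each = nrow(off)) + off[, 1]
    rr <- rep(ch[, 2], each = nrow(off)) + off[, 2]
    ok <- cc >= 1 & cc <= nc & rr >= 1 & rr <= nr
    px <- unique(cbind(cc[ok], rr[ok]))
    keep <- !excl[cbind(px[, 2], px[, 1])]
    jpx[[i]] <- px[keep, , drop = FALSE]
  }
  # bleaching normalization over the union of dilated junction pixels
  un <- unique(do.call(rbind, jpx))
  if (!nrow(un)) return(rep(NA_real_, length(jl)))
  scale <- sum(img[cbind(un[, 2], un[, 1])]) / nrow(un)
  if (scale == 0) scale <- 1
  vapply(seq_along(jl), function(i) {
    px <- jpx[[i]]
    if (!nrow(px)) return(NA_real_)
    sum(img[cbind(px[, 2], px[, 1])] / scale) / nrow(px)
  }, numeric(1))
}

# polygon area centroid
poly_centroid <- function(P) {
  k <- nrow(P)
  j <- c(2:k, 1)
  cr <- P[, 1] * P[j, 2] - P[j, 1] * P[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(P))
  c(sum((P[, 1] + P[j, 1]) * cr), sum((P[, 2] + P[j, 2]) * cr)) / (6 * a)
}

#' Internal and external aspect ratios of a T1 quartet
#'
#' Internal: distance between the centres of area (CoA) of the two cells
#' losing the junction divided by the CoA distance of the gaining pair.
#' External: the same ratio computed from the intersections of each CoA
#' axis with the outer perimeter of the four-cell cluster.
#'
#' @param polys named list of four polygons (k x 2 matrices), names are
#'   cell ids.
#' @param losing,gaining character/integer pairs of cell ids.
#' @return List with \code{internal}, \code{external} (NA when an axis
#'   misses the perimeter), and the CoA table.
#' @export
quartet_aspect_ratios <- function(polys, losing, gaining) {
  ids <- names(polys)
  stopifnot(length(polys) == 4, all(as.character(losing) %in% ids),
            all(as.character(gaining) %in% ids))
  coa <- t(vapply(polys, poly_centroid, numeric(2)))
  d_int_l <- sqrt(sum((coa[as.character(losing[1]), ] -
                         coa[as.character(losing[2]), ])^2))
  d_int_g <- sqrt(sum((coa[as.character(gaining[1]), ] -
                         coa[as.character(gaining[2]), ])^2))
  internal <- d_int_l / d_int_g
  # outer perimeter: polygon edges not shared between two quartet members
  segs <- list()
  for (i in seq_along(polys)) {
    P <- polys[[i]]; k <- nrow(P)
    for (e in seq_len(k)) {
      segs[[length(segs) + 1L]] <- rbind(P[e, ], P[if (e == k) 1 else e + 1, ])
    }
  }
  skey <- vapply(segs, function(s) {
    s <- round(s, 6); s <- s[order(s[, 1], s[, 2]), , drop = FALSE]
    paste(c(t(s)), collapse = ",")
  }, "")
  outer_segs <- segs[skey %in% names(which(table(skey) == 1))]
  axis_span <- function(p1, p2) {
    dvec <- p2 - p1
    ts <- c()
    for (s in outer_segs) {
      # solve p1 + t d = s1 + u (s2-s1), u in [0,1]
      M <- cbind(dvec, s[1, ] - s[2, ])
      det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
      if (abs(det) < 1e-12) next
      rhs <- s[1, ] - p1
      t <- (rhs[1] * M[2, 2] - rhs[2] * M[1, 2]) / det
      u <- (M[1, 1] * rhs[2] - M[2, 1] * rhs[1]) / det
      if (u >= -1e-9 && u <= 1 + 1e-9) ts <- c(ts, t)
    }
    if (length(ts) < 2) return(NA_real_)
    (max(ts) - min(ts)) * sqrt(sum(dvec^2))
  }
  d_ext_l <- axis_span(coa[as.character(losing[1]), ],
                       coa[as.character(losing[2]), ])
  d_ext_g <- axis_span(coa[as.character(gaining[1]), ],
                       coa[as.character(gaining[2]), ])
  list(internal = internal,
       external = if (is.na(d_ext_l) || is.na(d_ext_g)) NA_real_
                  else d_ext_l / d_ext_g,
       coa = coa)
}

#' Kaplan-Meier survival of uni-directional configurations
#'
#' For each quartet's first exchange, the time to its reversal is the
#' event time; quartets never reversed are right-censored at
#' \code{observation_end}.  Estimated with the Kaplan-Meier estimator
#' (95% confidence band).
#'
#' @param events event table (classified or not; reversals are detected
#'   from losing/gaining pairs per quartet).
#' @param observation_end censoring time (min).
#' @return List with \code{fit} (a \code{survfit}), \code{table}
#'   (time, surv, lower, upper), \code{n_reversed}, \code{n_censored};
#'   NULL when there are no events.
#' @export
reversal_survival <- function(events, observation_end) {
  if (!nrow(events)) return(NULL)
  key <- apply(events[, c("q1", "q2", "q3", "q4")], 1,
               function(x) paste(sort(x), collapse = "_"))
  durs <- c(); status <- c()
  for (qk in unique(key)) {
    idx <- which(key == qk)
    idx <- idx[order(events$time_min[idx])]
    first <- idx[1]
    rev_t <- NA_real_
    for (i in idx[-1]) {
      if (setequal(c(events$losing1[i], events$losing2[i]),
                   c(events$gaining1[first], events$gaining2[first]))) {
        rev_t <- events$time_min[i]; break
      }
    }
    if (!is.na(rev_t)) {
      durs <- c(durs, rev_t - events$time_min[first]); status <- c(status, 1)
    } else {
      durs <- c(durs, observation_end - events$time_min[first])
      status <- c(status, 0)
    }
  }
  fit <- survival::survfit(survival::Surv(durs, status) ~ 1, conf.int = 0.95)
  list(fit = fit,
       table = data.frame(time = fit$time, surv = fit$surv,
                          lower = fit$lower, upper = fit$upper),
       n_reversed = sum(status == 1), n_censored = sum(status == 0))
}
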