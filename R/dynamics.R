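# Mechanics and stochastic dynamics of the vertex model.
#
# Energy: E = sum_edges gamma_ij * l_ij + sum_cells (K/2) (A_c - A0_c)^2.
# Overdamped motion: alpha dx/dt = f = -dE/dx (explicit Euler).
# Line tensions follow an Ornstein-Uhlenbeck process around per-edge
# reference tensions gamma0_ij = mean of the two adjacent cells' draws:
#   dgamma/dt = -(gamma - gamma0)/tau_m + xi,  <xi xi'> = 2 sigma_i^2/tau_m delta.

#' Model parameter set
#'
#' Returns the validated parameter list.  The defaults are the wild-type
#' calibration in nondimensional units: characteristic cell length l = 1,
#' mean line tension gamma = 1, time in minutes.  The packing time
#' tau_p = alpha*l/gamma = 4.4 min fixes the friction alpha; the
#' tension-to-area-elasticity ratio gamma/(K l^3) = 0.025 fixes K = 40;
#' preferred areas have mean 1 l^2 and SD 0.19 l^2; tension persistence is
#' tau_m = 2.2 min (the measured intensity decorrelation time).  The
#' intrinsic/extrinsic tension-fluctuation ratio follows the measured
#' intensity coefficients of variation, sigma_i/sigma_e = 0.08/0.13; the
#' magnitude sigma_e is the calibrated fluctuation strength, tuned (with
#' the T1 threshold at its default l_T1 = 0.05 l, l_new = 1.5 l_T1) so
#' that the wild-type simulation reproduces the measured T1 rate of
#' 8.5e-4 events/min/junction.  See the methods vignette for why the
#' magnitude, not the threshold, is the effective knob in this energy
#' functional.
#'
#' @param ... overrides for any field.
#' @return Named list of class \code{vm_params}.
#' @export
model_params <- function(...) {
  p <- list(
    gamma_mean = 1,
    sigma_e = 0.25,
    sigma_i = 0.25 * 0.08 / 0.13,
    tau_m = 2.2,
    l_char = 1,
    tau_p = 4.4,
    K = 40,
    A0_mean = 1,
    sigma_A = 0.19,
    l_T1 = 0.05,
    l_new = 0.075,
    dt = 0.02,
    seed = 1L)
  p$alpha <- p$tau_p * p$gamma_mean / p$l_char
  over <- list(...)
  unknown <- setdiff(names(over), c(names(p), "alpha"))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (!("alpha" %in% names(over))) p$alpha <- p$tau_p * p$gamma_mean / p$l_char
  validate_params(p)
  class(p) <- "vm_params"
  p
}

validate_params <- function(p) {
  num <- c("gamma_mean", "sigma_e", "sigma_i", "tau_m", "l_char", "tau_p",
           "K", "A0_mean", "sigma_A", "l_T1", "l_new", "dt", "alpha")
  bad <- character(0)
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      bad <- c(bad, sprintf("%s must be a nonnegative finite scalar", f))
    }
  }
  pos <- c("gamma_mean", "tau_m", "l_char", "tau_p", "K", "A0_mean",
           "l_T1", "l_new", "dt", "alpha")
  for (f in pos) if (is.numeric(p[[f]]) && length(p[[f]]) == 1 &&
                     is.finite(p[[f]]) && p[[f]] <= 0) {
    bad <- c(bad, sprintf("%s must be positive", f))
  }
  if (is.numeric(p$l_new) && is.numeric(p$l_T1) && p$l_new <= p$l_T1) {
    bad <- c(bad, "l_new must exceed l_T1")
  }
  if (is.numeric(p$dt) && p$dt >= min(p$tau_m, p$tau_p) / 10) {
    bad <- c(bad, "dt must be below min(tau_m, tau_p)/10")
  }
  if (abs(p$alpha - p$tau_p * p$gamma_mean / p$l_char) >
      1e-9 * p$alpha) {
    bad <- c(bad, "alpha inconsistent with tau_p * gamma_mean / l_char")
  }
  if (length(bad)) stop("invalid parameters:\n  ", paste(bad, collapse = "\n  "))
  invisible(p)
}

# Flattened geometry cache for vectorised area/force evaluation.
build_cache <- function(tis) {
  cyc <- tis$cells
  lens <- lengths(cyc)
  vidx <- unlist(cyc, use.names = FALSE)
  nxt <- unlist(lapply(cyc, function(v) v[c(2:length(v), 1)]), use.names = FALSE)
  n <- length(vidx)
  start <- c(0L, cumsum(lens))[seq_along(cyc)] + 1L
  ends <- cumsum(lens)
  prv_entry <- seq_len(n) - 1L
  prv_entry[start] <- ends
  list(cidx = rep(seq_along(cyc), lens), vidx = vidx, nxt = nxt,
       start_entry = rep(start, lens), prv_entry = prv_entry,
       nv = nrow(tis$pos), ncell = length(cyc),
       ev1 = tis$edges[, 1], ev2 = tis$edges[, 2])
}

# Areas of all cells from the cache (exclusive per-cell cumulative sums).
cache_areas <- function(pos, cache, box) {
  dx <- pos[cache$nxt, 1] - pos[cache$vidx, 1]
  dy <- pos[cache$nxt, 2] - pos[cache$vidx, 2]
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  n <- length(dx)
  ex <- c(0, cumsum(dx))[seq_len(n)]
  ey <- c(0, cumsum(dy))[seq_len(n)]
  sx <- ex - ex[cache$start_entry]
  sy <- ey - ey[cache$start_entry]
  cross <- sx * dy - sy * dx
  a <- rowsum(cross, cache$cidx, reorder = FALSE)
  list(area = 0.5 * as.vector(a), dx = dx, dy = dy)
}

#' Tissue mechanical energy
#'
#' \eqn{E = \sum_{edges} \gamma_{ij} l_{ij} + \sum_{cells} (K/2)(A_c - A_{0,c})^2}
#'
#' @param tissue a \code{vm_tissue}.
#' @param tension per-edge tension vector (edge-table order) or a tension
#'   state as returned by \code{init_tension}.
#' @param params a \code{vm_params}.
#' @return Scalar energy.
#' @export
tissue_energy <- function(tissue, tension, params) {
  g <- if (is.list(tension)) tension$gamma else tension
  lens <- edge_lengths(tissue)
  areas <- cell_areas(tissue)
  sum(g * lens) + 0.5 * params$K * sum((areas - tissue$A0)^2)
}

#' Forces on all vertices, f = -dE/dx
#'
#' Line tensions pull each endpoint toward the other with magnitude
#' \eqn{\gamma_{ij}}; the area term is the shoelace gradient scaled by
#' \eqn{-K (A_c - A_{0,c})}.
#'
#' @inheritParams tissue_energy
#' @param cache optional geometry cache (internal fast path).
#' @return nv x 2 matrix of force vectors.
#' @export
vertex_forces <- function(tissue, tension, params, cache = NULL) {
  g <- if (is.list(tension)) tension$gamma else tension
  if (is.null(cache)) cache <- build_cache(tissue)
  pos <- tissue$pos; box <- tissue$box
  dx <- pos[cache$ev2, 1] - pos[cache$ev1, 1]
  dy <- pos[cache$ev2, 2] - pos[cache$ev1, 2]
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  len <- sqrt(dx * dx + dy * dy)
  inv <- ifelse(len > 0, 1 / len, 0)
  tx <- g * dx * inv; ty <- g * dy * inv
  Ft <- rowsum(cbind(c(tx, -tx), c(ty, -ty)), c(cache$ev1, cache$ev2),
               reorder = TRUE)
  ar <- cache_areas(pos, cache, box)
  press <- params$K * (ar$area - tissue$A0)
  pe <- press[cache$cidx]
  gx <- 0.5 * (ar$dy + ar$dy[cache$prv_entry])
  gy <- -0.5 * (ar$dx + ar$dx[cache$prv_entry])
  Fa <- rowsum(cbind(-pe * gx, -pe * gy), cache$vidx, reorder = TRUE)
  F <- matrix(0, cache$nv, 2)
  F[as.integer(rownames(Ft)), ] <- F[as.integer(rownames(Ft)), ] + Ft
  F[as.integer(rownames(Fa)), ] <- F[as.integer(rownames(Fa)), ] + Fa
  F
}

#' Draw per-cell extrinsic tensions
#'
#' Samples from a normal distribution with mean \code{gamma_mean} and SD
#' \code{sigma_e}, truncated to nonnegative values (rejection sampling).
#'
#' @param params a \code{vm_params}.
#' @param n_cells number of draws.
#' @return Numeric vector of cell tension draws.
#' @export
draw_cell_tensions <- function(params, n_cells) {
  out <- numeric(n_cells)
  need <- seq_len(n_cells)
  while (length(need)) {
    out[need] <- stats::rnorm(length(need), params$gamma_mean, params$sigma_e)
    need <- need[out[need] < 0]
  }
  out
}

#' Per-edge reference tensions
#'
#' The reference tension of a junction is the mean of the extrinsic draws
#' of its two adjacent cells.
#'
#' @param tissue a \code{vm_tissue}.
#' @param cell_tensions per-cell draws.
#' @return Numeric vector in edge-table order.
#' @export
reference_tensions <- function(tissue, cell_tensions) {
  0.5 * (cell_tensions[tissue$edges[, 3]] + cell_tensions[tissue$edges[, 4]])
}

#' One Euler-Maruyama update of the tension OU process
#'
#' \eqn{\gamma' = \gamma - (dt/\tau_m)(\gamma - \gamma^0) +
#' \sqrt{2\sigma_i^2 dt/\tau_m}\, z}, clipped at zero.
#'
#' @param gamma current tensions.
#' @param gamma0 reference tensions.
#' @param params a \code{vm_params}.
#' @param dt time step (min); default \code{params$dt}.
#' @return List with \code{gamma} (updated) and \code{clipped} (count).
#' @export
ou_update <- function(gamma, gamma0, params, dt = params$dt) {
  g <- gamma - (dt / params$tau_m) * (gamma - gamma0) +
    sqrt(2 * params$sigma_i^2 * dt / params$tau_m) *
    stats::rnorm(length(gamma))
  nclip <- sum(g < 0)
  g[g < 0] <- 0
  list(gamma = g, clipped = nclip)
}

# Initialise tension state on a tissue: per-cell draws, per-edge reference
# tensions, instantaneous tensions started at the reference.
init_tension <- function(tissue, params) {
  cg <- draw_cell_tensions(params, length(tissue$cells))
  g0 <- reference_tensions(tissue, cg)
  list(cell_gamma = cg, gamma0 = g0, gamma = g0)
}

# Initial simulation state bundle.
sim_state <- function(tissue, params, tension = NULL) {
  if (is.null(tension)) tension <- init_tension(tissue, params)
  list(tissue = tissue, cache = build_cache(tissue),
       gamma = tension$gamma, gamma0 = tension$gamma0,
       cell_gamma = tension$cell_gamma,
       time = 0, events = list(), quartet_last = list(),
       clip_count = 0L, defer_count = 0L, n_events = 0L)
}

#' Advance the simulation by one time step
#'
#' Explicit Euler move of every vertex by \eqn{(dt/\alpha) f_i}, then an
#' OU update of every edge tension, then threshold-triggered T1 flips.
#'
#' @param state simulation state from \code{sim_state}.
#' @param params a \code{vm_params}.
#' @param noise logical; FALSE freezes tensions at their reference values
#'   (used by \code{relax_tissue}).
#' @return Updated state.
#' @export
sim_step <- function(state, params, noise = TRUE, dt = params$dt) {
  F <- vertex_forces(state$tissue, state$gamma, params, cache = state$cache)
  dxy <- (dt / params$alpha) * F
  if (max(abs(dxy)) > 0.5 * params$l_char) {
    stop(sprintf(paste0("numerical blow-up: max vertex displacement %.3g l ",
                        "in one step; reduce dt"), max(abs(dxy))))
  }
  state$tissue$pos <- wrap_point(state$tissue$pos + dxy, state$tissue$box)
  if (noise) {
    up <- ou_update(state$gamma, state$gamma0, params, dt = dt)
    state$gamma <- up$gamma
    state$clip_count <- state$clip_count + up$clipped
  }
  state <- handle_short_edges(state, params)
  state$time <- state$time + dt
  state
}

#' Flip all edges below the T1 threshold length
#'
#' Sub-threshold edges are processed in increasing length order; edges
#' sharing a vertex with an edge already flipped in this step are deferred
#' to the next step.  The new junction's reference tension is recomputed
#' from its new flanking cells and its instantaneous tension is reset to
#' that reference.  Events are appended to the log with reversal linkage.
#'
#' @param state simulation state.
#' @param params a \code{vm_params}.
#' @return Updated state.
#' @export
handle_short_edges <- function(state, params) {
  lens <- edge_lengths(state$tissue)
  short <- which(lens < params$l_T1)
  if (!length(short)) return(state)
  short_ids <- state$tissue$eid[short[order(lens[short])]]
  touched <- integer(0)
  for (eid in short_ids) {
    row <- match(eid, state$tissue$eid)
    if (is.na(row)) next  # edge vanished in an earlier flip this step
    vv <- state$tissue$edges[row, 1:2]
    if (any(vv %in% touched)) { state$defer_count <- state$defer_count + 1L; next }
    res <- t1_flip(state$tissue, eid, params$l_new)
    if (is.null(res$record)) { state$defer_count <- state$defer_count + 1L; next }
    old <- state$tissue
    state$tissue <- res$tissue
    # remap tension vectors onto the new edge table
    m <- match(state$tissue$eid, old$eid)
    gamma <- state$gamma[m]; gamma0 <- state$gamma0[m]
    nrow_new <- which(is.na(m))
    rec <- res$record
    g0 <- 0.5 * (state$cell_gamma[rec$gaining1] + state$cell_gamma[rec$gaining2])
    gamma0[nrow_new] <- g0
    gamma[nrow_new] <- g0
    state$gamma <- gamma; state$gamma0 <- gamma0
    touched <- c(touched, vv)
    # reversal linkage: same quartet, current losing pair equals the
    # previous event's gaining pair
    qkey <- paste(sort(c(rec$q1, rec$q2, rec$q3, rec$q4)), collapse = "_")
    prev <- state$quartet_last[[qkey]]
    rev_of <- NA_integer_
    if (!is.null(prev) &&
        setequal(c(rec$losing1, rec$losing2), prev$gaining)) {
      rev_of <- prev$id
    }
    state$n_events <- state$n_events + 1L
    ev <- data.frame(event_id = state$n_events, time_min = state$time,
                     rec, reversal_of = rev_of)
    state$events[[length(state$events) + 1L]] <- ev
    state$quartet_last[[qkey]] <- list(id = state$n_events,
                                       gaining = c(rec$gaining1, rec$gaining2))
    # rebuild row-dependent structures
    state$cache <- build_cache(state$tissue)
  }
  state
}

#' Relax a tissue to mechanical equilibrium without tension noise
#'
#' Iterates \code{sim_step} with tensions frozen at their reference values
#' until the maximum vertex force drops below \code{tol}.
#'
#' @param tissue a \code{vm_tissue}.
#' @param params a \code{vm_params}.
#' @param tension optional tension state (default: uniform at
#'   \code{gamma_mean}, i.e. no extrinsic spread).
#' @param tol force tolerance.
#' @param max_steps iteration cap.
#' @return List with \code{tissue}, \code{tension}, \code{steps},
#'   \code{residual}, and T1 \code{events} triggered during relaxation.
#' @export
relax_tissue <- function(tissue, params, tension = NULL, tol = 1e-3,
                         max_steps = 200000L) {
  if (is.null(tension)) {
    cg <- rep(params$gamma_mean, length(tissue$cells))
    tension <- list(cell_gamma = cg,
                    gamma0 = reference_tensions(tissue, cg))
    tension$gamma <- tension$gamma0
  } else {
    tension$gamma <- tension$gamma0
  }
  st <- sim_state(tissue, params, tension)
  for (k in seq_len(max_steps)) {
    F <- vertex_forces(st$tissue, st$gamma, params, cache = st$cache)
    res <- max(abs(F))
    if (res < tol) {
      return(list(tissue = st$tissue,
                  tension = list(cell_gamma = st$cell_gamma,
                                 gamma0 = st$gamma0, gamma = st$gamma),
                  steps = k - 1L, residual = res,
                  events = if (length(st$events)) do.call(rbind, st$events) else NULL))
    }
    # cap per-step displacement at 0.1 l (early relaxation forces can be
    # much larger than steady-state forces)
    dt_eff <- min(params$dt, 0.1 * params$l_char * params$alpha / res)
    st <- sim_step(st, params, noise = FALSE, dt = dt_eff)
  }
  stop(sprintf("relaxation did not converge in %d steps (residual %.3g)",
               max_steps, max(abs(F))))
}

#' Run a full stochastic vertex-model simulation
#'
#' Initializes the tissue (honeycomb or relaxed Voronoi), draws preferred
#' areas and extrinsic cell tensions, relaxes without intrinsic noise,
#' runs a burn-in, then integrates for \code{duration} minutes recording a
#' frame every \code{frame_interval} minutes (default 0.5 min, mirroring
#' 30 s imaging cadence) together with the full T1 event log.
#'
#' @param config list; recognised keys: \code{params} (a \code{vm_params}
#'   or list of overrides), \code{init} ("honeycomb" or "voronoi"),
#'   \code{n_cells}, \code{duration}, \code{frame_interval},
#'   \code{burn_in}, \code{seed}, \code{record_tissues} (logical; store a
#'   tissue snapshot per frame, needed for rasterization),
#'   \code{relax_tol}.
#' @return Object of class \code{vm_sim}: frames (per-frame edge tables),
#'   per-frame summary statistics, event log, initial/final tissue, run
#'   metadata.
#' @export
run_simulation <- function(config = list()) {
  cfg <- list(init = "honeycomb", n_cells = 64, duration = 30,
              frame_interval = 0.5, burn_in = 20, seed = 1L,
              record_tissues = FALSE, relax_tol = 1e-3)
  known <- c(names(cfg), "params")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  params <- if (inherits(cfg$params, "vm_params")) cfg$params
            else do.call(model_params, as.list(cfg$params))
  if (cfg$duration < 0) stop("duration must be >= 0")
  set.seed(cfg$seed)

  side <- sqrt(2 * params$A0_mean / (3 * sqrt(3)))
  tis <- if (cfg$init == "honeycomb") {
    nx <- max(2L, round(sqrt(cfg$n_cells)))
    ny <- max(2L, 2L * round(cfg$n_cells / nx / 2))
    build_honeycomb(nx, ny, side)
  } else if (cfg$init == "voronoi") {
    build_voronoi(cfg$n_cells, seed = NULL,
                  box = rep(sqrt(cfg$n_cells * params$A0_mean), 2))
  } else stop("init must be 'honeycomb' or 'voronoi'")

  ncell <- length(tis$cells)
  # preferred areas: normal, truncated positive, then rescaled so they sum
  # to the box area (the periodic tiling fixes the mean cell area)
  A0 <- stats::rnorm(ncell, params$A0_mean, params$sigma_A)
  while (any(A0 <= 0)) A0[A0 <= 0] <- stats::rnorm(sum(A0 <= 0),
                                                   params$A0_mean, params$sigma_A)
  tis$A0 <- A0 * prod(tis$box) / sum(A0)

  # relax with uniform tension (the extrinsic spread is part of the
  # fluctuating model and is switched on only after relaxation)
  rl <- relax_tissue(tis, params, tol = cfg$relax_tol)
  tis <- rl$tissue
  tension <- init_tension(tis, params)

  st <- sim_state(tis, params, tension)
  n_frames <- floor(cfg$duration / cfg$frame_interval) + 1L
  steps_per_frame <- max(1L, round(cfg$frame_interval / params$dt))
  burn_steps <- round(cfg$burn_in / params$dt)
  for (k in seq_len(burn_steps)) st <- sim_step(st, params)
  st$events <- list(); st$n_events <- 0L  # statistics start after burn-in
  st$time <- 0

  frames <- vector("list", n_frames)
  stats_rows <- vector("list", n_frames)
  snap <- function(st, fi) {
    lens <- edge_lengths(st$tissue)
    frames[[fi]] <<- list(
      time_min = (fi - 1) * cfg$frame_interval,  # exact grid
      edge_id = st$tissue$eid,
      length = lens,
      tension = st$gamma,
      tissue = if (cfg$record_tissues) st$tissue else NULL)
    sides <- lengths(st$tissue$cells)
    stats_rows[[fi]] <<- data.frame(
      time_min = (fi - 1) * cfg$frame_interval,
      disorder = stats::sd(sides) * sqrt((length(sides) - 1) / length(sides)),
      cv_length = pop_cv(lens),
      cv_tension = pop_cv(st$gamma),
      n_junctions = length(lens),
      n_cells = length(sides))
  }
  snap(st, 1L)
  n_junctions_t0 <- length(st$tissue$eid)
  if (n_frames > 1L) {
    for (fi in 2:n_frames) {
      for (k in seq_len(steps_per_frame)) st <- sim_step(st, params)
      snap(st, fi)
    }
  }
  events <- if (length(st$events)) do.call(rbind, st$events) else
    data.frame(event_id = integer(0), time_min = numeric(0),
               edge_old = integer(0), edge_new = integer(0),
               q1 = integer(0), q2 = integer(0), q3 = integer(0),
               q4 = integer(0), losing1 = integer(0), losing2 = integer(0),
               gaining1 = integer(0), gaining2 = integer(0),
               reversal_of = integer(0))
  out <- list(frames = frames, stats = do.call(rbind, stats_rows),
              events = events, params = params, config = cfg,
              tissue_final = st$tissue, n_junctions_t0 = n_junctions_t0,
              duration = st$time, clip_count = st$clip_count,
              defer_count = st$defer_count,
              total_steps = burn_steps + (n_frames - 1L) * steps_per_frame)
  class(out) <- "vm_sim"
  out
}

# population coefficient of variation (divide-by-n SD)
pop_cv <- function(x) {
  m <- mean(x)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  sqrt(mean((x - m)^2)) / m
}

#' @export
print.vm_sim <- function(x, ...) {
  cat(sprintf(paste0("vm_sim: %d frames over %.1f min, %d cells, ",
                     "%d junctions at t0, %d T1 events\n"),
              length(x$frames), x$duration,
              length(x$tissue_final$cells), x$n_junctions_t0,
              nrow(x$events)))
  invisible(x)
}
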