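# Summary statistics over tissues, trajectories and junction time series.
#
# Conventions: population (divide-by-n) standard deviations throughout;
# correlation lags on the frame grid; per-junction statistics computed
# junction by junction and then averaged.

#' T1 event rate per junction per minute
#'
#' @param events event log data.frame (or an event count).
#' @param n_junctions_t0 junction count in the frame at t = 0.
#' @param duration observation time (min).
#' @return Rate in events/min/junction.
#' @export
t1_rate <- function(events, n_junctions_t0, duration) {
  if (duration <= 0) stop("duration must be positive")
  if (n_junctions_t0 <= 0) stop("n_junctions_t0 must be positive")
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n / (n_junctions_t0 * duration)
}

#' Topological disorder: SD of per-cell neighbour counts
#'
#' @param tissue a \code{vm_tissue} (or an integer vector of side counts).
#' @return Population SD of the number of edges per cell.
#' @export
topological_disorder <- function(tissue) {
  sides <- if (inherits(tissue, "vm_tissue")) lengths(tissue$cells) else tissue
  if (length(sides) < 2) stop("need at least 2 cells")
  sqrt(mean((sides - mean(sides))^2))
}

#' Fractions of cells by neighbour count
#'
#' @param tissue a \code{vm_tissue} (or an integer vector of side counts).
#' @return Named numeric vector of fractions summing to one.
#' @export
polygon_fractions <- function(tissue) {
  sides <- if (inherits(tissue, "vm_tissue")) lengths(tissue$cells) else tissue
  tab <- table(sides)
  out <- as.numeric(tab) / length(sides)
  names(out) <- names(tab)
  out
}

#' Coefficient of variation of junction lengths across the tissue
#'
#' @param tissue a \code{vm_tissue} (or a numeric vector of lengths).
#' @return CV_L = population SD / mean.
#' @export
length_cv <- function(tissue) {
  lens <- if (inherits(tissue, "vm_tissue")) edge_lengths(tissue) else tissue
  if (length(lens) < 2) stop("need at least 2 edges")
  pop_cv(lens)
}

#' Snapshot coefficient of variation of tension (or intensity)
#'
#' Across-junction CV of instantaneous per-edge values at one time point.
#'
#' @param x numeric vector of per-junction values at one frame.
#' @return SD/mean (population convention).
#' @export
snapshot_tension_cv <- function(x) {
  if (length(x) < 2) stop("need at least 2 junctions")
  pop_cv(x)
}

#' Per-junction time series from a simulation
#'
#' Extracts aligned per-junction length and tension series for all
#' junctions present in every recorded frame (junctions that underwent a
#' T1 during the window are dropped, since their identity changed).
#'
#' @param sim a \code{vm_sim}.
#' @return List with matrices \code{length} and \code{tension}
#'   (junctions x frames), \code{time_min}, and \code{junction_id}.
#' @export
junction_series <- function(sim) {
  ids <- Reduce(intersect, lapply(sim$frames, function(f) f$edge_id))
  L <- vapply(sim$frames, function(f) f$length[match(ids, f$edge_id)],
              numeric(length(ids)))
  G <- vapply(sim$frames, function(f) f$tension[match(ids, f$edge_id)],
              numeric(length(ids)))
  if (length(ids) == 1L) { L <- matrix(L, 1); G <- matrix(G, 1) }
  list(length = L, tension = G,
       time_min = vapply(sim$frames, function(f) f$time_min, numeric(1)),
       junction_id = ids)
}

#' Junction-averaged normalized autocorrelation
#'
#' Per junction: \eqn{(\overline{I(t)I(t+\Delta t)} - \bar I^2)/\bar I^2}
#' with \eqn{\bar I} the junction's temporal mean; then averaged across
#' junctions.
#'
#' @param series junctions x frames matrix (a single series may be given
#'   as a vector).
#' @param dt frame interval (min).
#' @param max_lag maximum lag (min), default 10.
#' @return Object of class \code{vm_corr}: data.frame with \code{lag_min},
#'   \code{value}; attribute \code{n_junctions}.
#' @export
junction_autocorr <- function(series, dt, max_lag = 10) {
  if (is.null(dim(series))) series <- matrix(series, 1)
  nt <- ncol(series)
  K <- min(nt - 2L, floor(max_lag / dt))
  if (K < 1) stop("series too short for the requested max_lag")
  const <- apply(series, 1, function(x) stats::sd(x) == 0 || !all(is.finite(x)))
  n_const <- sum(const)
  curves <- matrix(0, nrow(series), K + 1L)
  for (j in which(!const)) {
    x <- series[j, ]
    m2 <- mean(x)^2
    curves[j, ] <- vapply(0:K, function(k) {
      (mean(x[1:(nt - k)] * x[(1 + k):nt]) - m2) / m2
    }, numeric(1))
  }
  value <- colMeans(curves[!const, , drop = FALSE])
  if (all(const)) value <- rep(0, K + 1L)
  out <- data.frame(lag_min = (0:K) * dt, value = value)
  attr(out, "n_junctions") <- nrow(series) - n_const
  attr(out, "n_constant") <- n_const
  class(out) <- c("vm_corr", "data.frame")
  out
}

#' Junction-averaged normalized cross-correlation and its extremal lag
#'
#' Per junction: deviations from the junction's own temporal mean,
#' normalized by the per-junction population SDs,
#' \eqn{\overline{\Delta a(t)\Delta b(t+\Delta t)}/(\sigma_a \sigma_b)};
#' averaged across junctions.  A positive lag of the minimum means
#' \code{a} leads \code{b}.
#'
#' @param series_a,series_b aligned junctions x frames matrices.
#' @param dt frame interval (min).
#' @param max_lag maximum |lag| (min), default 10.
#' @return \code{vm_corr} data.frame over symmetric lags, with attributes
#'   \code{lag_min_at_min} (lag of the minimum) and \code{n_excluded}.
#' @export
junction_crosscorr <- function(series_a, series_b, dt, max_lag = 10) {
  if (is.null(dim(series_a))) series_a <- matrix(series_a, 1)
  if (is.null(dim(series_b))) series_b <- matrix(series_b, 1)
  stopifnot(dim(series_a) == dim(series_b))
  nt <- ncol(series_a)
  K <- min(nt - 2L, floor(max_lag / dt))
  sda <- apply(series_a, 1, function(x) sqrt(mean((x - mean(x))^2)))
  sdb <- apply(series_b, 1, function(x) sqrt(mean((x - mean(x))^2)))
  ok <- sda > 0 & sdb > 0
  lags <- (-K):K
  curves <- matrix(0, nrow(series_a), length(lags))
  for (j in which(ok)) {
    da <- series_a[j, ] - mean(series_a[j, ])
    db <- series_b[j, ] - mean(series_b[j, ])
    curves[j, ] <- vapply(lags, function(k) {
      if (k >= 0) mean(da[1:(nt - k)] * db[(1 + k):nt])
      else mean(da[(1 - k):nt] * db[1:(nt + k)])
    }, numeric(1)) / (sda[j] * sdb[j])
  }
  value <- colMeans(curves[ok, , drop = FALSE])
  out <- data.frame(lag_min = lags * dt, value = value)
  attr(out, "n_junctions") <- sum(ok)
  attr(out, "n_excluded") <- sum(!ok)
  attr(out, "lag_min_at_min") <- lags[which.min(value)] * dt
  class(out) <- c("vm_corr", "data.frame")
  out
}

#' Fit an exponential decay to a correlation curve
#'
#' Nonlinear least squares of \eqn{y = a e^{-b x}} over nonnegative lags.
#' The printed-figure convention reports the coefficient of the exponent
#' with a negative sign; here \code{rate} is the positive decay rate and
#' \code{decorrelation_time = 1/rate}.
#'
#' @param curve a \code{vm_corr} (or data.frame with lag_min, value).
#' @param offset fit \eqn{y = a e^{-b x} + c} instead.  Correlation
#'   estimates built from each junction's own finite-series mean carry a
#'   small negative constant bias (approximately \eqn{-CV^2 S/n} with S
#'   the summed autocorrelation); the additive constant absorbs it so
#'   that \code{b} estimates the true decay rate.
#' @return List with \code{a}, \code{rate}, \code{decorrelation_time},
#'   standard errors \code{a_se}, \code{rate_se}, the fitted
#'   \code{offset_c}, and the \code{fit}.
#' @export
fit_exp_decay <- function(curve, offset = FALSE) {
  d <- curve[curve$lag_min >= 0, ]
  if (nrow(d) < 4) stop("need at least 4 nonnegative lag points")
  if (d$value[1] <= 0) stop("non-positive curve at lag 0; cannot fit decay")
  pos <- d$value > 0
  if (sum(pos) < 3) stop("curve has fewer than 3 positive values")
  lm0 <- stats::lm(log(value) ~ lag_min, data = d[pos, ])
  start <- list(a = exp(stats::coef(lm0)[[1]]),
                b = max(1e-6, -stats::coef(lm0)[[2]]))
  ctl <- stats::nls.control(maxiter = 200, warnOnly = TRUE, scaleOffset = 1)
  if (offset) {
    start$c <- min(d$value)
    fit <- stats::nls(value ~ a * exp(-b * lag_min) + c, data = d,
                      start = start, control = ctl)
  } else {
    fit <- stats::nls(value ~ a * exp(-b * lag_min), data = d, start = start,
                      control = ctl)
  }
  co <- summary(fit)$coefficients
  list(a = co["a", "Estimate"], rate = co["b", "Estimate"],
       decorrelation_time = 1 / abs(co["b", "Estimate"]),
       a_se = co["a", "Std. Error"], rate_se = co["b", "Std. Error"],
       offset_c = if (offset) co["c", "Estimate"] else 0,
       fit = fit)
}

#' Cumulative per-junction T1 count
#'
#' @param events event log with \code{time_min}.
#' @param n_junctions_t0 junction count at t = 0.
#' @return Step-curve data.frame (time_min, cum_per_junction).
#' @export
cumulative_t1_curve <- function(events, n_junctions_t0) {
  tt <- sort(events$time_min)
  data.frame(time_min = tt,
             cum_per_junction = seq_along(tt) / n_junctions_t0)
}

#' Fit a saturating exponential a(1 - exp(-b t)) to a cumulative curve
#'
#' @param curve data.frame (time_min, cum_per_junction).
#' @return List with \code{a}, \code{b}, standard errors and the fit.
#' @export
fit_saturating <- function(curve) {
  if (nrow(curve) < 2) stop("need at least 2 events to fit")
  y <- curve$cum_per_junction; t <- curve$time_min
  # starts: plateau slightly above the maximum, decay rate from a
  # log-linear fit of 1 - y/a0
  a0 <- max(y) * 1.05
  z <- 1 - y / a0
  ok <- z > 0
  b0 <- max(1e-6, -stats::coef(stats::lm(log(z[ok]) ~ 0 + t[ok]))[[1]])
  fit <- tryCatch(
    stats::nls(y ~ a * (1 - exp(-b * t)), start = list(a = a0, b = b0),
               control = stats::nls.control(maxiter = 500, warnOnly = TRUE,
                                            scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to direct least squares
    obj <- function(p) sum((y - p[1] * (1 - exp(-p[2] * t)))^2)
    op <- stats::optim(c(a0, b0), obj)
    return(list(a = op$par[1], b = op$par[2], a_se = NA_real_,
                b_se = NA_real_, fit = NULL))
  }
  co <- summary(fit)$coefficients
  list(a = co["a", "Estimate"], b = co["b", "Estimate"],
       a_se = co["a", "Std. Error"], b_se = co["b", "Std. Error"], fit = fit)
}

#' Windowed T1 rate from a cumulative curve
#'
#' Centered difference \eqn{(C(t+\Delta t/2) - C(t-\Delta t/2))/\Delta t}
#' of the cumulative step curve.
#'
#' @param curve data.frame (time_min, cum_per_junction).
#' @param window centered window width (min).
#' @param times evaluation grid; defaults to the event-time span.
#' @return data.frame (time_min, rate).
#' @export
windowed_rate <- function(curve, window, times = NULL) {
  C <- stats::approxfun(c(0, curve$time_min), c(0, curve$cum_per_junction),
                        method = "constant", rule = 2, f = 0)
  if (is.null(times)) {
    times <- seq(min(curve$time_min), max(curve$time_min), length.out = 50)
  }
  data.frame(time_min = times,
             rate = (C(times + window / 2) - C(times - window / 2)) / window)
}

#' Mean junction-length profiles aligned to T1 events
#'
#' For every event, the focal junction's length series (pre-flip identity
#' stitched to its post-flip identity) and the four first-neighbour
#' junction series are aligned at the four-way-vertex time; means and SDs
#' are taken across events.  The five-junction total tests length
#' conservation through the exchange.
#'
#' @param tracks track table: data.frame with junction_id, time_min,
#'   length (as from \code{sim_tracks} or the image pipeline).
#' @param events event log with time_min, edge_old, edge_new, n1..n4.
#' @param half_window half window (min).
#' @param dt frame interval (min).
#' @return List with \code{profile} data.frame (offset_min, focal_mean,
#'   focal_sd, neighbor_mean, total_mean, total_sd, n_events) and
#'   \code{n_excluded}.
#' @export
aligned_t1_profiles <- function(tracks, events, half_window, dt) {
  offs <- seq(-half_window, half_window, by = dt)
  series_of <- function(id) {
    s <- tracks[tracks$junction_id == id, ]
    if (nrow(s) < 2) return(function(t) rep(NA_real_, length(t)))
    stats::approxfun(s$time_min, s$length, rule = 1)
  }
  focal <- neigh <- total <- list()
  n_excluded <- 0L
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    # align on the frame grid: the pre-flip junction is last recorded at
    # the frame below the event time, the new junction from the next one
    t0 <- floor(ev$time_min / dt) * dt
    tq <- t0 + offs
    f_old <- series_of(ev$edge_old); f_new <- series_of(ev$edge_new)
    fo <- ifelse(offs <= 0, f_old(tq), f_new(tq))
    nb <- vapply(c(ev$n1, ev$n2, ev$n3, ev$n4),
                 function(id) series_of(id)(tq), numeric(length(offs)))
    if (anyNA(fo) || anyNA(nb)) { n_excluded <- n_excluded + 1L; next }
    focal[[length(focal) + 1L]] <- fo
    neigh[[length(neigh) + 1L]] <- rowMeans(nb)
    total[[length(total) + 1L]] <- fo + rowSums(nb)
  }
  if (!length(focal)) {
    return(list(profile = NULL, n_excluded = n_excluded))
  }
  Fm <- do.call(rbind, focal); Nm <- do.call(rbind, neigh)
  Tm <- do.call(rbind, total)
  psd <- function(M) apply(M, 2, function(x) sqrt(mean((x - mean(x))^2)))
  list(profile = data.frame(
    offset_min = offs,
    focal_mean = colMeans(Fm), focal_sd = psd(Fm),
    neighbor_mean = colMeans(Nm),
    total_mean = colMeans(Tm), total_sd = psd(Tm),
    n_events = nrow(Fm)),
    n_excluded = n_excluded)
}

#' Track table from a simulation
#'
#' Long-format per-junction series (junction_id, time_min, length,
#' tension) across all recorded frames.
#'
#' @param sim a \code{vm_sim}.
#' @return data.frame.
#' @export
sim_tracks <- function(sim) {
  do.call(rbind, lapply(sim$frames, function(f) {
    data.frame(junction_id = f$edge_id, time_min = f$time_min,
               length = f$length, tension = f$tension)
  }))
}

#' Frame-level summary statistics of a simulation
#'
#' @param sim a \code{vm_sim}.
#' @return The per-frame stats table with the run-level T1 rate as an
#'   attribute.
#' @export
sim_stats <- function(sim) {
  s <- sim$stats
  attr(s, "t1_rate") <- if (sim$duration > 0)
    t1_rate(sim$events, sim$n_junctions_t0, sim$duration) else 0
  s
}
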