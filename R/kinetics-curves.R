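# Cumulative sigmoidal size curves, logistic fits with lag time,
# nucleation/reversibility episode detection, energy-trace alignment, and
# (n_hbonds, n_contacts) structure maps.

#' Cumulative aggregate-size curves
#'
#' For each threshold s in 2..max_size, the probability of finding an
#' aggregate of at least size s at each time: an indicator for a single
#' run, the across-run fraction for an ensemble. Also reports the fraction
#' of peptides occurring as free monomers.
#'
#' @param runs a list of `cluster_partition` lists (one per run, same time
#'   grid), or a single partition list
#' @param max_size largest size threshold (default 9)
#' @return data.frame: time, monomer_fraction, ge2 .. ge<max_size>
#' @export
cumulative_size_curves <- function(runs, max_size = 9L) {
  if (length(runs) && inherits(runs[[1]], "cluster_partition")) runs <- list(runs)
  stopifnot(length(runs) >= 1L)
  nt <- length(runs[[1]])
  times <- vapply(runs[[1]], function(p) p$time, 1.0)
  largest <- vapply(runs, function(pp) vapply(pp, function(p) p$largest, 1L),
                    integer(nt))
  largest <- matrix(largest, nrow = nt)
  monf <- vapply(runs, function(pp) vapply(pp, function(p)
    length(p$monomers) / p$n_peptides, 1.0), numeric(nt))
  monf <- matrix(monf, nrow = nt)
  out <- data.frame(time = times, monomer_fraction = rowMeans(monf))
  for (s in 2:max_size)
    out[[paste0("ge", s)]] <- rowMeans(largest >= s)
  out
}

#' Least-squares logistic fit with lag-time extraction
#'
#' Fits y(t) = A / (1 + exp(-(t - t0)/tau)) and reports the lag time by
#' the standard tangent construction, lag = t0 - 2*tau. Data whose fit
#' quality (R^2) falls below `min_goodness`, or with no dynamic range, are
#' flagged non-sigmoidal and the parameters withheld.
#'
#' @param time,y numeric vectors (>= 10 points spanning the transition)
#' @param min_goodness minimum R^2 for an accepted fit
#' @return list: ok, amplitude, t0, tau, lag_time, goodness
#' @export
fit_sigmoid <- function(time, y, min_goodness = 0.9) {
  stopifnot(length(time) == length(y))
  bad <- list(ok = FALSE, amplitude = NA_real_, t0 = NA_real_,
              tau = NA_real_, lag_time = NA_real_, goodness = NA_real_)
  if (length(y) < 10L || sd(y) < 1e-12) return(bad)
  a0 <- max(y)
  t00 <- time[which.min(abs(y - a0 / 2))]
  tau0 <- max(diff(range(time)) / 10, 1e-6)
  fit <- tryCatch(suppressWarnings(
    nls(y ~ A / (1 + exp(-(time - t0) / tau)),
        start = list(A = a0, t0 = t00, tau = tau0),
        control = nls.control(maxiter = 200, tol = 1e-10, minFactor = 1e-10,
                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- coef(fit)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  if (!is.finite(r2) || r2 < min_goodness) { bad$goodness <- r2; return(bad) }
  list(ok = TRUE, amplitude = unname(p["A"]), t0 = unname(p["t0"]),
       tau = unname(p["tau"]),
       lag_time = unname(p["t0"] - 2 * p["tau"]), goodness = r2)
}

# first index at which cond stays TRUE for >= hold_time (truncated window
# at the series end counts if cond holds to the end)
.first_sustained <- function(times, cond, hold_time, from = 1L) {
  n <- length(cond)
  i <- from
  while (i <= n) {
    if (cond[i]) {
      j <- i
      while (j < n && cond[j + 1L]) j <- j + 1L
      if (times[j] - times[i] >= hold_time || j == n) return(i)
      i <- j + 1L
    }
    i <- i + 1L
  }
  NA_integer_
}

#' Nucleation and reversibility episodes in a largest-cluster-size series
#'
#' Nucleation: first time the largest cluster reaches at least `n_star`
#' sustained for `hold_time`. Reversal: subsequent drop of the largest
#' cluster below `dissolve_threshold` sustained for `hold_time`. Multiple
#' grow-dissolve episodes per run are supported.
#'
#' @param times time stamps (ps)
#' @param largest largest-cluster-size series
#' @param n_star nucleation size threshold (default 5, the critical
#'   nucleus scale)
#' @param hold_time sustain requirement, ps (default 500 ps = 0.5 ns)
#' @param dissolve_threshold reversal when largest < this (default 2,
#'   i.e. full dissolution to monomers)
#' @return list: `episodes` (data.frame nucleation_time, reversal_time),
#'   `n_episodes`, `n_reversals`, `reversal_fraction` (per episode) and
#'   `run_reversed` (any reversal in the run)
#' @export
detect_nucleation_and_reversibility <- function(times, largest, n_star = 5L,
                                                hold_time = 500,
                                                dissolve_threshold = 2L) {
  stopifnot(length(times) == length(largest))
  eps <- list()
  from <- 1L
  repeat {
    i <- .first_sustained(times, largest >= n_star, hold_time, from)
    if (is.na(i)) break
    j <- .first_sustained(times, largest < dissolve_threshold, hold_time,
                          from = i)
    eps[[length(eps) + 1L]] <- data.frame(
      nucleation_time = times[i],
      reversal_time = if (is.na(j)) NA_real_ else times[j])
    if (is.na(j)) break
    from <- j
  }
  episodes <- if (length(eps)) do.call(rbind, eps) else
    data.frame(nucleation_time = numeric(), reversal_time = numeric())
  nrev <- sum(!is.na(episodes$reversal_time))
  list(episodes = episodes, n_episodes = nrow(episodes), n_reversals = nrev,
       reversal_fraction = if (nrow(episodes)) nrev / nrow(episodes) else NA_real_,
       run_reversed = nrev > 0L)
}

#' Align energy traces at a threshold crossing and average
#'
#' Each trace is shifted in time so that its first crossing of `threshold`
#' (from above) sits at t = 0, then all traces are interpolated onto a
#' common grid spanning `window` on each side and averaged. Traces that
#' never cross are excluded with a warning.
#'
#' @param traces list of data.frames with columns `time` (ps) and `energy`
#'   (kcal/mol)
#' @param threshold alignment threshold, kcal/mol (default -80, roughly
#'   the midpoint of the aggregation energy drop)
#' @param window half-width of the common window, ps (default 5000 ps =
#'   5 ns on each side)
#' @param dt grid spacing, ps; defaults to the first trace's spacing
#' @return data.frame: time (relative), mean, sd, n (traces contributing)
#' @export
align_energy_traces <- function(traces, threshold = -80, window = 5000,
                                dt = NULL) {
  stopifnot(length(traces) >= 1L)
  shifted <- list()
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    idx <- which(tr$energy <= threshold)
    if (!length(idx)) {
      warning("trace ", k, " never reaches ", threshold, " kcal/mol; excluded")
      next
    }
    shifted[[length(shifted) + 1L]] <-
      data.frame(time = tr$time - tr$time[idx[1L]], energy = tr$energy)
  }
  if (!length(shifted)) stop("no trace crosses the alignment threshold")
  if (is.null(dt)) dt <- stats::median(diff(shifted[[1]]$time))
  grid <- seq(-window, window, by = dt)
  mat <- vapply(shifted, function(tr)
    approx(tr$time, tr$energy, xout = grid, rule = 1)$y, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  data.frame(time = grid,
             mean = rowMeans(mat, na.rm = TRUE),
             sd = apply(mat, 1, sd, na.rm = TRUE),
             n = rowSums(!is.na(mat)))
}

#' Structure maps over (n_hbonds, n_contacts)
#'
#' Three binned 2D maps over the hydrogen-bond count and side-chain
#' contact count plane: the last visit time, the visit density (normalized
#' to sum 1), and the mean parallel strand fraction. Empty bins are `NA`
#' (low-density discontinuities are a binning artifact, not data).
#'
#' @param metrics per-frame metrics data.frame from [cluster_timeseries()]
#' @param hb_bin,contact_bin bin widths on the two axes
#' @return list of class `structure_maps`: `last_time`, `density`,
#'   `parallel` matrices plus `hb_breaks`, `contact_breaks`
#' @export
structure_maps <- function(metrics, hb_bin = 2L, contact_bin = 5L) {
  hb <- metrics$n_hbonds; ct <- metrics$n_contacts
  hb_breaks <- seq(0, max(hb, 1) + hb_bin, by = hb_bin)
  ct_breaks <- seq(0, max(ct, 1) + contact_bin, by = contact_bin)
  bi <- findInterval(hb, hb_breaks, rightmost.closed = TRUE)
  bj <- findInterval(ct, ct_breaks, rightmost.closed = TRUE)
  ni <- length(hb_breaks) - 1L; nj <- length(ct_breaks) - 1L
  last_time <- matrix(NA_real_, ni, nj)
  dens <- matrix(0, ni, nj)
  psum <- matrix(0, ni, nj); pcnt <- matrix(0, ni, nj)
  for (k in seq_along(hb)) {
    i <- bi[k]; j <- bj[k]
    last_time[i, j] <- metrics$time[k]   # frames are in time order
    dens[i, j] <- dens[i, j] + 1
    if (!is.na(metrics$parallel_fraction[k])) {
      psum[i, j] <- psum[i, j] + metrics$parallel_fraction[k]
      pcnt[i, j] <- pcnt[i, j] + 1
    }
  }
  parallel <- ifelse(pcnt > 0, psum / pcnt, NA_real_)
  density <- dens / sum(dens)
  density[dens == 0] <- NA_real_
  structure(list(last_time = last_time, density = density,
                 parallel = parallel, hb_breaks = hb_breaks,
                 contact_breaks = ct_breaks),
            class = "structure_maps")
}
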