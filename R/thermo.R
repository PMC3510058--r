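# Occupancy statistics, free-energy profiles, critical-nucleus
# extraction, and the classical nucleation theory model.
#
# Free energies are reported in units of k_B*T throughout: F(n) =
# -ln P(n), shifted so that the minimum of the defined points is 0.
# A physical temperature is attached as a label; F/kBT and the nucleus
# location are invariant under it.

# Normalize partition inputs to a frames x sizes count matrix.
.size_matrix <- function(x, largest_only = FALSE) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "cluster_partition")) x <- list(x)
  stopifnot(length(x) >= 1L, inherits(x[[1]], "cluster_partition"))
  n <- x[[1]]$n_peptides
  m <- t(vapply(x, function(p) {
    if (largest_only) {
      h <- integer(n); h[p$largest] <- 1L; h
    } else p$size_hist
  }, integer(n)))
  m
}

#' Occupancy probability over aggregate sizes
#'
#' Pools per-frame aggregate-size counts across frames and runs into a
#' normalized occupancy P(n). Default weighting is per aggregate (each
#' aggregate present in a frame contributes one count at its size);
#' per-peptide weighting (each aggregate contributes its size) is also
#' available, since the choice is not standardized. Optionally splits the
#' input into k consecutive subsets to expose fluctuation bands.
#'
#' @param x list of `cluster_partition`s, list of such lists (runs), or a
#'   frames x sizes count matrix (e.g. KMC snapshots)
#' @param weighting `"per_aggregate"` (default) or `"per_peptide"`
#' @param largest_only count only the largest aggregate per frame
#' @param subsets number of consecutive subsets for fluctuation bands
#' @return list: `p` (named numeric over sizes), `counts`, and when
#'   `subsets > 1` a `p_subsets` matrix
#' @export
size_probability <- function(x, weighting = c("per_aggregate", "per_peptide"),
                             largest_only = FALSE, subsets = 1L) {
  weighting <- match.arg(weighting)
  if (is.list(x) && length(x) && is.list(x[[1]]) &&
      !inherits(x[[1]], "cluster_partition")) {
    m <- do.call(rbind, lapply(x, .size_matrix, largest_only = largest_only))
  } else {
    m <- .size_matrix(x, largest_only = largest_only)
  }
  if (!nrow(m) || sum(m) == 0) stop("size_probability: empty ensemble")
  w <- if (weighting == "per_peptide") seq_len(ncol(m)) else rep(1, ncol(m))
  tally <- colSums(m) * w
  p <- tally / sum(tally)
  names(p) <- seq_along(p)
  out <- list(p = p, counts = colSums(m), weighting = weighting)
  if (subsets > 1L) {
    grp <- cut(seq_len(nrow(m)), subsets, labels = FALSE)
    ps <- vapply(seq_len(subsets), function(g) {
      tg <- colSums(m[grp == g, , drop = FALSE]) * w
      tg / sum(tg)
    }, numeric(ncol(m)))
    out$p_subsets <- t(ps)
  }
  out
}

#' Free-energy profile from an occupancy distribution
#'
#' F(n) = -ln P(n) in k_B*T units, shifted so the minimum over defined
#' points is zero. F is undefined (NA) where P = 0 — gaps are never
#' imputed.
#'
#' @param p normalized occupancy (vector over the coordinate grid), or
#'   the result of [size_probability()]
#' @param temperature temperature label in K
#' @param coord coordinate values (defaults to `seq_along(p)`)
#' @return object of class `free_energy_profile`: coord, p, counts, f,
#'   temperature
#' @export
free_energy_profile <- function(p, temperature = 300, coord = NULL) {
  counts <- NULL
  if (is.list(p) && !is.null(p$p)) { counts <- p$counts; p <- p$p }
  if (all(p == 0)) stop("free_energy_profile: all-zero occupancy")
  if (abs(sum(p) - 1) > 1e-8) stop("free_energy_profile: P not normalized")
  if (is.null(coord)) coord <- seq_along(p)
  f <- ifelse(p > 0, -log(p), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  structure(list(coord = coord, p = unname(p), counts = counts, f = unname(f),
                 temperature = temperature),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("free-energy profile over", length(x$coord), "points (kB*T units), T =",
      x$temperature, "K\n")
  invisible(x)
}

#' Critical nucleus from a free-energy profile
#'
#' The critical nucleus is the argmax of F restricted to interior
#' coordinates (excluding both ends of the grid). Maxima tying within
#' `tol` (default 0.5 kB*T) around the argmax are reported as a range,
#' matching "between 4 and 5"-style statements. Profiles whose maximum
#' sits on the boundary of the defined points carry a no-nucleus flag.
#'
#' @param profile a `free_energy_profile` over aggregate size
#' @param tol plateau/tie tolerance in kB*T
#' @return list: `n_star`, `range` (c(lo, hi)), `f_max`, `no_nucleus`
#' @export
critical_nucleus <- function(profile, tol = 0.5) {
  stopifnot(inherits(profile, "free_energy_profile"))
  def <- which(!is.na(profile$f))
  if (length(def) < 3L)
    return(list(n_star = NA_integer_, range = c(NA, NA), f_max = NA_real_,
                no_nucleus = TRUE))
  interior <- def[def > min(def) & def < max(def)]
  # also exclude the grid's own ends (sizes 1 and N can never be a nucleus)
  interior <- interior[interior > 1L & interior < length(profile$f)]
  if (!length(interior))
    return(list(n_star = NA_integer_, range = c(NA, NA), f_max = NA_real_,
                no_nucleus = TRUE))
  imax <- interior[which.max(profile$f[interior])]
  fmax <- profile$f[imax]
  if (fmax <= max(profile$f[c(min(def), max(def))], na.rm = TRUE))
    return(list(n_star = NA_integer_, range = c(NA, NA), f_max = fmax,
                no_nucleus = TRUE))
  # contiguous plateau around the argmax within tol
  lo <- imax
  while ((lo - 1L) %in% interior && !is.na(profile$f[lo - 1L]) &&
         fmax - profile$f[lo - 1L] <= tol) lo <- lo - 1L
  hi <- imax
  while ((hi + 1L) %in% interior && !is.na(profile$f[hi + 1L]) &&
         fmax - profile$f[hi + 1L] <= tol) hi <- hi + 1L
  list(n_star = profile$coord[imax],
       range = c(profile$coord[lo], profile$coord[hi]),
       f_max = fmax, no_nucleus = FALSE)
}

#' Free-energy profile over the total beta-residue count
#'
#' Same estimator as [free_energy_profile()] with the coordinate being the
#' per-frame total number of residues in beta conformation. The critical
#' amount of secondary structure is the FIRST interior local maximum (the
#' later rise at high counts is a finite-size boundary effect: no more
#' monomers are available for growth — annotated, never corrected).
#'
#' @param beta_counts integer vector of per-frame total beta-residue
#'   counts (pooled over runs), or an `agg_trajectory` (computed via
#'   [beta_state_report()])
#' @param temperature temperature label (K)
#' @param criteria criteria used when `beta_counts` is a trajectory
#' @param tol tie tolerance in kB*T for the first-maximum search
#' @return list: `profile` (a `free_energy_profile` over counts),
#'   `critical` (first interior local maximum with range), `no_nucleus`
#' @export
beta_residue_free_energy <- function(beta_counts, temperature = 300,
                                     criteria = default_criteria(),
                                     tol = 0.5) {
  if (inherits(beta_counts, "agg_trajectory")) {
    traj <- beta_counts
    beta_counts <- vapply(traj$frames, function(fr)
      sum(beta_state_report(fr, traj$topology, criteria)$residue_flags$beta),
      1L)
  }
  grid <- 0:max(beta_counts)
  counts <- tabulate(beta_counts + 1L, nbins = length(grid))
  p <- counts / sum(counts)
  prof <- free_energy_profile(p, temperature, coord = grid)
  prof$counts <- counts
  f <- prof$f
  def <- which(!is.na(f))
  # first interior local maximum with prominence >= tol on both sides,
  # so counting noise cannot fake a barrier
  crit <- NULL
  for (k in seq_along(def)) {
    if (k == 1L || k == length(def)) next
    i <- def[k]
    prev <- def[k - 1L]; nxt <- def[k + 1L]
    if (f[i] < f[prev] || f[i] < f[nxt]) next
    left_min <- min(f[def[seq_len(k - 1L)]])
    right_min <- min(f[def[seq.int(k + 1L, length(def))]])
    if (f[i] - left_min < tol || f[i] - right_min < tol) next
    lo <- i; hi <- i
    while (lo > min(def) && !is.na(f[lo - 1L]) && f[i] - f[lo - 1L] <= tol)
      lo <- lo - 1L
    while (hi < max(def) && !is.na(f[hi + 1L]) && f[i] - f[hi + 1L] <= tol)
      hi <- hi + 1L
    crit <- list(count = grid[i], range = c(grid[lo], grid[hi]), f_max = f[i])
    break
  }
  list(profile = prof, critical = crit, no_nucleus = is.null(crit))
}

#' Classical nucleation theory free energy
#'
#' dG(n)/kBT = -n ln S + theta * n^(2/3): a bulk term driven by the
#' supersaturation S and a surface term with coefficient theta (in kB*T
#' units, encapsulating interfacial energy and geometry). For S > 1 the
#' barrier top is at n* = (2*theta / (3*ln S))^3 (exposed by
#' [cnt_nstar()]).
#'
#' @param n aggregate size(s), n >= 1
#' @param S supersaturation (dimensionless, > 0)
#' @param theta surface coefficient in kB*T units (>= 0)
#' @return dG in kB*T units
#' @export
cnt_free_energy <- function(n, S, theta) {
  if (S <= 0) stop("supersaturation S must be positive")
  if (theta < 0) stop("theta must be >= 0")
  if (any(n < 1)) stop("n must be >= 1")
  -n * log(S) + theta * n^(2 / 3)
}

#' Closed-form CNT barrier location
#' @param S supersaturation (> 1 for a barrier)
#' @param theta surface coefficient (kB*T units)
#' @return continuous n* (not rounded)
#' @export
cnt_nstar <- function(S, theta) {
  if (S <= 1) stop("cnt_nstar: barrier requires S > 1")
  (2 * theta / (3 * log(S)))^3
}

#' Fit the CNT model to a free-energy profile
#'
#' Least-squares fit of F(n) = c - n ln S + theta n^(2/3) (the additive
#' constant absorbs the profile's zero shift). For systems of at most 20
#' monomers a warning is attached: with so few peptides and a low critical
#' nucleus the continuous CNT expression cannot be fit reliably, and the
#' finite system size overestimates the nucleus — the fit must not be
#' silently trusted.
#'
#' @param profile a `free_energy_profile` over aggregate size (>= 4
#'   defined sizes)
#' @param small_system_max size at or below which the warning attaches
#' @return list: S, theta, goodness (R^2), degenerate flag, warning text
#'   (or NULL)
#' @export
cnt_fit <- function(profile, small_system_max = 20L) {
  stopifnot(inherits(profile, "free_energy_profile"))
  def <- which(!is.na(profile$f))
  if (length(def) < 4L) stop("cnt_fit: need >= 4 defined sizes")
  n <- profile$coord[def]; f <- profile$f[def]
  if (var(f) < 1e-12)
    return(list(S = NA_real_, theta = NA_real_, goodness = NA_real_,
                degenerate = TRUE, warning = "degenerate (flat) profile"))
  fit <- lm(f ~ n + I(n^(2 / 3)))
  co <- coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((f - mean(f))^2)
  wmsg <- NULL
  if (max(profile$coord) <= small_system_max) {
    wmsg <- paste("small finite system (<=", small_system_max, "monomers):",
                  "the continuous CNT form cannot be fit reliably and",
                  "finite size overestimates the critical nucleus;",
                  "do not trust this fit without external validation")
    warning(wmsg)
  }
  list(S = exp(-unname(co["n"])), theta = unname(co["I(n^(2/3))"]),
       goodness = r2, degenerate = FALSE, warning = wmsg)
}
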