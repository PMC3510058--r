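# Exact stochastic (Gillespie) aggregation simulator.
#
# Two modes:
#  * "multiset": the state is the full multiset of aggregate sizes;
#    channels are monomer attachment/detachment, oligomer fusion and
#    fragmentation, and direct monomers<->oligomer interconversion
#    (k >= 3). Propensities follow mass-action counting of reactant
#    combinations.
#  * "detailed_balance": a single tracked aggregate performs a
#    birth-death walk on sizes 1..N (the remaining peptides are free
#    monomers); detachment rates are derived from the attachment rates
#    and a target free-energy profile so the stationary distribution of
#    the walk is exactly exp(-F). This mode is the ground truth for
#    free-energy parameter-recovery tests.

#' Configuration for the Gillespie aggregation simulator
#'
#' @param n_peptides total peptides N (default 20)
#' @param mode `"detailed_balance"` or `"multiset"`
#' @param seed RNG seed: the single source of randomness
#' @param max_events number of events to simulate
#' @param t_max optional time horizon (whichever comes first)
#' @param attempt_rate base attachment attempt rate (1/ps)
#' @param target_profile free-energy profile F(n), kB*T units, length
#'   `n_peptides` (detailed-balance mode); detachment rates are derived
#'   from it
#' @param k_plus,k_minus per-size attachment/detachment rate constants
#'   (multiset mode; scalars or length-N vectors)
#' @param fusion_rate,frag_rate fusion/fragmentation rate constants
#' @param m2o_rate,o2m_rate direct monomers->oligomer / oligomer->monomers
#'   rate constants (k >= 3; 0 disables)
#' @param direct_max largest k for direct interconversion channels
#' @return object of class `kmc_config`
#' @export
kmc_config <- function(n_peptides = 20L,
                       mode = c("detailed_balance", "multiset"),
                       seed = 1L, max_events = 1e4, t_max = Inf,
                       attempt_rate = 1,
                       target_profile = NULL,
                       k_plus = 0.01, k_minus = 0.2,
                       fusion_rate = 0.002, frag_rate = 0.02,
                       m2o_rate = 0.001, o2m_rate = 0.005,
                       direct_max = 4L) {
  mode <- match.arg(mode)
  if (mode == "detailed_balance" && is.null(target_profile))
    target_profile <- barrier_profile(n_peptides)
  if (!is.null(target_profile) && length(target_profile) != n_peptides)
    stop("target_profile must have length n_peptides")
  cfg <- list(n_peptides = as.integer(n_peptides), mode = mode,
              seed = as.integer(seed), max_events = max_events, t_max = t_max,
              attempt_rate = attempt_rate, target_profile = target_profile,
              k_plus = rep_len(k_plus, n_peptides),
              k_minus = rep_len(k_minus, n_peptides),
              fusion_rate = fusion_rate, frag_rate = frag_rate,
              m2o_rate = m2o_rate, o2m_rate = o2m_rate,
              direct_max = as.integer(direct_max))
  class(cfg) <- "kmc_config"
  cfg
}

#' Reference nucleation-barrier free-energy profile
#'
#' The default "reference-barrier" stated world for a 20-peptide system: F rises
#' linearly from 0 at n = 1 to a barrier of 2.5 kB*T at n = 5 (the
#' critical nucleus), then decreases linearly to -2 kB*T at n = N
#' (aggregated state stable but reversible).
#'
#' @param n_peptides system size (>= 6)
#' @param barrier barrier height at `n_star`, kB*T
#' @param n_star barrier location
#' @param f_final free energy of the full aggregate, kB*T
#' @return numeric vector F(1..N) in kB*T units
#' @export
barrier_profile <- function(n_peptides = 20L, barrier = 2.5, n_star = 5L,
                               f_final = -2) {
  stopifnot(n_peptides > n_star, n_star >= 2L)
  f <- numeric(n_peptides)
  f[1:n_star] <- barrier * (0:(n_star - 1L)) / (n_star - 1L)
  f[n_star:n_peptides] <- barrier + (f_final - barrier) *
    (0:(n_peptides - n_star)) / (n_peptides - n_star)
  f
}

.kmc_db <- function(cfg) {
  N <- cfg$n_peptides
  f <- cfg$target_profile
  nu <- cfg$attempt_rate
  b <- rep(nu, N); b[N] <- 0                 # birth n -> n+1
  d <- c(0, nu * exp(f[-1] - f[-N]))         # death n -> n-1 (detailed balance)
  rtot <- b + d
  pup <- ifelse(rtot > 0, b / rtot, 0)
  nev <- as.integer(cfg$max_events)
  states <- integer(nev + 1L)
  states[1L] <- 1L
  u <- runif(nev)
  s <- 1L
  for (i in seq_len(nev)) {
    s <- if (u[i] < pup[s]) s + 1L else s - 1L
    states[i + 1L] <- s
  }
  hold <- rexp(nev + 1L, rtot[states])
  times <- c(0, cumsum(hold[-length(hold)]))
  up <- diff(states) > 0L
  before <- states[-length(states)]
  log <- data.frame(
    time = times[-1L],
    type = ifelse(up, "monomer_addition", "monomer_loss"),
    sizes_before = ifelse(up, paste0(before, "+1"), as.character(before)),
    sizes_after = ifelse(up, as.character(before + 1L),
                         paste0(before - 1L, "+1")),
    association = up, stringsAsFactors = FALSE)
  list(states = states, times = times, holding = hold, log = log)
}

# Precompute the full reaction-channel table for the multiset mode:
# per channel its type, a rate constant, how the propensity depends on
# the current histogram h, and the size changes it applies.
.kmc_channels <- function(cfg) {
  N <- cfg$n_peptides
  ch <- list()
  add <- function(type, kind, const, s1 = NA_integer_, s2 = NA_integer_,
                  before, after) {
    ch[[length(ch) + 1L]] <<- list(type = type, kind = kind, const = const,
                                   s1 = s1, s2 = s2, before = before,
                                   after = after)
  }
  add("monomer_addition", "pair11", cfg$k_plus[1L], 1L, 1L, c(1L, 1L), 2L)
  for (s in 2:(N - 1L))
    add("monomer_addition", "pair", cfg$k_plus[s], s, 1L, c(s, 1L), s + 1L)
  for (s in 2:N)
    add("monomer_loss", "single", cfg$k_minus[s], s, NA, s, c(s - 1L, 1L))
  for (a in 2:N) for (b2 in a:N) {
    if (a + b2 > N) break
    add("fusion", if (a == b2) "pair11" else "pair", cfg$fusion_rate,
        a, b2, c(a, b2), a + b2)
  }
  if (N >= 4L) for (s in 4:N) for (a in 2:(s %/% 2L))
    add("fragmentation", "single", cfg$frag_rate, s, NA, s, c(a, s - a))
  if (cfg$direct_max >= 3L) for (k in 3:min(cfg$direct_max, N)) {
    if (cfg$m2o_rate > 0)
      add("monomers_to_oligomer", "atleast", cfg$m2o_rate, 1L, k,
          rep(1L, k), k)
    if (cfg$o2m_rate > 0)
      add("oligomer_to_monomers", "single", cfg$o2m_rate, k, NA,
          k, rep(1L, k))
  }
  list(type = vapply(ch, `[[`, "", "type"),
       kind = vapply(ch, `[[`, "", "kind"),
       const = vapply(ch, `[[`, 1.0, "const"),
       s1 = vapply(ch, `[[`, 1L, "s1"),
       s2 = vapply(ch, function(x) as.integer(x$s2), 1L),
       before = lapply(ch, `[[`, "before"),
       after = lapply(ch, `[[`, "after"))
}

.kmc_multiset <- function(cfg) {
  N <- cfg$n_peptides
  tab <- .kmc_channels(cfg)
  kind <- tab$kind; s1 <- tab$s1; s2 <- tab$s2; const <- tab$const
  i_pair <- kind == "pair"; i_p11 <- kind == "pair11"
  i_single <- kind == "single"; i_atleast <- kind == "atleast"
  h <- integer(N); h[1L] <- N                # all monomers
  t <- 0
  nev <- as.integer(cfg$max_events)
  snapshots <- matrix(0L, nev + 1L, N)
  snapshots[1L, ] <- h
  ev_time <- numeric(nev); ev_ch <- integer(nev)
  prop <- numeric(length(const))
  i <- 0L
  repeat {
    if (i >= nev || t >= cfg$t_max) break
    prop[i_pair] <- const[i_pair] * h[s1[i_pair]] * h[s2[i_pair]]
    prop[i_p11] <- const[i_p11] * h[s1[i_p11]] * (h[s1[i_p11]] - 1L) / 2
    prop[i_single] <- const[i_single] * h[s1[i_single]]
    prop[i_atleast] <- const[i_atleast] * (h[s1[i_atleast]] >= s2[i_atleast])
    ptot <- sum(prop)
    if (ptot <= 0) break                     # absorbing state: clean stop
    t <- t + rexp(1L, ptot)
    if (t >= cfg$t_max) break
    pick <- sample.int(length(prop), 1L, prob = prop)
    for (s in tab$before[[pick]]) h[s] <- h[s] - 1L
    for (s in tab$after[[pick]]) h[s] <- h[s] + 1L
    i <- i + 1L
    snapshots[i + 1L, ] <- h
    ev_time[i] <- t; ev_ch[i] <- pick
  }
  log <- if (i > 0L) {
    idx <- ev_ch[seq_len(i)]
    data.frame(
      time = ev_time[seq_len(i)],
      type = tab$type[idx],
      sizes_before = vapply(tab$before[idx], function(s)
        paste(sort(s, decreasing = TRUE), collapse = "+"), ""),
      sizes_after = vapply(tab$after[idx], function(s)
        paste(sort(s, decreasing = TRUE), collapse = "+"), ""),
      association = tab$type[idx] %in% .ASSOC_TYPES,
      stringsAsFactors = FALSE)
  } else .event_row(0, "monomer_addition", 1, 1)[0, ]
  list(snapshots = snapshots[seq_len(i + 1L), , drop = FALSE], log = log,
       early_stop = i < nev)
}

#' Run the Gillespie aggregation simulator
#'
#' @param cfg a `kmc_config`
#' @return object of class `kmc_trace`: `log` (event data.frame with
#'   time, type, sizes), plus mode-specific state history —
#'   detailed-balance: `states`, `times`, `holding` (tracked aggregate
#'   size walk); multiset: `snapshots` (events+1 x N size histograms).
#'   Identical seeds give identical traces.
#' @export
gillespie_aggregation <- function(cfg) {
  stopifnot(inherits(cfg, "kmc_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  out <- if (cfg$mode == "detailed_balance") .kmc_db(cfg) else .kmc_multiset(cfg)
  out$config <- cfg
  class(out) <- "kmc_trace"
  out
}

#' @export
print.kmc_trace <- function(x, ...) {
  cat("KMC trace (", x$config$mode, "): ", nrow(x$log), " events, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Occupancy distribution of the tracked aggregate size (detailed balance)
#'
#' Holding-time-weighted occupancy of the birth-death walk — the exact
#' estimator whose stationary expectation is the target Boltzmann
#' distribution exp(-F)/Z.
#'
#' @param trace a detailed-balance `kmc_trace`
#' @param burn_in fraction of initial events discarded for equilibration
#' @return named numeric P(n) over 1..N (sums to 1), with attribute
#'   `visits` (number of visits per size after burn-in)
#' @export
kmc_occupancy <- function(trace, burn_in = 0.1) {
  stopifnot(inherits(trace, "kmc_trace"),
            trace$config$mode == "detailed_balance")
  n <- length(trace$states)
  keep <- seq.int(floor(burn_in * n) + 1L, n)
  N <- trace$config$n_peptides
  w <- vapply(split(trace$holding[keep], factor(trace$states[keep],
                                                levels = 1:N)), sum, 1.0)
  visits <- tabulate(trace$states[keep], nbins = N)
  structure(setNames(w / sum(w), 1:N), visits = visits)
}

#' Size histograms of a multiset KMC trace as a frames x sizes matrix
#'
#' @param trace a multiset-mode `kmc_trace`
#' @return integer matrix suitable for [size_probability()]
#' @export
kmc_size_matrix <- function(trace) {
  stopifnot(inherits(trace, "kmc_trace"))
  if (!is.null(trace$snapshots)) return(trace$snapshots)
  N <- trace$config$n_peptides
  t(vapply(trace$states, function(s) {
    h <- integer(N); h[s] <- 1L
    if (N - s > 0L) h[1L] <- h[1L] + (N - s)
    if (s == 1L) h[1L] <- N
    h
  }, integer(N)))
}
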