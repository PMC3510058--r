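# Lineage matching, event classification, rates, totals, curves,
# episodes, energy alignment, structure maps.

test_that("classify_transition recognizes the primitive event types", {
  cases <- list(
    list(c(5, 1), 6, "monomer_addition"),
    list(c(1, 1), 2, "monomer_addition"),
    list(6, c(5, 1), "monomer_loss"),
    list(c(3, 4), 7, "fusion"),
    list(7, c(3, 4), "fragmentation"),
    list(c(1, 1, 1), 3, "monomers_to_oligomer"),
    list(3, c(1, 1, 1), "oligomer_to_monomers"))
  for (cs in cases) {
    ev <- classify_transition(cs[[1]], cs[[2]])
    expect_equal(nrow(ev), 1)
    expect_equal(ev$type, cs[[3]])
  }
  expect_equal(nrow(classify_transition(c(3, 1), c(3, 1))), 0)
  expect_error(classify_transition(c(3, 1), 5), "mass")
})

test_that("compound transitions decompose deterministically and replay", {
  set.seed(31)
  for (k in 1:200) {
    n <- 20L
    # random before/after multisets with equal mass (<= 20)
    repeat {
      b <- sort(sample(1:6, sample(2:5, 1), replace = TRUE))
      a <- sort(sample(1:6, sample(2:5, 1), replace = TRUE))
      if (sum(b) == sum(a) && sum(b) <= 20) break
    }
    pad <- n - sum(b)
    B <- c(b, rep(1L, pad)); A <- c(a, rep(1L, pad))
    ev <- classify_transition(B, A, time = 1)
    hist0 <- tabulate(B, n)
    final <- replay_events(hist0, ev)[nrow(ev) + 1L, ]
    expect_identical(final, tabulate(A, n))
  }
})

test_that("time reversal mirrors the event-type multiset", {
  set.seed(17)
  for (k in 1:50) {
    repeat {
      b <- sample(1:6, sample(1:4, 1), replace = TRUE)
      a <- sample(1:6, sample(1:4, 1), replace = TRUE)
      if (sum(b) == sum(a)) break
    }
    fwd <- classify_transition(b, a)
    rev_ <- classify_transition(a, b)
    mirror <- c(monomer_addition = "monomer_loss",
                monomer_loss = "monomer_addition",
                fusion = "fragmentation", fragmentation = "fusion",
                monomers_to_oligomer = "oligomer_to_monomers",
                oligomer_to_monomers = "monomers_to_oligomer")
    expect_identical(sort(unname(mirror[fwd$type])), sort(rev_$type))
  }
})

test_that("match_clusters inheritance equals the max-overlap oracle", {
  set.seed(23)
  for (k in 1:30) {
    parts <- random_partition_sequence(8, 2)
    mp <- match_clusters(parts[[1]], parts[[2]])
    units_before <- c(parts[[1]]$clusters, as.list(parts[[1]]$monomers))
    for (j in seq_len(nrow(mp$inherits))) {
      target <- parts[[2]]$clusters[[mp$inherits$to[j]]]
      expect_equal(mp$inherits$from[j], oracle_best_source(target, units_before))
    }
  }
  # unchanged partition: identity, no event groups
  p <- partition_from_clusters(list(1:3, 4:5), 10, 0)
  p2 <- partition_from_clusters(list(1:3, 4:5), 10, 1)
  mp <- match_clusters(p, p2)
  expect_equal(mp$inherits$from, c(1, 2))
  expect_equal(length(mp$groups), 0)
})

test_that("classified events replay to every histogram (scripted)", {
  set.seed(41)
  for (k in 1:10) {
    parts <- random_partition_sequence(20, 25)
    expect_replay_consistent(parts)
  }
  # spec headline scripts
  growth <- lapply(seq_len(20), function(i)
    partition_from_clusters(if (i == 1) list() else list(1:i), 20, i - 1))
  ev <- classify_events(growth)
  expect_equal(nrow(ev), 19)
  expect_true(all(ev$type == "monomer_addition"))
  fus <- script_fusion(5, 5)
  parts <- lapply(fus$directives, function(d)
    partition_from_clusters(d$clusters, 20, d$time))
  ev2 <- classify_events(parts)
  expect_equal(ev2$type, "fusion")
  expect_equal(ev2$sizes_after, "10")
})

test_that("rate_series implements the per-bin definition with conservation", {
  ev <- classify_transition(c(4, 1, rep(1, 15)), c(5, rep(1, 15)), time = 4)
  rs <- rate_series(ev, bin_width = 5, n_max = 20, t_range = c(0, 5))
  expect_equal(unname(rs$rates["c_mono", 5, 1]), 0.2)
  expect_equal(unname(rs$rates["d_mono", 4, 1]), 0.2)
  expect_equal(unname(rs$rates["d_mono", 1, 1]), 0.2)
  expect_equal(sum(rs$net_counts * (1:20)), 0)
  # empty stream
  e0 <- classify_events(list(partition_from_clusters(list(), 5, 0),
                             partition_from_clusters(list(), 5, 1)))
  rs0 <- rate_series(e0, bin_width = 1)
  expect_true(all(rs0$counts == 0))
  expect_error(rate_series(ev, bin_width = 1, save_interval = 7.5),
               "save interval")
  # conservation holds per bin on random streams
  set.seed(8)
  parts <- random_partition_sequence(20, 40)
  evr <- classify_events(parts)
  rsr <- rate_series(evr, bin_width = 5, n_max = 20)
  expect_lt(max(abs(colSums(rsr$net_counts * (1:20)))), 1e-12)
  expect_true(all(rsr$counts >= 0))
})

test_that("event totals count single vs multi per bin", {
  adds <- do.call(rbind, lapply(1:3, function(i)
    classify_transition(c(i + 1, 1), i + 2, time = 1)))
  fus <- classify_transition(c(3, 2), 5, time = 2)
  et <- event_totals(rbind(adds, fus), bin_width = 5, t_range = c(0, 5))
  expect_equal(et$m_single_assoc, 3L)
  expect_equal(et$m_multi_assoc, 1L)
  expect_equal(et$fusion, 1L)
  e0 <- adds[0, ]
  expect_true(all(event_totals(e0, 5)[, 3:6] == 0))
})

test_that("KMC event totals equal the simulator's own log", {
  tr <- gillespie_aggregation(kmc_config(mode = "multiset", seed = 12,
                                         max_events = 1500))
  # classify from the snapshots, independent of the log's own types
  evs <- list()
  for (i in seq_len(nrow(tr$snapshots) - 1L)) {
    h1 <- tr$snapshots[i, ]; h2 <- tr$snapshots[i + 1L, ]
    d <- h2 - h1
    before <- rep(seq_along(d), pmax(-d, 0))
    after <- rep(seq_along(d), pmax(d, 0))
    evs[[i]] <- classify_transition(before, after, time = tr$log$time[i])
  }
  ev <- do.call(rbind, evs)
  expect_equal(nrow(ev), nrow(tr$log))
  expect_equal(table(ev$type), table(tr$log$type))
  et1 <- event_totals(ev, bin_width = diff(range(tr$log$time)) / 7)
  et2 <- event_totals(tr$log, bin_width = diff(range(tr$log$time)) / 7)
  expect_equal(et1, et2)
})

test_that("cumulative size curves are ordered steps with correct recounts", {
  growth <- lapply(seq_len(12), function(i)
    partition_from_clusters(if (i == 1) list() else list(1:i), 20, i - 1))
  cc <- cumulative_size_curves(growth, max_size = 9)
  # single run: indicator; step times non-decreasing in s
  steps <- vapply(2:9, function(s) min(cc$time[cc[[paste0("ge", s)]] > 0]), 1.0)
  expect_true(all(diff(steps) >= 0))
  expect_true(all(cc$ge2 %in% c(0, 1)))
  # recount oracle
  for (s in 2:9) {
    oracle <- vapply(growth, function(p) as.numeric(p$largest >= s), 1.0)
    expect_equal(cc[[paste0("ge", s)]], oracle)
  }
  mono <- lapply(1:5, function(i) partition_from_clusters(list(), 20, i))
  cm <- cumulative_size_curves(mono)
  expect_true(all(cm$monomer_fraction == 1))
  expect_true(all(as.matrix(cm[, -(1:2)]) == 0))
  # ensemble: fractions across runs
  ens <- cumulative_size_curves(list(growth, mono[rep(1, 12)]), max_size = 5)
  expect_true(all(ens$ge3 %in% c(0, 0.5)))
})

test_that("sigmoid fits recover exact and noisy logistic data", {
  t <- seq(0, 100, length.out = 60)
  y <- 0.8 / (1 + exp(-(t - 45) / 6))
  f <- fit_sigmoid(t, y)
  expect_true(f$ok)
  expect_equal(f$amplitude, 0.8, tolerance = 1e-6)
  expect_equal(f$t0, 45, tolerance = 1e-6)
  expect_equal(f$tau, 6, tolerance = 1e-6)
  expect_equal(f$lag_time, 45 - 12, tolerance = 1e-5)
  expect_false(fit_sigmoid(t, rep(0.4, 60))$ok)
  # noisy recovery: median parameter error < 10% over replicates
  set.seed(55)
  errs <- replicate(30, {
    yn <- y + rnorm(60, sd = 0.05 * 0.8)
    fn <- fit_sigmoid(t, yn, min_goodness = 0.8)
    if (fn$ok) abs(fn$t0 - 45) / 45 else NA_real_
  })
  expect_lt(median(errs, na.rm = TRUE), 0.10)
})

test_that("nucleation episodes and reversals are detected", {
  st <- script_grow_dissolve(10, final_size = 6, dt = 1, hold = 3)
  parts <- lapply(st$directives, function(d)
    partition_from_clusters(d$clusters, 10, d$time))
  largest <- vapply(parts, function(p) p$largest, 1L)
  times <- vapply(parts, function(p) p$time, 1.0)
  eps <- detect_nucleation_and_reversibility(times, largest, n_star = 5,
                                             hold_time = 2,
                                             dissolve_threshold = 2)
  expect_equal(eps$n_episodes, 2)
  expect_equal(eps$n_reversals, 1)
  expect_equal(eps$reversal_fraction, 0.5)
  expect_true(eps$run_reversed)
  # monotone growth: one episode, no reversal
  g <- seq_len(20)
  epg <- detect_nucleation_and_reversibility(seq_along(g), g, 5, 2, 2)
  expect_equal(epg$n_episodes, 1)
  expect_equal(epg$n_reversals, 0)
})

test_that("energy traces align at the threshold crossing", {
  t <- seq(0, 30000, by = 75)
  drop <- function(t0) -600 / (1 + exp(-(t - t0) / 400)) + 200
  # shifts that are exact multiples of the sampling interval: the sampled
  # sequences are identical, so alignment must superpose them exactly
  tr1 <- data.frame(time = t, energy = drop(8000))
  tr2 <- data.frame(time = t, energy = drop(8000 + 90 * 75))
  prof <- align_energy_traces(list(tr1, tr2), threshold = -80, window = 5000)
  expect_true(all(prof$sd[prof$n == 2] < 1e-9))   # shifted copies align exactly
  expect_equal(max(prof$mean, na.rm = TRUE) - min(prof$mean, na.rm = TRUE),
               600, tolerance = 0.02)
  flat <- data.frame(time = t, energy = rep(100, length(t)))
  expect_warning(align_energy_traces(list(tr1, flat)), "never reaches")
  # noisy amplitude recovery
  set.seed(77)
  traces <- lapply(1:5, function(i)
    data.frame(time = t, energy = drop(runif(1, 6000, 20000)) + rnorm(length(t), sd = 15)))
  profn <- align_energy_traces(traces, -80, 5000)
  amp <- max(profn$mean, na.rm = TRUE) - min(profn$mean, na.rm = TRUE)
  expect_equal(amp, 600, tolerance = 0.05)
})

test_that("structure maps bin correctly and normalize density", {
  m1 <- data.frame(time = c(1, 2, 3), n_hbonds = c(10, 10, 10),
                   n_contacts = c(40, 40, 40),
                   parallel_fraction = c(0.5, 0.7, 0.9))
  maps <- structure_maps(m1)
  expect_equal(sum(maps$density, na.rm = TRUE), 1)
  expect_equal(sum(!is.na(maps$density)), 1)      # single occupied bin
  occ <- which(!is.na(maps$last_time), arr.ind = TRUE)
  expect_equal(maps$last_time[occ], 3)            # last visit wins
  expect_equal(maps$parallel[occ], 0.7)           # mean parallel fraction
  # two-phase: early coil region, late sheet region
  m2 <- data.frame(time = 1:20,
                   n_hbonds = c(rep(2, 10), rep(80, 10)),
                   n_contacts = c(rep(5, 10), rep(150, 10)),
                   parallel_fraction = NA_real_)
  maps2 <- structure_maps(m2)
  expect_equal(sum(!is.na(maps2$density)), 2)
  expect_equal(sum(maps2$density, na.rm = TRUE), 1)
  lt <- maps2$last_time[!is.na(maps2$last_time)]
  expect_true(10 %in% lt && 20 %in% lt)
})
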