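# Scripted trajectories: geometric realization of a prescribed sequence
# of cluster partitions, returned together with the ground truth the
# kinetics stage must reproduce.

#' Construct a cluster partition directly from member lists
#'
#' Ground-truth constructor used by the scripted-scenario generator and
#' by tests; performs the same bookkeeping as [clusters()] without a
#' strand graph (orientation statistics are NA).
#'
#' @param cluster_list list of integer vectors (disjoint, sizes >= 2)
#' @param n_peptides total number of peptides
#' @param time frame time (ps)
#' @return a `cluster_partition`
#' @export
partition_from_clusters <- function(cluster_list, n_peptides, time = 0) {
  members <- unlist(cluster_list)
  if (anyDuplicated(members)) stop("peptide in two clusters")
  if (length(members) && (max(members) > n_peptides || min(members) < 1L))
    stop("peptide index out of range")
  if (any(vapply(cluster_list, length, 1L) < 2L))
    stop("clusters must have >= 2 members")
  cluster_list <- lapply(cluster_list, function(x) sort(as.integer(x)))
  ord <- order(vapply(cluster_list, min, 1L))
  cluster_list <- cluster_list[ord]
  monomers <- setdiff(seq_len(n_peptides), members)
  sizes <- vapply(cluster_list, length, 1L)
  size_hist <- tabulate(c(sizes, rep(1L, length(monomers))), nbins = n_peptides)
  structure(list(time = time, n_peptides = n_peptides,
                 clusters = cluster_list, monomers = monomers,
                 size_hist = size_hist, parallel_fraction = NA_real_,
                 cluster_parallel = rep(NA_real_, length(cluster_list)),
                 largest = if (length(sizes)) max(sizes) else 1L),
            class = "cluster_partition")
}

#' Scenario script
#'
#' An ordered list of (time, clusters) directives; the partition holds
#' until the next directive. Directives must be realizable: clusters
#' disjoint, member indices within 1..n_peptides.
#'
#' @param directives list of `list(time =, clusters = list(...))`
#' @param n_peptides total peptides (default 20)
#' @param box_edge cubic box (Angstrom)
#' @param noise coordinate noise amplitude (Angstrom) added to realized
#'   frames (default 0: fully deterministic)
#' @return object of class `scenario_script`
#' @export
scenario_script <- function(directives, n_peptides = 20L, box_edge = 200,
                            noise = 0) {
  stopifnot(length(directives) >= 1L)
  times <- vapply(directives, function(d) d$time, 1.0)
  if (any(diff(times) <= 0)) stop("directive times must be strictly increasing")
  for (d in directives)
    partition_from_clusters(d$clusters, n_peptides, d$time)  # validates
  structure(list(directives = directives, n_peptides = n_peptides,
                 box_edge = box_edge, noise = noise),
            class = "scenario_script")
}

# 20 well-separated lattice sites inside the box
.lattice_site <- function(k, box_edge) {
  spacing <- box_edge / 3.4
  i <- (k - 1L) %% 3L; j <- ((k - 1L) %/% 3L) %% 3L; l <- (k - 1L) %/% 9L
  c(i, j, l) * spacing + box_edge / 6
}

#' Realize a scenario script as a trajectory with ground truth
#'
#' Each directive becomes one frame: every scripted cluster is realized
#' as an ideal parallel sheet at a dedicated lattice site (keyed by its
#' smallest peptide index) and every monomer as a coil-conformation chain
#' at its own site; sites are at least ~`box_edge/3.4` apart so clusters
#' never touch. The returned ground-truth partitions are what the
#' clustering and kinetics stages must reproduce.
#'
#' @param script a `scenario_script`
#' @param criteria criteria for self-verification of realized frames
#' @param verify verify each realized frame against its directive
#'   (through the full analysis stack); on by default
#' @return list: `trajectory`, `partitions` (ground truth),
#'   `events` (ground-truth events from the scripted partitions), `script`
#' @export
script_trajectory <- function(script, criteria = default_criteria(),
                              verify = TRUE) {
  stopifnot(inherits(script, "scenario_script"))
  n <- script$n_peptides
  box <- script$box_edge
  topo <- topology("GNNQQNY", n_chains = n)
  n_res <- 7L
  sheet_cache <- list()
  sheet_coords <- function(k) {
    key <- as.character(k)
    if (is.null(sheet_cache[[key]])) {
      sh <- build_ideal_sheet(k, "parallel", box_edge = box,
                              criteria = criteria)
      cen <- colMeans(sh$frame$coords)
      sheet_cache[[key]] <<- sweep(sh$frame$coords, 2, cen)
    }
    sheet_cache[[key]]
  }
  coil <- build_peptide_coords(rep(60, n_res), rep(-60, n_res))
  coil <- sweep(coil, 2, colMeans(coil))
  frames <- vector("list", length(script$directives))
  truth <- vector("list", length(script$directives))
  for (fi in seq_along(script$directives)) {
    d <- script$directives[[fi]]
    part <- partition_from_clusters(d$clusters, n, d$time)
    truth[[fi]] <- part
    coords <- matrix(NA_real_, n_atoms(topo), 3)
    for (cl in part$clusters) {
      site <- .lattice_site(min(cl), box)
      sc <- sheet_coords(length(cl))
      for (si in seq_along(cl)) {
        rows <- ((si - 1L) * 6L * n_res + 1L):(si * 6L * n_res)
        dst <- which(topo$atoms$chain == cl[si])
        coords[dst, ] <- sweep(sc[rows, , drop = FALSE], 2, site, "+")
      }
    }
    for (m in part$monomers) {
      dst <- which(topo$atoms$chain == m)
      coords[dst, ] <- sweep(coil, 2, .lattice_site(m, box), "+")
    }
    if (script$noise > 0)
      coords <- coords + matrix(runif(length(coords), -script$noise,
                                      script$noise), ncol = 3)
    frames[[fi]] <- frame(coords, box, d$time)
    if (verify) {
      got <- clusters(strand_graph(frames[[fi]], topo, criteria))
      if (!identical(lapply(got$clusters, as.integer), part$clusters) ||
          !identical(got$monomers, part$monomers))
        stop("script_trajectory: frame ", fi,
             " does not realize its directive")
    }
  }
  traj <- trajectory(topo, frames)
  list(trajectory = traj, partitions = truth,
       events = classify_events(truth), script = script)
}

#' Convenience scripts: stepwise growth, fusion, grow-then-dissolve
#'
#' `script_growth` grows one cluster by single monomer additions from a
#' dimer up to `final_size`; `script_fusion` grows two clusters then
#' fuses them; `script_grow_dissolve` runs growth, full dissolution, and
#' regrowth (two nucleation episodes, one reversal).
#'
#' @param n_peptides total peptides
#' @param final_size target cluster size for growth
#' @param dt frame spacing, ps
#' @name scenario_presets
#' @export
script_growth <- function(n_peptides = 20L, final_size = n_peptides, dt = 7.5) {
  dirs <- list(list(time = 0, clusters = list()))
  for (k in 2:final_size)
    dirs[[length(dirs) + 1L]] <- list(time = (k - 1) * dt,
                                      clusters = list(1:k))
  scenario_script(dirs, n_peptides)
}

#' @rdname scenario_presets
#' @param size_a,size_b sizes of the two clusters to fuse
#' @export
script_fusion <- function(size_a = 5L, size_b = 5L, n_peptides = 20L,
                          dt = 7.5) {
  a <- 1:size_a; b <- (size_a + 1L):(size_a + size_b)
  scenario_script(list(
    list(time = 0, clusters = list(a, b)),
    list(time = dt, clusters = list(c(a, b)))), n_peptides)
}

#' @rdname scenario_presets
#' @param hold number of frames each plateau is held
#' @export
script_grow_dissolve <- function(n_peptides = 20L, final_size = 8L, dt = 7.5,
                                 hold = 3L) {
  dirs <- list()
  t <- 0
  push <- function(cl) {
    dirs[[length(dirs) + 1L]] <<- list(time = t, clusters = cl)
    t <<- t + dt
  }
  grow <- function() {
    for (k in 2:final_size) push(list(1:k))
    for (h in seq_len(hold)) push(list(1:final_size))
  }
  push(list())
  grow()
  for (k in rev(2:final_size)) push(list(1:k))
  for (h in seq_len(hold)) push(list())
  grow()
  scenario_script(dirs, n_peptides)
}
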