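# Beta-sheet cluster detection: strand-attachment graph, connected-
# component partitions, strand orientation statistics, and polymorph
# classification.

#' Per-frame strand-attachment graph
#'
#' Nodes are the peptides passing the peptide-level beta-state test; an
#' edge joins two peptides attached by at least `min_hbonds` DSSP-style
#' inter-strand hydrogen bonds (a per-pair threshold: the bonds must be to
#' a single partner strand, not summed over a cluster). Peptides failing
#' the beta test have no incident edges.
#'
#' @param fr an `agg_frame`
#' @param topo an `agg_topology`
#' @param criteria an `aggkin_criteria`
#' @return list of class `strand_graph`: `n_peptides`, `beta` (logical per
#'   peptide), `edges` (data.frame a, b, n_hbonds, orientation),
#'   `n_hbonds_total` (accepted inter-strand bonds over all pairs, beta or
#'   not — the "number of hydrogen bonds" axis of the structure maps)
#' @export
strand_graph <- function(fr, topo, criteria = default_criteria()) {
  rep_ <- beta_state_report(fr, topo, criteria)
  nc <- n_chains(topo)
  # prefilter peptide pairs by CA-centroid distance
  ca <- topo$atoms[topo$atoms$role == "CA", ]
  cent <- matrix(NA_real_, nc, 3)
  for (ch in seq_len(nc))
    cent[ch, ] <- colMeans(fr$coords[ca$atom[ca$chain == ch], , drop = FALSE])
  cd <- mi_dist_matrix(cent, cent, fr$box_edge)
  edges <- list()
  total_hb <- 0L
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      if (cd[i, j] > 25) next
      hb <- interstrand_hbonds(fr, topo, i, j, criteria)
      total_hb <- total_hb + nrow(hb)
      if (rep_$peptide_beta[i] && rep_$peptide_beta[j] &&
          nrow(hb) >= criteria$min_hbonds) {
        ori <- pair_orientation(fr, topo, i, j,
                                dead_zone_deg = criteria$orientation_dead_zone_deg)
        edges[[length(edges) + 1L]] <- data.frame(
          a = i, b = j, n_hbonds = nrow(hb), orientation = ori,
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = integer(), b = integer(), n_hbonds = integer(),
               orientation = character(), stringsAsFactors = FALSE)
  structure(list(n_peptides = nc, beta = rep_$peptide_beta, edges = edges,
                 n_hbonds_total = total_hb, beta_report = rep_,
                 time = fr$time),
            class = "strand_graph")
}

#' Relative orientation of two H-bonded strands
#'
#' Sign of the dot product of the two end-to-end CA vectors (first to last
#' residue): positive means parallel. A dot product of exactly zero is
#' classified antiparallel with a warning; a configurable dead zone around
#' 90 degrees returns `"undefined"` instead (excluded from statistics).
#'
#' @param fr an `agg_frame`
#' @param topo an `agg_topology`
#' @param a,b chain indices
#' @param dead_zone_deg half-width of the undefined zone around 90 degrees
#' @return `"parallel"`, `"antiparallel"`, or `"undefined"`
#' @export
pair_orientation <- function(fr, topo, a, b, dead_zone_deg = 0) {
  v <- function(ch) {
    nres <- topo$n_res[[ch]]
    fr$coords[atom_index(topo, ch, nres, "CA"), ] -
      fr$coords[atom_index(topo, ch, 1L, "CA"), ]
  }
  va <- v(a); vb <- v(b)
  na_ <- sqrt(sum(va^2)); nb_ <- sqrt(sum(vb^2))
  if (na_ < 1e-9 || nb_ < 1e-9) {
    warning("pair_orientation: zero-length end-to-end vector")
    return("undefined")
  }
  cosang <- sum(va * vb) / (na_ * nb_)
  if (dead_zone_deg > 0 &&
      abs(90 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi) < dead_zone_deg)
    return("undefined")
  if (cosang > 0) return("parallel")
  if (cosang == 0) warning("pair_orientation: perpendicular strands classified antiparallel")
  "antiparallel"
}

#' Cluster partition from a strand graph
#'
#' Clusters are the connected components of size >= 2 of the
#' strand-attachment graph; everything else is a free monomer. The size
#' histogram counts aggregates of each size, with monomers as size-1
#' aggregates, so sum(n * N_n) equals the total peptide count.
#'
#' @param sg a `strand_graph`
#' @return object of class `cluster_partition`: `time`, `clusters` (list
#'   of integer vectors), `monomers`, `size_hist` (length n_peptides),
#'   `parallel_fraction` (overall, NA when no H-bonded pair),
#'   `cluster_parallel` (per cluster), `largest`
#' @export
clusters <- function(sg) {
  stopifnot(inherits(sg, "strand_graph"))
  n <- sg$n_peptides
  if (nrow(sg$edges)) {
    g <- igraph::graph_from_data_frame(sg$edges[, c("a", "b")],
                                       directed = FALSE,
                                       vertices = data.frame(name = seq_len(n)))
    comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  } else {
    comp <- seq_len(n)
  }
  comp <- as.integer(comp)
  cl <- split(seq_len(n), comp)
  keep <- vapply(cl, length, 1L) >= 2L
  clusters_ <- unname(cl[keep])
  ord <- order(vapply(clusters_, min, 1L))
  clusters_ <- clusters_[ord]
  monomers <- as.integer(sort(unlist(unname(cl[!keep]))))
  sizes <- vapply(clusters_, length, 1L)
  size_hist <- tabulate(c(sizes, rep(1L, length(monomers))), nbins = n)
  pf_of <- function(members) {
    e <- sg$edges[sg$edges$a %in% members & sg$edges$b %in% members, ]
    e <- e[e$orientation != "undefined", ]
    if (!nrow(e)) return(NA_real_)
    mean(e$orientation == "parallel")
  }
  cluster_parallel <- vapply(clusters_, pf_of, 1.0)
  alle <- sg$edges[sg$edges$orientation != "undefined", ]
  pf <- if (nrow(alle)) mean(alle$orientation == "parallel") else NA_real_
  structure(list(time = sg$time, n_peptides = n, clusters = clusters_,
                 monomers = monomers, size_hist = size_hist,
                 parallel_fraction = pf, cluster_parallel = cluster_parallel,
                 largest = if (length(sizes)) max(sizes) else 1L),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("partition at t =", x$time, "ps:",
      length(x$clusters), "cluster(s),", length(x$monomers), "monomer(s);",
      "largest =", x$largest, "\n")
  invisible(x)
}

#' Fraction of parallel H-bonded strand pairs
#'
#' By the H-bond-based cluster convention the antiparallel fraction is
#' exactly 1 minus this value whenever it is defined.
#'
#' @param x a `cluster_partition` or `strand_graph`
#' @return fraction in [0, 1], `NA` when no H-bonded pair exists
#' @export
parallel_fraction <- function(x) {
  if (inherits(x, "cluster_partition")) return(x$parallel_fraction)
  stopifnot(inherits(x, "strand_graph"))
  e <- x$edges[x$edges$orientation != "undefined", ]
  if (!nrow(e)) return(NA_real_)
  mean(e$orientation == "parallel")
}

#' Per-frame cluster partitions and metrics for a whole trajectory
#'
#' Streams over frames (constant memory in the number of frames beyond
#' the outputs).
#'
#' @param traj an `agg_trajectory`
#' @param criteria an `aggkin_criteria`
#' @param contact_cutoff SC-SC contact cutoff (Angstrom)
#' @return list: `partitions` (list of `cluster_partition`), `metrics`
#'   (data.frame frame, time, n_hbonds, n_contacts, beta_fraction,
#'   largest_cluster_size, parallel_fraction)
#' @export
cluster_timeseries <- function(traj, criteria = default_criteria(),
                               contact_cutoff = criteria$contact_cutoff) {
  stopifnot(inherits(traj, "agg_trajectory"))
  nfr <- n_frames(traj)
  partitions <- vector("list", nfr)
  metrics <- data.frame(frame = seq_len(nfr), time = traj$times,
                        n_hbonds = NA_integer_, n_contacts = NA_integer_,
                        beta_fraction = NA_real_,
                        largest_cluster_size = NA_integer_,
                        parallel_fraction = NA_real_)
  for (i in seq_len(nfr)) {
    fr <- traj$frames[[i]]
    sg <- strand_graph(fr, traj$topology, criteria)
    part <- clusters(sg)
    partitions[[i]] <- part
    metrics$n_hbonds[i] <- sg$n_hbonds_total
    metrics$n_contacts[i] <- as.integer(sidechain_contacts(fr, traj$topology,
                                                           contact_cutoff))
    metrics$beta_fraction[i] <- sg$beta_report$beta_fraction
    metrics$largest_cluster_size[i] <- part$largest
    metrics$parallel_fraction[i] <- part$parallel_fraction
  }
  list(partitions = partitions, metrics = metrics)
}

#' Polymorph class of a final-frame partition
#'
#' A "sheet" is operationalized as a ladder: a maximal connected set of
#' strands in which every strand has at most two H-bonded neighbours.
#' Branch nodes (degree >= 3) split sheets and are not counted toward any
#' ladder. Structures with exactly two sheets of at least `min_sheet_len`
#' strands are `two_sheet`, three or more are `three_plus_sheet`,
#' everything else (including all-monomer frames) is `disordered`.
#'
#' @param partition a `cluster_partition`
#' @param sg the matching `strand_graph`
#' @param min_sheet_len minimum strands per counted sheet
#' @return class label, with attribute `n_sheets`
#' @export
classify_polymorph <- function(partition, sg, min_sheet_len = 3L) {
  stopifnot(inherits(partition, "cluster_partition"), inherits(sg, "strand_graph"))
  e <- sg$edges
  if (!nrow(e)) return(structure("disordered", n_sheets = 0L))
  deg <- tabulate(c(e$a, e$b), nbins = sg$n_peptides)
  branch <- which(deg >= 3L)
  keep <- !(e$a %in% branch) & !(e$b %in% branch)
  e2 <- e[keep, , drop = FALSE]
  nodes <- setdiff(which(deg > 0L), branch)
  n_sheets <- 0L
  if (length(nodes)) {
    g <- igraph::graph_from_data_frame(e2[, c("a", "b")], directed = FALSE,
                                       vertices = data.frame(name = nodes))
    cs <- igraph::components(g)$csize
    n_sheets <- sum(cs >= min_sheet_len)
  }
  label <- if (n_sheets == 2L) "two_sheet"
           else if (n_sheets >= 3L) "three_plus_sheet"
           else "disordered"
  structure(label, n_sheets = n_sheets)
}
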