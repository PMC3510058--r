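# Frame-to-frame cluster lineage tracking and kinetic event
# classification.
#
# Event taxonomy (sizes are peptide counts; monomers are size 1):
#   monomer_addition      (n) + (1) -> (n+1)        association
#   monomer_loss          (n) -> (n-1) + (1)        dissociation
#   fusion                (a) + (b) -> (a+b), a,b>=2
#   fragmentation         (a+b) -> (a) + (b), a,b>=2
#   monomers_to_oligomer  k monomers -> (k), k>=3
#   oligomer_to_monomers  (k) -> k monomers, k>=3
# Dimer formation/destruction {1,1} <-> {2} is a monomer event: only
# oligomers bigger than dimers count as direct monomers<->oligomers
# interconversion.

.ASSOC_TYPES <- c("monomer_addition", "fusion", "monomers_to_oligomer")
.DISSOC_TYPES <- c("monomer_loss", "fragmentation", "oligomer_to_monomers")

.MIRROR_TYPE <- c(monomer_addition = "monomer_loss",
                  monomer_loss = "monomer_addition",
                  fusion = "fragmentation",
                  fragmentation = "fusion",
                  monomers_to_oligomer = "oligomer_to_monomers",
                  oligomer_to_monomers = "monomers_to_oligomer")

# fast data.frame assembly from equal-length vectors (hot path)
.fast_df <- function(lst) {
  n <- length(lst[[1]])
  class(lst) <- "data.frame"
  attr(lst, "row.names") <- .set_row_names(n)
  lst
}

.EMPTY_EVENTS <- NULL  # initialized on first use

.empty_events <- function() {
  if (is.null(.EMPTY_EVENTS))
    utils::assignInMyNamespace(".EMPTY_EVENTS", .fast_df(list(
      time = numeric(0), type = character(0), sizes_before = character(0),
      sizes_after = character(0), association = logical(0),
      compound = logical(0))))
  .EMPTY_EVENTS
}

.event_row <- function(time, type, before, after, compound = FALSE) {
  data.frame(time = time, type = type,
             sizes_before = paste(sort(before, decreasing = TRUE), collapse = "+"),
             sizes_after = paste(sort(after, decreasing = TRUE), collapse = "+"),
             association = type %in% .ASSOC_TYPES,
             compound = compound, stringsAsFactors = FALSE)
}

#' Parse an event size string back into an integer vector
#' @param s size string such as `"5+1"`
#' @export
parse_sizes <- function(s) as.integer(strsplit(s, "+", fixed = TRUE)[[1]])

# Remove the common part of two multisets; returns list(B, A) leftovers.
.cancel_common <- function(B, A) {
  for (x in unique(B)) {
    k <- min(sum(B == x), sum(A == x))
    if (k > 0L) {
      B <- B[-which(B == x)[seq_len(k)]]
      A <- A[-which(A == x)[seq_len(k)]]
    }
  }
  list(B = B, A = A)
}

#' Classify the transition between two aggregate-size multisets
#'
#' Decomposes the change from size multiset `before` to `after` (same
#' total mass) into primitive kinetic events. Primitive transformations
#' map to a single event; compound changes are decomposed greedily —
#' monomer events first, then fusion/fragmentation — deterministically,
#' with the `compound` flag set, and are never dropped.
#'
#' @param before,after integer vectors of aggregate sizes (monomers as 1),
#'   not necessarily sorted; total mass must be conserved
#' @param time event time stamp attached to every emitted event
#' @return data.frame of events (possibly 0 rows): time, type,
#'   sizes_before, sizes_after, association, compound
#' @export
classify_transition <- function(before, after, time = NA_real_) {
  if (sum(before) != sum(after))
    stop("classify_transition: mass not conserved (", sum(before), " -> ",
         sum(after), ")")
  cc <- .cancel_common(sort(before, decreasing = TRUE),
                       sort(after, decreasing = TRUE))
  B <- cc$B; A <- cc$A
  if (!length(B) && !length(A)) return(.empty_events())
  # accumulate plain vectors; one data.frame at the end (hot path)
  v_type <- character(); v_sb <- character(); v_sa <- character()
  v_cmp <- logical()
  add <- function(type, b, a, compound = FALSE) {
    k <- length(v_type) + 1L
    v_type[k] <<- type
    v_sb[k] <<- paste(sort(b, decreasing = TRUE), collapse = "+")
    v_sa[k] <<- paste(sort(a, decreasing = TRUE), collapse = "+")
    v_cmp[k] <<- compound
  }

  assemble <- function(B, target, compound) {
    # association: B (>=2 parts) -> single cluster of size target
    if (all(B == 1L)) {
      if (length(B) == 2L) add("monomer_addition", c(1L, 1L), 2L, compound)
      else add("monomers_to_oligomer", B, target, compound)
      return(invisible())
    }
    B <- sort(B, decreasing = TRUE)
    cur <- B[1]; pool <- B[-1]
    cmp <- compound || length(pool) > 1L
    for (x in pool[pool == 1L]) {     # monomer events first
      add("monomer_addition", c(cur, 1L), cur + 1L, cmp)
      cur <- cur + 1L
    }
    for (x in sort(pool[pool > 1L], decreasing = TRUE)) {
      add("fusion", c(cur, x), cur + x, cmp)
      cur <- cur + x
    }
  }
  disassemble <- function(source, A, compound) {
    # dissociation: single cluster of size source -> A (>=2 parts)
    if (all(A == 1L)) {
      if (length(A) == 2L) add("monomer_loss", 2L, c(1L, 1L), compound)
      else add("oligomer_to_monomers", source, A, compound)
      return(invisible())
    }
    A <- sort(A, decreasing = TRUE)
    cur <- source; pool <- A[-1]
    cmp <- compound || length(pool) > 1L
    for (x in sort(pool[pool > 1L], decreasing = TRUE)) {
      add("fragmentation", cur, c(cur - x, x), cmp)
      cur <- cur - x
    }
    for (x in pool[pool == 1L]) {
      add("monomer_loss", cur, c(cur - 1L, 1L), cmp)
      cur <- cur - 1L
    }
  }

  if (length(A) == 1L) {
    assemble(B, A, compound = FALSE)
  } else if (length(B) == 1L) {
    disassemble(B, A, compound = FALSE)
  } else if (length(B) == length(A)) {
    # peptide transfer between clusters: per-pair monomer chains, losses
    # first (freeing monomers), then additions (consuming them)
    delta <- A - B
    for (i in which(delta < 0)) {
      cur <- B[i]
      for (k in seq_len(-delta[i])) {
        add("monomer_loss", cur, c(cur - 1L, 1L), TRUE)
        cur <- cur - 1L
      }
    }
    for (i in which(delta > 0)) {
      cur <- B[i]
      for (k in seq_len(delta[i])) {
        add("monomer_addition", c(cur, 1L), cur + 1L, TRUE)
        cur <- cur + 1L
      }
    }
  } else {
    # rare irregular compound: full dissolve-and-rebuild, logged via flag
    for (b in B[B > 1L]) disassemble(b, rep(1L, b), compound = TRUE)
    for (a in A[A > 1L]) assemble(rep(1L, a), a, compound = TRUE)
  }
  .fast_df(list(time = rep(time, length(v_type)), type = v_type,
                sizes_before = v_sb, sizes_after = v_sa,
                association = v_type %in% .ASSOC_TYPES, compound = v_cmp))
}

#' Lineage mapping between two consecutive cluster partitions
#'
#' Bipartite matching by shared-peptide overlap. Every cluster at t+dt
#' inherits the identity of the t-cluster contributing the most peptides
#' (ties broken by the lower minimum peptide index). Overlap-connected
#' groups of clusters whose size multisets differ are the event groups.
#'
#' @param p1,p2 `cluster_partition`s over the same peptide set
#' @return list: `inherits` (data.frame to, from), `groups` (list of
#'   list(before, after) size multisets with member sets)
#' @export
match_clusters <- function(p1, p2) {
  stopifnot(inherits(p1, "cluster_partition"), inherits(p2, "cluster_partition"),
            p1$n_peptides == p2$n_peptides)
  n <- p1$n_peptides
  # membership vectors; each monomer is its own singleton group
  memb <- function(p) {
    m <- integer(n)
    for (i in seq_along(p$clusters)) m[p$clusters[[i]]] <- i
    k <- length(p$clusters)
    for (mm in p$monomers) { k <- k + 1L; m[mm] <- k }
    m
  }
  units <- function(p) c(p$clusters, as.list(p$monomers))
  m1 <- memb(p1); m2 <- memb(p2)
  u1 <- units(p1); u2 <- units(p2)
  # inheritance for true clusters of p2
  inh <- data.frame(to = seq_along(p2$clusters),
                    from = rep(NA_integer_, length(p2$clusters)))
  for (j in seq_along(p2$clusters)) {
    src <- m1[p2$clusters[[j]]]
    ov <- table(src)
    best <- as.integer(names(ov)[ov == max(ov)])
    if (length(best) > 1L) {
      mins <- vapply(best, function(b) min(u1[[b]]), 1L)
      best <- best[which.min(mins)]
    }
    inh$from[j] <- best
  }
  # overlap-connected event groups over units
  edges <- unique(data.frame(a = m1, b = m2 + length(u1)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = seq_len(length(u1) + length(u2))))
  comp <- igraph::components(g)$membership
  groups <- list()
  for (cid in unique(comp)) {
    ids <- as.integer(names(comp)[comp == cid])
    b_ids <- ids[ids <= length(u1)]
    a_ids <- ids[ids > length(u1)] - length(u1)
    before <- vapply(u1[b_ids], length, 1L)
    after <- vapply(u2[a_ids], length, 1L)
    if (!identical(sort(before), sort(after)) || length(b_ids) != length(a_ids))
      groups[[length(groups) + 1L]] <- list(
        before = before, after = after,
        members = sort(unique(unlist(u1[b_ids]))))
  }
  list(inherits = inh, groups = groups)
}

#' Classify kinetic events along a partition time series
#'
#' @param partitions list of `cluster_partition` in time order
#' @param times optional time stamps (defaults to the partitions' own)
#' @return data.frame of events: time (interval end), type, sizes_before,
#'   sizes_after, association, compound, participants (comma-separated
#'   peptide indices)
#' @export
classify_events <- function(partitions, times = NULL) {
  stopifnot(length(partitions) >= 2L)
  if (is.null(times)) times <- vapply(partitions, function(p) p$time, 1.0)
  out <- list()
  for (i in seq_len(length(partitions) - 1L)) {
    mp <- match_clusters(partitions[[i]], partitions[[i + 1L]])
    for (grp in mp$groups) {
      ev <- classify_transition(grp$before, grp$after, time = times[i + 1L])
      if (nrow(ev)) {
        ev$participants <- paste(grp$members, collapse = ",")
        out[[length(out) + 1L]] <- ev
      }
    }
  }
  if (!length(out)) {
    e <- .event_row(0, "monomer_addition", 1, 1)[0, ]
    e$participants <- character(0)
    return(e)
  }
  do.call(rbind, out)
}

#' Replay classified events over a size histogram
#'
#' Applies events in order to an initial histogram of aggregate sizes
#' (index = size, monomers included at size 1). Used to verify the event
#' stream <-> partition consistency invariant.
#'
#' @param initial_hist integer vector, `initial_hist[n]` = number of
#'   aggregates of size n
#' @param events event data.frame from [classify_events()] or a KMC log
#' @return matrix (`nrow(events)+1`) x length(initial_hist) of histograms
#' @export
replay_events <- function(initial_hist, events) {
  h <- as.integer(initial_hist)
  out <- matrix(0L, nrow(events) + 1L, length(h))
  out[1L, ] <- h
  if (nrow(events)) for (i in seq_len(nrow(events))) {
    for (s in parse_sizes(events$sizes_before[i])) {
      if (h[s] <= 0L) stop("replay_events: event ", i,
                           " removes absent size ", s)
      h[s] <- h[s] - 1L
    }
    for (s in parse_sizes(events$sizes_after[i])) h[s] <- h[s] + 1L
    out[i + 1L, ] <- h
  }
  out
}
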