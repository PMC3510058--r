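# Independent oracles and fixture generators shared across the suite.
# These deliberately avoid the package's own code paths.

# Brute-force connected components by BFS on an adjacency list.
# Returns an integer membership vector of length n (component ids).
oracle_components <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- edges$a[k]; b <- edges$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  memb <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (memb[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (memb[v] != 0L) next
      memb[v] <- cid
      queue <- c(queue, adj[[v]])
    }
  }
  memb
}

# Random undirected graph on n nodes with edge probability p.
random_graph_edges <- function(n, p = 0.3) {
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  data.frame(a = pairs[keep, 1], b = pairs[keep, 2])
}

# Independent random rotation (QR of a Gaussian matrix, det fixed to +1).
oracle_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Brute-force O(n^2) inter-chain contact count with minimum image.
oracle_contacts <- function(xyz, chain, cutoff, box) {
  cnt <- 0L
  n <- nrow(xyz)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (chain[i] == chain[j]) next
    d <- xyz[j, ] - xyz[i, ]
    d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) <= cutoff) cnt <- cnt + 1L
  }
  cnt
}

# Brute-force maximum-overlap source for one target member set.
oracle_best_source <- function(target_members, units_before) {
  ov <- vapply(units_before, function(u) length(intersect(u, target_members)), 1L)
  best <- which(ov == max(ov))
  if (length(best) > 1L) {
    mins <- vapply(units_before[best], min, 1L)
    best <- best[which.min(mins)]
  }
  best
}

# Random valid partition sequence on n peptides: a stream of random merge /
# split / transfer moves applied to the cluster structure.
random_partition_sequence <- function(n = 20L, n_frames = 30L, dt = 1) {
  pick <- function(x, k = 1L) x[sample.int(length(x), k)]   # no scalar trap
  cl <- list()                 # list of integer vectors
  out <- vector("list", n_frames)
  out[[1]] <- aggkin::partition_from_clusters(cl, n, 0)
  for (f in 2:n_frames) {
    monomers <- setdiff(seq_len(n), unlist(cl))
    move <- pick(c("grow", "shrink", "merge", "split", "form", "dissolve"))
    if (move == "grow" && length(cl) && length(monomers)) {
      i <- sample.int(length(cl), 1L)
      cl[[i]] <- c(cl[[i]], pick(monomers))
    } else if (move == "shrink" && length(cl)) {
      i <- sample.int(length(cl), 1L)
      if (length(cl[[i]]) > 2L) cl[[i]] <- cl[[i]][-1L] else cl[i] <- NULL
    } else if (move == "merge" && length(cl) >= 2L) {
      ij <- sample.int(length(cl), 2L)
      cl[[ij[1]]] <- c(cl[[ij[1]]], cl[[ij[2]]]); cl[ij[2]] <- NULL
    } else if (move == "split" && length(cl)) {
      i <- sample.int(length(cl), 1L)
      if (length(cl[[i]]) >= 4L) {
        k <- pick(2:(length(cl[[i]]) - 2L))
        cl[[length(cl) + 1L]] <- cl[[i]][seq_len(k)]
        cl[[i]] <- cl[[i]][-seq_len(k)]
      }
    } else if (move == "form" && length(monomers) >= 3L) {
      k <- pick(3:min(5L, length(monomers)))
      cl[[length(cl) + 1L]] <- pick(monomers, k)
    } else if (move == "dissolve" && length(cl)) {
      cl[sample.int(length(cl), 1L)] <- NULL
    }
    out[[f]] <- aggkin::partition_from_clusters(cl, n, (f - 1) * dt)
  }
  out
}

# Check that replaying classified events reproduces every frame histogram.
expect_replay_consistent <- function(partitions) {
  ev <- aggkin::classify_events(partitions)
  hists <- aggkin::replay_events(partitions[[1]]$size_hist, ev)
  times <- vapply(partitions, function(p) p$time, 1.0)
  for (fi in seq_along(partitions)) {
    rows <- which(c(0, ev$time) <= times[fi] + 1e-9)
    expect_identical(hists[max(rows), ], partitions[[fi]]$size_hist,
                     label = paste("replayed histogram at frame", fi))
  }
  invisible(ev)
}

# Small geometric fixtures reused across files (built once per session).
fixture_sheet <- local({
  cache <- list()
  function(n = 3L, orientation = "parallel") {
    key <- paste(n, orientation)
    if (is.null(cache[[key]]))
      cache[[key]] <<- aggkin::build_ideal_sheet(n, orientation)
    cache[[key]]
  }
})
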