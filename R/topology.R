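# Domain types for coarse-grained peptide systems.
#
# A residue is represented by six atom roles: the full heavy backbone
# (N, H, CA, C, O) plus a single side-chain bead (SC). Chain identity is
# positional (file order), so systems with more than 26 chains survive PDB
# chain-letter recycling.

.ROLES <- c("N", "H", "CA", "C", "O", "SC")

.AA1TO3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
             G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
             M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
             S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
.AA3TO1 <- setNames(names(.AA1TO3), .AA1TO3)

#' Build a coarse-grained topology from chain sequences
#'
#' @param sequences character vector of one-letter sequences, one per chain;
#'   recycled from `n_chains` copies of the default GNNQQNY when a single
#'   sequence and `n_chains` are given
#' @param n_chains optional number of chains when `sequences` has length 1
#' @return an `agg_topology`: atom table (chain, res, resname, role, name),
#'   per-chain sequences, and a role index array for O(1) atom lookup
#' @examples
#' topo <- topology(n_chains = 20)
#' n_chains(topo)
#' @export
topology <- function(sequences = "GNNQQNY", n_chains = NULL) {
  if (!is.null(n_chains)) {
    stopifnot(length(sequences) == 1L)
    sequences <- rep(sequences, n_chains)
  }
  stopifnot(length(sequences) >= 1L, all(nchar(sequences) >= 1L))
  rows <- list()
  for (ch in seq_along(sequences)) {
    aa <- strsplit(sequences[[ch]], "")[[1]]
    bad <- setdiff(aa, names(.AA1TO3))
    if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
    for (r in seq_along(aa)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, res = r, resname = .AA1TO3[[aa[[r]]]],
        role = .ROLES, name = .ROLES, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$atom <- seq_len(nrow(atoms))
  new_topology(atoms, sequences)
}

new_topology <- function(atoms, sequences) {
  nres <- vapply(sequences, nchar, 1L)
  idx <- array(NA_integer_,
               dim = c(length(.ROLES), length(sequences), max(nres)),
               dimnames = list(.ROLES, NULL, NULL))
  ii <- cbind(match(atoms$role, .ROLES), atoms$chain, atoms$res)
  idx[ii] <- atoms$atom
  structure(list(atoms = atoms, sequences = unname(sequences),
                 n_res = unname(nres), index = idx),
            class = "agg_topology")
}

#' Number of chains in a topology
#' @param topo an `agg_topology`
#' @export
n_chains <- function(topo) length(topo$sequences)

#' Total number of atoms in a topology
#' @param topo an `agg_topology`
#' @export
n_atoms <- function(topo) nrow(topo$atoms)

# Atom row index for (chain, residue, role); NA if absent.
atom_index <- function(topo, chain, res, role) {
  topo$index[cbind(match(role, .ROLES), chain, res)]
}

#' Validate topology invariants
#'
#' Checks that every residue exposes exactly the six atom roles and that
#' residue indices are contiguous per chain. Glycine side-chain beads are
#' allowed to coincide with CA (coarse-grained convention) — callers that
#' care receive the flagged chains via the `gly_sc` attribute.
#'
#' @param topo an `agg_topology`
#' @return `TRUE` invisibly; hard error naming chain/residue on violation
#' @export
validate_topology <- function(topo) {
  stopifnot(inherits(topo, "agg_topology"))
  a <- topo$atoms
  for (ch in seq_len(n_chains(topo))) {
    resv <- sort(unique(a$res[a$chain == ch]))
    if (!identical(resv, seq_len(topo$n_res[[ch]])))
      stop("chain ", ch, ": residue indices not contiguous")
    for (r in resv) {
      roles <- a$role[a$chain == ch & a$res == r]
      if (anyDuplicated(roles))
        stop("chain ", ch, " residue ", r, ": duplicate atom role ",
             roles[duplicated(roles)][1])
      miss <- setdiff(.ROLES, roles)
      if (length(miss))
        stop("chain ", ch, " residue ", r, ": missing role(s) ",
             paste(miss, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' @export
print.agg_topology <- function(x, ...) {
  cat("CG topology:", n_chains(x), "chain(s),", n_atoms(x), "atoms\n")
  cat("sequences:", paste(unique(x$sequences), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a single coordinate frame
#'
#' @param coords numeric matrix (n_atoms x 3), Angstrom
#' @param box_edge cubic box edge, Angstrom (> 0)
#' @param time frame time stamp in ps (>= 0)
#' @return an `agg_frame`
#' @export
frame <- function(coords, box_edge, time = 0) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  if (anyNA(coords) || any(!is.finite(coords)))
    stop("frame coordinates contain NA/non-finite values")
  if (box_edge <= 0) stop("box_edge must be positive")
  if (time < 0) stop("time must be non-negative")
  structure(list(coords = coords, box_edge = box_edge, time = time),
            class = "agg_frame")
}

validate_frame <- function(fr, topo) {
  stopifnot(inherits(fr, "agg_frame"))
  if (nrow(fr$coords) != n_atoms(topo))
    stop("frame has ", nrow(fr$coords), " atoms; topology expects ", n_atoms(topo))
  invisible(TRUE)
}

#' Construct a trajectory from frames
#'
#' @param topology an `agg_topology`
#' @param frames list of `agg_frame` with strictly increasing times
#' @param temperature temperature label in K (metadata only)
#' @return an `agg_trajectory`; `save_interval` (ps) is inferred from the
#'   time stamps and must be uniform within 1e-6 relative tolerance
#' @export
trajectory <- function(topology, frames, temperature = NA_real_) {
  stopifnot(inherits(topology, "agg_topology"), length(frames) >= 1L)
  for (fr in frames) validate_frame(fr, topology)
  times <- vapply(frames, function(f) f$time, 1.0)
  if (length(times) > 1L) {
    if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-6 * max(dt, 1e-12))
      warning("non-uniform save interval (", signif(min(dt), 6), " .. ",
              signif(max(dt), 6), " ps)")
    save_interval <- stats::median(dt)
  } else {
    save_interval <- NA_real_
  }
  structure(list(topology = topology, frames = frames, times = times,
                 save_interval = save_interval, temperature = temperature),
            class = "agg_trajectory")
}

#' @export
print.agg_trajectory <- function(x, ...) {
  cat("CG trajectory:", length(x$frames), "frame(s),",
      n_chains(x$topology), "chains,",
      "save interval", format(x$save_interval), "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `agg_trajectory`
#' @export
n_frames <- function(traj) length(traj$frames)

#' Select a frame range from a trajectory
#'
#' Thermalization or equilibration frames can be excluded explicitly rather
#' than guessed by the loaders.
#'
#' @param traj an `agg_trajectory`
#' @param first,last 1-based frame indices (inclusive)
#' @export
frame_range <- function(traj, first = 1L, last = n_frames(traj)) {
  stopifnot(first >= 1L, last <= n_frames(traj), first <= last)
  trajectory(traj$topology, traj$frames[first:last], traj$temperature)
}
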