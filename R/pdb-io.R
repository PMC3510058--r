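# PDB I/O for coarse-grained topologies and multi-model trajectories.
#
# Fixed-width PDB writer/reader supporting ATOM, TER, MODEL/ENDMDL and
# CRYST1 records. Atom names are the role names (N, H, CA, C, O, SC).
# Chain identity is positional: a new chain starts at TER or when the
# residue number decreases; the PDB chain letter is recycled A..Z and is
# not trusted for identity.

.pdb_chain_letter <- function(i) LETTERS[(i - 1L) %% 26L + 1L]

format_atom_record <- function(serial, name, resname, chain_letter, resseq, xyz) {
  # name in columns 13-16: pad per PDB convention (short names start col 14)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial %% 100000L, nm, resname, chain_letter, resseq %% 10000L,
          xyz[1], xyz[2], xyz[3])
}

#' Write a topology + frames as a (multi-model) PDB file
#'
#' @param traj an `agg_trajectory`, or an `agg_frame` together with `topo`
#' @param path output file
#' @param topo topology when `traj` is a single frame
#' @return `path` invisibly
#' @export
write_pdb <- function(traj, path, topo = NULL) {
  if (inherits(traj, "agg_frame")) {
    stopifnot(!is.null(topo))
    traj <- trajectory(topo, list(traj))
  }
  stopifnot(inherits(traj, "agg_trajectory"))
  topo <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(traj$frames) > 1L
  box <- traj$frames[[1]]$box_edge
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    box, box, box, 90, 90, 90), con)
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf("REMARK   6 TIME_PS %.6f", fr$time), con)
    serial <- 0L
    a <- topo$atoms
    for (ch in seq_len(n_chains(topo))) {
      rows <- which(a$chain == ch)
      for (k in rows) {
        serial <- serial + 1L
        writeLines(format_atom_record(
          a$atom[k], a$name[k], a$resname[k], .pdb_chain_letter(ch),
          a$res[k], fr$coords[a$atom[k], ]), con)
      }
      writeLines("TER", con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.parse_pdb_models <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) return(list(lines))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stop("malformed PDB: MODEL/ENDMDL mismatch")
  Map(function(s, e) lines[s:e], model_starts, model_ends)
}

.parse_atom_lines <- function(lines) {
  sel <- grepl("^ATOM  |^HETATM|^TER", lines)
  lines <- lines[sel]
  ter <- grepl("^TER", lines)
  al <- lines[!ter]
  data.frame(
    name = trimws(substr(al, 13, 16)),
    resname = trimws(substr(al, 18, 20)),
    chain_letter = substr(al, 22, 22),
    resseq = as.integer(substr(al, 23, 26)),
    x = as.numeric(substr(al, 31, 38)),
    y = as.numeric(substr(al, 39, 46)),
    z = as.numeric(substr(al, 47, 54)),
    after_ter = cumsum(ter)[!ter],
    stringsAsFactors = FALSE)
}

.role_from_name <- function(name) {
  up <- toupper(name)
  out <- rep(NA_character_, length(up))
  out[up %in% c("N")] <- "N"
  out[up %in% c("H", "HN", "H1")] <- "H"
  out[up %in% c("CA")] <- "CA"
  out[up %in% c("C")] <- "C"
  out[up %in% c("O", "O1", "OXT")] <- "O"
  out[up %in% c("SC", "CB", "SC1")] <- "SC"
  out
}

#' Load a coarse-grained topology from a PDB file
#'
#' Atom roles are assigned from atom names (N, H/HN, CA, C, O, SC/CB).
#' Chains are delimited by TER records / chain-letter changes / residue
#' renumbering; identity is positional. Missing or duplicated backbone
#' roles are hard errors naming the chain and residue.
#'
#' @param path PDB file
#' @return an `agg_topology` (validated); unassignable atom names are
#'   collected in attribute `errors`
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  models <- .parse_pdb_models(lines)
  at <- .parse_atom_lines(models[[1]])
  if (!nrow(at)) stop("no ATOM records in ", path)
  at$role <- .role_from_name(at$name)
  errors <- character()
  if (anyNA(at$role)) {
    errors <- sprintf("unassignable atom name '%s' (res %d)",
                      at$name[is.na(at$role)], at$resseq[is.na(at$role)])
    at <- at[!is.na(at$role), ]
  }
  # chain break: TER seen, chain letter change, or residue number decrease
  key <- paste(at$after_ter, at$chain_letter)
  newchain <- c(TRUE, key[-1] != key[-length(key)]) |
    c(TRUE, diff(at$resseq) < 0)
  at$chain <- cumsum(newchain)
  # contiguous residue index within chain
  at$res <- NA_integer_
  seqs <- character()
  for (ch in unique(at$chain)) {
    rows <- which(at$chain == ch)
    ures <- unique(at$resseq[rows])
    at$res[rows] <- match(at$resseq[rows], ures)
    rn <- at$resname[rows][match(ures, at$resseq[rows])]
    one <- .AA3TO1[rn]
    if (anyNA(one)) stop("unknown residue name(s): ",
                         paste(unique(rn[is.na(one)]), collapse = ", "))
    seqs[ch] <- paste(one, collapse = "")
  }
  atoms <- data.frame(chain = at$chain, res = at$res, resname = at$resname,
                      role = at$role, name = at$name, stringsAsFactors = FALSE)
  atoms$atom <- seq_len(nrow(atoms))
  topo <- new_topology(atoms, seqs)
  validate_topology(topo)   # missing/duplicate role -> hard error
  attr(topo, "errors") <- errors
  topo
}

#' Load a multi-model PDB trajectory
#'
#' @param path multi-model PDB file
#' @param topology an `agg_topology` the frames must match
#' @param temperature temperature label (K)
#' @return an `agg_trajectory`; frame times come from `REMARK 6 TIME_PS`
#'   records, falling back to the model index (ps) when absent
#' @export
load_trajectory_pdb <- function(path, topology, temperature = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  cry <- grep("^CRYST1", lines, value = TRUE)
  box <- if (length(cry)) as.numeric(substr(cry[[1]], 7, 15)) else Inf
  models <- .parse_pdb_models(lines)
  frames <- vector("list", length(models))
  for (i in seq_along(models)) {
    at <- .parse_atom_lines(models[[i]])
    if (nrow(at) != n_atoms(topology))
      stop("model ", i, ": atom count ", nrow(at),
           " does not match topology (", n_atoms(topology), ")")
    tm <- grep("^REMARK   6 TIME_PS", models[[i]], value = TRUE)
    t_ps <- if (length(tm)) as.numeric(sub(".*TIME_PS ", "", tm[[1]])) else i - 1
    coords <- as.matrix(at[, c("x", "y", "z")])
    if (anyNA(coords)) stop("model ", i, ": NaN/NA coordinates")
    dimnames(coords) <- NULL
    frames[[i]] <- frame(coords, box, t_ps)
  }
  trajectory(topology, frames, temperature)
}
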