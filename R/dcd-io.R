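# Minimal CHARMM-style DCD trajectory I/O (binary, little-endian).
#
# Layout: Fortran sequential records (int32 byte-count sentinels around
# each block). Header block "CORD" + 20 int32 control words (nframes in
# icntrl[1], save frequency in icntrl[3], timestep as float32 in
# icntrl[10], unit-cell flag in icntrl[11]); a title block; an natoms
# block; then per frame a 6-double unit-cell block followed by X, Y, Z
# float32 blocks. Times are written with the timestep field in ps, so a
# write/read round trip preserves time stamps to float32 precision.

.write_record <- function(con, writer) {
  raw_con <- rawConnection(raw(0), "wb")
  writer(raw_con)
  payload <- rawConnectionValue(raw_con)
  close(raw_con)
  writeBin(length(payload), con, size = 4L, endian = "little")
  writeBin(payload, con)
  writeBin(length(payload), con, size = 4L, endian = "little")
}

.read_record <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(n)) return(NULL)
  payload <- readBin(con, "raw", n)
  n2 <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(n, n2)) stop("corrupt DCD record (sentinel mismatch)")
  payload
}

#' Write a trajectory as a DCD binary file
#'
#' @param traj an `agg_trajectory`
#' @param path output file
#' @return `path` invisibly
#' @export
write_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "agg_trajectory"))
  con <- file(path, "wb")
  on.exit(close(con))
  nfr <- length(traj$frames)
  dt_ps <- if (is.na(traj$save_interval)) 1 else traj$save_interval
  t0 <- traj$times[[1]]
  .write_record(con, function(rc) {
    writeBin(charToRaw("CORD"), rc)
    icntrl <- integer(20)
    icntrl[1] <- nfr
    icntrl[2] <- as.integer(round(t0 / dt_ps))  # first step
    icntrl[3] <- 1L                             # save frequency
    icntrl[11] <- 1L                            # unit cell present
    icntrl[20] <- 24L                           # CHARMM version tag
    writeBin(icntrl[1:9], rc, size = 4L, endian = "little")
    writeBin(as.numeric(dt_ps), rc, size = 4L, endian = "little")  # icntrl[10]
    writeBin(icntrl[11:20], rc, size = 4L, endian = "little")
  })
  .write_record(con, function(rc) {
    writeBin(1L, rc, size = 4L, endian = "little")
    title <- sprintf("%-80s", "written by aggkin")
    writeBin(charToRaw(title), rc)
  })
  .write_record(con, function(rc)
    writeBin(n_atoms(traj$topology), rc, size = 4L, endian = "little"))
  for (fr in traj$frames) {
    b <- fr$box_edge
    .write_record(con, function(rc)
      writeBin(c(b, 90, b, 90, 90, b), rc, size = 8L, endian = "little"))
    for (ax in 1:3) {
      .write_record(con, function(rc)
        writeBin(as.numeric(fr$coords[, ax]), rc, size = 4L, endian = "little"))
    }
  }
  invisible(path)
}

#' Load a DCD binary trajectory
#'
#' @param path DCD file
#' @param topology an `agg_topology` the frames must match
#' @param temperature temperature label (K)
#' @return an `agg_trajectory` (coordinates at float32 precision)
#' @export
load_trajectory_dcd <- function(path, topology, temperature = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .read_record(con)
  if (is.null(hdr) || rawToChar(hdr[1:4]) != "CORD") stop("not a DCD file: ", path)
  icntrl19 <- readBin(hdr[5:length(hdr)], "integer", 20L, size = 4L,
                      endian = "little")
  nfr <- icntrl19[1]
  first_step <- icntrl19[2]
  dt_ps <- readBin(hdr[(4 + 9 * 4 + 1):(4 + 10 * 4)], "numeric", 1L,
                   size = 4L, endian = "little")
  has_cell <- icntrl19[11] == 1L
  .read_record(con)  # title
  natoms <- readBin(.read_record(con), "integer", 1L, size = 4L,
                    endian = "little")
  if (natoms != n_atoms(topology))
    stop("DCD atom count ", natoms, " does not match topology (",
         n_atoms(topology), ")")
  frames <- vector("list", nfr)
  for (i in seq_len(nfr)) {
    box <- Inf
    if (has_cell) {
      cell <- readBin(.read_record(con), "numeric", 6L, size = 8L,
                      endian = "little")
      box <- cell[1]
    }
    xyz <- matrix(NA_real_, natoms, 3)
    for (ax in 1:3) {
      xyz[, ax] <- readBin(.read_record(con), "numeric", natoms, size = 4L,
                           endian = "little")
    }
    if (anyNA(xyz)) stop("frame ", i, ": NaN coordinates in DCD")
    frames[[i]] <- frame(xyz, box, (first_step + (i - 1L)) * dt_ps)
  }
  trajectory(topology, frames, temperature)
}

#' Load a trajectory, dispatching on file extension
#'
#' Supports multi-model PDB (`.pdb`) and binary DCD (`.dcd`).
#'
#' @param path trajectory file
#' @param topology an `agg_topology`
#' @param temperature temperature label (K)
#' @return an `agg_trajectory`
#' @export
load_trajectory <- function(path, topology, temperature = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdb = load_trajectory_pdb(path, topology, temperature),
         dcd = load_trajectory_dcd(path, topology, temperature),
         stop("unsupported trajectory format: .", ext))
}
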