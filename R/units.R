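#' Molar concentration of n molecules in a cubic box
#'
#' Converts a molecule count in a cubic periodic box to a molar
#' concentration. For the reference system (20 peptides, 200 Angstrom box)
#' this gives 4.15 mM.
#'
#' @param n_molecules number of molecules (>= 0)
#' @param box_edge cubic box edge length in Angstrom (> 0)
#' @return concentration in mM, with attribute `volume_litres`
#' @examples
#' concentration(20, 200)  # ~4.15 mM
#' @export
concentration <- function(n_molecules, box_edge) {
  stopifnot(is.numeric(n_molecules), is.numeric(box_edge))
  if (any(n_molecules < 0)) stop("n_molecules must be >= 0")
  if (any(box_edge <= 0)) stop("box_edge must be positive")
  # 1 Angstrom = 1e-9 dm, so V[L] = (edge * 1e-9)^3
  v_litres <- (box_edge * 1e-9)^3
  mM <- n_molecules / (.AVOGADRO * v_litres) * 1e3
  structure(mM, volume_litres = v_litres)
}

#' Convert an integration step count to a physical duration
#'
#' @param n_steps number of integration steps (>= 0)
#' @param dt timestep in femtoseconds (> 0); default 1.5 fs
#' @return object of class `aggkin_duration`: the duration rendered in the
#'   largest unit (fs/ps/ns) whose value is >= 1, with `$ps` always holding
#'   the value in picoseconds
#' @examples
#' steps_to_time(5000, 1.5)  # 7.5 ps
#' steps_to_time(50, 1.5)    # 75 fs
#' @export
steps_to_time <- function(n_steps, dt = 1.5) {
  stopifnot(length(n_steps) == 1L, length(dt) == 1L)
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (dt <= 0) stop("dt must be positive")
  fs <- n_steps * dt
  units <- c(fs = 1, ps = 1e3, ns = 1e6)
  if (fs == 0) {
    pick <- "fs"
  } else {
    ok <- which(fs / units >= 1)
    pick <- names(units)[if (length(ok)) max(ok) else 1L]
  }
  structure(list(value = fs / units[[pick]], unit = pick, ps = fs / 1e3),
            class = "aggkin_duration")
}

#' @export
print.aggkin_duration <- function(x, ...) {
  cat(format(x$value), x$unit, "\n")
  invisible(x)
}

#' @export
format.aggkin_duration <- function(x, ...) paste(format(x$value), x$unit)
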