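# Per-frame structural descriptors: backbone dihedrals, Ramachandran
# beta-window classification, Kabsch-Sander (DSSP-style) hydrogen bonds,
# and side-chain contact counts.

# Kabsch-Sander electrostatic H-bond model: E = q1*q2*f*(1/rON + 1/rCH -
# 1/rOH - 1/rCN) with q1 = 0.42 e, q2 = 0.20 e, f = 332 kcal*A/(mol*e^2).
.DSSP_PREFACTOR <- 0.42 * 0.20 * 332   # 27.888 kcal/mol * Angstrom

#' Default analysis criteria
#'
#' Central authority for every tunable criterion: the beta dihedral
#' windows (degrees, closed intervals; the default assignment is the one
#' under which the canonical beta-sheet point (-120, +130) lies inside the
#' region), the H-bond energy acceptance threshold (kcal/mol), the minimum
#' number of inter-strand H-bonds defining strand attachment, the minimum
#' number of beta residues for a peptide-level beta state, and the
#' side-chain contact cutoff (Angstrom; unspecified upstream, default
#' 6.5 A between SC bead centres — contact-map axes depend on it).
#'
#' @param phi_windows,psi_windows 2-column matrices of closed intervals
#' @param hb_threshold H-bond acceptance threshold, kcal/mol (bond iff E < threshold)
#' @param min_hbonds minimum H-bonds for strand attachment
#' @param min_beta_residues minimum beta residues per peptide
#' @param contact_cutoff SC-SC contact cutoff, Angstrom
#' @param orientation_dead_zone_deg half-width (degrees) around 90 degrees
#'   in which pair orientation is reported undefined; 0 disables
#' @return a list of class `aggkin_criteria`
#' @export
default_criteria <- function(phi_windows = rbind(c(-180, 0), c(150, 180)),
                             psi_windows = rbind(c(-180, -150), c(0, 180)),
                             hb_threshold = -0.5,
                             min_hbonds = 2L,
                             min_beta_residues = 3L,
                             contact_cutoff = 6.5,
                             orientation_dead_zone_deg = 0) {
  structure(list(phi_windows = phi_windows, psi_windows = psi_windows,
                 hb_threshold = hb_threshold, min_hbonds = min_hbonds,
                 min_beta_residues = min_beta_residues,
                 contact_cutoff = contact_cutoff,
                 orientation_dead_zone_deg = orientation_dead_zone_deg),
            class = "aggkin_criteria")
}

#' Backbone phi/psi dihedrals of every residue
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' Angles undefined at termini (or for degenerate geometry) are `NA` with
#' the matching `defined` flag `FALSE`, never silently 0.
#'
#' @param fr an `agg_frame`
#' @param topo an `agg_topology`
#' @return data.frame: chain, res, phi, psi, phi_defined, psi_defined
#' @export
residue_dihedrals <- function(fr, topo) {
  validate_frame(fr, topo)
  xyz <- fr$coords
  out <- topo$atoms[topo$atoms$role == "CA", c("chain", "res")]
  out$phi <- NA_real_; out$psi <- NA_real_
  for (k in seq_len(nrow(out))) {
    ch <- out$chain[k]; r <- out$res[k]
    nres <- topo$n_res[[ch]]
    if (r > 1L) {
      p <- dihedral(xyz[atom_index(topo, ch, r - 1L, "C"), ],
                    xyz[atom_index(topo, ch, r, "N"), ],
                    xyz[atom_index(topo, ch, r, "CA"), ],
                    xyz[atom_index(topo, ch, r, "C"), ])
      out$phi[k] <- as.numeric(p)
    }
    if (r < nres) {
      p <- dihedral(xyz[atom_index(topo, ch, r, "N"), ],
                    xyz[atom_index(topo, ch, r, "CA"), ],
                    xyz[atom_index(topo, ch, r, "C"), ],
                    xyz[atom_index(topo, ch, r + 1L, "N"), ])
      out$psi[k] <- as.numeric(p)
    }
  }
  out$phi_defined <- !is.na(out$phi)
  out$psi_defined <- !is.na(out$psi)
  rownames(out) <- NULL
  out
}

.in_windows <- function(x, windows) {
  any(x >= windows[, 1] & x <= windows[, 2])   # closed intervals
}

#' Beta-region membership of a (phi, psi) pair
#'
#' @param phi,psi backbone dihedrals in degrees; `NA` means undefined
#' @param criteria an `aggkin_criteria` (windows are closed intervals)
#' @return logical; `FALSE` with attribute `reason = "undefined"` when
#'   either angle is undefined (terminus/degenerate)
#' @export
residue_beta_state <- function(phi, psi, criteria = default_criteria()) {
  if (is.na(phi) || is.na(psi))
    return(structure(FALSE, reason = "undefined"))
  .in_windows(phi, criteria$phi_windows) && .in_windows(psi, criteria$psi_windows)
}

#' Peptide-level beta state from per-residue flags
#'
#' A peptide is in a beta state when at least `min_count` of its residues
#' are in the beta region (default 3 for the GNNQQNY heptapeptide).
#'
#' @param flags logical vector of per-residue beta flags
#' @param min_count minimum number of beta residues
#' @export
peptide_beta_state <- function(flags, min_count = 3L) {
  stopifnot(length(flags) >= 1L)
  sum(flags, na.rm = TRUE) >= min_count
}

#' Per-frame beta-state report
#'
#' @param fr an `agg_frame`
#' @param topo an `agg_topology`
#' @param criteria an `aggkin_criteria`
#' @return list: `residue_flags` (data.frame chain,res,beta),
#'   `peptide_counts`, `peptide_beta` (logical per chain), and
#'   `beta_fraction` (residues in beta / total residues)
#' @export
beta_state_report <- function(fr, topo, criteria = default_criteria()) {
  dih <- residue_dihedrals(fr, topo)
  flags <- mapply(function(phi, psi)
    as.logical(residue_beta_state(phi, psi, criteria)), dih$phi, dih$psi)
  counts <- tapply(flags, dih$chain, sum)
  pep <- as.vector(counts) >= criteria$min_beta_residues
  list(residue_flags = data.frame(chain = dih$chain, res = dih$res, beta = flags),
       peptide_counts = as.vector(counts),
       peptide_beta = pep,
       beta_fraction = mean(flags))
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' E = 27.888 * (1/r(ON) + 1/r(CH) - 1/r(OH) - 1/r(CN)) kcal/mol for a
#' donor N-H and acceptor C=O. A bond is accepted iff E < threshold
#' (default -0.5 kcal/mol). Any of the four relevant distances below
#' 0.5 Angstrom is treated as a steric clash: no bond, with a warning.
#'
#' @param N,H,C,O length-3 coordinates (Angstrom) of donor N, donor H,
#'   acceptor C, acceptor O
#' @param box_edge cubic box for minimum-image distances; `NULL` disables
#' @return energy in kcal/mol (`Inf` for a clash)
#' @export
hbond_energy <- function(N, H, C, O, box_edge = NULL) {
  rON <- mi_dist(O, N, box_edge); rCH <- mi_dist(C, H, box_edge)
  rOH <- mi_dist(O, H, box_edge); rCN <- mi_dist(C, N, box_edge)
  if (min(rON, rCH, rOH, rCN) < 0.5) {
    warning("hbond_energy: interatomic distance below 0.5 A, treated as clash")
    return(Inf)
  }
  .DSSP_PREFACTOR * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

#' Inter-strand hydrogen bonds between two peptides
#'
#' Scans all donor->acceptor residue pairs across the two peptides in both
#' directions, applying the Kabsch-Sander criterion. Intra-peptide bonds
#' are excluded by construction.
#'
#' @param fr an `agg_frame`
#' @param topo an `agg_topology`
#' @param a,b distinct chain indices
#' @param criteria an `aggkin_criteria`
#' @return data.frame: donor_chain, donor_res, acceptor_chain,
#'   acceptor_res, energy (accepted bonds only)
#' @export
interstrand_hbonds <- function(fr, topo, a, b, criteria = default_criteria()) {
  if (a == b) stop("interstrand_hbonds: a and b must differ")
  validate_frame(fr, topo)
  xyz <- fr$coords; box <- fr$box_edge
  scan <- function(dch, ach) {
    res <- list()
    for (i in seq_len(topo$n_res[[dch]])) {
      Ni <- xyz[atom_index(topo, dch, i, "N"), ]
      Hi <- xyz[atom_index(topo, dch, i, "H"), ]
      for (j in seq_len(topo$n_res[[ach]])) {
        Cj <- xyz[atom_index(topo, ach, j, "C"), ]
        Oj <- xyz[atom_index(topo, ach, j, "O"), ]
        # cheap prefilter: N...O beyond 5.5 A cannot reach threshold
        if (mi_dist(Ni, Oj, box) > 5.5) next
        e <- suppressWarnings(hbond_energy(Ni, Hi, Cj, Oj, box))
        if (is.finite(e) && e < criteria$hb_threshold)
          res[[length(res) + 1L]] <- data.frame(
            donor_chain = dch, donor_res = i,
            acceptor_chain = ach, acceptor_res = j, energy = e)
      }
    }
    res
  }
  out <- c(scan(a, b), scan(b, a))
  if (!length(out))
    return(data.frame(donor_chain = integer(), donor_res = integer(),
                      acceptor_chain = integer(), acceptor_res = integer(),
                      energy = numeric()))
  do.call(rbind, out)
}

#' Inter-peptide side-chain contact count
#'
#' Counts unordered SC-bead pairs from different peptides whose
#' minimum-image distance is at most `cutoff`.
#'
#' @param fr an `agg_frame`
#' @param topo an `agg_topology`
#' @param cutoff contact cutoff in Angstrom
#' @return total count, with attribute `pair_matrix` (chains x chains)
#' @export
sidechain_contacts <- function(fr, topo, cutoff = 6.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  validate_frame(fr, topo)
  sc <- topo$atoms[topo$atoms$role == "SC", ]
  xyz <- fr$coords[sc$atom, , drop = FALSE]
  nc <- n_chains(topo)
  pair <- matrix(0L, nc, nc)
  d <- mi_dist_matrix(xyz, xyz, fr$box_edge)
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit)) {
    ci <- sc$chain[hit[, 1]]; cj <- sc$chain[hit[, 2]]
    keep <- ci != cj
    for (k in which(keep)) {
      i <- min(ci[k], cj[k]); j <- max(ci[k], cj[k])
      pair[i, j] <- pair[i, j] + 1L
    }
  }
  structure(sum(pair), pair_matrix = pair)
}
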