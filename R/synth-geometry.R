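# Idealized coarse-grained structure generators: single peptides from
# backbone torsions, ideal parallel/antiparallel beta-sheets, and
# random-coil boxes. Every emitted fixture is self-verified through the
# analysis stack (structure metrics + sheet clustering) before it is
# returned; an invalid fixture is a hard error, never a silent artifact.

# standard backbone internal coordinates (Angstrom / degrees)
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.0,
            ca_sc = 2.5,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.5, ang_c_n_h = 119.5, ang_n_ca_sc = 110,
            omega = 180)

# Build one chain from per-residue (phi, psi); returns a 6*n_res x 3
# matrix in topology atom order (N, H, CA, C, O, SC per residue).
build_peptide_coords <- function(phi, psi, n_res = length(phi),
                                 sc_alternate = TRUE) {
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  N <- H <- CA <- C <- O <- SC <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$n_ca, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ],
                       .BB$ca_c, .BB$ang_n_ca_c, phi[1])
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                           .BB$c_n, .BB$ang_ca_c_n, psi[i - 1L])
      CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            .BB$n_ca, .BB$ang_c_n_ca, .BB$omega)
      C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                           .BB$ca_c, .BB$ang_n_ca_c, phi[i])
      # amide H: in the peptide plane, anti to the carbonyl O of i-1
      H[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                           .BB$n_h, .BB$ang_c_n_h, 0)
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         .BB$c_o, .BB$ang_ca_c_o, psi[i] + 180)
    sgn <- if (sc_alternate) (-1)^i else 1
    SC[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ],
                          .BB$ca_sc, .BB$ang_n_ca_sc, sgn * 120)
  }
  # N-terminal H: deterministic in-plane placement
  H[1, ] <- place_atom(C[1, ], CA[1, ], N[1, ], .BB$n_h, 118, 180)
  out <- matrix(NA_real_, 6L * n_res, 3)
  for (i in seq_len(n_res)) {
    base <- (i - 1L) * 6L
    out[base + 1L, ] <- N[i, ];  out[base + 2L, ] <- H[i, ]
    out[base + 3L, ] <- CA[i, ]; out[base + 4L, ] <- C[i, ]
    out[base + 5L, ] <- O[i, ];  out[base + 6L, ] <- SC[i, ]
  }
  out
}

# Rotate/translate a chain so the CA1->CAn axis is +x, the backbone
# best-fit plane is the xy-plane, and the CA centroid is the origin.
.canonicalize_strand <- function(coords, n_res) {
  ca_rows <- (seq_len(n_res) - 1L) * 6L + 3L
  bb_rows <- sort(c(ca_rows, ca_rows - 2L, ca_rows + 1L, ca_rows + 2L))
  cen <- colMeans(coords[ca_rows, , drop = FALSE])
  x <- coords[ca_rows[n_res], ] - coords[ca_rows[1L], ]
  x <- x / sqrt(sum(x^2))
  bb <- sweep(coords[bb_rows, , drop = FALSE], 2, cen)
  sv <- svd(bb)
  z <- sv$v[, 3]                       # least-variance direction
  z <- z - sum(z * x) * x
  z <- z / sqrt(sum(z^2))
  y <- cross3(z, x)
  R <- rbind(x, y, z)
  t(R %*% t(sweep(coords, 2, cen)))
}

#' Ideal beta-sheet fixture
#'
#' Builds `n_strands` near-extended peptides stacked at `spacing`
#' Angstrom, with the inter-strand registry chosen by a deterministic
#' scan maximizing the number of accepted DSSP-criterion hydrogen bonds
#' per adjacent pair. The result is verified through the analysis stack:
#' every strand passes the beta-residue rule, every adjacent pair shares
#' at least two H-bonds with the requested orientation, and the strand
#' graph is connected. Failure of any check is a hard error.
#'
#' @param n_strands number of strands (2..20)
#' @param orientation `"parallel"` or `"antiparallel"`
#' @param spacing inter-strand spacing, Angstrom
#' @param sequence one-letter peptide sequence (default GNNQQNY)
#' @param phi,psi backbone torsions, degrees (defaults -160/160: inside
#'   the default beta windows and nearly planar)
#' @param box_edge cubic box, Angstrom
#' @param criteria criteria used for self-verification
#' @return list: `frame` (an `agg_frame`), `topology`, `graph` (verified
#'   `strand_graph`), `partition`
#' @export
build_ideal_sheet <- function(n_strands, orientation = c("parallel", "antiparallel"),
                              spacing = 4.8, sequence = "GNNQQNY",
                              phi = -160, psi = 160, box_edge = 200,
                              criteria = default_criteria()) {
  orientation <- match.arg(orientation)
  if (n_strands < 2L || n_strands > 20L)
    stop("n_strands must be between 2 and 20")
  n_res <- nchar(sequence)
  template <- .canonicalize_strand(build_peptide_coords(phi, psi, n_res), n_res)
  flip_z <- template %*% diag(c(1, -1, -1))   # 180 deg about x
  rot_a <- template %*% diag(c(-1, -1, 1))    # 180 deg about z (reverses axis)
  rot_a_flip <- rot_a %*% diag(c(1, -1, -1))
  topo2 <- topology(sequence, n_chains = 2L)
  count_hb <- function(prev, cand) {
    fr <- frame(rbind(prev, cand), box_edge, 0)
    nrow(interstrand_hbonds(fr, topo2, 1L, 2L, criteria))
  }
  strands <- vector("list", n_strands)
  strands[[1L]] <- template
  for (s in 2L:n_strands) {
    cands <- if (orientation == "parallel") list(template, flip_z)
             else list(rot_a, rot_a_flip)
    if (orientation == "antiparallel" && s %% 2L == 1L)
      cands <- list(template, flip_z)
    best <- NULL; best_n <- -1L; best_dx <- NA
    for (cand in cands) {
      for (dx in seq(-4, 4, by = 0.1)) {
        shifted <- sweep(cand, 2, c(-dx, -(s - 1L) * spacing, 0))
        nhb <- count_hb(strands[[s - 1L]], shifted)
        if (nhb > best_n || (nhb == best_n && abs(dx) < abs(best_dx))) {
          best_n <- nhb; best <- shifted; best_dx <- dx
        }
      }
    }
    if (best_n < criteria$min_hbonds)
      stop("build_ideal_sheet: could not realize >= ", criteria$min_hbonds,
           " H-bonds between strands ", s - 1L, " and ", s,
           " (best ", best_n, ")")
    strands[[s]] <- best
  }
  coords <- do.call(rbind, strands)
  coords <- sweep(coords, 2, box_edge / 2 - colMeans(coords), "+")
  topo <- topology(sequence, n_chains = n_strands)
  fr <- frame(coords, box_edge, 0)
  sg <- strand_graph(fr, topo, criteria)
  part <- clusters(sg)
  # --- self-verification through the analysis stack ---
  if (!all(sg$beta))
    stop("build_ideal_sheet: strand(s) ", paste(which(!sg$beta), collapse = ","),
         " fail the beta-residue rule")
  for (s in 2L:n_strands) {
    e <- sg$edges[(sg$edges$a == s - 1L & sg$edges$b == s), ]
    if (!nrow(e) || e$n_hbonds < criteria$min_hbonds)
      stop("build_ideal_sheet: adjacent pair ", s - 1L, "-", s, " not attached")
    if (e$orientation != orientation)
      stop("build_ideal_sheet: pair ", s - 1L, "-", s, " is ", e$orientation,
           ", wanted ", orientation)
  }
  if (length(part$clusters) != 1L || part$largest != n_strands)
    stop("build_ideal_sheet: strands do not form a single cluster")
  list(frame = fr, topology = topo, graph = sg, partition = part)
}

#' Random-coil box fixture
#'
#' Places `n_peptides` coil-conformation chains (all backbone torsions
#' outside the beta windows) at random positions and orientations with a
#' guaranteed minimum-image centroid separation. Because no residue is in
#' the beta region, the strand graph is empty by construction; this is
#' verified before returning.
#'
#' @param n_peptides number of chains
#' @param box_edge cubic box, Angstrom
#' @param min_separation minimum centroid separation, Angstrom; must be
#'   below `box_edge / 2` (the minimum-image guarantee radius)
#' @param sequence one-letter peptide sequence
#' @param criteria criteria used for self-verification
#' @param max_attempts rejection-sampling budget per chain
#' @return list: `frame`, `topology`, `graph` (verified empty edges)
#' @export
build_random_coil <- function(n_peptides, box_edge = 200, min_separation = 10,
                              sequence = "GNNQQNY",
                              criteria = default_criteria(),
                              max_attempts = 2000L) {
  if (min_separation >= box_edge / 2)
    stop("infeasible: min_separation must be < box_edge/2 ",
         "(minimum-image guarantee)")
  n_res <- nchar(sequence)
  centers <- matrix(NA_real_, n_peptides, 3)
  chains <- vector("list", n_peptides)
  for (k in seq_len(n_peptides)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      cand <- runif(3, 0, box_edge)
      if (k == 1L || all(mi_dist_matrix(matrix(cand, 1),
                                        centers[seq_len(k - 1L), , drop = FALSE],
                                        box_edge) >= min_separation)) {
        centers[k, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible placement density: gave up after ",
                      max_attempts, " attempts for chain ", k)
    # torsions strictly outside the beta windows (phi in (0,150),
    # psi in (-150,0) complement regions)
    phi <- runif(n_res, 30, 120)
    psi <- runif(n_res, -120, -30)
    ch <- build_peptide_coords(phi, psi, n_res)
    ch <- sweep(ch, 2, colMeans(ch))
    ch <- ch %*% t(random_rotation())
    chains[[k]] <- sweep(ch, 2, centers[k, ], "+")
  }
  topo <- topology(sequence, n_chains = n_peptides)
  fr <- frame(do.call(rbind, chains), box_edge, 0)
  sg <- strand_graph(fr, topo, criteria)
  if (nrow(sg$edges))
    stop("build_random_coil: self-verification failed (strand graph not empty)")
  if (any(sg$beta))
    stop("build_random_coil: self-verification failed (beta-state peptide)")
  list(frame = fr, topology = topo, graph = sg)
}
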