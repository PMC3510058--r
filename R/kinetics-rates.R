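# Per-size creation/destruction rate bookkeeping and event totals.
#
# For each aggregate size n and time bin, four rate groups are kept
# separate: creation of size n via the monomer route (n-1 -> n and the
# monomer(s) released by losses), creation via multi-monomer routes
# (fusion, direct monomers->oligomer), and the two matching destruction
# groups. The net rate of creation of size-n species is the combination
# C_mono + C_multi - D_mono - D_multi; summed over n with weight n it
# vanishes in every bin (global mass conservation). Both raw event counts
# and per-time rates are reported, since whether the source normalizes by
# concentration or by time alone is not stated upstream.

# per-event contributions to the four groups; sizes are parsed vectors.
# Returns list(size = integer, group = character), creations first.
.rate_contrib <- function(type, before, after) {
  switch(type,
    monomer_addition = list(size = c(after[1], before),    # destroys n and 1
                            group = c("c_mono", rep("d_mono", length(before)))),
    monomer_loss = list(size = c(after, before[1]),        # creates n-1 and 1
                        group = c(rep("c_mono", length(after)), "d_mono")),
    fusion = list(size = c(after[1], before),
                  group = c("c_multi", rep("d_multi", length(before)))),
    fragmentation = list(size = c(after, before[1]),
                         group = c(rep("c_multi", length(after)), "d_multi")),
    monomers_to_oligomer = list(size = c(after[1], before),
                                group = c("c_multi",
                                          rep("d_multi", length(before)))),
    oligomer_to_monomers = list(size = c(after, before[1]),
                                group = c(rep("c_multi", length(after)),
                                          "d_multi")),
    stop("unknown event type: ", type))
}

.bin_index <- function(time, t0, bin_width) {
  pmax(1L, ceiling((time - t0) / bin_width + 1e-9))
}

#' Per-size, per-bin creation/destruction rates
#'
#' @param events event data.frame ([classify_events()]), sorted by time
#' @param bin_width time bin width (same unit as event times, ps by
#'   convention); must not be smaller than the frame save interval when
#'   one is supplied
#' @param n_max largest aggregate size tracked (default 20)
#' @param t_range length-2 time range; defaults to the event span
#' @param save_interval optional frame save interval for validation
#' @return object of class `rate_series`: arrays `counts[group, size,
#'   bin]`, `rates` (= counts / bin_width), `net_rate[size, bin]`, bin
#'   edges
#' @export
rate_series <- function(events, bin_width, n_max = 20L, t_range = NULL,
                        save_interval = NULL) {
  if (!is.null(save_interval) && !is.na(save_interval) &&
      bin_width < save_interval)
    stop("bin_width (", bin_width, ") below the frame save interval (",
         save_interval, ")")
  if (is.unsorted(events$time)) stop("events must be sorted by time")
  if (is.null(t_range))
    t_range <- if (nrow(events)) range(events$time) else c(0, bin_width)
  nbins <- max(1L, ceiling((t_range[2] - t_range[1]) / bin_width - 1e-9))
  groups <- c("c_mono", "c_multi", "d_mono", "d_multi")
  counts <- array(0, dim = c(4L, n_max, nbins),
                  dimnames = list(groups, NULL, NULL))
  if (nrow(events)) for (i in seq_len(nrow(events))) {
    b <- .bin_index(events$time[i], t_range[1], bin_width)
    if (b > nbins) b <- nbins
    contrib <- .rate_contrib(events$type[i],
                             parse_sizes(events$sizes_before[i]),
                             parse_sizes(events$sizes_after[i]))
    for (k in seq_along(contrib$size)) {
      s <- contrib$size[k]
      if (s <= n_max)
        counts[contrib$group[k], s, b] <- counts[contrib$group[k], s, b] + 1
    }
  }
  net <- counts["c_mono", , , drop = FALSE][1, , ] +
    counts["c_multi", , , drop = FALSE][1, , ] -
    counts["d_mono", , , drop = FALSE][1, , ] -
    counts["d_multi", , , drop = FALSE][1, , ]
  net <- matrix(net, nrow = n_max)
  structure(list(counts = counts, rates = counts / bin_width,
                 net_counts = net, net_rate = net / bin_width,
                 bin_width = bin_width,
                 bin_edges = t_range[1] + bin_width * (0:nbins)),
            class = "rate_series")
}

#' Event totals per time bin
#'
#' M_single counts monomer addition/loss events; M_multi counts oligomer
#' fusion/fragmentation plus direct monomers<->oligomers events,
#' association and dissociation reported separately (with the
#' fusion/fragmentation and direct components also split out).
#'
#' @param events event data.frame
#' @param bin_width time bin width (default 5 ps)
#' @param t_range length-2 time range; defaults to the event span
#' @return data.frame per bin: bin_start, bin_end, m_single_assoc,
#'   m_single_dissoc, m_multi_assoc, m_multi_dissoc, fusion, fragmentation,
#'   monomers_to_oligomer, oligomer_to_monomers
#' @export
event_totals <- function(events, bin_width = 5, t_range = NULL) {
  if (is.null(t_range))
    t_range <- if (nrow(events)) range(events$time) else c(0, bin_width)
  nbins <- max(1L, ceiling((t_range[2] - t_range[1]) / bin_width - 1e-9))
  out <- data.frame(bin_start = t_range[1] + bin_width * (seq_len(nbins) - 1L),
                    bin_end = t_range[1] + bin_width * seq_len(nbins),
                    m_single_assoc = 0L, m_single_dissoc = 0L,
                    m_multi_assoc = 0L, m_multi_dissoc = 0L,
                    fusion = 0L, fragmentation = 0L,
                    monomers_to_oligomer = 0L, oligomer_to_monomers = 0L)
  if (nrow(events)) for (i in seq_len(nrow(events))) {
    b <- min(.bin_index(events$time[i], t_range[1], bin_width), nbins)
    ty <- events$type[i]
    col <- switch(ty,
                  monomer_addition = "m_single_assoc",
                  monomer_loss = "m_single_dissoc",
                  fusion = , monomers_to_oligomer = "m_multi_assoc",
                  fragmentation = , oligomer_to_monomers = "m_multi_dissoc")
    out[b, col] <- out[b, col] + 1L
    if (ty %in% c("fusion", "fragmentation", "monomers_to_oligomer",
                  "oligomer_to_monomers"))
      out[b, ty] <- out[b, ty] + 1L
  }
  out
}

#' Mirror an event stream under time reversal
#'
#' Reversing a trajectory in time swaps addition and loss, fusion and
#' fragmentation, and the two direct monomers<->oligomers types.
#'
#' @param events event data.frame
#' @return event data.frame of the mirrored stream
#' @export
mirror_events <- function(events) {
  out <- events
  out$type <- unname(.MIRROR_TYPE[events$type])
  out$sizes_before <- events$sizes_after
  out$sizes_after <- events$sizes_before
  out$association <- out$type %in% .ASSOC_TYPES
  out
}
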