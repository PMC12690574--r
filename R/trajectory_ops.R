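# Splitting a global multicopy trajectory into per-ligand trajectories and
# the distance screens / residence-time descriptor computed on them.

subset_trajectory <- function(traj, atom_idx, n_ligand_copies = NULL,
                              renumber_copy = FALSE) {
  at <- traj$topology$atoms[atom_idx, , drop = FALSE]
  if (renumber_copy) {
    lig <- at$kind == "ligand"
    at$copy[lig] <- 1L
  }
  if (is.null(n_ligand_copies))
    n_ligand_copies <- length(unique(stats::na.omit(at$copy)))
  cols <- as.vector(rbind(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx))
  topo <- fd_topology(at, n_ligand_copies = n_ligand_copies)
  fd_trajectory(topo, traj$xyz[, cols, drop = FALSE], traj$times_ns,
                box = traj$box, times_known = traj$times_known)
}

#' Strip solvent and split a multicopy trajectory per ligand copy
#'
#' Waters and ions are removed; each ligand copy is paired with the full
#' receptor, yielding one receptor + single-ligand trajectory per copy with
#' frame times preserved.
#'
#' @param traj multicopy [fd_trajectory()].
#' @param replicate_id identifier of the simulation replicate the input
#'   came from (carried on each output).
#' @return list of `fd_trajectory` objects, each with fields `copy_id` and
#'   `replicate` attached.
#' @export
strip_and_split <- function(traj, replicate_id = 1L) {
  at <- traj$topology$atoms
  n_cop <- traj$topology$n_ligand_copies
  if (n_cop < 1) stop("trajectory contains no ligand copies")
  rec_idx <- which(at$kind == "receptor")
  out <- vector("list", n_cop)
  for (cp in seq_len(n_cop)) {
    lig_idx <- which(at$kind == "ligand" & at$copy == cp)
    sub <- subset_trajectory(traj, c(rec_idx, lig_idx), n_ligand_copies = 1L,
                             renumber_copy = TRUE)
    sub$copy_id <- cp
    sub$replicate <- replicate_id
    out[[cp]] <- sub
  }
  out
}

#' Minimum central-atom / receptor distance in one frame
#'
#' The distance between the flagged repulsive-centre (central) atom of the
#' ligand and the nearest receptor atom.
#'
#' @param traj receptor + single-ligand [fd_trajectory()].
#' @param frame frame index (default last).
#' @return distance in Angstrom.
#' @export
central_atom_min_distance <- function(traj, frame = n_frames(traj)) {
  at <- traj$topology$atoms
  cen <- which(at$kind == "ligand" & at$is_central)
  if (length(cen) != 1L)
    stop("exactly one flagged central atom required (found ", length(cen), ")")
  rec <- which(at$kind == "receptor")
  cr <- frame_coords(traj, frame)
  min(sqrt(colSums((t(cr[rec, , drop = FALSE]) - cr[cen, ])^2)))
}

#' Per-frame central-atom minimum-distance series
#' @param traj receptor + single-ligand [fd_trajectory()].
#' @return numeric vector, one distance (Angstrom) per frame.
#' @export
min_distance_series <- function(traj) {
  vapply(seq_len(n_frames(traj)),
         function(i) central_atom_min_distance(traj, i), numeric(1))
}

#' End-of-trajectory distance screen
#'
#' A per-ligand trajectory is discarded when, in its final frame, the
#' central atom sits strictly farther than `cutoff` from every receptor
#' atom.
#'
#' @param traj receptor + single-ligand [fd_trajectory()].
#' @param cutoff screening distance (Angstrom, default 5).
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
end_screen <- function(traj, cutoff = 5) {
  central_atom_min_distance(traj, n_frames(traj)) <= cutoff
}

#' Residence time of a ligand trajectory
#'
#' The residence time (RT) here is a stability descriptor, not a kinetic
#' unbinding time: the duration of the longest window ending at the final
#' frame in which at least `fraction` of the frames have the central atom
#' within `threshold` of the receptor. RT is 0 when the final frame itself
#' is unbound.
#'
#' @param traj receptor + single-ligand [fd_trajectory()] with physical
#'   frame times.
#' @param threshold interaction distance (Angstrom, default 5).
#' @param fraction required bound-frame occupancy of the window (default
#'   0.90).
#' @param scan_all_windows also report the longest qualifying window
#'   anywhere in the trajectory (`rt_any_window_ns`), not only the
#'   end-anchored one.
#' @param series optional precomputed [min_distance_series()].
#' @return list of class `fd_residence` with `rt_ns`, `window_start_ns`,
#'   `window_end_ns`, `bound_fraction` and `final_distance`.
#' @export
residence_time <- function(traj, threshold = 5, fraction = 0.90,
                           scan_all_windows = FALSE, series = NULL) {
  if (!traj$times_known)
    stop("residence time needs physical frame times; supply frame_interval_ns")
  n <- n_frames(traj)
  if (n < 2) stop("residence time needs at least 2 frames")
  if (is.null(series)) series <- min_distance_series(traj)
  bound <- series < threshold
  t <- traj$times_ns
  res <- list(rt_ns = 0, window_start_ns = t[n], window_end_ns = t[n],
              bound_fraction = if (bound[n]) 1 else 0,
              final_distance = series[n])
  if (bound[n]) {
    # suffix windows [i..n]: occupancy via reverse cumulative sum
    suff <- rev(cumsum(rev(bound)))
    len <- n - seq_len(n) + 1
    frac <- suff / len
    ok <- which(frac >= fraction)
    i0 <- min(ok)
    res$rt_ns <- t[n] - t[i0]
    res$window_start_ns <- t[i0]
    res$bound_fraction <- frac[i0]
  }
  if (scan_all_windows) {
    best <- 0; b_i <- NA; b_j <- NA
    cs <- cumsum(bound)
    for (i in seq_len(n)) for (j in i:n) {
      occ <- (cs[j] - cs[i] + bound[i]) / (j - i + 1)
      if (occ >= fraction && t[j] - t[i] > best) {
        best <- t[j] - t[i]; b_i <- i; b_j <- j
      }
    }
    res$rt_any_window_ns <- best
  }
  structure(res, class = "fd_residence")
}

#' Keep the reactive trajectories
#'
#' Reactive trajectories are those whose residence time reaches at least
#' `rt_cutoff` ns of simulation; only these enter the descriptor analysis.
#'
#' @param records list of entries, each a list with elements `traj` and
#'   `residence` (an [residence_time()] result).
#' @param rt_cutoff minimum residence time (ns, default 50).
#' @return the reactive subset of `records`.
#' @export
reactive_filter <- function(records, rt_cutoff = 50) {
  keep <- vapply(records, function(r) r$residence$rt_ns >= rt_cutoff,
                 logical(1))
  records[keep]
}
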