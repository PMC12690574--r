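# Binding-site definition from residue contact sets, Jaccard merging of
# sites, per-site descriptor aggregation across replicates, and the
# consensus vote selecting the most favorable site.

#' Residue contact set of a ligand trajectory
#'
#' Receptor residues with any atom strictly closer than `cutoff` to any
#' ligand atom in the selected frame; the set of residues lining the
#' binding site the ligand occupies.
#'
#' @param traj receptor + single-ligand [fd_trajectory()].
#' @param cutoff contact distance (Angstrom, default 4.5).
#' @param frame frame index (default last, matching the end-anchored
#'   residence window).
#' @param mode `"last"` uses the single frame; `"rt_window"` keeps residues
#'   present in at least half of the frames of the window `[window_start_ns,
#'   last]`.
#' @param window_start_ns start of the averaging window for
#'   `mode = "rt_window"`.
#' @return character vector of residue keys `"chain:resid:resname"`,
#'   sorted; class `fd_contact_set` with the source frame time attached.
#' @export
contact_residues <- function(traj, cutoff = 4.5, frame = n_frames(traj),
                             mode = c("last", "rt_window"),
                             window_start_ns = NULL) {
  mode <- match.arg(mode)
  at <- traj$topology$atoms
  rec <- which(at$kind == "receptor")
  lig <- which(at$kind == "ligand")
  if (!length(lig)) stop("no ligand atoms")
  key <- paste(at$chain[rec], at$resid[rec], at$resname[rec], sep = ":")
  one_frame <- function(f) {
    cc <- frame_coords(traj, f)
    dmin <- cross_min_dist(cc[rec, , drop = FALSE], cc[lig, , drop = FALSE])
    unique(key[dmin < cutoff])
  }
  if (mode == "last") {
    res <- one_frame(frame)
  } else {
    if (is.null(window_start_ns)) stop("window_start_ns required")
    frames <- which(traj$times_ns >= window_start_ns)
    tab <- table(unlist(lapply(frames, one_frame)))
    res <- names(tab)[tab >= length(frames) / 2]
  }
  if (!length(res))
    warning("empty contact set on a reactive trajectory")
  structure(sort(res), class = "fd_contact_set",
            frame_time_ns = traj$times_ns[frame])
}

#' Jaccard index of two sets
#'
#' `J(A, B) = |intersection| / |union|`, with the convention
#' `J(empty, empty) = 0`.
#'
#' @param a,b vectors treated as sets.
#' @return similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(unclass(a)); b <- unique(unclass(b))
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Cluster contact sets into binding sites
#'
#' Greedy sequential clustering in the supplied (deterministic) order: each
#' contact set joins the existing cluster against whose canonical residue
#' set it has the highest Jaccard index, provided that index strictly
#' exceeds `threshold`; otherwise it founds a new site. The canonical set
#' is the running union of members.
#'
#' @param contact_sets list of contact sets, ordered by (replicate,
#'   copy id).
#' @param threshold Jaccard threshold (default 0.35; a tie at exactly the
#'   threshold founds a new site).
#' @return list of clusters, each with `site_id`, `canonical_residues` and
#'   `members` (indices into `contact_sets`).
#' @export
assign_sites <- function(contact_sets, threshold = 0.35) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  clusters <- list()
  for (i in seq_along(contact_sets)) {
    cs <- contact_sets[[i]]
    best_j <- -1; best_c <- 0L
    for (c in seq_along(clusters)) {
      j <- jaccard(cs, clusters[[c]]$canonical_residues)
      if (j > best_j) { best_j <- j; best_c <- c }
    }
    if (best_c > 0L && best_j > threshold) {
      cl <- clusters[[best_c]]
      cl$canonical_residues <- sort(union(cl$canonical_residues,
                                          unclass(cs)))
      cl$members <- c(cl$members, i)
      clusters[[best_c]] <- cl
    } else {
      clusters[[length(clusters) + 1L]] <- list(
        site_id = length(clusters) + 1L,
        canonical_residues = sort(unclass(cs)),
        members = i
      )
    }
  }
  clusters
}

# descriptor columns entering the consensus vote and their favorable sense
.vote_columns <- c(
  n_reactive = "max", best_rt_ns = "max",
  best_e_inter_rt = "min", avg_e_inter_rt = "min",
  best_dg_rt = "min", avg_dg_rt = "min", avg_dg_last20 = "min",
  best_pct_sasa_last = "min", max_hbonds = "max"
)

#' Aggregate per-trajectory descriptors into per-site ranking rows
#'
#' For each site: the count of distinct replicates contributing a reactive
#' trajectory (capped by the number of replicates performed), the best
#' residence time, best and averaged interaction and MM/GBSA energies over
#' the residence window and the last 20 ns, ligand solvent exposure, and
#' the maximum retained hydrogen-bond count. Averages follow the
#' replicate-normalised rule: sum of the site's reactive-trajectory values
#' divided by `n_replicates` (not by the member count).
#'
#' @param clusters output of [assign_sites()].
#' @param records data.frame of per-trajectory descriptors, one row per
#'   contact set, in the same order as the contact sets given to
#'   [assign_sites()]. Expected columns: `replicate`, `copy_id`, `rt_ns`,
#'   `e_inter_rt`, `e_inter_last20`, `dg_rt`, `dg_last20`,
#'   `pct_sasa_last`, `pct_sasa_rt`, `n_hbonds`.
#' @param n_replicates number of independent simulation replicates.
#' @return data.frame of class `fd_ranking`, one row per site.
#' @export
aggregate_sites <- function(clusters, records, n_replicates) {
  rows <- lapply(clusters, function(cl) {
    m <- records[cl$members, , drop = FALSE]
    avg <- function(x) sum(x, na.rm = TRUE) / n_replicates
    data.frame(
      site_id = cl$site_id,
      n_reactive = min(length(unique(m$replicate)), n_replicates),
      n_members = nrow(m),
      best_rt_ns = max(m$rt_ns),
      best_e_inter_rt = min(m$e_inter_rt),
      avg_e_inter_rt = avg(m$e_inter_rt),
      best_e_inter_last20 = min(m$e_inter_last20),
      avg_e_inter_last20 = avg(m$e_inter_last20),
      best_dg_rt = min(m$dg_rt),
      avg_dg_rt = avg(m$dg_rt),
      best_dg_last20 = min(m$dg_last20),
      avg_dg_last20 = avg(m$dg_last20),
      best_pct_sasa_last = min(m$pct_sasa_last),
      best_pct_sasa_rt = min(m$pct_sasa_rt),
      max_hbonds = max(m$n_hbonds),
      votes = 0L
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fd_ranking", class(out))
  out
}

#' Consensus vote over per-site descriptor columns
#'
#' Each ranked descriptor column awards one vote to the site holding its
#' most favorable value (all sites tied at the optimum share the vote).
#' The site with the most votes is selected; exact vote ties are broken by
#' the lower averaged MM/GBSA energy, then the lower averaged interaction
#' energy, and flagged as tie-broken.
#'
#' @param rows an `fd_ranking` data.frame from [aggregate_sites()].
#' @return list with `ranking` (rows with votes, ordered by votes then
#'   tie-breakers), `selected_site` and `tie_broken`.
#' @export
consensus_vote <- function(rows) {
  if (!nrow(rows)) stop("no ranking rows")
  votes <- integer(nrow(rows))
  for (col in names(.vote_columns)) {
    v <- rows[[col]]
    best <- if (.vote_columns[[col]] == "max") max(v) else min(v)
    winners <- which(v == best)
    votes[winners] <- votes[winners] + 1L
  }
  rows$votes <- votes
  top <- which(votes == max(votes))
  tie_broken <- FALSE
  if (length(top) > 1) {
    tie_broken <- TRUE
    ord <- order(rows$avg_dg_rt[top], rows$avg_e_inter_rt[top])
    top <- top[ord[1]]
  }
  ord_all <- order(-rows$votes, rows$avg_dg_rt, rows$avg_e_inter_rt)
  list(ranking = rows[ord_all, , drop = FALSE],
       selected_site = rows$site_id[top[1]],
       tie_broken = tie_broken)
}
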