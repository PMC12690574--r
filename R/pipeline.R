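# End-to-end analysis: multicopy replicate trajectories in, consensus
# binding-site ranking out.

#' Analyze a ligand trajectory into its descriptor record
#'
#' Runs the full per-trajectory descriptor battery on one stripped
#' receptor + single-ligand trajectory: distance screens, residence time,
#' interaction and MM/GBSA energies over the residence window and the last
#' 20 ns, the block stability filter, solvent exposure, hydrogen bonds and
#' the residue contact set.
#'
#' @param traj receptor + single-ligand [fd_trajectory()] (from
#'   [strip_and_split()]).
#' @param config an [load_config()] configuration.
#' @param n_points SASA point count used inside the pipeline.
#' @param max_energy_frames cap on the number of frames entering the
#'   MM/GBSA averages (frames are taken at a uniform stride of the
#'   residence window).
#' @return `NULL` when the trajectory fails the end screen or the reactive
#'   cutoff; otherwise a one-row data.frame of descriptors plus attributes
#'   `contact_set` and `stability`.
#' @export
analyze_ligand_trajectory <- function(traj, config = load_config(),
                                      n_points = 240,
                                      max_energy_frames = 60) {
  series <- min_distance_series(traj)
  n <- n_frames(traj)
  if (series[n] > config$interaction_cutoff) return(NULL)   # end screen
  res <- residence_time(traj, threshold = config$interaction_cutoff,
                        fraction = config$rt_occupancy_fraction,
                        series = series)
  if (res$rt_ns < config$rt_cutoff_ns) return(NULL)         # reactive cutoff
  t <- traj$times_ns
  # energy/SASA averages run over the *bound* frames of the residence
  # window: the occupancy criterion tolerates brief unbound blips, whose
  # non-interacting frames would only dilute the binding-energy estimates
  bound <- series < config$interaction_cutoff
  rt_frames <- which(t >= res$window_start_ns & bound)
  last20_frames <- which(t >= max(t) - config$hbond_window_ns)
  stride <- max(1L, ceiling(length(rt_frames) / max_energy_frames))
  eval_frames <- sort(union(rt_frames[seq(1, length(rt_frames), by = stride)],
                            last20_frames))
  mm <- mmgbsa_binding(traj, frames = eval_frames, n_points = n_points)
  pf <- mm$per_frame
  in20 <- pf$time_ns >= max(t) - config$hbond_window_ns
  stab <- stability_filter(pf$time_ns, pf$dG_bind,
                           block_ns = config$stability_block_ns,
                           scale = config$stability_sd_scale)
  sasa_last <- percent_exposed(traj, n_points = n_points)
  sasa_frames <- rt_frames[unique(round(seq(1, length(rt_frames),
                                            length.out = min(8, length(rt_frames)))))]
  pct_rt <- mean(vapply(sasa_frames, function(f)
    percent_exposed(traj, frame = f, n_points = n_points)$percent_exposed,
    numeric(1)))
  hb <- hydrogen_bonds(traj, window_ns = config$hbond_window_ns,
                       dist_cutoff = config$hbond_distance_cutoff,
                       angle_min_deg = config$hbond_angle_min_deg,
                       occupancy_min = config$hbond_occupancy_min)
  cs <- contact_residues(traj, cutoff = config$contact_cutoff)
  rec <- data.frame(
    replicate = traj$replicate %||% NA_integer_,
    copy_id = traj$copy_id %||% NA_integer_,
    rt_ns = res$rt_ns,
    bound_fraction = res$bound_fraction,
    final_distance = res$final_distance,
    e_inter_rt = mean(pf$E_inter),
    e_inter_last20 = mean(pf$E_inter[in20]),
    dg_rt = mean(pf$dG_bind),
    dg_last20 = mean(pf$dG_bind[in20]),
    pct_sasa_last = sasa_last$percent_exposed,
    pct_sasa_rt = pct_rt,
    n_hbonds = hb$n_retained,
    stability_keep = stab$keep
  )
  attr(rec, "contact_set") <- cs
  attr(rec, "stability") <- stab
  rec
}

#' Full multicopy analysis across replicates
#'
#' Splits each replicate's multicopy trajectory per ligand copy, applies
#' the end-of-trajectory distance screen, the residence-time (reactive)
#' cutoff and the block stability filter, computes the descriptor battery
#' for the surviving trajectories, clusters their residue contact sets
#' into binding sites by Jaccard similarity, aggregates descriptors per
#' site and runs the consensus vote.
#'
#' @param replicate_trajs list of multicopy [fd_trajectory()] objects, one
#'   per independent replicate.
#' @param config an [load_config()] configuration.
#' @param n_points SASA point count used inside the pipeline.
#' @return list of class `fd_analysis` with `records` (per reactive
#'   trajectory), `contact_sets`, `clusters`, `ranking`, `consensus`
#'   (see [consensus_vote()]) and screening counters.
#' @export
analyze_replicates <- function(replicate_trajs, config = load_config(),
                               n_points = 240) {
  records <- list(); contact_sets <- list()
  n_total <- 0L; n_screened_out <- 0L; n_unstable <- 0L
  for (r in seq_along(replicate_trajs)) {
    ligs <- strip_and_split(replicate_trajs[[r]], replicate_id = r)
    for (lt in ligs) {
      n_total <- n_total + 1L
      rec <- analyze_ligand_trajectory(lt, config, n_points = n_points)
      if (is.null(rec)) { n_screened_out <- n_screened_out + 1L; next }
      if (!rec$stability_keep) { n_unstable <- n_unstable + 1L; next }
      records[[length(records) + 1L]] <- rec
      contact_sets[[length(contact_sets) + 1L]] <- attr(rec, "contact_set")
    }
  }
  if (!length(records))
    return(structure(list(records = NULL, contact_sets = list(),
                          clusters = list(), ranking = NULL, consensus = NULL,
                          n_total = n_total, n_screened_out = n_screened_out,
                          n_unstable = n_unstable),
                     class = "fd_analysis"))
  rec_df <- do.call(rbind, records)
  ord <- order(rec_df$replicate, rec_df$copy_id)
  rec_df <- rec_df[ord, , drop = FALSE]
  contact_sets <- contact_sets[ord]
  clusters <- assign_sites(contact_sets, threshold = config$jaccard_threshold)
  ranking <- aggregate_sites(clusters, rec_df, config$n_replicates)
  consensus <- consensus_vote(ranking)
  structure(list(records = rec_df, contact_sets = contact_sets,
                 clusters = clusters, ranking = ranking,
                 consensus = consensus, n_total = n_total,
                 n_screened_out = n_screened_out, n_unstable = n_unstable),
            class = "fd_analysis")
}

#' @export
print.fd_analysis <- function(x, ...) {
  cat("fd_analysis:", x$n_total, "ligand trajectories;",
      x$n_screened_out, "screened out;", x$n_unstable, "unstable;",
      length(x$clusters), "binding sites\n")
  if (!is.null(x$consensus)) {
    cat("selected site:", x$consensus$selected_site,
        if (x$consensus$tie_broken) "(tie-broken)\n" else "\n")
  }
  invisible(x)
}
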