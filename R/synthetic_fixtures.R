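# Synthetic fixtures: a coarse bead receptor with cup-shaped pockets, rigid
# fragment copies following programmed binding/unbinding event schedules,
# and analytically known ground truth (residence times, contact residues,
# dominant site). Everything is reproducible from (spec, seed) alone.
#
# Trajectories are kinematic - programmed positions plus seeded noise - not
# dynamical. Energetic ordering between sites is controlled through the
# assigned charges, so "tight" sites really do score better on the energy
# descriptors.

#' Specification of a synthetic multicopy fixture
#'
#' @param seed RNG seed; every derived structure and trajectory is a pure
#'   function of the spec including this seed.
#' @param n_residues receptor residues (two beads each: backbone CA and one
#'   sidechain bead).
#' @param n_pockets number of binding pockets (1..4), built as concave bead
#'   cups at maximally separated surface anchors.
#' @param pocket_size residues per pocket.
#' @param n_copies ligand copies per replicate.
#' @param n_replicates independent replicates.
#' @param production_ns trajectory length (ns).
#' @param frame_interval_ns frame spacing (ns).
#' @param events per-replicate, per-copy event schedules; `NULL` selects
#'   the default dominant-site programme (see
#'   [default_event_schedule()]).
#' @param pose_jitter_A tangential pose offset drawn once per bound event
#'   (Angstrom).
#' @param vib_A thermal-motion amplitude (Angstrom): smooth randomized
#'   low-frequency breathing around the pose, emulating the autocorrelated
#'   motion of a bound ligand.
#' @return list of class `fd_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_residues = 40, n_pockets = 2,
                         pocket_size = 6, n_copies = 4, n_replicates = 4,
                         production_ns = 400, frame_interval_ns = 4,
                         events = NULL, pose_jitter_A = 0.25,
                         vib_A = 0.12) {
  if (n_pockets < 1 || n_pockets > 4) stop("n_pockets must be 1..4")
  if (n_residues < 2 * n_pockets * pocket_size)
    stop("n_residues too small for the requested pockets")
  spec <- structure(list(
    seed = seed, n_residues = n_residues, n_pockets = n_pockets,
    pocket_size = pocket_size, n_copies = n_copies,
    n_replicates = n_replicates, production_ns = production_ns,
    frame_interval_ns = frame_interval_ns, events = events,
    pose_jitter_A = pose_jitter_A, vib_A = vib_A
  ), class = "fd_fixture_spec")
  if (is.null(spec$events)) spec$events <- default_event_schedule(spec)
  validate_events(spec)
  spec
}

validate_events <- function(spec) {
  for (r in seq_len(spec$n_replicates)) for (cp in seq_len(spec$n_copies)) {
    ev <- spec$events[[r]][[cp]]
    if (any(ev$start_ns >= ev$end_ns)) stop("empty fixture event")
    if (nrow(ev) > 1 && any(ev$start_ns[-1] < ev$end_ns[-nrow(ev)]))
      stop("overlapping fixture events for copy ", cp)
    bad <- !is.na(ev$site) & (ev$site < 1 | ev$site > spec$n_pockets)
    if (any(bad)) stop("event references unknown pocket")
  }
  invisible(TRUE)
}

#' Default dominant-site event programme
#'
#' Copy 1 binds the dominant pocket (site 1) from early-to-mid trajectory
#' to the end (residence times staggered across replicates); copy 2 binds
#' the secondary pocket late in replicates 1-2 only; copy 3 never binds;
#' copy 4 binds early but unbinds, so the end-of-trajectory screen drops
#' it. The dominant site therefore leads on reactive count, residence time,
#' interaction energies (larger pocket charges, shorter contact) and
#' hydrogen bonds.
#'
#' @param spec an [fixture_spec()] (its `events` field is ignored).
#' @return nested list `events[[replicate]][[copy]]`, each a data.frame
#'   with columns `site` (`NA` = unbound), `start_ns`, `end_ns`,
#'   `dist_A`.
#' @export
default_event_schedule <- function(spec) {
  P <- spec$production_ns
  lapply(seq_len(spec$n_replicates), function(r) {
    tb <- 0.30 * P + (r - 1) * 0.025 * P
    lapply(seq_len(spec$n_copies), function(cp) {
      if (cp == 1) {
        data.frame(site = c(NA, 1), start_ns = c(0, tb), end_ns = c(tb, P),
                   dist_A = c(NA, 2.85))
      } else if (cp == 2 && r <= 2) {
        data.frame(site = c(NA, 2), start_ns = c(0, 0.8 * P),
                   end_ns = c(0.8 * P, P), dist_A = c(NA, 3.4))
      } else if (cp == 4) {
        data.frame(site = c(1, NA), start_ns = c(0, 0.5 * P),
                   end_ns = c(0.5 * P, P), dist_A = c(2.85, NA))
      } else {
        data.frame(site = NA, start_ns = 0, end_ns = P, dist_A = NA)
      }
    })
  })
}

.pocket_anchors <- rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0), c(-1, 0, 0))

# two unit tangents orthogonal to u
tangent_frame <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- a - sum(a * u) * u
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  rbind(t1, t2)
}

#' Build the toy bead receptor of a fixture
#'
#' `n_residues` residues on a spherical shell (radius 11 Angstrom), one
#' backbone CA bead and one sidechain bead each. Pocket residues get their
#' sidechain beads rearranged into a concave cup around a site point 4
#' Angstrom above the surface anchor: one acceptor bead at the cup bottom
#' and the rest as a surrounding ring. Cup beads carry elevated positive
#' charges (dominant pocket strongest), everything else near-neutral.
#'
#' @param spec an [fixture_spec()].
#' @return list with `topology`, `coords` (single frame), `pockets` (per
#'   pocket: residue keys, site point, anchor unit vector, bottom-bead
#'   index) and `radius`.
#' @export
make_toy_receptor <- function(spec) {
  set.seed(spec$seed)
  R <- 11
  n <- spec$n_residues
  dirs <- sphere_points(n)
  # assign pocket residues: nearest CAs to each anchor, disjoint
  pocket_of <- rep(NA_integer_, n)
  for (p in seq_len(spec$n_pockets)) {
    u <- .pocket_anchors[p, ]
    sc <- dirs %*% u
    sc[!is.na(pocket_of)] <- -Inf
    pocket_of[order(sc, decreasing = TRUE)[seq_len(spec$pocket_size)]] <- p
  }
  ca <- dirs * R
  sc_pos <- dirs * (R + 1.5)
  sc_el <- rep("C", n)
  sc_q <- rep_len(c(0.05, -0.05), n)
  pockets <- vector("list", spec$n_pockets)
  for (p in seq_len(spec$n_pockets)) {
    u <- .pocket_anchors[p, ]
    site_point <- u * (R + 4)
    idx <- which(pocket_of == p)
    # order by angular closeness to the anchor; first becomes the cup bottom
    idx <- idx[order(-(dirs[idx, ] %*% u))]
    tf <- tangent_frame(u)
    bottom_dist <- if (p == 1) 2.85 else 3.4
    sc_pos[idx[1], ] <- site_point - bottom_dist * u
    ring <- idx[-1]
    th <- 2 * pi * (seq_along(ring) - 1) / max(1, length(ring))
    for (k in seq_along(ring)) {
      v <- -0.3 * u + 0.95 * (cos(th[k]) * tf[1, ] + sin(th[k]) * tf[2, ])
      v <- v / sqrt(sum(v^2))
      sc_pos[ring[k], ] <- site_point + 3.3 * v
    }
    # acidic cup: strong acceptor charges in the dominant pocket, weak in
    # the others, so the cationic probe binds it measurably tighter
    sc_el[idx] <- if (p == 1) "O" else "N"
    sc_q[idx] <- if (p == 1) -0.25 else -0.08
    sc_q[idx[1]] <- if (p == 1) -0.45 else -0.15
    pockets[[p]] <- list(
      residues = sort(paste("A", idx, "ALA", sep = ":")),
      site_point = site_point, anchor = u,
      bottom_residue = idx[1]
    )
  }
  atoms <- data.frame(
    serial = seq_len(2 * n),
    name = rep(c("CA", "CB"), n),
    element = as.vector(rbind(rep("C", n), sc_el)),
    resname = "ALA", resid = rep(seq_len(n), each = 2), chain = "A",
    kind = "receptor", stringsAsFactors = FALSE
  )
  atoms$charge <- as.vector(rbind(rep(0, n), sc_q))
  atoms$lj_epsilon <- ifelse(atoms$element == "H", 0.016, 0.12)
  atoms$lj_rmin_half <- c(H = 0.6, C = 1.91, N = 1.82, O = 1.66,
                          S = 2.0)[atoms$element]
  coords <- matrix(NA_real_, 2 * n, 3)
  coords[seq(1, 2 * n, 2), ] <- ca
  coords[seq(2, 2 * n, 2), ] <- sc_pos
  topo <- fd_topology(atoms, n_ligand_copies = 0L)
  list(topology = topo, coords = coords, pockets = pockets, radius = R)
}

# rigid 4-atom fragment template in a local frame (u = outward unit at the
# site, t = tangent): N1 is the central atom at the origin; net charge +0.6
# (a protonated-amine-like probe)
.ligand_template <- function() {
  data.frame(
    name = c("N1", "H1", "C1", "C2"),
    element = c("N", "H", "C", "C"),
    charge = c(-0.30, 0.35, 0.30, 0.25),
    lj_epsilon = c(0.17, 0.016, 0.11, 0.11),
    lj_rmin_half = c(1.82, 0.6, 1.91, 1.91),
    stringsAsFactors = FALSE
  )
}

ligand_local_coords <- function(u, t1) {
  rbind(c(0, 0, 0),          # N1 (central)
        -1.0 * u,            # H1, pointing at the cup-bottom acceptor
        1.3 * u + 0.5 * t1,  # C1
        2.4 * u)             # C2
}

#' Generate a programmed multicopy trajectory with ground truth
#'
#' Each ligand copy follows its event schedule: during bound events the
#' central atom sits at the pocket's site point (tangential pose offset
#' drawn once per event, small AR(1) vibration per frame); during unbound
#' events the copy is parked on a far shell (> 12 Angstrom from every
#' receptor atom). A decorative water/ion set exercises solvent stripping.
#' The ground truth (residence times via an independent exhaustive window
#' scan over the programmed bound mask, true contact residues, dominant
#' site) is computed from the spec alone.
#'
#' @param receptor output of [make_toy_receptor()].
#' @param spec the same [fixture_spec()].
#' @param replicate replicate index (seeds the trajectory noise).
#' @return list with `trajectory` (multicopy [fd_trajectory()]) and
#'   `truth` (per-copy data.frame plus pocket residue lists and
#'   `best_site`).
#' @export
make_programmed_trajectory <- function(receptor, spec, replicate = 1L) {
  set.seed(spec$seed + 7919L * replicate)
  R <- receptor$radius
  times <- seq(0, spec$production_ns, by = spec$frame_interval_ns)
  nf <- length(times)
  events <- spec$events[[replicate]]
  lt <- .ligand_template()
  n_lig_at <- nrow(lt)

  # pre-draw all noise in a fixed order (independent of the schedule)
  pose_off <- lapply(seq_len(spec$n_copies), function(cp)
    matrix(stats::runif(2 * nrow(events[[cp]]), -spec$pose_jitter_A,
                        spec$pose_jitter_A), ncol = 2))
  # thermal motion emulated as smooth low-frequency breathing (bound-ligand
  # coordinates in MD are strongly autocorrelated, not white noise); a
  # single randomized oscillation mode per event
  vib_par <- lapply(seq_len(spec$n_copies), function(cp) {
    ne <- nrow(events[[cp]])
    dir <- matrix(stats::rnorm(3 * ne), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    list(dir = dir,
         amp = stats::runif(ne, 0.5, 1) * spec$vib_A,
         period = stats::runif(ne, 50, 130),
         phase = stats::runif(ne, 0, 2 * pi))
  })
  vib_at <- function(cp, k, t) {
    vp <- vib_par[[cp]]
    vp$amp[k] * sin(2 * pi * t / vp$period[k] + vp$phase[k]) * vp$dir[k, ]
  }
  far_dir <- lapply(seq_len(spec$n_copies), function(cp) {
    m <- matrix(stats::rnorm(3 * nf), ncol = 3)
    m / sqrt(rowSums(m^2))
  })

  # waters + ions, parked far out
  n_wat <- 12L
  wat_dir <- sphere_points(n_wat)
  wat_pos <- wat_dir * (R + 28)
  ion_pos <- rbind(c(0, 0, R + 32), c(0, 0, -(R + 32)))

  rec_at <- receptor$topology$atoms
  lig_at <- do.call(rbind, lapply(seq_len(spec$n_copies), function(cp) {
    a <- lt
    a$resname <- "LIG"; a$resid <- 1000L + cp; a$chain <- "L"
    a$kind <- "ligand"; a$copy <- cp
    a$is_central <- a$name == "N1"
    a$type <- ifelse(a$name == "N1", "N99", a$name)
    a
  }))
  wat_at <- data.frame(
    name = "O", element = "O", charge = -0.834, lj_epsilon = 0.152,
    lj_rmin_half = 1.77, resname = "WAT",
    resid = 2000L + seq_len(n_wat), chain = "W", kind = "water",
    stringsAsFactors = FALSE
  )
  ion_at <- data.frame(
    name = "NA", element = "NA", charge = 1, lj_epsilon = 0.0874,
    lj_rmin_half = 1.369, resname = "NA+", resid = 3000L + 1:2,
    chain = "I", kind = "ion", stringsAsFactors = FALSE
  )
  fill <- function(df) {
    for (col in c("copy")) if (is.null(df[[col]])) df[[col]] <- NA_integer_
    if (is.null(df$is_central)) df$is_central <- FALSE
    if (is.null(df$type)) df$type <- df$name
    df
  }
  cols <- c("name", "element", "resname", "resid", "chain", "kind", "copy",
            "charge", "lj_epsilon", "lj_rmin_half", "is_central", "type")
  all_at <- rbind(fill(rec_at)[cols], fill(lig_at)[cols], fill(wat_at)[cols],
                  fill(ion_at)[cols])
  all_at$serial <- seq_len(nrow(all_at))
  topo <- fd_topology(all_at, n_ligand_copies = spec$n_copies)

  n_rec <- nrow(rec_at)
  n_at <- nrow(all_at)
  xyz <- matrix(NA_real_, nf, 3 * n_at)
  base <- matrix(NA_real_, n_at, 3)
  base[seq_len(n_rec), ] <- receptor$coords
  base[n_rec + spec$n_copies * n_lig_at + seq_len(n_wat), ] <- wat_pos
  base[n_rec + spec$n_copies * n_lig_at + n_wat + 1:2, ] <- ion_pos

  for (f in seq_len(nf)) {
    cc <- base
    t <- times[f]
    for (cp in seq_len(spec$n_copies)) {
      ev <- events[[cp]]
      k <- findInterval(t, ev$start_ns)
      site <- ev$site[k]
      rows <- n_rec + (cp - 1) * n_lig_at + seq_len(n_lig_at)
      if (is.na(site)) {
        u <- far_dir[[cp]][f, ]
        centre <- u * (R + 30)
        tf <- tangent_frame(u)
        cc[rows, ] <- sweep(ligand_local_coords(u, tf[1, ]), 2, centre, "+")
      } else {
        pk <- receptor$pockets[[site]]
        u <- pk$anchor
        tf <- tangent_frame(u)
        off <- pose_off[[cp]][k, ]
        centre <- pk$site_point + off[1] * tf[1, ] + off[2] * tf[2, ] +
          vib_at(cp, k, t)
        # aim H1 at the cup-bottom acceptor so the bond stays near-linear
        bottom <- 2L * pk$bottom_residue
        aim <- centre - receptor$coords[bottom, ]
        aim <- aim / sqrt(sum(aim^2))
        cc[rows, ] <- sweep(ligand_local_coords(aim, tf[1, ]), 2, centre, "+")
      }
    }
    wrows <- n_rec + spec$n_copies * n_lig_at + seq_len(n_wat)
    cc[wrows, ] <- wat_pos + matrix(stats::rnorm(3 * n_wat, sd = 0.1),
                                    ncol = 3)
    xyz[f, ] <- as.vector(t(cc))
  }
  traj <- fd_trajectory(topo, xyz, times, times_known = TRUE)
  list(trajectory = traj,
       truth = fixture_ground_truth(spec, receptor, replicate))
}

# independent exhaustive suffix-window scan (O(n^2)); the analysis oracle
rt_truth_scan <- function(times, bound, fraction = 0.90) {
  n <- length(times)
  if (!bound[n]) return(0)
  for (i in seq_len(n)) {
    if (mean(bound[i:n]) >= fraction) return(times[n] - times[i])
  }
  0
}

# programmed bound/unbound mask of one copy on the frame grid
events_bound_mask <- function(ev, times) {
  !is.na(ev$site[findInterval(times, ev$start_ns)])
}

#' Ground truth of a programmed fixture
#'
#' Derived deterministically from the event schedule alone: per-copy final
#' site, residence time (independent exhaustive window scan over the
#' programmed bound mask), and the dominant (best) site across all
#' replicates — the site with reactive trajectories from the most distinct
#' replicates, ties broken by the longest residence time.
#'
#' @param spec an [fixture_spec()].
#' @param receptor output of [make_toy_receptor()] (for the pocket residue
#'   lists).
#' @param replicate replicate whose per-copy table to return.
#' @param rt_cutoff reactive-trajectory cutoff used for the dominant-site
#'   tally (ns).
#' @return list with `per_copy`, `pocket_residues` and `best_site`.
#' @export
fixture_ground_truth <- function(spec, receptor, replicate = 1L,
                                 rt_cutoff = 50) {
  times <- seq(0, spec$production_ns, by = spec$frame_interval_ns)
  nf <- length(times)
  copy_row <- function(r, cp) {
    ev <- spec$events[[r]][[cp]]
    mask <- events_bound_mask(ev, times)
    data.frame(replicate = r, copy = cp,
               site = ev$site[findInterval(times[nf], ev$start_ns)],
               bound_at_end = mask[nf],
               true_rt_ns = rt_truth_scan(times, mask))
  }
  all_rows <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(r)
    do.call(rbind, lapply(seq_len(spec$n_copies), function(cp)
      copy_row(r, cp)))))
  reactive <- all_rows[!is.na(all_rows$site) & all_rows$bound_at_end &
                         all_rows$true_rt_ns >= rt_cutoff, , drop = FALSE]
  best_site <- NA_integer_
  if (nrow(reactive)) {
    counts <- tapply(reactive$replicate, reactive$site,
                     function(x) length(unique(x)))
    rts <- tapply(reactive$true_rt_ns, reactive$site, max)
    ord <- order(-counts, -rts)
    best_site <- as.integer(names(counts)[ord[1]])
  }
  list(per_copy = all_rows[all_rows$replicate == replicate, , drop = FALSE],
       pocket_residues = lapply(receptor$pockets, `[[`, "residues"),
       best_site = best_site)
}

#' Generate one complete seeded fixture (all replicates)
#'
#' @param seed integer seed.
#' @param ... passed to [fixture_spec()].
#' @return list with `spec`, `receptor`, `replicates` (list of
#'   [make_programmed_trajectory()] outputs) and `truth` of the first
#'   replicate's schedule.
#' @export
make_fixture <- function(seed = 1, ...) {
  spec <- fixture_spec(seed = seed, ...)
  receptor <- make_toy_receptor(spec)
  reps <- lapply(seq_len(spec$n_replicates), function(r)
    make_programmed_trajectory(receptor, spec, r))
  list(spec = spec, receptor = receptor, replicates = reps)
}

#' Random small two-group system for energy-oracle tests
#'
#' Non-overlapping random atoms (minimum separation 1.5 Angstrom) with
#' random finite charges and Lennard-Jones parameters in physical ranges,
#' split into a receptor group and a ligand group.
#'
#' @param n_rec,n_lig group sizes.
#' @param seed RNG seed.
#' @return list with `topology` and `coords`.
#' @export
make_energy_test_system <- function(n_rec = 10, n_lig = 15, seed = 1) {
  set.seed(seed)
  n <- n_rec + n_lig
  coords <- matrix(NA_real_, n, 3)
  placed <- 0L
  while (placed < n) {
    cand <- stats::runif(3, 0, 14)
    if (placed == 0L ||
        min(sqrt(colSums((t(coords[seq_len(placed), , drop = FALSE]) -
                            cand)^2))) > 1.5) {
      placed <- placed + 1L
      coords[placed, ] <- cand
    }
  }
  atoms <- data.frame(
    serial = seq_len(n),
    name = paste0("X", seq_len(n)),
    element = sample(c("C", "N", "O"), n, replace = TRUE),
    resname = c(rep("REC", n_rec), rep("LIG", n_lig)),
    resid = c(rep(1L, n_rec), rep(2L, n_lig)),
    chain = c(rep("A", n_rec), rep("L", n_lig)),
    kind = c(rep("receptor", n_rec), rep("ligand", n_lig)),
    copy = c(rep(NA_integer_, n_rec), rep(1L, n_lig)),
    charge = stats::runif(n, -0.5, 0.5),
    lj_epsilon = stats::runif(n, 0.05, 0.3),
    lj_rmin_half = stats::runif(n, 1.2, 2.0),
    stringsAsFactors = FALSE
  )
  list(topology = fd_topology(atoms, n_ligand_copies = 1L), coords = coords)
}
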