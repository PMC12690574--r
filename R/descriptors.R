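# Per-trajectory descriptor battery: intermolecular nonbonded energy,
# generalized-Born polar solvation, Shrake-Rupley SASA, the MM/GBSA binding
# free energy under the one-trajectory approximation, the block-wise
# stability filter, ligand solvent exposure and hydrogen-bond occupancy.

#' Intermolecular nonbonded energy between receptor and ligand
#'
#' Sum over all receptor-ligand atom pairs of the Lennard-Jones energy
#' (epsilon/rmin combination by Lorentz-Berthelot) plus the Coulomb energy
#' `332.0637 * qi * qj / r`. No cutoff, vacuum dielectric 1. Pairs of
#' flagged repulsive-centre atoms use the purely repulsive branch.
#'
#' @param coords single-frame n x 3 coordinates.
#' @param topology an [fd_topology()] with parameters loaded.
#' @param group_a,group_b atom index vectors; default receptor vs all
#'   ligand atoms.
#' @return list with `E_vdW`, `E_elec` and `E_inter = E_vdW + E_elec`
#'   (kcal/mol).
#' @export
nonbonded_inter_energy <- function(coords, topology, group_a = NULL,
                                   group_b = NULL) {
  at <- topology$atoms
  cc <- matrix(as.numeric(coords), ncol = 3)
  if (is.null(group_a)) group_a <- which(at$kind == "receptor")
  if (is.null(group_b)) group_b <- which(at$kind == "ligand")
  if (!length(group_a) || !length(group_b))
    stop("both atom groups must be nonempty")
  need <- c(group_a, group_b)
  if (any(!is.finite(at$charge[need])) || any(!is.finite(at$lj_epsilon[need])))
    stop("nonbonded parameters missing; run read_params() first")
  r <- cross_dist(cc[group_a, , drop = FALSE], cc[group_b, , drop = FALSE])
  if (any(r < 1e-6)) {
    w <- which(r < 1e-6, arr.ind = TRUE)[1, ]
    stop("overlapping atoms: serial ", at$serial[group_a[w[1]]], " and ",
         at$serial[group_b[w[2]]])
  }
  eps <- sqrt(outer(at$lj_epsilon[group_a], at$lj_epsilon[group_b]))
  rmin <- outer(at$lj_rmin_half[group_a], at$lj_rmin_half[group_b], "+")
  sr6 <- (rmin / r)^6
  lj <- eps * (sr6^2 - 2 * sr6)
  both_central <- outer(at$is_central[group_a], at$is_central[group_b], "&")
  if (any(both_central)) lj[both_central] <- (eps * sr6^2)[both_central]
  qq <- outer(at$charge[group_a], at$charge[group_b])
  elec <- COULOMB_CONST * qq / r
  e_vdw <- sum(lj); e_elec <- sum(elec)
  list(E_vdW = e_vdw, E_elec = e_elec, E_inter = e_vdw + e_elec)
}

# HCT pairwise-descreening effective Born radii (no dielectric offset, so a
# lone atom's effective radius equals its intrinsic radius)
hct_effective_radii <- function(coords, radii, scales) {
  cc <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(cc)
  if (any(radii <= 0)) stop("intrinsic radii must be > 0")
  inv <- 1 / radii
  if (n > 1) {
    r <- cross_dist(cc, cc)                       # r[i, j]
    rho <- matrix(radii, n, n)                    # rho_i by row
    s <- matrix(scales * radii, n, n, byrow = TRUE)  # descreener s_j by col
    L <- pmax(rho, abs(r - s))
    U <- r + s
    diag(r) <- 1                                  # dummy, masked below
    I <- 1 / L - 1 / U + 0.25 * (r - s^2 / r) * (1 / U^2 - 1 / L^2) +
      0.5 * log(L / U) / r
    engulfed <- rho < s - r
    I[engulfed] <- I[engulfed] + (2 * (1 / rho - 1 / L))[engulfed]
    I[U <= rho] <- 0                              # descreener buried inside i
    diag(I) <- 0
    inv <- inv - 0.5 * rowSums(I)
  }
  ifelse(inv > 1 / 30, 1 / inv, 30)  # clamp runaway radii at 30 A
}

#' Generalized-Born polar solvation energy
#'
#' Pairwise generalized-Born energy with Still's interpolation function and
#' HCT-style pairwise-descreening effective radii; interior dielectric 1,
#' solvent dielectric 78.5. For one atom this reduces to the Born ion
#' formula `-0.5 * (1 - 1/78.5) * 332.0637 * q^2 / rho`.
#'
#' @param coords n x 3 coordinates.
#' @param charges partial charges (elementary units).
#' @param radii intrinsic (element-based) radii (Angstrom); looked up from
#'   `elements` when `NULL`.
#' @param elements element symbols, used for radii and descreening scale
#'   factors.
#' @param eps_solvent solvent dielectric constant.
#' @return polar solvation energy (kcal/mol), `<= 0` for any nonzero
#'   charge set.
#' @export
gb_polar_energy <- function(coords, charges, radii = NULL, elements = NULL,
                            eps_solvent = 78.5) {
  cc <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(cc)
  if (length(charges) != n) stop("one charge per atom required")
  if (is.null(radii)) {
    if (is.null(elements)) stop("supply radii or elements")
    radii <- element_radius(elements)
  }
  if (any(radii <= 0)) stop("radii must be > 0")
  scales <- if (is.null(elements)) rep(0.80, n) else hct_scale_factor(elements)
  reff <- hct_effective_radii(cc, radii, scales)
  pref <- -0.5 * (1 - 1 / eps_solvent) * COULOMB_CONST
  if (n == 1) return(pref * charges^2 / reff)
  r2 <- cross_dist(cc, cc)^2
  rr <- outer(reff, reff)
  fgb <- sqrt(r2 + rr * exp(-r2 / (4 * rr)))
  diag(fgb) <- reff
  qq <- outer(charges, charges)
  pref * sum(qq / fgb)
}

# deterministic quasi-uniform sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA on a deterministic golden-spiral point grid: for each
#' atom, the fraction of test points on its solvent-expanded sphere not
#' buried inside any neighbour's expanded sphere.
#'
#' @param coords n x 3 coordinates.
#' @param elements element symbols (radii from the built-in table), or
#'   supply `radii` directly.
#' @param radii per-atom radii (Angstrom), overriding the element lookup.
#' @param probe probe radius (Angstrom, default 1.4, water).
#' @param n_points test points per atom (default 960).
#' @return list with `total` (Angstrom^2) and `per_atom`.
#' @export
sasa <- function(coords, elements = NULL, radii = NULL, probe = 1.4,
                 n_points = 960) {
  cc <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(cc)
  if (is.null(radii)) {
    if (is.null(elements)) stop("supply radii or elements")
    radii <- element_radius(elements)
  }
  if (length(radii) != n) stop("one radius per atom required")
  rx <- radii + probe
  pts <- sphere_points(n_points)
  per_atom <- numeric(n)
  if (n > 1) d <- cross_dist(cc, cc)
  for (i in seq_len(n)) {
    nb <- if (n > 1) which(d[i, ] < rx[i] + rx & seq_len(n) != i) else integer(0)
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * rx[i]^2
      next
    }
    sp <- sweep(pts * rx[i], 2, cc[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (sp[, 1] - cc[j, 1])^2 + (sp[, 2] - cc[j, 2])^2 +
        (sp[, 3] - cc[j, 3])^2
      free <- free & d2 >= rx[j]^2
      if (!any(free)) break
    }
    per_atom[i] <- 4 * pi * rx[i]^2 * sum(free) / n_points
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Nonpolar (surface-area) solvation energy
#'
#' Linear surface-area model `dG_SA = gamma * SASA` with
#' `gamma = 0.0072 kcal/(mol*Angstrom^2)` and zero offset.
#'
#' @param sasa_total total SASA (Angstrom^2), `>= 0`.
#' @param gamma surface tension coefficient.
#' @return energy (kcal/mol).
#' @export
sa_nonpolar_energy <- function(sasa_total, gamma = 0.0072) {
  if (any(!is.finite(sasa_total)) || any(sasa_total < 0))
    stop("sasa must be a non-negative finite area")
  gamma * sasa_total
}

#' MM/GBSA binding free energy (one-trajectory approximation)
#'
#' End-point estimate on complex frames only: receptor and ligand energies
#' are evaluated on their coordinates within the same complex frame, so all
#' intramolecular terms cancel exactly (`dE_intra = 0`; the estimator has no
#' bonded-energy code path) and the entropy term `-T*dS` is omitted as a
#' declared constant. Per frame,
#' `dG_bind = E_inter + [GB(complex) - GB(receptor) - GB(ligand)]
#'  + gamma * [SASA(complex) - SASA(receptor) - SASA(ligand)]`.
#'
#' @param traj receptor + single-ligand [fd_trajectory()] with parameters.
#' @param frames frame indices to evaluate (default all).
#' @param gamma nonpolar surface coefficient (kcal/(mol*Angstrom^2)).
#' @param n_points SASA point count per atom.
#' @return list with `per_frame` (data.frame: time_ns, E_vdW, E_elec,
#'   E_inter, dG_GB, dG_SA, dG_bind) and `mean` (window-averaged report of
#'   class `fd_energy_report` including `dE_intra = 0` and the omitted
#'   `TdS_term`).
#' @export
mmgbsa_binding <- function(traj, frames = NULL, gamma = 0.0072,
                           n_points = 240) {
  at <- traj$topology$atoms
  rec <- which(at$kind == "receptor")
  lig <- which(at$kind == "ligand")
  if (!length(rec) || !length(lig))
    stop("trajectory must contain receptor and ligand atoms")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  el <- at$element
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cc <- frame_coords(traj, f)
    e <- nonbonded_inter_energy(cc, traj$topology, rec, lig)
    gb_c <- gb_polar_energy(cc, at$charge, elements = el)
    gb_r <- gb_polar_energy(cc[rec, , drop = FALSE], at$charge[rec],
                            elements = el[rec])
    gb_l <- gb_polar_energy(cc[lig, , drop = FALSE], at$charge[lig],
                            elements = el[lig])
    sa_c <- sasa(cc, elements = el, n_points = n_points)$total
    sa_r <- sasa(cc[rec, , drop = FALSE], elements = el[rec],
                 n_points = n_points)$total
    sa_l <- sasa(cc[lig, , drop = FALSE], elements = el[lig],
                 n_points = n_points)$total
    dg_gb <- gb_c - gb_r - gb_l
    dg_sa <- sa_nonpolar_energy(sa_c, gamma) - sa_nonpolar_energy(sa_r, gamma) -
      sa_nonpolar_energy(sa_l, gamma)
    rows[[fi]] <- data.frame(
      time_ns = traj$times_ns[f], E_vdW = e$E_vdW, E_elec = e$E_elec,
      E_inter = e$E_inter, dG_GB = dg_gb, dG_SA = dg_sa,
      dG_bind = e$E_inter + dg_gb + dg_sa
    )
  }
  per_frame <- do.call(rbind, rows)
  mean_rep <- structure(list(
    E_vdW = mean(per_frame$E_vdW), E_elec = mean(per_frame$E_elec),
    E_inter = mean(per_frame$E_inter), dG_GB = mean(per_frame$dG_GB),
    dG_SA = mean(per_frame$dG_SA),
    dG_solv = mean(per_frame$dG_GB) + mean(per_frame$dG_SA),
    dE_intra = 0, TdS_term = "omitted-constant",
    dG_bind_mmgbsa = mean(per_frame$dG_bind)
  ), class = "fd_energy_report")
  list(per_frame = per_frame, mean = mean_rep)
}

#' Block-wise stability filter on a binding-energy series
#'
#' The per-frame binding free energy is averaged in consecutive time blocks
#' (default 10 ns); a trajectory is discarded when any block mean deviates
#' from the overall mean of block means by strictly more than
#' `scale * SD(block means)`, flagging energy fluctuations that indicate an
#' unconverged, unstably bound ligand.
#'
#' @param times_ns per-frame times.
#' @param dg per-frame binding energy series.
#' @param block_ns block length (ns).
#' @param scale standard-deviation multiplier.
#' @return list with `keep`, `evaluable` (FALSE for series spanning fewer
#'   than 2 blocks, kept with a warning), `block_means`, `block_sd` and
#'   `overall_mean`.
#' @export
stability_filter <- function(times_ns, dg, block_ns = 10, scale = 2.0) {
  if (length(times_ns) != length(dg)) stop("times and series lengths differ")
  blk <- floor((times_ns - min(times_ns)) / block_ns)
  means <- tapply(dg, blk, mean)
  if (length(means) < 2) {
    warning("series spans fewer than 2 blocks; stability not evaluable")
    return(list(keep = TRUE, evaluable = FALSE,
                block_means = as.numeric(means),
                block_sd = NA_real_, overall_mean = mean(dg)))
  }
  m <- mean(means)
  s <- stats::sd(means)
  dev <- abs(means - m)
  keep <- !any(dev > scale * s)
  list(keep = keep, evaluable = TRUE, block_means = as.numeric(means),
       block_sd = s, overall_mean = m)
}

#' Ligand solvent exposure
#'
#' SASA of the ligand within the complex as a percentage of the free SASA
#' of the same ligand conformation; low values flag deep burial.
#'
#' @param traj receptor + single-ligand [fd_trajectory()].
#' @param frame frame index (default last).
#' @param probe probe radius (Angstrom).
#' @param n_points SASA points per atom.
#' @return list of class `fd_sasa_report` with `sasa_ligand_complexed`,
#'   `sasa_ligand_free` and `percent_exposed`.
#' @export
percent_exposed <- function(traj, frame = n_frames(traj), probe = 1.4,
                            n_points = 240) {
  at <- traj$topology$atoms
  lig <- which(at$kind == "ligand")
  if (!length(lig)) stop("no ligand atoms")
  cc <- frame_coords(traj, frame)
  sa_cplx <- sasa(cc, elements = at$element, probe = probe,
                  n_points = n_points)
  complexed <- sum(sa_cplx$per_atom[lig])
  free <- sasa(cc[lig, , drop = FALSE], elements = at$element[lig],
               probe = probe, n_points = n_points)$total
  if (free <= 0) stop("degenerate ligand: zero free SASA")
  structure(list(sasa_ligand_complexed = complexed, sasa_ligand_free = free,
                 percent_exposed = 100 * complexed / free),
            class = "fd_sasa_report")
}

# infer donor-hydrogen covalent pairs from one frame: H within bond_max of
# an N/O/S heavy atom
infer_donors <- function(coords, atoms, idx, bond_max = 1.25) {
  hy <- idx[atoms$element[idx] == "H"]
  heavy <- idx[atoms$element[idx] %in% c("N", "O", "S")]
  if (!length(hy) || !length(heavy)) return(NULL)
  cc <- matrix(as.numeric(coords), ncol = 3)
  d <- cross_dist(cc[hy, , drop = FALSE], cc[heavy, , drop = FALSE])
  out <- NULL
  for (i in seq_along(hy)) {
    j <- which.min(d[i, ])
    if (d[i, j] <= bond_max)
      out <- rbind(out, c(donor = heavy[j], hydrogen = hy[i]))
  }
  out
}

#' Intermolecular hydrogen-bond occupancy
#'
#' Over the last `window_ns` of the trajectory, each receptor-ligand
#' donor-hydrogen / acceptor combination is tested frame by frame against a
#' heavy-atom distance cutoff and a donor-hydrogen-acceptor angle minimum;
#' occupancy is the fraction of window frames satisfying both. Pairs with
#' occupancy strictly above `occupancy_min` are retained.
#'
#' @param traj receptor + single-ligand [fd_trajectory()] with hydrogens.
#' @param window_ns evaluation window measured back from the final frame
#'   (default 20 ns).
#' @param dist_cutoff donor-acceptor heavy-atom distance cutoff (Angstrom).
#' @param angle_min_deg minimum D-H...A angle (degrees).
#' @param occupancy_min retention threshold (fraction of window frames).
#' @return list of class `fd_hbond_report` with `pairs` (data.frame:
#'   donor/hydrogen/acceptor serials + occupancy + retained) and
#'   `n_retained`.
#' @export
hydrogen_bonds <- function(traj, window_ns = 20, dist_cutoff = 3.0,
                           angle_min_deg = 135, occupancy_min = 0.45) {
  at <- traj$topology$atoms
  lig <- which(at$kind == "ligand")
  rec <- which(at$kind == "receptor")
  t <- traj$times_ns
  frames <- which(t >= max(t) - window_ns)
  cc1 <- frame_coords(traj, frames[1])
  don_l <- infer_donors(cc1, at, lig)
  don_r <- infer_donors(cc1, at, rec)
  acc_l <- lig[at$element[lig] %in% c("N", "O", "S")]
  acc_r <- rec[at$element[rec] %in% c("N", "O", "S")]
  combos <- NULL
  if (!is.null(don_l) && length(acc_r))
    combos <- rbind(combos, cbind(don_l[rep(seq_len(nrow(don_l)),
                                            each = length(acc_r)), ,
                                        drop = FALSE],
                                  acceptor = rep(acc_r, nrow(don_l))))
  if (!is.null(don_r) && length(acc_l))
    combos <- rbind(combos, cbind(don_r[rep(seq_len(nrow(don_r)),
                                            each = length(acc_l)), ,
                                        drop = FALSE],
                                  acceptor = rep(acc_l, nrow(don_r))))
  if (is.null(combos) || !nrow(combos)) {
    return(structure(list(pairs = data.frame(), n_retained = 0L),
                     class = "fd_hbond_report"))
  }
  hits <- matrix(0L, nrow(combos), length(frames))
  for (fi in seq_along(frames)) {
    cc <- frame_coords(traj, frames[fi])
    dvec <- cc[combos[, "acceptor"], , drop = FALSE] -
      cc[combos[, "donor"], , drop = FALSE]
    dd <- sqrt(rowSums(dvec^2))
    hvec1 <- cc[combos[, "donor"], , drop = FALSE] -
      cc[combos[, "hydrogen"], , drop = FALSE]
    hvec2 <- cc[combos[, "acceptor"], , drop = FALSE] -
      cc[combos[, "hydrogen"], , drop = FALSE]
    cosang <- rowSums(hvec1 * hvec2) /
      (sqrt(rowSums(hvec1^2)) * sqrt(rowSums(hvec2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    hits[, fi] <- as.integer(dd <= dist_cutoff & ang >= angle_min_deg)
  }
  occ <- rowMeans(hits)
  pairs <- data.frame(
    donor = at$serial[combos[, "donor"]],
    hydrogen = at$serial[combos[, "hydrogen"]],
    acceptor = at$serial[combos[, "acceptor"]],
    occupancy = occ,
    retained = occ > occupancy_min
  )
  pairs <- pairs[occ > 0, , drop = FALSE]
  structure(list(pairs = pairs, n_retained = sum(pairs$retained)),
            class = "fd_hbond_report")
}
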