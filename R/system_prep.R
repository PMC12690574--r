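# Multicopy system preparation: principal-axis alignment, tiling of a
# pre-equilibrated ligand/water template box around the receptor, clash
# pruning, the anti-aggregation repulsive Lennard-Jones term, and the GaMD
# equilibration schedule derived from the system atom count.

#' Principal axes of a point set
#'
#' Eigenvectors of the mass-weighted covariance (gyration) tensor about the
#' centre of mass, ordered by descending spatial extent and returned as a
#' right-handed orthonormal frame.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param masses per-point masses (amu); unit masses when `NULL`.
#' @return list with `axes` (3 x 3 matrix, rows are the axes), `values`
#'   (eigenvalues, descending) and `com` (centre of mass).
#' @export
principal_axes <- function(coords, masses = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  if (n < 3) stop("principal axes need at least 3 points")
  if (is.null(masses)) masses <- rep(1, n)
  if (length(masses) != n || any(masses <= 0))
    stop("masses must be positive, one per point")
  w <- masses / sum(masses)
  com <- colSums(coords * w)
  cc <- sweep(coords, 2, com)
  cov <- crossprod(cc * sqrt(w))          # mass-weighted gyration tensor
  ev <- eigen(cov, symmetric = TRUE)
  vals <- ev$values
  if (vals[1] <= 0 || vals[2] / vals[1] < 1e-12)
    stop("degenerate (collinear) point set: principal axes undefined")
  axes <- t(ev$vectors)                   # rows = axes, descending extent
  # deterministic sign: largest-magnitude component of each axis positive
  for (i in 1:3) {
    j <- which.max(abs(axes[i, ]))
    if (axes[i, j] < 0) axes[i, ] <- -axes[i, ]
  }
  # right-handed frame
  if (det(axes) < 0) axes[3, ] <- -axes[3, ]
  list(axes = axes, values = vals, com = com)
}

#' Rotate a structure onto its principal axes
#'
#' After alignment the axis of largest spatial extent lies along x, the
#' second along y, and the centre of mass sits at the origin. The motion is
#' rigid: all interatomic distances are preserved.
#'
#' @param coords n x 3 coordinate matrix.
#' @param masses per-point masses (amu); unit masses when `NULL`.
#' @return list with `coords` (rotated), `rotation` (the 3 x 3 matrix
#'   applied, rows are the principal axes) and `com` (original centre of
#'   mass).
#' @export
align_to_principal_axes <- function(coords, masses = NULL) {
  pa <- principal_axes(coords, masses)
  cc <- sweep(matrix(as.numeric(coords), ncol = 3), 2, pa$com)
  list(coords = cc %*% t(pa$axes), rotation = pa$axes, com = pa$com)
}

#' Align a single-frame trajectory onto its principal axes
#' @param traj an [fd_trajectory()] (first frame is used).
#' @return the trajectory with rotated coordinates; the rotation matrix is
#'   attached as attribute `"rotation"`.
#' @export
align_structure <- function(traj) {
  cr <- frame_coords(traj, 1)
  al <- align_to_principal_axes(cr, traj$topology$atoms$mass)
  traj$xyz <- matrix(t(al$coords), nrow = 1)
  attr(traj, "rotation") <- al$rotation
  traj
}

# molecule grouping key: each ligand copy or solvent residue is one molecule
molecule_key <- function(atoms) {
  paste(atoms$kind, atoms$chain, atoms$resid,
        ifelse(is.na(atoms$copy), 0L, atoms$copy), sep = "|")
}

#' Assemble a multicopy simulation box around a receptor
#'
#' Replicates a pre-equilibrated template box (ligand copy + waters) on the
#' minimal lattice covering the receptor extent plus `shell` on all sides,
#' then removes — whole molecules only — every template molecule with any
#' atom strictly closer than `clash` to a receptor atom, and molecules
#' falling entirely outside the shell region. Both species are aligned to
#' their principal axes first (the receptor's alignment defines the frame).
#'
#' @param receptor single-frame [fd_trajectory()] of the receptor.
#' @param template single-frame [fd_trajectory()] of the solvated-ligand
#'   template box; must carry `box` lengths.
#' @param shell solvation shell around the receptor (Angstrom, default 20).
#' @param clash clash-removal distance (Angstrom, default 1.0).
#' @param align align both species to their principal axes first.
#' @return list with `system` (combined single-frame trajectory) and
#'   `report` (class `fd_prep_report`: copies placed, clash removals,
#'   final box lengths, rotations applied).
#' @export
assemble_multicopy_box <- function(receptor, template, shell = 20,
                                   clash = 1.0, align = TRUE) {
  if (is.null(template$box)) stop("template box lengths are required")
  if (nrow(template$topology$atoms) == 0) stop("empty template")
  rot_rec <- diag(3); rot_lig <- diag(3)
  if (align) {
    receptor <- align_structure(receptor)
    rot_rec <- attr(receptor, "rotation")
    template <- align_structure(template)
    rot_lig <- attr(template, "rotation")
  }
  rc <- frame_coords(receptor, 1)
  box_len <- as.numeric(template$box)
  extent <- apply(rc, 2, max) - apply(rc, 2, min)
  n_rep <- pmax(1L, as.integer(ceiling((extent + 2 * shell) / box_len)))
  com <- colMeans(rc * receptor$topology$atoms$mass) /
    mean(receptor$topology$atoms$mass)
  lo <- apply(rc, 2, min) - shell
  hi <- apply(rc, 2, max) + shell

  tc <- frame_coords(template, 1)
  t_at <- template$topology$atoms
  mol <- molecule_key(t_at)
  mol_ids <- unique(mol)

  keep_atoms <- list(); keep_coords <- list()
  n_clash <- 0L; n_outside <- 0L; n_copies <- 0L
  # lattice centred on the receptor centre of mass
  offs <- lapply(1:3, function(a) {
    (seq_len(n_rep[a]) - 1 - (n_rep[a] - 1) / 2) * box_len[a] + com[a]
  })
  for (ix in offs[[1]]) for (iy in offs[[2]]) for (iz in offs[[3]]) {
    shift <- c(ix, iy, iz)
    cc <- sweep(tc, 2, shift, "+")
    dmin <- cross_min_dist(cc, rc)
    for (m in mol_ids) {
      sel <- which(mol == m)
      if (min(dmin[sel]) < clash) { n_clash <- n_clash + 1L; next }
      mc <- cc[sel, , drop = FALSE]
      inside <- mc >= matrix(lo, nrow(mc), 3, byrow = TRUE) &
        mc <= matrix(hi, nrow(mc), 3, byrow = TRUE)
      if (!any(rowSums(inside) == 3L)) { n_outside <- n_outside + 1L; next }
      aa <- t_at[sel, , drop = FALSE]
      if (aa$kind[1] == "ligand") {
        n_copies <- n_copies + 1L
        aa$copy <- n_copies
      }
      keep_atoms[[length(keep_atoms) + 1L]] <- aa
      keep_coords[[length(keep_coords) + 1L]] <- mc
    }
  }
  r_at <- receptor$topology$atoms
  all_at <- rbind(r_at, do.call(rbind, keep_atoms))
  all_at$serial <- seq_len(nrow(all_at))
  all_xyz <- rbind(rc, do.call(rbind, keep_coords))
  topo <- fd_topology(all_at, n_ligand_copies = n_copies)
  sys <- fd_trajectory(topo, matrix(t(all_xyz), nrow = 1), times_ns = 0,
                       box = extent + 2 * shell, times_known = FALSE)
  report <- structure(list(
    n_copies_placed = n_copies,
    n_molecules_removed_clash = n_clash,
    n_molecules_removed_outside = n_outside,
    final_box_lengths = extent + 2 * shell,
    n_replications = n_rep,
    rotation_receptor = rot_rec,
    rotation_ligand = rot_lig
  ), class = "fd_prep_report")
  list(system = sys, report = report)
}

#' Select the default central atom of a ligand copy
#'
#' Heuristic used when no atom name is supplied: the heteroatom (non-carbon,
#' non-hydrogen; falling back to carbon) nearest the copy's unweighted
#' centroid.
#'
#' @param topology an [fd_topology()].
#' @param coords single-frame n x 3 coordinates matching the topology.
#' @param copy ligand copy index.
#' @return the atom name of the selected centre.
#' @export
select_central_atom <- function(topology, coords, copy = 1L) {
  at <- topology$atoms
  idx <- which(at$kind == "ligand" & at$copy == copy)
  if (!length(idx)) stop("no ligand atoms for copy ", copy)
  cc <- matrix(as.numeric(coords), ncol = 3)[idx, , drop = FALSE]
  centroid <- colMeans(cc)
  het <- !(at$element[idx] %in% c("C", "H"))
  cand <- if (any(het)) idx[het] else idx[at$element[idx] == "C"]
  if (!length(cand)) cand <- idx
  cc2 <- matrix(as.numeric(coords), ncol = 3)[cand, , drop = FALSE]
  d <- sqrt(rowSums(sweep(cc2, 2, centroid)^2))
  at$name[cand[which.min(d)]]
}

#' Inject the anti-aggregation repulsive term
#'
#' Flags one atom per ligand copy as the repulsive centre and retypes it by
#' element to C99/N99/O99/S99. Pairs of repulsive centres interact through a
#' purely repulsive Lennard-Jones term (the attractive r^-6 coefficient set
#' to zero); all other pair interactions are unchanged. This keeps the
#' ligand copies from aggregating during the multicopy simulation.
#'
#' @param topology an [fd_topology()].
#' @param central_atom_name atom name of the centre in each copy; when
#'   `NULL`, the [select_central_atom()] heuristic picks it (requires
#'   `coords`).
#' @param coords optional single-frame coordinates, needed only for the
#'   heuristic.
#' @return the updated topology.
#' @export
inject_repulsive_term <- function(topology, central_atom_name = NULL,
                                  coords = NULL) {
  at <- topology$atoms
  if (topology$n_ligand_copies < 1) stop("topology has no ligand copies")
  if (is.null(central_atom_name)) {
    if (is.null(coords))
      stop("coords are required for the central-atom heuristic")
    central_atom_name <- select_central_atom(topology, coords, 1L)
  }
  at$is_central <- FALSE
  for (cp in seq_len(topology$n_ligand_copies)) {
    idx <- which(at$kind == "ligand" & at$copy == cp &
                   at$name == central_atom_name)
    if (!length(idx))
      stop("central atom '", central_atom_name, "' absent from ligand copy ",
           cp)
    idx <- idx[1]
    el <- at$element[idx]
    if (!el %in% c("C", "N", "O", "S"))
      stop("unsupported central-atom element '", el,
           "' (must be C, N, O or S)")
    at$is_central[idx] <- TRUE
    at$type[idx] <- paste0(el, "99")
  }
  topology$atoms <- at
  topology
}

#' Lennard-Jones pair energy (AMBER epsilon/rmin convention)
#'
#' Lorentz-Berthelot combination of per-atom (epsilon, rmin/2) parameters.
#' Between two repulsive-centre atoms only the r^-12 repulsive branch acts.
#'
#' @param eps_i,eps_j well depths (kcal/mol).
#' @param rmin_half_i,rmin_half_j half pair-minimum distances (Angstrom).
#' @param r separation (Angstrom).
#' @param repulsive_only logical; drop the attractive r^-6 term.
#' @return energy in kcal/mol (vectorised over `r`).
#' @export
lj_pair_energy <- function(eps_i, eps_j, rmin_half_i, rmin_half_j, r,
                           repulsive_only = FALSE) {
  eps <- sqrt(eps_i * eps_j)
  rmin <- rmin_half_i + rmin_half_j
  sr6 <- (rmin / r)^6
  if (repulsive_only) eps * sr6^2 else eps * (sr6^2 - 2 * sr6)
}

#' GaMD equilibration schedule from the system atom count
#'
#' The potential-statistics averaging window is set to four times the total
#' number of atoms, and the conventional-MD preparation, boost preparation
#' and conventional-MD step counts follow as fixed multiples of it.
#'
#' @param n_atoms total number of atoms in the prepared system.
#' @return list of class `fd_equil_schedule` with `n_atoms`, `ntave`
#'   (`4 * n_atoms`), `ntcmdprep` (`2 * ntave`), `ntebprep` (`2 * ntave`)
#'   and `ntcmd` (`5 * ntave`), all in integrator steps.
#' @export
gamd_equilibration_schedule <- function(n_atoms) {
  n_atoms <- as.numeric(n_atoms)
  if (length(n_atoms) != 1 || !is.finite(n_atoms) || n_atoms < 1 ||
      n_atoms != floor(n_atoms))
    stop("n_atoms must be a positive integer")
  ntave <- 4 * n_atoms
  structure(list(n_atoms = n_atoms, ntave = ntave, ntcmdprep = 2 * ntave,
                 ntebprep = 2 * ntave, ntcmd = 5 * ntave),
            class = "fd_equil_schedule")
}

#' @export
print.fd_equil_schedule <- function(x, ...) {
  cat(sprintf("GaMD equilibration schedule (Natoms = %d):\n", x$n_atoms))
  for (f in c("ntave", "ntcmdprep", "ntebprep", "ntcmd"))
    cat(sprintf("  %-10s= %d\n", f, x[[f]]))
  invisible(x)
}
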