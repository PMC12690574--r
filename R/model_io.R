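# Data model: topology (atom metadata + nonbonded parameters), trajectory
# (time-stamped multi-frame coordinates), analysis configuration, and the
# PDB / JSON-sidecar readers and writers.

.water_resnames <- c("WAT", "HOH", "TIP3", "TIP", "T3P", "SOL", "SPC")
.ion_resnames <- c(
  "NA+", "CL-", "K+", "MG2", "ZN2", "Na+", "Cl-", "NA", "CL", "K", "MG",
  "ZN", "CA2", "CS+", "LI+", "BR-", "IOD"
)
.protein_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HIE", "HID", "HIP", "CYX", "CYM", "ASH", "GLH", "LYN", "ACE", "NME"
)

.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, "NA" = 22.990,
  K = 39.098, MG = 24.305, ZN = 65.38, FE = 55.845
)

element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "MG", "ZN", "FE", "NA", "SE") &
           !grepl("^N[A-Z]?[0-9]", nm), two,
         substr(gsub("^[0-9]+", "", nm), 1, 1))
}

#' Construct a topology
#'
#' A topology is the per-atom metadata table of a simulation system: names,
#' elements, residue labels, molecule kind (receptor / ligand / water / ion),
#' the ligand copy index, nonbonded parameters (partial charge, Lennard-Jones
#' epsilon and rmin/2 in the AMBER convention) and the repulsive-center flag.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `kind`, `copy`, `charge`, `lj_epsilon`,
#'   `lj_rmin_half`, `is_central`, `mass` (missing parameter columns are
#'   initialised to `NA` and filled by [read_params()]).
#' @param n_ligand_copies number of ligand copies in the system.
#' @return an object of class `fd_topology`.
#' @export
fd_topology <- function(atoms, n_ligand_copies = 0L) {
  needed <- c("serial", "name", "element", "resname", "resid", "chain", "kind")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) stop("topology atoms missing columns: ",
                         paste(miss, collapse = ", "))
  for (col in c("charge", "lj_epsilon", "lj_rmin_half"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (is.null(atoms$copy)) atoms$copy <- NA_integer_
  if (is.null(atoms$is_central)) atoms$is_central <- FALSE
  if (is.null(atoms$type)) atoms$type <- atoms$name
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(atoms$mass <= 0, na.rm = TRUE)) stop("atom masses must be > 0")
  ok_eps <- is.na(atoms$lj_epsilon) | atoms$lj_epsilon >= 0
  if (!all(ok_eps)) stop("lj_epsilon must be >= 0")
  ok_rmin <- is.na(atoms$lj_rmin_half) | atoms$lj_rmin_half > 0
  if (!all(ok_rmin)) stop("lj_rmin_half must be > 0")
  lig <- atoms$kind == "ligand"
  if (any(lig)) {
    cp <- atoms$copy[lig]
    if (anyNA(cp) || any(cp < 1L) || any(cp > n_ligand_copies))
      stop("every ligand atom must carry a copy label in [1, n_ligand_copies]")
  }
  structure(list(atoms = atoms,
                 n_ligand_copies = as.integer(n_ligand_copies)),
            class = "fd_topology")
}

#' @export
print.fd_topology <- function(x, ...) {
  cat("fd_topology:", nrow(x$atoms), "atoms;",
      x$n_ligand_copies, "ligand copies\n")
  cat("  kinds:", paste(sprintf("%s=%d", names(table(x$atoms$kind)),
                                table(x$atoms$kind)), collapse = " "), "\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' @param topology an [fd_topology()].
#' @param xyz numeric matrix, one row per frame, columns `x1,y1,z1,x2,...`
#'   (Angstrom).
#' @param times_ns per-frame time stamps. Strictly increasing.
#' @param box optional 3-vector of box lengths (Angstrom).
#' @param times_known logical; `FALSE` when times are bare frame indices
#'   (no physical frame interval supplied). Residence-time analyses refuse
#'   to run on such trajectories.
#' @return an object of class `fd_trajectory`.
#' @export
fd_trajectory <- function(topology, xyz, times_ns, box = NULL,
                          times_known = TRUE) {
  if (!inherits(topology, "fd_topology")) stop("topology must be fd_topology")
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_at <- nrow(topology$atoms)
  if (ncol(xyz) != 3L * n_at)
    stop("coordinate count (", ncol(xyz) / 3, ") does not match topology (",
         n_at, " atoms)")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (length(times_ns) != nrow(xyz)) stop("one time stamp per frame required")
  if (any(times_ns < 0)) stop("times must be non-negative")
  if (nrow(xyz) > 1 && any(diff(times_ns) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, xyz = xyz,
                 times_ns = as.numeric(times_ns), box = box,
                 times_known = isTRUE(times_known)),
            class = "fd_trajectory")
}

#' @export
print.fd_trajectory <- function(x, ...) {
  cat("fd_trajectory:", nrow(x$xyz), "frames x", nrow(x$topology$atoms),
      "atoms; t =", min(x$times_ns), "..", max(x$times_ns),
      if (x$times_known) "ns\n" else "(frame units)\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `fd_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame as an n x 3 coordinate matrix
#' @param traj an `fd_trajectory`.
#' @param i frame index.
#' @export
frame_coords <- function(traj, i = n_frames(traj)) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

classify_kind <- function(resname, ligand_resnames = NULL) {
  rn <- trimws(resname)
  kind <- rep("ligand", length(rn))
  kind[rn %in% .protein_resnames] <- "receptor"
  kind[toupper(rn) %in% .water_resnames] <- "water"
  kind[rn %in% .ion_resnames | toupper(rn) %in% toupper(.ion_resnames)] <- "ion"
  if (!is.null(ligand_resnames)) {
    kind[rn %in% ligand_resnames] <- "ligand"
    kind[!(rn %in% ligand_resnames) & kind == "ligand"] <- "receptor"
  }
  kind
}

# Pre-scan a PDB file: coordinate fields must parse; MODEL blocks must have
# identical atom counts. Gives line-numbered errors that bio3d would not.
validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_atom)) {
    flds <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
              substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(flds))))
      stop("malformed ATOM/HETATM record at line ", i, ": ", lines[i])
  }
  starts <- grepl("^MODEL", lines)
  if (any(starts)) {
    model_id <- cumsum(starts)
    counts <- table(model_id[is_atom & model_id > 0])
    if (length(unique(as.integer(counts))) > 1)
      stop("inconsistent atom counts between MODEL blocks: ",
           paste(as.integer(counts), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a (multi-model) PDB structure into a trajectory
#'
#' Each `MODEL` block becomes one frame (a single frame when no MODEL
#' records are present). Molecule kinds are classified from residue names;
#' ligand copies are numbered in order of appearance over distinct
#' (chain, residue id) ligand groups.
#'
#' @param path PDB file path.
#' @param frame_interval_ns physical time between successive models, in ns.
#'   When `NULL`, frames are stamped `0, 1, 2, ...` in bare frame units and
#'   time-based analyses (residence time) will refuse the trajectory.
#' @param ligand_resnames optional character vector naming the ligand
#'   residue(s); residues not listed are treated as receptor (waters and
#'   ions are always recognised by name).
#' @return an [fd_trajectory()].
#' @export
read_structure <- function(path, frame_interval_ns = NULL,
                           ligand_resnames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(as.numeric(xyz), nrow = 1)
  el <- at$elesy
  if (is.null(el) || anyNA(el) || any(!nzchar(trimws(el))))
    el <- guess_element(at$elety)
  el <- toupper(trimws(el))
  kind <- classify_kind(at$resid, ligand_resnames)
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = el,
    resname = trimws(at$resid), resid = at$resno, chain = chain,
    kind = kind, stringsAsFactors = FALSE
  )
  # ligand copy numbering: distinct (chain, resid) groups in file order
  atoms$copy <- NA_integer_
  lig <- which(atoms$kind == "ligand")
  n_cop <- 0L
  if (length(lig)) {
    key <- paste(atoms$chain[lig], atoms$resid[lig], sep = "|")
    atoms$copy[lig] <- as.integer(factor(key, levels = unique(key)))
    n_cop <- max(atoms$copy[lig])
  }
  topo <- fd_topology(atoms, n_ligand_copies = n_cop)
  nf <- nrow(xyz)
  if (is.null(frame_interval_ns)) {
    times <- seq_len(nf) - 1
    known <- FALSE
  } else {
    times <- (seq_len(nf) - 1) * frame_interval_ns
    known <- TRUE
  }
  fd_trajectory(topo, xyz, times, times_known = known)
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' @param traj an [fd_trajectory()].
#' @param path output path.
#' @export
write_structure <- function(traj, path) {
  at <- traj$topology$atoms
  nf <- n_frames(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt_name <- function(nm) {
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
           sprintf(" %-3s", nm))
  }
  names4 <- fmt_name(at$name)
  multi <- nf > 1
  for (f in seq_len(nf)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    cr <- frame_coords(traj, f)
    lines <- sprintf(
      "%-6s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(at$kind == "receptor", "ATOM", "HETATM"),
      at$serial %% 100000L, names4, "", substr(at$resname, 1, 4),
      substr(at$chain, 1, 1), at$resid %% 10000L, "",
      cr[, 1], cr[, 2], cr[, 3], 1, 0, substr(at$element, 1, 2)
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a JSON nonbonded-parameter sidecar into a topology
#'
#' The sidecar is a JSON array of records; each record addresses atoms
#' either by `serial` or by (`resname`, `name`) and carries `charge`
#' (elementary units), `lj_epsilon` (kcal/mol), `lj_rmin_half` (Angstrom)
#' and optionally `element`, `mass`, `is_repulsive_center`.
#'
#' @param topology an [fd_topology()].
#' @param path JSON sidecar path.
#' @return the updated topology; every atom is guaranteed a finite charge
#'   and Lennard-Jones parameter set.
#' @export
read_params <- function(topology, path) {
  if (!file.exists(path)) stop("file not found: ", path)
  entries <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(dim(entries))) stop("parameter sidecar must be a JSON array")
  at <- topology$atoms
  matched <- rep(FALSE, nrow(at))
  for (k in seq_len(nrow(entries))) {
    e <- entries[k, , drop = FALSE]
    if (!is.null(e$serial) && !is.na(e$serial)) {
      idx <- which(at$serial == e$serial)
    } else {
      idx <- which(at$resname == e$resname & at$name == e$name)
    }
    if (!length(idx)) next
    if (!is.null(e$lj_epsilon) && is.finite(e$lj_epsilon) && e$lj_epsilon < 0)
      stop("negative lj_epsilon in sidecar entry ", k)
    for (col in c("charge", "lj_epsilon", "lj_rmin_half", "mass")) {
      if (!is.null(e[[col]]) && !is.na(e[[col]])) at[[col]][idx] <- e[[col]]
    }
    if (!is.null(e$element) && !is.na(e$element))
      at$element[idx] <- toupper(e$element)
    if (!is.null(e$is_repulsive_center) && !is.na(e$is_repulsive_center))
      at$is_central[idx] <- as.logical(e$is_repulsive_center)
    matched[idx] <- TRUE
  }
  incomplete <- !is.finite(at$charge) | !is.finite(at$lj_epsilon) |
    !is.finite(at$lj_rmin_half)
  if (any(incomplete)) {
    off <- at[incomplete, c("serial", "resname", "name")]
    stop("atoms left without parameters: ",
         paste(sprintf("%d/%s/%s", off$serial, off$resname, off$name),
               collapse = ", "))
  }
  topology$atoms <- at
  topology
}

#' Write the JSON nonbonded-parameter sidecar of a topology
#' @param topology an [fd_topology()].
#' @param path output path.
#' @export
write_params <- function(topology, path) {
  at <- topology$atoms
  df <- data.frame(
    serial = at$serial, resname = at$resname, name = at$name,
    element = at$element, charge = at$charge, lj_epsilon = at$lj_epsilon,
    lj_rmin_half = at$lj_rmin_half, mass = at$mass,
    is_repulsive_center = at$is_central, stringsAsFactors = FALSE
  )
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.config_defaults <- list(
  box_margin_dmin = 15, solvation_shell = 20, clash_cutoff = 1.0,
  interaction_cutoff = 5.0, rt_occupancy_fraction = 0.90, rt_cutoff_ns = 50,
  contact_cutoff = 4.5, jaccard_threshold = 0.35, hbond_window_ns = 20,
  hbond_occupancy_min = 0.45, hbond_distance_cutoff = 3.0,
  hbond_angle_min_deg = 135, stability_block_ns = 10, stability_sd_scale = 2.0,
  n_replicates = 4L, production_length_ns = 400
)

#' Build the analysis configuration
#'
#' Returns the defaults of the full analysis protocol (distance screens,
#' residence-time cutoff, contact and Jaccard thresholds, hydrogen-bond
#' geometry/occupancy, stability-filter blocks, replicate count) with any
#' overrides applied.
#'
#' @param overrides named list of fields to override; unknown names are an
#'   error.
#' @return a named list of class `fd_config`.
#' @export
load_config <- function(overrides = list()) {
  cfg <- .config_defaults
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  cuts <- c("box_margin_dmin", "solvation_shell", "clash_cutoff",
            "interaction_cutoff", "rt_cutoff_ns", "contact_cutoff",
            "hbond_window_ns", "hbond_distance_cutoff", "stability_block_ns",
            "production_length_ns")
  for (f in cuts) if (cfg[[f]] <= 0) stop("config field ", f, " must be > 0")
  for (f in c("rt_occupancy_fraction", "hbond_occupancy_min"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1)
      stop("config field ", f, " must be in (0, 1]")
  if (cfg$jaccard_threshold < 0 || cfg$jaccard_threshold > 1)
    stop("jaccard_threshold must be in [0, 1]")
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1")
  structure(cfg, class = "fd_config")
}

#' Read an analysis configuration file (YAML or JSON)
#'
#' Field names mirror [load_config()] exactly.
#' @param path config file path.
#' @return an `fd_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ov <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  load_config(ov)
}
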