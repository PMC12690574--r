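# Independent brute-force oracles and tiny in-code fixtures shared by the
# test files. Oracles are written as explicit loops, independent of the
# package's vectorised implementations.

# explicit double-loop receptor-ligand nonbonded energy
brute_inter_energy <- function(coords, topology, ia, ib) {
  at <- topology$atoms
  e_vdw <- 0; e_elec <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    eps <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[j])
    rmin <- at$lj_rmin_half[i] + at$lj_rmin_half[j]
    if (at$is_central[i] && at$is_central[j]) {
      e_vdw <- e_vdw + eps * (rmin / r)^12
    } else {
      e_vdw <- e_vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    }
    e_elec <- e_elec + 332.0637 * at$charge[i] * at$charge[j] / r
  }
  list(E_vdW = e_vdw, E_elec = e_elec, E_inter = e_vdw + e_elec)
}

# explicit double-loop minimum distance between two coordinate blocks
brute_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  }
  best
}

# exhaustive O(n^2) scan over end-anchored residence windows
brute_residence <- function(times, bound, fraction = 0.90) {
  n <- length(times)
  if (!bound[n]) return(0)
  best <- 0
  for (i in seq_len(n)) {
    if (sum(bound[i:n]) / (n - i + 1) >= fraction) {
      best <- max(best, times[n] - times[i])
    }
  }
  best
}

# a minimal receptor(1 atom) + ligand(2 atoms) trajectory whose per-frame
# central-atom/receptor distance follows `dists`
make_distance_traj <- function(dists, interval_ns = 1) {
  atoms <- data.frame(
    serial = 1:3, name = c("CA", "N1", "C1"), element = c("C", "N", "C"),
    resname = c("ALA", "LIG", "LIG"), resid = c(1L, 2L, 2L),
    chain = c("A", "L", "L"), kind = c("receptor", "ligand", "ligand"),
    copy = c(NA, 1L, 1L), charge = 0, lj_epsilon = 0.1, lj_rmin_half = 1.8,
    is_central = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE
  )
  topo <- fd_topology(atoms, n_ligand_copies = 1L)
  xyz <- t(vapply(dists, function(d)
    c(0, 0, 0, d, 0, 0, d + 1.5, 0, 0), numeric(9)))
  fd_trajectory(topo, xyz, (seq_along(dists) - 1) * interval_ns)
}

# small all-atom topology builder for geometric tests
make_simple_topology <- function(df, n_copies = 0L) {
  defaults <- list(charge = 0, lj_epsilon = 0.1, lj_rmin_half = 1.8,
                   is_central = FALSE)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  if (is.null(df$serial)) df$serial <- seq_len(nrow(df))
  fd_topology(df, n_ligand_copies = n_copies)
}

# random rigid rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
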