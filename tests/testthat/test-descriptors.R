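test_that("nonbonded energy matches the explicit double-loop oracle", {
  for (s in 1:5) {
    sys <- make_energy_test_system(10, 15, seed = s)
    at <- sys$topology$atoms
    ia <- which(at$kind == "receptor"); ib <- which(at$kind == "ligand")
    got <- nonbonded_inter_energy(sys$coords, sys$topology)
    want <- brute_inter_energy(sys$coords, sys$topology, ia, ib)
    expect_equal(got$E_vdW, want$E_vdW, tolerance = 1e-9)
    expect_equal(got$E_elec, want$E_elec, tolerance = 1e-9)
    expect_identical(got$E_inter, got$E_vdW + got$E_elec)
  }
})

test_that("nonbonded energy limits: zero charges, LJ minimum, singularity", {
  sys <- make_energy_test_system(4, 4, seed = 1)
  sys$topology$atoms$charge <- 0
  expect_equal(nonbonded_inter_energy(sys$coords, sys$topology)$E_elec, 0)
  # one pair at the combined rmin sits exactly at -epsilon
  at <- data.frame(
    serial = 1:2, name = c("A1", "B1"), element = c("C", "C"),
    resname = c("REC", "LIG"), resid = 1:2, chain = c("A", "L"),
    kind = c("receptor", "ligand"), copy = c(NA, 1L), charge = 0,
    lj_epsilon = c(0.2, 0.05), lj_rmin_half = c(1.7, 2.1),
    stringsAsFactors = FALSE
  )
  topo <- fd_topology(at, 1L)
  cc <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  expect_equal(nonbonded_inter_energy(cc, topo)$E_vdW, -sqrt(0.2 * 0.05),
               tolerance = 1e-12)
  cc2 <- rbind(c(0, 0, 0), c(1e-8, 0, 0))
  expect_error(nonbonded_inter_energy(cc2, topo), "overlapping")
})

test_that("generalized Born reduces to the Born ion and is additive at
           long range", {
  # single ion: closed-form Born energy with the intrinsic radius
  q <- 0.8; rho <- 1.5
  want <- -0.5 * (1 - 1 / 78.5) * 332.0637 * q^2 / rho
  expect_equal(gb_polar_energy(rbind(c(0, 0, 0)), q, radii = rho), want,
               tolerance = 1e-12)
  # two distant ions: sum of the Born self-energies
  cc <- rbind(c(0, 0, 0), c(1e4, 0, 0))
  got <- gb_polar_energy(cc, c(0.8, -0.5), radii = c(1.5, 1.7))
  want2 <- -0.5 * (1 - 1 / 78.5) * 332.0637 * (0.8^2 / 1.5 + 0.5^2 / 1.7)
  expect_equal(got, want2, tolerance = abs(want2) * 1e-3)
  # zero charges give exactly zero
  expect_equal(gb_polar_energy(cc, c(0, 0), radii = c(1.5, 1.7)), 0)
})

test_that("generalized Born is negative and scales as q^2", {
  set.seed(3)
  cc <- matrix(runif(24, 0, 8), ncol = 3)
  q <- runif(8, -0.6, 0.6)
  el <- sample(c("C", "N", "O", "H"), 8, replace = TRUE)
  e1 <- gb_polar_energy(cc, q, elements = el)
  expect_lt(e1, 0)
  e2 <- gb_polar_energy(cc, 2 * q, elements = el)
  expect_equal(e2, 4 * e1, tolerance = 1e-9)
  expect_error(gb_polar_energy(cc, q, radii = rep(-1, 8)), "radii")
})

test_that("SASA reproduces the isolated sphere, burial, and additivity", {
  got <- sasa(rbind(c(0, 0, 0)), elements = "C", n_points = 960)
  expect_equal(got$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  # an atom caged by large spheres loses almost all its surface
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1), c(1, 1, 1) / sqrt(3),
                c(-1, -1, -1) / sqrt(3), c(1, -1, 1) / sqrt(3),
                c(-1, 1, -1) / sqrt(3), c(1, 1, -1) / sqrt(3),
                c(-1, -1, 1) / sqrt(3))
  cage <- rbind(c(0, 0, 0), dirs * 2.2)
  got2 <- sasa(cage, radii = c(1.5, rep(2.5, nrow(dirs))), n_points = 960)
  expect_lt(got2$per_atom[1], 0.01 * 4 * pi * (1.5 + 1.4)^2)
  # two far atoms: exact additivity
  two <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), elements = c("C", "O"),
              n_points = 960)
  ind <- sasa(rbind(c(0, 0, 0)), elements = "C", n_points = 960)$total +
    sasa(rbind(c(0, 0, 0)), elements = "O", n_points = 960)$total
  expect_equal(two$total, ind, tolerance = 1e-6)
  expect_error(sasa(rbind(c(0, 0, 0)), elements = "XX"), "radius")
})

test_that("nonpolar surface term is linear with the documented coefficient", {
  expect_equal(sa_nonpolar_energy(0), 0)
  expect_equal(sa_nonpolar_energy(1000), 7.2)
  expect_equal(sa_nonpolar_energy(500) * 2, sa_nonpolar_energy(1000))
  expect_error(sa_nonpolar_energy(-1), "non-negative")
})

make_two_particle_complex <- function(sep) {
  at <- data.frame(
    serial = 1:2, name = c("O1", "N1"), element = c("O", "N"),
    resname = c("REC", "LIG"), resid = 1:2, chain = c("A", "L"),
    kind = c("receptor", "ligand"), copy = c(NA, 1L),
    charge = c(-0.5, 0.5), lj_epsilon = c(0.2, 0.17),
    lj_rmin_half = c(1.66, 1.82), is_central = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  topo <- fd_topology(at, 1L)
  fd_trajectory(topo, matrix(c(0, 0, 0, sep, 0, 0), nrow = 1), 0)
}

test_that("MM/GBSA vanishes at infinite separation and is favorable at
           contact for opposite charges", {
  far <- mmgbsa_binding(make_two_particle_complex(5000), n_points = 960)
  expect_lt(abs(far$mean$dG_bind_mmgbsa), 1e-3)
  near <- mmgbsa_binding(make_two_particle_complex(3.4), n_points = 960)
  expect_lt(near$mean$dG_bind_mmgbsa, 0)
  expect_identical(near$mean$dE_intra, 0)
  # decomposition closure on every frame
  pf <- near$per_frame
  expect_identical(pf$E_inter, pf$E_vdW + pf$E_elec)
  expect_equal(pf$dG_bind, pf$E_inter + pf$dG_GB + pf$dG_SA)
})

test_that("MM/GBSA reduces to vdW plus surface term for a zero-charge system", {
  tr <- make_two_particle_complex(3.4)
  tr$topology$atoms$charge <- 0
  out <- mmgbsa_binding(tr, n_points = 960)
  expect_equal(out$mean$dG_GB, 0)
  expect_equal(out$mean$dG_bind_mmgbsa, out$mean$E_vdW + out$mean$dG_SA)
})

test_that("stability filter discards shifted blocks and keeps boundary cases", {
  times <- seq(0, 99, by = 1)
  expect_true(stability_filter(times, rep(-20, 100))$keep)
  # one block shifted far out, validated against independent block stats
  dg <- rep(-20, 100) + rnorm(100, sd = 0.1)
  dg[41:50] <- dg[41:50] + 30
  blocks <- split(dg, floor(times / 10))
  bm <- vapply(blocks, mean, numeric(1))
  expect_gt(max(abs(bm - mean(bm))), 2 * sd(bm))   # the series really deviates
  expect_false(stability_filter(times, dg)$keep)
  # exactly at scale * SD stays kept (strictly-exceeding discards)
  bm2 <- c(-1, 1, -1, 1, -1, 1)
  t2 <- seq(0, 59, by = 10)
  s <- sd(bm2)
  expect_true(all(abs(bm2 - mean(bm2)) <= 2 * s))
  expect_true(stability_filter(t2, bm2)$keep)
  expect_warning(st <- stability_filter(1:5, rep(1, 5)), "fewer than 2")
  expect_true(st$keep)
  expect_false(st$evaluable)
})

test_that("ligand solvent exposure spans the unburied and caged limits", {
  fx <- make_fixture(seed = 12, n_replicates = 1, production_ns = 40,
                     frame_interval_ns = 8)
  ligs <- strip_and_split(fx$replicates[[1]]$trajectory)
  # copy 3 never binds: fully exposed
  free <- percent_exposed(ligs[[3]], frame = 1, n_points = 960)
  expect_gt(free$percent_exposed, 99)
  # a ligand atom set enclosed in a cage of large spheres is deeply buried
  lig_at <- data.frame(
    serial = 1, name = "N1", element = "N", resname = "LIG", resid = 1L,
    chain = "L", kind = "ligand", copy = 1L, charge = 0, lj_epsilon = 0.17,
    lj_rmin_half = 1.82, is_central = TRUE, stringsAsFactors = FALSE
  )
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1), c(1, 1, 1) / sqrt(3),
                c(-1, -1, -1) / sqrt(3), c(1, -1, -1) / sqrt(3),
                c(-1, 1, 1) / sqrt(3), c(-1, 1, -1) / sqrt(3),
                c(1, -1, 1) / sqrt(3))
  cage_at <- data.frame(
    serial = 1 + seq_len(nrow(dirs)), name = "CA", element = "S",
    resname = "ALA", resid = 1 + seq_len(nrow(dirs)), chain = "A",
    kind = "receptor", copy = NA_integer_, charge = 0, lj_epsilon = 0.25,
    lj_rmin_half = 2.0, is_central = FALSE, stringsAsFactors = FALSE
  )
  topo <- fd_topology(rbind(lig_at, cage_at), 1L)
  cc <- rbind(c(0, 0, 0), dirs * 2.4)
  tr <- fd_trajectory(topo, matrix(t(cc), nrow = 1), 0)
  caged <- percent_exposed(tr, n_points = 960)
  expect_lt(caged$percent_exposed, 5)
  # rigid-body motion leaves the ratio unchanged
  R <- random_rotation()
  cc2 <- sweep(cc %*% t(R), 2, c(8, -3, 5), "+")
  tr2 <- fd_trajectory(topo, matrix(t(cc2), nrow = 1), 0)
  expect_equal(percent_exposed(tr2, n_points = 960)$percent_exposed,
               caged$percent_exposed, tolerance = 1e-6)
})

test_that("hydrogen-bond detection matches geometry rules and brute force", {
  # ideal linear N-H...O at 2.9 A in every frame
  at <- data.frame(
    serial = 1:3, name = c("O", "N1", "H1"), element = c("O", "N", "H"),
    resname = c("ALA", "LIG", "LIG"), resid = c(1L, 2L, 2L),
    chain = c("A", "L", "L"), kind = c("receptor", "ligand", "ligand"),
    copy = c(NA, 1L, 1L), charge = 0, lj_epsilon = 0.1, lj_rmin_half = 1.7,
    is_central = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE
  )
  topo <- fd_topology(at, 1L)
  cc <- c(0, 0, 0, 2.9, 0, 0, 1.9, 0, 0)   # O ... N with H between
  xyz <- matrix(rep(cc, 5), nrow = 5, byrow = TRUE)
  tr <- fd_trajectory(topo, xyz, seq(0, 20, length.out = 5))
  hb <- hydrogen_bonds(tr)
  expect_equal(nrow(hb$pairs), 1)
  expect_equal(hb$pairs$occupancy, 1.0)
  expect_equal(hb$n_retained, 1L)
  # satisfied in only 40% of frames: below the 45% retention rule
  xyz2 <- matrix(rep(cc, 10), nrow = 10, byrow = TRUE)
  far <- c(0, 0, 0, 6, 0, 0, 5, 0, 0)
  for (f in 1:6) xyz2[f, ] <- far
  tr2 <- fd_trajectory(topo, xyz2, seq(0, 18, by = 2))
  hb2 <- hydrogen_bonds(tr2)
  expect_equal(hb2$pairs$occupancy, 0.4)
  expect_equal(hb2$n_retained, 0L)
  # brute-force all-triples scan on a random polar fixture
  set.seed(14)
  fx <- make_fixture(seed = 14, n_replicates = 1, production_ns = 40,
                     frame_interval_ns = 8)
  lt <- strip_and_split(fx$replicates[[1]]$trajectory)[[1]]
  hb3 <- hydrogen_bonds(lt, window_ns = 40)
  atl <- lt$topology$atoms
  # oracle: explicit loop over (hydrogen, donor, acceptor) triples
  brute_hits <- 0
  frames <- seq_len(n_frames(lt))
  found <- list()
  for (f in frames) {
    cc <- frame_coords(lt, f)
    for (ih in which(atl$element == "H")) {
      heavy <- which(atl$element %in% c("N", "O", "S"))
      dh <- sqrt(rowSums(sweep(cc[heavy, , drop = FALSE], 2, cc[ih, ])^2))
      if (min(dh) > 1.25) next
      id <- heavy[which.min(dh)]
      for (ia in heavy) {
        if (atl$kind[ia] == atl$kind[id]) next
        dda <- sqrt(sum((cc[id, ] - cc[ia, ])^2))
        v1 <- cc[id, ] - cc[ih, ]; v2 <- cc[ia, ] - cc[ih, ]
        cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(min(1, max(-1, cs))) * 180 / pi
        if (dda <= 3.0 && ang >= 135) {
          key <- paste(id, ih, ia)
          found[[key]] <- (found[[key]] %||% 0) + 1
        }
      }
    }
  }
  got_occ <- sort(hb3$pairs$occupancy[hb3$pairs$occupancy > 0])
  want_occ <- sort(unlist(found) / length(frames))
  expect_equal(as.numeric(got_occ), as.numeric(want_occ), tolerance = 1e-12)
})
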