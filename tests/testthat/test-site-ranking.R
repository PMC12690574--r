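test_that("contact residues match a brute-force all-pairs distance scan", {
  # constructed frame: residues 10, 11, 42 placed within 4.5 A of the ligand
  n_res <- 50
  rec <- data.frame(
    serial = seq_len(n_res), name = "CA", element = "C", resname = "ALA",
    resid = seq_len(n_res), chain = "A", kind = "receptor",
    copy = NA_integer_, stringsAsFactors = FALSE
  )
  lig <- data.frame(
    serial = n_res + 1L, name = "N1", element = "N", resname = "LIG",
    resid = 100L, chain = "L", kind = "ligand", copy = 1L,
    stringsAsFactors = FALSE
  )
  topo <- make_simple_topology(rbind(rec, lig), n_copies = 1L)
  topo$atoms$is_central[n_res + 1] <- TRUE
  set.seed(2)
  cc <- matrix(runif(3 * (n_res + 1), 20, 60), ncol = 3)
  cc[n_res + 1, ] <- c(0, 0, 0)
  cc[10, ] <- c(3.0, 0, 0); cc[11, ] <- c(0, 4.4, 0); cc[42, ] <- c(0, 0, 2.0)
  tr <- fd_trajectory(topo, matrix(t(cc), nrow = 1), 0)
  got <- contact_residues(tr)
  expect_setequal(unclass(got), c("A:10:ALA", "A:11:ALA", "A:42:ALA"))
  # oracle: explicit all-pairs scan
  want <- character(0)
  for (i in seq_len(n_res)) {
    if (sqrt(sum((cc[i, ] - cc[n_res + 1, ])^2)) < 4.5)
      want <- c(want, paste("A", i, "ALA", sep = ":"))
  }
  expect_setequal(unclass(got), want)
  # degenerate cutoffs
  expect_length(suppressWarnings(contact_residues(tr, cutoff = 0)), 0)
  cc[10, ] <- cc[11, ] <- cc[42, ] <- c(30, 30, 30)
  tr2 <- fd_trajectory(topo, matrix(t(cc), nrow = 1), 0)
  expect_warning(far <- contact_residues(tr2), "empty contact set")
  expect_length(far, 0)
})

test_that("Jaccard index follows the set formula and its properties", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0.0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d", "e")), 0.4)
  expect_equal(jaccard(character(0), character(0)), 0)
  set.seed(6)
  pool <- letters
  for (i in 1:20) {
    A <- sample(pool, sample(0:10, 1))
    B <- sample(pool, sample(0:10, 1))
    j <- jaccard(A, B)
    expect_identical(j, jaccard(B, A))
    expect_gte(j, 0); expect_lte(j, 1)
    if (length(A) && j == 1) expect_setequal(A, B)
  }
})

test_that("greedy site assignment honors the strict threshold", {
  s1 <- c("r1", "r2", "r3", "r4")
  s2 <- c("r1", "r2", "r3", "r5")           # J = 3/5 = 0.6
  cl <- assign_sites(list(s1, s2), threshold = 0.35)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, c(1, 2))
  expect_setequal(cl[[1]]$canonical_residues, union(s1, s2))
  s3 <- c("r1", "x2", "x3", "x4", "x5")      # J = 1/8 = 0.125
  expect_length(assign_sites(list(s1, s3), threshold = 0.35), 2)
  # J exactly at the threshold founds a new site (strictly-greater joins)
  a <- c("r1", "r2", "r3", "r4", "r5", "r6", "r7")
  b <- c("r1", "r2", "r3", "r4", "r5", "x1", "x2", "x3", "x4", "x5",
         "x6", "x7", "x8")                   # |I|=5, |U|=15... adjust
  b <- c(a[1:7], paste0("x", 1:13))          # J = 7/20 = 0.35
  expect_equal(jaccard(a, b), 0.35)
  expect_length(assign_sites(list(a, b), threshold = 0.35), 2)
  # partition property: every set lands in exactly one cluster
  set.seed(8)
  sets <- replicate(12, sample(letters, sample(3:8, 1)), simplify = FALSE)
  cl2 <- assign_sites(sets)
  expect_setequal(unlist(lapply(cl2, `[[`, "members")), seq_along(sets))
})

make_records <- function(df) {
  defaults <- data.frame(
    rt_ns = 100, e_inter_rt = -10, e_inter_last20 = -10, dg_rt = -5,
    dg_last20 = -5, pct_sasa_last = 50, pct_sasa_rt = 50, n_hbonds = 1
  )
  out <- defaults[rep(1, nrow(df)), , drop = FALSE]
  for (nm in names(df)) out[[nm]] <- df[[nm]]
  rownames(out) <- NULL
  out
}

test_that("per-site aggregation caps replicates and averages by replicate
           count", {
  recs <- make_records(data.frame(replicate = c(1, 1, 3),
                                  copy_id = 1:3,
                                  dg_rt = c(-20, -10, -6)))
  cl <- list(list(site_id = 1L, canonical_residues = "r1",
                  members = 1:3))
  row <- aggregate_sites(cl, recs, n_replicates = 4)
  expect_equal(row$n_reactive, 2)           # replicates {1, 3}
  expect_equal(row$avg_dg_rt, (-20 - 10 - 6) / 4)
  expect_equal(row$best_dg_rt, -20)
  recs2 <- make_records(data.frame(replicate = c(1, 2), copy_id = 1:2,
                                   dg_rt = c(-20, -10)))
  cl2 <- list(list(site_id = 1L, canonical_residues = "r1", members = 1:2))
  row2 <- aggregate_sites(cl2, recs2, n_replicates = 4)
  expect_equal(row2$avg_dg_rt, -7.5)        # NOT divided by member count
  expect_equal(row2$best_dg_rt, -20)
})

test_that("consensus vote selects the majority-descriptor site and
           tie-breaks by energy", {
  # site 1 sweeps every column
  recs <- make_records(data.frame(
    replicate = c(1, 2, 3, 1), copy_id = c(1, 1, 1, 2),
    rt_ns = c(300, 280, 260, 80),
    e_inter_rt = c(-50, -45, -40, -10), e_inter_last20 = c(-50, -45, -40, -10),
    dg_rt = c(-25, -22, -20, -4), dg_last20 = c(-25, -22, -20, -4),
    pct_sasa_last = c(30, 32, 35, 70), pct_sasa_rt = c(30, 32, 35, 70),
    n_hbonds = c(2, 1, 1, 0)))
  cl <- list(list(site_id = 1L, canonical_residues = "a", members = 1:3),
             list(site_id = 2L, canonical_residues = "b", members = 4L))
  rows <- aggregate_sites(cl, recs, n_replicates = 4)
  out <- consensus_vote(rows)
  expect_equal(out$selected_site, 1L)
  expect_equal(max(out$ranking$votes), 9)   # all nine ranked columns
  expect_false(out$tie_broken)
  # split columns: the site with more favorable majorities wins
  recs2 <- make_records(data.frame(
    replicate = c(1, 2, 3, 4, 1, 2), copy_id = c(1, 1, 1, 1, 2, 2),
    rt_ns = c(300, 280, 260, 240, 90, 85),
    e_inter_rt = c(-50, -45, -40, -38, -60, -58),
    e_inter_last20 = c(-50, -45, -40, -38, -60, -58),
    dg_rt = c(-25, -22, -20, -19, -8, -7),
    dg_last20 = c(-25, -22, -20, -19, -8, -7),
    pct_sasa_last = c(40, 41, 42, 43, 20, 22),
    pct_sasa_rt = c(40, 41, 42, 43, 20, 22),
    n_hbonds = c(2, 2, 1, 1, 0, 0)))
  cl2 <- list(list(site_id = 1L, canonical_residues = "a", members = 1:4),
              list(site_id = 2L, canonical_residues = "b", members = 5:6))
  out2 <- consensus_vote(aggregate_sites(cl2, recs2, 4))
  # site 1 leads n_reactive, rt, dg columns, hbonds (6); site 2 takes
  # best/avg e_inter... site 1 still averages better by replicate rule
  expect_equal(out2$selected_site, 1L)
  expect_gt(out2$ranking$votes[out2$ranking$site_id == 1],
            out2$ranking$votes[out2$ranking$site_id == 2])
  # exact vote tie (two winning columns each, rest shared) resolved by the
  # lower averaged MM/GBSA energy and flagged
  recs3 <- make_records(data.frame(
    replicate = c(1, 1), copy_id = 1:2,
    dg_rt = c(-12, -9),            # site 1 takes best and averaged MM/GBSA
    pct_sasa_last = c(50, 30),     # site 2 takes burial
    n_hbonds = c(1, 2)))           # site 2 takes hydrogen bonds
  rows3 <- aggregate_sites(
    list(list(site_id = 1L, canonical_residues = "a", members = 1L),
         list(site_id = 2L, canonical_residues = "b", members = 2L)),
    recs3, 4)
  out3 <- consensus_vote(rows3)
  expect_equal(sort(out3$ranking$votes), c(7, 7))
  expect_true(out3$tie_broken)
  expect_equal(out3$selected_site, 1L)
})
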