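# Complex evaluation: distance tables, cluster geometry, reports, PDB
# round-trips.

fixture_model <- function() {
  # 4-residue chains, residue "2" of A and "1" of B placed exactly 7 apart
  ca_a <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0))
  ca_b <- rbind(c(3.8, 7, 0), c(7.6, 7, 0), c(11.4, 7, 0), c(15.2, 7, 0))
  structure(list(ca_a = ca_a, ca_b = ca_b,
                 res_id_a = as.character(1:4), res_id_b = as.character(1:4),
                 sites_a = c("1", "2"), sites_b = c("1", "2"),
                 clash = list(count = 0L)),
            class = "docked_model")
}

test_that("pair distances are exact and keep candidate order", {
  m <- fixture_model()
  cand <- structure(data.frame(
    rank = 1:2, col_i = c(2, 1), col_j = c(1, 3), DI = c(0.9, 0.5),
    res_chain1 = c("2", "1"), res_chain2 = c("1", "3"),
    orientation = "AB", stringsAsFactors = FALSE),
    class = c("candidate_set", "data.frame"))
  tbl <- pair_distance_table(m, cand)
  expect_equal(nrow(tbl), nrow(cand))
  expect_equal(tbl$distance[1], 7)
  # brute-force check of all rows
  for (r in seq_len(nrow(tbl))) {
    ia <- as.integer(cand$res_chain1[r]); ib <- as.integer(cand$res_chain2[r])
    expect_equal(tbl$distance[r],
                 sqrt(sum((m$ca_a[ia, ] - m$ca_b[ib, ])^2)))
  }
  # an unmapped candidate is flagged, not dropped
  cand$res_chain2[2] <- "99"
  tbl2 <- pair_distance_table(m, cand)
  expect_equal(nrow(tbl2), 2L)
  expect_true(is.na(tbl2$distance[2]))
})

test_that("cluster distances follow the centroid construction", {
  m <- fixture_model()
  m$ca_b <- m$ca_a   # coincident chains
  expect_equal(cluster_distance(m), 0)
  # hand-placed centroids at (0,0,0) and (0,0,12.6)
  m2 <- fixture_model()
  m2$ca_a <- rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0), c(-1, 0, 0))
  m2$ca_b <- sweep(m2$ca_a, 2, c(0, 0, 12.6), "+")
  m2$sites_a <- m2$sites_b <- as.character(1:4)
  expect_equal(cluster_distance(m2), 12.6, tolerance = 1e-12)
  # the virtual site is the arithmetic mean of the coordinating C-alphas
  idx <- c(1L, 3L)
  expect_equal(ligand_site_centroid(m2$ca_a, idx),
               (m2$ca_a[1, ] + m2$ca_a[3, ]) / 2)
  # a missing coordinating residue is reported by name
  m3 <- fixture_model(); m3$sites_a <- c("1", "77")
  expect_error(cluster_distance(m3), "77")
})

test_that("evaluation reports are consistent and pure", {
  fx <- toy_fixture()
  restr <- build_restraints(fx$cand, fx$toy$chain_a, fx$toy$chain_b)
  native <- structure(list(
    ca_a = fx$toy$chain_a$ca, ca_b = fx$toy$chain_b$ca,
    res_id_a = fx$toy$chain_a$res_id, res_id_b = fx$toy$chain_b$res_id,
    sites_a = fx$toy$chain_a$ligand_site_residues,
    sites_b = fx$toy$chain_b$ligand_site_residues,
    clash = count_clashes(list(ca_a = fx$toy$chain_a$ca,
                               ca_b = fx$toy$chain_b$ca))),
    class = "docked_model")
  rep1 <- evaluate_model(native, fx$cand, restr)
  expect_equal(rep1$restraint_satisfaction, 1)
  expect_equal(rep1$single_interface, 1)
  expect_equal(rep1$fraction_within, 1)
  expect_equal(rep1$cluster_distance, fx$toy$ligand_distance,
               tolerance = 1e-9)
  # fraction within 10 A equals a direct recount from the distance table
  tbl <- pair_distance_table(native, fx$cand)
  expect_equal(rep1$fraction_within, mean(tbl$distance <= 10))
  # purity: identical reports on repeated calls
  expect_identical(rep1, evaluate_model(native, fx$cand, restr))
  # separated chains satisfy nothing
  far <- native
  far$ca_b <- sweep(far$ca_b, 2, c(75, 0, 0), "+")
  far$clash <- count_clashes(far)
  rep2 <- evaluate_model(far, fx$cand, restr)
  expect_equal(rep2$restraint_satisfaction, 0)
  expect_equal(rep2$fraction_within, 0)
})

test_that("PDB serialization preserves the evaluation metrics", {
  fx <- toy_fixture()
  restr <- build_restraints(fx$cand, fx$toy$chain_a, fx$toy$chain_b)
  native <- structure(list(
    ca_a = fx$toy$chain_a$ca, ca_b = fx$toy$chain_b$ca,
    res_id_a = fx$toy$chain_a$res_id, res_id_b = fx$toy$chain_b$res_id,
    sites_a = fx$toy$chain_a$ligand_site_residues,
    sites_b = fx$toy$chain_b$ligand_site_residues,
    clash = list(count = 0L)),
    class = "docked_model")
  path <- tempfile(fileext = ".pdb")
  write_docked_pdb(native, path)
  back <- read_docked_pdb(path, sites_a = native$sites_a,
                          sites_b = native$sites_b)
  expect_equal(back$ca_a, unname(native$ca_a), tolerance = 1e-3)
  # metrics recomputed from the file agree to within the coordinate
  # precision of the PDB format (3 decimals)
  expect_lt(abs(cluster_distance(back) - cluster_distance(native)), 5e-3)
  t1 <- pair_distance_table(native, fx$cand)$distance
  t2 <- pair_distance_table(back, fx$cand)$distance
  expect_lt(max(abs(t1 - t2)), 5e-3)
})

test_that("interface RMSD is zero under rigid motion of a perfect model", {
  fx <- toy_fixture()
  native <- list(ca_a = fx$toy$chain_a$ca, ca_b = fx$toy$chain_b$ca)
  expect_lt(interface_rmsd(native, fx$toy$chain_a$ca, fx$toy$chain_b$ca,
                           fx$toy$contacts), 1e-6)
  # a rigidly rotated + translated copy superposes back to zero
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(5, -3, 11)
  moved <- list(ca_a = sweep(fx$toy$chain_a$ca %*% t(R), 2, shift, "+"),
                ca_b = sweep(fx$toy$chain_b$ca %*% t(R), 2, shift, "+"))
  expect_lt(interface_rmsd(moved, fx$toy$chain_a$ca, fx$toy$chain_b$ca,
                           fx$toy$contacts), 1e-6)
  # displacing chain B alone registers as interface error; a 6 A shift of
  # the B-side interface residues gives RMSD sqrt(36 * nB / (nA + nB))
  off <- list(ca_a = fx$toy$chain_a$ca,
              ca_b = sweep(fx$toy$chain_b$ca, 2, c(6, 0, 0), "+"))
  n_if <- length(unique(c(fx$toy$contacts$i)))
  expected <- sqrt(36 * n_if / (2 * n_if))
  expect_equal(interface_rmsd(off, fx$toy$chain_a$ca, fx$toy$chain_b$ca,
                              fx$toy$contacts), expected, tolerance = 0.3)
})
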