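# Contact maps, solvent accessibility, and the three-way coupling filter.

test_that("contact maps match a brute-force distance scan", {
  # two C-alphas 5 A apart
  ch2 <- new_chain(rbind(c(0, 0, 0), c(5, 0, 0)), "AG")
  expect_warning(cm <- compute_contact_map(ch2, cutoff = 8,
                                           min_sequence_separation = 0),
                 "falling back")
  expect_equal(nrow(cm), 1L)
  expect_warning(cm0 <- compute_contact_map(ch2, cutoff = 0.1,
                                            min_sequence_separation = 0),
                 "falling back")
  expect_equal(nrow(cm0), 0L)
  # 10-residue random chain vs exhaustive O(n^2) scan
  set.seed(5)
  xyz <- matrix(cumsum(rnorm(30, sd = 2.5)), 10, 3)
  ch <- new_chain(xyz, paste(rep("A", 10), collapse = ""))
  cm <- compute_contact_map(ch, cutoff = 6, atom_mode = "ca",
                            min_sequence_separation = 2)
  brute <- 0
  for (i in 1:9) for (j in (i + 1):10)
    if (j - i >= 2 && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 6) {
      brute <- brute + 1
      expect_true(contact_map_has(cm, as.character(i), as.character(j)))
    }
  expect_equal(nrow(cm), brute)
})

test_that("heavy-atom contacts use the minimum inter-residue atom distance", {
  # CAs far apart but side-chain atoms close
  at <- data.frame(res_idx = c(1L, 1L, 2L, 2L),
                   elety = c("CA", "CB", "CA", "CB"),
                   element = "C",
                   x = c(0, 4, 9, 5), y = 0, z = 0)
  ch <- new_chain(rbind(c(0, 0, 0), c(9, 0, 0)), "AC", atoms = at)
  cm_heavy <- compute_contact_map(ch, cutoff = 2, atom_mode = "heavy",
                                  min_sequence_separation = 0)
  expect_equal(nrow(cm_heavy), 1L)  # CB-CB distance 1 A
  cm_ca <- compute_contact_map(ch, cutoff = 2, atom_mode = "ca",
                               min_sequence_separation = 0)
  expect_equal(nrow(cm_ca), 0L)     # CA-CA distance 9 A
})

test_that("solvent accessibility separates exposed from buried residues", {
  at <- data.frame(res_idx = 1L, elety = c("N", "CA", "C", "O", "CB"),
                   element = c("N", "C", "C", "O", "C"),
                   x = c(0, 1.5, 2.2, 3.4, 2.0),
                   y = c(0, 0, 1.2, 1.2, -1.4),
                   z = c(0, 0, 0, 0, 0.2))
  iso <- new_chain(matrix(c(1.5, 0, 0), 1, 3), "A", atoms = at)
  s_iso <- compute_sasa(iso)
  expect_gt(s_iso$sasa_rel[1], 0.8)
  # residue at the center of a dense synthetic shell is buried
  set.seed(1)
  sph <- matrix(rnorm(600), ncol = 3)
  sph <- sph / sqrt(rowSums(sph^2)) * runif(200, 3, 6.5)
  at2 <- data.frame(res_idx = c(1L, rep(2L, 200)),
                    elety = "CA", element = "C",
                    x = c(0, sph[, 1]), y = c(0, sph[, 2]),
                    z = c(0, sph[, 3]))
  ch2 <- new_chain(rbind(c(0, 0, 0), colMeans(sph)), "AG", atoms = at2)
  s2 <- compute_sasa(ch2)
  expect_lt(s2$sasa_rel[1], 0.05)
  # sampling-density convergence: doubling the sphere points moves the
  # total area by < 2%
  tot1 <- sum(compute_sasa(iso, n_sphere_points = 240)$sasa_abs)
  tot2 <- sum(compute_sasa(iso, n_sphere_points = 480)$sasa_abs)
  expect_lt(abs(tot2 - tot1) / tot1, 0.02)
})

test_that("homodimer contacts fold onto protomer residue indices", {
  xyz <- cbind(3.8 * (0:5), 0, 0)
  p1 <- new_chain(xyz, "ACDEFG")
  # far-apart protomers share no contacts
  p2_far <- new_chain(sweep(xyz, 2, c(0, 100, 0), "+"), "ACDEFG")
  expect_warning(hm0 <- homodimer_contacts(p1, p2_far, cutoff = 5), "C-alpha")
  expect_equal(nrow(hm0), 0L)
  # one designed cross-chain contact: residue 2 of copy 1 near residue 5 of
  # copy 2; folded onto protomer numbering as the unordered pair (2, 5)
  xyz2 <- sweep(xyz, 2, c(0, 40, 0), "+")
  xyz2[5, ] <- xyz[2, ] + c(0, 4, 0)
  p2 <- new_chain(xyz2, "ACDEFG")
  expect_warning(hm <- homodimer_contacts(p1, p2, cutoff = 5), "C-alpha")
  expect_equal(nrow(hm), 1L)
  expect_true(contact_map_has(hm, "2", "5"))
  expect_true(contact_map_has(hm, "5", "2"))  # unordered
  # mismatched protomer sequences are an assembly error
  p_bad <- new_chain(xyz, "ACDEFW")
  expect_error(homodimer_contacts(p1, p_bad), "sequences differ")
})

make_filter_fixture <- function() {
  # 6 ranked pairs; residue ids "1".."12" on both chains, identity maps
  ranked <- data.frame(i = 1:6, j = 7:12,
                       DI = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  map1 <- identity_map(12)
  map2 <- identity_map(12)
  monomer1 <- contact_map("1", "7")              # excludes (1, 7)
  monomer2 <- contact_map("2", "8")              # excludes (2, 8)
  sasa1 <- data.frame(res_id = as.character(1:12), res_name = "A",
                      sasa_abs = 100, sasa_rel = 0.8,
                      stringsAsFactors = FALSE)
  sasa1$sasa_rel[3] <- 0.01                      # buries (3, 9)
  sasa2 <- data.frame(res_id = as.character(1:12), res_name = "A",
                      sasa_abs = 100, sasa_rel = 0.8,
                      stringsAsFactors = FALSE)
  sasa2$sasa_rel[3] <- 0.01                      # ... in both orientations
  homod1 <- contact_map("4", "10", kind = "homodimer-interchain")
  list(ranked = ranked, map1 = map1, map2 = map2,
       monomer = list(monomer1, monomer2), sasa = list(sasa1, sasa2),
       homod = list(homod1, NULL))
}

test_that("the constructed six-pair fixture leaves the two known survivors", {
  fx <- make_filter_fixture()
  expect_warning(
    cand <- filter_couplings(fx$ranked, fx$map1, fx$map2,
                             monomer_maps = fx$monomer, sasa = fx$sasa,
                             homodimer_maps = fx$homod, K = 20),
    "2 pairs survived")
  surv <- unique(cand[, c("col_i", "col_j", "DI")])
  expect_equal(surv$col_i, c(5, 6))
  expect_equal(surv$col_j, c(11, 12))
  expect_true(all(diff(surv$DI) <= 0))
  audit <- filter_audit(cand)
  expect_equal(sum(audit$excluded), 4L)
  expect_equal(audit$reasons[1], "monomer_contact")
  expect_equal(audit$reasons[2], "monomer_contact")
  expect_equal(audit$reasons[3], "buried")
  expect_equal(audit$reasons[4], "homodimer_contact")
  # every removed pair carries at least one recorded reason
  expect_true(all(nzchar(audit$reasons[audit$excluded])))
  expect_true(all(!nzchar(audit$reasons[!audit$excluded])))
})

test_that("with no exclusion inputs the filter passes through the top K", {
  fx <- make_filter_fixture()
  cand <- filter_couplings(fx$ranked, fx$map1, fx$map2, K = 3)
  surv <- unique(cand[, c("col_i", "col_j")])
  expect_equal(surv$col_i, 1:3)
  expect_equal(surv$col_j, 7:9)
  # both orientations are carried for each surviving pair
  expect_equal(nrow(cand), 6L)
  expect_setequal(unique(cand$orientation), c("AB", "BA"))
})

test_that("an all-buried interface empties the candidate set with a warning", {
  fx <- make_filter_fixture()
  expect_warning(
    cand <- filter_couplings(fx$ranked, fx$map1, fx$map2,
                             sasa = fx$sasa, K = 20,
                             exposure_threshold = 1.0),
    "survived")
  expect_equal(nrow(cand), 0L)
})

test_that("raising the exposure threshold never adds survivors", {
  fx <- make_filter_fixture()
  counts <- vapply(c(0, 0.05, 0.5, 0.81, 1.0), function(thr) {
    cand <- suppressWarnings(
      filter_couplings(fx$ranked, fx$map1, fx$map2, sasa = fx$sasa,
                       K = 20, exposure_threshold = thr))
    nrow(unique(cand[, c("col_i", "col_j")]))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("unmapped columns are excluded with a recorded reason", {
  fx <- make_filter_fixture()
  map1 <- identity_map(12); map1 <- map1[map1$column != 5, ]
  map2 <- identity_map(12); map2 <- map2[map2$column != 5, ]
  cand <- suppressWarnings(
    filter_couplings(fx$ranked, map1, map2, K = 20))
  audit <- filter_audit(cand)
  expect_true(audit$excluded[audit$col_i == 5])
  expect_match(audit$reasons[audit$col_i == 5], "unmapped")
})
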