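# Mean-field DCA: reweighting, frequencies, coupling inversion, DI.

test_that("identity reweighting follows the neighbourhood-count rule", {
  # M identical sequences
  al <- msa(rep("ACDEFGHIKL", 5))
  w <- compute_weights(al, 0.8)
  expect_equal(w$w, rep(1 / 5, 5))
  expect_equal(w$Meff, 1)
  # all pairwise identities below the threshold
  al2 <- msa(c("ACDEFGHIKL", "LKIHGFEDCA", "WWWWWWWWWW"))
  w2 <- compute_weights(al2, 0.8)
  expect_equal(w2$w, rep(1, 3))
  expect_equal(w2$Meff, 3)
  # two identical plus one distinct
  al3 <- msa(c("ACDEFGHIKL", "ACDEFGHIKL", "WWWWWWWWWW"))
  w3 <- compute_weights(al3, 0.8)
  expect_equal(w3$w, c(0.5, 0.5, 1))
  expect_equal(w3$Meff, 2)
})

test_that("pseudocounted frequencies match the closed formula and limits", {
  al <- msa(c("AC", "AD"))
  w <- compute_weights(al, 0.8)
  expect_equal(w$Meff, 2)
  fr <- compute_frequencies(al, w, lambda = 2)
  cidx <- match("C", al$alphabet)
  expect_equal(fr$fi[2, cidx], (2 / 21 + 1) / 4, tolerance = 1e-12)
  expect_equal(fr$fi[2, cidx], 0.27381, tolerance = 1e-4)
  # lambda -> infinity pushes everything to the uniform distribution
  fr_inf <- compute_frequencies(al, w, lambda = 1e6 * w$Meff)
  expect_true(all(abs(fr_inf$fi - 1 / 21) < 1e-4))
  # single-column-information case: a column that is all 'A' at lambda = 0
  fr0 <- compute_frequencies(al, w, lambda = 0)
  aidx <- match("A", al$alphabet)
  expect_equal(fr0$fi[1, aidx], 1)
  expect_equal(sum(fr0$fi[1, -aidx]), 0)
})

test_that("frequency normalization and marginal consistency hold to 1e-12", {
  set.seed(11)
  for (rep in 1:3) {
    al <- sample_potts_msa(potts_spec(L = 6, q = 4, M = 80,
                                      couplings = planted_pairs(6, 2, 0.8),
                                      seed = rep))
    w <- compute_weights(al, 0.8)
    fr <- compute_frequencies(al, w)
    expect_true(all(abs(rowSums(fr$fi) - 1) < 1e-12))
    for (i in 1:6) for (j in 1:6) {
      blk <- fr$fij[, , i, j]
      expect_lt(abs(sum(blk) - 1), 1e-12)
      if (i != j)
        expect_lt(max(abs(rowSums(blk) - fr$fi[i, ])), 1e-12)
      else
        expect_equal(blk, diag(fr$fi[i, ]), tolerance = 1e-14)
    }
  }
})

test_that("independent columns give vanishing inter-column couplings", {
  # exact product alignment over a gapless 2-letter alphabet, lambda = 0
  al <- msa(c("AA", "AC", "CA", "CC"), alphabet = c("A", "C"))
  fr <- compute_frequencies(al, lambda = 0)
  cp <- infer_couplings(fr)
  expect_lt(abs(coupling_matrix(cp, 1, 2)[1, 1]), 1e-8)
  di <- direct_information(cp, fr, 1, 2)
  expect_lt(abs(di$DI), 1e-10)
  expect_equal(di$P_dir, tcrossprod(fr$fi[1, ], fr$fi[2, ]),
               tolerance = 1e-8)
})

test_that("the 2x2 inversion matches the hand-computed closed form", {
  al <- msa(c("AA", "AA", "AA", "AC", "CA", "CC"), alphabet = c("A", "C"))
  lambda <- 1
  fr <- compute_frequencies(al, lambda = lambda)
  cp <- infer_couplings(fr)
  # by hand: q = 2 reduces to one state per column; C is 2x2
  f1 <- (lambda / 2 + 4) / (lambda + 6)     # P(col1 = A)
  f2 <- (lambda / 2 + 4) / (lambda + 6)
  f12 <- (lambda / 4 + 3) / (lambda + 6)    # P(AA)
  c11 <- f1 * (1 - f1)
  c22 <- f2 * (1 - f2)
  c12 <- f12 - f1 * f2
  det <- c11 * c22 - c12^2
  e_hand <- c12 / det                       # -(C^-1)[1,2]
  expect_equal(coupling_matrix(cp, 1, 2)[1, 1], e_hand, tolerance = 1e-10)
})

test_that("a planted strong coupling carries the largest coupling norm", {
  pl <- data.frame(i = 2L, j = 5L, strength = 3)
  al <- sample_potts_msa(potts_spec(L = 6, q = 4, M = 1000, couplings = pl,
                                    seed = 5))
  w <- compute_weights(al, 0.8)
  fr <- compute_frequencies(al, w)
  cp <- infer_couplings(fr)
  nrm <- coupling_norms(cp)
  top <- which(nrm == max(nrm), arr.ind = TRUE)[1, ]
  expect_equal(sort(unname(top)), c(2L, 5L))
})

test_that("DI matches the enumeration oracle and mutual information", {
  set.seed(21)
  for (rep in 1:5) {
    al <- sample_potts_msa(potts_spec(L = 2, q = 3, M = 60,
                                      couplings = data.frame(
                                        i = 1L, j = 2L, strength = 1.2),
                                      seed = 30 + rep))
    w <- compute_weights(al, 0.8)
    fr <- compute_frequencies(al, w)
    cp <- infer_couplings(fr)
    di <- direct_information(cp, fr, 1, 2, tol = 1e-9)
    expect_equal(di$DI, di_ipf_oracle(al), tolerance = 1e-6)
    # DI is the mutual information of P_dir by construction
    P <- di$P_dir
    mi <- sum(P * log(P / tcrossprod(rowSums(P), colSums(P))))
    expect_equal(di$DI, mi, tolerance = 1e-5)
    # symmetric under site relabeling
    expect_equal(di$DI, direct_information(cp, fr, 2, 1, tol = 1e-9)$DI,
                 tolerance = 1e-9)
  }
})

test_that("DI is non-negative across random instances", {
  for (rep in 1:3) {
    al <- sample_potts_msa(potts_spec(L = 8, q = 4, M = 150,
                                      couplings = planted_pairs(8, 3, 1),
                                      seed = 40 + rep))
    w <- compute_weights(al, 0.8)
    fr <- compute_frequencies(al, w)
    di <- di_matrix(infer_couplings(fr), fr)
    expect_true(all(di >= -1e-10))
    expect_equal(di, t(di))
  }
})

test_that("pair ranking is DI-descending with lexicographic tie-breaks", {
  di <- matrix(0, 6, 6)
  di[1, 4] <- di[4, 1] <- 0.5
  di[2, 5] <- di[5, 2] <- 0.9
  di[3, 6] <- di[6, 3] <- 0.5   # tie with (1, 4)
  ranked <- rank_pairs(di, min_separation = 0)
  expect_equal(ranked$DI[1], 0.9)
  expect_equal(c(ranked$i[2], ranked$j[2]), c(1, 4))  # tie: (1,4) < (3,6)
  expect_equal(c(ranked$i[3], ranked$j[3]), c(3, 6))
  expect_true(all(diff(ranked$DI) <= 0))
  # separation filter equals a brute-force scan
  set.seed(7)
  dib <- matrix(0, 10, 10)
  dib[upper.tri(dib)] <- runif(45)
  dib <- dib + t(dib)
  ranked5 <- rank_pairs(dib, min_separation = 5)
  brute <- sum((col(dib) - row(dib))[upper.tri(dib)] >= 5)
  expect_equal(nrow(ranked5), brute)
  expect_true(all(ranked5$j - ranked5$i >= 5))
})

test_that("identical inputs give bit-identical DI rankings", {
  al <- sample_potts_msa(potts_spec(L = 6, q = 4, M = 200,
                                    couplings = planted_pairs(6, 2, 1),
                                    seed = 3))
  run <- function() {
    w <- compute_weights(al, 0.8)
    fr <- compute_frequencies(al, w)
    rank_pairs(di_matrix(infer_couplings(fr), fr), min_separation = 0)
  }
  expect_identical(run(), run())
})
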