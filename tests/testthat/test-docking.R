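# Structure-based model construction, restraints, annealing, clash counting
# and replica selection.

test_that("topology counts follow the chain length", {
  xyz <- helix10 <- cbind(2.3 * cos(1.75 * (0:9)), 2.3 * sin(1.75 * (0:9)),
                          1.5 * (0:9))
  # rescale consecutive distances to exactly 3.8
  for (k in 2:10) {
    d <- sqrt(sum((xyz[k, ] - xyz[k - 1, ])^2))
    xyz[k, ] <- xyz[k - 1, ] + (xyz[k, ] - xyz[k - 1, ]) * 3.8 / d
  }
  ch <- new_chain(xyz, paste(rep("A", 10), collapse = ""))
  top <- build_sbm(ch, contact_cutoff = 7)
  expect_length(top$b0, 9L)
  expect_length(top$theta0, 8L)
  expect_length(top$phi0, 7L)
  expect_true(all(top$contacts$j - top$contacts$i >= 3))
  top0 <- build_sbm(ch, contact_cutoff = 0)
  expect_equal(nrow(top0$contacts), 0L)
})

test_that("a broken backbone is reported with its position", {
  xyz <- cbind(3.8 * (0:5), 0, 0)
  xyz[4:6, 1] <- xyz[4:6, 1] + 10
  ch <- new_chain(xyz, "AAAAAA")
  expect_error(build_sbm(ch), "gap.*3")
})

test_that("the native structure sits at the model's minimum", {
  fx <- toy_fixture()
  mn <- sbm_minimize(fx$top_a, tol = 1e-6)
  expect_lt(mn$max_force, 1e-6)
  # and the minimizer barely moves the native coordinates
  expect_lt(max(abs(mn$coords - fx$top_a$ca_native)), 0.5)
})

test_that("restraint energy has the flat-bottom functional form", {
  ca_a <- matrix(c(0, 0, 0), 1, 3)
  mk_model <- function(d) list(ca_a = ca_a, ca_b = matrix(c(d, 0, 0), 1, 3))
  restr <- structure(list(
    pairs = data.frame(ia = 1L, ib = 1L, res_a = "1", res_b = "1",
                       r_upper = 10, k = 1, g_r0 = 8, g_w = 2, g_depth = 0),
    cluster = NULL, tolerance = 2, force_cap_width = 100),
    class = "restraint_set")
  at9 <- restraint_energy(restr, ca_a, mk_model(9)$ca_b)
  expect_equal(at9$total, 0)
  for (d in c(0.5, 1, 1.9)) {
    e <- restraint_energy(restr, ca_a, mk_model(10 + d)$ca_b)
    expect_equal(e$total, 0.5 * d^2, tolerance = 1e-12)
  }
})

test_that("initial placement is exact, sealed and reproducible", {
  fx <- toy_fixture()
  init <- initialize_complex(fx$toy$chain_a, fx$toy$chain_b,
                             separation = 75, seed = 3)
  com_d <- sqrt(sum((colMeans(init$ca_a) - colMeans(init$ca_b))^2))
  expect_equal(com_d, 75, tolerance = 1e-9)
  init2 <- initialize_complex(fx$toy$chain_a, fx$toy$chain_b,
                              separation = 75, seed = 3)
  expect_identical(init, init2)
  # no inter-chain contacts across 100 random seeds (brute-force scan)
  for (sd in 1:100) {
    ini <- initialize_complex(fx$toy$chain_a, fx$toy$chain_b,
                              separation = 75, seed = sd)
    expect_gt(min(coevodock:::cross_dist(ini$ca_a, ini$ca_b)), 8)
  }
  expect_error(initialize_complex(fx$toy$chain_a, fx$toy$chain_b,
                                  separation = 10),
               "radii of gyration")
})

test_that("without coupling restraints distant chains stay distant", {
  fx <- toy_fixture()
  restr <- build_restraints(NULL, fx$toy$chain_a, fx$toy$chain_b, k_c = 0)
  sched <- anneal_schedule(t_init = 0.2, t_final = 0.2, nsteps = 5000)
  m <- run_replica(fx$top_a, fx$top_b, restr, sched, seed = 2,
                   separation = 75)
  com_d <- sqrt(sum((colMeans(m$ca_a) - colMeans(m$ca_b))^2))
  expect_gt(com_d, 50)
})

test_that("a lone cluster restraint pulls the ligand sites to target", {
  fx <- toy_fixture()
  restr <- build_restraints(NULL, fx$toy$chain_a, fx$toy$chain_b,
                            r_cluster = 12)
  sched <- anneal_schedule(nsteps = 1e5)
  m <- run_replica(fx$top_a, fx$top_b, restr, sched, seed = 4,
                   separation = 40)
  expect_lt(abs(m$restraint$cluster_distance - 12), 2)
  # the monomer folds survive the pull-in
  expect_gt(m$q_a, 0.8)
  expect_gt(m$q_b, 0.8)
  # chain connectivity is preserved
  expect_lt(m$bond_max_rel_dev, 0.1)
})

test_that("annealing relaxes the potential energy", {
  fx <- toy_fixture()
  restr <- build_restraints(fx$cand, fx$toy$chain_a, fx$toy$chain_b)
  sched <- anneal_schedule(nsteps = 1e5)
  m <- run_replica(fx$top_a, fx$top_b, restr, sched, seed = 5,
                   separation = 30)
  tr <- m$trace
  n <- nrow(tr)
  first <- tr[tr[, "step"] <= 0.1 * max(tr[, "step"]), "energy"]
  last <- tr[tr[, "step"] >= 0.9 * max(tr[, "step"]), "energy"]
  expect_lt(mean(last), mean(first))
})

test_that("replicas are deterministic and ensembles replay bit-identically", {
  fx <- toy_fixture()
  restr <- build_restraints(fx$cand, fx$toy$chain_a, fx$toy$chain_b)
  sched <- anneal_schedule(nsteps = 5000)
  m1 <- run_replica(fx$top_a, fx$top_b, restr, sched, seed = 9)
  m2 <- run_replica(fx$top_a, fx$top_b, restr, sched, seed = 9)
  expect_identical(m1$ca_a, m2$ca_a)
  expect_identical(m1$ca_b, m2$ca_b)
  ens1 <- run_ensemble(fx$top_a, fx$top_b, restr, sched, n_replicas = 3,
                       base_seed = 7)
  ens2 <- run_ensemble(fx$top_a, fx$top_b, restr, sched, n_replicas = 3,
                       base_seed = 7)
  expect_length(ens1, 3L)
  expect_identical(lapply(ens1, `[[`, "ca_b"), lapply(ens2, `[[`, "ca_b"))
  # a single replica equals the ensemble's first member
  expect_identical(ens1[[1]]$ca_b,
                   run_replica(fx$top_a, fx$top_b, restr, sched,
                               seed = 7)$ca_b)
  expect_equal(vapply(ens1, `[[`, numeric(1), "seed"), c(7, 8, 9))
})

test_that("clash counting equals an exhaustive pair scan", {
  fx <- toy_fixture()
  # chains 75 A apart: no clashes
  far <- list(ca_a = fx$toy$chain_a$ca,
              ca_b = sweep(fx$toy$chain_b$ca, 2, c(200, 0, 0), "+"))
  expect_equal(count_clashes(far)$count, 0L)
  # two superposed identical chains
  sup <- list(ca_a = fx$toy$chain_a$ca, ca_b = fx$toy$chain_a$ca)
  rep_ <- count_clashes(sup, clash_threshold = 3.8)
  brute <- 0
  for (i in 1:fx$toy$spec$n) for (j in 1:fx$toy$spec$n)
    if (sqrt(sum((sup$ca_a[i, ] - sup$ca_b[j, ])^2)) < 3.8) brute <- brute + 1
  expect_equal(rep_$count, brute)
  expect_equal(nrow(rep_$pairs), rep_$count)
  # vanishing threshold counts nothing for physically distinct chains
  native <- list(ca_a = fx$toy$chain_a$ca, ca_b = fx$toy$chain_b$ca)
  expect_equal(count_clashes(native, clash_threshold = 1e-12)$count, 0L)
})

test_that("model selection minimizes clashes with stated tie-breaks", {
  mk <- function(seed, clash, viol)
    structure(list(seed = seed, clash = list(count = clash),
                   violation_energy = viol), class = "docked_model")
  sel <- select_model(list(mk(1, 4, 0), mk(2, 0, 5), mk(3, 2, 0)))
  expect_equal(sel$seed, 2)
  sel2 <- select_model(list(mk(1, 0, 3.1), mk(2, 0, 1.2)))
  expect_equal(sel2$seed, 2)
  sel3 <- select_model(list(mk(5, 0, 1), mk(4, 0, 1)))
  expect_equal(sel3$seed, 4)
  expect_error(select_model(list()), "empty")
  # property: the selected model's clash count is the ensemble minimum
  set.seed(8)
  for (rep in 1:20) {
    models <- lapply(1:6, function(s)
      mk(s, sample(0:4, 1), runif(1)))
    best <- select_model(models)
    expect_equal(best$clash$count,
                 min(vapply(models, function(m) m$clash$count, numeric(1))))
  }
})
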