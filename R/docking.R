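# Restrained docking: C-alpha structure-based models, flat-bottom coupling
# restraints plus a cluster-proximity restraint, simulated-annealing Langevin
# dynamics, replica ensembles, and clash-based model selection.

vnorm <- function(v) sqrt(sum(v^2))

angle_of <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  cs <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cs)))
}

dihedral_of <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(m1 * b2) / vnorm(b2), sum(n1 * n2))
}

#' Build a C-alpha structure-based (Go-type) topology for one chain
#'
#' The potential holds the chain at its native geometry: harmonic virtual
#' bonds and angles, native dihedrals with 1- and 3-fold terms,
#' Lennard-Jones-type (12-10) wells at the native distance for native
#' contacts, and generic excluded-volume repulsion for everything else.
#' Native contacts are residue pairs with sequence separation at least
#' `min_separation` whose inter-residue distance (heavy-atom minimum when
#' all-atom coordinates are available, C-alpha otherwise) is at most
#' `contact_cutoff`.
#'
#' @param chain a `chain`.
#' @param contact_cutoff native-contact distance cutoff (Angstrom). The
#'   default 4.5 suits heavy-atom mode; use ~7 for C-alpha-only chains.
#' @param min_separation minimum sequence separation of native contacts.
#' @param kb,ka,kd,eps,rep_sigma,rep_eps force-field constants in reduced
#'   units (energies in multiples of the contact depth `eps`).
#' @return An `sbm_topology` list.
#' @export
build_sbm <- function(chain, contact_cutoff = 4.5, min_separation = 3L,
                      kb = 200, ka = 40, kd = 3, eps = 1,
                      rep_sigma = 4, rep_eps = 1) {
  n <- chain$n
  if (n < 4L) stop("chain too short for a structure-based model (need >= 4)")
  ca <- chain$ca
  bl <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  gaps <- which(bl > 4.5)
  if (length(gaps))
    stop("broken backbone: C-alpha gap(s) after residue position(s) ",
         paste(gaps, collapse = ", "))
  theta0 <- vapply(seq_len(n - 2L), function(k)
    angle_of(ca[k, ], ca[k + 1L, ], ca[k + 2L, ]), numeric(1))
  phi0 <- vapply(seq_len(n - 3L), function(k)
    dihedral_of(ca[k, ], ca[k + 1L, ], ca[k + 2L, ], ca[k + 3L, ]),
    numeric(1))
  mode <- if (has_heavy_atoms(chain)) "heavy" else "ca"
  contacts <- data.frame(i = integer(0), j = integer(0), sigma = numeric(0))
  if (contact_cutoff > 0) {
    dmin <- residue_min_dist(chain, mode)
    idx <- which(upper.tri(dmin), arr.ind = TRUE)
    hit <- (idx[, 2] - idx[, 1]) >= min_separation & dmin[idx] <= contact_cutoff
    if (any(hit)) {
      ii <- idx[hit, 1]; jj <- idx[hit, 2]
      sigma <- sqrt(rowSums((ca[ii, , drop = FALSE] -
                               ca[jj, , drop = FALSE])^2))
      contacts <- data.frame(i = ii, j = jj, sigma = sigma)
    }
  }
  structure(list(n = n, ca_native = ca, res_id = chain$res_id,
                 b0 = bl, theta0 = theta0, phi0 = phi0, contacts = contacts,
                 ligand_site_residues = chain$ligand_site_residues,
                 params = list(kb = kb, ka = ka, kd = kd, eps = eps,
                               rep_sigma = rep_sigma, rep_eps = rep_eps)),
            class = "sbm_topology")
}

#' Build the restraint set for docking
#'
#' One flat-bottom restraint per candidate orientation (zero energy below
#' `r_couple`, harmonic `k/2 (d - r_couple)^2` above) between the mapped
#' C-alpha beads, plus one harmonic restraint `k_c/2 (d - r_cluster)^2`
#' between the ligand-site centroids of the two chains (the metal-cluster
#' transfer geometry).
#'
#' @param candidates a `candidate_set` (may be empty: cluster restraint only).
#' @param chain_a,chain_b the two `chain`s being docked; their
#'   `ligand_site_residues` define the cluster restraint (omitted when either
#'   is empty).
#' @param r_couple flat-bottom upper bound (Angstrom).
#' @param r_cluster cluster-restraint target distance (Angstrom).
#' @param k,k_c force constants (reduced energy / A^2).
#' @param tolerance satisfaction tolerance band added to `r_couple` when
#'   scoring restraint satisfaction (Angstrom).
#' @param force_cap_width width (Angstrom) of the harmonic region of every
#'   wall restraint; beyond it the wall becomes linear, capping the pulling
#'   force at `k * force_cap_width` so distant chains are reeled in gently
#'   without unfolding.
#' @param gauss_depth,gauss_r0,gauss_width short-range Gaussian localization
#'   well per coupling restraint (depth in contact units, minimum position
#'   and width in Angstrom); the well pulls a restrained pair toward a
#'   typical residue-contact distance once the chains are close, while the
#'   flat-bottom wall provides the long-range funnel. `gauss_depth = 0`
#'   disables it.
#' @return A `restraint_set` list with `pairs` (data.frame `ia, ib, res_a,
#'   res_b, r_upper, k, g_r0, g_w, g_depth`) and `cluster` (or `NULL`).
#' @export
build_restraints <- function(candidates, chain_a, chain_b, r_couple = 10,
                             r_cluster = 12, k = 1, k_c = 1, tolerance = 2,
                             force_cap_width = 2, gauss_depth = 1,
                             gauss_r0 = 8, gauss_width = 2) {
  pairs <- data.frame(ia = integer(0), ib = integer(0),
                      res_a = character(0), res_b = character(0),
                      r_upper = numeric(0), k = numeric(0),
                      g_r0 = numeric(0), g_w = numeric(0),
                      g_depth = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(candidates) && nrow(candidates) > 0L) {
    ia <- match(candidates$res_chain1, chain_a$res_id)
    ib <- match(candidates$res_chain2, chain_b$res_id)
    bad <- is.na(ia) | is.na(ib)
    if (any(bad))
      warning(sum(bad), " restraint(s) skipped: candidate references a ",
              "residue absent from the chain")
    pairs <- data.frame(ia = ia[!bad], ib = ib[!bad],
                        res_a = candidates$res_chain1[!bad],
                        res_b = candidates$res_chain2[!bad],
                        r_upper = r_couple, k = k,
                        g_r0 = gauss_r0, g_w = gauss_width,
                        g_depth = gauss_depth, stringsAsFactors = FALSE)
  }
  cluster <- NULL
  if (length(chain_a$ligand_site_residues) &&
      length(chain_b$ligand_site_residues)) {
    cluster <- list(idx_a = match(chain_a$ligand_site_residues, chain_a$res_id),
                    idx_b = match(chain_b$ligand_site_residues, chain_b$res_id),
                    r0 = r_cluster, k = k_c)
  }
  if (nrow(pairs) == 0L && is.null(cluster))
    stop("empty restraint set: no candidates and no ligand sites")
  structure(list(pairs = pairs, cluster = cluster, tolerance = tolerance,
                 force_cap_width = force_cap_width),
            class = "restraint_set")
}

#' Flat-bottom and cluster restraint energies of a configuration
#'
#' @param restraints a `restraint_set`.
#' @param ca_a,ca_b C-alpha coordinates of the two chains.
#' @return List with `pair_distances`, `pair_energies`, `cluster_distance`,
#'   `cluster_energy`, and `total`.
#' @export
restraint_energy <- function(restraints, ca_a, ca_b) {
  lin <- restraints$force_cap_width %||chr% 2
  wall_energy <- function(dr, k) {
    ifelse(dr <= lin, 0.5 * k * dr^2,
           0.5 * k * lin^2 + k * lin * (dr - lin))
  }
  p <- restraints$pairs
  d <- numeric(nrow(p)); e <- numeric(nrow(p))
  if (nrow(p) > 0L) {
    d <- sqrt(rowSums((ca_a[p$ia, , drop = FALSE] -
                         ca_b[p$ib, , drop = FALSE])^2))
    e <- wall_energy(pmax(0, d - p$r_upper), p$k)
  }
  cd <- NA_real_; ce <- 0
  if (!is.null(restraints$cluster)) {
    cl <- restraints$cluster
    cen_a <- colMeans(ca_a[cl$idx_a, , drop = FALSE])
    cen_b <- colMeans(ca_b[cl$idx_b, , drop = FALSE])
    cd <- vnorm(cen_a - cen_b)
    ce <- wall_energy(abs(cd - cl$r0), cl$k)
  }
  list(pair_distances = d, pair_energies = e, cluster_distance = cd,
       cluster_energy = ce, total = sum(e) + ce)
}

#' Annealing schedule
#'
#' @param t_init,t_final initial and final reduced temperatures (the schedule
#'   is linear in step number).
#' @param nsteps number of Langevin steps.
#' @param dt integrator timestep (reduced units).
#' @param friction Langevin friction coefficient (reduced units).
#' @param trace_stride energy-trace sampling stride (steps).
#' @return An `anneal_schedule` list.
#' @export
anneal_schedule <- function(t_init = 1.2, t_final = 0.2, nsteps = 2e5,
                            dt = 5e-4, friction = 1.0,
                            trace_stride = max(1L, as.integer(nsteps %/% 200))) {
  stopifnot(t_init >= 0, t_final >= 0, t_final <= t_init, nsteps >= 1)
  structure(list(t_init = t_init, t_final = t_final,
                 nsteps = as.integer(nsteps), dt = dt, friction = friction,
                 trace_stride = as.integer(trace_stride)),
            class = "anneal_schedule")
}

radius_of_gyration <- function(x) {
  c0 <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2L, c0)^2)))
}

random_rotation <- function() {
  repeat {
    m <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(m)
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    if (abs(det(Q) - 1) < 1e-9) return(Q)
  }
}

#' Random initial placement of the two chains
#'
#' Chain A keeps its native coordinates; chain B is given a random
#' orientation and placed so the centers of mass are exactly `separation`
#' apart along a random direction, with no inter-chain contacts.
#'
#' @param chain_a,chain_b `chain`s (or `sbm_topology`s; native coordinates
#'   are used).
#' @param separation center-of-mass distance (Angstrom); must exceed the sum
#'   of the chains' radii of gyration.
#' @param seed optional RNG seed (otherwise the current RNG stream is used).
#' @param min_clearance minimum allowed inter-chain C-alpha distance.
#' @return List with `ca_a`, `ca_b` coordinate matrices.
#' @export
initialize_complex <- function(chain_a, chain_b, separation = 75,
                               seed = NULL, min_clearance = 8) {
  if (!is.null(seed)) set.seed(seed)
  xa <- if (inherits(chain_a, "sbm_topology")) chain_a$ca_native else chain_a$ca
  xb <- if (inherits(chain_b, "sbm_topology")) chain_b$ca_native else chain_b$ca
  rga <- radius_of_gyration(xa); rgb <- radius_of_gyration(xb)
  if (separation <= rga + rgb)
    stop("separation must exceed the sum of radii of gyration (",
         round(rga + rgb, 1), " A)")
  for (try in 1:50) {
    u <- stats::rnorm(3); u <- u / vnorm(u)
    R <- random_rotation()
    xb_c <- sweep(xb, 2L, colMeans(xb))
    xb_new <- xb_c %*% t(R)
    xb_new <- sweep(xb_new, 2L, colMeans(xa) + separation * u, FUN = "+")
    dmin <- min(cross_dist(xa, xb_new))
    if (dmin >= min_clearance)
      return(list(ca_a = xa, ca_b = xb_new))
  }
  stop("could not place chains without inter-chain contacts")
}

cross_dist <- function(xa, xb) {
  na <- nrow(xa)
  d <- as.matrix(stats::dist(rbind(xa, xb)))
  d[seq_len(na), na + seq_len(nrow(xb)), drop = FALSE]
}

# Assemble the merged two-chain topology list consumed by the C++ engine.
merge_topology <- function(top_a, top_b, restraints) {
  nA <- top_a$n; nB <- top_b$n; n <- nA + nB
  seq_bonds <- function(top, off) {
    cbind(seq_len(top$n - 1L), seq_len(top$n - 1L) + 1L) + off
  }
  bonds <- rbind(seq_bonds(top_a, 0L), seq_bonds(top_b, nA))
  b0 <- c(top_a$b0, top_b$b0)
  seq_ang <- function(top, off) {
    k <- seq_len(top$n - 2L)
    cbind(k, k + 1L, k + 2L) + off
  }
  angles <- rbind(seq_ang(top_a, 0L), seq_ang(top_b, nA))
  a0 <- c(top_a$theta0, top_b$theta0)
  seq_dih <- function(top, off) {
    k <- seq_len(top$n - 3L)
    cbind(k, k + 1L, k + 2L, k + 3L) + off
  }
  dihedrals <- rbind(seq_dih(top_a, 0L), seq_dih(top_b, nA))
  d0 <- c(top_a$phi0, top_b$phi0)
  contacts <- rbind(as.matrix(top_a$contacts[, c("i", "j")]),
                    as.matrix(top_b$contacts[, c("i", "j")]) + nA)
  sigma <- c(top_a$contacts$sigma, top_b$contacts$sigma)
  p <- restraints$pairs
  rmat <- if (nrow(p)) cbind(p$ia, p$ib + nA) else matrix(0L, 0, 2)
  has_cluster <- !is.null(restraints$cluster)
  prm <- top_a$params
  list(n = n, nA = nA,
       bonds = matrix(as.integer(bonds), ncol = 2), b0 = b0, kb = prm$kb,
       angles = matrix(as.integer(angles), ncol = 3), a0 = a0, ka = prm$ka,
       dihedrals = matrix(as.integer(dihedrals), ncol = 4), d0 = d0,
       kd = prm$kd,
       contacts = matrix(as.integer(contacts), ncol = 2), sigma = sigma,
       eps = prm$eps, rep_sigma = prm$rep_sigma, rep_eps = prm$rep_eps,
       restraints = matrix(as.integer(rmat), ncol = 2),
       r_up = if (nrow(p)) p$r_upper else numeric(0),
       r_k = if (nrow(p)) p$k else numeric(0),
       g_r0 = if (nrow(p)) p$g_r0 else numeric(0),
       g_w = if (nrow(p)) p$g_w else numeric(0),
       g_depth = if (nrow(p)) p$g_depth else numeric(0),
       r_lin = restraints$force_cap_width %||chr% 2,
       has_cluster = has_cluster,
       cluster_a = if (has_cluster) as.integer(restraints$cluster$idx_a)
                   else integer(0),
       cluster_b = if (has_cluster)
                     as.integer(restraints$cluster$idx_b + nA)
                   else integer(0),
       cluster_r0 = if (has_cluster) restraints$cluster$r0 else 0,
       cluster_k = if (has_cluster) restraints$cluster$k else 0)
}

# single-chain topology (no partner, no restraints) for energy evaluation
single_topology <- function(top) {
  n <- top$n
  k <- seq_len(n - 2L); kd4 <- seq_len(n - 3L)
  prm <- top$params
  list(n = n, nA = n,
       bonds = cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), b0 = top$b0,
       kb = prm$kb,
       angles = cbind(k, k + 1L, k + 2L), a0 = top$theta0, ka = prm$ka,
       dihedrals = cbind(kd4, kd4 + 1L, kd4 + 2L, kd4 + 3L), d0 = top$phi0,
       kd = prm$kd,
       contacts = matrix(as.integer(as.matrix(top$contacts[, c("i", "j")])),
                         ncol = 2),
       sigma = top$contacts$sigma, eps = prm$eps,
       rep_sigma = prm$rep_sigma, rep_eps = prm$rep_eps,
       restraints = matrix(integer(0), 0, 2), r_up = numeric(0),
       r_k = numeric(0), g_r0 = numeric(0), g_w = numeric(0),
       g_depth = numeric(0), r_lin = 2,
       has_cluster = FALSE, cluster_a = integer(0),
       cluster_b = integer(0), cluster_r0 = 0, cluster_k = 0)
}

#' Potential energy and forces of one chain under its structure-based model
#'
#' @param top an `sbm_topology`.
#' @param ca coordinates (defaults to the native coordinates).
#' @return List with `energy`, per-term `components`, `forces`, `max_force`.
#' @export
sbm_energy <- function(top, ca = top$ca_native) {
  cpp_sbm_energy(as.matrix(ca), single_topology(top), TRUE)
}

#' Locally minimize one chain under its structure-based model
#'
#' FIRE minimization; used to verify that the native structure sits at the
#' model's minimum.
#'
#' @param top an `sbm_topology`.
#' @param ca starting coordinates (defaults to native).
#' @param tol stop when the largest force component falls below `tol`.
#' @param max_iter iteration cap.
#' @return List with `coords`, `energy`, `max_force`, `iterations`.
#' @export
sbm_minimize <- function(top, ca = top$ca_native, tol = 1e-6,
                         max_iter = 20000L) {
  cpp_minimize_fire(as.matrix(ca), single_topology(top), tol,
                    as.integer(max_iter))
}

#' Fraction of native contacts formed
#'
#' A native contact counts as formed when its distance is within a factor
#' `factor` of the native distance.
#'
#' @param top an `sbm_topology`.
#' @param ca coordinates of the chain.
#' @param factor formation threshold multiplier on the native distance.
#' @return Fraction in `[0, 1]` (1 when the topology has no contacts).
#' @export
native_contact_fraction <- function(top, ca, factor = 1.2) {
  ct <- top$contacts
  if (nrow(ct) == 0L) return(1)
  d <- sqrt(rowSums((ca[ct$i, , drop = FALSE] - ca[ct$j, , drop = FALSE])^2))
  mean(d <= factor * ct$sigma)
}

#' Run one restrained annealing replica
#'
#' Places the chains `separation` apart in a seed-determined random relative
#' orientation, runs Langevin dynamics under the merged structure-based +
#' restraint potential with a linear temperature ramp, then locally minimizes
#' the energy. All randomness is driven by `seed`, so identical inputs give
#' bit-identical models.
#'
#' @param top_a,top_b `sbm_topology` objects for the two chains.
#' @param restraints a `restraint_set`.
#' @param schedule an [anneal_schedule()].
#' @param seed integer seed for this replica.
#' @param separation initial center-of-mass distance (Angstrom).
#' @param clash_threshold inter-chain C-alpha distance under which a pair
#'   counts as a steric clash.
#' @param minimize_tol,minimize_iter local-minimization stopping parameters.
#' @return A `docked_model` list: final `ca_a`, `ca_b`, `seed`, energy
#'   `trace`, `restraint` summary, `clash` report, per-chain native-contact
#'   fractions `q_a`, `q_b`, and `bond_max_rel_dev`.
#' @export
run_replica <- function(top_a, top_b, restraints, schedule, seed,
                        separation = 75, clash_threshold = 3.8,
                        minimize_tol = 1e-4, minimize_iter = 2000L) {
  set.seed(seed)
  init <- initialize_complex(top_a, top_b, separation = separation)
  coords <- rbind(init$ca_a, init$ca_b)
  topo <- merge_topology(top_a, top_b, restraints)
  ann <- cpp_anneal(coords, topo, schedule$dt, schedule$friction,
                    schedule$t_init, schedule$t_final, schedule$nsteps,
                    schedule$trace_stride)
  mn <- cpp_minimize_fire(ann$coords, topo, minimize_tol,
                          as.integer(minimize_iter))
  x <- mn$coords
  nA <- top_a$n
  ca_a <- x[seq_len(nA), , drop = FALSE]
  ca_b <- x[nA + seq_len(top_b$n), , drop = FALSE]
  res <- restraint_energy(restraints, ca_a, ca_b)
  bl_a <- sqrt(rowSums((ca_a[-1, , drop = FALSE] -
                          ca_a[-nA, , drop = FALSE])^2))
  bl_b <- sqrt(rowSums((ca_b[-1, , drop = FALSE] -
                          ca_b[-top_b$n, , drop = FALSE])^2))
  bond_dev <- max(abs(c(bl_a / top_a$b0, bl_b / top_b$b0) - 1))
  model <- structure(
    list(ca_a = ca_a, ca_b = ca_b, seed = seed,
         res_id_a = top_a$res_id, res_id_b = top_b$res_id,
         sites_a = top_a$ligand_site_residues,
         sites_b = top_b$ligand_site_residues,
         trace = ann$trace, energy = mn$energy,
         restraint = res, violation_energy = res$total,
         q_a = native_contact_fraction(top_a, ca_a),
         q_b = native_contact_fraction(top_b, ca_b),
         bond_max_rel_dev = bond_dev),
    class = "docked_model")
  model$clash <- count_clashes(model, clash_threshold)
  model
}

#' Run a replica ensemble
#'
#' Replicas use consecutive seeds `base_seed .. base_seed + n_replicas - 1`.
#' A replica that fails numerically is recorded and skipped; the ensemble
#' errors only when every replica failed.
#'
#' @inheritParams run_replica
#' @param n_replicas number of independent replicas.
#' @param base_seed seed of the first replica.
#' @return A `docked_ensemble` list of `docked_model`s, with failed replica
#'   messages in `attr(, "failures")`.
#' @export
run_ensemble <- function(top_a, top_b, restraints, schedule,
                         n_replicas = 10L, base_seed = 1L, ...) {
  stopifnot(n_replicas >= 1L)
  models <- list()
  failures <- character(0)
  for (r in seq_len(n_replicas)) {
    seed <- base_seed + r - 1L
    m <- tryCatch(run_replica(top_a, top_b, restraints, schedule,
                              seed = seed, ...),
                  error = function(e) e)
    if (inherits(m, "error")) {
      failures <- c(failures,
                    sprintf("seed %d: %s", seed, conditionMessage(m)))
    } else {
      models[[length(models) + 1L]] <- m
    }
  }
  if (length(models) == 0L)
    stop("all replicas failed:\n", paste(failures, collapse = "\n"))
  structure(models, class = "docked_ensemble", failures = failures)
}

#' Count inter-chain steric clashes
#'
#' @param model a `docked_model` (or any list with `ca_a`, `ca_b`).
#' @param clash_threshold distance (Angstrom) under which an inter-chain
#'   C-alpha pair counts as a clash.
#' @return A `clash_report`: list with `count` and `pairs` (two-column index
#'   matrix).
#' @export
count_clashes <- function(model, clash_threshold = 3.8) {
  stopifnot(clash_threshold > 0)
  d <- cross_dist(model$ca_a, model$ca_b)
  hits <- which(d < clash_threshold, arr.ind = TRUE)
  structure(list(count = nrow(hits), pairs = hits,
                 threshold = clash_threshold),
            class = "clash_report")
}

#' Select the model with fewest steric clashes
#'
#' Ties are broken by lower total restraint-violation energy, then by lower
#' replica seed.
#'
#' @param models a `docked_ensemble` or list of `docked_model`s.
#' @return The selected `docked_model`.
#' @export
select_model <- function(models) {
  if (length(models) == 0L) stop("cannot select from an empty ensemble")
  clashes <- vapply(models, function(m) m$clash$count, numeric(1))
  viol <- vapply(models, function(m) m$violation_energy, numeric(1))
  seeds <- vapply(models, function(m) m$seed, numeric(1))
  models[[order(clashes, viol, seeds)[1L]]]
}
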