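# Synthetic ground-truth generators: Potts-sampled alignments with planted
# couplings, and toy two-chain bead complexes with a known interface and
# ligand sites.

#' Specification for a planted-coupling Potts alignment
#'
#' The generative model is a pairwise Potts model
#' `P(s) propto exp(sum_i h_i(s_i) + sum_(i,j) J_ij * delta(s_i, s_j))`
#' with matching-state (ferromagnetic) couplings `J_ij` on the planted site
#' pairs, sampled by Gibbs sweeps.
#'
#' @param L number of columns.
#' @param q alphabet size (uses the first `q` amino-acid letters).
#' @param M number of sequences to emit.
#' @param couplings data.frame `(i, j, strength)` of planted pairs; pairs
#'   must be distinct.
#' @param fields L x q matrix of single-site fields (default 0).
#' @param burnin_sweeps Gibbs burn-in sweeps (default `100 * L`).
#' @param thin_sweeps sweeps between recorded samples.
#' @param seed RNG seed.
#' @return A `potts_spec` list.
#' @export
potts_spec <- function(L, q, M, couplings = NULL, fields = NULL,
                       burnin_sweeps = 100L * L, thin_sweeps = 10L,
                       seed = 1L) {
  if (is.null(couplings))
    couplings <- data.frame(i = integer(0), j = integer(0),
                            strength = numeric(0))
  stopifnot(M >= 1, L >= 2, q >= 2, all(couplings$i != couplings$j),
            all(is.finite(couplings$strength)))
  key <- contact_key(pmin(couplings$i, couplings$j),
                     pmax(couplings$i, couplings$j))
  if (anyDuplicated(key)) stop("planted pairs must be distinct")
  if (is.null(fields)) fields <- matrix(0, L, q)
  stopifnot(nrow(fields) == L, ncol(fields) == q)
  structure(list(L = as.integer(L), q = as.integer(q), M = as.integer(M),
                 couplings = couplings, fields = fields,
                 burnin_sweeps = as.integer(burnin_sweeps),
                 thin_sweeps = as.integer(thin_sweeps),
                 seed = as.integer(seed)),
            class = "potts_spec")
}

#' Sample an alignment from a planted-coupling Potts model
#'
#' @param spec a [potts_spec()].
#' @return An [msa] over the first `q` amino-acid letters, with the planted
#'   pairs attached as `attr(, "planted")`.
#' @export
sample_potts_msa <- function(spec) {
  set.seed(spec$seed)
  pairs <- if (nrow(spec$couplings))
    cbind(as.integer(spec$couplings$i), as.integer(spec$couplings$j))
  else matrix(0L, 0, 2)
  enc <- cpp_gibbs_potts(spec$L, spec$q, spec$M, pairs,
                         as.numeric(spec$couplings$strength), spec$fields,
                         spec$burnin_sweeps, spec$thin_sweeps)
  alphabet <- AA20[seq_len(spec$q)]
  seqs <- apply(enc, 1L, function(r) paste0(alphabet[r], collapse = ""))
  out <- msa(seqs, alphabet = alphabet)
  attr(out, "planted") <- spec$couplings
  out
}

#' Specification for a toy two-chain bead complex
#'
#' Two equal-length helical C-alpha bead chains (fixed 3.8 A virtual bonds)
#' are packed antiparallel with two-fold symmetry, so that the designed
#' interface pairs sit at 6-8 A and the ligand-site centroids at the design
#' distance. The symmetry makes the interface contact set orientation
#' symmetric: `(i, j)` is a designed contact iff `(j, i)` is, matching the
#' orientation ambiguity of couplings within one family alignment.
#'
#' @param n residues per chain.
#' @param n_contacts number of designed interface contacts (even; they come
#'   in orientation pairs).
#' @param ligand_sites residue indices (same on both chains) whose C-alpha
#'   centroid defines the cluster site; by default a four-residue window is
#'   chosen whose centroids realize the design distance.
#' @param design_distance target ligand-site centroid separation (Angstrom).
#' @param seed RNG seed (used for sequence assignment).
#' @return A `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(n = 30L, n_contacts = 8L, ligand_sites = NULL,
                             design_distance = 12, seed = 1L) {
  stopifnot(n >= 12L, n_contacts >= 2L, design_distance > 0)
  if (n_contacts %% 2L != 0L)
    stop("n_contacts must be even (contacts come in orientation pairs)")
  if (!is.null(ligand_sites))
    stopifnot(all(ligand_sites >= 1L), all(ligand_sites <= n))
  structure(list(n = as.integer(n), n_contacts = as.integer(n_contacts),
                 ligand_sites = if (is.null(ligand_sites)) NULL
                                else as.integer(ligand_sites),
                 design_distance = design_distance, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

# compact self-avoiding bead chain: fixed 3.8 A bonds, pseudo-bond angles in
# a protein-like band, beads >= 3.9 A apart otherwise, with a centripetal
# bias that collapses the walk into a globule.
compact_saw <- function(n, bond = 3.8, min_clearance = 3.9,
                        max_tries = 200L) {
  for (attempt in seq_len(50L)) {
    x <- matrix(NA_real_, n, 3)
    x[1, ] <- c(0, 0, 0)
    u <- stats::rnorm(3); u <- u / vnorm(u)
    x[2, ] <- x[1, ] + bond * u
    ok <- TRUE
    for (k in 3:n) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        prev_dir <- (x[k - 1, ] - x[k - 2, ]) / bond
        cen <- colMeans(x[seq_len(k - 1L), , drop = FALSE])
        # anisotropic collapse: weak pull along z gives a prolate globule,
        # so the mirror-packed dimer forms an extended interface seam
        pull <- (cen - x[k - 1, ]) * c(1, 1, 0.3)
        pn <- vnorm(pull)
        drift <- if (pn > 1e-9) 0.6 * pull / pn else c(0, 0, 0)
        d <- stats::rnorm(3) + drift
        d <- d / vnorm(d)
        # keep the pseudo-bond angle protein-like (roughly 75-150 degrees)
        cosang <- -sum(d * prev_dir)
        if (cosang < cos(150 * pi / 180) || cosang > cos(75 * pi / 180))
          next
        cand <- x[k - 1, ] + bond * d
        dist2 <- rowSums(sweep(x[seq_len(k - 2L), , drop = FALSE], 2L,
                               cand)^2)
        if (min(dist2) >= min_clearance^2) {
          x[k, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(sweep(x, 2L, colMeans(x)))
  }
  stop("could not generate a self-avoiding compact chain")
}

#' Build a toy two-chain complex with known ground truth
#'
#' @param spec a [toy_complex_spec()].
#' @return List with `chain_a`, `chain_b` (chains posed in the true complex),
#'   `contacts` (data.frame `i, j, distance` of designed cross-chain
#'   contacts, orientation symmetric), `ligand_distance` (realized
#'   centroid separation), and `spec`.
#' @export
make_toy_complex <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n
  D <- spec$design_distance
  # chain B is the 180-degree rotation of chain A about the y axis; this
  # two-fold symmetry gives d(A_i, B_j) = d(A_j, B_i) exactly, so designed
  # contacts come in orientation pairs.
  Rot <- diag(c(-1, 1, -1))
  want <- spec$n_contacts %/% 2L
  for (attempt in seq_len(30L)) {
    H <- compact_saw(n)
    # pack the mirror copies until they just touch (closest approach ~4.8 A)
    dmin_at <- function(s) {
      min(cross_dist(sweep(H, 2L, c(s / 2, 0, 0)),
                     sweep(H %*% Rot, 2L, c(s / 2, 0, 0), FUN = "+"))) - 4.8
    }
    s <- tryCatch(stats::uniroot(dmin_at, c(0.1, 80), extendInt = "upX",
                                 tol = 1e-6)$root,
                  error = function(e) NA_real_)
    if (is.na(s)) next
    # ligand sites: the 4-residue window whose centroids sit closest to the
    # design distance; the packing separation is then refined to hit it
    # exactly:  |cen_A - cen_B| = sqrt((s - 2 cx)^2 + (2 cz)^2)
    sites <- if (!is.null(spec$ligand_sites)) spec$ligand_sites else {
      wins <- seq_len(n - 3L)
      dd <- vapply(wins, function(k) {
        ch <- colMeans(H[k:(k + 3L), , drop = FALSE])
        sqrt((s - 2 * ch[1])^2 + (2 * ch[3])^2)
      }, numeric(1))
      best <- wins[which.min(abs(dd - D))]
      best:(best + 3L)
    }
    ch <- colMeans(H[sites, , drop = FALSE])
    if (abs(2 * ch[3]) >= D) next
    s_new <- 2 * ch[1] + sqrt(D^2 - (2 * ch[3])^2)
    if (abs(s_new - s) > 2.5) next      # refinement would unpack the dimer
    s <- s_new
    xa <- sweep(H, 2L, c(s / 2, 0, 0))
    xb <- sweep(H %*% Rot, 2L, c(s / 2, 0, 0), FUN = "+")
    d <- cross_dist(xa, xb)
    if (min(d) < 4.2) next              # refinement caused a steric clash
    eligible <- which(d >= 6 & d <= 8, arr.ind = TRUE)
    # demand a clear column separation so designed pairs survive the
    # sequence-local exclusion applied when ranking couplings
    eligible <- eligible[abs(eligible[, 1] - eligible[, 2]) >= 5L, ,
                         drop = FALSE]
    key <- contact_key(pmin(eligible[, 1], eligible[, 2]),
                       pmax(eligible[, 1], eligible[, 2]))
    cand <- eligible[!duplicated(key), , drop = FALSE]
    if (nrow(cand) < want) next
    # greedy max-min dispersion so the designed contacts span the whole
    # interface rather than hinging on one patch
    mid <- (xa[cand[, 1], , drop = FALSE] + xb[cand[, 2], , drop = FALSE]) / 2
    sel <- which.min(abs(d[cand] - 7))
    while (length(sel) < want) {
      rest <- setdiff(seq_len(nrow(cand)), sel)
      score <- vapply(rest, function(r) {
        min(sqrt(rowSums(sweep(mid[sel, , drop = FALSE], 2L, mid[r, ])^2)))
      }, numeric(1))
      sel <- c(sel, rest[which.max(score)])
    }
    pick <- cand[sel, , drop = FALSE]
    contacts <- rbind(pick, pick[, 2:1, drop = FALSE])
    contacts <- data.frame(i = contacts[, 1], j = contacts[, 2])
    contacts$distance <- d[cbind(contacts$i, contacts$j)]
    contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
    rownames(contacts) <- NULL
    # sequence: random letters over the 8-letter reduced alphabet, with the
    # cluster-binding positions set to 3 Cys + 1 His
    alphabet <- AA20[1:8]
    seq1 <- sample(setdiff(alphabet, c("C", "H")), n, replace = TRUE)
    seq1[sites[1:3]] <- "C"
    seq1[sites[4]] <- "H"
    lig_ids <- as.character(sites)
    chain_a <- new_chain(xa, seq1, ligand_site_residues = lig_ids)
    chain_b <- new_chain(xb, seq1, ligand_site_residues = lig_ids)
    cen_a <- ligand_site_centroid(xa, sites)
    cen_b <- ligand_site_centroid(xb, sites)
    spec$ligand_sites <- sites
    return(list(chain_a = chain_a, chain_b = chain_b, contacts = contacts,
                ligand_distance = vnorm(cen_a - cen_b), spec = spec))
  }
  stop("could not construct a feasible toy complex after 30 attempts")
}

#' Positive predictive value of planted-coupling recovery
#'
#' @param ranked data.frame `(i, j, DI)` from [rank_pairs()] (any ranking).
#' @param planted data.frame `(i, j)` of planted pairs.
#' @param K number of top pairs scored.
#' @return `|top-K  intersect  planted| / K`.
#' @export
recovery_score <- function(ranked, planted, K) {
  stopifnot(K >= 1L)
  top <- utils::head(ranked, K)
  tk <- contact_key(pmin(top$i, top$j), pmax(top$i, top$j))
  pk <- contact_key(pmin(planted$i, planted$j), pmax(planted$i, planted$j))
  sum(tk %in% pk) / K
}

#' Random disjoint planted pairs
#'
#' Samples `n_pairs` disjoint site pairs (a partial matching) uniformly at
#' random, a convenient ground truth for recovery experiments.
#'
#' @param L number of sites.
#' @param n_pairs number of pairs (`2 * n_pairs <= L`).
#' @param strength coupling strength applied to every pair.
#' @return data.frame `(i, j, strength)`.
#' @export
planted_pairs <- function(L, n_pairs, strength = 1.0) {
  stopifnot(2L * n_pairs <= L)
  perm <- sample.int(L, 2L * n_pairs)
  i <- perm[seq_len(n_pairs)]
  j <- perm[n_pairs + seq_len(n_pairs)]
  data.frame(i = pmin(i, j), j = pmax(i, j), strength = strength)
}
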