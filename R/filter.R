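# Exclusion filtering of coupled pairs: monomer-fold contacts, solvent
# burial, and known homodimer-interface contacts.

#' Construct a contact map from residue-identifier pairs
#'
#' @param pairs_i,pairs_j residue identifiers of the contacting pairs
#'   (unordered; stored symmetrically).
#' @param kind `"intrachain"` or `"homodimer-interchain"`.
#' @param cutoff distance cutoff the map was built with (Angstrom).
#' @param atom_mode atom mode used (`"heavy"`, `"cb"` or `"ca"`).
#' @return A `contact_map` data.frame with columns `i`, `j`.
#' @export
contact_map <- function(pairs_i = character(0), pairs_j = character(0),
                        kind = "intrachain", cutoff = NA_real_,
                        atom_mode = NA_character_) {
  stopifnot(length(pairs_i) == length(pairs_j))
  df <- data.frame(i = as.character(pairs_i), j = as.character(pairs_j),
                   stringsAsFactors = FALSE)
  # fold unordered duplicates
  key <- ifelse(df$i <= df$j, paste(df$i, df$j, sep = "\r"),
                paste(df$j, df$i, sep = "\r"))
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("contact_map", "data.frame"),
            kind = kind, cutoff = cutoff, atom_mode = atom_mode)
}

contact_key <- function(i, j) {
  ifelse(i <= j, paste(i, j, sep = "\r"), paste(j, i, sep = "\r"))
}

#' Test contact-map membership
#'
#' @param map a `contact_map`.
#' @param i,j residue identifiers (vectors of equal length).
#' @return Logical vector: is the unordered pair in the map?
#' @export
contact_map_has <- function(map, i, j) {
  if (is.null(map) || nrow(map) == 0L) return(rep(FALSE, length(i)))
  contact_key(as.character(i), as.character(j)) %in%
    contact_key(map$i, map$j)
}

# minimum inter-residue distance matrix for a chain under an atom mode
residue_min_dist <- function(chain, atom_mode) {
  if (atom_mode == "ca") {
    xyz <- chain$ca
    ridx <- seq_len(chain$n)
  } else {
    at <- chain$atoms
    if (atom_mode == "cb") {
      keep <- at$elety == "CB" | (at$elety == "CA" &
                                    !(at$res_idx %in% at$res_idx[at$elety == "CB"]))
      at <- at[keep, , drop = FALSE]
    } else {
      at <- at[at$element != "H", , drop = FALSE]
    }
    xyz <- cbind(at$x, at$y, at$z)
    ridx <- at$res_idx
  }
  d <- as.matrix(stats::dist(xyz))
  n <- chain$n
  out <- matrix(Inf, n, n)
  for (r in seq_len(n)) {
    rows <- which(ridx == r)
    if (length(rows) == 0L) next
    block <- d[rows, , drop = FALSE]
    colmin <- apply(block, 2L, min)
    mins <- tapply(colmin, ridx, min)
    out[r, as.integer(names(mins))] <- mins
  }
  diag(out) <- 0
  pmin(out, t(out))
}

has_heavy_atoms <- function(chain) {
  any(chain$atoms$elety != "CA")
}

#' Intrachain contact map of a monomer
#'
#' A residue pair is a contact when its inter-residue distance under the
#' chosen atom mode is at most `cutoff` and the sequence separation is at
#' least `min_sequence_separation`. When heavy-atom or C-beta mode is
#' requested but the chain has only C-alpha coordinates, the computation
#' falls back to C-alpha mode with a warning.
#'
#' @param chain a `chain`.
#' @param cutoff distance cutoff (Angstrom).
#' @param atom_mode `"heavy"` (minimum over non-hydrogen atoms), `"cb"`, or
#'   `"ca"`.
#' @param min_sequence_separation minimum `|i - j|` along the chain.
#' @return A `contact_map` (kind `"intrachain"`).
#' @export
compute_contact_map <- function(chain, cutoff = 5, atom_mode = "heavy",
                                min_sequence_separation = 5L) {
  stopifnot(cutoff > 0)
  atom_mode <- match.arg(atom_mode, c("heavy", "cb", "ca"))
  if (atom_mode != "ca" && !has_heavy_atoms(chain)) {
    warning("chain has only C-alpha atoms; falling back to atom_mode = 'ca'")
    atom_mode <- "ca"
  }
  dmin <- residue_min_dist(chain, atom_mode)
  idx <- which(upper.tri(dmin), arr.ind = TRUE)
  sep_ok <- (idx[, 2] - idx[, 1]) >= min_sequence_separation
  hit <- dmin[idx] <= cutoff & sep_ok
  contact_map(chain$res_id[idx[hit, 1]], chain$res_id[idx[hit, 2]],
              kind = "intrachain", cutoff = cutoff, atom_mode = atom_mode)
}

#' Cross-chain contacts of a homodimer assembly
#'
#' Takes the two protomers of a crystal homodimer and returns the cross-chain
#' residue pairs within `cutoff`, folded onto single-protomer residue
#' identifiers (unordered).
#'
#' @param protomer1,protomer2 two `chain` objects with identical sequence.
#' @param cutoff distance cutoff (Angstrom).
#' @param atom_mode as in [compute_contact_map()].
#' @return A `contact_map` (kind `"homodimer-interchain"`).
#' @export
homodimer_contacts <- function(protomer1, protomer2, cutoff = 5,
                               atom_mode = "heavy") {
  stopifnot(cutoff > 0)
  if (protomer1$sequence != protomer2$sequence)
    stop("homodimer assembly error: protomer sequences differ")
  atom_mode <- match.arg(atom_mode, c("heavy", "cb", "ca"))
  if (atom_mode != "ca" &&
      (!has_heavy_atoms(protomer1) || !has_heavy_atoms(protomer2))) {
    warning("protomers have only C-alpha atoms; falling back to 'ca'")
    atom_mode <- "ca"
  }
  get_atoms <- function(chain) {
    if (atom_mode == "ca")
      return(list(xyz = chain$ca, ridx = seq_len(chain$n)))
    at <- chain$atoms[chain$atoms$element != "H", , drop = FALSE]
    list(xyz = cbind(at$x, at$y, at$z), ridx = at$res_idx)
  }
  a1 <- get_atoms(protomer1); a2 <- get_atoms(protomer2)
  ii <- integer(0); jj <- integer(0)
  for (r in seq_len(protomer1$n)) {
    rows <- which(a1$ridx == r)
    if (!length(rows)) next
    d2 <- outer(rowSums(a1$xyz[rows, , drop = FALSE]^2),
                rowSums(a2$xyz^2), "+") -
      2 * a1$xyz[rows, , drop = FALSE] %*% t(a2$xyz)
    hit_res <- unique(a2$ridx[which(apply(d2, 2L, min) <= cutoff^2 + 1e-12)])
    ii <- c(ii, rep(r, length(hit_res))); jj <- c(jj, hit_res)
  }
  contact_map(protomer1$res_id[ii], protomer1$res_id[jj],
              kind = "homodimer-interchain", cutoff = cutoff,
              atom_mode = atom_mode)
}

# van der Waals radii by element (Angstrom)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               SE = 1.90)

# Theoretical maximum SASA per residue type in a Gly-X-Gly tripeptide
# (Tien et al. 2013), A^2.
MAX_SASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
              G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
              P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA over all non-hydrogen atoms; per-atom areas are
#' summed per residue, and relative SASA divides by the residue type's
#' theoretical Gly-X-Gly maximum.
#'
#' @param chain a `chain` with all-atom coordinates.
#' @param probe_radius solvent probe radius (Angstrom).
#' @param n_sphere_points number of test points per atom.
#' @return A `sasa_profile` data.frame: `res_id`, `res_name`, `sasa_abs`
#'   (A^2), `sasa_rel`.
#' @export
compute_sasa <- function(chain, probe_radius = 1.4, n_sphere_points = 240L) {
  at <- chain$atoms[chain$atoms$element != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms available for SASA computation")
  radii <- VDW_RADII[at$element]
  radii[is.na(radii)] <- 1.70
  area <- cpp_sasa(cbind(at$x, at$y, at$z), radii, probe_radius,
                   as.integer(n_sphere_points))
  abs_sasa <- vapply(seq_len(chain$n),
                     function(r) sum(area[at$res_idx == r]), numeric(1))
  mx <- MAX_SASA[chain$seq1]
  mx[is.na(mx)] <- mean(MAX_SASA)
  structure(data.frame(res_id = chain$res_id, res_name = chain$seq1,
                       sasa_abs = abs_sasa,
                       sasa_rel = abs_sasa / mx,
                       stringsAsFactors = FALSE),
            class = c("sasa_profile", "data.frame"),
            probe_radius = probe_radius, n_sphere_points = n_sphere_points)
}

sasa_rel_of <- function(sasa, res_id) {
  sasa$sasa_rel[match(res_id, sasa$res_id)]
}

#' Filter DI-ranked pairs against fold, burial and homodimer signals
#'
#' A ranked column pair `(i, j)` is excluded when (a) it maps onto an
#' intrachain contact of either monomer (the coupling is explained by the
#' monomeric fold), (b) it has no orientation in which both mapped residues
#' are solvent accessible, (c) it maps onto a homodimer-interface contact of
#' either protein, or (d) neither orientation has both columns mapped. Both
#' orientations of a surviving pair (column i on chain 1 / column j on chain
#' 2, and vice versa) are carried, since a coupling within one family
#' alignment does not identify which protomer contributes which residue.
#'
#' @param ranked data.frame `(i, j, DI)` from [rank_pairs()].
#' @param map1,map2 `column_map`s for chains 1 and 2.
#' @param monomer_maps list of up to two intrachain `contact_map`s
#'   (chain 1, chain 2); `NULL` entries disable the fold exclusion.
#' @param sasa list of up to two `sasa_profile`s; `NULL` disables burial
#'   exclusion.
#' @param homodimer_maps list of up to two homodimer `contact_map`s; `NULL`
#'   disables the homodimer exclusion.
#' @param K number of surviving pairs to keep (top of the DI ranking).
#' @param exposure_threshold relative SASA at or above which a residue counts
#'   as solvent accessible.
#' @return A `candidate_set` data.frame with one row per surviving
#'   orientation: `rank`, `col_i`, `col_j`, `DI`, `res_chain1`, `res_chain2`,
#'   `orientation` (`"AB"` or `"BA"`); the exclusion audit is in
#'   `attr(, "audit")`.
#' @export
filter_couplings <- function(ranked, map1, map2,
                             monomer_maps = list(NULL, NULL),
                             sasa = list(NULL, NULL),
                             homodimer_maps = list(NULL, NULL),
                             K = 20L, exposure_threshold = 0.05) {
  stopifnot(K >= 1L)
  n <- nrow(ranked)
  audit <- data.frame(col_i = ranked$i, col_j = ranked$j, DI = ranked$DI,
                      excluded = FALSE, reasons = "",
                      stringsAsFactors = FALSE)
  rows <- list()
  kept <- 0L
  exposed <- function(s, res) {
    if (is.null(s)) return(rep(TRUE, length(res)))
    ok <- sasa_rel_of(s, res) >= exposure_threshold
    ok & !is.na(ok)
  }
  for (r in seq_len(n)) {
    i <- ranked$i[r]; j <- ranked$j[r]; di <- ranked$DI[r]
    r1i <- mapped_residue(map1, i); r1j <- mapped_residue(map1, j)
    r2i <- mapped_residue(map2, i); r2j <- mapped_residue(map2, j)
    reasons <- character(0)
    ab_ok <- !is.na(r1i) && !is.na(r2j)   # col i on chain1, col j on chain2
    ba_ok <- !is.na(r1j) && !is.na(r2i)
    if (!ab_ok && !ba_ok) reasons <- c(reasons, "unmapped")
    # (a) monomeric fold
    if (!is.na(r1i) && !is.na(r1j) &&
        contact_map_has(monomer_maps[[1]], r1i, r1j))
      reasons <- c(reasons, "monomer_contact")
    if (!is.na(r2i) && !is.na(r2j) &&
        contact_map_has(monomer_maps[[2]], r2i, r2j))
      reasons <- c(reasons, "monomer_contact")
    # (b) burial: an orientation survives only if both residues are exposed
    ab_exp <- ab_ok && exposed(sasa[[1]], r1i) && exposed(sasa[[2]], r2j)
    ba_exp <- ba_ok && exposed(sasa[[1]], r1j) && exposed(sasa[[2]], r2i)
    if ((ab_ok || ba_ok) && !ab_exp && !ba_exp)
      reasons <- c(reasons, "buried")
    # (c) homodimer interface
    if (!is.na(r1i) && !is.na(r1j) &&
        contact_map_has(homodimer_maps[[1]], r1i, r1j))
      reasons <- c(reasons, "homodimer_contact")
    if (!is.na(r2i) && !is.na(r2j) &&
        contact_map_has(homodimer_maps[[2]], r2i, r2j))
      reasons <- c(reasons, "homodimer_contact")
    reasons <- unique(reasons)
    if (length(reasons)) {
      audit$excluded[r] <- TRUE
      audit$reasons[r] <- paste(reasons, collapse = ",")
      next
    }
    if (kept >= K) next
    kept <- kept + 1L
    if (ab_exp)
      rows[[length(rows) + 1L]] <-
        data.frame(rank = kept, col_i = i, col_j = j, DI = di,
                   res_chain1 = r1i, res_chain2 = r2j, orientation = "AB",
                   stringsAsFactors = FALSE)
    if (ba_exp)
      rows[[length(rows) + 1L]] <-
        data.frame(rank = kept, col_i = i, col_j = j, DI = di,
                   res_chain1 = r1j, res_chain2 = r2i, orientation = "BA",
                   stringsAsFactors = FALSE)
  }
  if (kept < K)
    warning("only ", kept, " pairs survived filtering (requested K = ", K, ")")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rank = integer(0), col_i = integer(0), col_j = integer(0),
               DI = numeric(0), res_chain1 = character(0),
               res_chain2 = character(0), orientation = character(0),
               stringsAsFactors = FALSE)
  structure(out, class = c("candidate_set", "data.frame"),
            audit = audit, K = K, exposure_threshold = exposure_threshold)
}

#' Exclusion audit of a candidate set
#'
#' @param candidates a `candidate_set`.
#' @return data.frame with one row per ranked pair and its exclusion reasons.
#' @export
filter_audit <- function(candidates) attr(candidates, "audit")

#' Write a candidate set (and audit) as TSV
#'
#' @param candidates a `candidate_set`.
#' @param path candidates output path.
#' @param audit_path optional audit output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path, audit_path = NULL) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(audit_path))
    utils::write.table(filter_audit(candidates), audit_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
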