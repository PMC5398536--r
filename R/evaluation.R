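# Quantitative evaluation of a docked complex: coupling-pair distance table,
# cluster-site geometry, restraint satisfaction, interface connectivity, and
# PDB serialization.

model_index <- function(res_id_vec, res_id) match(res_id, res_id_vec)

#' Centroid of a ligand site
#'
#' The metal-cluster site of a chain is represented by the centroid of the
#' C-alpha positions of its coordinating residues (3 Cys + 1 His for a
#' 2Fe-2S site).
#'
#' @param ca C-alpha coordinate matrix.
#' @param idx row indices of the coordinating residues.
#' @return Numeric length-3 centroid.
#' @export
ligand_site_centroid <- function(ca, idx) {
  stopifnot(length(idx) >= 1L, all(idx >= 1L), all(idx <= nrow(ca)))
  colMeans(ca[idx, , drop = FALSE])
}

#' Distance between the two cluster sites of a docked model
#'
#' @param model a `docked_model` (fields `ca_a`, `ca_b`, `res_id_a`,
#'   `res_id_b`, `sites_a`, `sites_b`).
#' @param sites_a,sites_b optional residue-identifier overrides for the
#'   coordinating residues.
#' @return Euclidean distance between the two site centroids (Angstrom).
#' @export
cluster_distance <- function(model, sites_a = NULL, sites_b = NULL) {
  sites_a <- sites_a %||chr% model$sites_a
  sites_b <- sites_b %||chr% model$sites_b
  ia <- model_index(model$res_id_a, sites_a)
  ib <- model_index(model$res_id_b, sites_b)
  if (any(is.na(ia)))
    stop("missing coordinating residue on chain A: ",
         paste(sites_a[is.na(ia)], collapse = ", "))
  if (any(is.na(ib)))
    stop("missing coordinating residue on chain B: ",
         paste(sites_b[is.na(ib)], collapse = ", "))
  vnorm(ligand_site_centroid(model$ca_a, ia) -
          ligand_site_centroid(model$ca_b, ib))
}

`%||chr%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Distance table for candidate coupling pairs
#'
#' One row per candidate orientation, in DI order: the residue on each chain
#' and the minimum inter-residue distance in the final model (C-alpha for
#' C-alpha models). Candidates referencing residues absent from the model are
#' flagged (`NA` distance), not dropped.
#'
#' @param model a `docked_model`.
#' @param candidates a `candidate_set`.
#' @return data.frame `rank, res_chain1, res_chain2, DI, distance`.
#' @export
pair_distance_table <- function(model, candidates) {
  ia <- model_index(model$res_id_a, candidates$res_chain1)
  ib <- model_index(model$res_id_b, candidates$res_chain2)
  d <- rep(NA_real_, nrow(candidates))
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok))
    d[ok] <- sqrt(rowSums((model$ca_a[ia[ok], , drop = FALSE] -
                             model$ca_b[ib[ok], , drop = FALSE])^2))
  data.frame(rank = candidates$rank,
             res_chain1 = candidates$res_chain1,
             res_chain2 = candidates$res_chain2,
             DI = candidates$DI, distance = d,
             stringsAsFactors = FALSE)
}

#' Evaluate a docked model
#'
#' Computes the cluster-site distance, the fraction of candidate pairs within
#' `within` Angstrom, the clash count, the restraint-satisfaction fraction
#' (distance at most the flat-bottom bound plus the restraint set's tolerance
#' band), and a single-interface score: the fraction of satisfied pairs lying
#' in the largest spatially connected component (two pairs are connected when
#' their chain-A residues are within `connect_radius`).
#'
#' @param model a `docked_model`.
#' @param candidates a `candidate_set`.
#' @param restraints the `restraint_set` used for docking.
#' @param within distance defining a "close" coupling pair (Angstrom).
#' @param connect_radius chain-A linkage radius for interface connectivity.
#' @return An `evaluation_report` list.
#' @export
evaluate_model <- function(model, candidates, restraints, within = 10,
                           connect_radius = 15) {
  tbl <- pair_distance_table(model, candidates)
  frac_within <- if (nrow(tbl) > 0L) mean(tbl$distance <= within, na.rm = TRUE)
                 else NA_real_
  res <- restraint_energy(restraints, model$ca_a, model$ca_b)
  tol <- restraints$tolerance %||chr% 2
  sat <- if (length(res$pair_distances) > 0L)
    res$pair_distances <= restraints$pairs$r_upper + tol else logical(0)
  sat_frac <- if (length(sat)) mean(sat) else NA_real_
  single_interface <- NA_real_
  sat_idx <- which(sat)
  if (length(sat_idx) > 0L) {
    ia <- restraints$pairs$ia[sat_idx]
    pos <- model$ca_a[ia, , drop = FALSE]
    dd <- as.matrix(stats::dist(pos))
    adj <- dd <= connect_radius
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)
    single_interface <- max(comp$csize) / length(sat_idx)
  }
  structure(list(
    cluster_distance = if (!is.null(restraints$cluster) ||
                           length(model$sites_a))
      tryCatch(cluster_distance(model), error = function(e) NA_real_)
      else NA_real_,
    fraction_within = frac_within,
    within = within,
    clash_count = model$clash$count,
    restraint_satisfaction = sat_frac,
    single_interface = single_interface,
    n_candidates = nrow(tbl)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("docked-model evaluation:\n",
                     "  cluster-site distance : %.2f A\n",
                     "  pairs within %4.1f A   : %.2f\n",
                     "  restraint satisfaction: %.2f\n",
                     "  steric clashes        : %d\n",
                     "  single-interface score: %.2f\n"),
              x$cluster_distance, x$within, x$fraction_within,
              x$restraint_satisfaction, x$clash_count, x$single_interface))
  invisible(x)
}

#' Interface RMSD of a docked model against a reference complex
#'
#' Superposes the model onto the reference using the chain-A C-alphas
#' (Kabsch fit via `bio3d::fit.xyz`) and reports the RMSD over the interface
#' residues (the residues appearing in `contacts`) of both chains.
#'
#' @param model a `docked_model`.
#' @param ref_ca_a,ref_ca_b reference (true complex) coordinates.
#' @param contacts data.frame of true interface contacts with columns `i`
#'   (chain A residue index) and `j` (chain B residue index).
#' @return Interface C-alpha RMSD (Angstrom).
#' @export
interface_rmsd <- function(model, ref_ca_a, ref_ca_b, contacts) {
  nA <- nrow(ref_ca_a)
  fixed <- c(t(rbind(ref_ca_a, ref_ca_b)))
  mobile <- c(t(rbind(model$ca_a, model$ca_b)))
  a_inds <- bio3d::atom2xyz(seq_len(nA))
  fitted <- bio3d::fit.xyz(fixed, mobile, fixed.inds = a_inds,
                           mobile.inds = a_inds)
  fit_mat <- matrix(fitted, ncol = 3, byrow = TRUE)
  idx <- unique(c(contacts$i, nA + contacts$j))
  ref <- rbind(ref_ca_a, ref_ca_b)
  sqrt(mean(rowSums((fit_mat[idx, , drop = FALSE] -
                       ref[idx, , drop = FALSE])^2)))
}

#' Write a docked model as a two-chain C-alpha PDB file
#'
#' Chains are written as `A` and `B` (CA atoms only); the two ligand-site
#' centroids are appended as HETATM pseudo-atoms (residue name `FES`).
#'
#' @param model a `docked_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_docked_pdb <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  fmt <- function(record, serial, name, resn, chain, resno, x, y, z) {
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            record, serial, name, resn, chain, resno, x, y, z, 1, 0)
  }
  write_chain <- function(ca, chain_id, res_id) {
    for (k in seq_len(nrow(ca))) {
      serial <<- serial + 1L
      resno <- suppressWarnings(as.integer(gsub("[^0-9-]", "", res_id[k])))
      if (is.na(resno)) resno <- k
      writeLines(fmt("ATOM", serial, "CA", "ALA", chain_id, resno,
                     ca[k, 1], ca[k, 2], ca[k, 3]), con)
    }
  }
  write_chain(model$ca_a, "A", model$res_id_a)
  writeLines("TER", con)
  write_chain(model$ca_b, "B", model$res_id_b)
  writeLines("TER", con)
  if (length(model$sites_a) && length(model$sites_b)) {
    ca <- ligand_site_centroid(model$ca_a,
                               model_index(model$res_id_a, model$sites_a))
    cb <- ligand_site_centroid(model$ca_b,
                               model_index(model$res_id_b, model$sites_b))
    serial <- serial + 1L
    writeLines(fmt("HETATM", serial, "FE", "FES", "A", 9001,
                   ca[1], ca[2], ca[3]), con)
    serial <- serial + 1L
    writeLines(fmt("HETATM", serial, "FE", "FES", "B", 9002,
                   cb[1], cb[2], cb[3]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read back a docked model written by [write_docked_pdb()]
#'
#' @param path PDB path.
#' @param sites_a,sites_b optional ligand-site residue identifiers to attach.
#' @return A `docked_model`-like list (coordinates and residue identifiers;
#'   no trajectory or energies).
#' @export
read_docked_pdb <- function(path, sites_a = character(0),
                            sites_b = character(0)) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM" & pdb$atom$elety == "CA", ,
                 drop = FALSE]
  a <- at[at$chain == "A", , drop = FALSE]
  b <- at[at$chain == "B", , drop = FALSE]
  model <- list(ca_a = cbind(a$x, a$y, a$z), ca_b = cbind(b$x, b$y, b$z),
                res_id_a = as.character(a$resno),
                res_id_b = as.character(b$resno),
                sites_a = as.character(sites_a),
                sites_b = as.character(sites_b))
  model$clash <- count_clashes(model)
  class(model) <- "docked_model"
  model
}
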