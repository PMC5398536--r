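# Chain container, PDB reading, and alignment-column -> residue mapping.

#' Construct a chain from coordinates
#'
#' Builds a `chain` object directly from C-alpha coordinates (used by the
#' synthetic toy-complex generator and by tests). All-atom chains are
#' normally produced by [read_structure()].
#'
#' @param ca n x 3 matrix of C-alpha coordinates (Angstrom).
#' @param sequence one-letter sequence (string or character vector, length n).
#' @param res_id residue identifiers (author numbering, optionally with
#'   insertion code); defaults to `1..n`.
#' @param atoms optional all-atom data.frame with columns
#'   `res_idx, elety, element, x, y, z` (one C-alpha per residue among them).
#' @param ligand_site_residues residue identifiers coordinating the metal
#'   cluster (e.g. the 3 Cys + 1 His of a 2Fe-2S site).
#' @return An object of class `chain`.
#' @export
new_chain <- function(ca, sequence, res_id = NULL, atoms = NULL,
                      ligand_site_residues = character(0)) {
  ca <- as.matrix(ca)
  stopifnot(ncol(ca) == 3L, all(is.finite(ca)))
  seq1 <- if (length(sequence) == 1L) strsplit(sequence, "")[[1L]] else sequence
  n <- nrow(ca)
  stopifnot(length(seq1) == n)
  if (is.null(res_id)) res_id <- as.character(seq_len(n))
  res_id <- as.character(res_id)
  stopifnot(!anyDuplicated(res_id))
  if (is.null(atoms)) {
    atoms <- data.frame(res_idx = seq_len(n), elety = "CA",
                        element = "C", x = ca[, 1], y = ca[, 2], z = ca[, 3],
                        stringsAsFactors = FALSE)
  }
  if (!all(ligand_site_residues %in% res_id))
    stop("ligand site residues not in chain: ",
         paste(setdiff(ligand_site_residues, res_id), collapse = ", "))
  structure(
    list(res_id = res_id, sequence = paste0(seq1, collapse = ""),
         seq1 = seq1, ca = unname(ca), atoms = atoms,
         ligand_site_residues = as.character(ligand_site_residues),
         n = n),
    class = "chain")
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("chain: %d residues (%d atoms)%s\n", x$n, nrow(x$atoms),
              if (length(x$ligand_site_residues))
                paste0(", ligand site: ",
                       paste(x$ligand_site_residues, collapse = "+"))
              else ""))
  invisible(x)
}

#' Designate the cluster-coordinating residues of a chain
#'
#' @param chain a `chain`.
#' @param residues residue identifiers of the cluster-binding residues.
#' @return The chain with `ligand_site_residues` set.
#' @export
set_ligand_sites <- function(chain, residues) {
  residues <- as.character(residues)
  missing <- setdiff(residues, chain$res_id)
  if (length(missing))
    stop("ligand site residues not in chain: ", paste(missing, collapse = ", "))
  chain$ligand_site_residues <- residues
  chain
}

#' Read one chain from a PDB file
#'
#' Keeps ATOM records of the requested chain, resolves alternate locations to
#' the highest-occupancy copy, and drops (with a warning) residues lacking a
#' C-alpha atom. Author residue numbering and insertion codes are preserved as
#' residue identifiers.
#'
#' @param path PDB file path.
#' @param chain_id single chain identifier.
#' @return A `chain` object.
#' @export
read_structure <- function(path, chain_id) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain_id, "' not found in ", path)
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  at$rid <- paste0(at$resno, at$ins)
  # altloc: keep highest-occupancy copy of each (residue, atom name)
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$rid, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$rid, at$elety)), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  rid_order <- unique(at$rid)
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$rid), , drop = FALSE]
  missing_ca <- setdiff(rid_order, ca$rid)
  if (length(missing_ca)) {
    warning("dropping ", length(missing_ca),
            " residue(s) without a C-alpha atom: ",
            paste(missing_ca, collapse = ", "))
    at <- at[!(at$rid %in% missing_ca), , drop = FALSE]
    rid_order <- setdiff(rid_order, missing_ca)
  }
  if (length(rid_order) < 3L)
    stop("malformed structure: fewer than 3 residues with C-alpha atoms in ",
         path, " chain ", chain_id)
  ca <- ca[match(rid_order, ca$rid), , drop = FALSE]
  seq1 <- bio3d::aa321(ca$resid)
  seq1[is.na(seq1) | seq1 == ""] <- "X"
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- substr(gsub("[0-9]", "", at$elety), 1L, 1L)
  }
  element <- ifelse(is.na(element) | element == "",
                    substr(gsub("[0-9]", "", at$elety), 1L, 1L), element)
  atoms <- data.frame(res_idx = match(at$rid, rid_order), elety = at$elety,
                      element = toupper(element),
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  ch <- new_chain(ca = cbind(ca$x, ca$y, ca$z), sequence = seq1,
                  res_id = rid_order, atoms = atoms)
  ch$resname <- ca$resid
  ch
}

#' Map alignment columns onto chain residues
#'
#' Globally aligns the match-column consensus of the family alignment against
#' the chain sequence (Needleman-Wunsch with BLOSUM62; chain termini outside
#' the domain are tolerated) and records, for each aligned match column, the
#' residue identifier it corresponds to. The mapping is rejected when the
#' aligned identity falls below `identity_floor`, which guards against silent
#' misregistration.
#'
#' @param msa an [msa].
#' @param chain a `chain`.
#' @param identity_floor minimum aligned sequence identity to accept.
#' @param gap_opening,gap_extension alignment gap penalties.
#' @return A `column_map`: data.frame with columns `column` (MSA column
#'   index), `res_id`, `res_name`, plus attributes `coverage` (fraction of
#'   match columns mapped) and `identity`.
#' @export
map_columns_to_chain <- function(msa, chain, identity_floor = 0.9,
                                 gap_opening = 10, gap_extension = 0.5) {
  if (chain$n < 3L) stop("chain too short to map (need >= 3 residues)")
  cons <- msa_consensus(msa)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  sub_mat <- get("BLOSUM62", envir = data_env)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(paste0(cons, collapse = "")),
    subject = Biostrings::AAString(chain$sequence),
    substitutionMatrix = sub_mat, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global-local")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  p_pos <- 0L
  s_pos <- Biostrings::start(Biostrings::subject(pa)) - 1L
  cols <- integer(0); res <- integer(0); n_match <- 0L; n_aln <- 0L
  for (k in seq_along(ap)) {
    pg <- ap[k] == "-"; sg <- as_[k] == "-"
    if (!pg) p_pos <- p_pos + 1L
    if (!sg) s_pos <- s_pos + 1L
    if (!pg && !sg) {
      n_aln <- n_aln + 1L
      if (ap[k] == as_[k]) n_match <- n_match + 1L
      cols <- c(cols, p_pos); res <- c(res, s_pos)
    }
  }
  identity <- if (n_aln > 0L) n_match / n_aln else 0
  if (identity < identity_floor)
    stop(sprintf(paste0("column mapping rejected: aligned identity %.2f ",
                        "below floor %.2f"), identity, identity_floor))
  map <- data.frame(column = msa$match_columns[cols],
                    res_id = chain$res_id[res],
                    res_name = chain$seq1[res],
                    stringsAsFactors = FALSE)
  map <- map[order(map$column), , drop = FALSE]
  rownames(map) <- NULL
  structure(map, class = c("column_map", "data.frame"),
            coverage = length(cols) / length(msa$match_columns),
            identity = identity)
}

# Majority-rule consensus (non-gap) of the match columns; all-gap columns
# become 'X' so they stay alignable but rarely match.
msa_consensus <- function(msa) {
  vapply(msa$match_columns, function(j) {
    col <- msa$mat[, j]
    if ("-" %in% msa$alphabet) col <- col[col != "-"]
    if (length(col) == 0L) return("X")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1L]
  }, character(1))
}

#' Look up mapped residues for alignment columns
#'
#' @param map a `column_map`.
#' @param columns MSA column indices.
#' @return Character vector of residue identifiers (`NA` where unmapped).
#' @export
mapped_residue <- function(map, columns) {
  map$res_id[match(columns, map$column)]
}

#' Write a column map as TSV
#'
#' @param map a `column_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_column_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
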