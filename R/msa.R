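# Multiple sequence alignment container and readers.

#' Construct an MSA object
#'
#' An `msa` holds equal-length aligned sequences over a finite alphabet
#' (by default the 20 amino acids plus gap). Characters outside the alphabet
#' are normalized to gap.
#'
#' @param sequences character vector of aligned sequences (equal length).
#' @param ids sequence identifiers; defaults to `seq_1 ... seq_M`.
#' @param alphabet state alphabet; last element should be the gap character
#'   when gaps are possible. Defaults to [msa_alphabet()].
#' @param match_columns optional integer vector of family match-state columns
#'   (1-based); defaults to all columns.
#' @return An object of class `msa` with fields `mat` (M x L character
#'   matrix), `ids`, `alphabet`, `match_columns`, and counts `M`, `L`, `q`.
#' @export
msa <- function(sequences, ids = NULL, alphabet = msa_alphabet(),
                match_columns = NULL) {
  if (length(sequences) < 1L) stop("empty alignment: no sequences")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    lab <- if (!is.null(ids)) ids[bad] else paste0("record ", bad)
    stop("ragged alignment: ", lab, " has length ", lens[bad],
         ", expected ", lens[1L])
  }
  if (lens[1L] < 2L) stop("alignment must have at least 2 columns")
  if (is.null(ids)) ids <- paste0("seq_", seq_along(sequences))
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  mat[mat == "."] <- "-"
  if ("-" %in% alphabet) {
    mat[!(mat %in% alphabet)] <- "-"
  } else if (!all(mat %in% alphabet)) {
    stop("sequence characters outside the gapless alphabet: ",
         paste(utils::head(setdiff(unique(as.vector(mat)), alphabet)),
               collapse = ", "))
  }
  if (is.null(match_columns)) match_columns <- seq_len(ncol(mat))
  structure(
    list(mat = mat, ids = ids, alphabet = alphabet,
         match_columns = as.integer(match_columns),
         M = nrow(mat), L = ncol(mat), q = length(alphabet)),
    class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (q = %d, %d match columns)\n",
              x$M, x$L, x$q, length(x$match_columns)))
  invisible(x)
}

#' Sequences of an MSA as strings
#' @param x an `msa`.
#' @return Named character vector of aligned sequences.
#' @export
msa_sequences <- function(x) {
  stats::setNames(apply(x$mat, 1L, paste0, collapse = ""), x$ids)
}

#' Integer encoding of an MSA
#'
#' @param x an `msa`.
#' @return M x L integer matrix with states in `1..q` following the order of
#'   `x$alphabet`.
#' @export
msa_encode <- function(x) {
  m <- matrix(match(x$mat, x$alphabet), nrow = x$M, ncol = x$L)
  storage.mode(m) <- "integer"
  m
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA or Stockholm alignments. Unknown or ambiguous residue letters
#' (e.g. B, Z, X, U, O) are normalized to gap; `.` is read as gap. For
#' Stockholm input with a `#=GC RF` reference line, match columns are the
#' positions marked with `x` or an uppercase letter.
#'
#' @param path file path.
#' @param format `"fasta"` or `"stockholm"`; default guesses from content.
#' @return An [msa] object.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("empty alignment file: ", path)
  if (format == "auto")
    format <- if (grepl("^# STOCKHOLM", lines[1L])) "stockholm" else "fasta"
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty alignment file: ", path)
    return(msa(as.character(set), ids = names(set)))
  }
  read_stockholm(lines, path)
}

# Stockholm parser (possibly interleaved blocks); no installed R package
# provides one.
read_stockholm <- function(lines, path) {
  seqs <- list()
  rf <- character(0)
  order <- character(0)
  for (ln in lines) {
    if (grepl("^#=GC\\s+RF\\s", ln)) {
      rf <- c(rf, sub("^#=GC\\s+RF\\s+", "", ln))
    } else if (grepl("^#", ln) || grepl("^//", ln) || !nzchar(trimws(ln))) {
      next
    } else {
      parts <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(parts) != 2L)
        stop("malformed Stockholm sequence line in ", path, ": ", ln)
      id <- parts[1L]
      if (is.null(seqs[[id]])) {
        seqs[[id]] <- parts[2L]
        order <- c(order, id)
      } else {
        seqs[[id]] <- paste0(seqs[[id]], parts[2L])
      }
    }
  }
  if (length(seqs) == 0L) stop("empty alignment file: ", path)
  sequences <- unlist(seqs[order], use.names = FALSE)
  match_columns <- NULL
  if (length(rf) > 0L) {
    rfs <- strsplit(paste0(rf, collapse = ""), "")[[1L]]
    match_columns <- which(rfs == "x" | grepl("[A-Z]", rfs))
  }
  msa(sequences, ids = order, match_columns = match_columns)
}

#' Write an MSA as FASTA
#'
#' @param x an `msa`.
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path, width = 60L) {
  seqs <- msa_sequences(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Filter alignment sequences by gap content
#'
#' Retains sequences whose gap fraction over the match columns is at most
#' `max_gap_fraction` (order preserved).
#'
#' @param x an `msa`.
#' @param max_gap_fraction maximum allowed gap fraction in `[0, 1]`.
#' @return A filtered [msa].
#' @export
filter_sequences <- function(x, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  sub <- x$mat[, x$match_columns, drop = FALSE]
  frac <- if ("-" %in% x$alphabet) rowMeans(sub == "-") else rep(0, x$M)
  keep <- frac <= max_gap_fraction + 1e-12
  if (!any(keep)) stop("no sequences left after gap filtering (threshold ",
                       max_gap_fraction, ")")
  msa(apply(x$mat[keep, , drop = FALSE], 1L, paste0, collapse = ""),
      ids = x$ids[keep], alphabet = x$alphabet,
      match_columns = x$match_columns)
}
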