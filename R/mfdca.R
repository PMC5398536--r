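# Mean-field direct coupling analysis: reweighting, pseudocounted
# frequencies, coupling inference by covariance inversion, and
# direct-information scoring.

#' Identity-based sequence weights
#'
#' Each sequence receives weight `1 / n_m`, where `n_m` is the number of
#' sequences (itself included) whose identity with sequence `m`, computed
#' over all columns, is at least `x`. The effective sequence number is
#' `Meff = sum(w)`.
#'
#' @param msa an [msa].
#' @param x identity threshold in (0, 1); 0.8 is the customary choice.
#' @return A `sequence_weights` list with fields `w`, `Meff`, `x`.
#' @export
compute_weights <- function(msa, x = 0.8) {
  stopifnot(x > 0, x < 1)
  if (msa$M == 0L) stop("empty alignment")
  w <- cpp_sequence_weights(msa_encode(msa), x)
  structure(list(w = w, Meff = sum(w), x = x), class = "sequence_weights")
}

#' Pseudocounted frequency model
#'
#' Weighted single- and pair-column frequencies with a uniform pseudocount:
#' `f_i(A) = (lambda/q + sum_m w_m I(A_i^m = A)) / (lambda + Meff)` and
#' analogously for pairs with `lambda/q^2`. Diagonal pair blocks satisfy
#' `f_ii(A, A) = f_i(A)`.
#'
#' @param msa an [msa].
#' @param weights a `sequence_weights` from [compute_weights()]; defaults to
#'   uniform unit weights.
#' @param lambda pseudocount; the canonical mean-field choice is
#'   `lambda = Meff` (the default).
#' @return A `frequency_model` with fields `fi` (L x q), `fij`
#'   (q x q x L x L array), `lambda`, `Meff`, `q`, `L`.
#' @export
compute_frequencies <- function(msa, weights = NULL, lambda = NULL) {
  if (is.null(weights))
    weights <- structure(list(w = rep(1, msa$M), Meff = msa$M, x = NA),
                         class = "sequence_weights")
  if (is.null(lambda)) lambda <- weights$Meff
  stopifnot(lambda >= 0)
  res <- cpp_frequencies(msa_encode(msa), weights$w, msa$q, lambda)
  fij <- res$fij
  dim(fij) <- c(msa$q, msa$q, msa$L, msa$L)
  structure(list(fi = res$fi, fij = fij, lambda = lambda,
                 Meff = res$Meff, q = msa$q, L = msa$L),
            class = "frequency_model")
}

#' Infer pairwise couplings by mean-field inversion
#'
#' Builds the covariance matrix `C_ij(A,B) = f_ij(A,B) - f_i(A) f_j(B)` over
#' the first `q - 1` states of every column and takes couplings as the
#' negative inverse, `e_ij(A,B) = -(C^-1)_ij(A,B)` (mean-field
#' approximation). A positive pseudocount guarantees invertibility.
#'
#' @param freq a `frequency_model`.
#' @return A `coupling_model` with the gauge-reduced coupling matrix
#'   (`L*(q-1)` square) plus dimensions.
#' @export
infer_couplings <- function(freq) {
  L <- freq$L; q <- freq$q; qr <- q - 1L
  C <- matrix(0, L * qr, L * qr)
  for (i in seq_len(L)) {
    ri <- (i - 1L) * qr + seq_len(qr)
    for (j in seq_len(L)) {
      rj <- (j - 1L) * qr + seq_len(qr)
      C[ri, rj] <- freq$fij[seq_len(qr), seq_len(qr), i, j] -
        tcrossprod(freq$fi[i, seq_len(qr)], freq$fi[j, seq_len(qr)])
    }
  }
  invC <- tryCatch(solve(C), error = function(e)
    stop("covariance matrix is numerically singular; ",
         "use a positive pseudocount (lambda > 0): ", conditionMessage(e)))
  structure(list(e = -invC, L = L, q = q), class = "coupling_model")
}

#' Extract the coupling block for a column pair
#'
#' Returns the q x q coupling matrix `e_ij(A,B)` embedded from the
#' gauge-reduced inversion (zeros in the final row/column).
#'
#' @param couplings a `coupling_model`.
#' @param i,j column indices.
#' @return q x q numeric matrix.
#' @export
coupling_matrix <- function(couplings, i, j) {
  qr <- couplings$q - 1L
  out <- matrix(0, couplings$q, couplings$q)
  out[seq_len(qr), seq_len(qr)] <-
    couplings$e[(i - 1L) * qr + seq_len(qr), (j - 1L) * qr + seq_len(qr)]
  out
}

#' Frobenius norms of couplings in the zero-sum gauge
#'
#' @param couplings a `coupling_model`.
#' @return L x L symmetric matrix of gauge-invariant coupling norms.
#' @export
coupling_norms <- function(couplings) {
  L <- couplings$L
  out <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in seq(i + 1L, L)) {
      K <- coupling_matrix(couplings, i, j)
      K <- K - outer(rowMeans(K), rep(1, couplings$q)) -
        outer(rep(1, couplings$q), colMeans(K)) + mean(K)
      out[i, j] <- out[j, i] <- sqrt(sum(K^2))
    }
  }
  out
}

#' Direct information of a column pair
#'
#' Builds the two-site direct distribution
#' `P_dir(A,B) = exp(e_ij(A,B)) * mu_i(A) * mu_j(B) / Z`, where the auxiliary
#' single-site factors are found by damped fixed-point iteration so that the
#' marginals of `P_dir` match the empirical `f_i` and `f_j`. The DI value is
#' the mutual information of `P_dir` against the product `f_i * f_j`.
#'
#' @param couplings a `coupling_model`.
#' @param freq the `frequency_model` the couplings were inferred from.
#' @param i,j distinct column indices.
#' @param tol fixed-point tolerance on the marginal mismatch.
#' @param max_iter maximum fixed-point iterations.
#' @param damping damping factor in `[0, 1)` for the update.
#' @return List with `P_dir` (q x q), `mu_i`, `mu_j`, and `DI`.
#' @export
direct_information <- function(couplings, freq, i, j, tol = 1e-6,
                               max_iter = 500L, damping = 0.5) {
  if (i == j) stop("direct information requires two distinct columns")
  W <- exp(coupling_matrix(couplings, i, j))
  fi <- freq$fi[i, ]
  fj <- freq$fi[j, ]
  q <- freq$q
  mu1 <- rep(1 / q, q); mu2 <- rep(1 / q, q)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    new1 <- fi / as.vector(W %*% mu2);  new1 <- new1 / sum(new1)
    new2 <- fj / as.vector(crossprod(W, mu1)); new2 <- new2 / sum(new2)
    delta <- max(abs(new1 - mu1), abs(new2 - mu2))
    mu1 <- damping * mu1 + (1 - damping) * new1
    mu2 <- damping * mu2 + (1 - damping) * new2
    if (delta < tol) { ok <- TRUE; break }
  }
  if (!ok)
    stop(sprintf(paste0("direct-information fixed point did not converge ",
                        "for pair (%d, %d); residual %.3g after %d ",
                        "iterations"), i, j, delta, max_iter))
  P <- W * tcrossprod(mu1, mu2)
  P <- P / sum(P)
  ref <- tcrossprod(fi, fj)
  DI <- sum(P * log(P / ref))
  list(P_dir = P, mu_i = mu1, mu_j = mu2, DI = DI)
}

#' Direct-information matrix over all column pairs
#'
#' @inheritParams direct_information
#' @return L x L symmetric matrix of DI values (zero diagonal).
#' @export
di_matrix <- function(couplings, freq, tol = 1e-6, max_iter = 500L,
                      damping = 0.5) {
  L <- freq$L
  di <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in seq(i + 1L, L)) {
      di[i, j] <- di[j, i] <-
        direct_information(couplings, freq, i, j, tol = tol,
                           max_iter = max_iter, damping = damping)$DI
    }
  }
  di
}

#' Rank column pairs by direct information
#'
#' @param di L x L DI matrix.
#' @param min_separation minimum `|i - j|`; near-diagonal pairs below it are
#'   dropped (standard practice for removing trivial sequence-local signal).
#' @return data.frame `(i, j, DI)` sorted by DI descending, ties broken by
#'   `(i, j)` ascending.
#' @export
rank_pairs <- function(di, min_separation = 5L) {
  stopifnot(min_separation >= 0)
  L <- nrow(di)
  idx <- which(upper.tri(di), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1]) >= min_separation
  idx <- idx[keep, , drop = FALSE]
  out <- data.frame(i = idx[, 1], j = idx[, 2], DI = di[idx])
  out <- out[order(-out$DI, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write ranked pairs (or any pair table) as TSV
#'
#' @param pairs data.frame of pairs.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
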