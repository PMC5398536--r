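# Shared fixtures and independent oracles for the test suite.

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# one correctly column-aligned PDB ATOM line
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = " ", record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name, alt, resn, chain, resno, x, y, z, occ, 0)
}

# 3-residue C-alpha-only chain
toy_pdb_3res <- function() {
  write_tmp_lines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "SER", "A", 3, 7.6, 0, 0),
    "TER", "END"), ext = ".pdb")
}

# independent direct-information oracle: iterative proportional fitting of
# exp(e_ij) to the empirical marginals, then mutual information; shares no
# code with the package's damped fixed point.
di_ipf_oracle <- function(al, i = 1, j = 2, x = 0.8, lambda = NULL,
                          tol = 1e-14) {
  w <- compute_weights(al, x)
  fr <- compute_frequencies(al, w, lambda = lambda)
  cp <- infer_couplings(fr)
  W <- exp(coupling_matrix(cp, i, j))
  fi <- fr$fi[i, ]; fj <- fr$fi[j, ]
  u <- rep(1, length(fi)); v <- rep(1, length(fj))
  for (it in 1:20000) {
    u_new <- fi / as.vector(W %*% v)
    v_new <- fj / as.vector(crossprod(W, u_new))
    if (max(abs(u_new - u), abs(v_new - v)) < tol) {
      u <- u_new; v <- v_new
      break
    }
    u <- u_new; v <- v_new
  }
  P <- W * outer(u, v)
  P <- P / sum(P)
  sum(P * log(P / outer(fi, fj)))
}

# enumerate all two-column alignments with M sequences over a q-letter
# alphabet, as joint count tables
enumerate_two_column_msas <- function(q, M, alphabet = c("A", "C", "D")[1:q]) {
  cells <- expand.grid(rep(list(0:M), q * q))
  cells <- cells[rowSums(cells) == M, , drop = FALSE]
  states <- expand.grid(a = 1:q, b = 1:q)
  lapply(seq_len(nrow(cells)), function(r) {
    counts <- as.integer(cells[r, ])
    seqs <- unlist(mapply(function(cnt, k)
      rep(paste0(alphabet[states$a[k]], alphabet[states$b[k]]), cnt),
      counts, seq_len(q * q)))
    msa(seqs, alphabet = alphabet)
  })
}

# candidate_set rows for the designed contacts of a toy complex
candidates_from_contacts <- function(contacts, di = 1) {
  structure(
    data.frame(rank = seq_len(nrow(contacts)),
               col_i = contacts$i, col_j = contacts$j, DI = di,
               res_chain1 = as.character(contacts$i),
               res_chain2 = as.character(contacts$j),
               orientation = "AB", stringsAsFactors = FALSE),
    class = c("candidate_set", "data.frame"))
}

# identity column map for toy chains whose residue ids are "1".."n"
identity_map <- function(n) {
  structure(data.frame(column = seq_len(n),
                       res_id = as.character(seq_len(n)),
                       res_name = "A", stringsAsFactors = FALSE),
            class = c("column_map", "data.frame"),
            coverage = 1, identity = 1)
}

# cached toy complex + topologies shared by the docking tests
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- make_toy_complex(toy_complex_spec(seed = 1))
      cache <<- list(
        toy = toy,
        top_a = build_sbm(toy$chain_a, contact_cutoff = 8),
        top_b = build_sbm(toy$chain_b, contact_cutoff = 8),
        cand = candidates_from_contacts(toy$contacts))
    }
    cache
  }
})
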