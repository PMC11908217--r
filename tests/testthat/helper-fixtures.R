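# Fixture builders and independent oracles shared across tests.

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z, elem,
                          het = FALSE, insert = "") {
  rec <- if (het) "HETATM" else "ATOM  "
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, " ", resn, chain, resno,
          if (insert == "") " " else insert, x, y, z, 1.00, 0.00, elem)
}

# residues: list of list(resno, resname, atoms = data.frame(name, x, y, z,
# elem), het = FALSE); writes a one-chain PDB fixture and returns its path
write_fixture_pdb <- function(residues, chain = "A",
                              path = tempfile(fileext = ".pdb")) {
  lines <- character(0)
  serial <- 0
  for (r in residues) {
    het <- isTRUE(r$het)
    for (i in seq_len(nrow(r$atoms))) {
      serial <- serial + 1
      a <- r$atoms[i, ]
      lines <- c(lines, pdb_atom_line(serial, a$name, r$resname, chain,
                                      r$resno, a$x, a$y, a$z, a$elem, het))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# minimal backbone placed at an offset; CA-only residues are enough for most
# structural fixtures
bb_atoms <- function(x0 = 0, y0 = 0) {
  data.frame(name = c("N", "CA", "C", "O"),
             x = x0 + c(-1.2, 0, 1.2, 1.8), y = y0 + c(0.8, 0, 0.8, 1.9),
             z = 0, elem = c("N", "C", "C", "O"),
             stringsAsFactors = FALSE)
}

# independent BFS all-pairs hop distances from an igraph graph
bfs_oracle_dists <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(i) {
    as.integer(igraph::neighbors(g, i))
  })
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in adj[[u]]) {
        if (!is.finite(D[s, v])) {
          D[s, v] <- D[s, u] + 1
          queue <- c(queue, v)
        }
      }
    }
  }
  D
}

# closeness centrality from first principles, using the BFS oracle
cc_oracle <- function(g) {
  n <- igraph::vcount(g)
  if (n <= 1) return(numeric(n))
  D <- bfs_oracle_dists(g)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    r <- sum(is.finite(d)) + 1
    if (r == 1) return(0)
    ((r - 1) / sum(d[is.finite(d)])) * ((r - 1) / (n - 1))
  }, numeric(1))
}

# independent rigid-body (Kabsch) superposition of one frame onto a reference
kabsch_oracle <- function(ref, mob) {
  cr <- colMeans(ref)
  cm <- colMeans(mob)
  H <- t(sweep(mob, 2, cm)) %*% sweep(ref, 2, cr)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(mob, 2, cm) %*% t(R), 2, cr, "+")
}
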