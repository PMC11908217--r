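test_that("entropy closed forms: conserved, uniform, and two-state columns", {
  # 20 sequences: col1 all A; col2 one of each amino acid; col3 half A half V
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  seqs <- vapply(1:20, function(i) {
    paste0("A", aas[i], if (i <= 10) "A" else "V")
  }, character(1))
  names(seqs) <- paste0("s", 1:20)
  msa <- alignment_block(seqs)
  p <- shannon_entropy(msa)
  expect_equal(p$entropy[1], 0)
  expect_equal(p$normalized[1], 0)
  expect_equal(p$normalized[2], 1)
  expect_equal(p$entropy[3], 1)                   # 1 bit
  expect_equal(p$normalized[3], 1 / log2(20), tolerance = 1e-12)
})

test_that("gap policy renormalizes and all-gap columns are missing", {
  msa <- alignment_block(c(a = "A-A-", b = "A-V-", c = "AAV-", d = "A-V-"))
  p <- shannon_entropy(msa)
  expect_equal(p$entropy[1], 0)
  # col2: gaps excluded -> single A observed -> entropy 0, low confidence
  expect_equal(p$entropy[2], 0)
  expect_true(p$low_confidence[2])
  # col3: A,V,V,V -> H = -(1/4 log 1/4 + 3/4 log 3/4)
  expect_equal(p$entropy[3], -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  expect_true(is.na(p$entropy[4]))
  expect_false(is.na(p$normalized[3]))
})

test_that("entropy is permutation-invariant over sequences and maximal only
           at uniformity", {
  set.seed(2)
  msa <- synth_msa(list(c(A = 0.5, V = 0.5), c(L = 0.9, I = 0.1)),
                   n_sequences = 50, seed = 2)
  p1 <- shannon_entropy(msa)
  perm <- msa[sample(nrow(msa)), , drop = FALSE]
  class(perm) <- class(msa)
  p2 <- shannon_entropy(perm)
  expect_equal(p1$entropy, p2$entropy)
  expect_lt(p1$normalized[2], 1)
})

test_that("synthetic MSA entropies converge to their specification", {
  unif <- setNames(rep(1 / 20, 20),
                   c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                     "K", "M", "F", "P", "S", "T", "W", "Y", "V"))
  msa <- synth_msa(list(unif, c(A = 0.5, V = 0.5), c(W = 1)),
                   n_sequences = 1e5, seed = 10)
  p <- shannon_entropy(msa)
  expect_equal(p$normalized[1], 1, tolerance = 0.01)
  expect_equal(p$entropy[2], 1, tolerance = 0.01)
  expect_equal(p$entropy[3], 0)
})

test_that("column profiles map onto structure residues through the query", {
  res <- lapply(1:4, function(i) {
    list(resno = i, resname = c("ALA", "GLY", "SER", "VAL")[i],
         atoms = bb_atoms(10 * i))
  })
  m <- load_structure(write_fixture_pdb(res))
  # gap-free query: identity mapping
  msa <- alignment_block(c(query = "AGSV", h1 = "AGTV", h2 = "AASV"))
  p <- shannon_entropy(msa)
  mp <- map_to_structure(p, msa, "query", m)
  expect_equal(mp$key, paste0("A:", 1:4))
  expect_equal(mp$column, 1:4)
  # query with internal gap columns: those columns unmapped, residues covered
  msa2 <- alignment_block(c(query = "AG--SV", h1 = "AGTTTV", h2 = "AAC-SV"))
  p2 <- shannon_entropy(msa2)
  mp2 <- map_to_structure(p2, msa2, "query", m)
  expect_equal(mp2$column, c(1, 2, 5, 6))
  expect_equal(nrow(mp2), 4)
  expect_error(map_to_structure(p, msa, "nope", m), "absent")
})

test_that("excessive unmappable residues raise a diagnostic error", {
  res <- lapply(1:10, function(i) {
    list(resno = i, resname = "ALA", atoms = bb_atoms(10 * i))
  })
  m <- load_structure(write_fixture_pdb(res))
  msa <- alignment_block(c(query = "AAAA", h1 = "AAAA"))  # 4 of 10 covered
  p <- shannon_entropy(msa)
  expect_error(map_to_structure(p, msa, "query", m), "unmappable")
})

test_that("identity and similarity behave on worked examples", {
  same <- pairwise_identity_similarity("ARNDC", "ARNDC")
  expect_equal(unname(same["identity"]), 100)
  expect_equal(unname(same["similarity"]), 100)
  v <- pairwise_identity_similarity("AAAA", "AAAV")
  expect_equal(unname(v["identity"]), 75)
  expect_gte(v["similarity"], v["identity"])  # A/V scores 0 in BLOSUM62
  expect_error(pairwise_identity_similarity("", "AAA"), "empty")
})

test_that("identity is symmetric and bounded by similarity", {
  set.seed(4)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:5) {
    a <- paste(sample(aas, 40, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 35, replace = TRUE), collapse = "")
    ab <- pairwise_identity_similarity(a, b)
    ba <- pairwise_identity_similarity(b, a)
    expect_equal(unname(ab["identity"]), unname(ba["identity"]))
    expect_lte(ab["identity"], ab["similarity"])
  }
})

test_that("UPGMA reproduces hand-computed topologies", {
  # d(A,B) < d(A,C) = d(B,C): A,B must be sisters
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_dendrogram(D)
  sisters <- ape::extract.clade(tr, ape::getMRCA(tr, c("A", "B")))$tip.label
  expect_setequal(sisters, c("A", "B"))

  # 4 taxa, hand agglomeration: (A,B) at 2 -> join C at mean(8,8)=8 ->
  # D joins last
  D4 <- matrix(c(0, 2, 8, 20,
                 2, 0, 8, 20,
                 8, 8, 0, 20,
                 20, 20, 20, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr4 <- build_dendrogram(D4)
  ab <- ape::extract.clade(tr4, ape::getMRCA(tr4, c("A", "B")))$tip.label
  expect_setequal(ab, c("A", "B"))
  abc <- ape::extract.clade(tr4, ape::getMRCA(tr4, c("A", "C")))$tip.label
  expect_setequal(abc, c("A", "B", "C"))
  expect_error(build_dendrogram(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("identical sequences form a zero-height cherry", {
  im <- identity_similarity_matrix(c(x = "ARNDCQ", y = "ARNDCQ",
                                     z = "WWWWWW"))
  D <- 100 - im$identity
  tr <- build_dendrogram(D)
  h <- ape::node.depth.edgelength(tr)
  xy <- ape::getMRCA(tr, c("x", "y"))
  # x and y coalesce at distance 0 from the tips
  expect_equal(max(h) - h[xy], 0, tolerance = 1e-9)
})

test_that("per-residue profiles spread onto a master alignment", {
  msa <- alignment_block(c(h1 = "AGSV", h2 = "AG-V", h3 = "AGSV"))
  out <- map_profiles_to_alignment(
    list(h1 = c(1, 2, 3, 4), h2 = c(9, 8, 7), h3 = c(5, 5, 5, 5)), msa)
  expect_equal(out["h1", ], c(1, 2, 3, 4))
  expect_equal(out["h2", ], c(9, 8, NA, 7))
  # terminal gap: trailing missing cells for the short homolog
  msa2 <- alignment_block(c(long = "AGSVLL", short = "AGSV--"))
  out2 <- map_profiles_to_alignment(
    list(long = 1:6, short = c(4, 3, 2, 1)), msa2)
  expect_true(all(is.na(out2["short", 5:6])))
  expect_error(map_profiles_to_alignment(list(h9 = 1:3), msa), "absent")
  expect_error(map_profiles_to_alignment(list(h1 = 1:3), msa),
               "non-gap")
})

test_that("alignments read back from FASTA files", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">query", "AG-SV", ">h1", "AGTSV"), p)
  msa <- read_alignment(p)
  expect_equal(nrow(msa), 2)
  expect_equal(paste(msa["query", ], collapse = ""), "AG-SV")
})
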