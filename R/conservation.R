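# Sequence conservation: per-column Shannon entropy of an MSA, mapping onto
# structure residues, pairwise identity/similarity, and a UPGMA dendrogram.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
.GAPS <- c("-", ".")

#' Construct an alignment block from aligned sequences
#'
#' @param seqs named character vector of equal-length aligned sequences over
#'   the 20 amino acids, gap characters (`-` or `.`) and `X`
#' @return an `AlignmentBlock`: character matrix, one row per sequence
#' @export
alignment_block <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1, !is.null(names(seqs)))
  n <- unique(nchar(seqs))
  if (length(n) != 1) stop("aligned sequences must all have equal length")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  bad <- setdiff(unique(as.vector(m)), c(.AA20, .GAPS, "X"))
  if (length(bad) > 0) {
    stop("alignment contains symbols outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "))
  }
  class(m) <- c("AlignmentBlock", class(m))
  m
}

#' Read a multiple sequence alignment from FASTA or Stockholm
#'
#' @param path alignment file
#' @param format `"fasta"` (default) or `"stockholm"`
#' @return an `AlignmentBlock`
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::unmasked(aln))
  alignment_block(seqs)
}

#' Per-column Shannon conservation entropy
#'
#' For each column, `H = -sum_a p_a log2 p_a` over the 20 amino acids, with
#' gaps excluded from the distribution (probabilities renormalized over
#' observed amino acids) under the default gap policy. Entropy is normalized
#' by `log2(20)` so the scale is fixed across alignments. Columns that are
#' entirely gaps get `NA` (undefined, not zero); columns with more than 50%
#' gaps are flagged low-confidence.
#'
#' @param msa an `AlignmentBlock` with at least 2 sequences
#' @param gap_policy `"exclude"` (default: drop gaps, renormalize) or
#'   `"as_missing"` (identical here; kept as an explicit name for the policy)
#' @return a `ConservationProfile` data.frame with columns `column`,
#'   `entropy` (bits), `normalized` in `[0, 1]`, `gap_fraction`,
#'   `low_confidence`
#' @export
shannon_entropy <- function(msa, gap_policy = c("exclude", "as_missing")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(msa, "AlignmentBlock"), nrow(msa) >= 2)
  ncolm <- ncol(msa)
  ent <- numeric(ncolm)
  gapf <- numeric(ncolm)
  for (j in seq_len(ncolm)) {
    col <- msa[, j]
    gapf[j] <- mean(col %in% c(.GAPS, "X"))
    aa <- col[col %in% .AA20]
    if (length(aa) == 0) {
      ent[j] <- NA_real_
      next
    }
    p <- table(aa) / length(aa)
    ent[j] <- -sum(p * log2(p))
  }
  out <- data.frame(
    column = seq_len(ncolm),
    entropy = ent,
    normalized = ent / log2(20),
    gap_fraction = gapf,
    low_confidence = gapf > 0.5
  )
  class(out) <- c("ConservationProfile", "data.frame")
  out
}

#' Map per-column conservation onto structure residues
#'
#' The MSA must contain the structure's own sequence as a designated query
#' row; its non-gap columns map 1:1, in order, onto the chain's polymer
#' residues.
#'
#' @param profile a `ConservationProfile` for `msa`
#' @param msa the `AlignmentBlock`
#' @param query row name of the structure's sequence in the MSA
#' @param model a `StructureModel`
#' @param chain chain identifier (default first polymer chain)
#' @param max_unmapped maximum tolerated fraction of residues without a
#'   column (default 0.05)
#' @return data.frame with columns `key`, `column`, `normalized`
#' @export
map_to_structure <- function(profile, msa, query, model, chain = NULL,
                             max_unmapped = 0.05) {
  stopifnot(inherits(msa, "AlignmentBlock"))
  if (!query %in% rownames(msa)) {
    stop("query row '", query, "' absent from alignment; rows: ",
         paste(head(rownames(msa), 5), collapse = ", "), " ...")
  }
  pol <- model$residues[model$residues$polymer, , drop = FALSE]
  if (is.null(chain)) chain <- pol$chain[1]
  res <- pol[pol$chain == chain, , drop = FALSE]
  qcols <- which(!(msa[query, ] %in% .GAPS))
  n_map <- min(length(qcols), nrow(res))
  unmapped <- nrow(res) - n_map
  if (unmapped / nrow(res) > max_unmapped) {
    stop(unmapped, " of ", nrow(res), " residues unmappable (> ",
         100 * max_unmapped, "%); query row has ", length(qcols),
         " non-gap columns. Query row: ",
         paste(msa[query, qcols[seq_len(min(60, length(qcols)))]],
               collapse = ""))
  }
  idx <- seq_len(n_map)
  data.frame(key = res$key[idx],
             column = qcols[idx],
             normalized = profile$normalized[qcols[idx]],
             stringsAsFactors = FALSE)
}

#' Pairwise sequence identity and similarity
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62 and affine gaps
#' (open 10, extend 0.5). Identity is the percentage of identical aligned
#' residue pairs among gap-free aligned positions; similarity additionally
#' counts pairs with a positive BLOSUM62 score.
#'
#' @param seq_a,seq_b amino-acid sequences (one-letter strings)
#' @param gap_opening,gap_extension affine gap penalties
#' @return named numeric vector `c(identity = , similarity = )` in percent
#' @export
pairwise_identity_similarity <- function(seq_a, seq_b, gap_opening = 10,
                                         gap_extension = 0.5) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("cannot align an empty sequence")
  }
  mat <- "BLOSUM62"
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = mat, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ok <- a != "-" & b != "-"
  a <- a[ok]; b <- b[ok]
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  B <- data_env$BLOSUM62
  ident <- mean(a == b) * 100
  simil <- mean(a == b | B[cbind(a, b)] > 0) * 100
  c(identity = ident, similarity = simil)
}

#' Full identity/similarity matrix for a set of sequences
#'
#' @param seqs named character vector of sequences
#' @param ... passed to [pairwise_identity_similarity()]
#' @return list with `identity` and `similarity` symmetric percent matrices
#'   (diagonal 100)
#' @export
identity_similarity_matrix <- function(seqs, ...) {
  n <- length(seqs)
  I <- S <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- pairwise_identity_similarity(seqs[[i]], seqs[[j]], ...)
      I[i, j] <- I[j, i] <- v["identity"]
      S[i, j] <- S[j, i] <- v["similarity"]
    }
  }
  list(identity = I, similarity = S)
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration; with distances taken as `100 - identity`
#' this reproduces the sequence dendrogram used for cross-enzyme comparison.
#'
#' @param D symmetric distance matrix with zero diagonal
#' @param newick_path optional path to write the tree in newick format
#' @return an `ape` `phylo` tree
#' @export
build_dendrogram <- function(D, newick_path = NULL) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(D)) > 1e-8)) stop("distance matrix must have zero diagonal")
  hc <- hclust(as.dist(D), method = "average")
  tree <- ape::as.phylo(hc)
  if (!is.null(newick_path)) ape::write.tree(tree, file = newick_path)
  tree
}

#' Place per-residue profiles of several homologs on a master alignment
#'
#' Each homolog's per-residue values are spread over the columns of the
#' master alignment according to its (gapped) row; gap columns get `NA`.
#' Used for cross-homolog heatmaps of sensitivity, centrality or entropy.
#'
#' @param profiles named list; each element a numeric vector of per-residue
#'   values in residue order for one homolog
#' @param msa master `AlignmentBlock` containing a row per homolog (matched
#'   by name)
#' @return numeric matrix, homologs x alignment columns, `NA` at gaps
#' @export
map_profiles_to_alignment <- function(profiles, msa) {
  stopifnot(inherits(msa, "AlignmentBlock"), is.list(profiles))
  out <- matrix(NA_real_, nrow = length(profiles), ncol = ncol(msa),
                dimnames = list(names(profiles), NULL))
  for (nm in names(profiles)) {
    if (!nm %in% rownames(msa)) {
      stop("homolog '", nm, "' absent from the master alignment")
    }
    cols <- which(!(msa[nm, ] %in% .GAPS))
    v <- profiles[[nm]]
    if (length(cols) != length(v)) {
      stop("homolog '", nm, "': ", length(v), " profile values but ",
           length(cols), " non-gap alignment columns")
    }
    out[nm, cols] <- v
  }
  out
}
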