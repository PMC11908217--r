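#' @importFrom stats sd cor prcomp kmeans dist as.dist hclust rnorm runif setNames lm coef
#' @importFrom utils write.csv read.csv head
NULL

# Standard amino acids recognised as polymer residues.
.STD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")

.WATER_RES <- c("HOH", "WAT", "DOD", "H2O", "SOL", "TIP3")

#' Residue identity key
#'
#' Residues are identified throughout the package by the author-assigned
#' `(chain, residue number, insertion code)` triple, rendered as
#' `"chain:number"` (with the insertion code appended when present), so that
#' all outputs align with the residue labels used in crystal structures.
#'
#' @param chain chain identifier(s)
#' @param resno author residue number(s)
#' @param insert insertion code(s); `""` or `NA` when absent
#' @return character vector of residue keys
#' @export
residue_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, insert)
}

#' Read a protein structure from a PDB file
#'
#' Parses a PDB file into a `StructureModel`: an ordered residue table plus a
#' per-atom table with coordinates in Angstrom. Waters are excluded; other
#' heteroatoms are retained and flagged. When alternate locations are present
#' the highest-occupancy conformer is kept (ties: first encountered).
#'
#' @param path path to a PDB file
#' @return an object of class `StructureModel` with elements `atom`
#'   (data.frame: eleno, elety, resid, chain, resno, insert, x, y, z, elesy,
#'   het), `residues` (data.frame: chain, resno, insert, resname, key,
#'   polymer, first, last) and `source`
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at <- at[!(at$resid %in% .WATER_RES), , drop = FALSE]
  if (nrow(at) == 0) stop("empty-model error: no non-water atoms in ", path)

  # altloc: keep highest occupancy per (chain, resno, insert, elety); tie ->
  # first encountered
  alt <- ifelse(is.na(at$alt), "", at$alt)
  if (any(alt != "")) {
    grp <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
                 at$elety, sep = "\r")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), grp), function(i) {
      i[which.max(occ[i])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }

  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$het <- at$type == "HETATM"
  # element symbol: take from file when present, else first letter of name
  ele <- at$elesy
  ele[is.na(ele) | ele == ""] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                                     at$elety[is.na(ele) | ele == ""])
  at$elesy <- toupper(trimws(ele))

  # stable residue ordering: chain, then author number, then insertion code
  ord <- order(at$chain, at$resno, at$insert)
  at <- at[ord, , drop = FALSE]
  rkey <- residue_key(at$chain, at$resno, at$insert)
  ridx <- match(rkey, unique(rkey))
  first <- which(!duplicated(ridx))
  residues <- data.frame(
    chain = at$chain[first],
    resno = at$resno[first],
    insert = at$insert[first],
    resname = at$resid[first],
    key = rkey[first],
    polymer = !at$het[first],
    stringsAsFactors = FALSE
  )
  residues$first <- first
  residues$last <- c(first[-1] - 1L, nrow(at))

  if (!any(residues$polymer)) {
    stop("empty-model error: zero polymer residues in ", path)
  }

  model <- list(
    atom = data.frame(
      eleno = at$eleno, elety = at$elety, resid = at$resid,
      chain = at$chain, resno = at$resno, insert = at$insert,
      x = at$x, y = at$y, z = at$z, elesy = at$elesy, het = at$het,
      reskey = rkey, stringsAsFactors = FALSE
    ),
    residues = residues,
    source = path
  )
  class(model) <- "StructureModel"
  model
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", sum(x$residues$polymer), "polymer residues,",
      sum(!x$residues$polymer), "hetero residues,",
      nrow(x$atom), "atoms\n")
  cat("  chains:", paste(unique(x$residues$chain), collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in a StructureModel
#' @param model a `StructureModel`
#' @return integer atom count
#' @export
n_atoms <- function(model) nrow(model$atom)

#' Extract the one-letter sequence of a chain
#'
#' One letter per standard polymer residue in residue-number order;
#' nonstandard residues (e.g. MSE) map to `X` with a message.
#'
#' @param model a `StructureModel`
#' @param chain chain identifier; defaults to the first polymer chain
#' @return one-letter amino-acid string
#' @export
extract_sequence <- function(model, chain = NULL) {
  pol <- model$residues[model$residues$polymer, , drop = FALSE]
  chains <- unique(pol$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    stop("unknown chain '", chain, "'; available chains: ",
         paste(chains, collapse = ", "))
  }
  res <- pol[pol$chain == chain, , drop = FALSE]
  if (nrow(res) == 0) stop("chain '", chain, "' has no polymer residues")
  aa <- ifelse(res$resname %in% .STD_AA,
               bio3d::aa321(res$resname), "X")
  nonstd <- res$resname[!(res$resname %in% .STD_AA)]
  if (length(nonstd) > 0) {
    message("mapped ", length(nonstd), " nonstandard residue(s) to 'X': ",
            paste(unique(nonstd), collapse = ", "))
  }
  paste(aa, collapse = "")
}

#' Open a conformational ensemble at one temperature
#'
#' Wraps a multi-frame coordinate source as an `EnsembleHandle` whose frames
#' are aligned to the atom order of `model`. Accepts a multi-model PDB file,
#' a DCD trajectory file, or an in-memory coordinate matrix with one frame
#' per row (columns `x1,y1,z1,x2,...`).
#'
#' @param model the reference `StructureModel`
#' @param trajectory path to a multi-model PDB / DCD file, or a numeric
#'   matrix of frames
#' @param temperature temperature label in Kelvin (> 0)
#' @return an `EnsembleHandle` with elements `model`, `xyz`, `n_frames`,
#'   `temperature` and a `get_frame(i)` accessor returning an n_atoms x 3
#'   coordinate matrix
#' @export
open_ensemble <- function(model, trajectory, temperature) {
  stopifnot(inherits(model, "StructureModel"))
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      is.na(temperature) || temperature <= 0) {
    stop("temperature label must be a single positive number (Kelvin)")
  }
  if (is.matrix(trajectory)) {
    xyz <- trajectory
  } else if (is.character(trajectory)) {
    if (grepl("\\.dcd$", trajectory, ignore.case = TRUE)) {
      xyz <- bio3d::read.dcd(trajectory, verbose = FALSE)
    } else {
      p <- bio3d::read.pdb(trajectory, multi = TRUE, verbose = FALSE)
      xyz <- p$xyz
      if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    }
  } else {
    stop("trajectory must be a file path or a frames x (3*atoms) matrix")
  }
  na <- n_atoms(model)
  if (ncol(xyz) != 3L * na) {
    stop("atom-count mismatch: model has ", na, " atoms but frames have ",
         ncol(xyz) / 3, " atoms")
  }
  h <- list(
    model = model,
    xyz = xyz,
    n_frames = nrow(xyz),
    temperature = temperature,
    get_frame = function(i) matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  )
  class(h) <- "EnsembleHandle"
  h
}

#' @export
print.EnsembleHandle <- function(x, ...) {
  cat("EnsembleHandle:", x$n_frames, "frames,",
      n_atoms(x$model), "atoms, T =", x$temperature, "K\n")
  invisible(x)
}

#' Write a StructureModel to a PDB file
#'
#' Optionally places a per-atom scalar in the B-factor column and writes
#' multiple MODEL records when a frame matrix is supplied.
#'
#' @param model a `StructureModel`
#' @param path output PDB path
#' @param bfactor optional numeric vector, one value per atom
#' @param xyz optional frames x (3*atoms) coordinate matrix; default uses the
#'   model's own coordinates
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path, bfactor = NULL, xyz = NULL) {
  at <- model$atom
  if (is.null(xyz)) xyz <- matrix(as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                                  nrow = 1)
  if (is.null(bfactor)) bfactor <- rep(0, nrow(at))
  stopifnot(length(bfactor) == nrow(at))
  bio3d::write.pdb(
    file = path, xyz = xyz, resno = at$resno, chain = at$chain,
    resid = at$resid, eleno = at$eleno, elety = at$elety,
    insert = ifelse(at$insert == "", NA, at$insert),
    type = ifelse(at$het, "HETATM", "ATOM"),
    b = round(bfactor, 2), elesy = at$elesy
  )
  invisible(path)
}
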