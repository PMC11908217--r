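# Synthetic inputs with planted ground truth for every pipeline stage.
#
# Ensembles are built geometrically, not physically: residues sit on a wide
# grid (far beyond every contact cutoff) and each scheduled contact moves a
# dedicated probe group of the partner residue inside its geometric
# criterion in exactly the scheduled frames, so recovered contact
# frequencies equal schedule occupancies by construction. All generators are
# pure functions of their spec plus seed.

.SYNTH_SPACING <- 40  # Angstrom between residue anchors; > all cutoffs

# residue archetypes used by the generator: atom names and local offsets (A)
.SYNTH_RES <- list(
  GLY = list(atoms = c("N", "CA", "C", "O"),
             off = rbind(c(-1.2, 0.8, 0), c(0, 0, 0), c(1.2, 0.8, 0),
                         c(1.8, 1.9, 0))),
  ARG = list(atoms = c("N", "CA", "CB", "NE", "CZ", "NH1", "NH2"),
             off = rbind(c(-1.2, 0.8, 0), c(0, 0, 0), c(0.8, -1.2, 0),
                         c(2.0, -2.5, 0), c(2.8, -3.3, 0),
                         c(3.6, -2.9, 0), c(2.8, -4.5, 0))),
  ASP = list(atoms = c("N", "CA", "CB", "CG", "OD1", "OD2"),
             off = rbind(c(-1.2, 0.8, 0), c(0, 0, 0), c(0.8, -1.2, 0),
                         c(1.8, -2.0, 0), c(2.6, -2.6, 0),
                         c(1.4, -3.1, 0))),
  LEU = list(atoms = c("N", "CA", "CB", "CG", "CD1", "CD2"),
             off = rbind(c(-1.2, 0.8, 0), c(0, 0, 0), c(0.8, -1.2, 0),
                         c(1.8, -2.0, 0), c(2.8, -2.6, 0),
                         c(1.2, -3.2, 0))),
  SER = list(atoms = c("N", "CA", "CB", "OG"),
             off = rbind(c(-1.2, 0.8, 0), c(0, 0, 0), c(0.8, -1.2, 0),
                         c(1.9, -1.9, 0))),
  LYS = list(atoms = c("N", "CA", "CB", "NZ"),
             off = rbind(c(-1.2, 0.8, 0), c(0, 0, 0), c(0.8, -1.2, 0),
                         c(2.4, -2.4, 0))),
  PHE = list(atoms = c("N", "CA", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
                       "CZ"),
             off = rbind(c(-1.2, 0.8, 0), c(0, 0, 0), c(0.8, -1.2, 0),
                         c(1.60, -2.20, 0), c(2.99, -2.20, 0),
                         c(0.90, -3.41, 0), c(3.69, -3.41, 0),
                         c(1.60, -4.62, 0), c(2.99, -4.62, 0)))
)

# residue types per scheduled contact type: c(type of i, type of j) and the
# probe atoms whose separation realizes the contact
.SYNTH_PAIR <- list(
  salt_bridge = list(res = c("ARG", "ASP"), probe = c("NE", "OD1"),
                     on_dist = 3.0),
  hydrophobic = list(res = c("LEU", "LEU"), probe = c("CD1", "CD1"),
                     on_dist = 3.8),
  hbond = list(res = c("SER", "SER"), probe = c("OG", "OG"),
               on_dist = 2.9),
  cation_pi = list(res = c("LYS", "PHE"), probe = c("NZ", "CG"),
                   on_dist = 4.0),
  pi_stack = list(res = c("PHE", "PHE"), probe = c("CG", "CG"),
                  on_dist = 3.6)
)

#' Generate a toy structure plus per-temperature ensembles with scheduled
#' contacts
#'
#' Builds a single-chain toy polymer whose residues are spaced far apart, and
#' one ensemble per temperature in which each scheduled contact's geometric
#' criterion is satisfied in exactly `round(occupancy * n_frames)` frames
#' (the leading frames) and violated otherwise. Each residue may take part in
#' at most one scheduled contact; conflicting schedules are rejected.
#'
#' @param schedule data.frame with columns `i`, `j` (residue numbers,
#'   `|i - j| >= 3`), `type` (see [contact_params()])
#' @param occupancy numeric matrix, `nrow(schedule)` x
#'   `length(temperatures)`, entries in `[0, 1]`
#' @param temperatures temperature ladder (K), strictly increasing
#' @param n_frames frames per ensemble
#' @param n_residues total residues in the toy chain (default: enough to
#'   hold the schedule)
#' @param seed random seed (mandatory; fixed-schedule generation is
#'   deterministic, the seed feeds only the tiny coordinate jitter)
#' @param jitter SD (Angstrom) of Gaussian coordinate noise, small enough
#'   never to cross any cutoff (default 0.05)
#' @return list with `model` (`StructureModel`), `ensembles` (list of
#'   `EnsembleHandle`, one per temperature), `truth` (data.frame: contact
#'   key, one occupancy column per temperature as realized after rounding)
#' @export
synth_ensemble <- function(schedule, occupancy, temperatures,
                           n_frames = 100L, n_residues = NULL, seed,
                           jitter = 0.05) {
  stopifnot(is.data.frame(schedule),
            all(c("i", "j", "type") %in% names(schedule)))
  if (missing(seed)) stop("seed is mandatory")
  occupancy <- matrix(occupancy, nrow = max(nrow(schedule), 1))
  if (nrow(schedule) > 0) {
    stopifnot(nrow(occupancy) == nrow(schedule),
              ncol(occupancy) == length(temperatures))
    if (any(occupancy < 0 | occupancy > 1)) {
      stop("schedule occupancies must lie in [0, 1]")
    }
    if (any(abs(schedule$i - schedule$j) < 3)) {
      stop("geometrically unsatisfiable schedule: pairs with |i - j| <= 2 ",
           "are excluded by the sequence-separation rule")
    }
    used <- c(schedule$i, schedule$j)
    if (anyDuplicated(used)) {
      stop("geometrically unsatisfiable schedule: residue(s) ",
           paste(unique(used[duplicated(used)]), collapse = ", "),
           " appear in more than one contact")
    }
    if (!all(schedule$type %in% names(.SYNTH_PAIR))) {
      stop("unknown contact type(s) in schedule")
    }
  }
  if (is.null(n_residues)) {
    n_residues <- max(c(10L, schedule$i, schedule$j))
  }
  stopifnot(n_residues >= max(c(1L, schedule$i, schedule$j)))

  # residue types: GLY except scheduled participants
  restype <- rep("GLY", n_residues)
  if (nrow(schedule) > 0) {
    for (s in seq_len(nrow(schedule))) {
      pr <- .SYNTH_PAIR[[schedule$type[s]]]
      restype[schedule$i[s]] <- pr$res[1]
      restype[schedule$j[s]] <- pr$res[2]
    }
  }

  # anchors on a wide 2D grid
  grid_n <- ceiling(sqrt(n_residues))
  anchors <- cbind(
    .SYNTH_SPACING * ((seq_len(n_residues) - 1) %% grid_n),
    .SYNTH_SPACING * ((seq_len(n_residues) - 1) %/% grid_n),
    0
  )

  # base coordinates and atom bookkeeping
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(r) {
    a <- .SYNTH_RES[[restype[r]]]
    data.frame(resno = r, resname = restype[r], elety = a$atoms,
               x = anchors[r, 1] + a$off[, 1],
               y = anchors[r, 2] + a$off[, 2],
               z = anchors[r, 3] + a$off[, 3],
               stringsAsFactors = FALSE)
  }))
  natoms <- nrow(atoms)
  base <- as.matrix(atoms[, c("x", "y", "z")])

  # For each scheduled contact, precompute the "on" displacement of residue
  # j's whole atom set: translate j so its probe sits on_dist from i's probe.
  disp <- vector("list", nrow(schedule))
  if (nrow(schedule) > 0) {
    for (s in seq_len(nrow(schedule))) {
      pr <- .SYNTH_PAIR[[schedule$type[s]]]
      ai <- which(atoms$resno == schedule$i[s] & atoms$elety == pr$probe[1])
      aj <- which(atoms$resno == schedule$j[s] & atoms$elety == pr$probe[2])
      jrows <- which(atoms$resno == schedule$j[s])
      target <- base[ai, ] + c(pr$on_dist, 0, 0)
      disp[[s]] <- list(rows = jrows, shift = target - base[aj, ])
    }
  }

  # write the reference model through the real PDB reader so generated
  # fixtures exercise structure_io as well
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = as.vector(t(base)),
                   resno = atoms$resno, chain = rep("A", natoms),
                   resid = atoms$resname, eleno = seq_len(natoms),
                   elety = atoms$elety)
  model <- load_structure(tmp)
  unlink(tmp)

  set.seed(seed)
  truth_occ <- matrix(0, nrow(schedule), length(temperatures))
  ensembles <- vector("list", length(temperatures))
  for (t in seq_along(temperatures)) {
    xyz <- matrix(NA_real_, n_frames, 3 * natoms)
    on_frames <- lapply(seq_len(max(nrow(schedule), 0)), function(s) {
      n_on <- round(occupancy[s, t] * n_frames)
      truth_occ[s, t] <<- n_on / n_frames
      seq_len(n_on)
    })
    for (f in seq_len(n_frames)) {
      fr <- base
      if (nrow(schedule) > 0) {
        for (s in seq_len(nrow(schedule))) {
          if (f %in% on_frames[[s]]) {
            fr[disp[[s]]$rows, ] <- sweep(fr[disp[[s]]$rows, , drop = FALSE],
                                          2, disp[[s]]$shift, "+")
          }
        }
      }
      if (jitter > 0) fr <- fr + matrix(rnorm(3 * natoms, 0, jitter),
                                        ncol = 3)
      xyz[f, ] <- as.vector(t(fr))
    }
    ensembles[[t]] <- open_ensemble(model, xyz, temperatures[t])
  }

  truth <- NULL
  if (nrow(schedule) > 0) {
    res <- model$residues
    key_of <- function(r, name) paste0(res$key[match(r, res$resno)], ":",
                                       name)
    keys <- vapply(seq_len(nrow(schedule)), function(s) {
      pr <- .SYNTH_PAIR[[schedule$type[s]]]
      a <- sort(c(schedule$i[s], schedule$j[s]))
      nm <- if (a[1] == schedule$i[s]) pr$res else rev(pr$res)
      paste0(key_of(a[1], nm[1]), "|", key_of(a[2], nm[2]), "|",
             schedule$type[s])
    }, character(1))
    truth <- data.frame(contact = keys, truth_occ)
    names(truth)[-1] <- as.character(temperatures)
  }
  list(model = model, ensembles = ensembles, truth = truth)
}

#' Generate a contact-frequency matrix with planted melting/forming curves
#'
#' Melting contacts follow `f(T) = 1 / (1 + exp((T - Tm) / w))` (decreasing
#' in temperature), forming contacts the mirrored curve, inert contacts a
#' constant baseline; truncated Gaussian noise is added and values clipped to
#' `[0, 1]`. The defaults reproduce the study conditions: a six-point ladder
#' from 283 K to 393 K.
#'
#' @param n_melting,n_forming,n_inert contact counts per class
#' @param temperatures temperature ladder (K)
#' @param midpoints optional vector of logistic midpoints (K) recycled over
#'   the melting then forming contacts; default: staggered across the inner
#'   80% of the ladder span
#' @param width logistic width (K)
#' @param noise_sd Gaussian noise SD on frequencies
#' @param seed random seed (mandatory)
#' @return list with `matrix` (a `ContactFrequencyMatrix`) and `labels`
#'   (character vector: melting / forming / inert per row)
#' @export
synth_contact_ladder <- function(n_melting = 20L, n_forming = 20L,
                                 n_inert = 60L,
                                 temperatures = seq(283, 393,
                                                    length.out = 6),
                                 midpoints = NULL, width = 15,
                                 noise_sd = 0.02, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(noise_sd >= 0, width > 0)
  n <- n_melting + n_forming + n_inert
  span <- range(temperatures)
  if (is.null(midpoints)) {
    lo <- span[1] + 0.1 * diff(span)
    hi <- span[2] - 0.1 * diff(span)
    midpoints <- seq(lo, hi, length.out = max(n_melting + n_forming, 2))
  }
  if (any(midpoints < span[1] | midpoints > span[2])) {
    stop("logistic midpoints must lie within the temperature ladder span")
  }
  midpoints <- rep_len(midpoints, max(n_melting + n_forming, 1))
  set.seed(seed)
  rows <- matrix(NA_real_, n, length(temperatures))
  labels <- c(rep("melting", n_melting), rep("forming", n_forming),
              rep("inert", n_inert))
  mi <- 0
  for (r in seq_len(n)) {
    if (labels[r] == "melting") {
      mi <- mi + 1
      rows[r, ] <- 1 / (1 + exp((temperatures - midpoints[mi]) / width))
    } else if (labels[r] == "forming") {
      mi <- mi + 1
      rows[r, ] <- 1 / (1 + exp(-(temperatures - midpoints[mi]) / width))
    } else {
      rows[r, ] <- runif(1, 0.2, 0.8)
    }
  }
  if (noise_sd > 0) {
    rows <- rows + matrix(rnorm(length(rows), 0, noise_sd), nrow = n)
  }
  rows <- pmin(pmax(rows, 0), 1)
  # synthetic keys: distinct residue pairs on one chain, hydrophobic type so
  # the matrix can also feed the network stage
  i <- seq_len(n)
  keys <- paste0("A:", i, ":LEU|A:", i + n + 3, ":LEU|hydrophobic")
  rownames(rows) <- keys
  list(matrix = contact_matrix(rows, temperatures),
       labels = setNames(labels, keys))
}

#' Generate a synthetic MSA with known column distributions
#'
#' Columns are sampled independently from the given symbol distributions; a
#' designated gap-free query row (named `"query"`) carries the modal symbol
#' of each column, so empirical column entropies converge to the spec
#' entropies as the number of sequences grows.
#'
#' @param column_specs list of named probability vectors over the amino-acid
#'   alphabet (plus `-` for gaps), one per column
#' @param n_sequences number of sampled rows (>= 2)
#' @param seed random seed (mandatory)
#' @return an `AlignmentBlock` with rows `query`, `seq_1` ... `seq_n`
#' @export
synth_msa <- function(column_specs, n_sequences, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_sequences >= 2, length(column_specs) >= 1)
  for (j in seq_along(column_specs)) {
    p <- column_specs[[j]]
    if (abs(sum(p) - 1) > 1e-9) {
      stop("column ", j, " distribution sums to ", sum(p), ", not 1")
    }
    if (is.null(names(p)) || !all(names(p) %in% c(.AA20, "-"))) {
      stop("column ", j, " distribution must be named over the amino-acid ",
           "alphabet (plus '-')")
    }
  }
  set.seed(seed)
  cols <- lapply(column_specs, function(p) {
    sample(names(p), n_sequences, replace = TRUE, prob = p)
  })
  m <- do.call(cbind, cols)
  query <- vapply(column_specs, function(p) {
    aa <- p[names(p) != "-"]
    if (length(aa) == 0) stop("query row cannot be gap-free for an all-gap ",
                              "column spec")
    names(aa)[which.max(aa)]
  }, character(1))
  seqs <- c(paste(query, collapse = ""),
            apply(m, 1, paste, collapse = ""))
  names(seqs) <- c("query", paste0("seq_", seq_len(n_sequences)))
  alignment_block(seqs)
}

#' Generate a residue feature table with planted clusters
#'
#' Gaussian blobs in the three-feature space (entropy, sensitivity,
#' centrality) with known labels, for clustering-recovery tests.
#'
#' @param centers k x 3 matrix of blob centers (columns: entropy,
#'   sensitivity, cc)
#' @param spreads per-blob SD (recycled)
#' @param sizes per-blob point counts
#' @param seed random seed (mandatory)
#' @return list with `table` (a `ResidueFeatureTable`) and `labels` (true
#'   blob of each row)
#' @export
synth_feature_clusters <- function(centers, spreads, sizes, seed) {
  if (missing(seed)) stop("seed is mandatory")
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3, nrow(centers) == length(sizes))
  spreads <- rep_len(spreads, nrow(centers))
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(b) {
    matrix(rnorm(3 * sizes[b], mean = rep(centers[b, ], each = sizes[b]),
                 sd = spreads[b]), ncol = 3)
  }))
  labels <- rep(seq_len(nrow(centers)), sizes)
  keys <- paste0("A:", seq_len(nrow(pts)))
  tab <- assemble_features(
    entropy = setNames(pts[, 1], keys),
    sensitivity = setNames(pts[, 2], keys),
    cc = setNames(pts[, 3], keys)
  )
  list(table = tab, labels = labels[match(tab$key, keys)])
}
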