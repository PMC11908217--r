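# Typed noncovalent contact detection and per-temperature frequency tables.
#
# Geometric criteria operate on heavy atoms only, so crystal structures and
# trajectory frames are treated uniformly. Each (residue pair, type) is
# counted at most once per frame regardless of how many atom pairs satisfy
# the criterion, and pairs closer than 3 residues apart in sequence within
# one chain are excluded.

.CONTACT_TYPES <- c("salt_bridge", "hydrophobic", "hbond", "cation_pi",
                    "pi_stack")

.HYDRO_RES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")
.BACKBONE <- c("N", "CA", "C", "O", "OXT")

.BASIC_N <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                 HIS = c("ND1", "NE2"))
.ACID_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.CATION_GROUP <- list(ARG = c("NE", "CZ", "NH1", "NH2"), LYS = "NZ")
.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

#' Default geometric criteria for contact detection
#'
#' Distance cutoffs in Angstrom for each interaction type, all overridable:
#' `salt_bridge` (4.0; Arg/Lys/His sidechain N to Asp/Glu carboxylate O),
#' `hydrophobic` (4.5; sidechain C of ALA/VAL/LEU/ILE/MET/PHE/TRP/PRO pairs),
#' `hbond` (3.5; heavy-atom N/O donor-acceptor proxy), `cation_pi` (6.0;
#' Arg/Lys cationic-group centroid to aromatic ring centroid) and `pi_stack`
#' (5.5; ring centroid to ring centroid). `min_seq_sep` is the smallest
#' |i - j| in author numbering (same chain) at which a pair is counted.
#'
#' @param salt_bridge,hydrophobic,hbond,cation_pi,pi_stack distance cutoffs
#'   in Angstrom
#' @param min_seq_sep minimum same-chain residue-number separation (default 3,
#'   i.e. pairs with |i - j| <= 2 are excluded)
#' @return a named list of parameters
#' @export
contact_params <- function(salt_bridge = 4.0, hydrophobic = 4.5, hbond = 3.5,
                           cation_pi = 6.0, pi_stack = 5.5, min_seq_sep = 3) {
  list(salt_bridge = salt_bridge, hydrophobic = hydrophobic, hbond = hbond,
       cation_pi = cation_pi, pi_stack = pi_stack,
       min_seq_sep = as.integer(min_seq_sep))
}

# Pre-resolve, per interaction type, which atom rows / atom groups of the
# model participate. Done once per model, reused across frames.
.contact_index <- function(model) {
  at <- model$atom
  pol <- !at$het
  res_of <- match(at$reskey, model$residues$key)

  sel_named <- function(map) {
    keep <- logical(nrow(at))
    for (rn in names(map)) {
      keep <- keep | (pol & at$resid == rn & at$elety %in% map[[rn]])
    }
    which(keep)
  }

  hyd <- which(pol & at$resid %in% .HYDRO_RES & at$elesy == "C" &
               !(at$elety %in% .BACKBONE))
  no <- which(pol & at$elesy %in% c("N", "O"))

  centroid_groups <- function(map) {
    idx <- sel_named(map)
    split(idx, res_of[idx])
  }

  list(
    res_of = res_of,
    salt_a = sel_named(.BASIC_N),
    salt_b = sel_named(.ACID_O),
    hydro = hyd,
    hbond = no,
    cation = centroid_groups(.CATION_GROUP),
    rings = centroid_groups(.RING_ATOMS)
  )
}

.cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

.group_centroids <- function(coords, groups) {
  if (length(groups) == 0) {
    return(list(xyz = matrix(0, 0, 3), res = integer(0)))
  }
  xyz <- t(vapply(groups, function(i) colMeans(coords[i, , drop = FALSE]),
                  numeric(3)))
  list(xyz = xyz, res = as.integer(names(groups)))
}

# Given atom-pair hits, reduce to canonical unique residue pairs passing the
# sequence-separation rule. ra, rb: residue indices of the hit pairs.
.pairs_to_keys <- function(model, ra, rb, type, min_seq_sep) {
  keep <- ra != rb
  ra <- ra[keep]; rb <- rb[keep]
  if (length(ra) == 0) return(character(0))
  res <- model$residues
  same_chain <- res$chain[ra] == res$chain[rb]
  sep_ok <- !same_chain | abs(res$resno[ra] - res$resno[rb]) >= min_seq_sep
  ra <- ra[sep_ok]; rb <- rb[sep_ok]
  if (length(ra) == 0) return(character(0))
  # canonical order: lower chain, then lower residue number first
  swap <- res$chain[ra] > res$chain[rb] |
    (res$chain[ra] == res$chain[rb] & res$resno[ra] > res$resno[rb])
  tmp <- ra[swap]; ra[swap] <- rb[swap]; rb[swap] <- tmp
  keys <- paste0(res$key[ra], ":", res$resname[ra], "|",
                 res$key[rb], ":", res$resname[rb], "|", type)
  unique(keys)
}

#' Detect typed contacts in a single frame
#'
#' @param coords n_atoms x 3 coordinate matrix aligned to the model's atom
#'   order (Angstrom)
#' @param model the `StructureModel`
#' @param types character vector of interaction types to detect; see
#'   [contact_params()]
#' @param params geometry configuration from [contact_params()]
#' @param index optional precomputed atom index (internal reuse across frames)
#' @return character vector of canonical contact keys
#'   (`"A:10:ARG|A:183:ASP|salt_bridge"`)
#' @export
detect_contacts_frame <- function(coords, model, types = .CONTACT_TYPES,
                                  params = contact_params(), index = NULL) {
  bad <- setdiff(types, .CONTACT_TYPES)
  if (length(bad) > 0) {
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "),
         "; supported types: ", paste(.CONTACT_TYPES, collapse = ", "))
  }
  stopifnot(nrow(coords) == n_atoms(model))
  if (is.null(index)) index <- .contact_index(model)
  res_of <- index$res_of
  mss <- params$min_seq_sep
  out <- character(0)

  hit_pairs <- function(ia, ib, cutoff, symmetric = FALSE) {
    if (length(ia) == 0 || length(ib) == 0) return(NULL)
    D <- .cross_dist(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE])
    w <- which(D <= cutoff, arr.ind = TRUE)
    if (nrow(w) == 0) return(NULL)
    list(a = ia[w[, 1]], b = ib[w[, 2]])
  }

  if ("salt_bridge" %in% types) {
    h <- hit_pairs(index$salt_a, index$salt_b, params$salt_bridge)
    if (!is.null(h)) {
      out <- c(out, .pairs_to_keys(model, res_of[h$a], res_of[h$b],
                                   "salt_bridge", mss))
    }
  }
  if ("hydrophobic" %in% types) {
    h <- hit_pairs(index$hydro, index$hydro, params$hydrophobic)
    if (!is.null(h)) {
      out <- c(out, .pairs_to_keys(model, res_of[h$a], res_of[h$b],
                                   "hydrophobic", mss))
    }
  }
  if ("hbond" %in% types) {
    h <- hit_pairs(index$hbond, index$hbond, params$hbond)
    if (!is.null(h)) {
      out <- c(out, .pairs_to_keys(model, res_of[h$a], res_of[h$b],
                                   "hbond", mss))
    }
  }
  if (any(c("cation_pi", "pi_stack") %in% types)) {
    rg <- .group_centroids(coords, index$rings)
    if ("cation_pi" %in% types) {
      cg <- .group_centroids(coords, index$cation)
      if (nrow(cg$xyz) > 0 && nrow(rg$xyz) > 0) {
        D <- .cross_dist(cg$xyz, rg$xyz)
        w <- which(D <= params$cation_pi, arr.ind = TRUE)
        if (nrow(w) > 0) {
          out <- c(out, .pairs_to_keys(model, cg$res[w[, 1]], rg$res[w[, 2]],
                                       "cation_pi", mss))
        }
      }
    }
    if ("pi_stack" %in% types && nrow(rg$xyz) > 1) {
      D <- .cross_dist(rg$xyz, rg$xyz)
      w <- which(D <= params$pi_stack, arr.ind = TRUE)
      if (nrow(w) > 0) {
        out <- c(out, .pairs_to_keys(model, rg$res[w[, 1]], rg$res[w[, 2]],
                                     "pi_stack", mss))
      }
    }
  }
  sort(unique(out))
}

#' Contact frequencies over an ensemble
#'
#' For every contact observed in any sampled frame, the fraction of sampled
#' frames in which it is present.
#'
#' @param ensemble an `EnsembleHandle`
#' @param types interaction types to detect
#' @param params geometry configuration from [contact_params()]
#' @param stride sample every `stride`-th frame (default 1 = all frames)
#' @return a `ContactFrequencyTable`: list with `temperature`, `n_frames`
#'   (frames sampled) and `freq`, a named numeric vector of frequencies in
#'   `[0, 1]` keyed by canonical contact key
#' @export
contact_frequencies <- function(ensemble, types = .CONTACT_TYPES,
                                params = contact_params(), stride = 1L) {
  stopifnot(inherits(ensemble, "EnsembleHandle"))
  frames <- seq(1L, ensemble$n_frames, by = as.integer(stride))
  if (length(frames) == 0) stop("zero frames after striding")
  model <- ensemble$model
  index <- .contact_index(model)
  counts <- new.env(parent = emptyenv())
  for (f in frames) {
    keys <- detect_contacts_frame(ensemble$get_frame(f), model, types,
                                  params, index = index)
    for (k in keys) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  ks <- sort(ls(counts))
  freq <- vapply(ks, function(k) counts[[k]] / length(frames), numeric(1))
  tab <- list(temperature = ensemble$temperature, n_frames = length(frames),
              freq = freq)
  class(tab) <- "ContactFrequencyTable"
  tab
}

#' Parse canonical contact keys into a data frame
#'
#' @param keys character vector of canonical contact keys
#' @return data.frame with columns res_a, resname_a, res_b, resname_b, type
#' @export
parse_contact_keys <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  stopifnot(all(lengths(parts) == 3))
  split_res <- function(s) {
    # "chain:resno[insert]:RESNAME"
    m <- regmatches(s, regexec("^(.*):([A-Z0-9]{1,4})$", s))
    t(vapply(m, function(x) x[2:3], character(2)))
  }
  a <- split_res(vapply(parts, `[`, "", 1))
  b <- split_res(vapply(parts, `[`, "", 2))
  data.frame(res_a = a[, 1], resname_a = a[, 2],
             res_b = b[, 1], resname_b = b[, 2],
             type = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Assemble per-temperature tables into a contact-frequency matrix
#'
#' Rows are the union of contacts over all tables (a contact absent at some
#' temperature has entry 0); columns are temperatures sorted ascending.
#'
#' @param tables list of `ContactFrequencyTable` objects with distinct
#'   temperatures
#' @return a `ContactFrequencyMatrix`: list with `freq` (contacts x
#'   temperatures matrix, rownames = contact keys) and `temperatures`
#' @export
assemble_matrix <- function(tables) {
  stopifnot(length(tables) >= 2,
            all(vapply(tables, inherits, TRUE, "ContactFrequencyTable")))
  temps <- vapply(tables, `[[`, numeric(1), "temperature")
  if (anyDuplicated(temps)) {
    stop("duplicate temperature(s): ",
         paste(unique(temps[duplicated(temps)]), collapse = ", "))
  }
  ord <- order(temps)
  tables <- tables[ord]
  temps <- temps[ord]
  keys <- sort(unique(unlist(lapply(tables, function(t) names(t$freq)))))
  M <- matrix(0, nrow = length(keys), ncol = length(temps),
              dimnames = list(keys, as.character(temps)))
  for (j in seq_along(tables)) {
    f <- tables[[j]]$freq
    M[names(f), j] <- f
  }
  out <- list(freq = M, temperatures = temps)
  class(out) <- "ContactFrequencyMatrix"
  out
}

#' Construct a ContactFrequencyMatrix from a plain matrix
#'
#' @param freq contacts x temperatures numeric matrix in `[0, 1]`, rownames =
#'   canonical contact keys
#' @param temperatures strictly increasing temperature ladder (K)
#' @return a `ContactFrequencyMatrix`
#' @export
contact_matrix <- function(freq, temperatures) {
  stopifnot(is.matrix(freq), ncol(freq) == length(temperatures),
            !is.null(rownames(freq)))
  if (any(diff(temperatures) <= 0)) {
    stop("temperatures must be strictly increasing")
  }
  if (any(freq < 0 | freq > 1)) stop("frequencies must lie in [0, 1]")
  colnames(freq) <- as.character(temperatures)
  out <- list(freq = freq, temperatures = as.numeric(temperatures))
  class(out) <- "ContactFrequencyMatrix"
  out
}

#' @export
print.ContactFrequencyMatrix <- function(x, ...) {
  cat("ContactFrequencyMatrix:", nrow(x$freq), "contacts x",
      length(x$temperatures), "temperatures (",
      paste(range(x$temperatures), collapse = "-"), "K )\n")
  invisible(x)
}

#' Write a contact matrix as tidy and wide CSV
#'
#' @param mat a `ContactFrequencyMatrix`
#' @param tidy_path,wide_path output CSV paths (`NULL` to skip either)
#' @return invisibly, the tidy data.frame
#' @export
write_contact_csv <- function(mat, tidy_path = NULL, wide_path = NULL) {
  keys <- rownames(mat$freq)
  kd <- parse_contact_keys(keys)
  tidy <- do.call(rbind, lapply(seq_along(mat$temperatures), function(j) {
    data.frame(resA = kd$res_a, resB = kd$res_b, type = kd$type,
               temperature = mat$temperatures[j], frequency = mat$freq[, j],
               stringsAsFactors = FALSE)
  }))
  rownames(tidy) <- NULL
  if (!is.null(tidy_path)) write.csv(tidy, tidy_path, row.names = FALSE)
  if (!is.null(wide_path)) {
    wide <- data.frame(contact = keys, mat$freq, check.names = FALSE)
    write.csv(wide, wide_path, row.names = FALSE)
  }
  invisible(tidy)
}
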