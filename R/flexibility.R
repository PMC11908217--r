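# Per-residue flexibility: Calpha RMSF per temperature and the
# temperature-sensitivity score (population SD of RMSF across the ladder).

#' Indices of Calpha atoms of polymer residues
#' @param model a `StructureModel`
#' @return integer vector of atom rows
#' @export
calpha_indices <- function(model) {
  which(!model$atom$het & model$atom$elety == "CA")
}

#' Superpose ensemble frames onto the iteratively refined mean structure
#'
#' Each frame is rigid-body least-squares fitted (over the selected atoms) to
#' the running mean structure, which is recomputed and the fit repeated until
#' the mean moves less than `tol` or `max_iter` passes.
#'
#' @param ensemble an `EnsembleHandle`
#' @param sel atom indices used for fitting; default all polymer Calpha
#' @param tol convergence tolerance on mean-structure movement (Angstrom)
#' @param max_iter maximum refinement passes
#' @return list with `xyz` (aligned frames x (3*atoms) matrix), `sel`, and
#'   `iterations` used
#' @export
superpose_frames <- function(ensemble, sel = NULL, tol = 1e-6,
                             max_iter = 10L) {
  stopifnot(inherits(ensemble, "EnsembleHandle"))
  if (ensemble$n_frames < 2) stop("superposition needs at least 2 frames")
  if (is.null(sel)) sel <- calpha_indices(ensemble$model)
  if (length(sel) < 3) stop("superposition error: fewer than 3 selected atoms")
  ci <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  xyz <- ensemble$xyz
  ref <- xyz[1, ]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    xyz <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                          fixed.inds = ci, mobile.inds = ci)
    newref <- colMeans(xyz)
    delta <- sqrt(max(rowSums(matrix((newref - ref)[ci], ncol = 3,
                                     byrow = TRUE)^2)))
    ref <- newref
    if (delta < tol || iter >= max_iter) break
  }
  list(xyz = xyz, sel = sel, iterations = iter)
}

#' Root-mean-square fluctuation per residue
#'
#' RMSF of each selected atom about its time-average position over the
#' aligned frames: `sqrt(mean_t |x_i(t) - <x_i>|^2)`.
#'
#' @param aligned result of [superpose_frames()], or a frames x (3*atoms)
#'   matrix together with `sel`
#' @param model the `StructureModel` (used to label residues)
#' @param sel atom indices when `aligned` is a plain matrix
#' @param temperature optional temperature label (K) carried on the profile
#' @return an `RMSFProfile` data.frame with columns `key`, `rmsf` (Angstrom)
#'   and attribute `temperature`
#' @export
rmsf_profile <- function(aligned, model, sel = NULL, temperature = NA_real_) {
  if (is.list(aligned) && !is.null(aligned$xyz)) {
    sel <- aligned$sel
    xyz <- aligned$xyz
  } else {
    xyz <- aligned
  }
  stopifnot(is.matrix(xyz), !is.null(sel))
  if (nrow(xyz) < 2) stop("RMSF undefined for a single frame")
  vals <- vapply(sel, function(a) {
    cols <- (3 * a - 2):(3 * a)
    X <- xyz[, cols, drop = FALSE]
    mu <- colMeans(X)
    sqrt(mean(rowSums(sweep(X, 2, mu)^2)))
  }, numeric(1))
  out <- data.frame(key = model$atom$reskey[sel], rmsf = vals,
                    stringsAsFactors = FALSE)
  attr(out, "temperature") <- temperature
  class(out) <- c("RMSFProfile", "data.frame")
  out
}

#' RMSF at one temperature, from superposition to profile
#'
#' Convenience wrapper: superpose then compute RMSF over polymer Calpha.
#'
#' @inheritParams superpose_frames
#' @return an `RMSFProfile`
#' @export
ensemble_rmsf <- function(ensemble, sel = NULL) {
  al <- superpose_frames(ensemble, sel = sel)
  rmsf_profile(al, ensemble$model, temperature = ensemble$temperature)
}

#' Temperature-sensitivity score
#'
#' Per-residue population standard deviation of RMSF across the temperature
#' ladder; zero iff a residue's RMSF is identical at all temperatures. The
#' population (not sample) SD is used because the ladder is the full set of
#' conditions, not a sample from one.
#'
#' @param profiles list of `RMSFProfile` objects over identical residue sets
#' @return a `SensitivityProfile` data.frame with columns `key`,
#'   `sensitivity` (Angstrom)
#' @export
temperature_sensitivity <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  keys <- profiles[[1]]$key
  for (p in profiles[-1]) {
    if (!identical(sort(p$key), sort(keys))) {
      d <- union(setdiff(p$key, keys), setdiff(keys, p$key))
      stop("mismatched residue sets across RMSF profiles; differing keys: ",
           paste(head(d, 10), collapse = ", "))
    }
  }
  M <- vapply(profiles, function(p) p$rmsf[match(keys, p$key)],
              numeric(length(keys)))
  mu <- rowMeans(M)
  pop_sd <- sqrt(rowMeans((M - mu)^2))
  out <- data.frame(key = keys, sensitivity = pop_sd,
                    stringsAsFactors = FALSE)
  class(out) <- c("SensitivityProfile", "data.frame")
  out
}
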