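# Integrated per-residue feature table {conservation entropy, RMSF-SD
# temperature sensitivity, closeness centrality} and k-means clustering with
# elbow-based k selection. Features are z-score standardized before
# clustering because the three features carry incommensurate units.

#' Assemble the per-residue feature table
#'
#' Joins the three per-residue profiles on the residue key. Residues absent
#' from the hydrophobic graph receive closeness centrality 0; residues
#' without a mapped conservation column are dropped (with a message).
#'
#' @param entropy named numeric vector (or data.frame with `key`,
#'   `normalized`) of normalized conservation entropy per residue
#' @param sensitivity named numeric vector (or `SensitivityProfile`) of
#'   temperature-sensitivity scores (Angstrom)
#' @param cc named numeric vector (or `CentralityProfile`) of closeness
#'   centrality
#' @return a `ResidueFeatureTable` data.frame with columns `key`, `entropy`,
#'   `sensitivity`, `cc` and standardized copies `entropy_z`,
#'   `sensitivity_z`, `cc_z`
#' @export
assemble_features <- function(entropy, sensitivity, cc) {
  as_named <- function(x, value_col) {
    if (is.data.frame(x)) setNames(x[[value_col]], x$key) else x
  }
  entropy <- as_named(entropy, "normalized")
  sensitivity <- as_named(sensitivity, "sensitivity")
  cc <- as_named(cc, "cc")
  base <- intersect(names(sensitivity), names(entropy))
  base <- base[!is.na(entropy[base])]
  dropped <- setdiff(names(sensitivity), base)
  if (length(dropped) > 0) {
    message("dropping ", length(dropped),
            " residue(s) without conservation values")
  }
  if (length(base) == 0) {
    stop("empty intersection between entropy and sensitivity profiles")
  }
  ccv <- cc[base]
  ccv[is.na(ccv)] <- 0
  z <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  out <- data.frame(
    key = base,
    entropy = unname(entropy[base]),
    sensitivity = unname(sensitivity[base]),
    cc = unname(ccv),
    stringsAsFactors = FALSE
  )
  out$entropy_z <- z(out$entropy)
  out$sensitivity_z <- z(out$sensitivity)
  out$cc_z <- z(out$cc)
  class(out) <- c("ResidueFeatureTable", "data.frame")
  out
}

.feature_matrix <- function(table) {
  stopifnot(all(c("entropy_z", "sensitivity_z", "cc_z") %in% names(table)))
  as.matrix(table[, c("entropy_z", "sensitivity_z", "cc_z")])
}

#' Within-cluster sum of squares curve and elbow suggestion
#'
#' For each k, the best WCSS over `n_init` restarts. The suggested k uses a
#' scale-free elbow criterion: the discrete second difference
#' `W(k-1) - 2 W(k) + W(k+1)` divided by `W(k)` (relative curvature, so a
#' sharp bend late in an already-low curve is not drowned out by the large
#' early drops), with a parsimony tie-break: the smallest k whose relative
#' curvature reaches 75% of the maximum. On data with no real cluster
#' structure the relative curvature is nearly flat and the tie-break keeps
#' the suggestion small.
#'
#' @param table a `ResidueFeatureTable` (or numeric matrix of standardized
#'   features)
#' @param k_range integer vector of cluster counts to examine
#' @param seed random seed for the restart schedule
#' @param n_init restarts per k
#' @return list with `k`, `wcss` (non-increasing), `suggested_k`
#' @export
wcss_curve <- function(table, k_range = 1:10, seed = 1L, n_init = 25L) {
  X <- if (is.matrix(table)) table else .feature_matrix(table)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > nrow(X)) {
    stop("k_range must lie within [1, ", nrow(X), "]")
  }
  wcss <- vapply(k_range, function(k) {
    if (k >= nrow(unique(X))) return(0)
    set.seed(seed + k)
    km <- suppressWarnings(kmeans(X, centers = k, nstart = n_init,
                                  iter.max = 100))
    km$tot.withinss
  }, numeric(1))
  suggested <- if (length(k_range) >= 3) {
    m <- length(wcss)
    d2 <- wcss[-c(m - 1, m)] - 2 * wcss[-c(1, m)] + wcss[-c(1, 2)]
    rel <- d2 / pmax(wcss[-c(1, m)], 1e-12 * max(wcss, 1))
    k_range[which(rel >= 0.75 * max(rel))[1] + 1L]
  } else {
    k_range[which.min(wcss)]
  }
  list(k = k_range, wcss = wcss, suggested_k = suggested)
}

#' k-means clustering of residue features
#'
#' Runs k-means (Hartigan-Wong, `n_init` random restarts, deterministic
#' given `seed`) on the standardized features and relabels the clusters in
#' descending order of mean temperature sensitivity, so cluster 1 is always
#' the most temperature-sensitive group.
#'
#' @param table a `ResidueFeatureTable`
#' @param k number of clusters (default 4)
#' @param seed random seed
#' @param n_init random restarts
#' @return a `ClusterAssignment`: list with `assignment` (data.frame `key`,
#'   `cluster`), `centers` (k x 3, standardized space), `wcss` (total
#'   within-cluster sum of squares), `k`, `seed`
#' @export
kmeans_cluster <- function(table, k = 4L, seed = 1L, n_init = 25L) {
  X <- .feature_matrix(table)
  if (k > nrow(X)) stop("k = ", k, " exceeds the ", nrow(X), " residues")
  set.seed(seed)
  km <- suppressWarnings(kmeans(X, centers = k, nstart = n_init,
                                iter.max = 100))
  # order clusters by descending mean sensitivity for stable reporting
  sens <- tapply(table$sensitivity, km$cluster, mean)
  relabel <- match(km$cluster, as.integer(names(sort(sens,
                                                     decreasing = TRUE))))
  out <- list(
    assignment = data.frame(key = table$key, cluster = relabel,
                            stringsAsFactors = FALSE),
    centers = km$centers[as.integer(names(sort(sens, decreasing = TRUE))), ,
                         drop = FALSE],
    wcss = km$tot.withinss,
    k = as.integer(k),
    seed = as.integer(seed)
  )
  rownames(out$centers) <- seq_len(k)
  class(out) <- "ClusterAssignment"
  out
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment: k =", x$k, "over", nrow(x$assignment),
      "residues; WCSS =", signif(x$wcss, 5), "\n")
  print(table(x$assignment$cluster))
  invisible(x)
}

#' Write clustering results
#'
#' @param table the `ResidueFeatureTable`
#' @param assignment a `ClusterAssignment`
#' @param curve optional [wcss_curve()] result
#' @param csv_path per-residue CSV (residue, entropy, sensitivity, cc,
#'   cluster)
#' @param json_path JSON of centers and the WCSS curve
#' @return invisibly `NULL`
#' @export
write_clusters <- function(table, assignment, curve = NULL, csv_path = NULL,
                           json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- merge(as.data.frame(table)[, c("key", "entropy", "sensitivity",
                                         "cc")],
                assignment$assignment, by = "key", sort = FALSE)
    names(df)[1] <- "residue"
    write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(k = assignment$k, centers = assignment$centers,
           wcss = assignment$wcss,
           curve = if (is.null(curve)) NULL else
             list(k = curve$k, wcss = curve$wcss,
                  suggested_k = curve$suggested_k)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
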