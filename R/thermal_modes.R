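# Temperature-sensitive contact modes: PCA of the contact-frequency x
# temperature matrix, with observations = temperatures and variables =
# contacts. Contacts are centered across temperatures but not scaled to unit
# variance (frequencies already share the [0,1] scale, and scaling would
# inflate noise from near-constant contacts). Each mode is oriented so that
# its temperature scores increase with temperature; contacts that melt with
# temperature then carry negative loadings and contacts that form carry
# positive loadings.

#' Extract thermal contact modes by PCA
#'
#' @param mat a `ContactFrequencyMatrix`
#' @param n_modes number of principal components to retain (default 2; at
#'   most `n_temperatures - 1`)
#' @param top_k number of top-|loading| contacts used when classifying a mode
#'   as melting or forming
#' @return a `ThermalModeResult`: list with `loadings` (contacts x modes,
#'   unit-norm columns), `scores` (temperatures x modes),
#'   `explained_variance` (fractions, non-increasing), `labels` (per mode:
#'   melting / forming / mixed), `temperatures`, `stable_contacts` (keys of
#'   zero-variance contacts dropped before PCA)
#' @export
compute_thermal_modes <- function(mat, n_modes = 2L, top_k = 20L) {
  stopifnot(inherits(mat, "ContactFrequencyMatrix"))
  temps <- mat$temperatures
  if (length(temps) < 3) stop("need at least 3 temperatures for thermal modes")
  X <- t(mat$freq)  # temperatures x contacts
  v <- apply(X, 2, function(x) max(x) - min(x))
  stable <- colnames(X)[v == 0]
  X <- X[, v > 0, drop = FALSE]
  if (ncol(X) == 0) stop("no temperature-dependent variance in contact matrix")
  if (ncol(X) < 2) {
    # single varying contact: rank-1 PCA, handled uniformly below
    n_modes <- 1L
  }
  n_modes <- min(n_modes, length(temps) - 1L, ncol(X))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(n_modes, ncol(pc$rotation)))
  load <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  ev <- pc$sdev^2 / sum(pc$sdev^2)

  # sign convention: regression slope of scores on temperature >= 0
  for (m in seq_along(keep)) {
    slope <- coef(lm(scores[, m] ~ temps))[2]
    if (!is.na(slope) && slope < 0) {
      scores[, m] <- -scores[, m]
      load[, m] <- -load[, m]
    }
  }
  res <- list(
    loadings = load,
    scores = scores,
    explained_variance = ev[keep],
    temperatures = temps,
    stable_contacts = stable,
    top_k = as.integer(top_k)
  )
  class(res) <- "ThermalModeResult"
  res$labels <- classify_modes(res)
  res
}

#' Classify thermal modes as melting, forming or mixed
#'
#' For each mode, the reconstructed frequency trend of each of its top-k
#' |loading| contacts (`score_m(T) * loading_c`) is correlated with
#' temperature (Spearman). A mode is `melting` when >= 75% of its top
#' contacts trend downward with temperature, `forming` when >= 75% trend
#' upward, otherwise `mixed`.
#'
#' @param result a `ThermalModeResult`
#' @param majority fraction of concordant top contacts required (default 0.75)
#' @return character vector of per-mode labels
#' @export
classify_modes <- function(result, majority = 0.75) {
  stopifnot(inherits(result, "ThermalModeResult"))
  temps <- result$temperatures
  vapply(seq_len(ncol(result$loadings)), function(m) {
    l <- result$loadings[, m]
    k <- min(result$top_k, length(l))
    if (k < 2) {
      warning("fewer than 2 top contacts available; labeling mode mixed")
      return("mixed")
    }
    top <- order(abs(l), decreasing = TRUE)[seq_len(k)]
    rho <- vapply(top, function(c) {
      trend <- result$scores[, m] * l[c]
      if (sd(trend) == 0) return(0)
      suppressWarnings(cor(trend, temps, method = "spearman"))
    }, numeric(1))
    neg <- mean(rho < 0)
    pos <- mean(rho > 0)
    if (neg >= majority) "melting"
    else if (pos >= majority) "forming"
    else "mixed"
  }, character(1))
}

#' Top-loading contacts of a mode
#'
#' Under the sign convention used here (mode scores increase with
#' temperature), contacts that melt with temperature carry negative loadings
#' and contacts that form carry positive loadings, so a single mode can hold
#' both groups at its two loading extremes. `direction = "abs"` ranks by
#' |loading|; `"melting"` returns the most negative loadings (the melting
#' side of the mode) and `"forming"` the most positive.
#'
#' @param result a `ThermalModeResult`
#' @param mode mode index (1-based)
#' @param k number of contacts, or a fraction in (0, 1) of the contact count
#' @param direction `"abs"` (default), `"melting"` or `"forming"`
#' @return data.frame with columns `contact`, `loading`, sorted by the
#'   chosen criterion (ties broken by canonical contact-key order)
#' @export
top_contacts <- function(result, mode = 1L, k = 20L,
                         direction = c("abs", "melting", "forming")) {
  direction <- match.arg(direction)
  stopifnot(inherits(result, "ThermalModeResult"))
  if (mode < 1 || mode > ncol(result$loadings)) {
    stop("mode ", mode, " does not exist (", ncol(result$loadings),
         " modes available)")
  }
  l <- setNames(result$loadings[, mode], rownames(result$loadings))
  n <- length(l)
  if (k < 1) k <- ceiling(k * n)
  k <- as.integer(k)
  if (k > n) {
    message("requested ", k, " contacts but only ", n, " available; ",
            "returning all")
    k <- n
  }
  ord <- switch(direction,
    abs = order(-abs(l), names(l)),
    melting = order(l, names(l)),
    forming = order(-l, names(l))
  )
  top <- ord[seq_len(k)]
  data.frame(contact = names(l)[top], loading = unname(l[top]),
             stringsAsFactors = FALSE)
}

#' @export
print.ThermalModeResult <- function(x, ...) {
  cat("ThermalModeResult:", ncol(x$loadings), "modes over",
      length(x$temperatures), "temperatures\n")
  for (m in seq_len(ncol(x$loadings))) {
    cat(sprintf("  mode %d: %s, %.1f%% variance\n", m, x$labels[m],
                100 * x$explained_variance[m]))
  }
  if (length(x$stable_contacts) > 0) {
    cat(" ", length(x$stable_contacts),
        "temperature-stable contacts excluded from PCA\n")
  }
  invisible(x)
}

#' Write thermal-mode results to CSV/JSON
#'
#' @param result a `ThermalModeResult`
#' @param loadings_path CSV of contact, mode, loading, label
#' @param scores_path CSV of temperature, mode, score
#' @param summary_path JSON summary of explained variance and labels
#' @return invisibly, `result`
#' @export
write_thermal_modes <- function(result, loadings_path = NULL,
                                scores_path = NULL, summary_path = NULL) {
  nm <- ncol(result$loadings)
  if (!is.null(loadings_path)) {
    df <- do.call(rbind, lapply(seq_len(nm), function(m) {
      data.frame(contact = rownames(result$loadings), mode = m,
                 loading = result$loadings[, m], label = result$labels[m],
                 stringsAsFactors = FALSE)
    }))
    write.csv(df, loadings_path, row.names = FALSE)
  }
  if (!is.null(scores_path)) {
    df <- do.call(rbind, lapply(seq_len(nm), function(m) {
      data.frame(temperature = result$temperatures, mode = m,
                 score = result$scores[, m])
    }))
    write.csv(df, scores_path, row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(explained_variance = result$explained_variance,
           labels = result$labels,
           n_stable_contacts = length(result$stable_contacts)),
      summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
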