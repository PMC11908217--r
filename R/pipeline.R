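# End-to-end orchestration: contacts -> flexibility -> thermal modes ->
# hydrophobic network -> conservation -> residue clustering, from a single
# validated config, with every stage output written to disk plus a manifest
# of parameters and seeds. Deterministic stages are bit-reproducible for a
# fixed config; stochastic stages (k-means restarts) are reproducible given
# the seed.

#' Build and validate a run configuration
#'
#' @param inputs either `list(synthetic = TRUE)` to run on generated data, or
#'   `list(structure = , trajectories = data.frame(temperature, path),
#'   msa = , msa_query = , chain = )` for real inputs
#' @param contact_threshold minimum mean hydrophobic frequency for a network
#'   edge (default 0.75)
#' @param top_cc_fraction fraction of residues kept in the top-centrality
#'   subnetwork (default 0.20)
#' @param n_modes number of thermal modes (default 2)
#' @param k number of residue clusters (default 4)
#' @param seed master seed
#' @param stride frame stride for contact detection
#' @param types contact types to detect
#' @param outdir output directory
#' @return a validated `RunConfig` list
#' @export
run_config <- function(inputs = list(synthetic = TRUE),
                       contact_threshold = 0.75, top_cc_fraction = 0.20,
                       n_modes = 2L, k = 4L, seed = 1L, stride = 1L,
                       types = c("salt_bridge", "hydrophobic", "hbond"),
                       outdir = tempfile("thermocontact_run_")) {
  if (contact_threshold < 0 || contact_threshold > 1) {
    stop("contact_threshold must lie in [0, 1], got ", contact_threshold)
  }
  if (top_cc_fraction <= 0 || top_cc_fraction > 1) {
    stop("top_cc_fraction must lie in (0, 1], got ", top_cc_fraction)
  }
  if (n_modes < 1) stop("n_modes must be >= 1")
  if (k < 1) stop("k must be >= 1")
  cfg <- list(inputs = inputs, contact_threshold = contact_threshold,
              top_cc_fraction = top_cc_fraction, n_modes = as.integer(n_modes),
              k = as.integer(k), seed = as.integer(seed),
              stride = as.integer(stride), types = types, outdir = outdir)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level fields mirror the arguments of
#'   [run_config()]
#' @return a validated `RunConfig`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$inputs$trajectories)) {
    y$inputs$trajectories <- as.data.frame(y$inputs$trajectories)
  }
  do.call(run_config, y)
}

# Default synthetic study inputs: a toy chain with one scheduled contact per
# supported type, a six-point 283-393 K ladder, and a small family MSA.
.default_synthetic_inputs <- function(cfg) {
  temps <- seq(283, 393, length.out = 6)
  schedule <- data.frame(
    i = c(5, 12, 20, 28, 36),
    j = c(45, 52, 60, 68, 76),
    type = c("salt_bridge", "hydrophobic", "hbond", "cation_pi", "pi_stack")
  )
  # occupancies: melting, stable, forming, melting, stable
  occ <- rbind(
    seq(1, 0, length.out = 6),
    rep(1, 6),
    seq(0, 1, length.out = 6),
    seq(0.9, 0.3, length.out = 6),
    rep(0.8, 6)
  )
  se <- synth_ensemble(schedule, occ, temps, n_frames = 40,
                       n_residues = 80, seed = cfg$seed)
  nres <- sum(se$model$residues$polymer)
  q <- extract_sequence(se$model)
  specs <- lapply(strsplit(q, "")[[1]], function(a) {
    p <- c(0.7, 0.3)
    names(p) <- c(a, if (a == "A") "V" else "A")
    p
  })
  msa <- synth_msa(specs, n_sequences = 60, seed = cfg$seed + 1)
  list(se = se, msa = msa, msa_query = "query",
       chain = se$model$residues$chain[1], temperatures = temps)
}

.load_real_inputs <- function(cfg) {
  inp <- cfg$inputs
  model <- load_structure(inp$structure)
  traj <- inp$trajectories
  ens <- lapply(seq_len(nrow(traj)), function(i) {
    open_ensemble(model, traj$path[i], traj$temperature[i])
  })
  msa <- read_alignment(inp$msa)
  list(se = list(model = model, ensembles = ens), msa = msa,
       msa_query = inp$msa_query,
       chain = if (is.null(inp$chain)) NULL else inp$chain,
       temperatures = traj$temperature)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes CSV / GraphML /
#' newick / JSON / PDB outputs plus `manifest.json` under `cfg$outdir`. Any
#' stage failure aborts with the stage name; stages already completed are
#' listed in the partial manifest.
#'
#' @param cfg a `RunConfig`
#' @return invisibly, a list with all stage results (`contact_matrix`,
#'   `modes`, `graph`, `centrality`, `subnetwork`, `rmsf`, `sensitivity`,
#'   `conservation`, `features`, `clusters`, `wcss`)
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  done <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      jsonlite::write_json(
        list(completed_stages = done, failed_stage = name,
             error = conditionMessage(e)),
        file.path(cfg$outdir, "manifest.json"), auto_unbox = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    done <<- c(done, name)
    res
  }

  inp <- stage("inputs", {
    if (isTRUE(cfg$inputs$synthetic)) .default_synthetic_inputs(cfg)
    else .load_real_inputs(cfg)
  })
  model <- inp$se$model

  mat <- stage("contacts", {
    tabs <- lapply(inp$se$ensembles, contact_frequencies,
                   types = cfg$types, stride = cfg$stride)
    m <- assemble_matrix(tabs)
    write_contact_csv(m, file.path(cfg$outdir, "contacts_tidy.csv"),
                      file.path(cfg$outdir, "contacts_wide.csv"))
    m
  })

  flex <- stage("rmsf", {
    profs <- lapply(inp$se$ensembles, ensemble_rmsf)
    sens <- temperature_sensitivity(profs)
    rmsf_df <- do.call(rbind, lapply(profs, function(p) {
      data.frame(residue = p$key, temperature = attr(p, "temperature"),
                 rmsf = p$rmsf)
    }))
    write.csv(rmsf_df, file.path(cfg$outdir, "rmsf.csv"), row.names = FALSE)
    write.csv(data.frame(residue = sens$key, sensitivity = sens$sensitivity),
              file.path(cfg$outdir, "sensitivity.csv"), row.names = FALSE)
    list(profiles = profs, sensitivity = sens)
  })

  modes <- stage("modes", {
    m <- compute_thermal_modes(mat, n_modes = cfg$n_modes)
    write_thermal_modes(m,
                        file.path(cfg$outdir, "mode_loadings.csv"),
                        file.path(cfg$outdir, "mode_scores.csv"),
                        file.path(cfg$outdir, "mode_summary.json"))
    m
  })

  net <- stage("network", {
    g <- build_hydrophobic_graph(mat, threshold = cfg$contact_threshold)
    cc <- closeness_centrality(g)
    sub <- top_cc_subnetwork(g, cc, fraction = cfg$top_cc_fraction)
    write_network(g, cc, file.path(cfg$outdir, "network_edges.csv"),
                  file.path(cfg$outdir, "network.graphml"),
                  file.path(cfg$outdir, "closeness.csv"))
    list(graph = g, cc = cc, subnetwork = sub)
  })

  cons <- stage("conserve", {
    prof <- shannon_entropy(inp$msa)
    mapped <- map_to_structure(prof, inp$msa, inp$msa_query, model,
                               chain = inp$chain)
    write.csv(prof, file.path(cfg$outdir, "entropy_columns.csv"),
              row.names = FALSE)
    write.csv(mapped, file.path(cfg$outdir, "entropy_residues.csv"),
              row.names = FALSE)
    project_to_bfactor(model, setNames(mapped$normalized, mapped$key),
                       file.path(cfg$outdir, "entropy_projected.pdb"))
    list(profile = prof, mapped = mapped)
  })

  clus <- stage("cluster", {
    feats <- assemble_features(
      entropy = setNames(cons$mapped$normalized, cons$mapped$key),
      sensitivity = flex$sensitivity,
      cc = net$cc
    )
    kmax <- min(10L, nrow(feats) - 1L)
    curve <- wcss_curve(feats, k_range = seq_len(kmax), seed = cfg$seed)
    assign <- kmeans_cluster(feats, k = cfg$k, seed = cfg$seed)
    write_clusters(feats, assign, curve,
                   file.path(cfg$outdir, "clusters.csv"),
                   file.path(cfg$outdir, "clusters.json"))
    list(features = feats, curve = curve, assignment = assign)
  })

  stage("report", {
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("thermocontact")),
           seed = cfg$seed,
           parameters = cfg[c("contact_threshold", "top_cc_fraction",
                              "n_modes", "k", "stride", "types")],
           temperatures = inp$temperatures,
           completed_stages = c(done, "report")),
      file.path(cfg$outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    NULL
  })

  invisible(list(
    model = model, contact_matrix = mat, modes = modes,
    graph = net$graph, centrality = net$cc, subnetwork = net$subnetwork,
    rmsf = flex$profiles, sensitivity = flex$sensitivity,
    conservation = cons, features = clus$features, wcss = clus$curve,
    clusters = clus$assignment, outdir = cfg$outdir
  ))
}

#' Project a per-residue scalar into the B-factor column of a PDB file
#'
#' Values are min-max scaled to `[0, 99.99]`; residues without a value get 0.
#'
#' @param model a `StructureModel`
#' @param values named numeric vector keyed by residue key
#' @param path output PDB path
#' @return `path`, invisibly
#' @export
project_to_bfactor <- function(model, values, path) {
  keys <- model$residues$key
  if (!any(names(values) %in% keys)) {
    stop("no overlap between value names and model residue keys")
  }
  v <- values[match(keys, names(values))]
  rng <- range(v, na.rm = TRUE)
  scaled <- if (diff(rng) == 0) {
    ifelse(is.na(v), 0, 99.99)
  } else {
    ifelse(is.na(v), 0, (v - rng[1]) / diff(rng) * 99.99)
  }
  per_atom <- scaled[match(model$atom$reskey, keys)]
  write_structure(model, path, bfactor = per_atom)
}
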