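#' Serialize / restore an MSM as JSON
#'
#' @param msm An `msm` object.
#' @param path JSON path.
#' @export
write_msm <- function(msm, path) {
  payload <- list(
    transition = msm$transition, pi = msm$pi, active = msm$active,
    counts = msm$counts, lag = msm$lag, estimator = msm$estimator,
    converged = msm$converged, n_states_total = msm$n_states_total,
    frame_interval = msm$frame_interval
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_msm
#' @export
read_msm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(transition = as.matrix(p$transition), pi = as.numeric(p$pi),
         active = as.integer(p$active), counts = as.matrix(p$counts),
         lag = as.integer(p$lag), estimator = p$estimator,
         converged = isTRUE(p$converged), iterations = NA_integer_,
         n_states_total = as.integer(p$n_states_total),
         frame_interval = p$frame_interval),
    class = "msm"
  )
}

#' Validate and normalise a pipeline run configuration
#'
#' @param config A list or path to a YAML/JSON file. Required fields:
#'   `seed`, `out_dir`. A `synthetic` block (parameters of
#'   [ensemble_spec()] plus `threshold`) drives a fully synthetic run;
#'   `tica` (`lag_frames`, `var_cutoff`), `cluster` (`k`), `msm`
#'   (`lag_frames`, `estimator`), `dock` (`base`, `scale`, `temperature`)
#'   tune the stages.
#' @return Normalised config list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  problems <- character()
  if (is.null(config$seed)) problems <- c(problems, "seed: required")
  if (is.null(config$out_dir)) problems <- c(problems, "out_dir: required")
  if (is.null(config$synthetic))
    problems <- c(problems, "synthetic: required (this build runs synthetic ensembles)")
  if (length(problems) > 0L)
    stop("invalid run config:\n  ", paste(problems, collapse = "\n  "))
  config$tica <- utils::modifyList(
    list(lag_frames = 10L, var_cutoff = 0.9), config$tica %||% list())
  config$cluster <- utils::modifyList(
    list(k = 10L), config$cluster %||% list())
  config$msm <- utils::modifyList(
    list(lag_frames = 5L, estimator = "reversible_mle"),
    config$msm %||% list())
  config$dock <- utils::modifyList(
    list(base = 3L, scale = 2000L, temperature = 310),
    config$dock %||% list())
  config
}

spec_from_config <- function(config) {
  sy <- config$synthetic
  ensemble_spec(
    transition = matrix(unlist(sy$transition), nrow = length(sy$transition),
                        byrow = TRUE),
    dihedral_means = matrix(unlist(sy$dihedral_means),
                            nrow = length(sy$dihedral_means), byrow = TRUE),
    dihedral_kappa = sy$dihedral_kappa %||% 8,
    volume_mean = unlist(sy$volume_mean), volume_sd = unlist(sy$volume_sd),
    score_mean = unlist(sy$score_mean), score_sd = unlist(sy$score_sd),
    n_traj = sy$n_traj %||% 4L, n_frames = sy$n_frames %||% 5000L,
    frame_interval = sy$frame_interval %||% 20, seed = config$seed
  )
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order on a synthetic
#' reference ensemble: `simulate` (generate features/volumes), `msm` (tICA,
#' clustering, MSM fit), `popen` (opening probability at the configured
#' threshold), `sample` (docking structure plan), `aggregate` (synthetic
#' docking table and ensemble free energy). Every output is written under
#' `out_dir` and listed, with its MD5 checksum, in the returned manifest.
#'
#' @param config See [load_run_config()].
#' @param stages Character subset of
#'   `c("simulate", "msm", "popen", "sample", "aggregate")` (default all).
#' @return Manifest list: `artifacts` (data.frame path/md5), `results`
#'   (key numbers computed), `seed`.
#' @export
run_pipeline <- function(config, stages = c("simulate", "msm", "popen",
                                            "sample", "aggregate")) {
  config <- load_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  results <- list(seed = config$seed)
  artifacts <- character()
  spec <- spec_from_config(config)
  threshold <- config$synthetic$threshold %||% 0
  ens <- NULL; model <- NULL; cl <- NULL

  need_ens <- function() {
    if (is.null(ens)) ens <<- simulate_reference_ensemble(spec)
    ens
  }

  if ("simulate" %in% stages) {
    need_ens()
    write_volume_series(ens$volumes, out("volumes.csv"))
    artifacts <- c(artifacts, out("volumes.csv"))
  }
  if (any(c("msm", "popen", "sample", "aggregate") %in% stages)) {
    need_ens()
    tica <- fit_tica(ens$features, lag = config$tica$lag_frames,
                     var_cutoff = config$tica$var_cutoff)
    proj <- project_tica(tica, ens$features)
    cl <- cluster_assign(proj, k = config$cluster$k,
                         seed = derive_seed(config$seed, 1L))
    model <- fit_msm(cl$dtrajs, lag = config$msm$lag_frames,
                     estimator = config$msm$estimator,
                     frame_interval = spec$frame_interval)
    write_msm(model, out("msm.json"))
    artifacts <- c(artifacts, out("msm.json"))
    results$n_active_states <- length(model$active)
  }
  if ("popen" %in% stages) {
    w <- frame_weights(model, cl$dtrajs)
    po <- p_open(ens$volumes, w, holo_volume = threshold)
    results$p_open <- po$p_open
    jsonlite::write_json(list(p_open = po$p_open,
                              holo_volume = threshold,
                              seed = config$seed),
                         out("popen.json"), auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, out("popen.json"))
  }
  samples <- NULL
  if (any(c("sample", "aggregate") %in% stages)) {
    samples <- sample_docking_structures(
      model, cl$dtrajs, base = config$dock$base, scale = config$dock$scale,
      seed = derive_seed(config$seed, 2L))
    utils::write.csv(samples, out("samples.csv"), row.names = FALSE)
    artifacts <- c(artifacts, out("samples.csv"))
  }
  if ("aggregate" %in% stages) {
    scores <- make_docking_table(spec, ens$states, samples,
                                 seed = derive_seed(config$seed, 3L),
                                 path = out("scores.csv"))
    artifacts <- c(artifacts, out("scores.csv"))
    rec <- ingest_docking_scores(scores, cl$dtrajs, msm = model)
    est <- aggregate_binding_free_energy(
      rec, model, samples, temperature = config$dock$temperature)
    results$dG_total <- est$dG_total
    results$K_d <- est$K_d
    jsonlite::write_json(list(dG_total = est$dG_total, K_d = est$K_d,
                              temperature = est$temperature,
                              seed = config$seed),
                         out("affinity.json"), auto_unbox = TRUE,
                         digits = NA)
    artifacts <- c(artifacts, out("affinity.json"))
  }
  manifest <- list(
    artifacts = data.frame(path = artifacts,
                           md5 = unname(tools::md5sum(artifacts)),
                           stringsAsFactors = FALSE),
    results = results, seed = config$seed
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest
}
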