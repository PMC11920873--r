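#' Run the full multi-omics eigen-phase pipeline
#'
#' Orchestrates the stages — preprocess, stratify, align on a unified
#' timeline, estimate inter-dataset lags with perturbation CIs, and
#' interpret the reference's molecule-eigenvectors — over a declarative
#' configuration, writing per-stage outputs and a machine-readable
#' `summary.json` under `outdir`.
#'
#' The configuration is a named list (or a YAML file path, read with the
#' `yaml` package when installed):
#' \describe{
#'   \item{datasets}{Named list; each entry has either `path` + `meta_path`
#'     (TSV on disk) or `matrix` (an [omics_matrix()]), optionally
#'     `curve`/`curve_path` (oxygen [indicator_curve()]) and logical
#'     `log_transform` / `normalize` preprocessing switches.}
#'   \item{reference}{Name of the reference dataset (exactly one).}
#'   \item{gene_sets}{Optional GMT path or named list of sets.}
#'   \item{params}{Analysis parameters with defaults: `levels = c(1, 2)`,
#'     `resolution = 0.001` h, `max_lag = NULL` (auto), `ci_R = 1000`,
#'     `ci_fraction = 0.1`, `marker_R = 1000`, `marker_p_max = 0.01`,
#'     `min_set_size = 5`, `seed = 1`.}
#'   \item{outdir}{Output directory; `NULL` suppresses file output.}
#' }
#'
#' @param config Configuration list or YAML path.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)
  p <- cfg$params
  set.seed(p$seed)

  mats <- lapply(names(cfg$datasets), function(nm) {
    d <- cfg$datasets[[nm]]
    mat <- if (!is.null(d$matrix)) d$matrix
    else read_omics_table(d$path, d$meta_path, omics_label = nm)
    if (isTRUE(d$log_transform)) mat <- log_transform(mat)
    if (isTRUE(d$normalize))
      mat <- normalize_to_reference(mat, select_reference_sample(mat))
    mat
  })
  names(mats) <- names(cfg$datasets)

  decs <- lapply(mats, stratify)
  contribs <- lapply(decs, relative_contributions)
  phases <- lapply(decs, function(d)
    tryCatch(call_phases(d), error = function(e) NULL))

  ref <- cfg$reference
  curves <- lapply(cfg$datasets, function(d) {
    if (!is.null(d$curve)) d$curve
    else if (!is.null(d$curve_path)) read_curve(d$curve_path)
    else NULL
  })
  timelines <- lapply(names(mats), function(nm) {
    if (nm == ref || is.null(curves[[nm]]) || is.null(curves[[ref]]))
      return(identity_timeline(mats[[nm]]$sample_times, nm, ref))
    qc <- curves[[nm]]
    rc <- crop_curve(curves[[ref]], min(qc$times), max(qc$times))
    align_to_reference(rc, qc, mats[[nm]]$sample_times)
  })
  names(timelines) <- names(mats)

  lag_reports <- list()
  for (nm in setdiff(names(mats), ref)) {
    est <- lag_ci(decs[[nm]], decs[[ref]],
                  timelines[[nm]], timelines[[ref]],
                  levels = p$levels, R = p$ci_R, fraction = p$ci_fraction,
                  seed = p$seed, resolution = p$resolution,
                  max_lag = p$max_lag)
    lag_reports[[nm]] <- list(
      pair = est$pair, lag_h = est$lag, lag_min = 60 * est$lag,
      rho = est$rho, ci_h = est$ci,
      per_level = est$per_level, R = est$n_perturbations)
  }

  refdec <- decs[[ref]]
  enrich <- NULL
  if (!is.null(cfg$gene_sets)) {
    sets <- if (is.character(cfg$gene_sets)) read_gmt(cfg$gene_sets)
    else cfg$gene_sets
    enrich <- lapply(p$levels, function(k) {
      u <- refdec$u[, level_col(refdec, k)]
      names(u) <- refdec$molecule_ids
      wilcoxon_enrich(u, sets, min_size = p$min_set_size)
    })
    names(enrich) <- paste0("level", p$levels)
  }
  markers <- marker_randomization(refdec, k = 1L, R = p$marker_R,
                                  seed = p$seed, p_max = p$marker_p_max)
  contrib_tables <- lapply(setdiff(names(mats), ref), function(nm)
    tryCatch(phase_contributions(mats[[nm]], refdec),
             error = function(e) NULL))
  names(contrib_tables) <- setdiff(names(mats), ref)

  summary <- list(
    reference = ref,
    seed = p$seed,
    contributions = lapply(contribs, function(cc)
      list(top2 = cc$top2, entropy = cc$entropy,
           normalized_entropy = cc$normalized_entropy,
           ratios = cc$ratios)),
    phases = lapply(phases, function(ph)
      if (is.null(ph)) NULL else list(cyclic_order = ph$cyclic_order,
                                      calls = ph$calls)),
    lags = lag_reports,
    n_markers = sum(markers$marker),
    phase_contributions = lapply(contrib_tables, function(ct)
      if (is.null(ct)) NULL else list(contributions = as.list(ct$contributions),
                                      cv = ct$cv)),
    parameters = p)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(decs))
      write_decomposition(decs[[nm]], file.path(cfg$outdir, nm), phases[[nm]])
    utils::write.table(markers, file.path(cfg$outdir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enrich))
      for (nm in names(enrich))
        utils::write.table(enrich[[nm]],
                           file.path(cfg$outdir, paste0("enrich_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(summary)
}

validate_pipeline_config <- function(config) {
  if (is.null(config$datasets) || !length(config$datasets))
    stop("config$datasets is required")
  if (is.null(names(config$datasets)) || any(!nzchar(names(config$datasets))))
    stop("datasets must be named")
  if (is.null(config$reference))
    stop("config$reference (the reference dataset name) is required")
  if (!config$reference %in% names(config$datasets))
    stop("reference dataset '", config$reference, "' not among datasets")
  for (nm in names(config$datasets)) {
    d <- config$datasets[[nm]]
    if (is.null(d$matrix)) {
      if (is.null(d$path) || is.null(d$meta_path))
        stop("dataset '", nm, "' needs matrix or path + meta_path")
      for (f in c(d$path, d$meta_path, d$curve_path))
        if (!is.null(f) && !file.exists(f))
          stop("dataset '", nm, "': file not found: ", f)
    }
  }
  defaults <- list(levels = c(1L, 2L), resolution = 0.001, max_lag = NULL,
                   ci_R = 1000L, ci_fraction = 0.1, marker_R = 1000L,
                   marker_p_max = 0.01, min_set_size = 5L, seed = 1L)
  config$params <- utils::modifyList(defaults, config$params %||% list())
  config
}
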