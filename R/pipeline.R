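# Orchestration of the simulate -> fit -> derive -> regress -> report
# pipeline with schema validation and a checksummed run manifest.

#' Table schemas used by the pipeline
#'
#' Column specifications (name, type, optional range) for the CSV tables
#' the pipeline reads and writes.
#'
#' @param name One of `"measurements"`, `"metadata"`, `"fits"`, `"derived"`.
#' @return List of column specs.
#' @export
table_schema <- function(name = c("measurements", "metadata", "fits",
                                  "derived")) {
  name <- match.arg(name)
  col <- function(nm, type, min = -Inf, max = Inf)
    list(name = nm, type = type, min = min, max = max)
  switch(name,
    measurements = list(col("subject_id", "character"),
                        col("age", "numeric", 0, 25),
                        col("height", "numeric", 30, 220),
                        col("weight", "numeric", 0, 150)),
    metadata = list(col("subject_id", "character"),
                    col("birth_date", "character"),
                    col("gestational_age_days", "numeric", 150, 320),
                    col("birth_length", "numeric", 30, 65),
                    col("birth_weight", "numeric", 0.3, 7),
                    col("mother_height", "numeric", 120, 220),
                    col("father_height", "numeric", 120, 230),
                    col("menarche_mode", "character")),
    fits = list(col("subject_id", "character"),
                col("Emax", "numeric", 0, 200),
                col("Qmax", "numeric", 0, 200),
                col("Pmax", "numeric", 0, 200),
                col("Etsc", "numeric", 0.4, 2.5),
                col("Ptsc", "numeric", 0.4, 2.5),
                col("AgeP50", "numeric", 5, 20)),
    derived = list(col("subject_id", "character"),
                   col("age_menarche", "numeric", 6, 20)))
}

#' Validate a CSV table against a schema
#'
#' Checks column presence, type, and value ranges; every violation is
#' reported, not just the first.
#'
#' @param path CSV file path.
#' @param schema List of column specs ([table_schema()]).
#' @return List with `ok` (logical) and `violations` (character vector).
#' @export
validate_table <- function(path, schema) {
  if (!file.exists(path)) stop(sprintf("I/O error: cannot read '%s'", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  violations <- character()
  for (sp in schema) {
    if (!sp$name %in% names(tab)) {
      violations <- c(violations,
                      sprintf("missing column '%s' in %s", sp$name, path))
      next
    }
    x <- tab[[sp$name]]
    if (sp$type == "numeric") {
      if (!is.numeric(x)) {
        violations <- c(violations,
                        sprintf("column '%s' is not numeric", sp$name))
        next
      }
      bad <- which(!is.na(x) & (x < sp$min | x > sp$max))
      if (length(bad) > 0)
        violations <- c(violations,
                        sprintf("column '%s': %d value(s) outside [%g, %g] (e.g. row %d: %g)",
                                sp$name, length(bad), sp$min, sp$max,
                                bad[1], x[bad[1]]))
    }
  }
  list(ok = length(violations) == 0, violations = violations)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory.
#' @param seed Master seed recorded in the manifest and used for the
#'   generator.
#' @param n_subjects Cohort size for the simulate stage.
#' @param consts [qeps_shape()].
#' @param generator [cohort_config()] (seed and size overridden by `seed`
#'   and `n_subjects`).
#' @param fit [qeps_fit_config()].
#' @param alpha Stepwise entry/removal threshold.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1990, n_subjects = 793,
                       consts = qeps_shape(), generator = cohort_config(),
                       fit = qeps_fit_config(), alpha = 0.05) {
  generator$seed <- seed
  generator$n_subjects <- n_subjects
  structure(list(out_dir = out_dir, seed = seed, n_subjects = n_subjects,
                 consts = consts, generator = generator, fit = fit,
                 alpha = alpha), class = "run_config")
}

write_stage_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes `simulate -> fit -> derive -> regress` and writes one CSV per
#' stage plus a JSON manifest with the seed, the shape constants and an
#' md5 checksum of every file. Any stage failure aborts with an error
#' naming the stage. Reruns with the same configuration are byte-identical.
#'
#' @param config [run_config()].
#' @param progress Print fit progress dots (default FALSE).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    res
  }

  coh <- stage("simulate", simulate_cohort(config$generator, config$consts))
  paths$measurements <- write_stage_csv(
    coh$measurements, file.path(config$out_dir, "measurements.csv"))
  paths$metadata <- write_stage_csv(
    coh$metadata, file.path(config$out_dir, "metadata.csv"))
  paths$truth <- write_stage_csv(
    coh$truth, file.path(config$out_dir, "truth.csv"))

  v <- validate_table(paths$measurements, table_schema("measurements"))
  if (!v$ok) stop(sprintf("pipeline stage 'fit' failed: %s",
                          paste(v$violations, collapse = "; ")))
  fits <- stage("fit", fit_cohort(coh$measurements, config$consts,
                                  config$fit, progress = progress))
  paths$fits <- write_stage_csv(fits, file.path(config$out_dir, "fits.csv"))

  derived <- stage("derive", derive_cohort(fits, coh$measurements,
                                           coh$metadata, config$consts))
  paths$derived <- write_stage_csv(derived,
                                   file.path(config$out_dir, "derived.csv"))

  models <- stage("regress", milestone_models(derived, "age_menarche",
                                              alpha = config$alpha))
  report <- do.call(rbind, lapply(names(models), function(g) {
    m <- models[[g]]$model
    if (is.null(m) || nrow(m$table) == 0)
      return(data.frame(milestone = g, variable = NA_character_,
                        beta = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        partial_r2 = NA_real_, model_r2 = models[[g]]$r2,
                        n = if (is.null(m)) NA_integer_ else m$n))
    cbind(milestone = g, m$table, model_r2 = m$r2, n = m$n)
  }))
  paths$report <- write_stage_csv(report,
                                  file.path(config$out_dir, "regression_report.csv"))
  uni <- do.call(rbind, lapply(names(models), function(g)
    cbind(milestone = g, models[[g]]$univariable)))
  paths$univariable <- write_stage_csv(uni,
    file.path(config$out_dir, "univariable_report.csv"))

  manifest <- list(
    seed = config$seed, n_subjects = config$n_subjects,
    shape_constants = unclass(config$consts),
    alpha = config$alpha,
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [run_config()],
#'   [qeps_shape()], [cohort_config()] and [qeps_fit_config()].
#' @return [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  consts <- do.call(qeps_shape, y$shape %||% list())
  generator <- do.call(cohort_config, y$generator %||% list())
  fitcfg <- do.call(qeps_fit_config, y$fit %||% list())
  run_config(out_dir = y$out_dir %||% "qeps_run",
             seed = y$seed %||% 1990,
             n_subjects = y$n_subjects %||% generator$n_subjects,
             consts = consts, generator = generator, fit = fitcfg,
             alpha = y$alpha %||% 0.05)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
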