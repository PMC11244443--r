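#' Read and write two-column time series
#'
#' Series travel as tab-delimited text with an explicit unit-bearing
#' header: `time_min` plus either `bac_g_dl` (%BAC in g/dL, subject data)
#' or `conc_mol_m3` (model-side concentrations). The header decides whether
#' unit conversion applies downstream.
#'
#' @param path File path.
#' @return `read_series()`: a `subject_series` (for `bac_g_dl`) or a
#'   `sensor_series` (for `conc_mol_m3`).
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop("empty data section in ", path)
  if (!"time_min" %in% names(df))
    stop(path, ": first column must be 'time_min'")
  unit_col <- intersect(c("bac_g_dl", "conc_mol_m3"), names(df))
  if (length(unit_col) != 1)
    stop(path, ": need exactly one of 'bac_g_dl' or 'conc_mol_m3' columns")
  bad <- which(!is.finite(df$time_min) | !is.finite(df[[unit_col]]))
  if (length(bad))
    stop(path, ": malformed numeric values at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (unit_col == "bac_g_dl") {
    structure(list(subject = NA_integer_, times_min = df$time_min,
                   bac_gdl = df$bac_g_dl, onset_min = NA_real_),
              class = "subject_series")
  } else {
    structure(list(times_min = df$time_min, conc = df$conc_mol_m3),
              class = "sensor_series")
  }
}

#' @rdname read_series
#' @param x A `subject_series`, `sensor_series` or `average_series`.
#' @export
write_series <- function(x, path) {
  df <- if (inherits(x, "subject_series")) {
    data.frame(time_min = x$times_min, bac_g_dl = x$bac_gdl)
  } else if (inherits(x, "average_series")) {
    data.frame(time_min = x$times_min, conc_mol_m3 = x$conc_mol_m3)
  } else if (inherits(x, "sensor_series")) {
    data.frame(time_min = x$times_min, conc_mol_m3 = x$conc)
  } else stop("cannot serialize object of class ", class(x)[1])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' End-to-end pipeline: cohort, average, three-family fit, ranking
#'
#' Generates (or ingests) a cohort, averages it, fits all three input
#' profile families against the average, and writes every artifact plus a
#' manifest to the output directory. A run is reproducible from its config
#' and seed alone; every output records the config hash and seed.
#'
#' @param config Named list (or path to a YAML file) with any of:
#'   `out_dir` (required), `seed`, `data_files` (existing subject files;
#'   if absent a synthetic cohort is generated), `cohort` (overrides for
#'   [cohort_spec()]), `solver` (overrides for [solver_config()]),
#'   `n_samples` (Monte Carlo budget per family), `families`, `cutoff_min`.
#' @return Invisibly, a list with the average series, the three
#'   `optimization_result`s and the ranking (families sorted ascending by
#'   objective).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config needs 'out_dir'")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  cohort <- stage("cohort", {
    if (!is.null(config$data_files)) {
      lapply(config$data_files, read_series)
    } else {
      cspec <- do.call(cohort_spec,
                       modifyList(list(seed = seed),
                                  as.list(config$cohort %||% list())))
      co <- generate_cohort(cspec)
      for (s in co)
        write_series(s, file.path(out, sprintf("subject_%02d.tsv", s$subject)))
      co
    }
  })

  cutoff <- config$cutoff_min %||% 130
  avg <- stage("average", average_series(cohort, cutoff_min = cutoff))
  write_series(avg, file.path(out, "average.tsv"))

  scfg <- do.call(solver_config, as.list(config$solver %||% list()))
  families <- unlist(config$families %||%
                       c("piecewise_linear", "exponential_linear", "hoerl"))
  stack <- default_layer_stack()
  opt <- as.list(config$optimization %||% list())
  opt$n_samples <- opt$n_samples %||% config$n_samples %||% 10000
  scale <- stage("fit", input_scale(avg, stack, scfg))
  fits <- stage("fit", lapply(families, function(fam) {
    box <- default_parameter_box(fam, avg, scale = scale)
    spec <- do.call(optimization_spec,
                    c(list(family = fam, lower = box$lower,
                           upper = box$upper, seed = seed), opt))
    fit_profile(fam, avg, spec = spec, stack = stack, config = scfg)
  }))
  names(fits) <- families

  ranking <- families[order(vapply(fits, `[[`, 0, "objective"))]
  report <- lapply(fits, function(f)
    list(family = f$family, params = as.list(f$params),
         objective = f$objective, mc_best_value = f$mc_best_value,
         seed = f$seed))
  yaml::write_yaml(list(config_hash = cfg_hash, seed = seed,
                        ranking = as.list(ranking), fits = report),
                   file.path(out, "fit_report.yaml"))
  yaml::write_yaml(list(config_hash = cfg_hash, seed = seed,
                        package = "tracsim",
                        version = as.character(utils::packageVersion("tracsim")),
                        cutoff_min = cutoff,
                        n_subjects = length(cohort),
                        files = list.files(out)),
                   file.path(out, "manifest.yaml"))
  invisible(list(average = avg, fits = fits, ranking = ranking,
                 config_hash = cfg_hash))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
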