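# End-to-end experiment runners: simulate -> measure -> classify -> test,
# with reproducibility manifests. Configuration is a plain named list, or a
# YAML file with the same structure.

#' Read a run configuration
#'
#' @param config a named list, or the path to a YAML file containing one.
#' @return the validated configuration list (class \code{"run_config"}).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file '%s' does not exist", config),
           call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  if (!is.null(config$output_dir) && !dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  config$master_seed <- as.integer(config$master_seed %||% 1L)
  class(config) <- c("run_config", "list")
  config
}

# md5 of the canonicalized config, for the manifest
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

manifest_block <- function(config, params) {
  list(package_version = as.character(utils::packageVersion("lacoquant")),
       master_seed = config$master_seed,
       config_md5 = config_hash(config),
       parameters = params)
}

#' Run a full morphology experiment
#'
#' Generates (or accepts pre-generated) cohorts of synthetic nuclei,
#' measures every cell, classifies decondensation of each test cohort
#' against the control quantile threshold, and runs the statistical
#' battery: Shapiro-Wilk/Levene gate, Wilcoxon rank-sum of every test
#' cohort versus control with Bonferroni cutoff, Pearson correlation of
#' normalized intensity versus surface factor per cohort, and box-plot
#' summaries. Per-cell failures are logged and skipped; more than 20\%
#' failures aborts the run.
#'
#' The configuration needs: \code{cohorts}, a named list in which each
#' element holds \code{scene_spec} arguments (the name is the construct
#' label); \code{control_label}; optionally \code{n_per_spec} (default
#' 30), \code{master_seed}, \code{analysis} (\code{smoothing_sigma},
#' \code{min_volume}, \code{control_quantile}, \code{m}, \code{alpha},
#' \code{calibration_factor}) and \code{output_dir}.
#'
#' @param config list or YAML path (see \code{\link{read_run_config}}).
#' @return report list (invisibly written to \code{output_dir} as JSON/CSV
#'   when configured) with elements \code{cohort_table},
#'   \code{classification}, \code{normality}, \code{wilcoxon},
#'   \code{pearson}, \code{box_stats}, \code{failures}, \code{manifest}.
#' @export
run_morphology_experiment <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$cohorts) || length(config$cohorts) < 2L)
    stop("config$cohorts must name at least a control and one test cohort",
         call. = FALSE)
  ctrl <- config$control_label %||% names(config$cohorts)[1]
  if (!ctrl %in% names(config$cohorts))
    stop(sprintf("control label '%s' is not among the cohorts", ctrl),
         call. = FALSE)
  an <- config$analysis %||% list()
  smoothing_sigma <- an$smoothing_sigma %||% 0.1
  min_volume <- an$min_volume %||% 0.05
  control_quantile <- an$control_quantile %||% 0.20
  alpha <- an$alpha %||% 0.05
  m <- an$m %||% (length(config$cohorts) - 1L)
  calibration <- an$calibration_factor %||% 1

  specs <- lapply(config$cohorts, function(args)
    do.call(scene_spec, args[setdiff(names(args), "n")]))
  coh <- generate_cohort(specs, n_per_spec = config$n_per_spec %||% 30L,
                         master_seed = config$master_seed)

  rows <- list(); failures <- character(0)
  for (id in names(coh$stacks)) {
    res <- tryCatch(
      measure_domain(coh$stacks[[id]], smoothing_sigma = smoothing_sigma,
                     min_volume = min_volume,
                     calibration_factor = calibration),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", id, conditionMessage(res)))
      next
    }
    mrow <- coh$manifest[coh$manifest$cell_id == id, ]
    rows[[id]] <- data.frame(
      cell_id = id, construct_label = mrow$construct_label,
      volume = res$volume, surface_area = res$surface_area,
      surface_factor = res$surface_factor,
      total_intensity = res$total_intensity,
      mean_intensity = res$mean_intensity,
      normalized_intensity = res$normalized_intensity,
      true_surface_factor = mrow$true_surface_factor,
      stringsAsFactors = FALSE)
  }
  if (length(failures) > 0.2 * nrow(coh$manifest))
    stop(sprintf("aborting: %d of %d cells failed measurement:\n%s",
                 length(failures), nrow(coh$manifest),
                 paste(failures, collapse = "\n")), call. = FALSE)
  tab <- validate_cohort_table(do.call(rbind, rows))
  sf_by <- split(tab$surface_factor, tab$construct_label)
  test_labels <- setdiff(names(config$cohorts), ctrl)
  classification <- lapply(test_labels, function(lb)
    classify_decondensed(sf_by[[lb]], sf_by[[ctrl]], control_quantile))
  names(classification) <- test_labels
  gate <- normality_gate(sf_by[c(ctrl, test_labels)], alpha = alpha)
  wil <- wilcoxon_vs_control(sf_by[[ctrl]], sf_by[test_labels], m = m,
                             alpha = alpha)
  pear <- lapply(split(tab, tab$construct_label), function(d)
    tryCatch(pearson_intensity_vs_shape(d), error = function(e)
      conditionMessage(e)))
  report <- list(
    cohort_table = tab,
    classification = classification,
    normality = gate,
    wilcoxon = wil,
    pearson = pear,
    box_stats = cohort_box_stats(sf_by),
    failures = failures,
    manifest = manifest_block(config, list(
      control_label = ctrl, n_per_spec = config$n_per_spec %||% 30L,
      smoothing_sigma = smoothing_sigma, min_volume = min_volume,
      control_quantile = control_quantile, m = m, alpha = alpha,
      bonferroni_cutoff = alpha / m, calibration_factor = calibration)))
  write_morphology_report(report, config$output_dir)
  report
}

write_morphology_report <- function(report, output_dir) {
  if (is.null(output_dir)) return(invisible(NULL))
  write_cohort_csv(report$cohort_table,
                   file.path(output_dir, "cohort_table.csv"))
  utils::write.csv(report$box_stats,
                   file.path(output_dir, "box_stats.csv"),
                   row.names = FALSE)
  slim <- report
  slim$cohort_table <- NULL
  slim$classification <- lapply(report$classification, function(cl)
    cl[c("threshold", "control_quantile", "percent_decondensed",
         "control_percent_decondensed")])
  jsonlite::write_json(slim, file.path(output_dir, "morphology_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(NULL)
}

#' Run a full kinetics experiment
#'
#' Simulates (per scenario) a cohort of FLIP/FRAP curves, normalizes and
#' fits each with the bi-exponential decomposition, and reports the
#' recovered pool fractions and half-times together with
#' recovery-versus-truth deltas.
#'
#' The configuration needs \code{scenarios}: either the string
#' \code{"default"} (all rows of \code{\link{flip_scenarios}}) or a named
#' list in which each element holds \code{f_bound}, \code{thalf_fast},
#' \code{thalf_slow}, \code{noise_sigma} and optionally \code{n_curves}
#' and \code{mode}; optionally \code{master_seed}, \code{n_curves}
#' (default 50), \code{fit} (\code{t_start}, \code{offset},
#' \code{average_first}) and \code{output_dir}.
#'
#' @param config list or YAML path.
#' @return report list: per-scenario cohort fits, pool summaries and
#'   truth deltas, plus a manifest.
#' @export
run_kinetics_experiment <- function(config) {
  config <- read_run_config(config)
  sc <- config$scenarios
  if (is.null(sc) || (is.list(sc) && length(sc) == 0L))
    stop("config$scenarios must not be empty", call. = FALSE)
  if (identical(sc, "default")) {
    tabsc <- flip_scenarios()
    sc <- lapply(seq_len(nrow(tabsc)), function(i) as.list(tabsc[i, ]))
    names(sc) <- tabsc$scenario
  }
  fit_opts <- config$fit %||% list()
  n_default <- config$n_curves %||% 50L
  out <- list()
  for (i in seq_along(sc)) {
    s <- sc[[i]]
    nm <- names(sc)[i] %||% paste0("scenario", i)
    curves <- simulate_flip_cohort(
      f_bound = s$f_bound, thalf_fast = s$thalf_fast,
      thalf_slow = s$thalf_slow, noise_sigma = s$noise_sigma %||% 0.02,
      n_curves = s$n_curves %||% n_default,
      master_seed = derive_seed(config$master_seed, i),
      mode = s$mode %||% "FLIP")
    ch <- fit_cohort(curves, average_first = fit_opts$average_first %||%
                       FALSE, t_start = fit_opts$t_start %||% 0,
                     offset = fit_opts$offset %||% FALSE)
    smm <- ch$summary
    out[[nm]] <- list(
      parameters = s,
      pool = list(free_percent = 100 * smm["f_fast", "mean"],
                  bound_percent = 100 * smm["f_slow", "mean"],
                  thalf_fast = smm["thalf_fast", "mean"],
                  thalf_slow = smm["thalf_slow", "mean"],
                  n = smm["f_slow", "n"],
                  n_unconverged = ch$n_unconverged),
      truth_delta = list(
        bound_percent = 100 * (smm["f_slow", "mean"] - s$f_bound),
        thalf_fast = smm["thalf_fast", "mean"] - s$thalf_fast,
        thalf_slow = smm["thalf_slow", "mean"] - s$thalf_slow))
  }
  report <- list(scenarios = out,
                 manifest = manifest_block(config, c(
                   fit_opts, list(n_curves = n_default))))
  if (!is.null(config$output_dir))
    jsonlite::write_json(report,
                         file.path(config$output_dir,
                                   "kinetics_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  report
}

#' Demonstration morphology configuration
#'
#' A control-plus-constructs design: lacR control and four dummy
#' constructs, the "unfolding" ones rendered as fibres and the others as
#' spheres, about 30 cells each -- a compact mirror of a typical targeting
#' experiment.
#'
#' @param n_per_spec cells per cohort.
#' @param master_seed master seed.
#' @return a configuration list for
#'   \code{\link{run_morphology_experiment}}.
#' @export
morphology_demo_config <- function(n_per_spec = 30L, master_seed = 1L) {
  sphere <- list(shape_kind = "sphere")
  fiber <- list(shape_kind = "fiber")
  list(cohorts = list(lacR = sphere, MeCP2 = fiber, VP16 = fiber,
                      MBD = sphere, R133C = fiber),
       control_label = "lacR", n_per_spec = n_per_spec,
       master_seed = master_seed,
       analysis = list(m = 7, alpha = 0.05))
}
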