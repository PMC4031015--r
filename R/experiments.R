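# Scenario suite: runs the canonical study comparisons end-to-end and
# compares computed peaks against the peak values published for the
# original (Abaqus) implementation of this model.

#' Suite configuration
#'
#' @param scenarios Scenario names (see \code{\link{scenario_names}}).
#' @param target_edge Mesh resolution, micrometres.
#' @param mode Solver mode override (\code{NULL} keeps each scenario's
#'   default), \code{"dynamic_newmark"} or \code{"quasi_static"}.
#' @param steps_per_cycle Optional override of the implicit step count.
#' @param out_dir Optional output directory for persisted series, the
#'   summary CSV and a log.
#' @param seed Integer seed echoed into outputs (the pipeline is
#'   deterministic; the seed is recorded for provenance).
#' @return A \code{suite_config} list.
#' @export
suite_config <- function(scenarios = scenario_names(), target_edge = 0.8,
                         mode = NULL, steps_per_cycle = NULL,
                         out_dir = NULL, seed = 1L) {
  bad <- setdiff(scenarios, scenario_names())
  if (length(bad)) stopf("unknown scenarios: %s", paste(bad, collapse = ", "))
  structure(list(scenarios = scenarios, target_edge = target_edge,
                 mode = mode, steps_per_cycle = steps_per_cycle,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "suite_config")
}

apply_overrides <- function(spec, config) {
  if (!is.null(config$mode)) spec$solver_options$mode <- config$mode
  if (!is.null(config$steps_per_cycle))
    spec$solver_options$steps_per_cycle <- config$steps_per_cycle
  spec
}

#' Run a scenario suite
#'
#' Meshes once per distinct geometry (fiber-free scenarios share a mesh),
#' runs every scenario, extracts region peaks and writes the summary table.
#' Per-scenario failures are isolated: the suite continues and reports
#' them.
#'
#' @param config A \code{\link{suite_config}}.
#' @param keep_series Keep the solution series in the returned list
#'   (memory-heavy for large suites; they are always persisted when
#'   \code{out_dir} is set).
#' @return List with \code{table} (see \code{\link{summary_table}}),
#'   \code{errors} (named character) and optionally \code{series}.
#' @export
run_suite <- function(config, keep_series = FALSE) {
  set.seed(config$seed)
  base_mesh <- NULL
  series_list <- list()
  errors <- character(0)
  log <- function(fmt, ...) message(sprintf(fmt, ...))
  for (nm in config$scenarios) {
    res <- tryCatch({
      spec <- apply_overrides(paper_scenario(nm), config)
      if (is.null(base_mesh))
        base_mesh <- generate_cell_mesh(spec$geometry, spec$nucleus,
                                        target_edge = config$target_edge)
      mesh <- base_mesh
      if (!is.null(spec$fibers)) {
        net <- build_fiber_network(spec$fibers, spec$geometry, spec$nucleus)
        mesh <- attach_fiber_elements(mesh, net)
      }
      model <- build_discrete_model(spec, mesh)
      series <- run_transient(model)
      if (!is.null(config$out_dir)) {
        save_series(series, file.path(config$out_dir,
                                      paste0(nm, "_series.rds")))
        scenario_to_json(spec, file.path(config$out_dir,
                                         paste0(nm, "_spec.json")))
      }
      log("suite: %s done (%d frames)", nm, length(series$times))
      series
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[nm] <- conditionMessage(res)
      log("suite: %s FAILED: %s", nm, errors[nm])
    } else {
      series_list[[nm]] <- res
    }
  }
  tab <- if (length(series_list)) summary_table(series_list) else NULL
  if (!is.null(config$out_dir) && !is.null(tab)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(config$out_dir, "suite_summary.csv"),
              row.names = FALSE)
  }
  out <- list(table = tab, errors = errors, config = config)
  if (keep_series) out$series <- series_list
  out
}

#' Relaxation-time sensitivity of peak cytoplasmic stress
#'
#' For each frequency present, the maximum relative deviation of the peak
#' cytoplasmic Von Mises stress across the relaxation-time sweep
#' (tau = 0.1, 1, 10 s) with the linear-elastic run as reference:
#' \eqn{\max_\tau |p_\tau - p_{el}| / p_{el}}.
#'
#' @param table A \code{\link{summary_table}} result containing the
#'   \code{tau*} and \code{elastic} scenarios.
#' @return Data frame with \code{frequency_hz} and
#'   \code{max_rel_deviation_pct}.
#' @export
tau_sensitivity <- function(table) {
  sel <- table$region == "cytoplasm" & table$quantity == "stress"
  tab <- table[sel, , drop = FALSE]
  fam <- sub("_[0-9]+Hz$", "", tab$scenario)
  freqs <- sort(unique(tab$frequency_hz[fam %in%
                                          c("tau0.1", "tau1", "tau10")]))
  need <- as.vector(outer(c("tau0.1", "tau1", "tau10", "elastic"),
                          paste0(freqs, "Hz"), paste, sep = "_"))
  missing <- setdiff(need, tab$scenario)
  if (length(missing))
    stopf("tau_sensitivity: missing runs: %s", paste(missing, collapse = ", "))
  out <- lapply(freqs, function(f) {
    ref <- tab$peak[tab$scenario == sprintf("elastic_%gHz", f)]
    tv <- tab$peak[fam %in% c("tau0.1", "tau1", "tau10") &
                     tab$frequency_hz == f]
    data.frame(frequency_hz = f,
               max_rel_deviation_pct = 100 * max(abs(tv - ref) / ref))
  })
  do.call(rbind, out)
}

#' Published reference peak values
#'
#' Peak stress and strain values reported for the original implementation
#' of this cell model, used as comparison targets. Strain entries are in
#' microstrain, stress in Pa; \code{citation} is a descriptive locator in
#' the original study's results.
#'
#' @return Data frame: scenario, region, quantity, paper_value, units,
#'   citation.
#' @export
reference_values <- function() {
  rbind(
    data.frame(scenario = "baseline_45Hz", region = "cytoplasm",
               quantity = "stress", paper_value = 118, units = "Pa",
               citation = "results: Von Mises stress distribution"),
    data.frame(scenario = "baseline_45Hz", region = "nucleus",
               quantity = "stress", paper_value = 87, units = "Pa",
               citation = "results: Von Mises stress distribution"),
    data.frame(scenario = "baseline_1Hz", region = "cytoplasm",
               quantity = "strain", paper_value = 2600, units = "ustrain",
               citation = "results: strain distribution"),
    data.frame(scenario = "baseline_1Hz", region = "nucleus",
               quantity = "strain", paper_value = 760, units = "ustrain",
               citation = "results: strain distribution"),
    data.frame(scenario = "baseline_45Hz", region = "cytoplasm",
               quantity = "strain", paper_value = 14500, units = "ustrain",
               citation = "results: strain distribution"),
    data.frame(scenario = "baseline_45Hz", region = "nucleus",
               quantity = "strain", paper_value = 2100, units = "ustrain",
               citation = "results: strain distribution"),
    data.frame(scenario = "isoelastic_nucleus_1Hz", region = "nucleus",
               quantity = "stress", paper_value = 40, units = "Pa",
               citation = "results: effect of viscoelasticity, iso-elastic case"),
    data.frame(scenario = "cytoskeleton_1Hz", region = "nucleus",
               quantity = "stress", paper_value = 330, units = "Pa",
               citation = "results: effect of cytoskeleton, distal regions"),
    data.frame(scenario = "cytoskeleton_1Hz", region = "cytoplasm",
               quantity = "stress", paper_value = 45, units = "Pa",
               citation = "results: effect of cytoskeleton, distal regions"),
    data.frame(scenario = "cytoskeleton_45Hz", region = "cytoplasm",
               quantity = "stress", paper_value = 110, units = "Pa",
               citation = "results: effect of cytoskeleton, distal regions"),
    data.frame(scenario = "cytoskeleton_45Hz", region = "nucleus",
               quantity = "strain", paper_value = 7900, units = "ustrain",
               citation = "results: effect of cytoskeleton, distal regions"),
    data.frame(scenario = "cytoskeleton_1Hz", region = "cytoplasm",
               quantity = "strain", paper_value = 3700, units = "ustrain",
               citation = "results: effect of cytoskeleton, distal regions"),
    data.frame(scenario = "cytoskeleton_45Hz", region = "cytoplasm",
               quantity = "strain", paper_value = 14000, units = "ustrain",
               citation = "results: effect of cytoskeleton, distal regions")
  )
}

#' Compare computed peaks to the published reference values
#'
#' @param table A \code{\link{summary_table}} result.
#' @param references A \code{\link{reference_values}}-shaped data frame.
#' @param tolerance Relative tolerance band for the pass flag (default
#'   0.30, i.e. +/-30 percent).
#' @return Data frame joining computed and reference values with
#'   \code{ratio} and \code{pass}; empty (with a warning) when
#'   \code{references} is empty.
#' @export
compare_to_reference <- function(table, references = reference_values(),
                                 tolerance = 0.30) {
  if (!nrow(references)) {
    warnf("empty reference list; nothing to compare")
    return(data.frame())
  }
  out <- merge(references, table,
               by = c("scenario", "region", "quantity"))
  if (!nrow(out)) return(out)
  out$computed <- out$peak
  out$ratio <- out$computed / out$paper_value
  out$pass <- abs(out$ratio - 1) <= tolerance
  out[, c("scenario", "region", "quantity", "paper_value", "units",
          "computed", "ratio", "pass", "citation")]
}
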