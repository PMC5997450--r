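# Pipeline orchestration: load or generate -> geometry -> annotation ->
# statistics -> reports, with a run manifest for exact reproduction.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate connectomes from a genotype model;
#'   requires a seed) or `"tables"` (load annotation-table directories).
#' @param input_dirs Character vector of specimen table directories
#'   (tables mode).
#' @param model A [genotype_model()] (synthetic mode).
#' @param n_specimens Number of synthetic specimens to generate.
#' @param geometry A [geometry_config()].
#' @param annotation An [annotation_config()].
#' @param grouping Hair-cell grouping for preference and specificity
#'   (`"polarity"` or `"ap_position"`); defaults to `"ap_position"` for
#'   genotypes in which bundle polarity is uninformative.
#' @param out_dir Output directory for reports.
#' @param seed Integer seed (required in synthetic mode).
#' @param log_level `"debug"`, `"info"`, `"warn"`, or `"quiet"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "tables"),
                       input_dirs = NULL, model = genotype_model(),
                       n_specimens = 8L,
                       geometry = geometry_config(),
                       annotation = annotation_config(),
                       grouping = NULL, out_dir = NULL, seed = NULL,
                       log_level = "info") {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(seed)) {
    stop("config error: synthetic mode requires a seed")
  }
  if (mode == "tables" && (is.null(input_dirs) || !length(input_dirs))) {
    stop("config error: tables mode requires input_dirs")
  }
  if (is.null(grouping)) {
    grouping <- if (mode == "synthetic" && model$genotype != "wild-type")
      "ap_position" else "polarity"
  }
  structure(list(mode = mode, input_dirs = input_dirs, model = model,
                 n_specimens = n_specimens, geometry = geometry,
                 annotation = annotation, grouping = grouping,
                 out_dir = out_dir, seed = seed, log_level = log_level),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Loads or generates specimens, computes contacts from traces when
#' needed, annotates every connectome, and derives the full report
#' bundle: specificity, redundancy, dominance, sibling exclusivity,
#' mixed-terminal fraction, and branch counts.  When `out_dir` is set,
#' JSON reports, a GraphML graph per specimen, and a run manifest
#' (config, seed, package version) are written; rerunning with the same
#' config and seed reproduces the reports byte for byte.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result`: `connectomes`, `ledgers`
#'   (synthetic mode), `reports`, `per_specimen_metrics`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  old <- options(neuromast.log_level = config$log_level)
  on.exit(options(old))

  stage <- "input"
  result <- tryCatch({
    ledgers <- NULL
    if (config$mode == "synthetic") {
      gens <- lapply(seq_len(config$n_specimens), function(i) {
        generate_connectome(config$model, seed = config$seed + i - 1L,
                            specimen_id = sprintf("SYN%02d", i))
      })
      conns <- lapply(gens, `[[`, "connectome")
      ledgers <- lapply(gens, `[[`, "ledger")
    } else {
      conns <- lapply(config$input_dirs, load_annotation_tables)
    }

    stage <- "geometry"
    conns <- lapply(conns, function(conn) {
      if (is.null(conn$contacts) && nrow(conn$traces)) {
        conn <- compute_contacts(conn, config$geometry)
      }
      conn
    })

    stage <- "annotation"
    conns <- lapply(conns, annotate_connectome, config = config$annotation,
                    grouping = config$grouping)

    stage <- "statistics"
    reports <- list(
      specificity = specificity_stats(conns, grouping = config$grouping),
      redundancy = redundancy_stats(conns),
      dominance = dominance_stats(conns, grouping = config$grouping),
      sibling = sibling_exclusivity(conns),
      mixed = mixed_terminal_fraction(conns),
      branches = branch_count_stats(conns))

    per_specimen <- merge(reports$specificity$per_specimen,
                          reports$branches$per_specimen,
                          by = "specimen_id")
    per_specimen <- merge(per_specimen, reports$mixed$per_specimen,
                          by = "specimen_id")
    names(per_specimen)[names(per_specimen) == "fraction"] <- "mixed_fraction"

    out <- structure(list(connectomes = conns, ledgers = ledgers,
                          reports = reports,
                          per_specimen_metrics = per_specimen,
                          config = config),
                     class = "pipeline_result")
    if (!is.null(config$out_dir)) {
      stage <- "output"
      write_report_bundle(out, config$out_dir)
    }
    out
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d specimen(s), grouping '%s'\n",
              length(x$connectomes), x$config$grouping))
  print(x$reports$specificity)
  print(x$reports$branches)
  print(x$reports$sibling)
  print(x$reports$mixed)
  invisible(x)
}

write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(obj, name) {
    jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  r <- result$reports
  wj(list(grouping = r$specificity$grouping, by_age = r$specificity$by_age,
          pooled = r$specificity$pooled,
          per_specimen = r$specificity$per_specimen), "specificity")
  wj(list(by_age = r$redundancy$by_age), "redundancy")
  wj(list(per_cell_by_age = r$dominance$per_cell_by_age,
          ranked = r$dominance$ranked), "dominance")
  wj(list(shared_count = r$sibling$shared_count,
          total_count = r$sibling$total_count,
          shared_weight = r$sibling$shared_weight,
          total_weight = r$sibling$total_weight,
          per_pair = r$sibling$per_pair), "sibling")
  wj(list(fraction = r$mixed$fraction,
          fraction_count = r$mixed$fraction_count,
          per_specimen = r$mixed$per_specimen), "mixed_fraction")
  wj(list(mean = r$branches$mean, sem = r$branches$sem,
          per_specimen = r$branches$per_specimen), "branch_counts")
  for (conn in result$connectomes) {
    write_connectome_graph(conn,
                           file.path(out_dir,
                                     paste0(conn$specimen_id, ".graphml")))
  }
  cfg <- result$config
  manifest <- list(mode = cfg$mode, seed = cfg$seed,
                   n_specimens = cfg$n_specimens,
                   grouping = cfg$grouping,
                   genotype = if (cfg$mode == "synthetic")
                     cfg$model$genotype else NA,
                   geometry = unclass(cfg$geometry),
                   annotation = unclass(cfg$annotation),
                   package_version = as.character(utils::packageVersion("neuromast")))
  wj(manifest, "manifest")
  invisible(out_dir)
}

#' Compare two report bundles metric by metric
#'
#' Runs the two-tailed pooled-variance t test on every per-specimen
#' metric shared between two pipeline results (group A vs group B), with
#' star coding at 0.05 / 0.01 / 0.001.
#'
#' @param result_a,result_b [run_pipeline()] results, each with at least
#'   two specimens.
#' @return Data frame: `metric`, group means and SEMs, `t`, `p`, `stars`.
#' @export
compare_runs <- function(result_a, result_b) {
  ma <- result_a$per_specimen_metrics
  mb <- result_b$per_specimen_metrics
  if (nrow(ma) < 2L || nrow(mb) < 2L) {
    stop("each group needs at least two specimens")
  }
  metrics <- intersect(setdiff(names(ma), "specimen_id"),
                       setdiff(names(mb), "specimen_id"))
  metrics <- metrics[vapply(metrics, function(m)
    is.numeric(ma[[m]]) && is.numeric(mb[[m]]), logical(1L))]
  if (!length(metrics)) stop("the two reports share no numeric metrics")
  rows <- lapply(metrics, function(m) {
    a <- ma[[m]][!is.na(ma[[m]])]
    b <- mb[[m]][!is.na(mb[[m]])]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    tt <- two_tailed_t(a, b)
    data.frame(metric = m, mean_a = tt$mean_a, sem_a = tt$sem_a,
               mean_b = tt$mean_b, sem_b = tt$sem_b, t = tt$t, p = tt$p,
               stars = tt$stars, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop("no shared metric had two values per group")
  do.call(rbind, rows)
}
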