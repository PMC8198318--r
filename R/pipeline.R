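# End-to-end orchestration: imaging pipeline (segment -> foci -> stats) and
# table pipeline (dose-response + growth fits), with machine-readable JSON
# reports that embed the exact configuration used.

#' Imaging pipeline configuration
#'
#' @param conditions named list; each element describes one condition as a
#'   list with `dapi` (matrix or TIFF path), optionally `foci` (matrix or
#'   path) and optionally `labels` (precomputed nucleus label matrix or
#'   path). Without `labels`, nuclei are segmented from the DAPI channel
#'   (threshold -> connected components -> seeded splitting of
#'   under-segmented regions).
#' @param threshold a [threshold_config()].
#' @param mitotic a [mitotic_filter_config()].
#' @param nuclei_args list of arguments for [detect_nuclei()].
#' @param foci_args list of arguments for [detect_foci()].
#' @param min_n low-n flag threshold for [tabulate_foci()].
#' @param seed global seed recorded in the report.
#' @return a `run_config` list.
#' @export
run_config <- function(conditions, threshold = threshold_config(),
                       mitotic = mitotic_filter_config(),
                       nuclei_args = list(), foci_args = list(),
                       min_n = 100, seed = 1) {
  stopifnot(is.list(conditions), length(names(conditions)) ==
              length(conditions))
  structure(list(conditions = conditions, threshold = threshold,
                 mitotic = mitotic, nuclei_args = nuclei_args,
                 foci_args = foci_args, min_n = min_n,
                 seed = as.integer(seed)),
            class = "run_config")
}

load_channel <- function(x) {
  if (is.character(x)) read_image(x) else x
}

config_echo <- function(cfg) {
  list(threshold = unclass(cfg$threshold),
       mitotic = unclass(cfg$mitotic),
       nuclei_args = cfg$nuclei_args, foci_args = cfg$foci_args,
       min_n = cfg$min_n, seed = cfg$seed)
}

#' Run the imaging pipeline
#'
#' For every condition: segment nuclei (or use provided labels), build
#' nucleus ROIs, exclude mitotic nuclei, detect and tabulate foci, then
#' compare per-nucleus foci counts between conditions (Tukey HSD) when two
#' or more conditions are present. Reruns with the same config and inputs
#' produce identical report bodies.
#'
#' @param cfg a [run_config()].
#' @return report list: per-condition row counts and summaries, pairwise
#'   comparisons, the echoed config and the seed.
#' @export
run_imaging_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  per_cond <- list()
  all_counts <- list()
  for (cn in names(cfg$conditions)) {
    cond <- cfg$conditions[[cn]]
    dapi <- load_channel(cond$dapi)
    labels <- if (!is.null(cond$labels)) {
      lab <- cond$labels
      if (is.character(lab)) lab <- read_labels(lab)
      lab
    } else {
      seeds <- do.call(detect_nuclei, c(list(dapi), cfg$nuclei_args))
      mask <- threshold_foreground(dapi, cfg$threshold)
      lab0 <- label_regions(mask, cfg$threshold$connectivity)
      multi <- find_undersegmented(lab0, seeds)
      if (length(multi)) {
        seg <- segment_cells(dapi, dapi, cfg$threshold)
        seg$labels
      } else lab0
    }
    if (max(labels) == 0L) {
      per_cond[[cn]] <- list(n_nuclei = 0L, n_excluded = 0L,
                             n_foci = 0L, mean_foci = NA_real_)
      next
    }
    rois <- nucleus_rois(labels, dapi)
    flt <- filter_mitotic(rois, cfg$mitotic)
    detections <- if (!is.null(cond$foci)) {
      foci_img <- load_channel(cond$foci)
      keep_lab <- labels
      keep_lab[!(labels %in% flt$kept$nucleus)] <- 0L
      do.call(detect_foci, c(list(foci_img, keep_lab), cfg$foci_args))
    } else {
      data.frame(nucleus = integer(), row = integer(), col = integer(),
                 sigma = numeric(), peak = numeric())
    }
    tab <- tabulate_foci(detections, flt$kept, flt$excluded,
                         condition = cn, min_n = cfg$min_n)
    counts <- tab$per_nucleus[!tab$per_nucleus$excluded, ]
    all_counts[[cn]] <- counts$n_foci
    per_cond[[cn]] <- list(
      n_nuclei = nrow(rois), n_excluded = nrow(flt$excluded),
      n_foci = nrow(detections),
      mean_foci = tab$by_condition$mean_foci[1],
      sd_foci = tab$by_condition$sd_foci[1],
      n_analyzed = tab$by_condition$n_analyzed[1],
      low_n = tab$by_condition$low_n[1])
  }
  comparisons <- if (length(all_counts) >= 2 &&
                     all(lengths(all_counts) >= 2)) {
    cmp <- tryCatch(compare_groups(all_counts, "tukey"),
                    error = function(e) NULL)
    if (is.null(cmp)) NULL else as.data.frame(cmp)
  } else NULL
  list(stage = "imaging", conditions = per_cond,
       comparisons = comparisons, config = config_echo(cfg),
       seed = cfg$seed)
}

#' Run the table pipeline
#'
#' Dose-response tables are fitted per condition with AIC model selection;
#' growth tables get a log2-linear doubling-time fit per condition.
#'
#' @param dose_response optional data.frame with columns `condition`,
#'   `dose_uM`, `replicate`, `viability`.
#' @param growth optional data.frame with columns `condition`, `time_h`,
#'   `replicate` and `count` or `signal`.
#' @param seed seed recorded in the report.
#' @return report list with one fit block per condition.
#' @export
run_table_pipeline <- function(dose_response = NULL, growth = NULL,
                               seed = 1) {
  report <- list(stage = "tables", seed = as.integer(seed))
  if (!is.null(dose_response)) {
    need <- c("condition", "dose_uM", "viability")
    miss <- setdiff(need, names(dose_response))
    if (length(miss))
      stop2("dose_response is missing column(s): ",
            paste(miss, collapse = ", "))
    report$dose_response <- lapply(
      split(dose_response, dose_response$condition), function(sub) {
        fit <- select_model(sub)
        list(family = fit$family, coef = fit$coef, rss = fit$rss,
             n = fit$n, aic = fit$aic, ed50 = fit$ed50,
             ed50_ci = fit$ed50_ci, converged = fit$converged,
             note = fit$note)
      })
  }
  if (!is.null(growth)) {
    need <- c("condition", "time_h")
    miss <- setdiff(need, names(growth))
    if (length(miss))
      stop2("growth is missing column(s): ", paste(miss, collapse = ", "))
    report$growth <- lapply(
      split(growth, growth$condition), function(sub) {
        fit <- fit_doubling_time(sub)
        list(doubling_time_h = fit$doubling_time_h, slope = fit$slope,
             r_squared = fit$r_squared, ci = fit$ci,
             defined = fit$defined)
      })
  }
  report
}

#' Write a pipeline report as JSON
#'
#' @param report list from [run_imaging_pipeline()] or
#'   [run_table_pipeline()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
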