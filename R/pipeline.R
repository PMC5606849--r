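# End-to-end workflows wiring the modules together, with a flat config
# whose defaults are the workflow's published constants.

#' Pipeline configuration
#'
#' @param correction IsoData threshold correction factor.
#' @param buffer Centrum dilation buffer, voxels.
#' @param vertebrae Vertebra analysis window.
#' @param alpha Significance level.
#' @param step,window Separation-line extension step and vote window,
#'   voxels.
#' @param connectivity Foreground connectivity.
#' @param calibration A [ct_calibration()].
#' @param seed RNG seed recorded in outputs.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(correction = 0.73, buffer = 5, vertebrae = 1:16,
                       alpha = 0.05, step = 2, window = 10,
                       connectivity = 26, calibration = ct_calibration(),
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the segmentation-to-phenome pipeline on one fish
#'
#' Threshold (IsoData x correction), separate vertebrae from the seed
#' lines, split each vertebra into elements, and measure the 25 phenome
#' columns. Deterministic: rerunning with the same inputs and config
#' gives identical output.
#'
#' @param input A [ct_volume()] or a directory holding a DICOM series.
#' @param seeds A [seed_lines()] tibble or path to a seed TSV.
#' @param config A [run_config()].
#' @param outline Optional fish outline on the lateral maximum projection.
#' @param standard_length,fish_id,group Phenome metadata.
#' @return List: `threshold`, `vmap` (`vertebra_map`), `phenome`,
#'   `config`.
#' @export
run_pipeline <- function(input, seeds, config = run_config(),
                         outline = NULL, standard_length = NA,
                         fish_id = NA_character_, group = NA_character_) {
  if (is.character(seeds)) {
    if (!file.exists(seeds)) abort(sprintf("seed file %s not found", seeds))
    seeds <- read_seed_lines(seeds)
  }
  vol <- if (is.character(input))
    read_dicom_series(input, calibration = config$calibration) else input
  stopifnot(inherits(vol, "ct_volume"))
  thr <- compute_threshold(vol, outline = outline,
                           correction = config$correction)
  mask <- binarize(vol, thr)
  vmap <- separate_vertebrae(mask, seeds, step = config$step,
                             window = config$window,
                             connectivity = config$connectivity)
  vmap$threshold <- thr
  ph <- assemble_phenome(vmap, vol, buffer = config$buffer,
                         standard_length = standard_length,
                         fish_id = fish_id, group = group)
  list(threshold = thr, vmap = vmap, phenome = ph, config = config)
}

#' Compare a mutant cohort against controls
#'
#' Runs the global test per feature over the configured vertebra window
#' (the ten headline features by default), extracts significantly
#' associated vertebrae, and computes skeletal barcodes of every fish
#' against the control population. Controls can optionally be
#' allometrically normalized to a reference length first (mutants are
#' never normalized).
#'
#' @param controls,mutants Lists of `phenome` objects (>= 2 fish each).
#' @param features Feature short names to test.
#' @param config A [run_config()].
#' @param normalize Normalize controls allometrically before testing?
#' @param models Allometric model tibble (required when `normalize`).
#' @param x_ref Reference length; defaults to the mutant group's mean
#'   standard length.
#' @return List of class `compare_result`: `tests` tibble (feature,
#'   statistic, p), `components` (list of significant-vertebra vectors),
#'   `barcodes`, `config`.
#' @export
run_compare <- function(controls, mutants,
                        features = c("Cent.Vol", "Neur.Vol", "Haem.Vol",
                                     "Cent.TMD", "Neur.TMD", "Haem.TMD",
                                     "Cent.Th", "Neur.Th", "Haem.Th",
                                     "Cent.Le"),
                        config = run_config(), normalize = FALSE,
                        models = NULL, x_ref = NULL) {
  if (length(controls) < 2 || length(mutants) < 2)
    abort("need at least 2 phenomes per group for the global test")
  if (normalize) {
    if (is.null(models)) abort("`models` required when normalize = TRUE")
    if (is.null(x_ref)) {
      sl <- vapply(mutants, function(p) as.numeric(attr(p, "standard_length")),
                   0.0)
      x_ref <- mean(sl, na.rm = TRUE)
    }
    controls <- lapply(controls, normalize_phenome, models = models,
                       x_ref = x_ref)
  }
  for (i in seq_along(controls)) attr(controls[[i]], "group") <- "control"
  for (i in seq_along(mutants)) attr(mutants[[i]], "group") <- "mutant"
  cohort <- c(controls, mutants)
  vv <- config$vertebrae
  rows <- list(); comps <- list()
  for (f in features) {
    fc <- feature_curve(cohort, f, vv)
    keep <- complete.cases(fc[paste0("v", vv)])
    if (sum(keep) < length(cohort))
      warn(sprintf("%s: %d fish dropped for missing vertebrae", f,
                   length(cohort) - sum(keep)))
    gt <- global_test(fc[keep, ])
    rows[[f]] <- tibble::tibble(feature = f, statistic = gt$statistic,
                                p = gt$p)
    comps[[f]] <- covariate_components(gt, alpha = config$alpha)
  }
  barcodes <- lapply(cohort, standard_scores, controls = controls,
                     vertebrae = vv)
  structure(list(tests = dplyr::bind_rows(rows), components = comps,
                 barcodes = barcodes, x_ref = if (normalize) x_ref else NA,
                 config = config),
            class = "compare_result")
}

#' @export
print.compare_result <- function(x, ...) {
  cat("Global tests per feature:\n")
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}
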