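# Synthetic phenome cohorts: statistically realistic per-fish tables of
# the 25 vertebral measures, used to exercise the statistical workflow
# when no scan-derived tables are available. The generative model is
# allometric (every morphological family scales as a power of standard
# length) with a fish-level random factor per feature family (capturing
# fish-to-fish physiology shared along the column) and per-vertebra
# residual noise. See the methods vignette for the parameter choices.

#' Parameters of the synthetic phenome generator
#'
#' Baselines are values at the 20 mm reference length for an adult
#' zebrafish vertebra; `b` are allometric exponents (volumes and
#' thicknesses mildly negatively allometric, TMD weakly positive);
#' `sd_fish` is the fish-level log-SD shared across vertebrae of a
#' feature, `sd_vert` the per-vertebra residual log-SD. TMD noise is
#' small relative to morphology, and the fish factor dominates the
#' vertebra residual, reflecting how strongly single-fish curves track
#' their own level along the column.
#'
#' @return Nested list of family parameters.
#' @export
phenome_sim_params <- function() {
  list(
    Vol = list(base = c(Cent = 2.0e7, Neur = 8.0e6, Haem = 8.0e6),
               b = 2.6, sd_fish = 0.08, sd_vert = 0.05),
    SA = list(base = c(Cent = 2.0e6, Neur = 1.4e6, Haem = 1.2e6),
              b = 1.9, sd_fish = 0.06, sd_vert = 0.04),
    Th = list(base = c(Cent = 45, Neur = 35, Haem = 30),
              b = 0.8, sd_fish = 0.05, sd_vert = 0.03),
    TMD = list(base = c(Cent = 480, Neur = 430, Haem = 420),
               b = 0.3, sd_fish = 0.04, sd_vert = 0.015),
    Le = list(base = 850, b = 1.0, sd_fish = 0.03, sd_vert = 0.02),
    tmd_sd_frac = 0.15, th_sd_frac = 0.25, sd_noise = 0.10,
    ref_length = 20,
    # anterior vertebrae carry pleural ribs: haemal volume/area roughly
    # halves past vertebra 10
    haem_rib_drop = list(after = 10, factor = 0.45),
    tmd_gradient = 0.004, le_gradient = -0.005)
}

#' Simulate a cohort of per-fish phenome tables
#'
#' Draws `n_fish` standard lengths, then generates the 25 measures for
#' `n_vertebrae` vertebrae per fish from the allometric model described
#' in [phenome_sim_params()]. `Tot.*` columns are derived from the
#' elements (sums for Vol/SA, volume-weighted means for TMD/Th).
#' Optionally shifts selected features in every vertebra to emulate a
#' mutant group.
#'
#' @param n_fish Number of fish.
#' @param n_vertebrae Vertebrae per fish.
#' @param sl_mean,sl_sd Standard length distribution, mm.
#' @param group Group label attribute.
#' @param params Generator parameters ([phenome_sim_params()]).
#' @param effect Optional named list `feature -> d` of mean shifts in
#'   within-group SD units applied uniformly across vertebrae (crude
#'   mutant emulation; for patterned effects use [simulate_cohort()] on
#'   an estimated model instead).
#' @param seed Optional RNG seed.
#' @return List of `phenome` objects with `standard_length` attributes.
#' @export
simulate_phenome_cohort <- function(n_fish, n_vertebrae = 24,
                                    sl_mean = 20.4, sl_sd = 0.9,
                                    group = "WT",
                                    params = phenome_sim_params(),
                                    effect = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  els <- c("Cent", "Neur", "Haem")
  sl <- pmax(rnorm(n_fish, sl_mean, sl_sd), 8)
  vv <- seq_len(n_vertebrae)
  cohort <- vector("list", n_fish)
  for (f in seq_len(n_fish)) {
    rel <- (sl[f] / p$ref_length)
    tb <- tibble::tibble(vertebra = vv)
    vals <- list()
    for (fam in c("Vol", "SA", "Th", "TMD")) {
      pf <- p[[fam]]
      for (el in els) {
        profile <- rep(1, n_vertebrae)
        if (el == "Haem" && fam %in% c("Vol", "SA"))
          profile[vv > p$haem_rib_drop$after] <- p$haem_rib_drop$factor
        if (fam == "TMD") profile <- 1 + p$tmd_gradient * (vv - 1)
        fish_fac <- rnorm(1, 0, pf$sd_fish)
        noise <- rnorm(n_vertebrae, 0, pf$sd_vert)
        vals[[paste0(el, ".", fam)]] <-
          pf$base[[el]] * profile * rel^pf$b * exp(fish_fac + noise)
      }
    }
    le_fac <- rnorm(1, 0, p$Le$sd_fish)
    vals[["Cent.Le"]] <- p$Le$base * (1 + p$le_gradient * (vv - 1)) *
      rel^p$Le$b * exp(le_fac + rnorm(n_vertebrae, 0, p$Le$sd_vert))
    # intra-specimen variation measures ride on their parent's level
    for (el in els) {
      vals[[paste0(el, ".TMD.sd")]] <- p$tmd_sd_frac *
        vals[[paste0(el, ".TMD")]] * exp(rnorm(n_vertebrae, 0, p$sd_noise))
      vals[[paste0(el, ".Th.sd")]] <- p$th_sd_frac *
        vals[[paste0(el, ".Th")]] * exp(rnorm(n_vertebrae, 0, p$sd_noise))
    }
    # totals from the elements
    vol_mat <- sapply(els, function(el) vals[[paste0(el, ".Vol")]])
    w <- vol_mat / rowSums(vol_mat)
    vals[["Tot.Vol"]] <- rowSums(vol_mat)
    vals[["Tot.SA"]] <- rowSums(sapply(els, function(el)
      vals[[paste0(el, ".SA")]]))
    for (fam in c("TMD", "Th")) {
      m <- sapply(els, function(el) vals[[paste0(el, ".", fam)]])
      vals[[paste0("Tot.", fam)]] <- rowSums(m * w)
      msd <- sapply(els, function(el) vals[[paste0(el, ".", fam, ".sd")]])
      vals[[paste0("Tot.", fam, ".sd")]] <- rowSums(msd * w)
    }
    for (nm in names(vals)) tb[[nm]] <- vals[[nm]]
    tb <- tb[, c("vertebra", names(measure_names()))]
    cohort[[f]] <- new_phenome(tb, standard_length = sl[f],
                               fish_id = sprintf("%s_%02d", group, f),
                               group = group)
  }
  names(cohort) <- vapply(cohort, function(ph) attr(ph, "fish_id"), "")
  if (!is.null(effect)) {
    for (feat in names(effect)) {
      mat <- sapply(cohort, function(ph) ph[[feat]])
      sds <- apply(mat, 1, sd)
      for (f in seq_along(cohort))
        cohort[[f]][[feat]] <- cohort[[f]][[feat]] + effect[[feat]] * sds
    }
  }
  cohort
}
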