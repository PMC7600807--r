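# End-to-end orchestration: (optional) simulate -> localize -> region stats,
# with reproducibility metadata.  A single global seed deterministically
# derives the per-stage seeds, so one integer reproduces a whole run.

#' Pipeline run configuration
#'
#' Either `simulation` (a [simulation_config()]) or both `manifest_path` and
#' `mask_path` must be supplied.
#'
#' @param out_dir Output directory for all run artifacts.
#' @param simulation Optional [simulation_config()]; when given, a synthetic
#'   cohort is generated and written under `out_dir/cohort/`.
#' @param manifest_path,mask_path Inputs for a real (pre-registered) cohort.
#' @param tfce A [tfce_params()].
#' @param perm A [perm_config()]; its `rng_seed` and the simulation's are
#'   overridden by seeds derived from `seed`.
#' @param sided Sidedness of the Welch test in the reports.
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, simulation = NULL, manifest_path = NULL,
                       mask_path = NULL, tfce = tfce_params(),
                       perm = perm_config(), sided = "two.sided", seed = 1L) {
  if (is.null(simulation) && (is.null(manifest_path) || is.null(mask_path))) {
    stop("run_config: supply either a simulation config or manifest + mask paths")
  }
  structure(list(out_dir = out_dir, simulation = simulation,
                 manifest_path = manifest_path, mask_path = mask_path,
                 tfce = tfce, perm = perm, sided = sided,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile(); on.exit(unlink(tf), add = TRUE)
  writeBin(serialize(config, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

# Derive independent sub-seeds (< 2^31) from one global seed.
derive_seeds <- function(seed, n = 2L) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

write_report_tsvs <- function(report, prefix) {
  gs <- report$group_summary
  summary_df <- data.frame(
    metric = c("n_control", "n_patient", "mean_control", "mean_patient",
               "variance_control", "variance_patient", "cohens_d",
               "welch_t", "welch_df", "welch_p", "anova_age_p",
               "r2_control", "r2_patient"),
    value = c(gs$control$n, gs$patient$n, gs$control$mean, gs$patient$mean,
              gs$control$variance, gs$patient$variance, report$cohens_d,
              report$welch$t, report$welch$df, report$welch$p,
              report$anova_age_p,
              report$effect_coded$r_squared[["control"]],
              report$effect_coded$r_squared[["patient"]])
  )
  utils::write.table(summary_df, paste0(prefix, "_summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report$effect_coded$coefficients,
                     paste0(prefix, "_regression.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(report$ancova),
                     paste0(prefix, "_ancova.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) optional synthetic-cohort generation, written under
#' `out_dir/cohort/`; (2) cohort loading under the mask; (3) permutation
#' localizer with TFCE and FWE correction, writing the region mask and all
#' p/statistic maps as NIfTI; (4) region statistics for the whole mask and
#' for the extracted region (skipped with a notice when the region is
#' empty), written as TSV tables.  A `run_metadata.txt` captures every
#' parameter, derived seed and the config hash.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `voxel_pmaps`, the whole-mask and
#'   region `stats_report`s (the latter possibly `NULL`), and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 2L)
  hash <- config_hash(config)

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$rng_seed <- seeds[1]
    message("[ironmap] simulating cohort (seed ", seeds[1], ")")
    cohort <- generate_cohort(sim)
    manifest_path <- write_cohort(cohort, file.path(config$out_dir, "cohort"))
    mask_path <- file.path(config$out_dir, "cohort", "mask.nii.gz")
  } else {
    manifest_path <- config$manifest_path
    mask_path <- config$mask_path
  }

  message("[ironmap] loading cohort")
  stack <- load_cohort(manifest_path, mask_path)

  perm <- config$perm
  perm$rng_seed <- seeds[2]
  message("[ironmap] localizing (", perm$n_permutations, " permutations, FWE ",
          perm$fwe_method, ")")
  pmaps <- localize_regions(stack, tfce = config$tfce, cfg = perm)

  write_region_mask(pmaps$region, stack,
                    file.path(config$out_dir, "region.nii.gz"))
  for (map in c("raw_stat", "tfce_stat", "p_voxel", "p_adjusted",
                "signed_difference")) {
    write_nifti(region_to_volume(pmaps[[map]], stack,
                                 fill = if (grepl("^p_", map)) 1 else 0),
                file.path(config$out_dir, paste0(map, ".nii.gz")),
                affine = stack$affine, datatype = "float64")
  }

  message("[ironmap] whole-mask statistics")
  whole <- stats_report_from_stack(stack, NULL, mask_name = "whole_mask",
                                   sided = config$sided)
  write_report_tsvs(whole, file.path(config$out_dir, "stats_whole"))

  region_report <- NULL
  if (any(pmaps$region)) {
    message("[ironmap] iron-accumulation region statistics (",
            sum(pmaps$region), " voxels)")
    region_report <- stats_report_from_stack(stack, pmaps$region,
                                             mask_name = "iron_region",
                                             sided = config$sided)
    write_report_tsvs(region_report, file.path(config$out_dir, "stats_region"))
  } else {
    message("[ironmap] extracted region is empty; region statistics skipped")
  }

  meta <- c(
    paste0("config_hash = ", hash),
    paste0("global_seed = ", config$seed),
    paste0("sim_seed = ", seeds[1]),
    paste0("perm_seed = ", seeds[2]),
    paste0("simulated = ", !is.null(config$simulation)),
    paste0("manifest = ", manifest_path),
    paste0("mask = ", mask_path),
    paste0("n_permutations = ", perm$n_permutations),
    paste0("fwe_method = ", perm$fwe_method),
    paste0("alpha = ", perm$alpha),
    paste0("direction_constraint = ", perm$direction_constraint),
    paste0("tfce_E = ", config$tfce$E),
    paste0("tfce_H = ", config$tfce$H),
    paste0("tfce_n_steps = ", config$tfce$n_steps),
    paste0("connectivity = ", config$tfce$connectivity),
    paste0("welch_sided = ", config$sided),
    paste0("region_voxels = ", sum(pmaps$region))
  )
  writeLines(meta, file.path(config$out_dir, "run_metadata.txt"))

  invisible(list(pmaps = pmaps, whole_report = whole,
                 region_report = region_report, stack = stack,
                 out_dir = config$out_dir))
}

#' Diagnostic plots for a region analysis
#'
#' Group-wise boxplot of the per-subject means and an age-versus-intensity
#' scatter with per-group least-squares lines (the layout used to inspect
#' age-dependent iron accumulation).
#'
#' @param values Per-subject mean intensities.
#' @param ages Ages in years.
#' @param labels `"control"` / `"patient"` per subject.
#' @param main Title prefix.
#' @return `NULL`, invisibly (draws on the current device).
#' @export
plot_region_diagnostics <- function(values, ages, labels, main = "region") {
  g <- group_vector(labels)
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old), add = TRUE)
  graphics::boxplot(values ~ factor(g), xlab = "", ylab = "mean intensity",
                    main = paste0(main, ": groups"))
  graphics::plot(ages, values, pch = ifelse(g == "patient", 19, 1),
                 xlab = "age (years)", ylab = "mean intensity",
                 main = paste0(main, ": age trend"))
  for (grp in c("control", "patient")) {
    sel <- g == grp
    graphics::abline(stats::lm(values[sel] ~ ages[sel]),
                     lty = if (grp == "patient") 1 else 2)
  }
  invisible(NULL)
}
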