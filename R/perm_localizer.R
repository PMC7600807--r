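# Voxel-wise permutation localizer: covariate residualization, absolute
# group mean-difference statistic, TFCE, permutation null, FWE correction.
#
# The observed labeling counts as one additional permutation in Monte-Carlo
# mode, so p = (1 + #{T_perm >= T_obs}) / (1 + N) and p > 0 always; in
# exhaustive mode the observed labeling is one of the enumerated ones and
# p = #{T >= T_obs} / N.  Ties count toward the tail (conservative).

#' TFCE parameters
#'
#' @param E Extent exponent (> 0); default 0.5, the cited method's standard.
#' @param H Height exponent (> 0); default 2.
#' @param n_steps Number of Riemann integration steps (>= 10); default 100.
#' @param connectivity Neighborhood: 6 (faces), 18 (+edges) or 26 (+corners).
#' @return A list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, n_steps = 100L, connectivity = 26L) {
  stopifnot(E > 0, H > 0)
  n_steps <- as.integer(n_steps)
  if (n_steps < 10L) stop("tfce_params: n_steps must be >= 10")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("tfce_params: connectivity must be 6, 18 or 26")
  }
  structure(list(E = E, H = H, n_steps = n_steps, connectivity = connectivity),
            class = "tfce_params")
}

#' Permutation-test configuration
#'
#' @param n_permutations Number of random relabelings; the publication-scale
#'   default is 10,000.  Fewer than 100 triggers a warning (too coarse for
#'   inference).
#' @param rng_seed Integer seed for the relabeling draw.
#' @param fwe_method `"max_statistic"` (operational default: FWE from the
#'   permutation distribution of the maximum enhanced statistic) or
#'   `"bonferroni"` (per-voxel permutation p times the number of in-mask
#'   voxels).  Note the Bonferroni granularity bound: with N permutations the
#'   smallest attainable per-voxel p is about 1/N, so Bonferroni over more
#'   than about alpha * N voxels can never reject.
#' @param alpha Family-wise significance level.
#' @param direction_constraint If `TRUE` (default) the extracted region is
#'   restricted to voxels where the adjusted patient mean exceeds the control
#'   mean, encoding the one-sided alternative that iron raises phase-filtered
#'   SWI intensity.
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 10000L, rng_seed = 1L,
                        fwe_method = c("max_statistic", "bonferroni"),
                        alpha = 0.05, direction_constraint = TRUE) {
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop("perm_config: n_permutations must be >= 1")
  if (n_permutations < 100L) {
    warning("n_permutations < 100 is too coarse for inferential use")
  }
  fwe_method <- match.arg(fwe_method)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(n_permutations = n_permutations, rng_seed = as.integer(rng_seed),
                 fwe_method = fwe_method, alpha = alpha,
                 direction_constraint = isTRUE(direction_constraint)),
            class = "perm_config")
}

#' Residualize intensities on nuisance covariates
#'
#' Replaces every voxel column by its residuals from an ordinary
#' least-squares fit on `[intercept, age, sex]`.  Group labels are NOT part
#' of the nuisance model.  Permuting group labels over these residuals is
#' the residualization scheme used throughout the localizer.
#'
#' @param stack A `masked_stack`.
#' @param manifest A `cohort_manifest` aligned with the stack rows; defaults
#'   to the stack's own manifest.
#' @return A `masked_stack` with identical geometry and residualized `data`.
#' @export
residualize_covariates <- function(stack, manifest = stack$manifest) {
  if (nrow(stack$data) < 3L) stop("residualize_covariates: need >= 3 subjects")
  if (!identical(manifest$subject_id, stack$subject_order)) {
    stop("Manifest rows do not match the stack's subject order")
  }
  X <- cbind(intercept = 1, age = manifest$age_years,
             sex = as.numeric(manifest$sex == "M"))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning("Nuisance design is rank-deficient; keeping columns: ",
            paste(colnames(X)[keep], collapse = ", "))
    qx <- qr(X[, keep, drop = FALSE])
  }
  out <- stack
  out$data <- qr.resid(qx, stack$data)
  rownames(out$data) <- rownames(stack$data)
  out
}

#' Absolute group mean-difference statistic per voxel
#'
#' The localizer's test statistic: the absolute difference of the average
#' voxel-wise intensity between patients and controls (after covariate
#' adjustment), together with its sign.
#'
#' @param adjusted A `masked_stack` (normally residualized) or a
#'   subjects-by-voxels matrix.
#' @param labels Character vector of `"patient"` / `"control"` per subject;
#'   defaults to the stack manifest's groups.
#' @return List with `raw_stat` (absolute difference) and
#'   `signed_difference` (patient mean minus control mean) per voxel.
#' @export
voxel_statistic <- function(adjusted, labels = NULL) {
  data <- if (inherits(adjusted, "masked_stack")) adjusted$data else adjusted
  if (is.null(labels) && inherits(adjusted, "masked_stack")) {
    labels <- adjusted$manifest$group
  }
  is_pat <- labels == "patient"
  if (sum(is_pat) == 0L || sum(!is_pat) == 0L) {
    stop("voxel_statistic: both groups must be non-empty")
  }
  signed <- colMeans(data[is_pat, , drop = FALSE]) -
            colMeans(data[!is_pat, , drop = FALSE])
  list(raw_stat = abs(signed), signed_difference = signed)
}

# CSR adjacency of in-mask voxels (internal; cached by callers)
build_adjacency <- function(voxel_index, grid_shape, connectivity) {
  cpp_build_adjacency(as.matrix(voxel_index), as.integer(grid_shape),
                      as.integer(connectivity))
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' For each in-mask voxel the non-negative statistic is enhanced to
#' (approximately) the integral over thresholds h of
#' `extent(h)^E * h^H dh`, where `extent(h)` is the size of the connected
#' supra-threshold component containing the voxel.  The integral is a right
#' endpoint Riemann sum with `n_steps` steps up to the map maximum.
#'
#' @param stat Non-negative statistic vector over in-mask voxels.
#' @param voxel_index Voxels-by-3 integer matrix of 0-based grid coordinates.
#' @param grid_shape Length-3 integer grid dimensions.
#' @param params A [tfce_params()] object.
#' @return Enhanced statistic vector, same length as `stat`.
#' @export
tfce_enhance <- function(stat, voxel_index, grid_shape, params = tfce_params()) {
  if (any(stat < 0)) stop("tfce_enhance: statistic must be non-negative")
  adj <- build_adjacency(voxel_index, grid_shape, params$connectivity)
  cpp_tfce(as.numeric(stat), adj$ptr, adj$idx,
           params$E, params$H, params$n_steps)
}

# All distinct two-group labelings for exhaustive mode (columns of combn)
exhaustive_labelings <- function(n_subjects, patient_idx) {
  combos <- utils::combn(n_subjects, length(patient_idx))
  lab <- matrix(0L, nrow = ncol(combos), ncol = n_subjects)
  for (j in seq_len(ncol(combos))) lab[j, combos[, j]] <- 1L
  lab
}

#' Permutation null distribution of the enhanced statistic
#'
#' Relabels subjects (group sizes preserved), recomputes the absolute
#' adjusted mean-difference statistic and its TFCE enhancement for every
#' relabeling, and records per voxel the count of permuted enhanced values
#' `>=` the observed one plus the per-permutation maximum enhanced value.
#' Random labelings are drawn with replacement from the labeling space; if
#' the number of distinct labelings is smaller than `n_permutations` the
#' test switches to exhaustive enumeration with a message.
#'
#' @param adjusted A residualized `masked_stack` (see
#'   [residualize_covariates()]).
#' @param manifest Aligned `cohort_manifest`; defaults to the stack's.
#' @param tfce A [tfce_params()] object.
#' @param cfg A [perm_config()] object.
#' @return A list of class `perm_null` holding the observed maps, the
#'   per-voxel exceedance counts, the max-statistic distribution, and mode
#'   metadata.
#' @export
permutation_null <- function(adjusted, manifest = adjusted$manifest,
                             tfce = tfce_params(), cfg = perm_config()) {
  labels <- manifest$group
  n <- length(labels)
  patient_idx <- which(labels == "patient")
  n_distinct <- choose(n, length(patient_idx))

  obs <- voxel_statistic(adjusted, labels)
  adj <- build_adjacency(adjusted$voxel_index, adjusted$grid_shape,
                         tfce$connectivity)
  obs_tfce <- cpp_tfce(obs$raw_stat, adj$ptr, adj$idx,
                       tfce$E, tfce$H, tfce$n_steps)

  exhaustive <- n_distinct < cfg$n_permutations
  if (exhaustive) {
    message("Distinct labelings (", n_distinct, ") < requested permutations (",
            cfg$n_permutations, "); enumerating exhaustively.")
    labelings <- exhaustive_labelings(n, patient_idx)
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()), add = TRUE)
    set.seed(cfg$rng_seed)
    labelings <- matrix(0L, nrow = cfg$n_permutations, ncol = n)
    for (p in seq_len(cfg$n_permutations)) {
      labelings[p, sample.int(n, length(patient_idx))] <- 1L
    }
  }

  nul <- cpp_perm_null(adjusted$data, labelings, obs_tfce,
                       adj$ptr, adj$idx, tfce$E, tfce$H, tfce$n_steps)

  structure(list(
    raw_stat = obs$raw_stat,
    signed_difference = obs$signed_difference,
    tfce_stat = obs_tfce,
    count_ge = nul$count_ge,
    max_stat = nul$max_stat,
    n_performed = nrow(labelings),
    exhaustive = exhaustive,
    n_voxels = ncol(adjusted$data),
    voxel_index = adjusted$voxel_index,
    grid_shape = adjusted$grid_shape,
    affine = adjusted$affine,
    tfce = tfce, cfg = cfg
  ), class = "perm_null")
}

#' FWE-correct the permutation null and extract the significant region
#'
#' Per-voxel p-values use the `(1 + count) / (1 + N)` convention in
#' Monte-Carlo mode and `count / N` under exhaustive enumeration (where the
#' observed labeling is one of the N).  Bonferroni multiplies by the number
#' of in-mask voxels (capped at 1); max-statistic compares each observed
#' enhanced value against the null distribution of per-permutation maxima.
#' The region is `p_adjusted < alpha`, intersected with
#' `signed_difference > 0` when the direction constraint is on.
#'
#' @param null_record A `perm_null` from [permutation_null()].
#' @param cfg A [perm_config()]; defaults to the one stored in the record.
#' @return A list of class `voxel_pmaps` with `raw_stat`, `tfce_stat`,
#'   `p_voxel`, `p_adjusted`, `region`, `signed_difference`, and geometry.
#' @export
correct_and_extract <- function(null_record, cfg = null_record$cfg) {
  N <- null_record$n_performed
  if (null_record$exhaustive) {
    p_voxel <- null_record$count_ge / N
    p_floor <- 1 / N
  } else {
    p_voxel <- (1 + null_record$count_ge) / (1 + N)
    p_floor <- 1 / (1 + N)
  }

  if (cfg$fwe_method == "bonferroni") {
    if (p_floor * null_record$n_voxels >= cfg$alpha) {
      warning("Bonferroni floor: with ", N, " permutations and ",
              null_record$n_voxels, " voxels the smallest attainable ",
              "adjusted p is ", signif(p_floor * null_record$n_voxels, 3),
              " >= alpha = ", cfg$alpha, "; no voxel can be significant. ",
              "Consider fwe_method = 'max_statistic' or more permutations.")
    }
    p_adjusted <- pmin(1, p_voxel * null_record$n_voxels)
  } else {
    counts <- vapply(null_record$tfce_stat,
                     function(t_obs) sum(null_record$max_stat >= t_obs),
                     numeric(1))
    p_adjusted <- if (null_record$exhaustive) counts / N
                  else (1 + counts) / (1 + N)
  }
  p_adjusted <- pmax(p_adjusted, p_voxel)

  region <- p_adjusted < cfg$alpha
  if (cfg$direction_constraint) {
    region <- region & null_record$signed_difference > 0
  }

  structure(list(
    raw_stat = null_record$raw_stat,
    tfce_stat = null_record$tfce_stat,
    p_voxel = p_voxel,
    p_adjusted = p_adjusted,
    region = region,
    signed_difference = null_record$signed_difference,
    voxel_index = null_record$voxel_index,
    grid_shape = null_record$grid_shape,
    affine = null_record$affine,
    n_permutations = N,
    exhaustive = null_record$exhaustive,
    fwe_method = cfg$fwe_method,
    alpha = cfg$alpha,
    tfce = null_record$tfce
  ), class = "voxel_pmaps")
}

#' Run the full localizer on a cohort
#'
#' Convenience wrapper: residualize on age and sex, build the permutation
#' null of the TFCE-enhanced absolute mean-difference statistic, and extract
#' the FWE-significant iron-accumulation region.
#'
#' @param stack A `masked_stack` from [load_cohort()] or
#'   [cohort_to_stack()].
#' @param tfce A [tfce_params()] object.
#' @param cfg A [perm_config()] object.
#' @return A `voxel_pmaps` object.
#' @export
localize_regions <- function(stack, tfce = tfce_params(), cfg = perm_config()) {
  adjusted <- residualize_covariates(stack)
  nul <- permutation_null(adjusted, tfce = tfce, cfg = cfg)
  correct_and_extract(nul, cfg)
}

#' @export
print.voxel_pmaps <- function(x, ...) {
  cat("<voxel_pmaps> ", length(x$p_voxel), " voxels, ", x$n_permutations,
      if (x$exhaustive) " exhaustive labelings" else " permutations",
      ", FWE: ", x$fwe_method, " (alpha ", x$alpha, ")\n", sep = "")
  cat("  significant region: ", sum(x$region), " voxels; min adjusted p = ",
      signif(min(x$p_adjusted), 3), "\n", sep = "")
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2 |A and B| / (|A| + |B|)` between two binary masks or logical vectors;
#' defined as 1 when both are empty.
#'
#' @param a,b Logical vectors or arrays of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("dice: length mismatch")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
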