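# Region-level statistical suite on per-subject average intensities:
# group summaries, Cohen's D for unequal variances, Welch t-test, additive
# two-way ANOVA (age effect), effect-coded multivariate regression, and
# sequential ANCOVA with the Group x Age interaction that quantifies the
# degree of age-dependent iron accumulation.
#
# Effect coding is sum-to-zero with patients = +1 and controls = -1, so the
# fit y = b + db*g + a*x + da*g*x splits into a grand intercept/slope and
# mirror-image group deviations sharing one standard error.

group_vector <- function(labels) {
  g <- as.character(labels)
  if (!all(g %in% c("control", "patient"))) {
    stop("labels must be 'control' / 'patient'")
  }
  g
}

#' Per-subject mean intensity over a region
#'
#' @param stack A `masked_stack`.
#' @param region Logical vector over the stack's in-mask voxels, or a binary
#'   3D array on the stack grid.  Must select at least one voxel.
#' @return Named numeric vector, one mean per subject in stack order.
#' @export
region_means <- function(stack, region) {
  if (!is.null(dim(region))) {
    if (!identical(dim(region), stack$grid_shape)) {
      stop("region grid does not match the stack grid")
    }
    lin <- 1L + stack$voxel_index %*% c(1L, stack$grid_shape[1],
                                        stack$grid_shape[1] * stack$grid_shape[2])
    region <- as.vector(region[as.vector(lin)] != 0)
  }
  region <- as.logical(region)
  if (length(region) != ncol(stack$data)) {
    stop("region length does not match the number of in-mask voxels")
  }
  if (!any(region)) stop("region_means: region is empty")
  rowMeans(stack$data[, region, drop = FALSE])
}

#' Group-wise summary of per-subject intensities
#'
#' @param values Per-subject scalars.
#' @param labels `"control"` / `"patient"` per subject.
#' @return A list of class `group_summary` with per-group `n`, `mean`,
#'   `variance` (denominator n-1) and boxplot five-number summaries.
#' @export
group_summary <- function(values, labels) {
  g <- group_vector(labels)
  per_group <- lapply(split(values, g), function(v) {
    list(n = length(v), mean = mean(v),
         variance = if (length(v) > 1) stats::var(v) else 0,
         fivenum = stats::fivenum(v))
  })
  structure(per_group, class = "group_summary")
}

#' Cohen's D for unequal variances
#'
#' `|m1 - m2| / sqrt((v1 + v2) / 2)`: the absolute mean difference divided
#' by the root of the unweighted average of the two group variances.
#'
#' @param m1,v1 Mean and variance of one group.
#' @param m2,v2 Mean and variance of the other group.
#' @return Non-negative scalar effect size.
#' @export
cohens_d_unequal <- function(m1, v1, m2, v2) {
  stopifnot(v1 >= 0, v2 >= 0)
  if (v1 == 0 && v2 == 0) {
    stop("cohens_d_unequal is undefined when both variances are zero")
  }
  abs(m1 - m2) / sqrt((v1 + v2) / 2)
}

#' Welch two-sample t-test (patient minus control)
#'
#' @param values Per-subject scalars.
#' @param labels `"control"` / `"patient"` per subject; each group needs at
#'   least 2 subjects.
#' @param sided `"two.sided"` (default) or `"greater"` (patients higher).
#' @return List `(t, df, p)` with the Welch statistic, Welch-Satterthwaite
#'   degrees of freedom, and p-value.
#' @export
welch_ttest <- function(values, labels, sided = c("two.sided", "greater")) {
  sided <- match.arg(sided)
  g <- group_vector(labels)
  pat <- values[g == "patient"]
  ctl <- values[g == "control"]
  if (length(pat) < 2L || length(ctl) < 2L) {
    stop("welch_ttest: each group needs >= 2 subjects")
  }
  tt <- stats::t.test(pat, ctl, var.equal = FALSE, alternative = sided)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

# Shared fit for the effect-coded models; checks the spec preconditions.
fit_effect_coded <- function(values, ages, labels, interaction = TRUE) {
  g <- group_vector(labels)
  if (length(values) < 4L) stop("need >= 4 subjects")
  if (length(unique(g)) < 2L) stop("both groups must be present")
  if (stats::var(ages) == 0) stop("age is constant; design is singular")
  gnum <- ifelse(g == "patient", 1, -1)
  df <- data.frame(y = values, g = gnum, x = ages)
  fit <- if (interaction) stats::lm(y ~ g + x + g:x, data = df)
         else stats::lm(y ~ g + x, data = df)
  if (anyNA(stats::coef(fit))) {
    stop("singular design: effect-coded model is rank-deficient")
  }
  fit
}

#' Effect-coded multivariate regression of intensity on age and group
#'
#' Fits `y = b + db*g + a*x + da*g*x` with sum-to-zero group coding
#' (patients `g = +1`, controls `g = -1`), so `b`/`a` are the grand
#' intercept/slope and `db`/`da` the patient deviations; the control
#' deviations are their exact negations with the same standard error.  Also
#' reports each group's simple-regression R-squared.
#'
#' @param values Per-subject scalars.
#' @param ages Ages in years.
#' @param labels `"control"` / `"patient"` per subject.
#' @return A list of class `effect_coded_fit` with `coefficients` (a
#'   6-row table mirroring the published layout: Intercept b, db Controls,
#'   db Patients, Slope a, da Controls, da Patients), `r_squared` per group,
#'   and the underlying `lm` fit.
#' @export
effect_coded_regression <- function(values, ages, labels) {
  fit <- fit_effect_coded(values, ages, labels, interaction = TRUE)
  sm <- summary(fit)$coefficients  # Estimate, Std. Error, t value, Pr(>|t|)
  rows <- list(
    c("Intercept b",        1,  "(Intercept)"),
    c("db Controls",       -1,  "g"),
    c("db Patients",        1,  "g"),
    c("Slope a",            1,  "x"),
    c("da Controls",       -1,  "g:x"),
    c("da Patients",        1,  "g:x")
  )
  tab <- do.call(rbind, lapply(rows, function(r) {
    s <- as.numeric(r[2])
    est <- sm[r[3], "Estimate"] * s
    data.frame(term = r[1], estimate = est,
               std_error = sm[r[3], "Std. Error"],
               t = sm[r[3], "t value"] * s,
               p = sm[r[3], "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL

  g <- group_vector(labels)
  r2 <- vapply(c(control = "control", patient = "patient"), function(grp) {
    sel <- g == grp
    summary(stats::lm(values[sel] ~ ages[sel]))$r.squared
  }, numeric(1))

  structure(list(coefficients = tab, r_squared = r2, fit = fit),
            class = "effect_coded_fit")
}

#' Sequential ANCOVA table (Group, Age, Group x Age, Error)
#'
#' Sequential (Type I) sums of squares in the fixed order Group, then Age,
#' then the Group x Age interaction, whose F-test quantifies the group
#' difference in the age slope (the degree of iron accumulation).  The four
#' rows decompose the total corrected sum of squares exactly, with error
#' degrees of freedom `n - 4`.
#'
#' @inheritParams effect_coded_regression
#' @return A data frame of class `ancova_table` with columns `term`, `df`,
#'   `sum_sq`, `mean_sq`, `F`, `p` (F and p are `NA` for the Error row).
#' @export
ancova_table <- function(values, ages, labels) {
  fit <- fit_effect_coded(values, ages, labels, interaction = TRUE)
  a <- stats::anova(fit)   # sequential Type I SS: g, x, g:x, Residuals
  out <- data.frame(
    term = c("Group", "Age", "Group x Age", "Error"),
    df = a$Df,
    sum_sq = a$`Sum Sq`,
    mean_sq = a$`Mean Sq`,
    F = a$`F value`,
    p = a$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ancova_table", "data.frame")
  out
}

#' Age-effect p-value from the additive two-way model
#'
#' Sequential ANOVA of `y ~ Group + Age` (no interaction); returns the Age
#' row's p-value.
#'
#' @inheritParams effect_coded_regression
#' @return Scalar p-value.
#' @export
anova_age_effect <- function(values, ages, labels) {
  fit <- fit_effect_coded(values, ages, labels, interaction = FALSE)
  a <- stats::anova(fit)
  a$`Pr(>F)`[rownames(a) == "x"]
}

#' Full region-level statistics report
#'
#' Runs the six-step suite on per-subject average intensities: (1) group
#' summaries, (2) Cohen's D for unequal variances, (3) Welch t-test,
#' (4) additive two-way ANOVA age effect, (5) effect-coded multivariate
#' regression with per-group R-squared, (6) sequential ANCOVA with the
#' Group x Age interaction.
#'
#' @param values Per-subject mean intensities (e.g. from [region_means()]).
#' @param ages Ages in years.
#' @param labels `"control"` / `"patient"` per subject.
#' @param mask_name Label recorded in the report's provenance.
#' @param sided Sidedness of the Welch test (default two-sided).
#' @return A list of class `stats_report`.
#' @export
stats_report <- function(values, ages, labels, mask_name = "region",
                         sided = c("two.sided", "greater")) {
  sided <- match.arg(sided)
  gs <- group_summary(values, labels)
  d <- cohens_d_unequal(gs$control$mean, gs$control$variance,
                        gs$patient$mean, gs$patient$variance)
  w <- welch_ttest(values, labels, sided = sided)
  age_p <- anova_age_effect(values, ages, labels)
  ec <- effect_coded_regression(values, ages, labels)
  an <- ancova_table(values, ages, labels)

  key <- serialize(list(values, ages, as.character(labels), mask_name), NULL)
  tf <- tempfile(); on.exit(unlink(tf), add = TRUE)
  writeBin(key, tf)
  structure(list(group_summary = gs, cohens_d = d, welch = w,
                 anova_age_p = age_p, effect_coded = ec, ancova = an,
                 provenance = list(mask_name = mask_name,
                                   n_subjects = length(values),
                                   sided = sided,
                                   hash = unname(tools::md5sum(tf)))),
            class = "stats_report")
}

#' Report from a masked stack and region
#'
#' Convenience wrapper: averages the (unadjusted) intensities over `region`
#' per subject and calls [stats_report()].
#'
#' @param stack A `masked_stack`.
#' @param region Logical vector over in-mask voxels, binary 3D array, or
#'   `NULL` for the whole mask.
#' @param mask_name Provenance label.
#' @param sided Sidedness of the Welch test.
#' @return A `stats_report`.
#' @export
stats_report_from_stack <- function(stack, region = NULL,
                                    mask_name = if (is.null(region)) "whole_mask" else "region",
                                    sided = c("two.sided", "greater")) {
  if (is.null(region)) region <- rep(TRUE, ncol(stack$data))
  values <- region_means(stack, region)
  stats_report(values, stack$manifest$age_years, stack$manifest$group,
               mask_name = mask_name, sided = match.arg(sided))
}

#' @export
print.group_summary <- function(x, ...) {
  for (g in names(x)) {
    cat(sprintf("  %-8s n = %2d  mean = %8.2f  variance = %10.2f\n",
                g, x[[g]]$n, x[[g]]$mean, x[[g]]$variance))
  }
  invisible(x)
}

#' @export
print.effect_coded_fit <- function(x, ...) {
  cat("Effect-coded regression f(x) = a * x + b (g: patients +1, controls -1)\n")
  tab <- x$coefficients
  cat(sprintf("  %-12s %9s %9s %7s %7s\n", "term", "Estimate", "Std.Err", "T", "p"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-12s %9.2f %9.2f %7.2f %7.3f\n", tab$term[i],
                tab$estimate[i], tab$std_error[i], tab$t[i], tab$p[i]))
  }
  cat(sprintf("  R^2: controls %.2f, patients %.2f\n",
              x$r_squared[["control"]], x$r_squared[["patient"]]))
  invisible(x)
}

#' @export
print.ancova_table <- function(x, ...) {
  cat("Analysis of covariance (sequential SS)\n")
  cat(sprintf("  %-12s %3s %14s %14s %8s %7s\n",
              "term", "df", "Sum sq.", "Mean sq.", "F", "p"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %3d %14.2f %14.2f %8s %7s\n", x$term[i], x$df[i],
                x$sum_sq[i], x$mean_sq[i],
                if (is.na(x$F[i])) "" else sprintf("%.2f", x$F[i]),
                if (is.na(x$p[i])) "" else sprintf("%.3f", x$p[i])))
  }
  invisible(x)
}

#' @export
print.stats_report <- function(x, ...) {
  cat("== Region statistics report (", x$provenance$mask_name, ", n = ",
      x$provenance$n_subjects, ") ==\n", sep = "")
  cat("Step 1: group summaries\n")
  print(x$group_summary)
  cat(sprintf("Step 2: Cohen's D (unequal variances) = %.2f\n", x$cohens_d))
  cat(sprintf("Step 3: Welch t-test (%s): t = %.2f, df = %.1f, p = %.3g\n",
              x$provenance$sided, x$welch$t, x$welch$df, x$welch$p))
  cat(sprintf("Step 4: two-way ANOVA age effect: p = %.3g\n", x$anova_age_p))
  cat("Step 5: ")
  print(x$effect_coded)
  cat("Step 6: ")
  print(x$ancova)
  invisible(x)
}
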