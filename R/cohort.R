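# Two-group phantom cohorts with prescribed intraMAT volume distributions.

# Draw from a normal truncated at zero (strictly positive) by rejection.
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > 0) { out[i] <- v; break }
    }
  }
  out
}

# Muscle-compartment voxel count of the anatomy generated by `spec` (depends
# on the seeded wedge partition, hence on spec$seed).
muscle_capacity_voxels <- function(spec) {
  tpl <- with_seed(spec$seed, build_template(spec))
  sum(tpl$lab >= 10L) * spec$grid_shape[1]
}

#' Plan a two-group phantom cohort
#'
#' Draws each subject's target intraMAT volume from a zero-truncated normal
#' with the group's mean/SD, derives per-subject seeds from the cohort seed,
#' and solves for the `intramat_fraction` that realizes the target given that
#' subject's muscle capacity. The plan is a plain data frame; phantoms are
#' materialized one at a time by [phantom_from_plan()] (used by
#' [generate_cohort()] and the pipeline).
#'
#' @param n_per_group integer >= 2, subjects per group.
#' @param group_means_cm3,group_sds_cm3 length-2 numerics: target intraMAT
#'   mean and SD (cm^3) for the affected and unaffected group.
#' @param base_spec a [phantom_spec()] providing geometry and corruption
#'   settings shared by all subjects.
#' @param seed integer cohort seed.
#' @return data frame with columns `subject_id`, `group`, `target_cm3`,
#'   `subject_seed`, `intramat_fraction`.
#' @export
cohort_plan <- function(n_per_group, group_means_cm3, group_sds_cm3,
                        base_spec, seed) {
  stopifnot(n_per_group >= 2, length(group_means_cm3) == 2,
            length(group_sds_cm3) == 2, all(group_means_cm3 > 0),
            all(group_sds_cm3 >= 0))
  groups <- c("affected", "unaffected")
  with_seed(seed, {
    targets <- c(rtruncnorm_pos(n_per_group, group_means_cm3[1], group_sds_cm3[1]),
                 rtruncnorm_pos(n_per_group, group_means_cm3[2], group_sds_cm3[2]))
    subject_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_group)
  })
  plan <- data.frame(
    subject_id = sprintf("%s_%02d", rep(c("aff", "unaff"), each = n_per_group),
                         rep(seq_len(n_per_group), 2L)),
    group = rep(groups, each = n_per_group),
    target_cm3 = targets,
    subject_seed = subject_seeds,
    stringsAsFactors = FALSE)

  vv_cm3 <- prod(base_spec$pixel_spacing_mm) * base_spec$slice_thickness_mm / 1000
  plan$intramat_fraction <- vapply(seq_len(nrow(plan)), function(i) {
    sp <- base_spec; sp$seed <- plan$subject_seed[i]
    cap <- muscle_capacity_voxels(sp)
    f <- plan$target_cm3[i] / (vv_cm3 * cap)
    if (f > 0.9)
      stop(sprintf(
        "subject %s: target intraMAT volume %.1f cm^3 exceeds muscle capacity (%.1f cm^3)",
        plan$subject_id[i], plan$target_cm3[i], 0.9 * vv_cm3 * cap))
    f
  }, numeric(1))
  plan
}

#' @rdname cohort_plan
#' @param plan one row of a cohort plan (or the plan plus an index `i`).
#' @param i row index into `plan`.
#' @export
phantom_from_plan <- function(plan, i, base_spec) {
  sp <- base_spec
  sp$seed <- plan$subject_seed[i]
  sp$intramat_fraction <- plan$intramat_fraction[i]
  generate_phantom(sp)
}

#' Generate a two-group phantom cohort
#'
#' Materializes the full cohort described by [cohort_plan()]: for each
#' subject a phantom whose realized ground-truth intraMAT volume matches the
#' subject's drawn target up to speckle quantization.
#'
#' @inheritParams cohort_plan
#' @return an object of class `phantom_cohort`: a list with the `plan` and a
#'   list `subjects` of `(group_id, phantom)` pairs in plan order.
#' @examples
#' spec <- phantom_spec(profile = "test", noise_sigma = 0, bias_amplitude = 0)
#' coh <- generate_cohort(2, c(9.9, 6.2), c(5.0, 3.5), spec, seed = 1)
#' sapply(coh$subjects, function(s) s$phantom$truth_intramat_cm3)
#' @export
generate_cohort <- function(n_per_group, group_means_cm3, group_sds_cm3,
                            base_spec, seed) {
  plan <- cohort_plan(n_per_group, group_means_cm3, group_sds_cm3,
                      base_spec, seed)
  subjects <- lapply(seq_len(nrow(plan)), function(i) {
    list(group_id = plan$group[i],
         subject_id = plan$subject_id[i],
         phantom = phantom_from_plan(plan, i, base_spec))
  })
  structure(list(plan = plan, subjects = subjects), class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects (%d per group)\n",
              nrow(x$plan), nrow(x$plan) / 2L))
  agg <- stats::aggregate(target_cm3 ~ group, x$plan, function(v)
    c(mean = mean(v), sd = stats::sd(v)))
  print(agg)
  invisible(x)
}
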