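#' Bootstrap configuration
#'
#' Settings for the village-stratified bootstrap of the full estimation
#' pipeline. Defaults follow the study design: 499 resamples, strata =
#' villages, central 95% percentile intervals.
#'
#' @param replicates number of bootstrap resamples.
#' @param unit resampling unit: "subject" (subjects with all their waves,
#'   drawn with replacement within village strata; default) or "village"
#'   (villages as primary sampling units within regions).
#' @param percentile central mass of the interval (default 0.95).
#' @param base_seed integer; replicate r uses seed base_seed + r for both
#'   the resampling draw and its microsimulation stream.
#' @param microsim_size cohort size per replicate when the pipeline runs in
#'   microsimulation mode.
#' @param max_failure_rate replicate-failure fraction above which
#'   [bootstrap_he()] errors rather than warns.
#' @return object of class "bootstrap_config".
#' @export
bootstrap_config <- function(replicates = 499L,
                             unit = c("subject", "village"),
                             percentile = 0.95, base_seed = 1L,
                             microsim_size = 100000L,
                             max_failure_rate = 0.1) {
  unit <- match.arg(unit)
  stopifnot(replicates >= 1, percentile > 0, percentile < 1)
  structure(
    list(replicates = as.integer(replicates), unit = unit,
         percentile = percentile, base_seed = as.integer(base_seed),
         microsim_size = as.integer(microsim_size),
         max_failure_rate = max_failure_rate),
    class = "bootstrap_config"
  )
}

#' Stratified resample of a wave-level panel
#'
#' Draws subjects (with all their waves) with replacement within each
#' village, preserving every village's original subject count; or, in
#' "village" mode, draws villages with replacement within each region.
#' Subject identities are re-keyed so repeated draws never collide.
#' Deterministic given the config's base seed and the replicate index.
#'
#' @param records wave-level records carrying `village` (and `region`).
#' @param config a "bootstrap_config".
#' @param replicate_index replicate number (1-based).
#' @return resampled records with re-keyed `subject_id`.
#' @export
resample_panel <- function(records, config, replicate_index) {
  stopifnot(inherits(config, "bootstrap_config"))
  set.seed(config$base_seed + as.integer(replicate_index))
  rows_of <- split(seq_len(nrow(records)), records$subject_id)
  vvec <- records$village
  rvec <- records$region
  first_row <- vapply(rows_of, `[`, 0L, 1L)
  subj_village <- vvec[first_row]
  subj_region <- rvec[first_row]
  names(subj_village) <- names(subj_region) <- names(rows_of)
  ids <- names(rows_of)

  drawn <- if (config$unit == "subject") {
    unlist(lapply(split(ids, subj_village), function(v_ids) {
      v_ids[sample.int(length(v_ids), length(v_ids), replace = TRUE)]
    }), use.names = FALSE)
  } else {
    villages <- split(ids, subj_village)
    v_region <- vapply(villages, function(v) subj_region[v[1L]], 0)
    unlist(lapply(split(names(villages), v_region), function(v_names) {
      take <- v_names[sample.int(length(v_names), length(v_names),
                                 replace = TRUE)]
      unlist(villages[take], use.names = FALSE)
    }), use.names = FALSE)
  }

  take <- rows_of[drawn]
  out <- records[unlist(take, use.names = FALSE), , drop = FALSE]
  # integer re-keys avoid collisions between repeated draws; the original
  # identity is kept in source_id
  out$source_id <- rep(drawn, lengths(take))
  out$subject_id <- rep(seq_along(drawn), lengths(take))
  rownames(out) <- NULL
  out
}

#' Full estimation pipeline: records to health expectancies
#'
#' Applies the sample filters, builds person-periods, fits the hazard model
#' and computes health expectancies for each cohort specification, either
#' by exact matrix propagation or by microsimulation.
#'
#' @param records coded wave-level records (a `state` column present).
#' @param cohort_specs a "cohort_spec" or list of them.
#' @param method "analytic" (default) or "microsim".
#' @param credit person-year crediting rule, see [run_microsim()].
#' @param fit_args extra arguments to [fit_transition_model()].
#' @return list with `he` (stacked "he_table" over cohort specs) and `fit`
#'   (the "transition_model").
#' @export
he_pipeline <- function(records, cohort_specs,
                        method = c("analytic", "microsim"),
                        credit = "midcycle", fit_args = list()) {
  method <- match.arg(method)
  if (inherits(cohort_specs, "cohort_spec")) cohort_specs <-
      list(cohort_specs)
  filt <- apply_sample_filters(records)
  pp <- build_person_periods(filt)
  fit <- do.call(fit_transition_model, c(list(pp), fit_args))
  he <- do.call(rbind, lapply(cohort_specs, function(cs) {
    if (method == "analytic") {
      analytic_expectancies(fit$params, cs, credit = credit)
    } else {
      health_expectancies(run_microsim(fit$params, cs, credit = credit))
    }
  }))
  rownames(he) <- NULL
  list(he = he, fit = fit)
}

# linear-interpolation percentile of sorted replicate values: with R
# replicates and target probability q, the percentile sits at position
# 1 + q (R - 1) and is linearly interpolated between the two bracketing
# order statistics (quantile type 7, stated here bit-exactly).
percentile_interp <- function(x, q) {
  x <- sort(x)
  R <- length(x)
  h <- 1 + q * (R - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

#' Bootstrap confidence intervals for health expectancies
#'
#' Re-runs the full pipeline (resample, refit, recompute expectancies) on
#' stratified resamples and forms central percentile intervals per cell.
#' The point estimate comes from the full sample. In microsimulation mode
#' each replicate reruns the microsimulation with its own seed, so the
#' intervals reflect both parameter and simulation uncertainty. Replicates
#' whose refit fails are dropped and counted; more than
#' `config$max_failure_rate` failures is an error unless `allow_failures`.
#'
#' @inheritParams he_pipeline
#' @param config a "bootstrap_config".
#' @param resample set FALSE to disable resampling (every replicate sees
#'   the original data; used to isolate microsimulation noise in tests).
#' @param allow_failures tolerate any failure rate (with a warning).
#' @param keep_replicates attach the replicate-by-cell matrix as attribute
#'   "replicates".
#' @return a "he_table" in long form: one row per (starting_age, sex,
#'   measure) with columns estimate, lower, upper, plus attributes
#'   "n_failed" and optionally "replicates".
#' @export
bootstrap_he <- function(records, cohort_specs, config = bootstrap_config(),
                         method = c("analytic", "microsim"),
                         credit = "midcycle", fit_args = list(),
                         resample = TRUE, allow_failures = FALSE,
                         keep_replicates = FALSE) {
  method <- match.arg(method)
  if (inherits(cohort_specs, "cohort_spec")) cohort_specs <-
      list(cohort_specs)
  point_run <- he_pipeline(records, cohort_specs, method = method,
                           credit = credit, fit_args = fit_args)
  point <- point_run$he
  # warm-start replicate refits at the full-sample estimate
  fit_args_r <- c(fit_args, list(start = point_run$fit$params))
  state_cols <- c(intersect(c(living_states(), "limited"), names(point)),
                  "total")
  long0 <- do.call(rbind, lapply(state_cols, function(sc) {
    data.frame(starting_age = point$starting_age, sex = point$sex,
               measure = sc, estimate = point[[sc]])
  }))

  reps <- matrix(NA_real_, config$replicates, nrow(long0))
  n_failed <- 0L
  for (r in seq_len(config$replicates)) {
    dat <- if (resample) resample_panel(records, config, r) else records
    cs_r <- lapply(cohort_specs, function(cs) {
      cohort_spec(cs$starting_age,
                  if (method == "microsim") config$microsim_size else cs$size,
                  cs$initial_distribution, cs$age_cap,
                  seed = config$base_seed + r)
    })
    he_r <- tryCatch(
      he_pipeline(dat, cs_r, method = method, credit = credit,
                  fit_args = if (resample) fit_args_r else fit_args)$he,
      error = function(e) NULL
    )
    if (is.null(he_r)) { n_failed <- n_failed + 1L; next }
    vals <- unlist(lapply(state_cols, function(sc) he_r[[sc]]),
                   use.names = FALSE)
    if (length(vals) == nrow(long0)) reps[r, ] <- vals else
      n_failed <- n_failed + 1L
  }
  fail_rate <- n_failed / config$replicates
  if (fail_rate > config$max_failure_rate) {
    msg <- sprintf("%d of %d bootstrap replicates failed (%.1f%%)",
                   n_failed, config$replicates, 100 * fail_rate)
    if (allow_failures) warning(msg, call. = FALSE) else
      stop(msg, call. = FALSE)
  }
  alpha <- (1 - config$percentile) / 2
  ok <- stats::complete.cases(reps)
  long0$lower <- apply(reps[ok, , drop = FALSE], 2L, percentile_interp,
                       q = alpha)
  long0$upper <- apply(reps[ok, , drop = FALSE], 2L, percentile_interp,
                       q = 1 - alpha)
  attr(long0, "n_failed") <- n_failed
  if (keep_replicates) attr(long0, "replicates") <- reps
  class(long0) <- c("he_table", "data.frame")
  long0
}
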