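#' Disability-status cross-tabulation by age group and wave
#'
#' Counts and percentages of respondents by disability state within age
#' group for each wave. For the first wave the denominator is living
#' respondents; for later waves respondents who died since the previous
#' interview are a "dead" row and are included in the denominator, matching
#' the convention of panel descriptive tables where between-wave mortality
#' is part of the outcome distribution.
#'
#' @param records coded wave-level records.
#' @param age_breaks lower break points of the age groups (default 45 and
#'   65, i.e. groups 45-64 and 65+). Ages are taken at the record's wave.
#' @return data frame ("cross_tab"): wave, year, age_group, state, n, prop
#'   (full precision), pct (rounded to 1 decimal).
#' @export
wave_cross_tab <- function(records, age_breaks = c(45, 65)) {
  if (is.null(records$state)) stop("records must carry coded states",
                                   call. = FALSE)
  rec <- records[!is.na(records$state), , drop = FALSE]
  labs <- c(paste0(age_breaks[-length(age_breaks)], "-",
                   age_breaks[-1L] - 1L),
            paste0(age_breaks[length(age_breaks)], "+"))
  rec$age_group <- labs[findInterval(rec$age, age_breaks)]
  first_wave <- min(rec$wave)
  rec <- rec[rec$vital_status == "alive" | rec$wave > first_wave, ,
             drop = FALSE]
  out <- list()
  states <- levels(rec$state)
  for (w in sort(unique(rec$wave))) {
    for (g in labs) {
      blk <- rec[rec$wave == w & rec$age_group == g, , drop = FALSE]
      if (!nrow(blk)) next
      tab <- table(factor(as.character(blk$state), levels = states))
      if (w == first_wave) tab <- tab[names(tab) != .dead]
      keep <- names(tab)
      n <- as.integer(tab)
      out[[length(out) + 1L]] <- data.frame(
        wave = w, year = blk$year[1L], age_group = g, state = keep,
        n = n, prop = n / sum(n), pct = round(100 * n / sum(n), 1L)
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cross_tab", "data.frame")
  res
}

#' Auxiliary item percentages by disability state
#'
#' Percentage of respondents working for income, reporting that pain
#' interfered with work at least "moderately", and reporting low life
#' satisfaction ("somewhat unsatisfied" or "very unsatisfied"), by age
#' group and disability state at one wave. Respondents with a missing value
#' on an item are removed from that item's denominator; a cell with an
#' empty denominator is reported missing, not zero.
#'
#' @param records coded wave-level records.
#' @param wave wave number (default: the last wave).
#' @param age_breaks as in [wave_cross_tab()].
#' @return data frame: age_group, state, and per item `n_<item>` (non-
#'   missing denominator) and `pct_<item>`.
#' @export
auxiliary_by_state <- function(records, wave = max(records$wave),
                               age_breaks = c(45, 65)) {
  if (is.null(records$state)) stop("records must carry coded states",
                                   call. = FALSE)
  rec <- records[records$wave == wave & records$vital_status == "alive" &
                   !is.na(records$state), , drop = FALSE]
  labs <- c(paste0(age_breaks[-length(age_breaks)], "-",
                   age_breaks[-1L] - 1L),
            paste0(age_breaks[length(age_breaks)], "+"))
  rec$age_group <- labs[findInterval(rec$age, age_breaks)]
  pain_hi <- c("moderately", "quite a bit", "extremely")
  sat_lo <- c("somewhat unsatisfied", "very unsatisfied")
  items <- list(
    work = list(val = rec$work_income == 1L, miss = is.na(rec$work_income)),
    pain = list(val = rec$pain_item %in% pain_hi, miss = is.na(rec$pain_item)),
    low_satisfaction = list(val = rec$life_sat %in% sat_lo,
                            miss = is.na(rec$life_sat))
  )
  out <- list()
  living <- setdiff(levels(rec$state), .dead)
  for (g in labs) {
    for (s in living) {
      sel <- rec$age_group == g & rec$state == s
      row <- data.frame(age_group = g, state = s, n = sum(sel))
      for (nm in names(items)) {
        ok <- sel & !items[[nm]]$miss
        row[[paste0("n_", nm)]] <- sum(ok)
        row[[paste0("pct_", nm)]] <- if (sum(ok) == 0L) NA_real_ else
          round(100 * sum(items[[nm]]$val[ok]) / sum(ok), 1L)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Observed versus simulated state proportions by age band
#'
#' Compares the age profile of disability prevalence in the panel (living
#' respondents pooled over waves, binned in age bands) with the state
#' distribution of person-years in a simulated occupancy table. Optionally
#' adds village-stratified bootstrap percentile bands around the observed
#' proportions. No smoothing is applied.
#'
#' @param records coded wave-level records.
#' @param occ an "occupancy" with matching states.
#' @param band_width age-band width in years (default 5).
#' @param by_sex stratify by sex.
#' @param replicates if > 0, number of bootstrap resamples for the observed
#'   bands.
#' @param config "bootstrap_config" used when `replicates > 0`.
#' @return data frame: age_band, (sex), state, n_obs, obs_prop, sim_prop,
#'   and lower/upper when bands are requested; bands with no observations
#'   have NA observed proportions.
#' @export
observed_vs_simulated_proportions <- function(records, occ, band_width = 5,
                                              by_sex = FALSE,
                                              replicates = 0L,
                                              config = bootstrap_config(
                                                replicates = replicates)) {
  rec <- records[records$vital_status == "alive" & !is.na(records$state) &
                   records$state != .dead, , drop = FALSE]
  states <- occ$states
  ages <- as.integer(dimnames(occ$py)[[1L]])
  breaks <- seq(min(ages) - (min(ages) %% band_width),
                max(max(rec$age, ages)) + band_width, by = band_width)
  band_of <- function(a) breaks[findInterval(a, breaks)]
  rec$band <- band_of(rec$age)
  sim_band <- band_of(ages)

  obs_prop_tab <- function(r) {
    tab <- table(factor(r$band, levels = unique(sim_band)),
                 factor(as.character(r$state), levels = states))
    den <- rowSums(tab)
    prop <- sweep(unclass(tab), 1L, ifelse(den > 0, den, NA), "/")
    list(prop = prop, n = den)
  }

  build <- function(r, pym) {
    ob <- obs_prop_tab(r)
    sim_tot <- rowsum(pym, sim_band)
    sim_prop <- sweep(sim_tot, 1L, rowSums(sim_tot), "/")
    bands <- unique(sim_band)
    out <- do.call(rbind, lapply(seq_along(bands), function(bi) {
      b <- bands[bi]
      data.frame(age_band = b, state = states,
                 n_obs = unname(ob$n[as.character(b)]),
                 obs_prop = as.vector(ob$prop[as.character(b), ]),
                 sim_prop = if (as.character(b) %in% rownames(sim_prop))
                   as.vector(sim_prop[as.character(b), ]) else NA_real_)
    }))
    out
  }

  if (by_sex) {
    res <- do.call(rbind, lapply(c(female = 0L, male = 1L), function(m) {
      pym <- occ$py[, m + 1L, , drop = TRUE]
      if (is.null(dim(pym))) pym <- matrix(pym, nrow = length(ages))
      cbind(sex = if (m == 0L) "female" else "male",
            build(rec[rec$male == m, , drop = FALSE], pym))
    }))
  } else {
    pym <- occ$py[, 1L, , drop = TRUE] + occ$py[, 2L, , drop = TRUE]
    if (is.null(dim(pym))) pym <- matrix(pym, nrow = length(ages))
    res <- build(rec, pym)
  }
  rownames(res) <- NULL

  if (replicates > 0L) {
    alpha <- (1 - config$percentile) / 2
    reps <- array(NA_real_, c(replicates, nrow(res)))
    for (r in seq_len(replicates)) {
      rs <- resample_panel(records, config, r)
      rs <- rs[rs$vital_status == "alive" & !is.na(rs$state) &
                 rs$state != .dead, , drop = FALSE]
      rs$band <- band_of(rs$age)
      if (by_sex) {
        v <- unlist(lapply(0:1, function(m) {
          as.vector(t(obs_prop_tab(rs[rs$male == m, , drop = FALSE])$prop))
        }))
      } else {
        v <- as.vector(t(obs_prop_tab(rs)$prop))
      }
      reps[r, ] <- v
    }
    res$lower <- apply(reps, 2L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2L) NA_real_ else percentile_interp(x, alpha)
    })
    res$upper <- apply(reps, 2L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2L) NA_real_ else percentile_interp(x, 1 - alpha)
    })
  }
  res
}
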