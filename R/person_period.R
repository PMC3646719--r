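#' Apply the analysis-sample filters to coded wave records
#'
#' Retains subjects who were interviewed at least twice, or interviewed once
#' and died between waves, and who were aged 45+ at their first retained
#' interview. Rows with missing sex, age or coded state are dropped first
#' (a death row's state is "dead", never missing). Counts of what each
#' filter removed are attached for logging.
#'
#' @param records coded wave-level records (a `state` column as from
#'   [code_records()]).
#' @return filtered records, with attribute "filter_counts": a named list
#'   (n_rows_in, dropped_missing, dropped_participation, dropped_age,
#'   n_subjects_kept, n_rows_out).
#' @export
apply_sample_filters <- function(records) {
  if (is.null(records$state)) {
    stop("records must carry coded states; run code_records() first",
         call. = FALSE)
  }
  n_in <- nrow(records)
  ok <- !is.na(records$state) & !is.na(records$male) & !is.na(records$age)
  dropped_missing <- sum(!ok)
  rec <- records[ok, , drop = FALSE]

  alive <- rec$vital_status == "alive"
  n_int <- tapply(alive, rec$subject_id, sum)
  died <- tapply(!alive, rec$subject_id, any)
  keep_ids <- names(n_int)[n_int >= 2L | (n_int >= 1L & died)]
  dropped_participation <-
    length(unique(rec$subject_id)) - length(keep_ids)
  rec <- rec[rec$subject_id %in% keep_ids, , drop = FALSE]

  first_age <- tapply(rec$age[rec$vital_status == "alive"],
                      rec$subject_id[rec$vital_status == "alive"], min)
  young <- names(first_age)[first_age < 45]
  dropped_age <- length(young)
  rec <- rec[!rec$subject_id %in% young, , drop = FALSE]
  rec <- rec[order(rec$subject_id, rec$wave), , drop = FALSE]
  rownames(rec) <- NULL

  attr(rec, "filter_counts") <- list(
    n_rows_in = n_in, dropped_missing = dropped_missing,
    dropped_participation = dropped_participation,
    dropped_age = dropped_age,
    n_subjects_kept = length(unique(rec$subject_id)),
    n_rows_out = nrow(rec)
  )
  rec
}

#' Build annual person-period records under the midpoint convention
#'
#' Expands each observed interval between consecutive attended waves into
#' annual at-risk records, assuming exactly one transition per interval
#' placed at the integer year nearest the interval midpoint. For the usual
#' 2-year interval from state A at age a to state B: (a, A->B) and
#' (a+1, B->B) if B is living, or the single record (a, A->DEAD) if the
#' subject died (exact death dates are unknown, so the death is assigned to
#' the interval midpoint). A skipped wave (a 4-year interval) yields a
#' stayer year before the transition and stayer years after it; intervals
#' longer than `max_gap` years are dropped instead when `drop_long = TRUE`.
#'
#' @param records filtered, coded wave-level records (see
#'   [apply_sample_filters()]).
#' @param max_gap longest interval (years) expanded when `drop_long = TRUE`.
#' @param drop_long drop intervals longer than `max_gap` instead of
#'   expanding them.
#' @return data frame of person-periods: subject_id, age_at_start, male,
#'   origin, destination, village, region. Origins are living states only.
#' @export
#' @examples
#' rec <- data.frame(
#'   subject_id = 1, wave = 1:2, year = c(2006, 2008), age = c(62, 64),
#'   male = 0, village = 1, region = 1, vital_status = "alive",
#'   state = factor(c("healthy", "moderate"), levels = disability_states())
#' )
#' build_person_periods(rec)
build_person_periods <- function(records, max_gap = 4L, drop_long = FALSE) {
  if (is.null(records$state)) {
    stop("records must carry coded states", call. = FALSE)
  }
  rec <- records[order(records$subject_id, records$year), , drop = FALSE]
  same <- c(rec$subject_id[-1L] == rec$subject_id[-nrow(rec)], FALSE)
  i1 <- which(same)
  i2 <- i1 + 1L
  if (!length(i1)) {
    return(data.frame(subject_id = rec$subject_id[0], age_at_start = integer(),
                      male = integer(), origin = character(),
                      destination = character(), village = integer(),
                      region = integer()))
  }
  origin <- as.character(rec$state[i1])
  dest <- as.character(rec$state[i2])
  if (any(origin == .dead)) {
    stop("data-integrity error: interval starting in the dead state",
         call. = FALSE)
  }
  gap <- rec$year[i2] - rec$year[i1]
  if (drop_long && any(gap > max_gap)) {
    keep <- gap <= max_gap
    i1 <- i1[keep]; i2 <- i2[keep]
    origin <- origin[keep]; dest <- dest[keep]; gap <- gap[keep]
  }

  states <- levels(rec$state) %||% disability_states()
  # transition placed during year k0 (0-based offset) = floor(gap/2) - 1
  k0 <- gap %/% 2L - 1L
  n_rows <- ifelse(dest == .dead, k0 + 1L, gap)
  pair <- rep(seq_along(i1), n_rows)
  off <- sequence(n_rows) - 1L

  # off < k0: stay in origin; off == k0: origin -> dest; off > k0: stay dest
  kp <- k0[pair]
  o_p <- dest[pair]
  sel <- off <= kp
  o_p[sel] <- origin[pair][sel]
  d_p <- dest[pair]
  sel <- off < kp
  d_p[sel] <- origin[pair][sel]

  out <- data.frame(
    subject_id = rec$subject_id[i1][pair],
    age_at_start = rec$age[i1][pair] + off,
    male = rec$male[i1][pair],
    origin = factor(o_p, levels = states[-length(states)]),
    destination = factor(d_p, levels = states),
    village = rec$village[i1][pair],
    region = rec$region[i1][pair]
  )
  rownames(out) <- NULL
  out
}
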