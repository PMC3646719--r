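#' Synthetic cohort specification for the multistate life table
#'
#' Describes one synthetic cohort to be aged forward under a transition
#' schedule: starting age, cohort size, the joint initial distribution over
#' sex and living state, the age cap and the simulation seed.
#'
#' @param starting_age integer age at which the cohort starts (45+).
#' @param size cohort size (default 100,000).
#' @param initial_distribution numeric matrix, rows c("female", "male"),
#'   one column per living state, entries summing to 1 (the joint
#'   distribution of sex and initial state).
#' @param age_cap simulation cap in years; anyone still alive in the year
#'   before the cap receives a terminal half-year credit and dies (no one
#'   reaches the cap alive).
#' @param seed integer seed for the microsimulation stream.
#' @return object of class "cohort_spec".
#' @export
#' @examples
#' cohort_spec(65, size = 1000,
#'             initial_distribution = rbind(female = c(0.3, 0.15, 0.05),
#'                                          male = c(0.35, 0.1, 0.05)))
cohort_spec <- function(starting_age, size = 100000L,
                        initial_distribution, age_cap = 110L, seed = 1L) {
  stopifnot(starting_age >= 45, size >= 1, age_cap > starting_age)
  if (is.null(dim(initial_distribution)) || nrow(initial_distribution) != 2L) {
    stop("initial_distribution must be a 2-row (female, male) matrix",
         call. = FALSE)
  }
  rownames(initial_distribution) <- c("female", "male")
  check_prob_vector(as.vector(initial_distribution),
                    "initial_distribution (joint over sex x state)")
  structure(
    list(starting_age = as.integer(starting_age), size = as.integer(size),
         initial_distribution = initial_distribution,
         age_cap = as.integer(age_cap), seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Empirical sex-by-state distribution at a starting age
#'
#' The joint initial distribution for a synthetic cohort, taken from coded
#' records: living respondents within `band` years of the target age, over
#' all waves.
#'
#' @param records coded wave-level records.
#' @param age target starting age.
#' @param band half-width of the age window in years.
#' @param living living state labels (columns of the result).
#' @return 2 x n_living matrix (female, male) summing to 1.
#' @export
empirical_initial_distribution <- function(records, age, band = 2,
                                           living = living_states()) {
  ok <- records$vital_status == "alive" & !is.na(records$state) &
    records$state != .dead & abs(records$age - age) <= band
  r <- records[ok, , drop = FALSE]
  if (!nrow(r)) stop("no living respondents within the age band",
                     call. = FALSE)
  tab <- table(factor(ifelse(r$male == 1, "male", "female"),
                      levels = c("female", "male")),
               factor(as.character(r$state), levels = living))
  m <- unclass(tab) / sum(tab)
  m
}

# per-cycle person-year credits, shared by microsim and analytic propagator
# midcycle: stayers 1.0 in state; living movers 0.5 origin + 0.5 dest;
#           deaths 0.5 in origin
# fullyear: any living transition credits 1.0 to the origin state;
#           deaths credit 0.5 in origin
credit_rules <- function(credit) {
  credit <- match.arg(credit, c("midcycle", "fullyear"))
  credit
}

#' Microsimulation of a synthetic cohort
#'
#' Ages `spec$size` individuals forward one year at a time. Each starts at
#' (sex, state) drawn from the joint initial distribution; each annual cycle
#' draws a destination from the fitted annual transition probabilities at
#' the person's current age and sex. Person-year credits per cycle follow
#' the mid-cycle convention (stayers a full year in their state, living
#' movers half a year in origin and destination, deaths half a year in the
#' origin); survivors in the year before the age cap receive a terminal
#' half-year credit and die. Reproducible given `spec$seed`.
#'
#' @param params a "transition_params" (fitted or true).
#' @param spec a "cohort_spec".
#' @param credit "midcycle" (default) or "fullyear" (sensitivity variant in
#'   which living transitions credit the full year to the origin state).
#' @return object of class "occupancy": list with `py` (array
#'   age x sex x living state of person-years), `deaths` (age x sex),
#'   `person_years` (size x living-state matrix of per-person totals),
#'   `person_male` (0/1 per person), plus the spec, states and credit rule.
#' @export
run_microsim <- function(params, spec, credit = "midcycle") {
  stopifnot(inherits(params, "transition_params"),
            inherits(spec, "cohort_spec"))
  credit <- credit_rules(credit)
  set.seed(spec$seed)
  living <- params$living
  L <- length(living)
  if (ncol(spec$initial_distribution) != L) {
    stop("initial_distribution has ", ncol(spec$initial_distribution),
         " state columns but the model has ", L, " living states",
         call. = FALSE)
  }
  n <- spec$size
  p0 <- as.vector(t(spec$initial_distribution))  # (f,s1..sL, m,s1..sL)
  draw <- sample.int(2L * L, n, replace = TRUE, prob = p0)
  male <- as.integer(draw > L)
  state <- ifelse(draw > L, draw - L, draw)

  ages <- spec$starting_age:(spec$age_cap - 1L)
  py <- array(0, dim = c(length(ages), 2L, L),
              dimnames = list(ages, c("female", "male"), living))
  deaths <- matrix(0L, length(ages), 2L,
                   dimnames = list(ages, c("female", "male")))
  pys <- matrix(0, n, L, dimnames = list(NULL, living))
  alive <- rep(TRUE, n)
  ptab <- lapply(0:1, function(m) lapply(seq_len(L), function(s) {
    transition_probs(params, living[s], ages, m)[, c(living, params$dead),
                                                 drop = FALSE]
  }))

  for (ai in seq_along(ages)) {
    age <- ages[ai]
    idx_alive <- which(alive)
    if (!length(idx_alive)) break
    if (age == spec$age_cap - 1L) {
      # forced terminal death: half-year credit in the current state
      for (m in 0:1) for (s in seq_len(L)) {
        grp <- idx_alive[male[idx_alive] == m & state[idx_alive] == s]
        if (!length(grp)) next
        py[ai, m + 1L, s] <- py[ai, m + 1L, s] + 0.5 * length(grp)
        pys[grp, s] <- pys[grp, s] + 0.5
        deaths[ai, m + 1L] <- deaths[ai, m + 1L] + length(grp)
      }
      alive[idx_alive] <- FALSE
      break
    }
    u <- stats::runif(length(idx_alive))
    dest <- integer(length(idx_alive))
    for (m in 0:1) {
      for (s in seq_len(L)) {
        sel <- which(male[idx_alive] == m & state[idx_alive] == s)
        if (!length(sel)) next
        pr <- ptab[[m + 1L]][[s]][ai, ]
        dest[sel] <- findInterval(u[sel], cumsum(pr)[-length(pr)]) + 1L
      }
    }
    org <- state[idx_alive]
    died <- dest == L + 1L
    stay <- !died & dest == org
    move <- !died & !stay
    w_org <- ifelse(died, 0.5, ifelse(stay, 1,
                    if (credit == "midcycle") 0.5 else 1))
    pys[cbind(idx_alive, org)] <- pys[cbind(idx_alive, org)] + w_org
    if (credit == "midcycle" && any(move)) {
      pys[cbind(idx_alive[move], dest[move])] <-
        pys[cbind(idx_alive[move], dest[move])] + 0.5
    }
    for (m in 0:1) {
      mi <- male[idx_alive] == m
      for (s in seq_len(L)) {
        add <- sum(w_org[mi & org == s]) +
          if (credit == "midcycle") 0.5 * sum(mi & move & dest == s) else 0
        py[ai, m + 1L, s] <- py[ai, m + 1L, s] + add
      }
      deaths[ai, m + 1L] <- deaths[ai, m + 1L] + sum(died[mi])
    }
    state[idx_alive] <- ifelse(died, state[idx_alive], dest)
    alive[idx_alive[died]] <- FALSE
  }

  structure(
    list(py = py, deaths = deaths, person_years = pys, person_male = male,
         spec = spec, states = living, credit = credit,
         source = "microsim"),
    class = "occupancy"
  )
}

#' @export
print.occupancy <- function(x, ...) {
  cat("State occupancy (", x$source, "), cohort of ", x$spec$size,
      " starting at age ", x$spec$starting_age, "\n", sep = "")
  cat("total person-years:", format(sum(x$py), digits = 8), "\n")
  invisible(x)
}

#' Health expectancies from a state-occupancy table
#'
#' Expected remaining years in each living state: person-years credited to
#' the state divided by the number of cohort members (within the sex stratum
#' when `by_sex`). Total expectancy is the sum over states, exactly
#' additive. Monte-Carlo standard errors (microsimulation occupancies only)
#' are attached as columns `se_<state>` and `se_total`.
#'
#' @param occ an "occupancy" from [run_microsim()] or
#'   [analytic_expectancies()]'s internal propagator.
#' @param by_sex also report per-sex strata (default TRUE).
#' @return data frame ("he_table"): one row per stratum with columns
#'   starting_age, sex ("female"/"male"/"all"), n, one expectancy column per
#'   living state, and total.
#' @export
health_expectancies <- function(occ, by_sex = TRUE) {
  stopifnot(inherits(occ, "occupancy"))
  L <- length(occ$states)
  strata <- if (by_sex) c("female", "male", "all") else "all"
  rows <- list()
  for (sx in strata) {
    if (occ$source == "microsim") {
      sel <- switch(sx, female = occ$person_male == 0L,
                    male = occ$person_male == 1L,
                    all = rep(TRUE, length(occ$person_male)))
      n <- sum(sel)
      if (n == 0L) {
        e <- rep(NA_real_, L); se <- rep(NA_real_, L)
        se_tot <- NA_real_
      } else {
        sub <- occ$person_years[sel, , drop = FALSE]
        e <- colMeans(sub)
        se <- apply(sub, 2L, stats::sd) / sqrt(n)
        se_tot <- stats::sd(rowSums(sub)) / sqrt(n)
      }
    } else {
      mass <- occ$initial_mass  # per sex
      n <- switch(sx, female = mass[1L], male = mass[2L], all = sum(mass))
      pysx <- switch(sx,
        female = apply(occ$py[, 1L, , drop = FALSE], 3L, sum),
        male = apply(occ$py[, 2L, , drop = FALSE], 3L, sum),
        all = apply(occ$py, 3L, sum))
      e <- if (n > 0) pysx / n else rep(NA_real_, L)
      se <- rep(0, L); se_tot <- 0
    }
    row <- data.frame(starting_age = occ$spec$starting_age, sex = sx, n = n)
    for (j in seq_len(L)) row[[occ$states[j]]] <- e[j]
    row$total <- sum(e)
    for (j in seq_len(L)) row[[paste0("se_", occ$states[j])]] <- se[j]
    row$se_total <- se_tot
    rows[[sx]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("he_table", "data.frame")
  out
}

#' Proportions of remaining life by state
#'
#' Per stratum, each state expectancy divided by the total.
#'
#' @param he a "he_table" from [health_expectancies()].
#' @param states living state labels present in `he`.
#' @return data frame with the expectancy columns replaced by proportions.
#' @export
he_proportions <- function(he, states = intersect(living_states(),
                                                  names(he))) {
  out <- he[c("starting_age", "sex", "n", "total")]
  for (s in states) out[[paste0("prop_", s)]] <- he[[s]] / he$total
  out
}

# deterministic cohort projection sharing the microsim's crediting rules
propagate_cohort <- function(params, spec, credit = "midcycle") {
  credit <- credit_rules(credit)
  living <- params$living
  L <- length(living)
  ages <- spec$starting_age:(spec$age_cap - 1L)
  py <- array(0, dim = c(length(ages), 2L, L),
              dimnames = list(ages, c("female", "male"), living))
  deaths <- matrix(0, length(ages), 2L,
                   dimnames = list(ages, c("female", "male")))
  x <- t(spec$initial_distribution)  # L x 2 (cols female, male)
  mass0 <- colSums(x)
  # precompute per-sex, per-origin probabilities over the whole age range
  ptab <- lapply(0:1, function(m) lapply(seq_len(L), function(s) {
    transition_probs(params, living[s], ages, m)[, c(living, params$dead),
                                                 drop = FALSE]
  }))
  for (ai in seq_along(ages)) {
    age <- ages[ai]
    if (age == spec$age_cap - 1L) {
      py[ai, , ] <- t(x) * 0.5
      deaths[ai, ] <- colSums(x)
      x[] <- 0
      break
    }
    for (m in 0:1) {
      P <- matrix(0, L, L + 1L)
      for (s in seq_len(L)) P[s, ] <- ptab[[m + 1L]][[s]][ai, ]
      xs <- x[, m + 1L]
      Pl <- P[, seq_len(L), drop = FALSE]
      pd <- P[, L + 1L]
      flow <- xs * Pl                     # flow[i, j] = mass i -> j
      stay_credit <- diag(flow)
      move_out <- rowSums(flow) - stay_credit
      move_in <- colSums(flow) - stay_credit
      if (credit == "midcycle") {
        py[ai, m + 1L, ] <- py[ai, m + 1L, ] + stay_credit +
          0.5 * move_out + 0.5 * move_in + 0.5 * xs * pd
      } else {
        py[ai, m + 1L, ] <- py[ai, m + 1L, ] + stay_credit + move_out +
          0.5 * xs * pd
      }
      deaths[ai, m + 1L] <- deaths[ai, m + 1L] + sum(xs * pd)
      x[, m + 1L] <- colSums(flow)
    }
  }
  structure(
    list(py = py, deaths = deaths, person_years = NULL, person_male = NULL,
         spec = spec, states = living, credit = credit,
         initial_mass = mass0, source = "analytic"),
    class = "occupancy"
  )
}

#' Exact matrix-propagation health expectancies
#'
#' Deterministic counterpart of [run_microsim()]: propagates the expected
#' state-occupancy vector through the age-specific transition matrices with
#' the identical crediting rules, yielding the exact expected value of every
#' microsimulation cell (no Monte-Carlo error). Serves as the oracle the
#' microsimulation is checked against.
#'
#' @inheritParams run_microsim
#' @param by_sex report per-sex strata.
#' @return a "he_table" (see [health_expectancies()]). The underlying
#'   occupancy is attached as attribute "occupancy".
#' @export
analytic_expectancies <- function(params, spec, credit = "midcycle",
                                  by_sex = TRUE) {
  occ <- propagate_cohort(params, spec, credit)
  he <- health_expectancies(occ, by_sex = by_sex)
  # analytic expectancies are per unit initial mass; scale n to spec size
  he$n <- he$n * spec$size
  attr(he, "occupancy") <- occ
  he
}

#' Health expectancies conditional on the initial disability state
#'
#' Identical to the unconditional table but with the entire cohort started
#' in one living state; the sex mix is unchanged (the marginal sex
#' distribution of `spec$initial_distribution` is kept).
#'
#' @inheritParams run_microsim
#' @param initial_state a living state label.
#' @param method "analytic" (exact propagation, default) or "microsim".
#' @return a "he_table" with an extra column `conditioned_on`.
#' @export
conditional_expectancies <- function(params, spec, initial_state,
                                     method = c("analytic", "microsim"),
                                     credit = "midcycle") {
  method <- match.arg(method)
  living <- params$living
  if (!initial_state %in% living) {
    stop("initial_state must be a living state", call. = FALSE)
  }
  sex_marg <- rowSums(spec$initial_distribution)
  init <- matrix(0, 2L, length(living),
                 dimnames = list(c("female", "male"), living))
  init[, initial_state] <- sex_marg
  spec2 <- cohort_spec(spec$starting_age, spec$size, init, spec$age_cap,
                       spec$seed)
  he <- if (method == "analytic") {
    analytic_expectancies(params, spec2, credit = credit)
  } else {
    health_expectancies(run_microsim(params, spec2, credit = credit))
  }
  he$conditioned_on <- initial_state
  he
}
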