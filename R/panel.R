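#' Specification of a synthetic three-wave survey population
#'
#' Describes the true population from which the synthetic panel generator
#' simulates: who is sampled (ages 45+, sex ratio, village/region
#' clustering), the true annual transition schedule driving latent health
#' histories, the survey design (wave calendar years), per-wave attrition,
#' and the state-conditional distributions of the auxiliary items. The
#' defaults emulate a three-wave biennial rural survey of mature adults:
#' ~2,000 subjects aged 45+ clustered in 121 villages over 3 regions,
#' interviewed in 2006, 2008 and 2010, with initial disability prevalence by
#' age band matching the first-wave cross-tab of such a survey and attrition
#' that rises with age and limitation.
#'
#' @param n_subjects number of subjects sampled at the first wave.
#' @param sex_ratio proportion male in [0, 1].
#' @param n_villages,n_regions cluster counts; villages are assigned to
#'   regions in contiguous blocks.
#' @param wave_years strictly increasing calendar years of the waves.
#' @param age_distribution list(ages=, weights=): distribution of integer
#'   age at the first wave (ages >= 45).
#' @param initial_state_distribution list(breaks=, probs=): age-band lower
#'   breaks and a matrix of initial living-state probabilities, one row per
#'   band, rows summing to 1.
#' @param true_params "transition_params" object driving the latent annual
#'   histories.
#' @param attrition named vector c(intercept, age, moderate, severe) of a
#'   per-wave response logit: P(respond) = plogis(intercept + age*(age-45) +
#'   moderate*I(state==moderate) + severe*I(state==severe)). Death is always
#'   ascertained regardless of response. Use attrition = NULL (or a +Inf
#'   intercept) for full response.
#' @param too_ill_prob probability that a severely limited respondent is too
#'   ill to answer the items (interviewer codes the flag, items missing).
#' @param aux list of state-conditional auxiliary item distributions:
#'   `work` (P(worked for income) per living state), `pain` and
#'   `satisfaction` (matrices, one row per living state, columns the 5
#'   ordered levels), `missing_prob` (independent item missingness).
#' @param age_cap latent simulation cap in years; anyone reaching it is
#'   recorded dead in that year.
#' @param seed integer seed; one seed controls population, histories,
#'   attrition and items, in that fixed order.
#' @return object of class "panel_spec".
#' @export
#' @examples
#' sp <- panel_spec(n_subjects = 200, seed = 7)
#' pan <- simulate_panel(sp)
#' head(pan$records)
panel_spec <- function(n_subjects = 2000,
                       sex_ratio = 0.47,
                       n_villages = 121,
                       n_regions = 3,
                       wave_years = c(2006, 2008, 2010),
                       age_distribution = list(
                         ages = 45:89,
                         weights = exp(-0.07 * (0:44))
                       ),
                       initial_state_distribution = list(
                         breaks = c(45, 65),
                         probs = rbind(c(0.724, 0.223, 0.053),
                                       c(0.540, 0.317, 0.143))
                       ),
                       true_params = default_true_params(),
                       attrition = c(intercept = 2.8, age = -0.025,
                                     moderate = -0.35, severe = -0.7),
                       too_ill_prob = 0.02,
                       aux = list(
                         work = c(healthy = 0.38, moderate = 0.32,
                                  severe = 0.20),
                         pain = rbind(
                           healthy  = c(0.60, 0.25, 0.10, 0.04, 0.01),
                           moderate = c(0.15, 0.33, 0.30, 0.17, 0.05),
                           severe   = c(0.05, 0.20, 0.30, 0.30, 0.15)
                         ),
                         satisfaction = rbind(
                           healthy  = c(0.35, 0.45, 0.16, 0.03, 0.01),
                           moderate = c(0.25, 0.45, 0.20, 0.08, 0.02),
                           severe   = c(0.15, 0.35, 0.23, 0.17, 0.10)
                         ),
                         missing_prob = 0.01
                       ),
                       age_cap = 110,
                       seed = 1L) {
  stopifnot(n_subjects >= 1, n_villages >= 1, n_regions >= 1,
            sex_ratio >= 0, sex_ratio <= 1)
  if (any(diff(wave_years) <= 0)) {
    stop("wave_years must be strictly increasing", call. = FALSE)
  }
  if (any(age_distribution$ages < 45)) {
    stop("age_distribution covers ages >= 45 only", call. = FALSE)
  }
  w <- age_distribution$weights
  if (any(w < 0) || sum(w) <= 0) stop("invalid age weights", call. = FALSE)
  age_distribution$weights <- w / sum(w)
  pr <- initial_state_distribution$probs
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
  for (i in seq_len(nrow(pr))) {
    check_prob_vector(pr[i, ], "initial_state_distribution row")
  }
  initial_state_distribution$probs <- pr
  if (!inherits(true_params, "transition_params")) {
    stop("true_params must be a transition_params object", call. = FALSE)
  }
  for (s in living_states()) {
    check_prob_vector(aux$pain[s, ], paste("aux$pain", s))
    check_prob_vector(aux$satisfaction[s, ], paste("aux$satisfaction", s))
  }
  structure(
    list(n_subjects = as.integer(n_subjects), sex_ratio = sex_ratio,
         n_villages = as.integer(n_villages),
         n_regions = as.integer(n_regions),
         wave_years = as.integer(wave_years),
         age_distribution = age_distribution,
         initial_state_distribution = initial_state_distribution,
         true_params = true_params, attrition = attrition,
         too_ill_prob = too_ill_prob, aux = aux,
         age_cap = as.integer(age_cap), seed = as.integer(seed)),
    class = "panel_spec"
  )
}

# initial living-state probabilities for a vector of ages
initial_state_probs <- function(spec, ages) {
  band <- findInterval(ages, spec$initial_state_distribution$breaks)
  band[band < 1] <- 1L
  band[band > nrow(spec$initial_state_distribution$probs)] <-
    nrow(spec$initial_state_distribution$probs)
  spec$initial_state_distribution$probs[band, , drop = FALSE]
}

# draw one categorical outcome per row of a probability matrix
draw_categorical <- function(P) {
  cum <- t(apply(P, 1L, cumsum))
  u <- stats::runif(nrow(P))
  1L + rowSums(u > cum)
}

#' Simulate latent annual health histories
#'
#' Draws the population (sex, village, region, entry age, initial state at
#' the first wave year) and simulates each subject's state annually as a
#' first-order Markov chain under the spec's true transition schedule, from
#' the first wave year until death or the age cap (anyone reaching the cap
#' is recorded dead in that year). Reproducible given `spec$seed`.
#'
#' @param spec a "panel_spec".
#' @return object of class "latent_histories": list with `subjects` (one row
#'   per subject: subject_id, male, village, region, entry_age) and `paths`
#'   (long data frame: subject_id, year, age, state) covering every year
#'   from entry to death (inclusive) or the cap.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  states <- spec$true_params$states
  living <- spec$true_params$living
  ndead <- length(states)

  male <- as.integer(stats::runif(n) < spec$sex_ratio)
  village <- sample.int(spec$n_villages, n, replace = TRUE)
  region <- ceiling(village * spec$n_regions / spec$n_villages)
  entry_age <- sample(spec$age_distribution$ages, n, replace = TRUE,
                      prob = spec$age_distribution$weights)
  st0 <- draw_categorical(initial_state_probs(spec, entry_age))

  y0 <- spec$wave_years[1L]
  max_steps <- spec$age_cap - min(entry_age)
  state_mat <- matrix(NA_integer_, n, max_steps + 1L)
  state_mat[, 1L] <- st0
  cur <- st0
  for (step in seq_len(max_steps)) {
    age <- entry_age + step - 1L
    alive <- which(cur < ndead & age <= spec$age_cap - 1L)
    nxt <- cur
    nxt[cur == ndead] <- ndead
    if (length(alive)) {
      # forced terminal death in the year reaching the cap
      at_cap <- alive[age[alive] == spec$age_cap - 1L]
      todo <- setdiff(alive, at_cap)
      u <- stats::runif(length(alive))
      names(u) <- as.character(alive)
      for (si in seq_along(living)) {
        grp <- todo[cur[todo] == si]
        if (!length(grp)) next
        P <- transition_probs(spec$true_params, living[si], age[grp],
                              male[grp])
        cum <- t(apply(P, 1L, cumsum))
        nxt[grp] <- 1L + rowSums(u[as.character(grp)] > cum)
      }
      nxt[at_cap] <- ndead
    }
    state_mat[, step + 1L] <- nxt
    cur <- nxt
    if (all(cur == ndead)) {
      state_mat <- state_mat[, seq_len(step + 1L), drop = FALSE]
      break
    }
  }

  # long paths: entry year .. year of death (inclusive) or last simulated
  n_steps <- ncol(state_mat)
  keep <- !is.na(state_mat)
  # truncate after first dead year per subject
  first_dead <- apply(state_mat == ndead, 1L, function(z) {
    i <- which(z)
    if (length(i)) i[1L] else ncol(state_mat)
  })
  col_idx <- col(state_mat)
  keep <- keep & (col_idx <= first_dead[row(state_mat)])
  # drop years past the cap for immortals (cannot happen: forced death)
  sub <- row(state_mat)[keep]
  stp <- col_idx[keep]
  ord <- order(sub, stp)
  sub <- sub[ord]; stp <- stp[ord]
  paths <- data.frame(
    subject_id = sub,
    year = y0 + stp - 1L,
    age = entry_age[sub] + stp - 1L,
    state = factor(states[state_mat[cbind(sub, stp)]], levels = states)
  )
  subjects <- data.frame(subject_id = seq_len(n), male = male,
                         village = village, region = region,
                         entry_age = entry_age)
  structure(list(subjects = subjects, paths = paths, spec_seed = spec$seed),
            class = "latent_histories")
}

#' @export
print.latent_histories <- function(x, ...) {
  cat("Latent annual health histories:", nrow(x$subjects), "subjects,",
      nrow(x$paths), "person-years\n")
  invisible(x)
}

# latent state of each subject at a given calendar year (NA once truncated)
state_at_year <- function(histories, year) {
  p <- histories$paths[histories$paths$year == year, ]
  st <- rep(NA_character_, nrow(histories$subjects))
  st[p$subject_id] <- as.character(p$state)
  # subjects whose path ended (dead) before this year stay dead
  last <- tapply(as.character(histories$paths$state),
                 histories$paths$subject_id, function(s) s[length(s)])
  lasty <- tapply(histories$paths$year, histories$paths$subject_id, max)
  idx <- as.integer(names(lasty))
  gone <- idx[lasty < year & last == .dead]
  st[gone] <- .dead
  st
}

#' Observe latent histories through the survey instrument
#'
#' Produces one wave-level record per subject per attended wave. Every
#' subject is interviewed at the first wave; at later waves response follows
#' the spec's attrition logit in age and current limitation state. Deaths
#' between waves always produce a vital-status "dead" record at the first
#' wave after death (mortality is ascertained by the survey team even for
#' non-respondents); dead subjects produce no later records. Limitation
#' items are realised so that the three-level coding inverts the latent
#' state exactly: healthy -> both items "not limited"; moderate -> one item
#' (chosen uniformly) "limited a little", the other "not limited"; severe ->
#' one item (chosen uniformly) "limited a lot", the other "limited a
#' little", unless the respondent is drawn too-ill (items missing, flag
#' set). Auxiliary items are drawn independently across waves given state.
#'
#' @param histories a "latent_histories" from [generate_population()].
#' @param spec the same "panel_spec".
#' @return data frame of wave-level records: subject_id, wave, year, age,
#'   male, village, region, vital_status ("alive"/"dead"), moderate_item,
#'   strenuous_item, too_ill, pain_item, work_income, life_sat.
#' @export
observe_waves <- function(histories, spec) {
  stopifnot(inherits(histories, "latent_histories"),
            inherits(spec, "panel_spec"))
  set.seed(spec$seed + 1L)
  subj <- histories$subjects
  lv <- item_levels()
  dead_reported <- rep(FALSE, nrow(subj))
  out <- list()

  for (w in seq_along(spec$wave_years)) {
    yw <- spec$wave_years[w]
    st <- state_at_year(histories, yw)
    age_w <- subj$entry_age + (yw - spec$wave_years[1L])
    is_dead <- !is.na(st) & st == .dead

    # death rows: first wave at which the subject is dead
    drow <- which(is_dead & !dead_reported)
    dead_reported[is_dead] <- TRUE

    alive <- which(!is.na(st) & st != .dead)
    if (w == 1L) {
      resp <- alive
    } else if (is.null(spec$attrition)) {
      resp <- alive
    } else {
      a <- spec$attrition
      eta <- a[["intercept"]] + a[["age"]] * (age_w[alive] - 45) +
        a[["moderate"]] * (st[alive] == "moderate") +
        a[["severe"]] * (st[alive] == "severe")
      resp <- alive[stats::runif(length(alive)) < stats::plogis(eta)]
    }

    n_r <- length(resp)
    mod_it <- str_it <- rep(NA_character_, n_r)
    too_ill <- rep(FALSE, n_r)
    if (n_r) {
      s_r <- st[resp]
      pick <- stats::runif(n_r) < 0.5  # which item carries the limitation
      h <- s_r == "healthy"
      mod_it[h] <- str_it[h] <- "not limited"
      m <- s_r == "moderate"
      mod_it[m] <- ifelse(pick[m], "limited a little", "not limited")
      str_it[m] <- ifelse(pick[m], "not limited", "limited a little")
      sv <- s_r == "severe"
      ill <- sv & (stats::runif(n_r) < spec$too_ill_prob)
      sv_it <- sv & !ill
      mod_it[sv_it] <- ifelse(pick[sv_it], "limited a lot",
                              "limited a little")
      str_it[sv_it] <- ifelse(pick[sv_it], "limited a little",
                              "limited a lot")
      too_ill[ill] <- TRUE
      mod_it[ill] <- str_it[ill] <- NA_character_

      # auxiliary items, conditional on state, independent across waves
      sidx <- match(s_r, living_states())
      work <- as.integer(stats::runif(n_r) < spec$aux$work[sidx])
      pain <- draw_categorical(spec$aux$pain[sidx, , drop = FALSE])
      sat <- draw_categorical(spec$aux$satisfaction[sidx, , drop = FALSE])
      miss <- matrix(stats::runif(3L * n_r) < spec$aux$missing_prob,
                     n_r, 3L)
      work[miss[, 1L]] <- NA_integer_
      pain[miss[, 2L]] <- NA_integer_
      sat[miss[, 3L]] <- NA_integer_
      pain_lab <- lv$pain$label[pain]
      sat_lab <- lv$satisfaction$label[sat]

      out[[length(out) + 1L]] <- data.frame(
        subject_id = subj$subject_id[resp], wave = w, year = yw,
        age = age_w[resp], male = subj$male[resp],
        village = subj$village[resp], region = subj$region[resp],
        vital_status = "alive",
        moderate_item = mod_it, strenuous_item = str_it, too_ill = too_ill,
        pain_item = pain_lab, work_income = work, life_sat = sat_lab,
        stringsAsFactors = FALSE
      )
    }
    if (length(drow)) {
      out[[length(out) + 1L]] <- data.frame(
        subject_id = subj$subject_id[drow], wave = w, year = yw,
        age = age_w[drow], male = subj$male[drow],
        village = subj$village[drow], region = subj$region[drow],
        vital_status = "dead",
        moderate_item = NA_character_, strenuous_item = NA_character_,
        too_ill = FALSE, pain_item = NA_character_,
        work_income = NA_integer_, life_sat = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  rec <- do.call(rbind, out)
  rec <- rec[order(rec$subject_id, rec$wave), ]
  rownames(rec) <- NULL
  rec
}

#' Simulate a complete synthetic panel
#'
#' Convenience wrapper: [generate_population()] then [observe_waves()].
#'
#' @param spec a "panel_spec".
#' @return list with `records` (wave-level records) and `truth` (the
#'   "latent_histories" sidecar for oracle checks).
#' @export
simulate_panel <- function(spec) {
  truth <- generate_population(spec)
  list(records = observe_waves(truth, spec), truth = truth)
}
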