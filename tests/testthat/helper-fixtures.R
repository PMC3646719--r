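# shared fixtures built in code

# small parameter set with mild age effects, no structural zeros
tiny_params <- function() {
  transition_params(list(
    healthy = rbind(moderate = c(-2.5, 0.04, 1e-4, -0.3),
                    severe   = c(-3.5, 0.06, 2e-4, -0.2),
                    dead     = c(-4.0, 0.07, 2e-4, 0.3)),
    moderate = rbind(healthy  = c(-1.0, -0.05, 1e-4, 0.2),
                     severe   = c(-2.2, 0.05, 2e-4, -0.2),
                     dead     = c(-3.4, 0.07, 2e-4, 0.3)),
    severe = rbind(healthy  = c(-2.4, -0.08, 0, 0.2),
                   moderate = c(-1.5, -0.04, 1e-4, 0.1),
                   dead     = c(-2.5, 0.06, 3e-4, 0.2))
  ))
}

# parameters with every transition probability forced ~0 except stay
frozen_params <- function() {
  transition_params(list(
    healthy  = rbind(moderate = c(-40, 0, 0, 0), severe = c(-40, 0, 0, 0),
                     dead = c(-40, 0, 0, 0)),
    moderate = rbind(healthy = c(-40, 0, 0, 0), severe = c(-40, 0, 0, 0),
                     dead = c(-40, 0, 0, 0)),
    severe   = rbind(healthy = c(-40, 0, 0, 0), moderate = c(-40, 0, 0, 0),
                     dead = c(-40, 0, 0, 0))
  ))
}

# certain death from every state at every age
certain_death_params <- function() {
  transition_params(list(
    healthy  = rbind(dead = c(40, 0, 0, 0)),
    moderate = rbind(dead = c(40, 0, 0, 0)),
    severe   = rbind(dead = c(40, 0, 0, 0))
  ))
}

# constant annual death probability q, no disability dynamics
constant_q_params <- function(q) {
  b0 <- log(q / (1 - q))
  transition_params(list(
    healthy  = rbind(dead = c(b0, 0, 0, 0)),
    moderate = rbind(dead = c(b0, 0, 0, 0)),
    severe   = rbind(dead = c(b0, 0, 0, 0))
  ))
}

# draw a random well-behaved parameter set (uses the current RNG stream)
random_params <- function() {
  rc <- function() c(runif(1, -5, -1.5), runif(1, -0.04, 0.07),
                     runif(1, 0, 4e-4), runif(1, -0.5, 0.5))
  transition_params(list(
    healthy  = rbind(moderate = rc(), severe = rc(), dead = rc()),
    moderate = rbind(healthy = rc(), severe = rc(), dead = rc()),
    severe   = rbind(healthy = rc(), moderate = rc(), dead = rc())
  ))
}

# balanced sex/state initial mix
even_init <- function(living = living_states()) {
  m <- matrix(1 / (2 * length(living)), 2, length(living),
              dimnames = list(c("female", "male"), living))
  m
}

# a small wave-record data frame from explicit per-subject wave histories;
# `waves` is a list: each element list(subject_id, waves, years, ages,
# states, male, village)
manual_records <- function(subjects) {
  rows <- lapply(subjects, function(s) {
    k <- length(s$waves)
    data.frame(
      subject_id = s$subject_id, wave = s$waves, year = s$years,
      age = s$ages, male = s$male %||% 0,
      village = s$village %||% 1, region = s$region %||% 1,
      vital_status = s$vital_status %||% rep("alive", k),
      state = factor(s$states, levels = disability_states()),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast default panel used by several tests
small_panel_spec <- function(n = 400, seed = 42, ...) {
  panel_spec(n_subjects = n, seed = seed, ...)
}
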