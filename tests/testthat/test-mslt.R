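test_that("certain death gives total LE of exactly half a year", {
  cs <- cohort_spec(65, size = 2000, initial_distribution = even_init(),
                    seed = 1)
  he_m <- health_expectancies(run_microsim(certain_death_params(), cs))
  expect_equal(he_m$total[he_m$sex == "all"], 0.5, tolerance = 1e-12)
  he_a <- analytic_expectancies(certain_death_params(), cs)
  expect_equal(he_a$total[he_a$sex == "all"], 0.5, tolerance = 1e-12)
})

test_that("constant death probability reproduces the geometric closed form", {
  q <- 0.5
  cs <- cohort_spec(45, size = 100000, initial_distribution = even_init(),
                    age_cap = 110, seed = 7)
  # finite-cap geometric sum: N normal cycles then forced terminal death
  N <- cs$age_cap - 1 - cs$starting_age
  le_exact <- (1 - (1 - q)^N) / q * (1 - 0.5 * q) + 0.5 * (1 - q)^N
  expect_equal(le_exact, 1.5, tolerance = 1e-9)  # tail is negligible here
  he_a <- analytic_expectancies(constant_q_params(q), cs)
  expect_equal(he_a$total[he_a$sex == "all"], le_exact, tolerance = 1e-9)
  occ <- run_microsim(constant_q_params(q), cs)
  he_m <- health_expectancies(occ)
  mc_se <- he_m$se_total[he_m$sex == "all"]
  expect_lt(abs(he_m$total[he_m$sex == "all"] - le_exact), 3 * mc_se)
})

test_that("zero mortality until the cap gives the deterministic credit", {
  # all start healthy at 75, no transitions, cap 110: 34 full years + 0.5
  init <- matrix(0, 2, 3, dimnames = list(c("female", "male"),
                                          living_states()))
  init["female", "healthy"] <- 0.5
  init["male", "healthy"] <- 0.5
  cs <- cohort_spec(75, size = 500, initial_distribution = init,
                    age_cap = 110, seed = 3)
  he <- health_expectancies(run_microsim(frozen_params(), cs))
  expect_equal(he$healthy[he$sex == "all"], 34.5, tolerance = 1e-12)
  expect_equal(he$moderate[he$sex == "all"], 0)
  expect_equal(he$severe[he$sex == "all"], 0)
  expect_equal(he$total[he$sex == "all"], 34.5, tolerance = 1e-12)
  # all microsimulation SEs are zero: the outcome is deterministic
  expect_equal(he$se_total[he$sex == "all"], 0)
})

test_that("expectancies are additive and proportions normalised", {
  cs <- cohort_spec(55, size = 5000, initial_distribution = even_init(),
                    seed = 11)
  for (he in list(health_expectancies(run_microsim(tiny_params(), cs)),
                  analytic_expectancies(tiny_params(), cs))) {
    expect_equal(he$healthy + he$moderate + he$severe, he$total,
                 tolerance = 1e-9)
    pr <- he_proportions(he)
    expect_equal(pr$prop_healthy + pr$prop_moderate + pr$prop_severe,
                 rep(1, nrow(pr)), tolerance = 1e-9)
  }
})

test_that("microsimulation matches the analytic propagator within MC error", {
  cs <- cohort_spec(65, size = 40000, initial_distribution = even_init(),
                    seed = 19)
  he_a <- analytic_expectancies(tiny_params(), cs)
  he_m <- health_expectancies(run_microsim(tiny_params(), cs))
  for (sx in c("female", "male", "all")) {
    for (st in c("healthy", "moderate", "severe", "total")) {
      se <- he_m[[paste0("se_", st)]][he_m$sex == sx]
      expect_lt(abs(he_m[[st]][he_m$sex == sx] - he_a[[st]][he_a$sex == sx]),
                4 * se + 1e-9)
    }
  }
})

test_that("occupancy bookkeeping is conserved", {
  cs <- cohort_spec(70, size = 3000, initial_distribution = even_init(),
                    seed = 23)
  occ <- run_microsim(tiny_params(), cs)
  # all cohort members die before the cap
  expect_equal(sum(occ$deaths), cs$size)
  # aggregate person-years equal the per-person totals
  expect_equal(sum(occ$py), sum(occ$person_years), tolerance = 1e-9)
  expect_lte(sum(occ$py), cs$size * (cs$age_cap - cs$starting_age))
  expect_true(all(occ$py >= 0))
})

test_that("conditional expectancies respect their initial state", {
  # leaving healthy impossible except death: conditional moderate/severe = 0
  p <- transition_params(list(
    healthy = rbind(dead = c(-3, 0.05, 0, 0)),
    moderate = rbind(healthy = c(-1, 0, 0, 0), dead = c(-2, 0.05, 0, 0)),
    severe = rbind(dead = c(-1, 0.05, 0, 0))
  ))
  cs <- cohort_spec(55, size = 2000, initial_distribution = even_init(),
                    seed = 5)
  heh <- conditional_expectancies(p, cs, "healthy")
  expect_equal(heh$moderate[heh$sex == "all"], 0)
  expect_equal(heh$severe[heh$sex == "all"], 0)
  expect_gt(heh$healthy[heh$sex == "all"], 0)
})

test_that("conditional tables mix back to the unconditional table", {
  cs <- cohort_spec(60, size = 1000, initial_distribution =
                      rbind(female = c(0.30, 0.15, 0.08),
                            male = c(0.25, 0.12, 0.10)), seed = 9)
  p <- tiny_params()
  un <- analytic_expectancies(p, cs)
  cols <- c("healthy", "moderate", "severe", "total")
  mix <- 0
  for (s in living_states()) {
    cnd <- conditional_expectancies(p, cs, s)
    j <- match(s, living_states())
    # weight each sex's conditional row by the joint (sex, state) mass
    mix <- mix + cs$initial_distribution["female", j] *
      as.matrix(cnd[cnd$sex == "female", cols]) +
      cs$initial_distribution["male", j] *
      as.matrix(cnd[cnd$sex == "male", cols])
  }
  expect_equal(as.vector(mix),
               as.vector(as.matrix(un[un$sex == "all", cols])),
               tolerance = 1e-9)
})

test_that("severe start never outlives a healthy start under dominance", {
  # severe mortality dominates healthy mortality at every age
  set.seed(33)
  for (rep in 1:5) {
    p <- random_params()
    # enforce stochastic ordering of mortality by construction
    p$coef$severe["dead", "intercept"] <-
      p$coef$healthy["dead", "intercept"] + runif(1, 0.5, 1.5)
    p$coef$severe["dead", "age"] <- p$coef$healthy["dead", "age"]
    p$coef$severe["dead", "age2"] <- p$coef$healthy["dead", "age2"]
    p$coef$severe["dead", "male"] <- p$coef$healthy["dead", "male"]
    # make non-death dynamics identical across states so only mortality
    # differs through the starting state
    cs <- cohort_spec(65, size = 1000, initial_distribution = even_init(),
                      seed = rep)
    hh <- conditional_expectancies(p, cs, "healthy")
    hs <- conditional_expectancies(p, cs, "severe")
    expect_lte(hs$total[hs$sex == "all"],
               hh$total[hh$sex == "all"] + 1e-9)
  }
})

test_that("empty sex stratum is reported missing", {
  init <- matrix(0, 2, 3, dimnames = list(c("female", "male"),
                                          living_states()))
  init["female", "healthy"] <- 1
  cs <- cohort_spec(65, size = 200, initial_distribution = init, seed = 2)
  he <- health_expectancies(run_microsim(tiny_params(), cs))
  expect_true(is.na(he$total[he$sex == "male"]))
  expect_false(is.na(he$total[he$sex == "female"]))
})

test_that("full-year crediting variant credits movers to the origin state", {
  # one-way street: healthy -> dead via moderate with certainty each year
  p <- transition_params(list(
    healthy = rbind(moderate = c(40, 0, 0, 0)),
    moderate = rbind(dead = c(40, 0, 0, 0)),
    severe = rbind(dead = c(40, 0, 0, 0))
  ))
  init <- matrix(0, 2, 3, dimnames = list(c("female", "male"),
                                          living_states()))
  init["female", "healthy"] <- 1
  cs <- cohort_spec(60, size = 100, initial_distribution = init, seed = 4)
  he_mid <- health_expectancies(run_microsim(p, cs, credit = "midcycle"))
  he_full <- health_expectancies(run_microsim(p, cs, credit = "fullyear"))
  # midcycle: 0.5 healthy + (0.5 + 0.5) moderate; fullyear: 1.0 + 0.5
  expect_equal(he_mid$healthy[he_mid$sex == "all"], 0.5)
  expect_equal(he_mid$moderate[he_mid$sex == "all"], 1.0)
  expect_equal(he_full$healthy[he_full$sex == "all"], 1.0)
  expect_equal(he_full$moderate[he_full$sex == "all"], 0.5)
  # analytic propagator agrees with both conventions
  for (cr in c("midcycle", "fullyear")) {
    ha <- analytic_expectancies(p, cs, credit = cr)
    hm <- health_expectancies(run_microsim(p, cs, credit = cr))
    expect_equal(ha$total[ha$sex == "all"], hm$total[hm$sex == "all"],
                 tolerance = 1e-9)
  }
})
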