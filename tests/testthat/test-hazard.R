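test_that("intercept-only multinomial MLE equals empirical proportions", {
  set.seed(1)
  dest <- rep(c("healthy", "moderate", "severe", "dead"),
              times = c(70, 20, 5, 5))
  pp <- data.frame(
    subject_id = seq_along(dest), age_at_start = sample(45:80, 100, TRUE),
    male = rbinom(100, 1, 0.5),
    origin = factor("healthy", levels = living_states()),
    destination = factor(dest, levels = disability_states()),
    village = 1, region = 1
  )
  fit <- fit_transition_model(pp, terms = character(0))
  P <- transition_probs(fit$params, "healthy", 60, 1)
  expect_equal(as.vector(P),
               c(0.70, 0.20, 0.05, 0.05), tolerance = 1e-7)
})

test_that("inverse multinomial logit matches hand-computed values", {
  p <- transition_params(list(
    healthy  = rbind(moderate = c(-2, 0, 0, 0), severe = c(-2, 0, 0, 0),
                     dead = c(-2, 0, 0, 0)),
    moderate = rbind(healthy = c(0, 0, 0, 0)),
    severe   = rbind(dead = c(0, 0, 0, 0))
  ))
  pr <- transition_probs(p, "healthy", age = 65, male = 0)
  stay <- 1 / (1 + 3 * exp(-2))           # independent arithmetic: 0.7112
  other <- exp(-2) / (1 + 3 * exp(-2))    # 0.0963
  expect_equal(unname(pr[1, "healthy"]), stay, tolerance = 1e-12)
  expect_equal(unname(pr[1, c("moderate", "severe", "dead")]),
               rep(other, 3), tolerance = 1e-12)
  expect_equal(round(stay, 4), 0.7112)
  expect_equal(round(other, 4), 0.0963)
  # all-zero coefficients: symmetric 1/4
  p0 <- transition_params(list(
    healthy = rbind(moderate = c(0, 0, 0, 0), severe = c(0, 0, 0, 0),
                    dead = c(0, 0, 0, 0)),
    moderate = rbind(healthy = c(0, 0, 0, 0)),
    severe = rbind(dead = c(0, 0, 0, 0))
  ))
  expect_equal(as.vector(transition_probs(p0, "healthy", 50, 1)),
               rep(0.25, 4), tolerance = 1e-12)
})

test_that("dead origin is absorbing and rows are stochastic", {
  p <- tiny_params()
  expect_equal(as.vector(transition_probs(p, "dead", 71, 1)),
               c(0, 0, 0, 1))
  for (age in c(45, 60, 75, 90, 120)) {  # includes clamped ages
    M <- transition_matrix(p, age, 0)
    expect_equal(unname(rowSums(M)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(unname(M["dead", ]), c(0, 0, 0, 1))
  }
  # ages above the cap evaluate at the cap, never beyond
  expect_equal(transition_probs(p, "healthy", 120, 1),
               transition_probs(p, "healthy", p$age_cap, 1))
})

test_that("coefficients are recovered from data simulated at large n", {
  set.seed(77)
  true <- tiny_params()
  n <- 200000
  age <- sample(45:85, n, TRUE)
  male <- rbinom(n, 1, 0.5)
  org <- sample(living_states(), n, TRUE, prob = c(0.6, 0.25, 0.15))
  dest <- character(n)
  for (s in living_states()) {
    sel <- which(org == s)
    P <- transition_probs(true, s, age[sel], male[sel])
    cum <- t(apply(P, 1, cumsum))
    dest[sel] <- disability_states()[
      1L + rowSums(runif(length(sel)) > cum)]
  }
  pp <- data.frame(subject_id = 1:n, age_at_start = age, male = male,
                   origin = factor(org, levels = living_states()),
                   destination = factor(dest, levels = disability_states()),
                   village = 1, region = 1)
  fit <- fit_transition_model(pp)
  for (s in living_states()) {
    B <- fit$params$coef[[s]]
    SE <- fit$se[[s]]
    Bt <- true$coef[[s]][rownames(B), ]
    expect_true(all(abs(B - Bt) <= 3 * SE),
                info = paste("origin", s))
  }
})

test_that("empty destination cells become structural zeros", {
  set.seed(5)
  pp <- data.frame(
    subject_id = 1:300, age_at_start = sample(45:80, 300, TRUE),
    male = rbinom(300, 1, 0.5),
    origin = factor("severe", levels = living_states()),
    destination = factor(sample(c("severe", "moderate", "dead"), 300, TRUE),
                         levels = disability_states()),
    village = 1, region = 1
  )
  pp2 <- rbind(pp, data.frame(
    subject_id = 301:400, age_at_start = sample(45:80, 100, TRUE),
    male = rbinom(100, 1, 0.5),
    origin = factor("healthy", levels = living_states()),
    destination = factor("healthy", levels = disability_states()),
    village = 1, region = 1
  ), data.frame(
    subject_id = 401:500, age_at_start = sample(45:80, 100, TRUE),
    male = rbinom(100, 1, 0.5),
    origin = factor("moderate", levels = living_states()),
    destination = factor(sample(c("moderate", "healthy"), 100, TRUE),
                         levels = disability_states()),
    village = 1, region = 1
  ))
  fit <- fit_transition_model(pp2)
  sz <- structural_zeros(fit$params)
  expect_true(any(sz$origin == "severe" & sz$destination == "healthy"))
  for (age in c(45, 65, 85)) {
    expect_equal(
      unname(transition_probs(fit$params, "severe", age, 1)[1, "healthy"]),
      0)
  }
})

test_that("fit agrees with an independent multinomial logit implementation", {
  skip_if_not_installed("nnet")
  sp <- small_panel_spec(n = 800, seed = 31)
  pp <- build_person_periods(apply_sample_filters(
    code_records(simulate_panel(sp)$records)))
  fit <- fit_transition_model(pp)
  for (s in living_states()) {
    sel <- pp$origin == s
    d <- droplevels(factor(as.character(pp$destination[sel])))
    d <- stats::relevel(d, ref = s)
    a <- pp$age_at_start[sel] - 65
    df <- data.frame(d = d, a = a, a2 = a^2, male = pp$male[sel])
    mm <- nnet::multinom(d ~ a + a2 + male, data = df, trace = FALSE,
                         maxit = 500, reltol = 1e-14)
    cf <- coef(mm)
    if (is.null(dim(cf))) cf <- matrix(cf, 1,
                                       dimnames = list(setdiff(levels(d), s),
                                                       names(cf)))
    B <- fit$params$coef[[s]][rownames(cf), ]
    expect_equal(unname(B), unname(cf), tolerance = 1e-3,
                 info = paste("origin", s))
  }
})

test_that("MLE log-likelihood dominates the intercept-only model", {
  sp <- small_panel_spec(n = 600, seed = 17)
  pp <- build_person_periods(apply_sample_filters(
    code_records(simulate_panel(sp)$records)))
  full <- fit_transition_model(pp)
  null <- fit_transition_model(pp, terms = character(0))
  expect_gte(full$loglik, null$loglik)
})

test_that("averaged fitted probabilities reproduce observed frequencies", {
  sp <- small_panel_spec(n = 800, seed = 19)
  pp <- build_person_periods(apply_sample_filters(
    code_records(simulate_panel(sp)$records)))
  fit <- fit_transition_model(pp)
  pu <- fit$params
  pu$age_cap <- 200  # evaluate on the unclamped linear predictor
  for (s in living_states()) {
    sel <- pp$origin == s
    P <- transition_probs(pu, s, pp$age_at_start[sel], pp$male[sel])
    obs <- table(factor(as.character(pp$destination[sel]),
                        levels = colnames(P))) / sum(sel)
    expect_lt(max(abs(colMeans(P) - as.numeric(obs))), 1e-8)
  }
})

test_that("binary-logit sensitivity mode yields valid probabilities", {
  sp <- small_panel_spec(n = 600, seed = 23)
  pp <- build_person_periods(apply_sample_filters(
    code_records(simulate_panel(sp)$records)))
  fit <- fit_transition_model(pp, mode = "binary")
  for (age in c(50, 70, 90)) {
    M <- transition_matrix(fit$params, age, 1)
    expect_equal(unname(rowSums(M)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(M >= 0))
  }
})

test_that("predicted curves are consistent and monotone where expected", {
  p <- tiny_params()
  cv <- predict_curves(p, ages = 45:90, male = 0)
  hm <- cv[cv$origin == "healthy" & cv$destination == "moderate", ]
  expect_equal(hm$probability,
               transition_probs(p, "healthy", 45:90, 0)[, "moderate"])
  # positive age slope, no quadratic turnover in range: increasing mortality
  pm <- transition_params(list(
    healthy = rbind(dead = c(-4, 0.08, 0, 0)),
    moderate = rbind(dead = c(-4, 0.08, 0, 0)),
    severe = rbind(dead = c(-4, 0.08, 0, 0))
  ))
  hd <- predict_curves(pm, 45:90, male = 1)
  hd <- hd[hd$origin == "healthy" & hd$destination == "dead", ]
  expect_true(all(diff(hd$probability) > 0))
  # constant-only parameters give flat curves
  pc <- transition_params(list(
    healthy = rbind(dead = c(-2.2, 0, 0, 0)),
    moderate = rbind(dead = c(-2.2, 0, 0, 0)),
    severe = rbind(dead = c(-2.2, 0, 0, 0))
  ))
  fh <- predict_curves(pc, 45:90, male = 0)
  fh <- fh[fh$origin == "healthy" & fh$destination == "dead", ]
  expect_equal(diff(fh$probability), rep(0, 45), tolerance = 1e-12)
})

test_that("parameter JSON round-trips exactly", {
  p <- tiny_params()
  tf <- tempfile(fileext = ".json")
  params_to_json(p, tf)
  q <- params_from_json(tf)
  expect_equal(q$coef, p$coef, tolerance = 1e-12)
  expect_equal(q$center, p$center)
  expect_equal(q$states, p$states)
})
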