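# Newton-Raphson fit of a multinomial logit with baseline category 0.
# X: n x p design; y: integer 0..K (0 = baseline). ridge = 0 gives the
# plain MLE; a positive ridge is used only for the quasi-separation
# fallback (see fit_origin_logit).
# Returns list(B [K x p], vcov [(K p) x (K p)], loglik, converged, iter).
row_max <- function(M) {
  out <- M[, 1L]
  for (j in seq_len(ncol(M))[-1L]) out <- pmax(out, M[, j])
  out
}

fit_multinom_newton <- function(X, y, K, ridge = 1e-6, max_iter = 200L,
                                tol = 1e-10, start = NULL) {
  n <- nrow(X); p <- ncol(X)
  # column scaling keeps the age^2 column from dominating the Hessian
  sc <- apply(abs(X), 2L, max)
  sc[sc == 0] <- 1
  Xs <- sweep(X, 2L, sc, "/")
  Y <- matrix(0, n, K)
  pos <- y > 0L
  Y[cbind(which(pos), y[pos])] <- 1

  B <- matrix(0, K, p)
  if (!is.null(start) && all(dim(start) == dim(B)) && all(is.finite(start))) {
    B <- sweep(start, 2L, sc, "*")  # warm start, on the scaled basis
  }
  pen_ll <- function(B) {
    eta <- Xs %*% t(B)
    m <- pmax(row_max(eta), 0)
    lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
    sum(eta[cbind(seq_len(n), pmax(y, 1L))][pos]) - sum(lse) -
      ridge * sum((t(B) / sc)^2)
  }
  probs <- function(B) {
    eta <- Xs %*% t(B)
    m <- pmax(row_max(eta), 0)
    denom <- exp(-m) + rowSums(exp(eta - m))
    exp(eta - m) / denom
  }
  ll_old <- pen_ll(B)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    P <- probs(B)
    G <- t(Y - P) %*% Xs - 2 * ridge * sweep(B, 2L, sc^2, "/")
    g <- as.vector(t(G))  # gradient, coefs of dest 1 first
    if (max(abs(g)) < tol * max(1, n)) { converged <- TRUE; break }
    H <- matrix(0, K * p, K * p)
    for (k in seq_len(K)) {
      for (l in k:K) {
        w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
        blk <- crossprod(Xs, Xs * w)
        rk <- (k - 1L) * p + seq_len(p)
        rl <- (l - 1L) * p + seq_len(p)
        H[rk, rl] <- blk
        if (l != k) H[rl, rk] <- t(blk)
      }
    }
    diag(H) <- diag(H) + 2 * ridge / rep(sc^2, times = K)
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8 * max(diag(H)), nrow(H)), g)
    })
    Bstep <- matrix(step, K, p, byrow = TRUE)
    lambda <- 1
    repeat {
      Bn <- B + lambda * Bstep
      lln <- pen_ll(Bn)
      if (lln >= ll_old - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-8) {  # line search exhausted: accept if near-stationary
      B <- Bn; ll_old <- lln
      converged <- max(abs(g)) < 1e-6 * max(1, n)
      break
    }
    B <- Bn
    ll_old <- lln
    if (ridge == 0 && max(abs(B)) > 16) break  # diverging: separation
  }
  # unpenalised log-likelihood and vcov on the original scale
  P <- probs(B)
  Pstay <- pmax(1 - rowSums(P), .Machine$double.xmin)
  ll <- sum(log(ifelse(pos, P[cbind(seq_len(n), pmax(y, 1L))], Pstay)))
  H <- matrix(0, K * p, K * p)
  for (k in seq_len(K)) {
    for (l in k:K) {
      w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
      blk <- crossprod(Xs, Xs * w)
      rk <- (k - 1L) * p + seq_len(p)
      rl <- (l - 1L) * p + seq_len(p)
      H[rk, rl] <- blk
      if (l != k) H[rl, rk] <- t(blk)
    }
  }
  diag(H) <- diag(H) + 2 * ridge / rep(sc^2, times = K)
  V <- tryCatch(solve(H), error = function(e) {
    solve(H + diag(1e-8 * max(diag(H)), nrow(H)))
  })
  S <- diag(rep(1 / sc, K))
  V <- S %*% V %*% S
  list(B = sweep(B, 2L, sc, "/"), vcov = V, loglik = ll,
       converged = converged, iter = it, max_scaled_coef = max(abs(B)))
}

# unpenalised maximum likelihood first; fall back to a ridge-penalised fit
# only when the unpenalised problem diverges (quasi-separation)
fit_origin_logit <- function(X, y, K, ridge = 1e-6, max_iter = 200L,
                             start = NULL) {
  ft <- fit_multinom_newton(X, y, K, ridge = 0, max_iter = max_iter,
                            start = start)
  if (ft$converged && ft$max_scaled_coef < 15) {
    ft$ridged <- FALSE
    return(ft)
  }
  ft <- fit_multinom_newton(X, y, K, ridge = ridge, max_iter = max_iter,
                            start = start)
  ft$ridged <- TRUE
  ft
}

#' Fit the discrete-time hazard model to person-period data
#'
#' For each living origin state, fits a multinomial logit over destinations
#' with baseline "remain in the origin state" and linear predictor
#' intercept + age + age^2 + male (age centred at `center`). Destinations
#' never observed from an origin are flagged as structural zeros and get
#' probability 0. A small ridge penalty keeps quasi-separated destinations
#' finite. The alternative "binary" mode fits one binary logit per
#' origin-destination pair and renormalises, for sensitivity analysis.
#'
#' @param periods person-period data frame from [build_person_periods()].
#' @param mode "multinomial" (default) or "binary".
#' @param center age-centering constant in years.
#' @param age_cap evaluation cap for the resulting parameters.
#' @param terms covariates included beyond the intercept; subset of
#'   c("age", "age2", "male"). `terms = character(0)` gives the
#'   intercept-only model, whose fitted probabilities equal the empirical
#'   destination proportions.
#' @param ridge ridge penalty used for quasi-separated destinations.
#' @param start optional "transition_params" used as warm start for the
#'   Newton iterations (e.g. the full-sample fit when refitting bootstrap
#'   resamples); the maximiser is unchanged.
#' @return object of class "transition_model": list with `params`
#'   (a "transition_params"), `se` (standard errors shaped like the
#'   coefficients), `vcov` (per-origin covariance of the stacked
#'   coefficients), `loglik`, `n_periods`, `counts` (origin x destination
#'   table) and `convergence` (per-origin diagnostics).
#' @export
fit_transition_model <- function(periods,
                                 mode = c("multinomial", "binary"),
                                 center = 65, age_cap = 90,
                                 terms = c("age", "age2", "male"),
                                 ridge = 1e-6, start = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("origin", "destination", "age_at_start", "male") %in%
                  names(periods)))
  living <- levels(factor(periods$origin))
  if (is.factor(periods$origin)) living <- levels(periods$origin)
  states <- if (is.factor(periods$destination)) {
    levels(periods$destination)
  } else {
    c(living, .dead)
  }
  a <- periods$age_at_start - center
  cols <- c(intercept = TRUE, age = "age" %in% terms,
            age2 = "age2" %in% terms, male = "male" %in% terms)
  Xfull <- cbind(intercept = 1, age = a, age2 = a * a,
                 male = periods$male)
  counts <- table(factor(periods$origin, levels = living),
                  factor(periods$destination, levels = states))

  coef <- list()
  se <- list()
  vcov <- list()
  conv <- list()
  loglik <- 0
  for (org in living) {
    idx <- which(periods$origin == org)
    if (!length(idx)) {
      # origin never at risk: every destination is a structural zero
      coef[[org]] <- matrix(numeric(0), 0, 4,
                            dimnames = list(NULL, colnames(Xfull)))
      se[[org]] <- coef[[org]]
      conv[[org]] <- list(converged = TRUE, iter = 0L, ridged = FALSE)
      next
    }
    dests_all <- setdiff(states, org)
    obs <- dests_all[counts[org, dests_all] > 0L]
    dd <- as.character(periods$destination[idx])
    if (!length(obs)) {  # everyone stays: all destinations structural zero
      coef[[org]] <- matrix(numeric(0), 0, 4,
                            dimnames = list(NULL, colnames(Xfull)))
      se[[org]] <- coef[[org]]
      conv[[org]] <- list(converged = TRUE, iter = 0L)
      next
    }
    y <- match(dd, obs)
    y[is.na(y)] <- 0L
    X <- Xfull[idx, cols, drop = FALSE]
    st0 <- NULL
    if (!is.null(start) && !is.null(start$coef[[org]]) &&
        all(obs %in% rownames(start$coef[[org]]))) {
      st0 <- start$coef[[org]][obs, cols, drop = FALSE]
    }
    ft <- fit_origin_logit(X, y, K = length(obs), ridge = ridge,
                           start = st0)
    if (!ft$converged) {
      stop("estimation error: no convergence for origin ", org,
           " after ", ft$iter, " iterations (max |score| too large)",
           call. = FALSE)
    }
    if (mode == "binary") {
      # refit each destination as a binary logit vs everything else
      Bb <- matrix(0, length(obs), ncol(X))
      Vb <- matrix(0, length(obs) * ncol(X), length(obs) * ncol(X))
      for (k in seq_along(obs)) {
        fk <- fit_origin_logit(X, as.integer(y == k), K = 1L,
                               ridge = ridge)
        Bb[k, ] <- fk$B
        rk <- (k - 1L) * ncol(X) + seq_len(ncol(X))
        Vb[rk, rk] <- fk$vcov
      }
      ft$B <- Bb
      ft$vcov <- Vb
      ft$loglik <- NA_real_
    }
    B <- matrix(0, length(obs), 4,
                dimnames = list(obs, colnames(Xfull)))
    SE <- B
    sev <- sqrt(pmax(diag(ft$vcov), 0))
    B[, cols] <- ft$B
    SE[, cols] <- matrix(sev, length(obs), ncol(X), byrow = TRUE)
    coef[[org]] <- B
    se[[org]] <- SE
    vcov[[org]] <- ft$vcov
    conv[[org]] <- list(converged = ft$converged, iter = ft$iter,
                        ridged = ft$ridged)
    if (mode == "multinomial") loglik <- loglik + ft$loglik
  }

  params <- transition_params(coef, states = states, center = center,
                              age_min = 45, age_cap = age_cap, mode = mode)
  structure(
    list(params = params, se = se, vcov = vcov,
         loglik = if (mode == "multinomial") loglik else NA_real_,
         n_periods = nrow(periods), counts = counts,
         convergence = conv, terms = terms),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Discrete-time hazard model fit (", x$params$mode, " logit)\n",
      sep = "")
  cat("person-periods:", x$n_periods, "; log-likelihood:",
      format(x$loglik, digits = 8), "\n")
  cat("\nobserved origin x destination counts:\n")
  print(x$counts)
  print(x$params)
  invisible(x)
}

#' @export
coef.transition_model <- function(object, ...) object$params$coef

#' @export
logLik.transition_model <- function(object, ...) {
  structure(object$loglik, df = sum(vapply(object$params$coef, length, 1L)),
            class = "logLik")
}
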