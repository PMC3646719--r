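#' Annual transition model parameters
#'
#' Container for the coefficients of the discrete-time hazard model: for each
#' living origin state i, a multinomial logit over destinations j with the
#' stay-in-i outcome as baseline and linear predictor
#' \deqn{\eta_{ij} = \beta_{0ij} + \beta_{1ij}(age - c) + \beta_{2ij}(age - c)^2
#'   + \beta_{3ij}\,male,}
#' where c is an age-centering constant that stabilises the quadratic term.
#' Destinations absent from an origin's coefficient matrix are structural
#' zeros: their transition probability is identically 0.
#'
#' @param coef named list with one element per living origin state; each
#'   element a numeric matrix with one row per (non-stay) destination, row
#'   names the destination states, and columns
#'   c("intercept", "age", "age2", "male").
#' @param states character vector of the full state set, death last.
#'   Defaults to the standard four-state set.
#' @param center age-centering constant c, in years.
#' @param age_min,age_cap evaluation range in years; ages outside it are
#'   clamped, never extrapolated (the quadratic predictor is unsupported
#'   beyond the observed range and can turn over).
#' @param mode "multinomial" (joint per-origin logit, the default) or
#'   "binary" (per-pair binary logits combined with renormalisation, kept as
#'   a sensitivity mode).
#' @return object of class "transition_params".
#' @export
#' @examples
#' p <- transition_params(list(
#'   healthy  = rbind(moderate = c(-3, 0.05, 0, -0.3),
#'                    severe   = c(-4, 0.07, 0, -0.3),
#'                    dead     = c(-4.5, 0.08, 0, 0.3)),
#'   moderate = rbind(healthy  = c(-1, -0.05, 0, 0.2),
#'                    severe   = c(-2, 0.05, 0, -0.2),
#'                    dead     = c(-3.5, 0.07, 0, 0.4)),
#'   severe   = rbind(healthy  = c(-2.5, -0.08, 0, 0.2),
#'                    moderate = c(-1.5, -0.05, 0, 0.1),
#'                    dead     = c(-2.5, 0.06, 0, 0.3))))
#' transition_probs(p, "healthy", age = 65, male = 0)
transition_params <- function(coef, states = disability_states(),
                              center = 65, age_min = 45, age_cap = 90,
                              mode = c("multinomial", "binary")) {
  mode <- match.arg(mode)
  living <- states[-length(states)]
  dead <- states[length(states)]
  if (!setequal(names(coef), living) && !all(names(coef) %in% living)) {
    stop("coef must be named by living origin states")
  }
  coef <- coef[intersect(living, names(coef))]
  cols <- c("intercept", "age", "age2", "male")
  for (org in names(coef)) {
    B <- coef[[org]]
    if (is.null(dim(B))) stop("coef[['", org, "']] must be a matrix")
    if (ncol(B) != 4L) stop("coefficient matrices need 4 columns")
    colnames(B) <- cols
    if (nrow(B) == 0L) { coef[[org]] <- B; next }
    dn <- rownames(B)
    if (is.null(dn) || any(!dn %in% setdiff(states, org))) {
      stop("destination rows of coef[['", org,
           "']] must be states other than the origin")
    }
    if (any(!is.finite(B))) stop("coefficients must be finite")
    coef[[org]] <- B
  }
  structure(
    list(coef = coef, states = states, living = living, dead = dead,
         center = center, age_min = age_min, age_cap = age_cap, mode = mode),
    class = "transition_params"
  )
}

#' @export
print.transition_params <- function(x, ...) {
  cat("Annual transition model (", x$mode, " logit), states: ",
      paste(x$states, collapse = " > "), "\n", sep = "")
  cat("age centered at ", x$center, ", evaluated on [", x$age_min, ", ",
      x$age_cap, "]\n", sep = "")
  for (org in names(x$coef)) {
    cat("\nfrom ", org, " (baseline = stay):\n", sep = "")
    print(round(x$coef[[org]], 4))
  }
  sz <- structural_zeros(x)
  if (nrow(sz)) {
    cat("\nstructural zeros: ",
        paste(sz$origin, "->", sz$destination, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Structural-zero transitions of a parameter set
#'
#' Destinations with no coefficient row for an origin are structural zeros
#' (probability fixed at 0 at every age).
#'
#' @param params a "transition_params" object.
#' @return data frame with columns origin, destination.
#' @export
structural_zeros <- function(params) {
  out <- do.call(rbind, lapply(params$living, function(org) {
    miss <- setdiff(setdiff(params$states, org),
                    rownames(params$coef[[org]]) %||% character())
    if (!length(miss)) return(NULL)
    data.frame(origin = org, destination = miss)
  }))
  out %||% data.frame(origin = character(), destination = character())
}

#' Annual transition probabilities for one origin state
#'
#' Evaluates the fitted (or true) annual transition probabilities from a
#' given origin state at given ages and sex, via the inverse multinomial
#' logit link: stay probability 1/(1 + sum_j exp(eta_ij)), destination j
#' probability exp(eta_ij)/(1 + sum exp(eta_ij)). Ages outside
#' [age_min, age_cap] are clamped to the boundary. The dead origin returns a
#' point mass on dead.
#'
#' @param params a "transition_params" object.
#' @param origin a single origin state label.
#' @param age numeric vector of ages in years.
#' @param male 0/1 indicator (recycled against age).
#' @return numeric matrix, one row per age, columns the full state set;
#'   rows sum to 1.
#' @export
transition_probs <- function(params, origin, age, male) {
  stopifnot(inherits(params, "transition_params"), length(origin) == 1L)
  origin <- as.character(origin)
  if (!origin %in% params$states) stop("unknown origin state: ", origin)
  n <- max(length(age), length(male))
  age <- rep_len(age, n); male <- rep_len(male, n)
  ns <- length(params$states)
  out <- matrix(0, n, ns, dimnames = list(NULL, params$states))
  if (origin == params$dead) {
    out[, params$dead] <- 1
    return(out)
  }
  B <- params$coef[[origin]]
  a <- pmin(pmax(age, params$age_min), params$age_cap) - params$center
  X <- cbind(1, a, a * a, male)
  if (is.null(B) || nrow(B) == 0L) {
    out[, origin] <- 1
    return(out)
  }
  eta <- X %*% t(B)
  if (params$mode == "multinomial") {
    m <- eta[, 1L]
    if (ncol(eta) > 1L) for (j in 2:ncol(eta)) m <- pmax(m, eta[, j])
    m <- pmax(m, 0)
    denom <- exp(-m) + rowSums(exp(eta - m))
    out[, rownames(B)] <- exp(eta - m) / denom
    out[, origin] <- exp(-m) / denom
  } else {
    # per-pair binary logits: q_j = expit(eta_j), stay = 1 - sum(q);
    # if the q's exceed 1 in total they are renormalised to sum to 1.
    q <- stats::plogis(eta)
    tot <- rowSums(q)
    over <- tot > 1
    if (any(over)) q[over, ] <- q[over, , drop = FALSE] / tot[over]
    out[, rownames(B)] <- q
    out[, origin] <- pmax(0, 1 - rowSums(q))
  }
  out
}

#' Full annual transition matrix at one age and sex
#'
#' Row-stochastic matrix over the full state set with rows from
#' [transition_probs()] and the absorbing dead row (0, ..., 0, 1).
#'
#' @inheritParams transition_probs
#' @param age single age in years.
#' @param male single 0/1 indicator.
#' @return square matrix with dimnames the state set.
#' @export
transition_matrix <- function(params, age, male) {
  stopifnot(length(age) == 1L, length(male) == 1L)
  st <- params$states
  P <- matrix(0, length(st), length(st), dimnames = list(st, st))
  for (org in st) P[org, ] <- transition_probs(params, org, age, male)
  P
}

#' Transition-probability curves over an age range
#'
#' Long-format table of annual transition probabilities by age, sex, origin
#' and destination, suitable for plotting probability-by-age panels.
#'
#' @inheritParams transition_probs
#' @param ages integer vector of ages.
#' @param male 0, 1 or c(0, 1) (both sexes).
#' @return data frame with columns age, male, origin, destination,
#'   probability.
#' @export
predict_curves <- function(params, ages = params$age_min:params$age_cap,
                           male = c(0, 1)) {
  out <- list()
  for (m in male) {
    for (org in params$living) {
      P <- transition_probs(params, org, ages, m)
      for (dst in params$states) {
        out[[length(out) + 1L]] <- data.frame(
          age = ages, male = m, origin = org, destination = dst,
          probability = P[, dst]
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Default generator truth: an annual transition schedule for a rural
#' mature-adult population
#'
#' A fixed parameter set used as the synthetic generator's truth. It encodes
#' the qualitative pattern reported for rural Malawian mature adults:
#' transitions towards disability and death rise steeply with age, recovery
#' from limitation declines with age, women enter limitation states more and
#' die less than men at given age, and mortality from severe limitation is
#' several times healthy mortality at age 45.
#'
#' @return a "transition_params" object on the standard four-state set.
#' @export
default_true_params <- function() {
  transition_params(list(
    healthy = rbind(
      moderate = c(-2.10,  0.055, 5e-4, -0.35),
      severe   = c(-3.60,  0.080, 5e-4, -0.30),
      dead     = c(-4.00,  0.085, 4e-4,  0.35)
    ),
    moderate = rbind(
      healthy  = c(-1.40, -0.045, 0e+0,  0.25),
      severe   = c(-2.20,  0.055, 2e-4, -0.20),
      dead     = c(-3.60,  0.065, 2e-4,  0.40)
    ),
    severe = rbind(
      healthy  = c(-2.93, -0.075, 0e+0,  0.15),
      moderate = c(-2.40, -0.040, 1e-4,  0.10),
      dead     = c(-2.43,  0.055, 2e-4,  0.25)
    )
  ))
}

#' Serialize transition parameters to JSON
#'
#' Explicitly labelled JSON (states, origins, destinations, coefficient
#' names) so a parameter file is self-describing.
#'
#' @param params a "transition_params" object.
#' @param path file path; if NULL the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
params_to_json <- function(params, path = NULL) {
  obj <- list(
    states = params$states, center = params$center,
    age_min = params$age_min, age_cap = params$age_cap, mode = params$mode,
    coef = lapply(params$coef, function(B) {
      lapply(seq_len(nrow(B)), function(i) {
        as.list(c(list(destination = rownames(B)[i]),
                  as.list(stats::setNames(B[i, ], colnames(B)))))
      })
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Read transition parameters from JSON written by [params_to_json()]
#' @param path file path or JSON string.
#' @return a "transition_params" object.
#' @export
params_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  coef <- lapply(obj$coef, function(rows) {
    B <- do.call(rbind, lapply(rows, function(r) {
      unlist(r[c("intercept", "age", "age2", "male")])
    }))
    rownames(B) <- vapply(rows, `[[`, "", "destination")
    B
  })
  transition_params(coef, states = unlist(obj$states), center = obj$center,
                    age_min = obj$age_min, age_cap = obj$age_cap,
                    mode = obj$mode)
}
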