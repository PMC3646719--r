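#' Disability state labels
#'
#' The analysis distinguishes three living states of functional limitation
#' plus death. "healthy" means no limitation on either the moderate-activity
#' or the strenuous-activity item; "moderate" means "limited a little" on at
#' least one item (and "limited a lot" on neither); "severe" means "limited a
#' lot" on at least one item, or being too ill to respond at all. Death is
#' absorbing everywhere in the package.
#'
#' @return Character vector of state labels, death last.
#' @export
#' @examples
#' disability_states()
disability_states <- function() c("healthy", "moderate", "severe", "dead")

#' Living disability states
#' @return Character vector of the three living states.
#' @export
living_states <- function() c("healthy", "moderate", "severe")

.dead <- "dead"

# coerce a vector of labels to a factor over a given state set, preserving NA
as_state <- function(x, states = disability_states()) {
  if (is.factor(x)) x <- as.character(x)
  bad <- !is.na(x) & !(x %in% states)
  if (any(bad)) {
    stop("unknown state label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = states)
}

# check a probability vector sums to one
check_prob_vector <- function(p, what, tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop(what, " must be finite and non-negative", call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(what, " must sum to 1 (got ", format(sum(p), digits = 17), ")",
         call. = FALSE)
  }
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
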