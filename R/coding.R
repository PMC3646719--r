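#' Item response levels for the limitation and auxiliary survey items
#'
#' One fixed dictionary of item labels and their integer encodings, shared by
#' the synthetic panel generator, the coding functions and any CSV output.
#' The two physical-limitation items (moderate activities, strenuous
#' activities) use a three-level scale; pain interference with normal work
#' and life satisfaction use five ordered levels.
#'
#' @return A named list of data frames, one per item family, with columns
#'   `code` (integer) and `label`.
#' @export
#' @examples
#' item_levels()$limitation
item_levels <- function() {
  list(
    limitation = data.frame(
      code = 1:3,
      label = c("not limited", "limited a little", "limited a lot")
    ),
    pain = data.frame(
      code = 1:5,
      label = c("not at all", "a little bit", "moderately", "quite a bit",
                "extremely")
    ),
    satisfaction = data.frame(
      code = 1:5,
      label = c("very satisfied", "satisfied", "neutral",
                "somewhat unsatisfied", "very unsatisfied")
    )
  )
}

# normalise a limitation item given as label or integer code to label; NA kept
normalize_item <- function(x, family = "limitation") {
  lv <- item_levels()[[family]]
  if (is.numeric(x)) {
    out <- lv$label[match(x, lv$code)]
    if (any(!is.na(x) & is.na(out))) stop("invalid ", family, " item code")
    return(out)
  }
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% lv$label)
  if (any(bad)) stop("invalid ", family, " item label: ",
                     paste(unique(x[bad]), collapse = ", "))
  x
}

#' Code the three-level disability state from the two limitation items
#'
#' Applies the coding rules used throughout the package: a respondent too ill
#' or weak to answer is severely limited regardless of the items; otherwise
#' "limited a lot" on either item codes severe, "limited a little" on either
#' (and "a lot" on neither) codes moderate, and "not limited" on both codes
#' healthy. If neither rule fires because a substantive item is missing, the
#' state is missing (we cannot rule out a limitation).
#'
#' @param moderate_item,strenuous_item responses to the moderate-activity and
#'   strenuous-activity limitation items; labels ("not limited",
#'   "limited a little", "limited a lot"), integer codes 1:3, or NA.
#' @param too_ill logical; interviewer assessed the respondent as too ill or
#'   weak to respond.
#' @return factor over the living states, NA where the state cannot be coded.
#' @export
#' @examples
#' code_state_3level("not limited", "not limited")
#' code_state_3level("limited a little", "limited a lot")
#' code_state_3level(NA, NA, too_ill = TRUE)
code_state_3level <- function(moderate_item, strenuous_item,
                              too_ill = FALSE) {
  m <- normalize_item(moderate_item)
  s <- normalize_item(strenuous_item)
  n <- max(length(m), length(s), length(too_ill))
  m <- rep_len(m, n); s <- rep_len(s, n)
  too_ill <- rep_len(as.logical(too_ill) %in% TRUE, n)

  a_lot    <- (m %in% "limited a lot") | (s %in% "limited a lot")
  a_little <- (m %in% "limited a little") | (s %in% "limited a little")
  none     <- (m %in% "not limited") & (s %in% "not limited")

  out <- rep(NA_character_, n)
  out[none] <- "healthy"
  out[a_little] <- "moderate"
  out[a_lot] <- "severe"
  out[too_ill] <- "severe"
  factor(out, levels = living_states())
}

#' Code the two-level disability state (healthy versus limited)
#'
#' Collapse of the three-level coding: limited iff moderately or severely
#' limited. Missingness propagates.
#'
#' @inheritParams code_state_3level
#' @return factor with levels "healthy", "limited"; NA where uncodable.
#' @export
code_state_2level <- function(moderate_item, strenuous_item,
                              too_ill = FALSE) {
  s3 <- code_state_3level(moderate_item, strenuous_item, too_ill)
  out <- ifelse(is.na(s3), NA_character_,
                ifelse(s3 == "healthy", "healthy", "limited"))
  factor(out, levels = c("healthy", "limited"))
}

#' Code a disability state from the pain-interference item
#'
#' Alternative disability classification based on how much pain interfered
#' with normal work in the past four weeks. The default mapping keeps the
#' binary cut at "moderately" (at or above it counts as limited) while
#' spreading the limited side over two states so that the same three-state
#' pipeline applies: {not at all, a little bit} -> healthy,
#' {moderately, quite a bit} -> moderate, {extremely} -> severe.
#'
#' @param pain_item response to the pain-interference item; label, integer
#'   code 1:5, or NA.
#' @param mapping character vector of length 5 over the living states,
#'   giving the coded state for each pain level in order.
#' @return factor over the living states, NA for a missing item.
#' @export
#' @examples
#' code_state_pain(c("not at all", "moderately", "extremely"))
code_state_pain <- function(pain_item,
                            mapping = c("healthy", "healthy", "moderate",
                                        "moderate", "severe")) {
  stopifnot(length(mapping) == 5L, all(mapping %in% living_states()))
  p <- normalize_item(pain_item, "pain")
  idx <- match(p, item_levels()$pain$label)
  factor(mapping[idx], levels = living_states())
}

#' Attach coded disability states to wave-level records
#'
#' Adds/overwrites a `state` column on a wave-level record data frame.
#' Rows with vital status "dead" are coded "dead"; living rows are coded
#' with the chosen variant. Under the two-level variant the "limited" state
#' is carried in a state set c("healthy", "limited", "dead").
#'
#' @param records wave-level records as produced by [observe_waves()] (or
#'   read from CSV with the same columns).
#' @param coding one of "threelevel" (default), "twolevel", "pain".
#' @return `records` with a `state` factor column; its levels are the state
#'   set used downstream (living states then "dead").
#' @export
code_records <- function(records,
                         coding = c("threelevel", "twolevel", "pain")) {
  coding <- match.arg(coding)
  living <- switch(coding,
    threelevel = living_states(),
    pain = living_states(),
    twolevel = c("healthy", "limited")
  )
  st <- switch(coding,
    threelevel = as.character(code_state_3level(records$moderate_item,
                                                records$strenuous_item,
                                                records$too_ill)),
    twolevel = as.character(code_state_2level(records$moderate_item,
                                              records$strenuous_item,
                                              records$too_ill)),
    pain = as.character(code_state_pain(records$pain_item))
  )
  st[records$vital_status == "dead"] <- .dead
  records$state <- factor(st, levels = c(living, .dead))
  records
}
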