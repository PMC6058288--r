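#' Grade a spot-dilution lysis series
#'
#' A phage is spotted as a dilution series (undiluted first) on a lawn of
#' the strain; each spot either clears or not. The ordinal grade is
#' 2 (full lysis, "+") when every spot up to the panel's reference depth
#' clears, 0 (full resistance, "-") when no spot clears, and 1 (partial
#' lysis, "(+)") otherwise. The dilution depth is the 0-based index of
#' the most dilute spot still cleared (-1 when none cleared).
#'
#' @param cleared logical vector of clearing outcomes, ordered from
#'   undiluted to most dilute; must be non-empty.
#' @param referenceDepth number of leading spots that must all clear for
#'   full lysis (defaults to the whole series).
#' @return List with `grade` (integer 0/1/2) and `depth` (integer >= -1).
#' @examples
#' gradeLysis(c(TRUE, TRUE, TRUE))   # full lysis
#' gradeLysis(c(TRUE, FALSE, FALSE)) # partial
#' @export
gradeLysis <- function(cleared, referenceDepth = length(cleared)) {
  if (!length(cleared)) stop("empty spot series")
  cleared <- as.logical(cleared)
  if (any(is.na(cleared))) stop("clearing outcomes must be TRUE/FALSE")
  referenceDepth <- min(referenceDepth, length(cleared))
  grade <- if (all(cleared[seq_len(referenceDepth)])) 2L
           else if (!any(cleared)) 0L
           else 1L
  depth <- if (any(cleared)) max(which(cleared)) - 1L else -1L
  list(grade = grade, depth = depth)
}

#' Compare a knockout lysis profile against the wild type
#'
#' Per phage of the panel: `increased` when the knockout lyses more than
#' the wild type, `decreased` when less, `no_change` when equal. A
#' ceiling flag records when the wild type is already at a boundary of
#' the scale — already fully lytic (`up`: no increase is observable) or
#' already fully resistant (`down`: no decrease is observable) — since a
#' predicted change in that direction cannot show up on a plate.
#'
#' @param wt,ko [LysisProfile] objects over the same phage panel.
#' @return A data.frame with columns `phage`, `wt`, `ko`, `change`
#'   (factor `increased`/`decreased`/`no_change`) and `ceiling` (factor
#'   `none`/`up`/`down`).
#' @examples
#' wt <- lysisProfile("WT", c(TP1 = 0, TP2 = 1, TP3 = 2))
#' ko <- lysisProfile("KO", c(TP1 = 2, TP2 = 0, TP3 = 2))
#' compareProfiles(wt, ko)
#' @export
compareProfiles <- function(wt, ko) {
  validObject(wt); validObject(ko)
  panel <- names(wt@grades)
  if (!setequal(panel, names(ko@grades)))
    stop("wild-type and knockout profiles cover different phage panels")
  kog <- ko@grades[panel]
  d <- kog - wt@grades
  change <- factor(ifelse(d > 0L, "increased",
                          ifelse(d < 0L, "decreased", "no_change")),
                   levels = c("increased", "decreased", "no_change"))
  ceiling <- factor(ifelse(wt@grades == 2L, "up",
                           ifelse(wt@grades == 0L, "down", "none")),
                    levels = c("none", "up", "down"))
  data.frame(phage = panel, wt = unname(wt@grades), ko = unname(kog),
             change = change, ceiling = ceiling)
}

#' Concordance of observed lysis changes with screen predictions
#'
#' A knockout of a resistance gene is predicted to show `increased_lysis`
#' (the cell lost a protective function) and a knockout of a
#' susceptibility gene `decreased_lysis`. Per phage, an observed change in
#' the predicted direction counts as agreement and one in the opposite
#' direction as opposition; a phage showing no change counts as
#' `unobservable` when the wild type was already at the boundary that
#' blocks the predicted direction (e.g. already fully lytic when an
#' increase was predicted), and as `no_change` otherwise. The four tallies
#' always sum to the panel size.
#'
#' @param predictions data.frame with columns `strain_id` and
#'   `predicted_change` (`increased_lysis`/`decreased_lysis`), one row per
#'   knockout.
#' @param wt wild-type [LysisProfile].
#' @param knockouts named list of knockout [LysisProfile] objects; every
#'   knockout must have a prediction.
#' @return A data.frame with one row per knockout: `strain_id`,
#'   `predicted_change`, `n_agree`, `n_oppose`, `n_no_change`,
#'   `n_unobservable`.
#' @export
concordance <- function(predictions, wt, knockouts) {
  need <- c("strain_id", "predicted_change")
  if (!all(need %in% names(predictions)))
    stop("predictions must have strain_id and predicted_change columns")
  if (!all(predictions$predicted_change %in%
           c("increased_lysis", "decreased_lysis")))
    stop("predicted_change must be increased_lysis or decreased_lysis")
  out <- lapply(names(knockouts), function(id) {
    pred <- predictions$predicted_change[predictions$strain_id == id]
    if (length(pred) != 1L)
      stop("missing (or duplicated) prediction for knockout ", id)
    cmp <- compareProfiles(wt, knockouts[[id]])
    predDir <- if (pred == "increased_lysis") "increased" else "decreased"
    blockedAt <- if (pred == "increased_lysis") "up" else "down"
    agree <- cmp$change == predDir
    oppose <- cmp$change %in% c("increased", "decreased") & !agree
    nochg <- cmp$change == "no_change"
    unobs <- nochg & cmp$ceiling == blockedAt
    data.frame(strain_id = id, predicted_change = pred,
               n_agree = sum(agree), n_oppose = sum(oppose),
               n_no_change = sum(nochg & !unobs),
               n_unobservable = sum(unobs))
  })
  do.call(rbind, out)
}
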