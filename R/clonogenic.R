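# Clonogenic-assay arithmetic: surviving fractions, sensitizer enhancement
# ratios, and median-survival fold improvements.

#' Colony-count record
#'
#' One plating condition of a clonogenic assay (a colony is >= 50 cells).
#'
#' @param condition treatment label.
#' @param nSeeded positive integer, cells seeded.
#' @param nColonies non-negative integer, colonies counted; must not exceed
#'   \code{nSeeded}.
#' @return classed list with the validated fields.
#' @examples
#' colonyCount("HT", nSeeded = 500, nColonies = 50)
#' @export
colonyCount <- function(condition, nSeeded, nColonies) {
  stopifnot(nSeeded >= 1, nColonies >= 0)
  if (nColonies > nSeeded)
    stop("nColonies (", nColonies, ") exceeds nSeeded (", nSeeded, ")")
  structure(list(condition = condition, nSeeded = as.integer(nSeeded),
                 nColonies = as.integer(nColonies)),
            class = "ColonyCount")
}

#' Clonogenic surviving fraction
#'
#' \code{(treated colonies / treated seeded) / (control colonies / control
#' seeded)} — the treated plating efficiency relative to the control plating
#' efficiency.
#'
#' @param treated,control [colonyCount()] records.
#' @return surviving fraction (positive real).
#' @examples
#' survivingFraction(colonyCount("HT", 500, 50), colonyCount("ctrl", 500, 100))
#' @export
survivingFraction <- function(treated, control) {
  stopifnot(inherits(treated, "ColonyCount"), inherits(control, "ColonyCount"))
  if (control$nColonies == 0)
    stop("control plating efficiency is zero: surviving fraction undefined")
  (treated$nColonies / treated$nSeeded) /
    (control$nColonies / control$nSeeded)
}

#' Sensitizer enhancement ratio
#'
#' Fold reduction in surviving fraction attributable to adding the sensitizer
#' to a regimen: \code{sfWithout / sfWith}. A value of 1 marks no enhancement.
#'
#' @param sfWithout surviving fraction without the sensitizer.
#' @param sfWith surviving fraction with the sensitizer; must be > 0 (a value
#'   of 0 means the enhancement is above the detection limit of the assay).
#' @return positive real; 1 iff the two fractions are equal.
#' @examples
#' enhancementRatio(0.2, 0.05)  # 4
#' @export
enhancementRatio <- function(sfWithout, sfWith) {
  stopifnot(sfWithout > 0)
  if (sfWith <= 0)
    stop("surviving fraction with sensitizer is 0: ",
         "enhancement above detection limit")
  sfWithout / sfWith
}

#' Median-survival fold improvement
#'
#' \code{median(treated) / median(reference)} with the standard even-length
#' convention (mean of the central pair).
#'
#' @param treatedDays,referenceDays non-empty numeric vectors of survival
#'   times (days).
#' @return positive real fold change.
#' @examples
#' medianSurvivalFold(c(10, 20, 30), c(5, 10, 15))  # 2
#' @export
medianSurvivalFold <- function(treatedDays, referenceDays) {
  stopifnot(length(treatedDays) >= 1, length(referenceDays) >= 1)
  ref <- median(referenceDays)
  if (ref == 0) stop("reference median survival is zero")
  median(treatedDays) / ref
}
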