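#' @import methods
NULL

#' Differential dose-volume histogram
#'
#' A binned representation of the dose distribution over an organ: bin
#' \code{i} covers the half-open dose interval
#' \code{[binEdges[i], binEdges[i+1])} in Gy and holds the fraction of the
#' organ volume receiving a dose in that interval. Fractional (relative)
#' volume is the canonical internal representation; the absolute organ
#' volume in cm^3, when known, is retained in \code{totalVolumeCc} and is
#' used only as a weight when histograms of separate structures (e.g. the
#' two ovaries) are merged.
#'
#' @slot organ single character label, e.g. \code{"ovaries"}.
#' @slot binEdges numeric vector of length B+1, strictly increasing,
#'   starting at a dose >= 0 Gy.
#' @slot binVolume numeric vector of length B, non-negative, summing to 1.
#' @slot totalVolumeCc absolute organ volume in cm^3, or \code{NA_real_}
#'   when the export carried only relative volumes.
#'
#' @seealso [DifferentialDVH()] for the user-facing constructor,
#'   [rebin()], [meanDose()], [dvhSurvival()].
#' @export
setClass("DifferentialDVH",
  representation(
    organ = "character",
    binEdges = "numeric",
    binVolume = "numeric",
    totalVolumeCc = "numeric"
  ),
  prototype(organ = NA_character_, totalVolumeCc = NA_real_)
)

setValidity("DifferentialDVH", function(object) {
  msgs <- character()
  e <- object@binEdges
  v <- object@binVolume
  if (length(object@organ) != 1L) {
    msgs <- c(msgs, "'organ' must be a single label")
  }
  if (length(e) != length(v) + 1L) {
    msgs <- c(msgs, "length(binEdges) must be length(binVolume) + 1")
  }
  if (length(e) >= 2L) {
    if (any(diff(e) <= 0)) {
      msgs <- c(msgs, "binEdges must be strictly increasing")
    }
    if (e[1L] < 0) {
      msgs <- c(msgs, "binEdges must start at a dose >= 0 Gy")
    }
  } else {
    msgs <- c(msgs, "a DVH needs at least one bin")
  }
  if (length(v)) {
    if (any(v < -1e-12)) {
      msgs <- c(msgs, "bin volumes must be non-negative")
    }
    s <- sum(v)
    if (!is.finite(s) || abs(s - 1) > 1e-6) {
      msgs <- c(msgs, sprintf(
        "relative bin volumes must sum to 1 (got %.8g); see DifferentialDVH(normalize=)", s))
    }
  }
  tv <- object@totalVolumeCc
  if (length(tv) != 1L || (!is.na(tv) && tv <= 0)) {
    msgs <- c(msgs, "totalVolumeCc must be a single positive value or NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' Cumulative dose-volume histogram
#'
#' The cumulative form exported by most planning systems: for each dose grid
#' point, the fraction of the organ volume receiving at least that dose.
#'
#' @slot organ single character label.
#' @slot doseGrid increasing dose values in Gy.
#' @slot volumeAtOrAbove non-increasing fractions starting at 1.
#' @slot totalVolumeCc absolute organ volume in cm^3 or \code{NA_real_}.
#'
#' @seealso [toDifferential()], [toCumulative()].
#' @export
setClass("CumulativeDVH",
  representation(
    organ = "character",
    doseGrid = "numeric",
    volumeAtOrAbove = "numeric",
    totalVolumeCc = "numeric"
  ),
  prototype(organ = NA_character_, totalVolumeCc = NA_real_)
)

setValidity("CumulativeDVH", function(object) {
  msgs <- character()
  d <- object@doseGrid
  V <- object@volumeAtOrAbove
  if (length(d) != length(V)) {
    msgs <- c(msgs, "doseGrid and volumeAtOrAbove must have equal length")
  }
  if (length(d) < 2L) {
    msgs <- c(msgs, "a cumulative DVH needs at least two grid points")
  } else {
    if (any(diff(d) <= 0)) msgs <- c(msgs, "doseGrid must be strictly increasing")
    if (d[1L] < 0) msgs <- c(msgs, "doseGrid must start at a dose >= 0 Gy")
  }
  if (length(V)) {
    if (any(diff(V) > 1e-12)) {
      msgs <- c(msgs, "volumeAtOrAbove must be non-increasing")
    }
    if (abs(V[1L] - 1) > 1e-9) {
      msgs <- c(msgs, "volumeAtOrAbove must start within 1e-9 of 1")
    }
    if (V[length(V)] < -1e-12) {
      msgs <- c(msgs, "volumeAtOrAbove must end >= 0")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' One treatment plan for one patient
#'
#' Holds the per-organ differential DVHs of a single plan, either the
#' involved-field (IFRT) or the involved-site (ISRT) target-volume concept.
#'
#' @slot patientId single character label.
#' @slot technique \code{"IFRT"} or \code{"ISRT"}.
#' @slot organs named list of [DifferentialDVH-class] objects; names are the
#'   unique organ labels.
#' @export
setClass("PlanRecord",
  representation(
    patientId = "character",
    technique = "character",
    organs = "list"
  )
)

.techniques <- c("IFRT", "ISRT")

setValidity("PlanRecord", function(object) {
  msgs <- character()
  if (length(object@patientId) != 1L || is.na(object@patientId)) {
    msgs <- c(msgs, "'patientId' must be a single label")
  }
  if (length(object@technique) != 1L || !object@technique %in% .techniques) {
    msgs <- c(msgs, "'technique' must be \"IFRT\" or \"ISRT\"")
  }
  nm <- names(object@organs)
  if (length(object@organs)) {
    if (is.null(nm) || anyDuplicated(nm) || any(nm == "")) {
      msgs <- c(msgs, "organ labels must be unique and non-empty")
    }
    ok <- vapply(object@organs, is, logical(1L), class2 = "DifferentialDVH")
    if (!all(ok)) {
      msgs <- c(msgs, "every organ entry must be a DifferentialDVH")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Paired IFRT/ISRT plans for one patient
#'
#' The unit of the paired plan comparison: both target-volume concepts
#' planned on the same patient. Both plans must carry an ovary DVH
#' (an \code{"ovaries"} entry, or an \code{"ovary_left"}/\code{"ovary_right"}
#' pair), since the follicle survival chain is the point of the comparison.
#'
#' @slot patientId single character label, shared by both plans.
#' @slot ifrt,isrt [PlanRecord-class] objects of the matching technique.
#' @export
setClass("PatientPair",
  representation(
    patientId = "character",
    ifrt = "PlanRecord",
    isrt = "PlanRecord"
  )
)

.hasOvary <- function(plan) {
  nm <- names(plan@organs)
  ("ovaries" %in% nm) || all(c("ovary_left", "ovary_right") %in% nm)
}

setValidity("PatientPair", function(object) {
  msgs <- character()
  if (!identical(object@patientId, object@ifrt@patientId) ||
      !identical(object@patientId, object@isrt@patientId)) {
    msgs <- c(msgs, "both plans must share the pair's patientId")
  }
  if (!identical(object@ifrt@technique, "IFRT")) {
    msgs <- c(msgs, "'ifrt' slot must hold an IFRT plan")
  }
  if (!identical(object@isrt@technique, "ISRT")) {
    msgs <- c(msgs, "'isrt' slot must hold an ISRT plan")
  }
  if (!.hasOvary(object@ifrt) || !.hasOvary(object@isrt)) {
    msgs <- c(msgs, "both plans must contain an ovary DVH")
  }
  if (length(msgs)) msgs else TRUE
})

#' Exact sign test result
#'
#' Result of the exact paired sign test: ties (differences within the zero
#' tolerance) are excluded, and the two-sided p-value is the doubled exact
#' binomial tail min(1, 2 * P(Bin(m, 1/2) >= max(k, m - k))) where m is the
#' number of non-zero differences and k the number of positive ones.
#'
#' @slot nTotal number of paired observations supplied.
#' @slot nNonzero differences exceeding the zero tolerance in magnitude.
#' @slot nPositive positive differences among the non-zero ones.
#' @slot pTwoSided exact two-sided p-value in [0, 1].
#' @seealso [exactSignTest()]
#' @export
setClass("SignTestResult",
  representation(
    nTotal = "integer",
    nNonzero = "integer",
    nPositive = "integer",
    pTwoSided = "numeric"
  )
)

setValidity("SignTestResult", function(object) {
  msgs <- character()
  if (object@nPositive > object@nNonzero || object@nNonzero > object@nTotal) {
    msgs <- c(msgs, "need nPositive <= nNonzero <= nTotal")
  }
  if (object@pTwoSided < 0 || object@pTwoSided > 1) {
    msgs <- c(msgs, "pTwoSided must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted log-hormone regression
#'
#' Coefficients, standard errors and two-sided t-test p-values of the
#' (weighted) least-squares regression of a log-transformed gonadotropin on
#' z-scored age, sex, their interaction, chemotherapy regimen and
#' radiotherapy field location. The exact variable coding, and the
#' age-standardisation statistics needed to evaluate the linear predictor on
#' new data, are stored with the fit.
#'
#' @slot outcome \code{"log_fsh"} or \code{"log_lh"} (free labels allowed
#'   for generic designs).
#' @slot terms ordered term labels.
#' @slot coefficients,standardErrors,pValues numeric vectors aligned with
#'   \code{terms}.
#' @slot nUsed number of records entering the fit.
#' @slot sigma residual standard deviation (unbiased).
#' @slot codingNote human-readable description of the variable coding.
#' @slot ageCenter,ageScale mean and SD used to z-score age (NA for generic
#'   designs).
#' @slot sexCoding \code{"symmetric"} (+/-1/2) or \code{"dummy"} (0/1).
#' @slot ageRange range of ages seen at fit time, used to warn on
#'   extrapolation.
#' @seealso [fitHormoneModel()], [predictHormoneGrid()]
#' @export
setClass("RegressionFit",
  representation(
    outcome = "character",
    terms = "character",
    coefficients = "numeric",
    standardErrors = "numeric",
    pValues = "numeric",
    nUsed = "integer",
    sigma = "numeric",
    codingNote = "character",
    ageCenter = "numeric",
    ageScale = "numeric",
    sexCoding = "character",
    ageRange = "numeric"
  ),
  prototype(ageCenter = NA_real_, ageScale = NA_real_,
            sexCoding = NA_character_, ageRange = c(NA_real_, NA_real_))
)

setValidity("RegressionFit", function(object) {
  msgs <- character()
  p <- length(object@terms)
  if (length(object@coefficients) != p || length(object@standardErrors) != p ||
      length(object@pValues) != p) {
    msgs <- c(msgs, "terms, coefficients, standardErrors and pValues must align")
  }
  pv <- object@pValues
  if (any(pv < 0 | pv > 1, na.rm = TRUE)) {
    msgs <- c(msgs, "p-values must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})
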