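.sdOrZero <- function(x) {
  if (length(x) < 2L) 0 else stats::sd(x)
}

.comparisonRow <- function(metric, ifrtVals, isrtVals, diffs, zeroTolerance,
                           nExcluded = 0L) {
  st <- exactSignTest(diffs, zeroTolerance = zeroTolerance)
  data.frame(
    metric = metric,
    n = length(diffs),
    n_excluded = nExcluded,
    mean_ifrt = mean(ifrtVals),
    sd_ifrt = .sdOrZero(ifrtVals),
    mean_isrt = mean(isrtVals),
    sd_isrt = .sdOrZero(isrtVals),
    mean_diff = mean(diffs),
    sd_diff = .sdOrZero(diffs),
    n_nonzero = st@nNonzero,
    n_positive = st@nPositive,
    p_value = st@pTwoSided,
    stringsAsFactors = FALSE)
}

#' Default organ-at-risk metric set
#'
#' The organs-at-risk summarized in the paired plan comparison, in fixed
#' table order, with the summary statistic per organ: mean dose everywhere
#' except the spinal cord, which is summarized by maximum dose.
#'
#' @return Named character vector mapping organ label to \code{"mean"} or
#'   \code{"max"}.
#' @export
defaultOarMetrics <- function() {
  c(small_bowel = "mean", bladder = "mean", femoral_head_left = "mean",
    femoral_head_right = "mean", rectum = "mean", spinal_cord = "max",
    uterus = "mean", ovaries = "mean")
}

#' Paired organ-at-risk dose comparison
#'
#' For every requested organ, summarizes the per-arm dose metric (mean dose,
#' or maximum dose where so specified) over the cohort and tests the paired
#' per-patient differences (IFRT minus ISRT) with the exact sign test.
#' Patients missing an organ in either plan are excluded from that organ's
#' row with a warning; the exclusion count is reported.
#'
#' @param cohort list of [PatientPair-class] objects.
#' @param metrics named character vector organ -> \code{"mean"}/\code{"max"}
#'   (default [defaultOarMetrics()]).
#' @param zeroTolerance tie tolerance in Gy for the sign test (default 1e-9).
#' @return A data.frame with one row per organ: per-arm mean/SD, difference
#'   mean/SD (IFRT - ISRT), sign-test counts and exact two-sided p-value.
#' @export
compareOarDoses <- function(cohort, metrics = defaultOarMetrics(),
                            zeroTolerance = 1e-9) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  rows <- list()
  for (org in names(metrics)) {
    stat <- if (metrics[[org]] == "max") maxDose else meanDose
    iVals <- sVals <- numeric(0)
    excluded <- 0L
    for (pp in cohort) {
      a <- pp@ifrt@organs[[org]]
      b <- pp@isrt@organs[[org]]
      if (is.null(a) || is.null(b)) {
        excluded <- excluded + 1L
        next
      }
      iVals <- c(iVals, stat(a))
      sVals <- c(sVals, stat(b))
    }
    if (excluded > 0L) {
      warning(excluded, " patient(s) lack organ '", org,
              "' in one plan; excluded from that row", call. = FALSE)
    }
    if (!length(iVals)) next
    rows[[org]] <- .comparisonRow(org, iVals, sVals, iVals - sVals,
                                  zeroTolerance, excluded)
  }
  if (!length(rows)) stop("no organ present in any pair", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.cohortSurvival <- function(cohort, width = 0.1) {
  g <- function(plan) dvhSurvival(ovaryDvh(plan, width), width = width)
  data.frame(
    patient_id = vapply(cohort, patientId, character(1L)),
    g_ifrt = vapply(cohort, function(pp) g(pp@ifrt), numeric(1L)),
    g_isrt = vapply(cohort, function(pp) g(pp@isrt), numeric(1L)))
}

#' Cohort summary of surviving NGF percentage
#'
#' Runs the both-ovaries DVH of each plan through the follicle survival
#' summation and summarizes the surviving percentage per arm, with the
#' exact sign test on the per-patient gains (ISRT minus IFRT, so a positive
#' difference is a benefit of the smaller target volume).
#'
#' @inheritParams compareOarDoses
#' @param width DVH rebin width in Gy for the survival summation.
#' @return A single-row data.frame in the [compareOarDoses()] shape, with
#'   \code{mean_diff} the mean ISRT - IFRT gain.
#' @export
survivingNgfSummary <- function(cohort, width = 0.1, zeroTolerance = 1e-9) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  gs <- .cohortSurvival(cohort, width)
  .comparisonRow("surviving_ngf_percent", gs$g_ifrt, gs$g_isrt,
                 gs$g_isrt - gs$g_ifrt, zeroTolerance)
}

#' Paired menopause-timing comparison over a theoretical age grid
#'
#' The full model chain per patient and arm: combined both-ovaries DVH ->
#' surviving NGF percentage -> predicted time to premature menopause at
#' every age of the grid. Per age the function reports per-arm mean/SD of
#' the predicted time, the mean gain from the smaller target volume
#' (ISRT minus IFRT) and the exact sign test on the per-patient gains.
#'
#' The default tie tolerance is half the 0.01-year rounding unit of the
#' output tables, so arms whose predicted times agree after rounding (in
#' particular ages where both arms floor at zero) count as ties and drive
#' the p-value toward 1.
#'
#' @inheritParams survivingNgfSummary
#' @param ages theoretical ages at treatment (default [defaultAgeGrid()]).
#' @param zeroTolerance tie tolerance in years (default 0.005).
#' @return A data.frame with one row per age: \code{age_years}, per-arm
#'   mean/SD, \code{mean_diff}/\code{sd_diff} (ISRT - IFRT gain), sign-test
#'   counts and p-value.
#' @export
compareMenopause <- function(cohort, ages = defaultAgeGrid(), width = 0.1,
                             zeroTolerance = 0.005) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  gs <- .cohortSurvival(cohort, width)
  n <- nrow(gs)
  rows <- vector("list", length(ages))
  for (j in seq_along(ages)) {
    tI <- timeToMenopause(ages[j], gs$g_ifrt)$time_to_menopause
    tS <- timeToMenopause(ages[j], gs$g_isrt)$time_to_menopause
    row <- .comparisonRow(sprintf("age_%d", ages[j]), tI, tS, tS - tI,
                          zeroTolerance)
    row <- cbind(age_years = ages[j], row)
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
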