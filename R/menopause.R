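.hansenA <- -0.00019
.hansenB <- 2.452
.hansenC <- 5.717
.menopauseAge <- 50.4

#' Non-growing follicle count at a given age
#'
#' The Hansen model of the decline of the resting follicle pool with age:
#' log10(n) = -0.00019 * age^2.452 + 5.717, so a newborn carries about
#' 5.2e5 NGFs and the count falls monotonically thereafter.
#'
#' @param age age in years; vectorized, non-negative.
#' @return Follicle count.
#' @examples
#' hansenNgf(c(18, 30, 50.4))
#' @seealso [reproductiveAge()] for the closed-form inverse.
#' @export
hansenNgf <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age))) {
    stop("'age' must be finite", call. = FALSE)
  }
  if (any(age < 0)) stop("'age' must be non-negative", call. = FALSE)
  10^(.hansenA * age^.hansenB + .hansenC)
}

#' Effective reproductive age from a follicle count
#'
#' Closed-form inverse of [hansenNgf()]: the age at which a healthy ovary
#' would hold \code{n} non-growing follicles,
#' r = ((5.717 - log10 n) / 0.00019)^(1/2.452). A woman whose
#' post-irradiation pool equals \code{n} is assigned this reproductive age.
#'
#' @param n follicle count; vectorized, in (0, 10^5.717].
#' @return Age in years.
#' @export
reproductiveAge <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n))) {
    stop("'n' must be finite", call. = FALSE)
  }
  nMax <- 10^.hansenC
  if (any(n <= 0) || any(n > nMax * (1 + 1e-12))) {
    stop("'n' must lie in (0, 10^5.717]: the model is undefined outside ",
         "the newborn pool size", call. = FALSE)
  }
  ((log10(pmin(n, nMax)) - .hansenC) / .hansenA)^(1 / .hansenB)
}

#' Default theoretical age grid
#'
#' Ages at start of therapy of 18 to 48 years in two-year steps, the grid
#' over which menopause-timing tables are evaluated.
#'
#' @return Integer vector 18, 20, ..., 48.
#' @export
defaultAgeGrid <- function() {
  seq(18L, 48L, by = 2L)
}

#' Predicted time to premature menopause
#'
#' Chains the follicle models: the age-matched initial NGF count
#' ([hansenNgf()]) is scaled by the surviving percentage g, the scaled count
#' is mapped back to an effective reproductive age ([reproductiveAge()]),
#' and the remaining time to menopause is 50.4 years (the average age at
#' natural menopause) minus that reproductive age, floored at zero. The
#' floor encodes that an ovary already depleted to a post-menopausal level
#' confers immediate menopause, not a negative time.
#'
#' @param ageAtTreatment age in years at the start of radiotherapy;
#'   vectorized, in [0, 50.4).
#' @param gPercent surviving NGF percentage in (0, 100]; vectorized
#'   (recycled against \code{ageAtTreatment}).
#' @return A data.frame with one row per (age, g) pair and columns
#'   \code{age_at_treatment}, \code{g_percent}, \code{ngf_initial},
#'   \code{ngf_post}, \code{reproductive_age} and \code{time_to_menopause}.
#' @examples
#' timeToMenopause(18, 11.87)   # ~15.5 years
#' timeToMenopause(25, 100)     # 25.4 years: no follicle loss
#' @export
timeToMenopause <- function(ageAtTreatment, gPercent) {
  if (any(!is.finite(ageAtTreatment)) || any(ageAtTreatment < 0) ||
      any(ageAtTreatment >= .menopauseAge)) {
    stop("'ageAtTreatment' must lie in [0, 50.4)", call. = FALSE)
  }
  if (any(!is.finite(gPercent)) || any(gPercent <= 0) ||
      any(gPercent > 100 + 1e-9)) {
    stop("'gPercent' must lie in (0, 100]", call. = FALSE)
  }
  k <- max(length(ageAtTreatment), length(gPercent))
  age <- rep_len(ageAtTreatment, k)
  g <- rep_len(gPercent, k)
  n0 <- hansenNgf(age)
  nPost <- n0 * g / 100
  r <- reproductiveAge(nPost)
  data.frame(
    age_at_treatment = age,
    g_percent = g,
    ngf_initial = n0,
    ngf_post = nPost,
    reproductive_age = r,
    time_to_menopause = pmax(0, .menopauseAge - r)
  )
}

#' Menopause predictions over an age grid
#'
#' Evaluates [timeToMenopause()] for one surviving fraction at every age of
#' a theoretical age grid. For fixed g the predicted time is non-increasing
#' in age, reaching zero where the model floors.
#'
#' @param gPercent a single surviving NGF percentage in (0, 100].
#' @param ages age grid in years (default [defaultAgeGrid()]).
#' @return The [timeToMenopause()] data.frame with one row per age.
#' @export
menopauseGrid <- function(gPercent, ages = defaultAgeGrid()) {
  stopifnot(length(gPercent) == 1L)
  timeToMenopause(ages, gPercent)
}
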