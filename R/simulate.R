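## Truncated-normal helpers (analytic moments + inverse-CDF sampling).

.truncMoments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

.qtrunc <- function(u, mu, sigma, lo, hi) {
  pa <- stats::pnorm(lo, mu, sigma)
  pb <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(pa + u * (pb - pa), mu, sigma)
}

## Solve for (mu, sigma) so the [lo, hi]-truncated normal has the target
## mean and SD. Errors when the targets are unattainable on the interval.
## A truncated normal on [0, hi] is log-concave, so its SD cannot exceed
## its mean (the exponential limit). The mean target must be hit tightly
## (otherwise the configuration is unsatisfiable); the SD is matched as
## closely as the family allows, which for targets at or past the
## log-concavity bound means a slightly smaller realized SD.
.truncCalibrate <- function(targetMean, targetSd, lo, hi) {
  obj <- function(par) {
    if (par[1L] < lo - 3 * (hi - lo) || exp(par[2L]) > 10 * (hi - lo)) {
      return(1e10)
    }
    mo <- .truncMoments(par[1L], exp(par[2L]), lo, hi)
    if (any(!is.finite(mo))) return(1e10)
    50 * ((mo["mean"] - targetMean) / max(targetMean, 1))^2 +
      ((mo["sd"] - targetSd) / max(targetSd, 1e-6))^2
  }
  fit <- stats::optim(c(targetMean, log(max(targetSd, 1e-3))), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  mo <- .truncMoments(fit$par[1L], exp(fit$par[2L]), lo, hi)
  if (any(!is.finite(mo)) ||
      abs(mo["mean"] - targetMean) > 5e-3 * max(1, abs(targetMean))) {
    stop("cannot realize mean ", targetMean, " (SD ", targetSd,
         ") with a truncated normal on [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  list(mu = fit$par[1L], sigma = exp(fit$par[2L]))
}

.defaultOarTargets <- function() {
  ## per organ: c(IFRT mean, IFRT sd, ISRT mean, ISRT sd) of the dose
  ## summary (mean dose; the generator treats the spinal cord the same way)
  list(
    small_bowel = c(13.29, 1.52, 7.88, 2.65),
    bladder = c(11.67, 3.56, 8.74, 3.36),
    femoral_head_left = c(17.51, 4.10, 14.47, 4.89),
    femoral_head_right = c(9.40, 7.23, 5.02, 5.13),
    rectum = c(10.03, 4.01, 6.44, 3.48),
    spinal_cord = c(15.5, 1.4, 12.4, 2.8),
    uterus = c(14.51, 5.41, 8.94, 4.43),
    ovaries = c(15.13, 6.34, 7.44, 5.64))
}

#' Configuration for the paired-plan DVH simulator
#'
#' Defines the study conditions the generator emulates: 13 paired
#' involved-field / involved-site plans at a 30 Gy prescription, with
#' cohort ovarian mean-dose targets of 15.13 +/- 6.34 Gy (IFRT) and
#' 7.44 +/- 5.64 Gy (ISRT) and the smaller target volume never worse within
#' a patient. Each organ's DVH is a two-component mixture: an in-field
#' fraction near the prescription dose plus a low-dose bath, the minimal
#' shape with which a rotational (VMAT) plan spreads dose over organs at
#' risk.
#'
#' @param nPatients number of patient pairs (default 13).
#' @param seed integer seed; each patient draws from its own substream so
#'   enlarging the cohort does not reshuffle existing patients.
#' @param prescriptionDose prescription dose in Gy (default 30).
#' @param meanDoseTargets list with elements \code{IFRT} and \code{ISRT},
#'   each \code{c(mean, sd)} of the target ovarian mean dose in Gy.
#' @param oarTargets named list organ -> \code{c(ifrtMean, ifrtSd,
#'   isrtMean, isrtSd)} for additional organs at risk.
#' @param bathDoseRange range in Gy from which each patient's low-dose bath
#'   centre is drawn.
#' @param inFieldFractionRange list with \code{IFRT} and \code{ISRT}
#'   elements, each \code{c(lo, hi)} clamping the in-field volume fraction;
#'   the default \code{c(0, 1)} leaves the fraction determined by the dose
#'   target. Clamping overrides the mean-dose calibration.
#' @return A validated configuration list of class \code{"DvhSimConfig"}.
#' @export
dvhSimConfig <- function(nPatients = 13L, seed = 1L, prescriptionDose = 30,
                         meanDoseTargets = list(IFRT = c(15.13, 6.34),
                                                ISRT = c(7.44, 5.64)),
                         oarTargets = .defaultOarTargets(),
                         bathDoseRange = c(0.5, 3),
                         inFieldFractionRange = list(IFRT = c(0, 1),
                                                     ISRT = c(0, 1))) {
  if (nPatients < 1L) stop("need at least one patient", call. = FALSE)
  if (prescriptionDose <= 0) stop("prescription must be positive",
                                  call. = FALSE)
  for (tech in .techniques) {
    tg <- meanDoseTargets[[tech]]
    if (length(tg) != 2L || tg[1L] <= 0 || tg[2L] < 0) {
      stop("meanDoseTargets$", tech, " must be c(mean > 0, sd >= 0)",
           call. = FALSE)
    }
    if (tg[1L] >= prescriptionDose) {
      stop("target mean dose for ", tech,
           " must be below the prescription dose", call. = FALSE)
    }
    fr <- inFieldFractionRange[[tech]]
    if (length(fr) != 2L || fr[1L] < 0 || fr[2L] > 1 || fr[1L] > fr[2L]) {
      stop("inFieldFractionRange$", tech, " must be within [0, 1]",
           call. = FALSE)
    }
  }
  if (bathDoseRange[1L] < 0 || diff(bathDoseRange) < 0 ||
      bathDoseRange[2L] >= prescriptionDose / 2) {
    stop("bathDoseRange must be a low-dose interval below half the ",
         "prescription", call. = FALSE)
  }
  structure(list(
    nPatients = as.integer(nPatients), seed = as.integer(seed),
    prescriptionDose = prescriptionDose, meanDoseTargets = meanDoseTargets,
    oarTargets = oarTargets, bathDoseRange = bathDoseRange,
    inFieldFractionRange = inFieldFractionRange), class = "DvhSimConfig")
}

.patientSeed <- function(seed, i, salt = 0) {
  as.integer((abs(as.numeric(seed)) * 100003 + salt * 997 + i) %%
               2147483647)
}

## One two-component organ DVH realizing mean dose m exactly:
## fraction f uniform on [p - h, p + h] (in-field), 1 - f uniform around
## the bath centre. f = (m - bath)/(p - bath), clamped to fRange.
.twoComponentDvh <- function(organ, m, bath, prescription, fRange) {
  h <- min(1, 0.05 * prescription)
  bath <- min(bath, m)
  f <- (m - bath) / (prescription - bath)
  f <- min(max(f, fRange[1L]), fRange[2L])
  wb <- min(0.4, bath)
  spLo <- prescription - h
  spHi <- prescription + h
  if (f >= 1 - 1e-12) {
    edges <- c(spLo, spHi); vols <- 1
  } else if (f <= 1e-12) {
    if (wb <= 1e-9) {
      edges <- c(0, max(2 * bath, 0.01)); vols <- 1
    } else {
      edges <- c(bath - wb, bath + wb); vols <- 1
    }
  } else {
    edges <- c(max(0, bath - wb), bath + wb, spLo, spHi)
    vols <- c(1 - f, 0, f)
  }
  DifferentialDVH(organ, edges, vols, normalize = TRUE)
}

#' Simulate a paired IFRT/ISRT DVH cohort
#'
#' For each patient and organ, a shared uniform quantile is pushed through
#' per-arm truncated-normal mean-dose distributions whose parameters are
#' moment-matched so the truncated mean/SD equal the configured targets;
#' the comonotone coupling (plus an explicit guard) makes the ISRT mean
#' dose no larger than the IFRT mean dose in every single patient, while
#' the marginal cohort moments converge to the targets as the cohort
#' grows. The drawn mean dose is then realized exactly by a two-component
#' (bath + in-field) differential DVH; the in-field fraction inherits the
#' per-patient ordering because bath and in-field doses are shared within
#' a patient.
#'
#' @param cfg a [dvhSimConfig()] configuration.
#' @return A list of [PatientPair-class] objects of length
#'   \code{cfg$nPatients}; byte-identical across runs for a given config.
#' @examples
#' cohort <- simulatePairedDvhCohort(dvhSimConfig(nPatients = 3, seed = 7))
#' compareOarDoses(cohort, metrics = c(ovaries = "mean"))
#' @export
simulatePairedDvhCohort <- function(cfg = dvhSimConfig()) {
  stopifnot(inherits(cfg, "DvhSimConfig"))
  p <- cfg$prescriptionDose
  targets <- cfg$oarTargets
  targets[["ovaries"]] <- c(cfg$meanDoseTargets$IFRT,
                            cfg$meanDoseTargets$ISRT)
  cal <- lapply(targets, function(tg) {
    list(IFRT = .truncCalibrate(tg[1L], tg[2L], 0, p),
         ISRT = .truncCalibrate(tg[3L], tg[4L], 0, p))
  })
  cohort <- vector("list", cfg$nPatients)
  for (i in seq_len(cfg$nPatients)) {
    set.seed(.patientSeed(cfg$seed, i))
    pid <- sprintf("P%02d", i)
    organsI <- organsS <- list()
    for (org in names(targets)) {
      u <- stats::runif(1L)
      bath <- stats::runif(1L, cfg$bathDoseRange[1L], cfg$bathDoseRange[2L])
      mI <- .qtrunc(u, cal[[org]]$IFRT$mu, cal[[org]]$IFRT$sigma, 0, p)
      mS <- .qtrunc(u, cal[[org]]$ISRT$mu, cal[[org]]$ISRT$sigma, 0, p)
      mS <- min(mS, mI)  # hard per-patient ordering guarantee
      organsI[[org]] <- .twoComponentDvh(org, mI, bath, p,
                                         cfg$inFieldFractionRange$IFRT)
      organsS[[org]] <- .twoComponentDvh(org, mS, bath, p,
                                         cfg$inFieldFractionRange$ISRT)
    }
    cohort[[i]] <- PatientPair(PlanRecord(pid, "IFRT", organsI),
                               PlanRecord(pid, "ISRT", organsS))
  }
  cohort
}

#' Configuration for the hormone cohort simulator
#'
#' Emulates the gonadotropin cohort the regression model was built for:
#' 499 patients (258 female, 241 male), 4.2% treated with
#' infradiaphragmatic fields, randomized roughly evenly between ABVD and
#' the 2+2 regimen, with log-scale outcomes generated from the regression
#' coefficients of the fitted model (intercept 2.069, age(z) 0.039, sex
#' 0.101, age x sex -0.040, ABVD -0.634, IDRT 0.598 for log FSH) plus
#' normal residuals.
#'
#' @param n cohort size (default 499).
#' @param seed integer seed.
#' @param coefficients list with \code{fsh} and \code{lh} elements, each a
#'   length-6 vector in [buildHormoneDesign()] term order.
#' @param residualSd log-scale residual SD (default 0.8), applied to both
#'   outcomes.
#' @param idrtFraction proportion with infradiaphragmatic fields
#'   (default 0.042).
#' @param femaleFraction proportion female (default 258/499).
#' @param abvdFraction proportion on ABVD (default 0.5).
#' @param sexCoding coding used to evaluate the generating linear
#'   predictor; must match the analysis coding.
#' @return A validated configuration list of class \code{"HormoneSimConfig"}.
#' @export
hormoneSimConfig <- function(n = 499L, seed = 1L,
                             coefficients = list(
                               fsh = c(intercept = 2.069, age_z = 0.039,
                                       sex = 0.101, age_sex = -0.040,
                                       chemo_abvd = -0.634,
                                       rt_idrt = 0.598),
                               lh = c(intercept = 1.624, age_z = 0.033,
                                      sex = -0.036, age_sex = -0.056,
                                      chemo_abvd = -0.243,
                                      rt_idrt = 0.349)),
                             residualSd = 0.8, idrtFraction = 0.042,
                             femaleFraction = 258 / 499,
                             abvdFraction = 0.5,
                             sexCoding = "symmetric") {
  if (n < 1L) stop("need at least one record", call. = FALSE)
  for (pr in c(idrtFraction, femaleFraction, abvdFraction)) {
    if (pr < 0 || pr > 1) stop("proportions must lie in [0, 1]",
                               call. = FALSE)
  }
  if (residualSd <= 0) stop("residualSd must be positive", call. = FALSE)
  for (outc in c("fsh", "lh")) {
    if (length(coefficients[[outc]]) != 6L) {
      stop("coefficients$", outc, " must have 6 entries (",
           paste(.hormoneTerms, collapse = ", "), ")", call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 coefficients = coefficients, residualSd = residualSd,
                 idrtFraction = idrtFraction,
                 femaleFraction = femaleFraction,
                 abvdFraction = abvdFraction, sexCoding = sexCoding),
            class = "HormoneSimConfig")
}

#' Simulate a hormone cohort
#'
#' Draws covariates (sex, age within the cohort's eligibility windows —
#' women 18-39, men 18-49 —, chemotherapy arm, field location) per the
#' configured proportions, evaluates the generating linear predictor with
#' the same coding as [buildHormoneDesign()] on the simulated cohort, adds
#' independent normal residuals per outcome on the log scale, and
#' exponentiates back to U/L.
#'
#' @param cfg a [hormoneSimConfig()] configuration.
#' @return A validated hormone cohort data.frame with columns
#'   \code{patient_id}, \code{sex}, \code{age_years}, \code{chemo},
#'   \code{rt_field}, \code{fsh_u_per_l}, \code{lh_u_per_l},
#'   \code{months_since_rt}.
#' @export
simulateHormoneCohort <- function(cfg = hormoneSimConfig()) {
  stopifnot(inherits(cfg, "HormoneSimConfig"))
  set.seed(.patientSeed(cfg$seed, 0L, salt = 17))
  n <- cfg$n
  sex <- ifelse(stats::runif(n) < cfg$femaleFraction, "female", "male")
  age <- ifelse(sex == "female",
                stats::runif(n, 18, 39.99),
                stats::runif(n, 18, 49.99))
  chemo <- ifelse(stats::runif(n) < cfg$abvdFraction, "ABVD", "2+2")
  rt <- ifelse(stats::runif(n) < cfg$idrtFraction, "IDRT", "SDRT")
  months <- pmax(1, round(stats::rnorm(n, 41.4, 19.2), 1))
  cohort <- data.frame(
    patient_id = sprintf("H%04d", seq_len(n)),
    sex = sex, age_years = round(age, 2), chemo = chemo, rt_field = rt,
    fsh_u_per_l = 1, lh_u_per_l = 1, months_since_rt = months,
    stringsAsFactors = FALSE)
  design <- buildHormoneDesign(cohort, sexCoding = cfg$sexCoding)
  for (outc in c("fsh", "lh")) {
    eta <- as.numeric(design$X %*% cfg$coefficients[[outc]])
    y <- eta + stats::rnorm(n, 0, cfg$residualSd)
    cohort[[paste0(outc, "_u_per_l")]] <- exp(y)
  }
  validateHormoneCohort(cohort)
  cohort
}
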