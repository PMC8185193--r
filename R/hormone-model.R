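.sexLevels <- c("female", "male")
.chemoLevels <- c("ABVD", "2+2")
.rtLevels <- c("IDRT", "SDRT")

#' Validate a hormone cohort table
#'
#' Checks the hormone cohort schema: columns \code{patient_id}, \code{sex}
#' (female|male), \code{age_years}, \code{chemo} (ABVD|2+2),
#' \code{rt_field} (IDRT|SDRT), \code{fsh_u_per_l}, \code{lh_u_per_l} and
#' optionally \code{months_since_rt} and \code{weight}. Hormone levels must
#' be strictly positive (the models work on the natural log); the cohort
#' definition admits women younger than 40 and men younger than 50 at
#' diagnosis.
#'
#' @param cohort a data.frame.
#' @return The cohort, invisibly, after validation.
#' @export
validateHormoneCohort <- function(cohort) {
  required <- c("patient_id", "sex", "age_years", "chemo", "rt_field",
                "fsh_u_per_l", "lh_u_per_l")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    stop("hormone cohort is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!nrow(cohort)) stop("hormone cohort is empty", call. = FALSE)
  badLevel <- function(col, levels) {
    i <- which(!cohort[[col]] %in% levels)
    if (length(i)) {
      stop("unknown ", col, " '", cohort[[col]][i[1L]], "' for patient ",
           cohort$patient_id[i[1L]], " (expected ",
           paste(levels, collapse = "|"), ")", call. = FALSE)
    }
  }
  badLevel("sex", .sexLevels)
  badLevel("chemo", .chemoLevels)
  badLevel("rt_field", .rtLevels)
  for (col in c("fsh_u_per_l", "lh_u_per_l")) {
    i <- which(!is.finite(cohort[[col]]) | cohort[[col]] <= 0)
    if (length(i)) {
      stop("non-positive ", col, " for patient ", cohort$patient_id[i[1L]],
           ": the log transform requires strictly positive levels",
           call. = FALSE)
    }
  }
  tooOld <- (cohort$sex == "female" & cohort$age_years >= 40) |
    (cohort$sex == "male" & cohort$age_years >= 50)
  if (any(tooOld)) {
    stop("age outside the cohort definition (female < 40, male < 50) for ",
         "patient ", cohort$patient_id[which(tooOld)[1L]], call. = FALSE)
  }
  if ("weight" %in% names(cohort)) {
    i <- which(!is.finite(cohort$weight) | cohort$weight <= 0)
    if (length(i)) {
      stop("weights must be positive (patient ",
           cohort$patient_id[i[1L]], ")", call. = FALSE)
    }
  }
  invisible(cohort)
}

#' Read a hormone cohort CSV
#'
#' @param path CSV file path with the schema of [validateHormoneCohort()].
#' @return A validated data.frame.
#' @export
readHormoneTable <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateHormoneCohort(cohort)
  cohort
}

#' Log-transform hormone levels
#'
#' Natural logarithm of the FSH and LH columns, the outcome scale of the
#' regression models.
#'
#' @param cohort a validated hormone cohort data.frame.
#' @return The cohort with extra columns \code{log_fsh} and \code{log_lh}.
#' @export
logTransformHormones <- function(cohort) {
  validateHormoneCohort(cohort)
  cohort$log_fsh <- log(cohort$fsh_u_per_l)
  cohort$log_lh <- log(cohort$lh_u_per_l)
  cohort
}

.hormoneTerms <- c("intercept", "age_z", "sex", "age_sex", "chemo_abvd",
                   "rt_idrt")

#' Build the hormone regression design matrix
#'
#' Columns, in order: intercept; age z-scored over the cohort; sex
#' (symmetric +1/2 female, -1/2 male by default, or 0/1 female dummy);
#' their product (the age-by-sex interaction); the chemotherapy indicator
#' (ABVD = 1 vs the 2+2 regimen = 0); and the field-location indicator
#' (infradiaphragmatic IDRT = 1 vs supradiaphragmatic SDRT = 0). Both
#' binary treatment contrasts are coded on the same 0/1 scale so their
#' coefficients are directly comparable effect sizes. The exact coding and
#' the age-standardization statistics are recorded so fits are fully
#' reproducible on new data.
#'
#' @param cohort a validated hormone cohort data.frame.
#' @param sexCoding \code{"symmetric"} (default) or \code{"dummy"}.
#' @param ageCenter,ageScale optional fixed standardization statistics;
#'   by default the cohort's mean and SD of age.
#' @return A list with elements \code{X} (model matrix with columns
#'   \code{intercept}, \code{age_z}, \code{sex}, \code{age_sex},
#'   \code{chemo_abvd}, \code{rt_idrt}), \code{codingNote},
#'   \code{ageCenter}, \code{ageScale}, \code{sexCoding}.
#' @export
buildHormoneDesign <- function(cohort, sexCoding = c("symmetric", "dummy"),
                               ageCenter = NULL, ageScale = NULL) {
  sexCoding <- match.arg(sexCoding)
  validateHormoneCohort(cohort)
  for (fac in list(c("sex", "female"), c("chemo", "ABVD"),
                   c("rt_field", "IDRT"))) {
    lv <- unique(cohort[[fac[1L]]])
    if (length(lv) < 2L) {
      warning("only one level of ", fac[1L], " present (", lv,
              "); its coefficient is not estimable", call. = FALSE)
    }
  }
  if (is.null(ageCenter)) ageCenter <- mean(cohort$age_years)
  if (is.null(ageScale)) ageScale <- stats::sd(cohort$age_years)
  if (!is.finite(ageScale) || ageScale <= 0) ageScale <- 1
  ageZ <- (cohort$age_years - ageCenter) / ageScale
  sex <- if (sexCoding == "symmetric") {
    ifelse(cohort$sex == "female", 0.5, -0.5)
  } else {
    ifelse(cohort$sex == "female", 1, 0)
  }
  X <- cbind(
    intercept = 1,
    age_z = ageZ,
    sex = sex,
    age_sex = ageZ * sex,
    chemo_abvd = as.numeric(cohort$chemo == "ABVD"),
    rt_idrt = as.numeric(cohort$rt_field == "IDRT"))
  note <- sprintf(
    paste0("age z-scored (center %.6g, scale %.6g); sex %s; ",
           "interaction = age_z * sex; chemo ABVD=1 vs 2+2=0; ",
           "rt_field IDRT=1 vs SDRT=0"),
    ageCenter, ageScale,
    if (sexCoding == "symmetric") "female=+0.5, male=-0.5"
    else "female=1, male=0")
  list(X = X, codingNote = note, ageCenter = ageCenter,
       ageScale = ageScale, sexCoding = sexCoding)
}

#' Fit a linear model on an explicit design matrix
#'
#' Ordinary or weighted least squares via [stats::lm.fit()] /
#' [stats::lm.wfit()]: coefficients solve the (weighted) normal equations,
#' standard errors use the unbiased residual variance, and two-sided
#' p-values come from the t distribution on n - p degrees of freedom.
#'
#' @param X numeric design matrix with named columns.
#' @param y numeric outcome vector.
#' @param weights optional positive case weights (default all 1, i.e. OLS).
#' @param outcome label stored with the fit.
#' @return A [RegressionFit-class] object.
#' @export
fitLinearModel <- function(X, y, weights = NULL, outcome = "y") {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y sizes disagree", call. = FALSE)
  if (nrow(X) <= ncol(X)) {
    stop("need more records (", nrow(X), ") than terms (", ncol(X), ")",
         call. = FALSE)
  }
  if (is.null(weights)) {
    fit <- stats::lm.fit(X, y)
  } else {
    if (any(!is.finite(weights) | weights <= 0)) {
      stop("weights must be positive", call. = FALSE)
    }
    fit <- stats::lm.wfit(X, y, w = weights)
  }
  p <- ncol(X)
  if (fit$rank < p) {
    aliased <- colnames(X)[fit$qr$pivot[(fit$rank + 1L):p]]
    stop("design is rank deficient; collinear term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  res <- fit$residuals
  if (!is.null(weights)) res <- res * sqrt(weights)
  dfRes <- nrow(X) - p
  sigma2 <- sum(res^2) / dfRes
  XtX <- if (is.null(weights)) crossprod(X) else crossprod(X, X * weights)
  covB <- sigma2 * solve(XtX)
  se <- sqrt(diag(covB))
  coef <- fit$coefficients[colnames(X)]
  tVal <- coef / se
  pv <- 2 * stats::pt(abs(tVal), dfRes, lower.tail = FALSE)
  new("RegressionFit", outcome = outcome, terms = colnames(X),
      coefficients = unname(coef), standardErrors = unname(se),
      pValues = unname(pv), nUsed = nrow(X), sigma = sqrt(sigma2),
      codingNote = "explicit design matrix")
}

#' Fit the log-hormone regression
#'
#' Builds the standard design ([buildHormoneDesign()]) and regresses the
#' natural log of the chosen gonadotropin on it by (weighted) least
#' squares. Per-record weights, when a \code{weight} column is present or
#' the \code{weights} argument is given, reproduce any weighted scheme;
#' the default is ordinary least squares.
#'
#' @param cohort a validated hormone cohort data.frame.
#' @param outcome \code{"fsh"} or \code{"lh"}.
#' @param weights optional positive weights; defaults to the cohort's
#'   \code{weight} column when present, else all 1.
#' @param sexCoding passed to [buildHormoneDesign()].
#' @return A [RegressionFit-class] carrying the coding metadata needed by
#'   [predictHormoneGrid()].
#' @examples
#' coh <- simulateHormoneCohort(hormoneSimConfig(n = 200, seed = 1))
#' fitHormoneModel(coh, "fsh")
#' @export
fitHormoneModel <- function(cohort, outcome = c("fsh", "lh"),
                            weights = NULL, sexCoding = "symmetric") {
  outcome <- match.arg(outcome)
  cohort <- logTransformHormones(cohort)
  design <- buildHormoneDesign(cohort, sexCoding = sexCoding)
  y <- if (outcome == "fsh") cohort$log_fsh else cohort$log_lh
  if (is.null(weights) && "weight" %in% names(cohort)) {
    weights <- cohort$weight
  }
  fit <- fitLinearModel(design$X, y, weights = weights,
                        outcome = paste0("log_", outcome))
  fit@codingNote <- design$codingNote
  fit@ageCenter <- design$ageCenter
  fit@ageScale <- design$ageScale
  fit@sexCoding <- design$sexCoding
  fit@ageRange <- range(cohort$age_years)
  fit
}

#' Coefficient table of a fitted regression
#'
#' @param fit a [RegressionFit-class].
#' @return A data.frame with columns \code{term}, \code{estimate},
#'   \code{std_error}, \code{p_value}.
#' @export
coefTable <- function(fit) {
  stopifnot(is(fit, "RegressionFit"))
  data.frame(term = fit@terms, estimate = fit@coefficients,
             std_error = fit@standardErrors, p_value = fit@pValues,
             stringsAsFactors = FALSE)
}

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit: %s on %d record(s), residual SD %.4g\n",
              object@outcome, object@nUsed, object@sigma))
  tab <- coefTable(object)
  tab$estimate <- signif(tab$estimate, 4)
  tab$std_error <- signif(tab$std_error, 4)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  cat("coding:", object@codingNote, "\n")
})

#' Stratified hormone summaries
#'
#' Group means and SDs of FSH and LH, on the original U/L scale and on the
#' natural-log scale, stratified two ways: by sex and age group (split at
#' 30 years) and by sex and field location (supra- vs infradiaphragmatic).
#' A stratum with a single record reports SD 0 with \code{sd_defined =
#' FALSE}; an empty stratum keeps its row with count 0 and NA statistics.
#'
#' @param cohort a validated hormone cohort data.frame.
#' @return A data.frame with columns \code{stratification}, \code{hormone},
#'   \code{sex}, \code{stratum}, \code{n}, \code{mean_raw}, \code{sd_raw},
#'   \code{mean_log}, \code{sd_log}, \code{sd_defined}.
#' @export
hormoneGroupSummary <- function(cohort) {
  cohort <- logTransformHormones(cohort)
  strata <- list(
    age_group = ifelse(cohort$age_years < 30, "age<30", "age>=30"),
    rt_field = cohort$rt_field)
  rows <- list()
  for (strat in names(strata)) {
    levs <- if (strat == "age_group") c("age<30", "age>=30") else
      c("SDRT", "IDRT")
    for (hormone in c("fsh", "lh")) {
      raw <- cohort[[paste0(hormone, "_u_per_l")]]
      lg <- cohort[[paste0("log_", hormone)]]
      for (sx in .sexLevels) {
        for (lv in levs) {
          sel <- cohort$sex == sx & strata[[strat]] == lv
          n <- sum(sel)
          rows[[length(rows) + 1L]] <- data.frame(
            stratification = strat, hormone = toupper(hormone), sex = sx,
            stratum = lv, n = n,
            mean_raw = if (n) mean(raw[sel]) else NA_real_,
            sd_raw = if (n) .sdOrZero(raw[sel]) else NA_real_,
            mean_log = if (n) mean(lg[sel]) else NA_real_,
            sd_log = if (n) .sdOrZero(lg[sel]) else NA_real_,
            sd_defined = n >= 2L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model-predicted hormone surface
#'
#' Evaluates the fitted linear predictor over all sex x chemotherapy x
#' field-location combinations at the requested ages, on the log scale and
#' optionally back-transformed to U/L by exponentiation. Ages outside the
#' range seen at fit time trigger an extrapolation warning.
#'
#' @param fit a [RegressionFit-class] from [fitHormoneModel()].
#' @param ages ages in years.
#' @param backTransform also report \code{predicted_u_per_l = exp(pred)}.
#' @return A data.frame with one row per grid cell.
#' @export
predictHormoneGrid <- function(fit, ages, backTransform = TRUE) {
  stopifnot(is(fit, "RegressionFit"))
  if (is.na(fit@ageCenter)) {
    stop("fit carries no age standardization; use fitHormoneModel()",
         call. = FALSE)
  }
  if (any(ages < fit@ageRange[1L] - 1e-9 | ages > fit@ageRange[2L] + 1e-9)) {
    warning("some ages lie outside the fitted range [",
            round(fit@ageRange[1L], 1), ", ", round(fit@ageRange[2L], 1),
            "]; predictions are extrapolations", call. = FALSE)
  }
  grid <- expand.grid(age_years = ages, sex = .sexLevels,
                      chemo = .chemoLevels, rt_field = .rtLevels,
                      stringsAsFactors = FALSE)
  ageZ <- (grid$age_years - fit@ageCenter) / fit@ageScale
  sex <- if (fit@sexCoding == "symmetric") {
    ifelse(grid$sex == "female", 0.5, -0.5)
  } else {
    ifelse(grid$sex == "female", 1, 0)
  }
  X <- cbind(1, ageZ, sex, ageZ * sex,
             as.numeric(grid$chemo == "ABVD"),
             as.numeric(grid$rt_field == "IDRT"))
  grid$predicted_log <- as.numeric(X %*% fit@coefficients)
  if (backTransform) grid$predicted_u_per_l <- exp(grid$predicted_log)
  grid
}
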