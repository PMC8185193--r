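.roundDf <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, logical(1L))
  keep <- names(df) %in% c("age_years", "n", "n_excluded", "n_nonzero",
                           "n_positive")
  for (j in which(num & !keep)) {
    df[[j]] <- ifelse(df[[j]] != 0 & abs(df[[j]]) < 10^-digits / 2,
                      signif(df[[j]], 3), round(df[[j]], digits))
  }
  df
}

#' Run the full paired-plan and hormone analysis
#'
#' End-to-end pipeline: load (or simulate) the paired DVH cohort and the
#' hormone cohort, then produce the four standard outputs — the
#' organ-at-risk dose table with the surviving-NGF row, the
#' menopause-timing table over the theoretical age grid, the log-hormone
#' regression coefficient table for both outcomes, and the stratified
#' hormone group summaries — plus a JSON manifest (package version, seed,
#' configuration echo, exclusion counts) from which every number is
#' recomputable. Tables are written to \code{outDir} as CSV (values
#' rounded to 2 decimals with a decimal point; tiny non-zero p-values keep
#' 3 significant digits). On any validation error, partial outputs are
#' removed.
#'
#' @param outDir output directory, created if needed.
#' @param dvhFile optional DVH table CSV ([readDvhTable()] schema); when
#'   \code{NULL} a cohort is simulated from \code{dvhConfig}.
#' @param hormoneFile optional hormone cohort CSV; when \code{NULL} a
#'   cohort is simulated from \code{hormoneConfig}.
#' @param seed integer seed used for any simulated input.
#' @param dvhConfig,hormoneConfig simulator configurations; their
#'   \code{seed} entries are overridden by \code{seed}.
#' @param ages theoretical age grid.
#' @param binWidth DVH rebin width in Gy.
#' @param zeroTolDose,zeroTolTime sign-test tie tolerances for dose rows
#'   (Gy) and menopause rows (years).
#' @return Invisibly, a list with the four tables and the manifest.
#' @examples
#' \donttest{
#' out <- runFullAnalysis(tempfile("report"), seed = 1)
#' names(out)
#' }
#' @export
runFullAnalysis <- function(outDir,
                            dvhFile = NULL, hormoneFile = NULL,
                            seed = 1L,
                            dvhConfig = dvhSimConfig(),
                            hormoneConfig = hormoneSimConfig(),
                            ages = defaultAgeGrid(), binWidth = 0.1,
                            zeroTolDose = 1e-9, zeroTolTime = 0.005) {
  if (is.null(dvhFile)) {
    dvhConfig$seed <- as.integer(seed)
    cohort <- simulatePairedDvhCohort(dvhConfig)
    dvhSource <- list(kind = "simulated", config = unclass(dvhConfig))
  } else {
    cohort <- pairPatients(readDvhTable(dvhFile))
    dvhSource <- list(kind = "file", path = dvhFile)
  }
  if (!length(cohort)) stop("empty DVH cohort", call. = FALSE)
  if (is.null(hormoneFile)) {
    hormoneConfig$seed <- as.integer(seed)
    hormones <- simulateHormoneCohort(hormoneConfig)
    hormoneSource <- list(kind = "simulated",
                          config = unclass(hormoneConfig))
  } else {
    hormones <- readHormoneTable(hormoneFile)
    hormoneSource <- list(kind = "file", path = hormoneFile)
  }

  exclusions <- 0L
  oar <- withCallingHandlers(
    rbind(compareOarDoses(cohort, zeroTolerance = zeroTolDose)[
      , c("metric", "n", "n_excluded", "mean_ifrt", "sd_ifrt", "mean_isrt",
          "sd_isrt", "mean_diff", "sd_diff", "n_nonzero", "n_positive",
          "p_value")],
      survivingNgfSummary(cohort, width = binWidth,
                          zeroTolerance = zeroTolDose)[
        , c("metric", "n", "n_excluded", "mean_ifrt", "sd_ifrt",
            "mean_isrt", "sd_isrt", "mean_diff", "sd_diff", "n_nonzero",
            "n_positive", "p_value")]),
    warning = function(w) {
      if (grepl("excluded", conditionMessage(w))) {
        exclusions <<- exclusions + 1L
        invokeRestart("muffleWarning")
      }
    })
  meno <- compareMenopause(cohort, ages = ages, width = binWidth,
                           zeroTolerance = zeroTolTime)
  fits <- lapply(c(fsh = "fsh", lh = "lh"), function(o)
    fitHormoneModel(hormones, o))
  regTab <- data.frame(
    term = fits$fsh@terms,
    coef_fsh = fits$fsh@coefficients, p_fsh = fits$fsh@pValues,
    coef_lh = fits$lh@coefficients, p_lh = fits$lh@pValues,
    stringsAsFactors = FALSE)
  groups <- hormoneGroupSummary(hormones)

  manifest <- list(
    package = "MenoRad",
    version = as.character(utils::packageVersion("MenoRad")),
    seed = as.integer(seed),
    bin_width_gy = binWidth,
    age_grid = as.integer(ages),
    zero_tolerance = list(dose_gy = zeroTolDose, time_years = zeroTolTime),
    dvh_input = dvhSource,
    hormone_input = hormoneSource,
    n_patient_pairs = length(cohort),
    n_hormone_records = nrow(hormones),
    oar_row_exclusions = exclusions,
    regression_coding = fits$fsh@codingNote)

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  staging <- file.path(tempdir(), paste0("menorad-", Sys.getpid(), "-",
                                         as.integer(seed)))
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  wr <- function(df, name) {
    utils::write.csv(.roundDf(df), file.path(staging, name),
                     row.names = FALSE, quote = FALSE, na = "")
  }
  wr(oar, "oar_doses.csv")
  wr(meno[, c("age_years", "mean_ifrt", "sd_ifrt", "mean_isrt", "sd_isrt",
              "mean_diff", "sd_diff", "p_value")], "time_to_menopause.csv")
  wr(regTab, "hormone_regression.csv")
  wr(groups, "hormone_groups.csv")
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(outDir, f), overwrite = TRUE)
  }
  invisible(list(oar = oar, menopause = meno, regression = regTab,
                 groups = groups, manifest = manifest))
}
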