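test_that("hormone cohort validation enforces the schema", {
  coh <- handHormoneCohort()
  expect_silent(validateHormoneCohort(coh))
  bad <- coh; bad$fsh_u_per_l[2] <- 0
  expect_error(validateHormoneCohort(bad), "patient B")
  bad <- coh; bad$sex[1] <- "unknown"
  expect_error(validateHormoneCohort(bad), "sex")
  bad <- coh; bad$age_years[1] <- 45  # female over the cohort limit
  expect_error(validateHormoneCohort(bad), "cohort definition")
  expect_error(validateHormoneCohort(coh[, -2]), "missing")
})

test_that("log transform is the natural log of the levels", {
  coh <- handHormoneCohort()
  coh$fsh_u_per_l[1] <- 1
  coh$lh_u_per_l[1] <- exp(2)
  lt <- logTransformHormones(coh)
  expect_equal(lt$log_fsh[1], 0)
  expect_equal(lt$log_lh[1], 2, tolerance = 1e-12)
})

test_that("design matrix coding follows the documented contract", {
  coh <- handHormoneCohort()
  des <- buildHormoneDesign(coh)
  X <- des$X
  expect_identical(colnames(X), c("intercept", "age_z", "sex", "age_sex",
                                  "chemo_abvd", "rt_idrt"))
  expect_equal(mean(X[, "age_z"]), 0, tolerance = 1e-12)
  expect_equal(sd(X[, "age_z"]), 1, tolerance = 1e-12)
  expect_equal(X[, "sex"], c(0.5, 0.5, -0.5, -0.5), ignore_attr = TRUE)
  expect_equal(X[, "age_sex"], X[, "age_z"] * X[, "sex"],
               ignore_attr = TRUE)
  expect_equal(X[, "rt_idrt"], c(0, 1, 0, 0), ignore_attr = TRUE)
  expect_equal(X[, "chemo_abvd"], c(1, 0, 1, 0), ignore_attr = TRUE)

  # records differing only in rt_field differ only in that column
  two <- coh[c(1, 1), ]; two$rt_field <- c("SDRT", "IDRT")
  X2 <- suppressWarnings(buildHormoneDesign(two))$X
  expect_equal(X2[2, "rt_idrt"] - X2[1, "rt_idrt"], 1, ignore_attr = TRUE)
  expect_equal(X2[1, -6], X2[2, -6], ignore_attr = TRUE)

  # dummy sex coding changes sex and interaction columns as advertised
  desD <- buildHormoneDesign(coh, sexCoding = "dummy")
  expect_equal(desD$X[, "sex"], c(1, 1, 0, 0), ignore_attr = TRUE)
  expect_match(desD$codingNote, "female=1")
})

test_that("least-squares fit matches the normal-equations oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 40
    X <- cbind(intercept = 1, a = rnorm(n), b = runif(n), c = rnorm(n))
    y <- rnorm(n)
    w <- if (rep %% 2) NULL else runif(n, 0.5, 2)
    fit <- fitLinearModel(X, y, weights = w)
    ora <- oracleWls(X, y, if (is.null(w)) rep(1, n) else w)
    expect_equal(fit@coefficients, ora$beta, tolerance = 1e-10)
    expect_equal(fit@standardErrors, ora$se, tolerance = 1e-10)
  }
})

test_that("fit recovers noise-free coefficients and flags collinearity", {
  coh <- simulateHormoneCohort(hormoneSimConfig(n = 120, seed = 8))
  des <- buildHormoneDesign(coh)
  beta <- c(2, 0.5, -0.3, 0.1, -0.6, 0.4)
  coh$fsh_u_per_l <- exp(as.numeric(des$X %*% beta))
  fit <- fitHormoneModel(coh, "fsh")
  expect_equal(fit@coefficients, beta, tolerance = 1e-8,
               ignore_attr = TRUE)

  # intercept-only model returns the outcome mean
  y <- rnorm(30)
  fit0 <- fitLinearModel(matrix(1, 30, 1,
                                dimnames = list(NULL, "intercept")), y)
  expect_equal(fit0@coefficients, mean(y), tolerance = 1e-12)

  X <- cbind(intercept = 1, a = 1:30, dup = 2 * (1:30))
  expect_error(fitLinearModel(X, rnorm(30)), "dup")
  expect_error(fitLinearModel(X[1:2, ], rnorm(2)), "more records")
})

test_that("coefficients are equivariant under sex recoding", {
  coh <- simulateHormoneCohort(hormoneSimConfig(n = 300, seed = 9))
  fitS <- fitHormoneModel(coh, "fsh", sexCoding = "symmetric")
  fitD <- fitHormoneModel(coh, "fsh", sexCoding = "dummy")
  bS <- fitS@coefficients; names(bS) <- fitS@terms
  bD <- fitD@coefficients; names(bD) <- fitD@terms
  # dummy = symmetric shifted by half a unit: intercept/age pick up half
  # the sex/interaction effect; sex and interaction slopes are unchanged
  expect_equal(bD[["sex"]], bS[["sex"]], tolerance = 1e-9)
  expect_equal(bD[["age_sex"]], bS[["age_sex"]], tolerance = 1e-9)
  expect_equal(bD[["intercept"]], bS[["intercept"]] - 0.5 * bS[["sex"]],
               tolerance = 1e-9)
  expect_equal(bD[["age_z"]], bS[["age_z"]] - 0.5 * bS[["age_sex"]],
               tolerance = 1e-9)
  # fitted values identical under either coding
  desS <- buildHormoneDesign(coh, sexCoding = "symmetric")
  desD <- buildHormoneDesign(coh, sexCoding = "dummy")
  expect_equal(as.numeric(desS$X %*% fitS@coefficients),
               as.numeric(desD$X %*% fitD@coefficients), tolerance = 1e-9)
})

test_that("group summary matches hand-computed strata", {
  coh <- handHormoneCohort()
  tab <- hormoneGroupSummary(coh)
  row <- tab[tab$stratification == "age_group" & tab$hormone == "FSH" &
               tab$sex == "female" & tab$stratum == "age<30", ]
  expect_equal(row$n, 1)
  expect_equal(row$mean_raw, 4)
  expect_equal(row$sd_raw, 0)
  expect_false(row$sd_defined)

  rowM <- tab[tab$stratification == "rt_field" & tab$hormone == "LH" &
                tab$sex == "male" & tab$stratum == "SDRT", ]
  expect_equal(rowM$n, 2)
  expect_equal(rowM$mean_raw, mean(c(3, 27)))
  expect_equal(rowM$mean_log, mean(log(c(3, 27))), tolerance = 1e-12)

  # empty stratum keeps its row with count 0
  rowE <- tab[tab$stratification == "rt_field" & tab$hormone == "FSH" &
                tab$sex == "male" & tab$stratum == "IDRT", ]
  expect_equal(rowE$n, 0)
  expect_true(is.na(rowE$mean_raw))
})

test_that("prediction grid reflects the model algebra", {
  coh <- simulateHormoneCohort(hormoneSimConfig(n = 400, seed = 10))
  fit <- fitHormoneModel(coh, "fsh")
  b <- fit@coefficients; names(b) <- fit@terms
  grid <- predictHormoneGrid(fit, ages = c(25, 35))

  at <- function(sex, chemo, rt, age) {
    grid$predicted_log[grid$sex == sex & grid$chemo == chemo &
                         grid$rt_field == rt & grid$age_years == age]
  }
  expect_equal(at("female", "ABVD", "IDRT", 25) -
                 at("female", "ABVD", "SDRT", 25),
               b[["rt_idrt"]], tolerance = 1e-9)
  expect_equal(at("male", "ABVD", "SDRT", 35) -
                 at("male", "2+2", "SDRT", 35),
               b[["chemo_abvd"]], tolerance = 1e-9)
  # sex gap changes with age at the interaction slope (per z-unit)
  gap25 <- at("female", "ABVD", "SDRT", 25) - at("male", "ABVD", "SDRT", 25)
  gap35 <- at("female", "ABVD", "SDRT", 35) - at("male", "ABVD", "SDRT", 35)
  dz <- 10 / fit@ageScale
  expect_equal(gap35 - gap25, b[["age_sex"]] * dz, tolerance = 1e-9)
  expect_equal(exp(grid$predicted_log), grid$predicted_u_per_l,
               tolerance = 1e-12)
  expect_warning(predictHormoneGrid(fit, ages = 70), "extrapolat")
})
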