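test_that("sign test handles unanimity, ties and single pairs", {
  allPos <- exactSignTest(rep(1, 13))
  expect_equal(pValue(allPos), 2 * 0.5^13, tolerance = 1e-12)
  expect_equal(allPos@nNonzero, 13L)
  expect_equal(allPos@nPositive, 13L)

  expect_equal(pValue(exactSignTest(rep(2, 4))), 0.125, tolerance = 1e-12)
  expect_equal(pValue(exactSignTest(c(0, 0, 0))), 1)
  expect_equal(pValue(exactSignTest(5)), 1)  # one pair: doubled tail capped
  expect_equal(pValue(exactSignTest(c(1, -1))), 1)

  # tie tolerance: values equal after rounding count as ties
  expect_equal(exactSignTest(c(0.004, 1, 1), zeroTolerance = 0.005)@nNonzero,
               2L)
  expect_error(exactSignTest(numeric(0)), "at least one")
})

test_that("sign test agrees with exhaustive enumeration and binom.test", {
  for (m in 1:12) {
    for (k in 0:m) {
      d <- c(rep(1, k), rep(-1, m - k))
      p <- pValue(exactSignTest(d))
      expect_equal(p, oracleSignP(m, k), tolerance = 1e-12,
                   label = sprintf("m=%d k=%d", m, k))
      expect_equal(p, binom.test(k, m, 0.5)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("sign test p is invariant under a global sign flip", {
  set.seed(5)
  for (i in 1:20) {
    d <- rnorm(sample(3:15, 1))
    expect_equal(pValue(exactSignTest(d)), pValue(exactSignTest(-d)),
                 tolerance = 1e-12)
  }
})

test_that("OAR dose comparison summarizes pairs and excludes gaps", {
  mkPair <- function(id, dI, dS, extraOrgan = TRUE) {
    org <- function(z, nm) DifferentialDVH(nm, c(z, z + 0.1), 1)
    oI <- list(ovaries = org(dI, "ovaries"))
    oS <- list(ovaries = org(dS, "ovaries"))
    if (extraOrgan) {
      oI$uterus <- org(dI + 1, "uterus")
      oS$uterus <- org(dS + 1, "uterus")
    }
    PatientPair(PlanRecord(id, "IFRT", oI), PlanRecord(id, "ISRT", oS))
  }
  cohort <- list(mkPair("a", 20, 10), mkPair("b", 15, 5),
                 mkPair("c", 12, 8, extraOrgan = FALSE))
  metrics <- c(ovaries = "mean", uterus = "mean")
  expect_warning(tab <- compareOarDoses(cohort, metrics), "uterus")
  ov <- tab[tab$metric == "ovaries", ]
  expect_equal(ov$n, 3)
  expect_equal(ov$mean_ifrt, mean(c(20, 15, 12)) + 0.05, tolerance = 1e-9)
  expect_equal(ov$mean_diff, mean(c(10, 10, 4)), tolerance = 1e-9)
  expect_equal(ov$p_value, 2 * 0.5^3)
  ut <- tab[tab$metric == "uterus", ]
  expect_equal(ut$n, 2)
  expect_equal(ut$n_excluded, 1)

  # identical plans: all ties, p = 1, SD 0
  same <- list(mkPair("x", 10, 10), mkPair("y", 12, 12))
  tabSame <- compareOarDoses(same, c(ovaries = "mean"))
  expect_equal(tabSame$p_value, 1)
  expect_equal(tabSame$mean_diff, 0)

  # single-patient cohort: zero SDs, doubled-capped p = 1
  solo <- compareOarDoses(list(mkPair("z", 9, 4)), c(ovaries = "mean"))
  expect_equal(solo$sd_ifrt, 0)
  expect_equal(solo$p_value, 1)

  expect_error(compareOarDoses(list()), "empty")
})

test_that("max-dose metric is used where configured", {
  org <- function(nm, edges, v) DifferentialDVH(nm, edges, v)
  pI <- PlanRecord("p", "IFRT", list(
    ovaries = org("ovaries", c(0, 0.1), 1),
    spinal_cord = org("spinal_cord", c(0, 10, 18, 19), c(0.8, 0.2, 0))))
  pS <- PlanRecord("p", "ISRT", list(
    ovaries = org("ovaries", c(0, 0.1), 1),
    spinal_cord = org("spinal_cord", c(0, 10, 15), c(0.9, 0.1))))
  tab <- compareOarDoses(list(PatientPair(pI, pS)),
                         c(spinal_cord = "max"))
  expect_equal(tab$mean_ifrt, 18)  # trailing empty bin ignored
  expect_equal(tab$mean_isrt, 15)
})

test_that("surviving-NGF summary matches hand-computed two-patient case", {
  cohort <- list(uniformDosePair("a", 10, 5),
                 uniformDosePair("b", 20, 2))
  s <- survivingNgfSummary(cohort)
  gI <- wallaceSurvival(c(10.05, 20.05))
  gS <- wallaceSurvival(c(5.05, 2.05))
  expect_equal(s$mean_ifrt, mean(gI), tolerance = 1e-9)
  expect_equal(s$mean_isrt, mean(gS), tolerance = 1e-9)
  expect_equal(s$mean_diff, mean(gS - gI), tolerance = 1e-9)
  expect_equal(s$n_positive, 2L)
  # means bracket the per-patient values
  expect_true(min(gI) <= s$mean_ifrt && s$mean_ifrt <= max(gI))

  # identical patients: SD 0
  twin <- list(uniformDosePair("a", 10, 5), uniformDosePair("b", 10, 5))
  expect_equal(survivingNgfSummary(twin)$sd_ifrt, 0)
})

test_that("menopause comparison reproduces deterministic columns", {
  # equal arms at 0 Gy: g = 100 both, times = 50.4 - age, all ties
  cohort <- list(uniformDosePair("a", 0, 0), uniformDosePair("b", 0, 0))
  tab <- compareMenopause(cohort)
  g0 <- wallaceSurvival(0.05)
  t0 <- timeToMenopause(defaultAgeGrid(), g0)$time_to_menopause
  expect_equal(tab$mean_ifrt, t0, tolerance = 1e-9)
  expect_equal(tab$sd_ifrt, rep(0, 16))
  expect_true(all(tab$p_value == 1))
  expect_true(all(abs(tab$mean_diff) < 1e-9))

  # strict ISRT advantage: unanimous positive gains at young ages
  adv <- list(uniformDosePair("a", 15, 5), uniformDosePair("b", 18, 7),
              uniformDosePair("c", 12, 4))
  tab2 <- compareMenopause(adv)
  expect_equal(tab2$p_value[1], 2 * 0.5^3, tolerance = 1e-12)
  expect_gt(tab2$mean_diff[1], 0)
  # gains shrink with age; saturation drives p to 1
  expect_true(all(diff(tab2$mean_diff) < 1e-9))

  # deep floor saturation at high age for heavily dosed patients
  deep <- list(uniformDosePair("a", 29, 25), uniformDosePair("b", 28, 26))
  tab3 <- compareMenopause(deep)
  last <- nrow(tab3)
  expect_equal(tab3$mean_ifrt[last], 0)
  expect_equal(tab3$mean_diff[last], 0)
  expect_equal(tab3$p_value[last], 1)
})
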