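test_that("cumulative/differential conversions are mutual inverses", {
  c1 <- CumulativeDVH("ovaries", c(0, 5, 10), c(1, 1, 0))
  d1 <- toDifferential(c1)
  expect_equal(binVolume(d1), c(0, 1))

  set.seed(42)
  for (i in 1:25) {
    d <- randomDvh()
    back <- toDifferential(toCumulative(d))
    expect_equal(binEdges(back), binEdges(d), tolerance = 1e-12)
    expect_equal(binVolume(back), binVolume(d), tolerance = 1e-12)
    cum <- toCumulative(d)
    expect_equal(volumeAtOrAbove(toCumulative(toDifferential(cum))),
                 volumeAtOrAbove(cum), tolerance = 1e-12)
  }
})

test_that("rebin apportions volume by overlap and conserves it", {
  d <- DifferentialDVH("ovaries", c(0, 0.2), 1)
  r <- rebin(d, 0.1)
  expect_equal(binVolume(r), c(0.5, 0.5), tolerance = 1e-12)

  # off-grid bin straddling an output edge: hand-computed 50/50 split
  d2 <- DifferentialDVH("ovaries", c(0.05, 0.15), 1)
  expect_equal(binVolume(rebin(d2, 0.1)), c(0.5, 0.5), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    d <- randomDvh()
    for (w in c(0.1, 0.37, 1.5)) {
      r <- rebin(d, w)
      expect_equal(sum(binVolume(r)), sum(binVolume(d)), tolerance = 1e-9)
      expect_lte(abs(meanDose(r) - meanDose(d)), w / 2 + 1e-9)
      expect_gte(binEdges(r)[length(binEdges(r))],
                 binEdges(d)[length(binEdges(d))] - 1e-9)
    }
  }
  expect_error(rebin(d, 0), "positive")
  expect_error(rebin(d, -1), "positive")
})

test_that("combineOrgans mixes by absolute volume, defaults to equal", {
  grid <- seq(0, 11, by = 0.1)
  mk <- function(lowFrac, cc = NA_real_) {
    v <- numeric(length(grid) - 1L)
    v[1] <- lowFrac          # [0, 0.1)
    v[101] <- 1 - lowFrac    # [10.0, 10.1)
    DifferentialDVH("ovary", grid, v, totalVolumeCc = cc)
  }
  left <- mk(0, cc = 2)   # all at 10 Gy
  right <- mk(1, cc = 2)  # all at 0 Gy
  comb <- combineOrgans(left, right)
  expect_equal(binVolume(comb)[1], 0.5, tolerance = 1e-12)
  expect_equal(binVolume(comb)[101], 0.5, tolerance = 1e-12)
  expect_equal(totalVolumeCc(comb), 4)

  # 3 cc at 10 Gy vs 1 cc at 0 Gy: 75/25 mixture
  comb2 <- combineOrgans(mk(0, cc = 3), mk(1, cc = 1))
  expect_equal(binVolume(comb2)[101], 0.75, tolerance = 1e-12)
  expect_equal(binVolume(comb2)[1], 0.25, tolerance = 1e-12)

  # idempotent on identical inputs, commutative
  same <- combineOrgans(left, left)
  expect_equal(binVolume(same), binVolume(left), tolerance = 1e-12)
  ab <- combineOrgans(mk(0, 3), mk(1, 1))
  ba <- combineOrgans(mk(1, 1), mk(0, 3))
  expect_equal(binVolume(ab), binVolume(ba), tolerance = 1e-12)

  # no absolute volumes: equal weighting with a warning
  expect_warning(combineOrgans(mk(0), mk(1)), "equally")

  # mismatched grids are refused
  other <- DifferentialDVH("ovary", c(0, 5, 10), c(0.5, 0.5))
  expect_error(combineOrgans(left, other), "rebin")
})

test_that("mean and max dose summaries behave at edges", {
  d <- DifferentialDVH("ovaries", c(9.95, 10.05), 1)
  expect_equal(meanDose(d), 10, tolerance = 1e-12)

  d2 <- DifferentialDVH("ovaries", c(0, 0.1, 20, 20.1), c(0.5, 0, 0.5))
  expect_equal(meanDose(d2), (0.05 + 20.05) / 2, tolerance = 1e-12)

  d3 <- DifferentialDVH("ovaries", c(5, 10), 1)
  expect_equal(maxDose(d3), 10)
  # trailing zero-volume bins are ignored
  d4 <- DifferentialDVH("ovaries", c(5, 10, 20, 30), c(1, 0, 0))
  expect_equal(maxDose(d4), 10)
  # all volume in the first bin
  d5 <- DifferentialDVH("ovaries", c(0, 0.1, 1), c(1, 0))
  expect_equal(maxDose(d5), 0.1)
})

test_that("ovaryDvh merges left/right when no combined entry exists", {
  grid <- seq(0, 10.1, by = 0.1)
  v1 <- numeric(length(grid) - 1); v1[1] <- 1
  v2 <- numeric(length(grid) - 1); v2[101] <- 1
  plan <- PlanRecord("p", "IFRT", list(
    ovary_left = DifferentialDVH("ovary_left", grid, v1, totalVolumeCc = 2),
    ovary_right = DifferentialDVH("ovary_right", grid, v2,
                                  totalVolumeCc = 2)))
  comb <- ovaryDvh(plan)
  expect_equal(sum(binVolume(comb)), 1, tolerance = 1e-12)
  expect_equal(meanDose(comb), (0.05 + 10.05) / 2, tolerance = 1e-9)
  noOvary <- PlanRecord("p", "IFRT",
                        list(uterus = DifferentialDVH("uterus", c(0, 1), 1)))
  expect_error(ovaryDvh(noOvary), "ovary")
})
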