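arr3 <- function(values) array(values, c(length(values), 1, 1))
mask3 <- function(n, on = seq_len(n)) {
  m <- array(FALSE, c(n, 1, 1)); m[on, 1, 1] <- TRUE; m
}

test_that("conformity index is the covered target fraction", {
  d <- arr3(c(70, 71, 72, 70, 70, 70, 70, 70, 60, 50))
  m <- mask3(10)
  expect_equal(conformity_index(d, m, 70), 0.8)
  expect_equal(conformity_index(arr3(rep(54, 6)), mask3(6), 54), 1)
  expect_equal(conformity_index(arr3(rep(0, 6)), mask3(6), 54), 0)
  expect_error(conformity_index(d, mask3(10, integer()), 70), "empty")
  # monotone under any voxelwise dose increase
  expect_gte(conformity_index(d + 1, m, 70), conformity_index(d, m, 70))
})

test_that("homogeneity index follows the sort-index convention", {
  u <- arr3(rep(66, 9))
  expect_equal(homogeneity_index(u, mask3(9), 66), 0)
  d <- arr3(seq(60, 80, by = 2))  # 11 voxels
  # oracle: D_5% = ceil(0.05*11)=1st hottest = 80; D_95% = ceil(10.45)=11th = 60
  expect_equal(homogeneity_index(d, mask3(11), 70), (80 - 60) / 70)
  # scale invariance: doubling dose and prescription together
  expect_equal(homogeneity_index(2 * d, mask3(11), 140),
               homogeneity_index(d, mask3(11), 70))
  expect_error(homogeneity_index(d, mask3(11), 0), "> 0")
})

test_that("DVH curves equal brute-force thresholding and are monotone", {
  set.seed(9)
  dose <- array(runif(5^3, 0, 60), c(5, 5, 5))
  mask <- array(runif(5^3) < 0.5, c(5, 5, 5))
  curve <- dvh_curve(dose, mask, bin_gy = 0.5)
  d <- dose[mask]
  oracle <- vapply(curve$dose, function(t) sum(d >= t) / length(d), 0)
  expect_equal(curve$volume, oracle)
  expect_equal(curve$volume[1], 1)
  expect_equal(curve$volume[nrow(curve)], 0)
  expect_true(all(diff(curve$volume) <= 0))
})

test_that("plan summaries match brute-force recomputation on a small grid", {
  case <- small_case()
  set.seed(21)
  dose <- array(0, case$vol$shape)
  dose[case$ss$masks[["Body"]]] <- runif(sum(case$ss$masks[["Body"]]), 0, 75)
  met <- summarize_plan(dose, case$ss, mu = 123)
  get <- function(st, metric) met$value[met$structure == st & met$metric == metric]
  for (nm in c("PTV-GTV", "PTV-LN(R)")) {
    d <- sort(dose[case$ss$masks[[nm]]], decreasing = TRUE)
    n <- length(d)
    px <- case$ss$prescriptions[[nm]]
    expect_equal(get(nm, "D_2%"), d[max(1, ceiling(0.02 * n))])
    expect_equal(get(nm, "D_98%"), d[ceiling(0.98 * n)])
    expect_equal(get(nm, "CI"), mean(d >= px))
    expect_equal(get(nm, "HI"),
                 (d[ceiling(0.05 * n)] - d[ceiling(0.95 * n)]) / px)
    expect_true(get(nm, "CI") >= 0 && get(nm, "CI") <= 1)
  }
  for (nm in c("Brainstem", "Left parotid gland")) {
    d <- dose[case$ss$masks[[nm]]]
    expect_equal(get(nm, "D_max"), max(d))
    expect_equal(get(nm, "D_mean"), mean(d))
    expect_equal(get(nm, "D_median"),
                 sort(d, decreasing = TRUE)[ceiling(length(d) / 2)])
    expect_gte(get(nm, "D_max"), get(nm, "D_mean"))
  }
  expect_equal(get("Plan", "MU"), 123)
  # missing structures are explicit absences, not zeros
  ss2 <- case$ss
  ss2$masks[["Chiasm"]] <- NULL
  met2 <- summarize_plan(dose, ss2)
  expect_true(all(is.na(met2$value[met2$structure == "Chiasm"])))
})

test_that("paired plan comparison flags systematic differences", {
  case <- small_case()
  set.seed(33)
  mk <- function(shift = 0) {
    dose <- array(0, case$vol$shape)
    dose[case$ss$masks[["Body"]]] <-
      runif(sum(case$ss$masks[["Body"]]), 30, 60) + shift
    summarize_plan(dose, case$ss, mu = 100)
  }
  arm_a <- lapply(1:10, function(i) mk())
  arm_b_same <- arm_a
  cmp0 <- compare_plans(arm_a, arm_b_same)
  expect_true(all(cmp0$mean_a == cmp0$mean_b))
  expect_false(any(cmp0$significant))
  # +1 Gy shift across all 10 pairs is significant on dose metrics
  arm_b <- lapply(1:10, function(i) mk(shift = 1))
  cmp <- compare_plans(arm_a, arm_b)
  dmean <- cmp[cmp$structure == "Body" & cmp$metric == "D_mean", ]
  expect_true(dmean$significant)
  expect_lt(dmean$p_value, 0.05)
  # arithmetic oracle for the arm means
  vals <- vapply(arm_a, function(m)
    m$value[m$structure == "Body" & m$metric == "D_mean"], 0)
  expect_equal(dmean$mean_a, mean(vals))
  # symmetry under arm exchange
  cmp_sw <- compare_plans(arm_b, arm_a)
  expect_equal(cmp_sw$p_value, cmp$p_value)
  expect_equal(cmp_sw$mean_a, cmp$mean_b)
  expect_error(compare_plans(arm_a, arm_a[1:3]), "paired")
})
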