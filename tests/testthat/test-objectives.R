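dose_from <- function(values) {
  n <- length(values)
  d <- array(values, c(n, 1, 1))
  list(dose = d, mask = array(TRUE, c(n, 1, 1)))
}

test_that("dose_at_volume follows the sort-and-index convention", {
  x <- dose_from(1:10)
  expect_equal(dose_at_volume(x$dose, x$mask, 20), 9)   # 2nd hottest
  expect_equal(dose_at_volume(x$dose, x$mask, 0), 10)
  expect_equal(dose_at_volume(x$dose, x$mask, 100), 1)
  u <- dose_from(rep(54, 7))
  for (xv in c(0, 13, 50, 99, 100))
    expect_equal(dose_at_volume(u$dose, u$mask, xv), 54)
  y <- dose_from(c(3, 7, 5))
  expect_equal(dose_at_volume(y$dose, y$mask, 0), 7)
  expect_error(dose_at_volume(x$dose, array(FALSE, c(10, 1, 1)), 50), "empty")
  expect_error(dose_at_volume(x$dose, x$mask, 101), "100")
})

test_that("dose_at_volume is non-increasing in the volume percentage", {
  set.seed(11)
  x <- dose_from(runif(37, 0, 80))
  xs <- seq(0, 100, by = 5)
  vals <- vapply(xs, function(v) dose_at_volume(x$dose, x$mask, v), 0)
  expect_true(all(diff(vals) <= 0))
})

test_that("gEUD matches its closed forms and limits", {
  x <- dose_from(c(2, 4, 6))
  expect_equal(geud(x$dose, x$mask, 1), 4)                       # mean
  y <- dose_from(c(3, 4))
  expect_equal(geud(y$dose, y$mask, 2), sqrt(12.5))              # power mean
  z <- dose_from(c(10, 50))
  expect_equal(geud(z$dose, z$mask, 200), 50, tolerance = 0.01)  # ~max
  expect_error(geud(x$dose, x$mask, 0), "nonzero")
  # mean <= gEUD <= max for a >= 1, monotone in every voxel dose
  set.seed(2)
  d <- runif(20, 0, 70)
  w <- dose_from(d)
  for (a in c(1, 3, 10, 20)) {
    g <- geud(w$dose, w$mask, a)
    expect_gte(g, mean(d) - 1e-12)
    expect_lte(g, max(d) + 1e-12)
    d2 <- d; d2[5] <- d2[5] + 1
    expect_gt(geud(dose_from(d2)$dose, w$mask, a), g)
  }
})

test_that("the derived objective set reproduces the planning template", {
  ctx <- small_ctx()
  obj <- ctx$objectives
  ref <- ctx$step1$dose
  ss <- ctx$ss_aug
  expect_s3_class(obj, "objective_set")
  expect_equal(nrow(obj), 27L)
  expect_true(all(obj$priority %in% c(50, 70, 150)))
  expect_true(all(obj$objective_dose >= 0))
  expect_true(all(is.na(obj$a) == (obj$kind != "max_gEUD")))

  row <- function(st, kind, xv = NULL) {
    sel <- obj$structure == st & obj$kind == kind
    if (!is.null(xv)) sel <- sel & obj$volume_percent == xv
    expect_equal(sum(sel), 1L)
    obj[sel, ]
  }
  # target rows: fixed numbers and prescription increments
  expect_equal(row("PTV-GTV", "max_dose_at_volume")$objective_dose, 73.5)
  expect_equal(row("PTV-GTV", "min_dose_at_volume")$objective_dose, 71.5)
  expect_equal(row("PTV-1-Crop", "max_dose_at_volume")$objective_dose, 60 + 3)
  expect_equal(row("PTV-1", "min_dose_at_volume")$objective_dose, 60)
  expect_equal(row("PTV-2-Crop", "max_dose_at_volume")$objective_dose, 54 + 6)
  expect_equal(row("PTV-2", "min_dose_at_volume")$objective_dose, 54)
  for (ln in c("PTV-LN(L)", "PTV-LN(R)")) {
    expect_equal(row(ln, "max_dose_at_volume")$objective_dose, 66 + 3)
    expect_equal(row(ln, "min_dose_at_volume")$objective_dose, 66 + 1.5)
    expect_equal(row(ln, "max_dose_at_volume")$priority, 70)
    expect_equal(row(ln, "min_dose_at_volume")$priority, 150)
  }
  # serial / parallel organ gEUD rows: a-parameter and tightening factor
  geud_spec <- list(
    list("Brainstem", 20, 0.85), list("Brainstem 3 mm", 20, 0.85),
    list("Spinal cord", 20, 0.85), list("Spinal cord 3 mm", 20, 0.85),
    list("Left normal parotid", 3, 0.75), list("Right normal parotid", 3, 0.75),
    list("Left optic nerve", 1, 1), list("Right optic nerve", 1, 1),
    list("Chiasm", 1, 1))
  for (gs in geud_spec) {
    r <- row(gs[[1]], "max_gEUD")
    expect_equal(r$a, gs[[2]])
    expect_equal(r$priority, 50)
    expect_equal(r$objective_dose,
                 gs[[3]] * geud(ref, ss$masks[[gs[[1]]]], gs[[2]]))
  }
  # dose-spill rows: 0.95 x the reference statistic on the same structure
  for (sp in list(c("Ring 2 cm", 15), c("40 Gy-PTV2", 10))) {
    nm <- sp[1]; a <- as.numeric(sp[2])
    for (xv in c(1, 20, 50))
      expect_equal(row(nm, "max_dose_at_volume", xv)$objective_dose,
                   0.95 * dose_at_volume(ref, ss$masks[[nm]], xv))
    r <- row(nm, "max_gEUD")
    expect_equal(r$a, a)
    expect_equal(r$objective_dose, 0.95 * geud(ref, ss$masks[[nm]], a))
    expect_true(all(obj$priority[obj$structure == nm] == 50))
  }
})

test_that("reference-derived objective doses scale with the reference dose", {
  ctx <- small_ctx()
  obj1 <- ctx$objectives
  obj2 <- derive_objectives(ctx$ss_aug, 1.3 * ctx$step1$dose)
  fixed <- obj1$structure %in% c("PTV-GTV", "PTV-1", "PTV-2", "PTV-1-Crop",
                                 "PTV-2-Crop", "PTV-LN(L)", "PTV-LN(R)")
  expect_equal(obj2$objective_dose[fixed], obj1$objective_dose[fixed])
  expect_equal(obj2$objective_dose[!fixed], 1.3 * obj1$objective_dose[!fixed])
})

test_that("objectives on missing structures are skipped with a warning", {
  ctx <- small_ctx()
  ss <- ctx$ss_aug
  ss$masks[["Chiasm"]] <- NULL
  expect_warning(obj <- derive_objectives(ss, ctx$step1$dose), "Chiasm")
  expect_equal(nrow(obj), 26L)
  expect_false("Chiasm" %in% obj$structure)
})
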