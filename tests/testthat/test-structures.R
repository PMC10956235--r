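# brute-force Euclidean expansion: all-pairs distance between voxel centres
expand_oracle <- function(mask, distance_mm, spacing) {
  sh <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, sh)
  all_idx <- which(array(TRUE, sh), arr.ind = TRUE)
  for (v in seq_len(nrow(all_idx))) {
    dv <- sweep(idx, 2, all_idx[v, ]) %*% diag(spacing)
    if (any(rowSums(dv^2) <= distance_mm^2)) out[v] <- TRUE
  }
  out
}

test_that("3 mm expansion of a single voxel on a 1 mm grid gives 123 voxels", {
  m <- array(FALSE, c(11, 11, 11)); m[6, 6, 6] <- TRUE
  ex <- expand_mask(m, 3, c(1, 1, 1))
  # lattice-count oracle: integer offsets with squared distance <= 9
  off <- expand.grid(-3:3, -3:3, -3:3)
  expect_equal(sum(rowSums(off^2) <= 9), 123L)
  expect_equal(sum(ex), 123L)
})

test_that("expansion identities: zero margin, empty mask, error on negative", {
  m <- array(FALSE, c(5, 5, 5)); m[2:3, 2:4, 3] <- TRUE
  expect_identical(expand_mask(m, 0, c(2, 2, 2)), m)
  empty <- array(FALSE, c(5, 5, 5))
  expect_identical(expand_mask(empty, 10, c(2, 2, 2)), empty)
  expect_error(expand_mask(m, -1, c(2, 2, 2)), ">= 0")
})

test_that("expansion is extensive, monotone, and matches the brute-force oracle", {
  sh <- c(9, 8, 7); sp <- c(2, 3, 2.5)  # anisotropic
  set.seed(42)
  for (rep in 1:3) {
    m1 <- array(runif(prod(sh)) < 0.05, sh)
    m2 <- m1 | array(runif(prod(sh)) < 0.05, sh)
    d <- c(3, 5, 6.5)[rep]
    e1 <- expand_mask(m1, d, sp)
    e2 <- expand_mask(m2, d, sp)
    expect_true(all(m1 <= e1))            # extensive
    expect_true(all(e1 <= e2))            # monotone
    expect_identical(e1, expand_oracle(m1, d, sp))
  }
})

test_that("mask subtraction is exact set difference", {
  a <- array(FALSE, c(4, 4, 4)); a[1, 1, 1] <- TRUE; a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[2, 2, 2] <- TRUE
  d <- subtract_mask(a, b)
  expect_true(d[1, 1, 1] && !d[2, 2, 2] && sum(d) == 1)
  expect_equal(sum(subtract_mask(a, a)), 0)
  expect_identical(subtract_mask(a, array(FALSE, c(4, 4, 4))), a)
  expect_error(subtract_mask(a, array(FALSE, c(4, 4, 5))), "differ")
})

test_that("auxiliary structures follow their defining identities", {
  ctx <- small_ctx()
  ss <- ctx$ss_aug
  sp <- ctx$case$vol$spacing
  m <- ss$masks
  # crop identities
  expect_identical(m[["PTV-1-Crop"]],
                   (m[["PTV-1"]] & !expand_mask(m[["PTV-GTV"]], 3, sp)) & m[["Body"]])
  expect_equal(sum(m[["PTV-1-Crop"]] & expand_mask(m[["PTV-GTV"]], 3, sp)), 0)
  # the ring never touches the 2 mm expansion of PTV-2
  expect_equal(sum(m[["Ring 2 cm"]] & expand_mask(m[["PTV-2"]], 2, sp)), 0)
  expect_true(any(m[["Ring 2 cm"]]))
  # normal parotid excludes every PTV
  ptvs <- Reduce(`|`, ctx$case$ss$masks[ptv_names()])
  expect_equal(sum(m[["Left normal parotid"]] & ptvs), 0)
  # all auxiliaries stay inside the body
  for (nm in c("PTV-1-Crop", "PTV-2-Crop", "Ring 2 cm", "40 Gy-PTV2",
               "Brainstem 3 mm", "Spinal cord 3 mm"))
    expect_true(all(m[[nm]] <= m[["Body"]]))
})

test_that("degenerate auxiliary inputs give empty structures or clear errors", {
  case <- small_case()
  vol <- case$vol
  # PTV-1 exactly the 3 mm expansion of PTV-GTV -> empty crop
  ss <- case$ss
  ss$masks[["PTV-1"]] <- expand_mask(ss$masks[["PTV-GTV"]], 3, vol$spacing) &
    ss$masks[["Body"]]
  ss$masks[["PTV-2"]] <- ss$masks[["PTV-2"]] | ss$masks[["PTV-1"]]
  cold_dose <- array(0, vol$shape)
  aug <- make_auxiliary_structures(ss, cold_dose, vol)
  expect_equal(sum(aug$masks[["PTV-1-Crop"]]), 0)
  # reference dose below 40 Gy everywhere -> empty 40 Gy-PTV2
  expect_equal(sum(aug$masks[["40 Gy-PTV2"]]), 0)
  # missing base structure is named in the error
  ss2 <- case$ss
  ss2$masks[["Brainstem"]] <- NULL
  expect_error(make_auxiliary_structures(ss2, cold_dose, vol), "Brainstem")
})
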