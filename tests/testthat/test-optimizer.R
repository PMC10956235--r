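test_that("composite objective penalties have their closed forms", {
  ti <- tiny_instance()
  n <- ncol(ti$D$matrix)
  # a satisfied objective set scores exactly zero
  w <- rep(1, n)
  dose <- compute_dose(ti$D, w)
  slack <- make_objective("Target", "max_dose_at_volume", 0,
                          max(dose) + 1, NA, 70)
  expect_equal(composite_objective(w, ti$D, slack, ti$ss)$value, 0)
  # uniform undershoot of delta gives weight * delta^2
  dhat <- 5
  obj_min <- make_objective("Target", "min_dose_at_volume", 100, dhat, NA, 150)
  f0 <- composite_objective(rep(0, n), ti$D, obj_min, ti$ss)$value
  expect_equal(f0, (150 / 100)^2 * dhat^2)
  expect_error(composite_objective(rep(-1, n), ti$D, obj_min, ti$ss), ">= 0")
})

test_that("analytic gradients match central finite differences", {
  ti <- tiny_instance()
  n <- ncol(ti$D$matrix)
  set.seed(31)
  w <- runif(n, 0.5, 1.5)
  objectives <- rbind(
    make_objective("Target", "min_dose_at_volume", 100, 12, NA, 150),
    make_objective("Target", "max_dose_at_volume", 0, 9, NA, 70),
    make_objective("OAR", "max_dose_at_volume", 20, 2, NA, 50),
    make_objective("OAR", "max_gEUD", NA, 1.5, 5, 50),
    make_objective("Body", "max_gEUD", NA, 0.5, 1, 50))
  ev <- composite_objective(w, ti$D, objectives, ti$ss)
  fd <- function(k, h = 1e-6) {
    wp <- w; wp[k] <- w[k] + h
    wm <- w; wm[k] <- w[k] - h
    (composite_objective(wp, ti$D, objectives, ti$ss, gradient = FALSE)$value -
       composite_objective(wm, ti$D, objectives, ti$ss, gradient = FALSE)$value) / (2 * h)
  }
  ks <- seq(1, n, by = 2)
  g_fd <- vapply(ks, fd, 0)
  scale <- max(abs(g_fd))
  expect_gt(scale, 0)
  expect_lt(max(abs(ev$gradient[ks] - g_fd)) / scale, 1e-4)
})

test_that("optimization is monotone, feasible and deterministic", {
  ctx <- small_ctx()
  cfg <- optimizer_config(max_iterations = 40, start_mode = "warm")
  r1 <- optimize_fluence(ctx$D, ctx$objectives, ctx$ss_aug,
                         init = ctx$fl, config = cfg)
  r2 <- optimize_fluence(ctx$D, ctx$objectives, ctx$ss_aug,
                         init = ctx$fl, config = cfg)
  expect_identical(r1$trace, r2$trace)                 # deterministic
  expect_identical(r1$w, r2$w)
  expect_true(all(r1$w >= 0))                          # feasible
  expect_true(all(diff(r1$trace$objective) <= 1e-12))  # monotone descent
  expect_lte(r1$value, r1$trace$objective[1])          # improvement
  expect_lte(r1$iterations_used, 40)
})

test_that("an already-optimal start returns immediately", {
  ti <- tiny_instance()
  n <- ncol(ti$D$matrix)
  w <- rep(1, n)
  dose <- compute_dose(ti$D, w)
  slack <- make_objective("Target", "max_dose_at_volume", 0, max(dose) + 1, NA, 70)
  res <- optimize_fluence(ti$D, slack, ti$ss, init = w,
                          config = optimizer_config(start_mode = "warm"))
  expect_equal(res$value, 0)
  expect_equal(res$iterations_used, 0L)
  expect_equal(res$termination_reason, "optimal")
  expect_identical(res$w, w)
})

test_that("cold start recovers a known-achievable plan on a small case", {
  ctx <- small_ctx()
  # reference generated by a known fluence; objectives derived from it
  wstar <- fluence_vector(surrogate_predict_fluence(
    ctx$case$vol, ctx$case$ss, ctx$beams, noise_sd = 0))
  ref <- compute_dose(ctx$D, wstar)
  ss_aug <- make_auxiliary_structures(ctx$case$ss, ref, ctx$case$vol)
  obj <- derive_objectives(ss_aug, ref)
  fstar <- composite_objective(wstar, ctx$D, obj, ss_aug)$value
  cold <- optimize_fluence(ctx$D, obj, ss_aug,
                           config = optimizer_config(start_mode = "cold"))
  expect_lte(cold$value, 1.05 * fstar)
  expect_true(cold$termination_reason %in%
                c("converged", "max_iterations", "optimal", "no_progress"))
})

test_that("warm start requires an initial fluence and validates it", {
  ctx <- small_ctx()
  expect_error(optimize_fluence(ctx$D, ctx$objectives, ctx$ss_aug,
                                config = optimizer_config(start_mode = "warm")),
               "warm start")
  expect_error(optimize_fluence(ctx$D, ctx$objectives, ctx$ss_aug,
                                init = rep(1, 5),
                                config = optimizer_config(start_mode = "warm")),
               "mismatch")
})
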