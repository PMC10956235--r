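#' Optimizer configuration
#'
#' @param max_iterations iteration cap, default 300.
#' @param start_mode `"warm"` (initialize at the predicted fluence) or
#'   `"cold"` (uniform fluence scaled so the mean PTV-GTV dose equals its
#'   prescription).
#' @param convergence_tol relative objective decrease over
#'   `convergence_window` iterations below which optimization stops.
#' @param convergence_window iterations over which the relative decrease is
#'   measured, default 10.
#' @param priority_exponent exponent of the priority-to-weight mapping
#'   `(priority / 100) ^ priority_exponent`, default 2.
#' @return list of class `optimizer_config`.
#' @export
optimizer_config <- function(max_iterations = 300L,
                             start_mode = c("warm", "cold"),
                             convergence_tol = 1e-6,
                             convergence_window = 10L,
                             priority_exponent = 2) {
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop("`max_iterations` must be >= 1")
  if (convergence_tol < 0) stop("`convergence_tol` must be >= 0")
  structure(
    list(max_iterations = max_iterations,
         start_mode = match.arg(start_mode),
         convergence_tol = convergence_tol,
         convergence_window = as.integer(convergence_window),
         priority_exponent = priority_exponent),
    class = "optimizer_config"
  )
}

# map structure masks to influence-matrix row indices, once per solve
.objective_rows <- function(D, objectives, ss) {
  lapply(seq_len(nrow(objectives)), function(k) {
    nm <- objectives$structure[k]
    m <- ss$masks[[nm]]
    if (is.null(m) || !any(m)) {
      warning(sprintf("objective on missing/empty structure '%s' skipped", nm))
      return(integer())
    }
    r <- match(which(as.vector(m)), D$voxel_idx)
    r[!is.na(r)]
  })
}

.composite_eval <- function(w, D, objectives, rows, priority_exponent,
                            gradient = TRUE) {
  dose <- as.numeric(D$matrix %*% w)
  f <- 0
  gvox <- if (gradient) numeric(length(dose)) else NULL
  for (k in seq_len(nrow(objectives))) {
    r <- rows[[k]]
    n <- length(r)
    if (!n) next
    d <- dose[r]
    dhat <- objectives$objective_dose[k]
    wt <- (objectives$priority[k] / 100)^priority_exponent
    kind <- objectives$kind[k]
    if (kind == "max_dose_at_volume") {
      xv <- objectives$volume_percent[k]
      allowed <- floor(xv * n / 100)
      if (allowed >= n) next
      if (allowed == 0) {
        v <- which(d > dhat)
      } else {
        ord <- order(d, decreasing = TRUE)
        cand <- ord[(allowed + 1L):n]
        v <- cand[d[cand] > dhat]
      }
      if (length(v)) {
        over <- d[v] - dhat
        f <- f + wt * sum(over^2) / n
        if (gradient) {
          idx <- r[v]
          gvox[idx] <- gvox[idx] + wt * 2 * over / n
        }
      }
    } else if (kind == "min_dose_at_volume") {
      v <- which(d < dhat)
      if (length(v)) {
        under <- dhat - d[v]
        f <- f + wt * sum(under^2) / n
        if (gradient) {
          idx <- r[v]
          gvox[idx] <- gvox[idx] - wt * 2 * under / n
        }
      }
    } else if (kind == "max_gEUD") {
      a <- objectives$a[k]
      dmax <- max(d)
      if (dmax == 0) next
      M <- mean((d / dmax)^a)
      g <- dmax * M^(1 / a)
      if (g > dhat) {
        f <- f + wt * (g - dhat)^2
        if (gradient) {
          # d(gEUD)/d(d_i) = (1/n) (d_i / dmax)^(a-1) M^((1-a)/a)
          dg <- (pmax(d, 0) / dmax)^(a - 1) * M^((1 - a) / a) / n
          gvox[r] <- gvox[r] + wt * 2 * (g - dhat) * dg
        }
      }
    } else stop("unknown objective kind: ", kind)
  }
  grad <- if (gradient) as.numeric(Matrix::crossprod(D$matrix, gvox)) else NULL
  list(value = f, gradient = grad, dose = dose)
}

#' Priority-weighted composite planning objective
#'
#' `F(w) = sum_k weight_k * penalty_k` over the objective rows, with
#' `weight_k = (priority_k / 100) ^ priority_exponent`. Penalties are
#' one-sided and quadratic: for a maximum dose-at-volume objective the mean
#' squared overshoot over the voxels exceeding the objective dose beyond the
#' allowed volume fraction (hottest-first selection); for a minimum
#' dose objective the mean squared undershoot over all structure voxels; for
#' a maximum gEUD objective the squared overshoot of the structure gEUD.
#' The analytic gradient with respect to the beamlet weights follows from
#' the chain rule through the influence matrix.
#'
#' @param w nonnegative beamlet weight vector.
#' @param D an [build_influence()] result.
#' @param objectives an [derive_objectives()] result.
#' @param ss the [structure_set()] with every referenced structure.
#' @param priority_exponent see [optimizer_config()].
#' @param gradient logical; also return the gradient?
#' @return list with `value` (scalar) and, if requested, `gradient`
#'   (numeric vector, same length as `w`).
#' @export
composite_objective <- function(w, D, objectives, ss, priority_exponent = 2,
                                gradient = TRUE) {
  if (any(w < 0)) stop("beamlet weights must be >= 0")
  rows <- .objective_rows(D, objectives, ss)
  out <- .composite_eval(w, D, objectives, rows, priority_exponent, gradient)
  out$dose <- NULL
  out
}

#' Fine-tune fluence maps against a dose-mimicking objective set
#'
#' Projected gradient descent with Barzilai-Borwein step lengths and a
#' monotone Armijo backtracking line search on the nonnegative orthant
#' (`w >= 0`). Warm start begins at the supplied (predicted) fluence; cold
#' start begins at a uniform fluence scaled so the mean PTV-GTV dose equals
#' its prescription. The iteration cap defaults to 300; the run stops early
#' when the relative objective decrease over the convergence window falls
#' below `convergence_tol`. The returned trace of composite objective values
#' is non-increasing and the final objective never exceeds the initial one.
#'
#' @param D an [build_influence()] result.
#' @param objectives an [derive_objectives()] result.
#' @param ss the [structure_set()].
#' @param init list of [fluence_map()] or beamlet vector; required for warm
#'   start, ignored for cold start.
#' @param config an [optimizer_config()].
#' @return list of class `optimization_result`: `fluence` (per-beam maps),
#'   `w`, `value`, `trace` (data.frame `iteration`, `objective`),
#'   `iterations_used`, `termination_reason`.
#' @export
optimize_fluence <- function(D, objectives, ss, init = NULL,
                             config = optimizer_config()) {
  rows <- .objective_rows(D, objectives, ss)
  pe <- config$priority_exponent

  if (config$start_mode == "warm") {
    if (is.null(init)) stop("warm start requires `init` fluence")
    w <- if (is.numeric(init)) init else fluence_vector(init)
    if (length(w) != ncol(D$matrix)) stop("init fluence dimension mismatch")
    w <- pmax(w, 0)
  } else {
    gtv <- ss$masks[["PTV-GTV"]]
    if (is.null(gtv) || !any(gtv)) stop("cold start requires PTV-GTV")
    r <- match(which(as.vector(gtv)), D$voxel_idx)
    r <- r[!is.na(r)]
    ones <- rep(1, ncol(D$matrix))
    mean_dose <- mean(as.numeric(D$matrix %*% ones)[r])
    if (mean_dose <= 0) stop("influence matrix deposits no dose in PTV-GTV")
    w <- ones * ss$prescriptions[["PTV-GTV"]] / mean_dose
  }

  ev <- .composite_eval(w, D, objectives, rows, pe)
  if (!is.finite(ev$value))
    stop(sprintf("non-finite composite objective at start (%g)", ev$value))
  f <- ev$value; g <- ev$gradient
  trace <- numeric(config$max_iterations + 1L)
  trace[1L] <- f
  iter <- 0L
  reason <- "max_iterations"

  if (f == 0) {
    reason <- "optimal"
  } else {
    gmax <- max(abs(g))
    alpha <- if (gmax > 0) 0.1 * (max(w) + 1) / gmax else 1
    w_prev <- NULL; g_prev <- NULL
    while (iter < config$max_iterations) {
      iter <- iter + 1L
      # Barzilai-Borwein step from the previous accepted move
      if (!is.null(w_prev)) {
        s <- w - w_prev; y <- g - g_prev
        sy <- sum(s * y)
        if (sy > 0) alpha <- sum(s * s) / sy
      }
      accepted <- FALSE
      a_try <- alpha
      for (bt in 1:40) {
        w_new <- pmax(w - a_try * g, 0)
        pred <- sum(g * (w - w_new))
        if (pred <= 0) break
        ev_new <- .composite_eval(w_new, D, objectives, rows, pe)
        if (ev_new$value <= f - 1e-4 * pred) {
          accepted <- TRUE
          break
        }
        a_try <- a_try / 2
      }
      if (!accepted) {
        iter <- iter - 1L
        reason <- "no_progress"
        break
      }
      w_prev <- w; g_prev <- g
      w <- w_new; f <- ev_new$value; g <- ev_new$gradient
      trace[iter + 1L] <- f
      win <- config$convergence_window
      if (iter >= win) {
        f_then <- trace[iter + 1L - win]
        if (f_then - f <= config$convergence_tol * max(f_then, .Machine$double.eps)) {
          reason <- "converged"
          break
        }
      }
      if (f == 0) {
        reason <- "optimal"
        break
      }
    }
  }

  trace <- trace[seq_len(iter + 1L)]
  structure(
    list(fluence = vector_to_fluence(w, D$beams),
         w = w,
         value = f,
         trace = data.frame(iteration = seq_along(trace) - 1L,
                            objective = trace),
         iterations_used = iter,
         termination_reason = reason,
         config = config),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "<optimization_result> F = %.6g after %d iterations (%s, %s start)\n",
    x$value, x$iterations_used, x$termination_reason, x$config$start_mode))
  invisible(x)
}
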