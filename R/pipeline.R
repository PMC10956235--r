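#' End-to-end pipeline configuration
#'
#' One declarative object driving the full automatic-planning run. All
#' downstream stages are pure functions of this configuration, so reruns
#' with an identical configuration are bit-identical.
#'
#' @param seed phantom / surrogate seed.
#' @param shape,spacing planning grid, see [generate_phantom()].
#' @param prescriptions named PTV prescriptions in Gy.
#' @param beams a [beam_setup()].
#' @param kernel a [pencil_beam_kernel()].
#' @param noise_sd surrogate fluence prediction error, see
#'   [surrogate_predict_fluence()].
#' @param start_modes character subset of `c("warm", "cold")`; one
#'   fine-tuned plan is produced per mode.
#' @param max_iterations,convergence_tol optimizer settings, see
#'   [optimizer_config()].
#' @param levels MLC sequencing intensity levels, see [sequence_fluence()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            shape = c(64L, 64L, 48L),
                            spacing = c(4, 4, 4),
                            prescriptions = c(
                              "PTV-GTV" = 70, "PTV-1" = 60, "PTV-2" = 54,
                              "PTV-LN(L)" = 66, "PTV-LN(R)" = 66),
                            beams = beam_setup(),
                            kernel = pencil_beam_kernel(),
                            noise_sd = 0.05,
                            start_modes = c("warm", "cold"),
                            max_iterations = 300L,
                            convergence_tol = 1e-6,
                            levels = 10L) {
  if (!all(start_modes %in% c("warm", "cold")) || !length(start_modes))
    stop("`start_modes` must be a non-empty subset of c('warm', 'cold')")
  structure(
    list(seed = as.integer(seed), shape = as.integer(shape),
         spacing = as.numeric(spacing), prescriptions = prescriptions,
         beams = beams, kernel = kernel, noise_sd = noise_sd,
         start_modes = start_modes,
         max_iterations = as.integer(max_iterations),
         convergence_tol = convergence_tol,
         levels = as.integer(levels)),
    class = "pipeline_config"
  )
}

#' Run the automatic plan-generation pipeline
#'
#' Executes, in order: phantom generation (or a pre-loaded case), surrogate
#' fluence prediction, influence-matrix build, Step 1 (MLC sequencing of the
#' predicted fluence and dose calculation, giving the predicted-fluence
#' plan), Step 2 (auxiliary structures from that reference dose), Step 3
#' (objective derivation), Step 4 (fluence fine-tuning per start mode,
#' re-sequencing, final dose), and plan-quality evaluation of every stage.
#' Per-stage wall times are recorded. With `out_dir` set, all artifacts
#' (fluence files, objective table, aperture sequences, metric tables,
#' optimization traces, timings) are written there.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @param case optional pre-built list `(vol, ss)`; skips phantom
#'   generation.
#' @return list of class `pipeline_result` with elements `case`,
#'   `predicted_fluence`, `influence`, `step1` (predicted-fluence
#'   [finalize_plan()] result), `ss_aug`, `objectives`, `plans` (named list
#'   per start mode: `opt` the [optimize_fluence()] result, `plan` the
#'   final [finalize_plan()] result, `opt_dose` the pre-sequencing dose),
#'   `metrics` (named list of [summarize_plan()] tables), `timings`
#'   (seconds per stage).
#' @export
run_pipeline <- function(cfg, out_dir = NULL, case = NULL) {
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    val
  }

  if (is.null(case))
    case <- tick("phantom", generate_phantom(
      cfg$seed, cfg$shape, cfg$spacing, cfg$prescriptions))
  fl_pred <- tick("fluence_prediction", surrogate_predict_fluence(
    case$vol, case$ss, cfg$beams, noise_sd = cfg$noise_sd, seed = cfg$seed))
  D <- tick("influence", build_influence(case$vol, cfg$beams, cfg$kernel))

  step1_seq <- tick("step1_sequencing",
                    lapply(fl_pred, sequence_fluence, levels = cfg$levels))
  step1 <- tick("step1_dose", finalize_plan(D, step1_seq))
  ss_aug <- tick("step2_auxiliary",
                 make_auxiliary_structures(case$ss, step1$dose, case$vol))
  objectives <- tick("step3_objectives", derive_objectives(ss_aug, step1$dose))

  plans <- list()
  for (mode in cfg$start_modes) {
    oc <- optimizer_config(max_iterations = cfg$max_iterations,
                           start_mode = mode,
                           convergence_tol = cfg$convergence_tol)
    opt <- tick(paste0("step4_optimize_", mode), optimize_fluence(
      D, objectives, ss_aug,
      init = if (mode == "warm") fl_pred else NULL, config = oc))
    seqs <- tick(paste0("step4_sequencing_", mode),
                 lapply(opt$fluence, sequence_fluence, levels = cfg$levels))
    plan <- tick(paste0("step4_dose_", mode), finalize_plan(D, seqs))
    plans[[mode]] <- list(opt = opt, plan = plan,
                          opt_dose = compute_dose(D, opt$w))
  }

  metrics <- tick("evaluation", {
    m <- list(predicted_fluence = summarize_plan(step1$dose, ss_aug,
                                                 mu = step1$total_MU))
    for (mode in names(plans))
      m[[mode]] <- summarize_plan(plans[[mode]]$plan$dose, ss_aug,
                                  mu = plans[[mode]]$plan$total_MU)
    m
  })

  res <- structure(
    list(case = case, predicted_fluence = fl_pred, influence = D,
         step1 = step1, ss_aug = ss_aug, objectives = objectives,
         plans = plans, metrics = metrics, timings = unlist(timings),
         config = cfg),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in fl_pred)
      write_fluence_file(f, file.path(out_dir,
                                      sprintf("predicted_fluence_beam%02d.flu", f$beam_index)))
    write_objectives(objectives, file.path(out_dir, "objectives.csv"))
    write_metrics(metrics$predicted_fluence,
                  file.path(out_dir, "metrics_predicted_fluence.csv"))
    for (mode in names(plans)) {
      write_metrics(metrics[[mode]],
                    file.path(out_dir, sprintf("metrics_%s.csv", mode)))
      write_sequences(plans[[mode]]$plan$sequences,
                      file.path(out_dir, sprintf("sequences_%s.json", mode)))
      utils::write.csv(plans[[mode]]$opt$trace,
                       file.path(out_dir, sprintf("trace_%s.csv", mode)),
                       row.names = FALSE)
    }
    utils::write.csv(
      data.frame(stage = names(res$timings), seconds = unname(res$timings)),
      file.path(out_dir, "timings.csv"), row.names = FALSE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> seed %d, %d fine-tuned plan(s): %s\n",
              x$config$seed, length(x$plans),
              paste(names(x$plans), collapse = ", ")))
  cat(sprintf("  total wall time %.1f s\n", sum(x$timings)))
  invisible(x)
}
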