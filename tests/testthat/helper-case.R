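# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# desk-scale phantom: same physical extents as the default case, 8 mm voxels
small_case <- function() {
  cached("small_case", function()
    generate_phantom(seed = 1, shape = c(32L, 32L, 24L), spacing = c(8, 8, 8)))
}

small_influence <- function() {
  cached("small_influence", function()
    build_influence(small_case()$vol, beam_setup()))
}

# predicted fluence -> sequenced step-1 plan -> auxiliaries -> objectives
small_ctx <- function() {
  cached("small_ctx", function() {
    case <- small_case()
    beams <- beam_setup()
    D <- small_influence()
    fl <- surrogate_predict_fluence(case$vol, case$ss, beams,
                                    noise_sd = 0.05, seed = 1)
    step1 <- finalize_plan(D, lapply(fl, sequence_fluence, levels = 10))
    ss_aug <- make_auxiliary_structures(case$ss, step1$dose, case$vol)
    objectives <- derive_objectives(ss_aug, step1$dose)
    list(case = case, beams = beams, D = D, fl = fl, step1 = step1,
         ss_aug = ss_aug, objectives = objectives)
  })
}

# clinical-resolution case shared by the heavier acceptance checks
full_ctx <- function() {
  cached("full_ctx", function() {
    case <- generate_phantom(seed = 1)
    beams <- beam_setup()
    D <- build_influence(case$vol, beams)
    list(case = case, beams = beams, D = D)
  })
}

# a homogeneous water block filling the whole grid (no air shell)
slab_volume <- function(shape = c(10L, 10L, 8L), spacing = c(8, 8, 8)) {
  volume_grid(array(1, shape), spacing)
}

make_objective <- function(structure, kind, volume_percent, objective_dose,
                           a, priority) {
  data.frame(structure = structure, kind = kind,
             volume_percent = volume_percent, objective_dose = objective_dose,
             a = a, priority = priority, stringsAsFactors = FALSE)
}

# a tiny two-structure instance for gradient and penalty checks
tiny_instance <- function() {
  cached("tiny_instance", function() {
    vol <- slab_volume(c(6L, 6L, 6L), c(8, 8, 8))
    beams <- beam_setup(gantry_angles = c(0, 90),
                        fluence_spacing = c(12, 12),
                        fluence_shape = c(4L, 4L))
    D <- build_influence(vol, beams)
    target <- array(FALSE, vol$shape); target[3:4, 3:4, 3:4] <- TRUE
    oar <- array(FALSE, vol$shape); oar[1:2, 3:4, 3:4] <- TRUE
    ss <- structure_set(list(Target = target, OAR = oar, Body = array(TRUE, vol$shape)),
                        prescriptions = c(Target = 10))
    list(vol = vol, beams = beams, D = D, ss = ss)
  })
}
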