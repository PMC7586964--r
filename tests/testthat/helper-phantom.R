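# Shared fixtures: small phantoms and cached registration sweeps so several
# test files (and the acceptance checks) can reuse expensive results.

small_spec <- function(...) {
  phantom_spec(in_plane_size = 128L, n_slices = 4L, ...)
}

tiny_spec <- function(...) {
  phantom_spec(in_plane_size = 64L, n_slices = 3L, ...)
}

# session-level cache
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# A registered mid-size phantom case with rotations, reused by mapping and
# registration tests.
registered_small_case <- function() {
  cached("small_case", {
    spec <- small_spec(max_rotation_deg = 15, seed = 77L)
    ph <- generate_phantom(spec)
    chains <- register_case(ph$mri, ph$stack)
    list(phantom = ph, chains = chains,
         report = evaluate_phantom_case(ph, chains))
  })
}

# Full-scale sweeps used by the acceptance checks (256 px, 6 slices, the
# study's default conditions). Seeds are fixed per sweep.
sweep_rotation <- function() {
  cached("sweep_rotation", {
    conds <- lapply(c(5, 10, 15, 20), function(r)
      phantom_spec(max_rotation_deg = r))
    run_phantom_experiment(conds, n_reps = 10, base_seed = 101L)
  })
}

sweep_shrink <- function() {
  cached("sweep_shrink", {
    conds <- lapply(c(0.05, 0.10), function(s)
      phantom_spec(shrink_factor = s))
    run_phantom_experiment(conds, n_reps = 10, base_seed = 202L)
  })
}

sweep_offset <- function() {
  cached("sweep_offset", {
    conds <- lapply(c(0, 10, 20, 30), function(r)
      phantom_spec(max_rotation_deg = r, slice_offset_mm = 2))
    run_phantom_experiment(conds, n_reps = 2, base_seed = 303L)
  })
}
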