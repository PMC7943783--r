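# Shared helpers: a small-geometry scenario for fast pipeline tests and a
# cache for the expensive full-geometry runs used by the acceptance checks.

small_spec <- function(appendage_count = 0, ...) {
  scenario_spec(appendage_count = appendage_count,
                object_radius_px = 60, object_circumference_px = 377,
                appendage_length_px = 20, canvas_pad_px = 30, ...)
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# full-geometry zero-appendage reference pipeline (shared by several
# acceptance checks; ~10 s)
exp1_reference <- function() {
  cached("exp1_reference", {
    pr <- process_scene(scenario_spec(appendage_count = 0))
    hei <- hei_threshold_from_reference(pr$analysis_values, mode = "fraction")
    list(processed = pr, hei = hei)
  })
}

# full-geometry basic + thickness + acuity-256 scenario curves (~3 min)
exp1_curves <- function() {
  cached("exp1_curves", {
    run_experiment1(families = c("basic", "thickness"))
  })
}
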