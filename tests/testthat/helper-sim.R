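# Shared fixtures, built in code.

# Small, fast simulation configuration; noiseless and unambiguous unless a
# test overrides it.
quiet_config <- function(...) {
  defaults <- list(n_patients = 2L, duration_noise_sd_ms = 0,
                   ambiguity_rate = 0, n_background = 3L, seed = 123L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# A three-circle layout: A and B far apart, C overlapping B.
tiny_layout <- function() {
  validate_roi_layout(tibble::tibble(
    site_id = c("A", "B", "C"),
    cx = c(100, 300, 340),
    cy = c(100, 100, 100),
    radius = c(30, 30, 30)
  ))
}

# Fixation stream helper.
stream_of <- function(x, y, duration_ms, t_start_ms = NULL) {
  if (is.null(t_start_ms)) {
    t_start_ms <- cumsum(c(0, head(duration_ms, -1) + 50))
  }
  tibble::tibble(
    t_start_ms = as.integer(t_start_ms),
    x = as.integer(x), y = as.integer(y),
    duration_ms = as.integer(duration_ms)
  )
}

# First-principles kappa from raw label pairs (independent of the package's
# contingency-table path).
kappa_brute <- function(eye, ref) {
  stopifnot(length(eye) == length(ref))
  po <- mean(eye == ref)
  classes <- union(eye, ref)
  pe <- sum(vapply(classes, function(cl) mean(eye == cl) * mean(ref == cl),
                   numeric(1)))
  (po - pe) / (1 - pe)
}

# Run the full generator -> assignment -> scoring pipeline for one patient
# and lesion, returning scores merged with the truth.
pipeline_scores <- function(truth, atlas, config, lesion, patient,
                            replicate = 1L) {
  layout <- build_roi_layout(atlas, lesion, config)
  stream <- simulate_reading(truth, layout, config, lesion,
                             replicate = replicate, patient = patient)
  summaries <- assign_fixations(stream, layout)
  scored <- score_reading(summaries, atlas, lesion)
  truth_p <- truth[truth$patient == patient & truth$lesion == lesion, ]
  merge(scored, truth_p, by = c("site_id", "lesion"))
}
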