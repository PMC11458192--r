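test_that("degenerate score means give all-zero truth", {
  atlas <- build_default_atlas()
  par <- gazesharp:::default_score_params()
  par$mean <- 0
  cfg <- quiet_config(score_params = par)
  truth <- simulate_true_scores(cfg, atlas)
  expect_true(all(truth$true_score == 0L))
  expect_equal(nrow(truth), 2L * (44L + 42L))
})

test_that("truth simulation is deterministic given the seed", {
  atlas <- build_default_atlas()
  cfg <- sim_config(n_patients = 4, seed = 99)
  expect_identical(simulate_true_scores(cfg, atlas),
                   simulate_true_scores(cfg, atlas))
  cfg2 <- sim_config(n_patients = 4, seed = 100)
  expect_false(identical(simulate_true_scores(cfg, atlas),
                         simulate_true_scores(cfg2, atlas)))
})

test_that("sampled scores recover the configured per-site means", {
  atlas <- build_default_atlas()
  cfg <- sim_config(n_patients = 2000, seed = 7)
  truth <- simulate_true_scores(cfg, atlas)
  mcp2 <- truth[truth$lesion == "erosion" &
                  truth$site_id %in% c("hand_r_mcp2", "hand_l_mcp2"), ]
  se <- sd(mcp2$true_score) / sqrt(nrow(mcp2))
  expect_lt(abs(mean(mcp2$true_score) - 0.90), 3 * se)
})

test_that("noiseless per-site durations follow baseline + 2 s per point", {
  atlas <- build_default_atlas()
  cfg <- quiet_config()
  truth <- simulate_true_scores(cfg, atlas)
  layout <- build_roi_layout(atlas, "jsn", cfg)
  stream <- simulate_reading(truth, layout, cfg, "jsn", 1, patient = 1)
  summaries <- assign_fixations(stream, layout)
  tr <- truth[truth$patient == 1 & truth$lesion == "jsn", ]
  m <- merge(summaries, tr, by = "site_id")
  expect_equal(m$total_fixation_ms, 1000 + 2000 * m$true_score)
  # baseline-only joints sit at exactly 1 s
  expect_true(all(m$total_fixation_ms[m$true_score == 0] == 1000))
})

test_that("fixation exports are byte-identical under the same seed", {
  atlas <- build_default_atlas()
  cfg <- sim_config(n_patients = 1, seed = 31)
  truth <- simulate_true_scores(cfg, atlas)
  layout <- build_roi_layout(atlas, "erosion", cfg)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_export(simulate_reading(truth, layout, cfg, "erosion", 1, 1), f1)
  write_fixation_export(simulate_reading(truth, layout, cfg, "erosion", 1, 1), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("fixation export round-trips through the TSV dialect", {
  empty <- stream_of(integer(), integer(), integer())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_export(empty, f)
  expect_equal(length(readLines(f)), 1L)  # header only
  expect_equal(nrow(read_fixation_export(f)), 0L)

  one <- stream_of(10, 20, 500)
  write_fixation_export(one, f)
  expect_equal(length(readLines(f)), 2L)
  expect_equal(read_fixation_export(f), one)

  set.seed(1)
  big <- stream_of(sample(0:1919, 1e4, TRUE), sample(0:1079, 1e4, TRUE),
                   sample(1:3000, 1e4, TRUE),
                   t_start_ms = cumsum(sample(1:3100, 1e4, TRUE)))
  write_fixation_export(big, f)
  expect_equal(read_fixation_export(f), big)
})

test_that("replicate readings differ in noise but share the truth", {
  atlas <- build_default_atlas()
  cfg <- sim_config(n_patients = 1, duration_noise_sd_ms = 300,
                    ambiguity_rate = 0, seed = 17)
  truth <- simulate_true_scores(cfg, atlas)
  layout <- build_roi_layout(atlas, "erosion", cfg)
  s1 <- simulate_reading(truth, layout, cfg, "erosion", 1, 1)
  s2 <- simulate_reading(truth, layout, cfg, "erosion", 2, 1)
  expect_false(identical(s1$duration_ms, s2$duration_ms))
})

test_that("ambiguity flags the configured fraction of pathological joints", {
  atlas <- build_default_atlas()
  rate <- 0.1
  cfg <- sim_config(n_patients = 40, duration_noise_sd_ms = 0,
                    ambiguity_rate = rate, seed = 11)
  truth <- simulate_true_scores(cfg, atlas)
  layout <- build_roi_layout(atlas, "erosion", cfg)
  flagged <- 0L
  path_n <- 0L
  for (p in seq_len(cfg$n_patients)) {
    st <- simulate_reading(truth, layout, cfg, "erosion", 1, patient = p)
    s <- assign_fixations(st, layout)
    tr <- truth[truth$patient == p & truth$lesion == "erosion", ]
    m <- merge(s, tr, by = "site_id")
    path <- m$true_score >= 1L
    path_n <- path_n + sum(path)
    flagged <- flagged + sum(!m$analyzable[path])
  }
  frac <- flagged / path_n
  # pair-level events: ~2 correlated sites per event
  mc_se <- sqrt(rate * (1 - rate) / (path_n / 2))
  expect_lt(abs(frac - rate), 3 * mc_se)
})
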