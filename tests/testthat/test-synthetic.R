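test_that("a seed fully determines the generated experiment", {
  cfg <- small_config(21)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$fixations, e2$fixations)
  expect_identical(e1$trials, e2$trials)
  e3 <- generate_experiment(small_config(22))
  expect_false(identical(e1$fixations, e3$fixations))
  expect_identical(names(e1$fixations), names(e3$fixations))
})

test_that("adding participants does not perturb existing trials", {
  base <- generate_experiment(small_config(23, n_participants = 3))
  more <- generate_experiment(small_config(23, n_participants = 5))
  expect_identical(base$fixations,
                   more$fixations[more$fixations$participant %in%
                                    sprintf("p%02d", 1:3), ])
})

identity_config <- function(seed) {
  small_config(seed, phi = 1, shape_fidelity = 1, direction_fidelity = 1,
               contraction = 1, offset_sd = 0, duration_inflation = 1,
               jitter_sd = 0, pos_noise_sd = 0)
}

test_that("the identity configuration replays encoding exactly", {
  cfg <- identity_config(24)
  enc <- generate_encoding(cfg, 1, 5)
  rec <- generate_recall(cfg, enc)
  expect_equal(rec$fixations$x, enc$fixations$x)
  expect_equal(rec$fixations$y, enc$fixations$y)
  expect_equal(rec$fixations$duration, enc$fixations$duration)
  expect_equal(as.numeric(sers(enc, rec)), rep(1, 5), tolerance = 1e-9)
})

test_that("pure contraction preserves direction but shortens saccades", {
  cfg <- identity_config(25)
  cfg$contraction <- 0.5
  obj_image <- cfg$n_images_per_type[["scene"]] + 1L  # large saccades
  enc <- generate_encoding(cfg, 2, obj_image)
  rec <- generate_recall(cfg, enc)
  s <- sers(enc, rec)
  expect_equal(s[["direction"]], 1, tolerance = 1e-9)
  expect_lt(s[["length"]], 1)
})

test_that("encoding durations fit the trial and recall shows the cited distortions", {
  cfg <- small_config(26)
  for (i in c(1, 6)) {
    enc <- generate_encoding(cfg, 1, i)
    expect_lte(sum(enc$fixations$duration), cfg$encoding_duration)
    expect_gte(nrow(enc$fixations), 2)
  }
  exp <- generate_experiment(cfg)
  byph <- split(exp$fixations, exp$fixations$phase)
  # longer fixations when looking at nothing; contracted saccades
  expect_gt(mean(byph$recall$duration_ms), mean(byph$encoding$duration_ms))
  amp <- function(d) {
    unlist(lapply(split(d, paste(d$participant, d$image)), function(tr)
      sqrt(diff(tr$x)^2 + diff(tr$y)^2)))
  }
  expect_lt(mean(amp(byph$recall)), mean(amp(byph$encoding)))
  expect_true(all(byph$recall$onset_ms < cfg$recall_duration))
})

test_that("object arrangements visit all four anchors in most trials", {
  cfg <- small_config(27, n_participants = 100)
  obj_image <- cfg$n_images_per_type[["scene"]] + 1L
  anchors <- gazereplay:::image_anchors(cfg, obj_image, "object_arrangement")
  covered <- vapply(1:100, function(p) {
    enc <- generate_encoding(cfg, p, obj_image)
    all(vapply(seq_len(4), function(a) {
      any(sqrt((enc$fixations$x - anchors[a, 1])^2 +
                 (enc$fixations$y - anchors[a, 2])^2) < 160)
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("the three ratings are highly correlated and average to the score", {
  cfg <- small_config(28, n_participants = 20, n_scene = 6, n_object = 6)
  exp <- generate_experiment(cfg)
  tr <- exp$trials
  cm <- cor(tr[, c("recollection_strength", "vividness", "spatial_accuracy")])
  expect_gte(min(cm[upper.tri(cm)]), 0.85)
  expect_equal(tr$mnemonic_content,
               mnemonic_content(tr$recollection_strength, tr$vividness,
                                tr$spatial_accuracy))
  expect_true(all(tr$mnemonic_content >= 0 & tr$mnemonic_content <= 100))
  expect_true(all(tr$surprise_accuracy %in% 0:1))
})

test_that("scenes are easier than object arrangements on average", {
  cfg <- small_config(29, n_participants = 20, n_scene = 6, n_object = 6)
  tr <- generate_experiment(cfg)$trials
  m <- tapply(tr$mnemonic_content, tr$image_type, mean)
  expect_gt(m[["scene"]], m[["object_arrangement"]])
})

test_that("with all rating effects at zero the ratings ignore the fidelities", {
  cfg <- small_config(30, n_participants = 20, n_scene = 6, n_object = 6,
                      b_pos = 0, b_shape = 0, b_dir = 0)
  exp <- generate_experiment(cfg)
  d <- exp$truth
  d$mn <- exp$trials$mnemonic_content
  expect_lt(abs(cor(d$mn, d$f_position)), 0.12)
  expect_lt(abs(cor(d$mn, d$f_shape)), 0.12)
})

test_that("the experiment table has one complete row per trial", {
  cfg <- small_config(31, n_participants = 5)
  exp <- generate_experiment(cfg)
  expect_equal(nrow(exp$trials), 5 * 8)
  expect_equal(nrow(exp$truth), 5 * 8)
  counts <- table(exp$fixations$participant, exp$fixations$phase)
  expect_true(all(counts > 0))
  keys <- paste(exp$fixations$participant, exp$fixations$image,
                exp$fixations$phase)
  expect_equal(length(unique(keys)), 5 * 8 * 2)
  expect_true(all(exp$trials$n_study_fixations >= 2))
})

test_that("invalid configuration fields are enumerated", {
  expect_error(simulation_config(contraction = 0), "contraction")
  expect_error(simulation_config(phi = 1.5), "phi")
  expect_error(simulation_config(duration_inflation = 0.5, offset_sd = -1),
               "duration_inflation, offset_sd")
})

test_that("mean position SERS decreases as sequential fidelity degrades", {
  cfg <- small_config(32)
  curve <- sers_fidelity_curve(cfg, phi_values = c(1, 0.5, 0), n_trials = 40)
  expect_equal(order(curve$mean_sers, decreasing = TRUE), 1:3)
})
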