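make_pair <- function(seed, n_enc = 6, n_rec = 6, image = "img01") {
  enc <- rand_scanpath(n_enc, seed, image = image)
  rec <- rand_scanpath(n_rec, seed + 1000, image = image, phase = "recall")
  list(enc = enc, rec = rec)
}

test_that("SERS delegates to the scanpath comparison", {
  p <- make_pair(1)
  expect_equal(sers(p$enc, p$rec), compare_scanpaths(p$enc, p$rec))
  expect_equal(as.numeric(sers(p$enc, {
    r <- p$enc; r$phase <- "recall"; r
  })), rep(1, 5))
})

test_that("SERS rejects mismatched trials", {
  p <- make_pair(2)
  other <- rand_scanpath(5, 99, image = "img02", phase = "recall")
  expect_error(sers(p$enc, other), "same participant and image")
  expect_error(sers(p$rec, p$rec), "encoding scanpath")
})

test_that("recalling fixations in reverse order lowers position SERS", {
  enc <- scanpath(x = c(100, 600, 1100, 1500), y = c(100, 800, 200, 900),
                  duration = rep(250, 4), warn_offscreen = FALSE)
  fwd <- scanpath(enc$fixations$x, enc$fixations$y, enc$fixations$duration,
                  phase = "recall", warn_offscreen = FALSE)
  rev_ <- scanpath(rev(enc$fixations$x), rev(enc$fixations$y),
                   rev(enc$fixations$duration), phase = "recall",
                   warn_offscreen = FALSE)
  s_fwd <- sers(enc, fwd)
  s_rev <- sers(enc, rev_)
  expect_lt(s_rev[["position"]], s_fwd[["position"]])
})

test_that("baseline averages pairwise comparisons with equal weight", {
  enc <- rand_scanpath(6, 5, image = "imgA")
  others <- lapply(1:3, function(k)
    rand_scanpath(6, 50 + k, image = paste0("imgB", k), phase = "recall"))
  b <- baseline_similarity(enc, others)
  manual <- rowMeans(sapply(others, function(r) compare_scanpaths(enc, r)))
  expect_equal(b, manual)
  expect_equal(baseline_similarity(enc, others[1]),
               compare_scanpaths(enc, others[[1]]), ignore_attr = TRUE)
})

test_that("baseline recalls must come from other same-type images", {
  enc <- rand_scanpath(6, 6, image = "imgA")
  same_image <- rand_scanpath(6, 61, image = "imgA", phase = "recall")
  expect_error(baseline_similarity(enc, list(same_image)), "differ in image")
})

fixtab_from <- function(sps) {
  dplyr::bind_rows(lapply(sps, function(sp) {
    tibble::tibble(participant = sp$participant, image = sp$image,
                   image_type = sp$image_type, phase = sp$phase,
                   fix_index = seq_len(nrow(sp$fixations)),
                   x = sp$fixations$x, y = sp$fixations$y,
                   onset_ms = sp$fixations$onset,
                   duration_ms = sp$fixations$duration)
  }))
}

test_that("replay is exactly SERS minus baseline, one row per trial", {
  cfg <- small_config(3)
  exp <- generate_experiment(cfg)
  rec <- replay_scores(exp$fixations)
  expect_equal(nrow(rec), 6 * 8)
  for (d in c("position", "duration", "shape", "direction", "length"))
    expect_equal(rec[[paste0("replay_", d)]],
                 rec[[paste0("sers_", d)]] - rec[[paste0("baseline_", d)]])
  expect_true(all(abs(rec$replay_position) <= 1))
})

test_that("an exactly replayed image earns positive position replay", {
  encs <- lapply(1:4, function(k) rand_scanpath(6, 200 + k,
                                                image = sprintf("img%02d", k)))
  recs <- c(list({
    r <- encs[[1]]; r$phase <- "recall"; r
  }), lapply(2:4, function(k) rand_scanpath(6, 300 + k,
                                            image = sprintf("img%02d", k),
                                            phase = "recall")))
  rec <- replay_scores(fixtab_from(c(encs, recs)))
  row_a <- rec[rec$image == "img01", ]
  expect_equal(row_a$sers_position, 1)
  expect_gt(row_a$replay_position, 0)
})

test_that("identical recalls for every image give exactly zero replay", {
  encs <- lapply(1:3, function(k) rand_scanpath(5, 400 + k,
                                                image = sprintf("img%02d", k)))
  template <- rand_scanpath(5, 999, phase = "recall")
  recs <- lapply(1:3, function(k) {
    r <- template; r$image <- sprintf("img%02d", k); r
  })
  rec <- replay_scores(fixtab_from(c(encs, recs)))
  for (d in c("position", "duration", "shape", "direction", "length"))
    expect_equal(rec[[paste0("replay_", d)]], rep(0, 3))
})

test_that("exclusions are reported with reason codes", {
  encs <- lapply(1:3, function(k) rand_scanpath(5, 500 + k,
                                                image = sprintf("img%02d", k)))
  recs <- lapply(1:2, function(k) rand_scanpath(5, 600 + k,
                                                image = sprintf("img%02d", k),
                                                phase = "recall"))
  tab <- fixtab_from(c(encs, recs))
  # a one-fixation recall trial must be dropped, and img03 has no recall
  tab <- dplyr::bind_rows(tab, tibble::tibble(
    participant = "p01", image = "img04", image_type = "scene",
    phase = "recall", fix_index = 1L, x = 10, y = 10, onset_ms = 0,
    duration_ms = 100))
  rec <- replay_scores(tab)
  excl <- attr(rec, "exclusions")
  expect_setequal(rec$image, c("img01", "img02"))
  expect_true(any(excl$reason == "too_few_fixations"))
  expect_true(any(excl$reason == "missing_counterpart" & excl$image == "img03"))
})

test_that("label shuffling permutes recall images within participant and type", {
  cfg <- small_config(7)
  exp <- generate_experiment(cfg)
  set.seed(1)
  shuf <- shuffle_recall_images(exp$fixations)
  expect_equal(dim(shuf), dim(exp$fixations))
  enc <- exp$fixations$phase == "encoding"
  expect_identical(shuf$image[enc], exp$fixations$image[enc])
  key <- paste(exp$fixations$participant, exp$fixations$image_type)
  for (k in unique(key[!enc]))
    expect_setequal(unique(shuf$image[!enc & key == k]),
                    unique(exp$fixations$image[!enc & key == k]))
})

test_that("AOI profiles count fixation proportions on half-open cells", {
  scr <- c(1680, 1050)
  one_q <- scanpath(x = rep(100, 5), y = rep(100, 5), duration = rep(100, 5),
                    screen = scr, warn_offscreen = FALSE)
  p <- aoi_profile(one_q, 4)
  expect_equal(p$proportions, c(1, 0, 0, 0))

  quads <- scanpath(x = c(100, 1000, 100, 1000), y = c(100, 100, 700, 700),
                    duration = rep(100, 4), screen = scr, warn_offscreen = FALSE)
  expect_equal(aoi_profile(quads, 4)$proportions, rep(0.25, 4))

  # exact boundary goes to the cell right/below
  mid <- scanpath(x = 840, y = 525, duration = 100, screen = scr,
                  warn_offscreen = FALSE)
  expect_equal(aoi_profile(mid, 4)$proportions, c(0, 0, 0, 1))
})

test_that("16-cell profiles match a manual recount and sum to 1", {
  sp <- rand_scanpath(40, 77)
  p <- aoi_profile(sp, 16)
  expect_equal(sum(p$proportions), 1)
  cx <- pmin(floor(sp$fixations$x / (1680 / 4)), 3)
  cy <- pmin(floor(sp$fixations$y / (1050 / 4)), 3)
  manual <- tabulate(cy * 4 + cx + 1, 16) / 40
  expect_equal(p$proportions, manual)
})

test_that("spatial overlap behaves as a bounded similarity", {
  sp <- rand_scanpath(20, 88)
  p <- aoi_profile(sp, 4)
  expect_equal(as.numeric(spatial_overlap(p, p)), 1)

  uni <- structure(list(grid = c(rows = 2L, cols = 2L),
                        proportions = rep(0.25, 4), n_fixations = 4L),
                   class = "aoi_profile")
  conc <- structure(list(grid = c(rows = 2L, cols = 2L),
                         proportions = c(1, 0, 0, 0), n_fixations = 4L),
                    class = "aoi_profile")
  disj <- structure(list(grid = c(rows = 2L, cols = 2L),
                         proportions = c(0, 1, 0, 0), n_fixations = 4L),
                    class = "aoi_profile")
  expect_equal(as.numeric(spatial_overlap(uni, conc)), 0.25)
  expect_equal(as.numeric(spatial_overlap(conc, disj)), 0)
  expect_equal(as.numeric(spatial_overlap(uni, conc)),
               as.numeric(spatial_overlap(conc, uni)))
  r <- spatial_overlap(uni, conc, metric = "rank")
  expect_true(r >= 0 && r <= 1)
  expect_equal(attr(r, "metric"), "rank")
  p8 <- aoi_profile(sp, 8)
  expect_error(spatial_overlap(p, p8), "different grids")
})

test_that("gaze transitions count consecutive label changes", {
  expect_equal(gaze_transitions(c("A", "A", "A")), 0)
  expect_equal(gaze_transitions(c("A", "B", "A", "C")), 3)
  expect_equal(gaze_transitions("A"), 0L)
  set.seed(5)
  labs <- sample(LETTERS[1:4], 20, replace = TRUE)
  expect_equal(gaze_transitions(labs), sum(labs[-1] != labs[-20]))
})

test_that("the AOI overlap table covers every grid and scored trial", {
  cfg <- small_config(9, n_participants = 3, n_scene = 2, n_object = 2)
  exp <- generate_experiment(cfg)
  tab <- aoi_overlap_table(exp$fixations)
  expect_equal(nrow(tab), 3 * 4 * 4)
  expect_setequal(unique(tab$grid), c(4, 8, 12, 16))
  expect_true(all(tab$overlap >= 0 & tab$overlap <= 1))
})
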