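params_default <- mm_params()

test_that("collinear saccades merge into their vector sum", {
  sp <- scanpath(x = c(0, 50, 100, 100), y = c(0, 0, 0, 80),
                 duration = c(200, 100, 200, 200), warn_offscreen = FALSE)
  simp <- simplify_scanpath(sp, mm_params())
  # (50,0)+(50,0) merge; the orthogonal (0,80) must survive
  expect_equal(simp$fixations$x, c(0, 100, 100))
  expect_equal(simp$fixations$y, c(0, 0, 80))
})

test_that("large orthogonal saccades never merge on direction", {
  sp <- scanpath(x = c(0, 500, 500), y = c(0, 0, 500),
                 duration = rep(200, 3), warn_offscreen = FALSE)
  simp <- simplify_scanpath(sp, mm_params())
  expect_equal(nrow(simp$fixations), 3)
})

test_that("small saccades with a brief intervening fixation merge on amplitude", {
  p <- mm_params()
  amp_px <- 0.10 * sqrt(sum(p$screen^2))
  step <- 0.4 * amp_px
  # two small orthogonal saccades: direction rule cannot fire (90 deg)
  sp_short <- scanpath(x = c(800, 800 + step, 800 + step),
                       y = c(500, 500, 500 + step),
                       duration = c(200, 100, 200), warn_offscreen = FALSE)
  expect_equal(nrow(simplify_scanpath(sp_short, p)$fixations), 2)
  # same geometry with a long intervening fixation must not merge
  sp_long <- scanpath(x = c(800, 800 + step, 800 + step),
                      y = c(500, 500, 500 + step),
                      duration = c(200, 400, 200), warn_offscreen = FALSE)
  expect_equal(nrow(simplify_scanpath(sp_long, p)$fixations), 3)
})

test_that("simplification reaches a fixpoint", {
  for (seed in 1:10) {
    sp <- rand_scanpath(12, seed + 100)
    s1 <- simplify_scanpath(sp, params_default)
    s2 <- simplify_scanpath(s1, params_default)
    expect_equal(s2$fixations, s1$fixations)
  }
})

test_that("cost matrix holds pairwise vector-difference norms", {
  a1 <- scanpath(x = c(0, 100), y = c(0, 0), duration = c(200, 200),
                 warn_offscreen = FALSE)
  expect_equal(unclass(mm_cost_matrix(a1, a1)), matrix(0, 1, 1))
  b1 <- scanpath(x = c(0, 0), y = c(0, 100), duration = c(200, 200),
                 warn_offscreen = FALSE)
  expect_equal(mm_cost_matrix(a1, b1)[1, 1], sqrt(100^2 + 100^2))

  a <- rand_scanpath(4, 11)
  b <- rand_scanpath(5, 12)
  m <- mm_cost_matrix(a, b)
  va <- saccade_vectors(a); vb <- saccade_vectors(b)
  for (i in 1:3) for (j in 1:4)
    expect_equal(m[i, j], sqrt((va$dx[i] - vb$dx[j])^2 + (va$dy[i] - vb$dy[j])^2))
})

test_that("alignment of a single-cell matrix is the single pair", {
  al <- mm_align(matrix(5, 1, 1))
  expect_equal(unname(al[, 1]), 1L)
  expect_equal(unname(al[, 2]), 1L)
  expect_equal(attr(al, "cost"), 5)
})

test_that("a zero-diagonal matrix aligns along the diagonal", {
  m <- matrix(10, 3, 3); diag(m) <- 0
  al <- mm_align(m)
  expect_equal(unname(al[, 1]), 1:3)
  expect_equal(unname(al[, 2]), 1:3)
  expect_equal(attr(al, "cost"), 0)
})

test_that("shortest-path cost matches exhaustive enumeration", {
  set.seed(99)
  for (r in 1:100) {
    n <- sample(1:4, 1); m <- sample(1:5, 1)
    cost <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    al <- mm_align(cost)
    expect_equal(attr(al, "cost"), brute_min_path_cost(cost))
  }
})

test_that("alignments are valid monotone paths for unequal lengths", {
  set.seed(7)
  for (r in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    cost <- matrix(runif(n * m), n, m)
    al <- mm_align(cost)
    expect_equal(unname(al[1, ]), c(1L, 1L))
    expect_equal(unname(al[nrow(al), ]), c(n, m))
    steps <- diff(al)
    expect_true(all(steps >= 0 & steps <= 1))
    expect_true(all(rowSums(steps) >= 1))
  }
})

test_that("self-similarity is 1 on all five dimensions", {
  sp <- rand_scanpath(6, 21)
  al <- cbind(i = 1:5, j = 1:5)
  expect_equal(unname(mm_similarity(sp, sp, al)), rep(1, 5))
  expect_equal(as.numeric(compare_scanpaths(sp, sp, params_default)), rep(1, 5))
})

test_that("orthogonal equal-length vectors give direction 0.5, length 1", {
  a <- scanpath(x = c(0, 100), y = c(0, 0), duration = c(200, 200),
                warn_offscreen = FALSE)
  b <- scanpath(x = c(0, 0), y = c(0, 100), duration = c(200, 200),
                warn_offscreen = FALSE)
  s <- mm_similarity(a, b, cbind(1, 1))
  expect_equal(s[["direction"]], 0.5)
  expect_equal(s[["length"]], 1)
})

test_that("each dimension matches an independent recomputation", {
  for (seed in 1:10) {
    a <- rand_scanpath(5, seed + 300)
    b <- rand_scanpath(7, seed + 400)
    m <- mm_cost_matrix(a, b)
    al <- mm_align(m)
    s <- mm_similarity(a, b, al)
    expect_equal(unname(s), unname(r_similarity(a, b, al)), tolerance = 1e-12)
  }
})

test_that("comparison is symmetric on random pairs", {
  for (seed in 1:20) {
    a <- rand_scanpath(sample(4:12, 1), seed + 500)
    b <- rand_scanpath(sample(4:12, 1), seed + 600)
    expect_equal(as.numeric(compare_scanpaths(a, b, params_default)),
                 as.numeric(compare_scanpaths(b, a, params_default)),
                 tolerance = 1e-9)
  }
})

test_that("similarities always lie in [0, 1]", {
  for (seed in 1:20) {
    a <- rand_scanpath(sample(2:10, 1), seed + 700)
    b <- rand_scanpath(sample(2:10, 1), seed + 800)
    s <- compare_scanpaths(a, b, params_default)
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("uniform contraction preserves direction but not length", {
  sp <- rand_scanpath(6, 31, min_amplitude = 500)
  shrunk <- scale_scanpath(sp, 0.5,
                           about = c(mean(sp$fixations$x), mean(sp$fixations$y)))
  s <- compare_scanpaths(sp, shrunk, params_default)
  expect_equal(s[["direction"]], 1, tolerance = 1e-12)
  expect_lt(s[["length"]], 1)
})

test_that("shape, direction, length and duration are translation-invariant; position is not", {
  a <- rand_scanpath(7, 41)
  b <- rand_scanpath(7, 42)
  b_shift <- translate_scanpath(b, 200, -150)
  s0 <- compare_scanpaths(a, b, params_default)
  s1 <- compare_scanpaths(a, b_shift, params_default)
  for (dim in c("shape", "direction", "length", "duration"))
    expect_equal(s1[[dim]], s0[[dim]], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(s1[["position"]], s0[["position"]])))
})

test_that("degenerate inputs are signalled", {
  one <- scanpath(x = 10, y = 10, duration = 100, warn_offscreen = FALSE)
  two <- rand_scanpath(4, 51)
  expect_error(compare_scanpaths(one, two), "degenerate")
  expect_error(compare_scanpaths(two, one), "degenerate")
  expect_error(mm_align(matrix(-1, 2, 2)), "non-negative")
})
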