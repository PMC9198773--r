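# helpers and independent oracles shared across the test files

rand_scanpath <- function(n, seed, screen = c(1680, 1050), phase = "encoding",
                          participant = "p01", image = "img01",
                          min_amplitude = 0) {
  set.seed(seed)
  repeat {
    x <- runif(n, 50, screen[1] - 50)
    y <- runif(n, 50, screen[2] - 50)
    amp <- sqrt(diff(x)^2 + diff(y)^2)
    if (all(amp >= min_amplitude)) break
  }
  scanpath(x, y, duration = runif(n, 100, 500),
           participant = participant, image = image, phase = phase,
           screen = screen, warn_offscreen = FALSE)
}

# exhaustive enumeration of all monotone paths through a cost matrix;
# cost of a path = sum of entered cells, start cell included
brute_min_path_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + cost[i, j]
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    if (j < m) recurse(i, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
  }
  recurse(1, 1, 0)
  best
}

# plain-R recomputation of the five similarity dimensions from an
# alignment, independent of the package's compiled implementation
r_similarity <- function(a, b, path, screen = c(1680, 1050)) {
  diag_px <- sqrt(sum(screen^2))
  fa <- a$fixations; fb <- b$fixations
  va <- cbind(diff(fa$x), diff(fa$y))
  vb <- cbind(diff(fb$x), diff(fb$y))
  wrap <- function(d) {
    d <- abs(d) %% (2 * pi)
    ifelse(d > pi, 2 * pi - d, d)
  }
  ds <- sapply(seq_len(nrow(path)), function(r) {
    i <- path[r, 1]; j <- path[r, 2]
    ampa <- sqrt(sum(va[i, ]^2)); ampb <- sqrt(sum(vb[j, ]^2))
    dura <- fa$duration[i + 1]; durb <- fb$duration[j + 1]
    c(position = sqrt((fa$x[i + 1] - fb$x[j + 1])^2 +
                        (fa$y[i + 1] - fb$y[j + 1])^2) / diag_px,
      duration = if (max(dura, durb) > 0) abs(dura - durb) / max(dura, durb) else 0,
      shape = sqrt(sum((va[i, ] - vb[j, ])^2)) / (2 * diag_px),
      direction = wrap(atan2(va[i, 2], va[i, 1]) - atan2(vb[j, 2], vb[j, 1])) / pi,
      length = abs(ampa - ampb) / diag_px)
  })
  1 - rowMeans(ds)
}

translate_scanpath <- function(sp, dx, dy) {
  out <- sp
  out$fixations$x <- out$fixations$x + dx
  out$fixations$y <- out$fixations$y + dy
  out
}

scale_scanpath <- function(sp, factor, about = c(0, 0)) {
  out <- sp
  out$fixations$x <- about[1] + factor * (out$fixations$x - about[1])
  out$fixations$y <- about[2] + factor * (out$fixations$y - about[2])
  out
}

small_config <- function(seed, n_participants = 6,
                         n_scene = 4, n_object = 4, ...) {
  simulation_config(
    n_participants = n_participants,
    n_images_per_type = c(scene = n_scene, object_arrangement = n_object),
    seed = seed, ...)
}
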