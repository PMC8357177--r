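test_that("sequences round-trip through PNG and PGM frames bit-exactly", {
  frames <- list(walker_frame(1, 0.2), walker_frame(1, 1.1),
                 walker_frame(1, 2.0))
  sq <- gait_sequence(frames, class_label = "S01")
  for (fmt in c("png", "pgm")) {
    d <- file.path(tempfile(), fmt)
    save_sequence(sq, d, format = fmt)
    back <- load_sequence(d, pattern = paste0("*.", fmt))
    expect_identical(back$frames, sq$frames)
  }
})

test_that("loading binarizes, orders frames, and rejects bad input", {
  d <- tempfile(); dir.create(d)
  f <- matrix(0, 8, 6); f[3:6, 2:5] <- 1
  # foreground stored at intensity 255/255 = 1 and 128/255: both nonzero -> 1
  png::writePNG(f * 0.5, file.path(d, "frame_0002.png"))
  png::writePNG(f, file.path(d, "frame_0001.png"))
  sq <- load_sequence(d)
  expect_length(sq$frames, 2)
  expect_identical(sq$frames[[1]], f)
  expect_identical(sq$frames[[2]], f)  # 0.5 intensity binarized to 1

  expect_error(load_sequence(tempfile()), "no frames")
  png::writePNG(matrix(1, 4, 4), file.path(d, "frame_0003.png"))
  expect_error(load_sequence(d), "mixed sizes")
  expect_error(gait_sequence(list(matrix(0.5, 2, 2))), "binary")
})

test_that("normalize_silhouette scales, centres and preserves the contract", {
  # solid 10x4 rectangle on a 20x10 target: solid 20x8, horizontally centred
  f <- matrix(0, 30, 30); f[11:20, 14:17] <- 1
  out <- normalize_silhouette(f, 20, 10)
  expect_equal(dim(out), c(20, 10))
  expect_true(all(out %in% c(0, 1)))
  expect_equal(unname(colSums(out)), c(0, rep(20, 8), 0))

  # bounding box already at target size: output equals the cropped input
  g <- matrix(0, 12, 12); g[1:8, 3:8] <- 1
  expect_equal(normalize_silhouette(g, 8, 6), g[1:8, 3:8])

  # idempotent on already-normalized frames
  wf <- walker_frame(3)
  expect_equal(normalize_silhouette(wf, 64, 44), wf)

  expect_error(normalize_silhouette(matrix(0, 5, 5), 8, 6), "empty frame")
  wide <- matrix(0, 10, 40); wide[4:6, 1:40] <- 1
  expect_warning(out2 <- normalize_silhouette(wide, 10, 20), "clip")
  expect_equal(dim(out2), c(10, 20))
})

test_that("gait cycle estimation recovers the rendered period", {
  sq <- render_sequence(walker_subject(42), gait_style(1, cadence = 1 / 24),
                        n_frames = 72)
  expect_lte(abs(estimate_gait_cycle(sq) - 24), 1)

  # constant sequence has no periodic signal
  const <- gait_sequence(replicate(12, walker_frame(2, 0.3),
                                   simplify = FALSE))
  expect_error(estimate_gait_cycle(const), "aperiodic")

  # a preset cycle length passes through unchanged
  sq$cycle_length <- 30L
  expect_identical(estimate_gait_cycle(sq), 30L)

  tr <- truncate_to_cycle(render_sequence(walker_subject(42),
                                          gait_style(1, cadence = 1 / 20),
                                          n_frames = 60))
  expect_lte(length(tr), 21)
})

test_that("the gait energy image is the per-pixel temporal mean", {
  f <- walker_frame(4)
  expect_equal(compute_gei(gait_sequence(list(f, f, f))), f)

  z <- matrix(0, 4, 3); o <- matrix(1, 4, 3)
  expect_equal(compute_gei(gait_sequence(list(z, o))), matrix(0.5, 4, 3))

  # brute-force per-pixel averaging oracle on a real sequence
  sq <- render_sequence(walker_subject(9), gait_style(1.2), 15)
  gei <- compute_gei(sq)
  oracle <- matrix(0, 64, 44)
  for (i in 1:64) for (j in 1:44)
    oracle[i, j] <- mean(vapply(sq$frames, function(f) f[i, j], numeric(1)))
  expect_equal(gei, oracle)
  expect_gte(min(gei), 0)
  expect_lte(max(gei), 1)
  expect_equal(mean(gei),
               mean(vapply(sq$frames, mean, numeric(1))))
})
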