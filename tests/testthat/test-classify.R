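test_that("frame rotation pads to a fixed square and preserves binarity", {
  f <- walker_frame(6)
  r0 <- rotate_frame(f, 0)
  S <- ceiling(sqrt(64^2 + 44^2))
  expect_equal(dim(r0), c(S, S))
  expect_equal(sum(r0), sum(f))

  # exact 90-degree rotation of a solid rectangle keeps the pixel count
  rect <- matrix(0, 20, 10); rect[5:16, 3:8] <- 1
  r90 <- rotate_frame(rect, 90)
  expect_equal(sum(r90), sum(rect))
  fg <- which(r90 == 1, arr.ind = TRUE)
  # the 12x6 box becomes 6x12
  expect_equal(diff(range(fg[, 1])) + 1, 6)
  expect_equal(diff(range(fg[, 2])) + 1, 12)

  # rotate there and back: nearest-neighbour loss below 5% on walker frames
  for (th in c(10, 20)) {
    fwd <- rotate_frame(f, th)
    back <- rotate_frame(fwd, -th)
    inner <- rotate_frame(f, 0)
    pad <- (nrow(back) - nrow(inner)) %/% 2
    core <- back[(pad + 1):(pad + nrow(inner)), (pad + 1):(pad + ncol(inner))]
    overlap <- sum(core * inner) / sum(inner)
    expect_gte(overlap, 0.95)
  }
  expect_true(all(rotate_frame(f, 33) %in% c(0, 1)))
  expect_true(all(rotate_frame(f, 33, "bilinear") %in% c(0, 1)))
})

test_that("rotation grids enumerate fine and coarse angles", {
  g <- build_rotation_grid(20, 2)
  expect_equal(g$angles, seq(-20, 20, 2))
  g2 <- build_rotation_grid(20, 2, coarse_step = 10, coarse_max = 90)
  expect_length(g2$angles, 35)
  expect_true(all(c(-90, -30, 0, 30, 90) %in% g2$angles))
  expect_equal(build_rotation_grid(0)$angles, 0)
  expect_error(build_rotation_grid(20, 3), "divide")
})

test_that("a probe identical to its class attains similarity one", {
  b <- small_bench()
  gal <- b$gallery[1:2]
  grid <- build_rotation_grid(0)
  tn <- similarity_tensor(gal, gal[[1]], grid, K = 8, DG = 10, DP = 10,
                          R = 2, dg_axis = c(4, 8), dp_axis = c(4, 8),
                          probe_id = "self")
  for (d in c("4", "8"))
    expect_equal(unname(tn["S01", "1", d, d, "0"]), 1, tolerance = 1e-8)
  expect_true(all(tn >= 0 & tn <= 1))
})

test_that("cross-class similarity is below same-class for disjoint content", {
  # two classes with disjoint foreground supports
  mk <- function(block) lapply(1:6, function(k) {
    m <- matrix(0, 16, 16)
    if (block == "top") m[2:7, (k):(k + 5)] <- 1
    else m[10:15, (k):(k + 5)] <- 1
    m
  })
  gal <- list(A = gait_sequence(mk("top")), B = gait_sequence(mk("bottom")))
  probe <- gait_sequence(mk("top"))
  tn <- similarity_tensor(gal, probe, build_rotation_grid(0), K = 6,
                          DG = 4, DP = 4, R = 1, dg_axis = 3, dp_axis = 3)
  expect_gt(tn["A", 1, 1, 1, 1], tn["B", 1, 1, 1, 1])
})

test_that("weak classifiers take the argmax with deterministic ties", {
  tn <- toy_tensor(matrix(c(0.9, 0.3), 2, 1,
                          dimnames = list(c("A", "B"), NULL)), thetas = 0)
  expect_equal(weak_classify(tn, list(r = 1, dg = 1, dp = 1, theta = 0)), "A")
  tie <- toy_tensor(matrix(c(0.5, 0.5), 2, 1,
                           dimnames = list(c("B", "A"), NULL)), thetas = 0)
  expect_message(
    lab <- weak_classify(tie, list(r = 1, dg = 1, dp = 1, theta = 0)), "tie")
  expect_equal(lab, "A")
  expect_error(weak_classify(tn, list(r = 1, dg = 2, dp = 1, theta = 0)),
               "off the tensor grid")
})

test_that("zero-noise equal-speed weak classification is perfect", {
  b <- small_bench()
  grid <- build_rotation_grid(0)
  model <- build_gallery_model(b$gallery, grid, K = 8, DG = 20)
  preds <- vapply(b$probes, function(p) {
    tn <- similarity_tensor(probe = p, model = model, DP = 20, R = 1,
                            dg_axis = 20, dp_axis = 20)
    suppressMessages(weak_classify(tn, list(r = 1, dg = 20, dp = 20,
                                            theta = 0)))
  }, character(1))
  expect_equal(unname(preds), b$labels$class_id)
})

test_that("a probe's similarity to class c responds only to class c's model", {
  b <- small_bench()
  probe <- b$probes[[1]]
  grid <- build_rotation_grid(0)
  args <- list(probe = probe, grid = grid, K = 8, DG = 10, DP = 10, R = 1,
               dg_axis = 8, dp_axis = 8)
  t1 <- do.call(similarity_tensor, c(list(gallery = b$gallery[1:2]), args))
  swapped <- list(S01 = b$gallery[[1]], S02 = b$gallery[[3]])
  t2 <- do.call(similarity_tensor, c(list(gallery = swapped), args))
  expect_equal(t1["S01", , , , ], t2["S01", , , , ])
  expect_false(isTRUE(all.equal(t1["S02", , , , ], t2["S02", , , , ])))
})
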