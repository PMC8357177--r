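test_that("weights initialize uniformly and errors sum over failures", {
  expect_equal(init_weights(4), rep(0.25, 4))
  expect_equal(init_weights(1), 1)
  expect_error(init_weights(0), "at least one")
  for (n in c(3, 7, 11)) expect_equal(sum(init_weights(n)), 1)

  w <- rep(0.1, 10)
  pred <- c(rep("A", 7), rep("B", 3)); truth <- rep("A", 10)
  expect_equal(weighted_error(pred, truth, w), 0.3)
  expect_equal(weighted_error(truth, truth, w), 0)
  expect_equal(weighted_error(c("A", "B"), c("A", "A"), c(0.7, 0.3)), 0.3)
  expect_error(weighted_error(c("A"), c("A", "B"), c(1)), "equal length")
})

test_that("confidence follows the log-odds with divergence clamping", {
  expect_equal(confidence(0.5, 10), 0)
  expect_equal(confidence(0.1, 10), 0.5 * log(9))
  # eps = 0 is clamped to 1/(2*10) = 0.05
  expect_message(a <- confidence(0, 10), "clamped")
  expect_equal(a, 0.5 * log(19))
  expect_message(a1 <- confidence(1, 10), "clamped")
  expect_equal(a1, -0.5 * log(19))
})

test_that("weight updates renormalize and concentrate on mistakes", {
  w <- rep(0.25, 4)
  expect_equal(update_weights(w, 0, c(TRUE, TRUE, FALSE, FALSE)), w)
  expect_equal(update_weights(w, 1.3, rep(TRUE, 4)), w)
  expect_equal(update_weights(c(0.5, 0.5), 0.5 * log(9), c(TRUE, FALSE)),
               c(0.1, 0.9))
  expect_error(update_weights(c(0, 0), 1, c(TRUE, TRUE)), "all-zero")

  # conservation and the half-mass property over random rounds
  set.seed(12)
  for (rep in 1:10) {
    n <- 8
    w <- init_weights(n)
    for (t in 1:5) {
      correct <- stats::runif(n) > 0.4
      if (all(correct) || !any(correct)) next
      eps <- sum(w[!correct])
      alpha <- suppressMessages(confidence(eps, n))
      w <- update_weights(w, alpha, correct)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      if (alpha > 0 && eps > 0)
        expect_equal(sum(w[!correct]), 0.5, tolerance = 1e-10)
    }
  }
})

test_that("boosting selects minimal-error classifiers deterministically", {
  # weak pool of 3 (thetas 0/10/20); classifier at theta 0 is perfect
  classes <- c("A", "B")
  mk <- function(v) toy_tensor(matrix(v, 2, 3,
                                      dimnames = list(classes, NULL)),
                               thetas = c(0, 10, 20))
  t1 <- mk(c(0.9, 0.1, 0.2, 0.8, 0.6, 0.4))  # theta0 -> A, theta10 -> B, theta20 -> A
  t2 <- mk(c(0.2, 0.8, 0.3, 0.7, 0.9, 0.1))  # theta0 -> B, theta10 -> B, theta20 -> A
  H <- suppressMessages(fit_boost(list(t1, t2), c("A", "B"), T = 1))
  expect_equal(nrow(H$rounds), 1)
  expect_equal(H$rounds$theta[1], 0)
  expect_equal(H$rounds$epsilon[1], 0)
  expect_equal(H$rounds$alpha[1], 0.5 * log(3))  # eps clamped to 1/(2*2)

  # two equal-error classifiers: the earlier grid position wins
  t3 <- mk(c(0.9, 0.1, 0.9, 0.1, 0.1, 0.9))
  t4 <- mk(c(0.1, 0.9, 0.1, 0.9, 0.9, 0.1))
  H2 <- suppressMessages(fit_boost(list(t3, t4), c("A", "B"), T = 1))
  expect_equal(H2$rounds$theta[1], 0)

  expect_identical(suppressMessages(fit_boost(list(t1, t2), c("A", "B"), 5)),
                   suppressMessages(fit_boost(list(t1, t2), c("A", "B"), 5)))
  expect_error(fit_boost(list(t1, t2), c("A", "A"), 2), ">= 2 classes")
})

test_that("training accuracy of the fused classifier does not degrade", {
  set.seed(13)
  classes <- c("A", "B", "C")
  truth <- rep(classes, times = 4)
  tensors <- lapply(truth, function(tr) {
    sims <- matrix(stats::runif(3 * 6, 0, 0.6), 3, 6,
                   dimnames = list(classes, NULL))
    # each weak classifier is right on a random 70% of probes
    for (j in 1:6) if (stats::runif(1) < 0.7)
      sims[tr, j] <- stats::runif(1, 0.7, 1)
    toy_tensor(sims, thetas = (1:6) * 5)
  })
  H <- suppressMessages(fit_boost(tensors, truth, T = 10))
  expect_gte(H$train_ccr[length(H$train_ccr)], H$train_ccr[1])
  # fusion is at least as accurate on training data as its best single round
  best_single <- max(vapply(seq_len(nrow(H$rounds)), function(k) {
    p <- H$rounds[k, c("r", "dg", "dp", "theta")]
    mean(vapply(seq_along(tensors), function(i)
      suppressMessages(weak_classify(tensors[[i]], p)), character(1)) ==
        truth)
  }, numeric(1)))
  expect_gte(H$train_ccr[length(H$train_ccr)] + 1e-12, best_single)
})

test_that("the strong vote weighs rounds by confidence with stable ties", {
  classes <- c("A", "B")
  tn <- toy_tensor(matrix(c(0.9, 0.1, 0.2, 0.8, 0.3, 0.7), 2, 3,
                          dimnames = list(classes, NULL)),
                   thetas = c(0, 10, 20))
  mkH <- function(rounds) structure(
    list(rounds = rounds, class_set = classes), class = "strong_classifier")
  # single round: reduces to that weak classifier
  H1 <- mkH(data.frame(t = 1, r = 1, dg = 1, dp = 1, theta = 0, alpha = 1,
                       epsilon = 0))
  expect_equal(strong_classify(H1, tn)$label, "A")
  # A with alpha 2 beats B with 1 + 0.5
  H2 <- mkH(data.frame(t = 1:3, r = 1, dg = 1, dp = 1,
                       theta = c(0, 10, 20), alpha = c(2, 1, 0.5),
                       epsilon = 0.1))
  r2 <- strong_classify(H2, tn)
  expect_equal(r2$label, "A")
  expect_equal(unname(r2$scores), c(2, 1.5))
  # exact tie goes to the lexicographically first class
  H3 <- mkH(data.frame(t = 1:2, r = 1, dg = 1, dp = 1, theta = c(0, 10),
                       alpha = c(1, 1), epsilon = 0.1))
  expect_message(r3 <- strong_classify(H3, tn), "tie")
  expect_equal(r3$label, "A")
  # a round off the tensor grid is an error
  H4 <- mkH(data.frame(t = 1, r = 1, dg = 1, dp = 1, theta = 55, alpha = 1,
                       epsilon = 0))
  expect_error(strong_classify(H4, tn), "off the tensor grid")
})

test_that("strong classifiers survive a JSON round trip", {
  rounds <- data.frame(t = 1:2, r = c(1, 2), dg = c(10, 20), dp = c(10, 10),
                       theta = c(-10, 20), alpha = c(1.2, 0.4),
                       epsilon = c(0.1, 0.3))
  H <- structure(list(rounds = rounds, class_set = c("A", "B"),
                      train_ccr = c(0.8, 0.9)),
                 class = "strong_classifier")
  p <- tempfile(fileext = ".json")
  write_strong_classifier(H, p)
  H2 <- read_strong_classifier(p)
  expect_equal(H2$rounds, H$rounds)
  expect_equal(H2$class_set, H$class_set)
})
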