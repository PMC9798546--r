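# class weights, weighted BCE, supervised contrastive loss

test_that("class weights follow (N - P) / P per target", {
  # the odor dataset's most frequent label: 1334 positives of 4365 samples
  lab <- matrix(0L, 4365, 1, dimnames = list(NULL, "fruity"))
  lab[seq_len(1334), 1] <- 1L
  expect_equal(unname(compute_class_weights(lab)), 3031 / 1334,
               tolerance = 1e-12)
  expect_equal(round(unname(compute_class_weights(lab)), 4), 2.2721)
  # balanced target -> weight 1; all-positive -> 0
  bal <- cbind(a = rep(c(0L, 1L), 50), b = rep(1L, 100))
  expect_equal(unname(compute_class_weights(bal)), c(1, 0))
  # scale invariance under dataset duplication
  expect_equal(compute_class_weights(rbind(bal, bal)),
               compute_class_weights(bal))
  expect_error(compute_class_weights(cbind(z = rep(0L, 10))), "z")
})

test_that("weighted BCE matches analytic values and a summation oracle", {
  # perfect fit
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(weighted_bce(y, y), 1e-6)
  # single sample, y = 1, p = 0.5, w = 2 -> 2 log 2
  expect_equal(weighted_bce(matrix(0.5), matrix(1), 2), 2 * log(2),
               tolerance = 1e-12)
  # random instance against an element-by-element hand summation
  withr::with_seed(10, {
    p <- matrix(runif(12), 4, 3)
    y <- matrix(rbinom(12, 1, 0.5), 4, 3)
    w <- c(2, 0.5, 1.7)
  })
  acc <- 0
  for (i in 1:4) for (t in 1:3)
    acc <- acc - (w[t] * y[i, t] * log(p[i, t]) +
                    (1 - y[i, t]) * log(1 - p[i, t]))
  expect_equal(weighted_bce(p, y, w), acc / 12, tolerance = 1e-12)
})

test_that("contrastive loss: trivial batches, oracle agreement, invariances", {
  # two samples, same label, identical unit vectors: log(1) = 0
  z <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(contrastive_loss(z, c(1, 1), tau = 1), 0)
  # two samples with different labels: empty positive sets contribute 0
  expect_equal(contrastive_loss(z, c(1, 0), tau = 1), 0)
  # batch of 1: warning and 0
  expect_warning(l1 <- contrastive_loss(z[1, , drop = FALSE], 1), "at least 2")
  expect_equal(l1, 0)
  # brute-force double-loop oracle on random batches
  withr::with_seed(11, {
    for (rep in 1:20) {
      B <- sample(3:8, 1)
      z <- matrix(rnorm(B * 6), B, 6)
      z <- z / sqrt(rowSums(z^2))
      y <- rbinom(B, 1, 0.5)
      tau <- runif(1, 0.3, 1.2)
      expect_equal(contrastive_loss(z, y, tau), oracle_contrastive(z, y, tau),
                   tolerance = 1e-8)
    }
  })
  # rotation invariance: depends only on inner products
  withr::with_seed(12, {
    z <- matrix(rnorm(5 * 4), 5, 4)
    z <- z / sqrt(rowSums(z^2))
    y <- c(1, 1, 0, 0, 1)
    R <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  })
  expect_equal(contrastive_loss(z, y, 0.7), contrastive_loss(z %*% R, y, 0.7),
               tolerance = 1e-10)
  # pulling a same-label pair together lowers the loss
  a <- c(1, 0, 0); b <- c(0, 1, 0); o <- c(0, 0, 1)
  close_b <- (a + 0.5 * b) / sqrt(sum((a + 0.5 * b)^2))
  far <- contrastive_loss(rbind(a, b, o), c(1, 1, 0), 0.7)
  near <- contrastive_loss(rbind(a, close_b, o), c(1, 1, 0), 0.7)
  expect_lt(near, far)
})

test_that("total loss composes BCE and the per-target contrastive term", {
  withr::with_seed(13, {
    B <- 6; Tn <- 2; d <- 5
    p <- matrix(runif(B * Tn), B, Tn)
    y <- matrix(rbinom(B * Tn, 1, 0.5), B, Tn)
    feats <- lapply(1:Tn, function(t) matrix(rnorm(B * d), B, d))
    w <- c(1.5, 2)
  })
  tl <- total_loss(p, feats, y, w, tau = 0.7, contrastive_weight = 0.8)
  con <- mean(vapply(1:Tn, function(t)
    oracle_contrastive(feats[[t]] / sqrt(rowSums(feats[[t]]^2)), y[, t], 0.7),
    0))
  expect_equal(tl$total, weighted_bce(p, y, w) + 0.8 * con, tolerance = 1e-8)
  expect_gte(tl$total, tl$bce)  # contrastive term is nonnegative here
  # weight 0 disables the term exactly
  tl0 <- total_loss(p, feats, y, w, tau = 0.7, contrastive_weight = 0)
  expect_identical(tl0$total, weighted_bce(p, y, w))
})
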