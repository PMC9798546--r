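# attention summation, localization, ensemble counters, rendering

uniform_record <- function(L, H, n) array(1 / n, c(L, H, n))

test_that("summed attention conserves total mass n_heads * n_layers", {
  r <- uniform_record(2, 3, 10)
  expect_equal(sum_attention(r), rep(2 * 3 / 10, 10))
  # single-atom molecule gets all the mass
  r1 <- uniform_record(2, 3, 1)
  expect_equal(sum_attention(r1), 6)
  # random record: total equals heads x layers
  rr <- withr::with_seed(30, {
    a <- array(rexp(4 * 2 * 7), c(4, 2, 7))
    sweep(a, c(1, 2), apply(a, c(1, 2), sum), "/")
  })
  expect_equal(sum(sum_attention(rr)), 4 * 2, tolerance = 1e-6)
  expect_error(sum_attention(list()), "empty")
})

test_that("localization statistics match the direct elementwise oracle", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      L <- sample(1:3, 1); H <- sample(1:4, 1); n <- sample(4:12, 1)
      a <- array(rexp(L * H * n), c(L, H, n))
      a <- sweep(a, c(1, 2), apply(a, c(1, 2), sum), "/")
      T_set <- sort(sample(n, sample(2:3, 1)))
      fast <- localization_stats(a, T_set)
      slow <- oracle_localization(a, T_set)
      expect_equal(fast$attn_sum, slow$attn_sum, tolerance = 1e-10)
      expect_equal(fast$normalized, slow$normalized, tolerance = 1e-10)
      expect_equal(fast$variance, slow$variance, tolerance = 1e-10)
      expect_gte(fast$normalized, 0)
      expect_lte(fast$normalized, 1 + 1e-12)
    }
  })
})

test_that("localization under uniform and concentrated attention", {
  # uniform attention, N = 10, |T| = 4 -> normalized = |T|/N = 0.4
  r <- uniform_record(2, 3, 10)
  expect_equal(localization_stats(r, 1:4)$normalized, 0.4)
  # all mass on the target atoms -> normalized = 1
  conc <- array(0, c(1, 2, 6))
  conc[1, , 1:2] <- 0.5
  expect_equal(localization_stats(conc, 1:2)$normalized, 1)
  # the printed variance mixes scales: uniform-over-target attention is NOT 0
  only_t <- array(0, c(2, 2, 5))
  only_t[, , 1:2] <- 0.5
  st <- localization_stats(only_t, 1:2)
  expect_equal(st$variance, oracle_localization(only_t, 1:2)$variance)
  expect_gt(st$variance, 0)
  # the corrected variant is 0 for uniform target attention
  expect_equal(localization_stats(only_t, 1:2, corrected = TRUE)$variance, 0)
  expect_error(localization_stats(r, integer(0)), "empty")
  expect_error(localization_stats(r, 11), "out of range")
})

test_that("ensemble top-k counters match a per-model sort oracle", {
  withr::with_seed(32, {
    M <- 7; k <- 3
    ids <- paste0("mol", 1:5)
    sizes <- c(8, 2, 5, 10, 4)
    recs <- lapply(1:M, function(m) {
      v <- lapply(sizes, function(n) rexp(n))
      names(v) <- ids
      v
    })
  })
  counter <- ensemble_topk_counts(recs, k = k)
  # brute-force recount
  for (i in seq_along(ids)) {
    expected <- integer(sizes[i])
    for (m in 1:M) {
      v <- recs[[m]][[ids[i]]]
      top <- head(order(v, decreasing = TRUE), min(k, length(v)))
      expected[top] <- expected[top] + 1L
    }
    expect_equal(unname(counter[[ids[i]]]), expected)
    expect_equal(sum(counter[[ids[i]]]), M * min(k, sizes[i]))
    expect_true(all(counter[[ids[i]]] <= M))
  }
  # unanimous top atom reaches the model count
  rec_same <- lapply(1:4, function(m) list(x = c(0.1, 0.9)))
  c2 <- ensemble_topk_counts(rec_same, k = 1)
  expect_equal(unname(c2$x), c(0L, 4L))
  # ties break toward the lower atom index
  rec_tie <- lapply(1:2, function(m) list(x = c(0.5, 0.5, 0.1)))
  ct <- ensemble_topk_counts(rec_tie, k = 1)
  expect_equal(unname(ct$x), c(2L, 0L, 0L))
  expect_error(ensemble_topk_counts(list(list(a = 1:3), list(b = 1:3))),
               "different molecule sets")
})

test_that("annotated-atom selection is strictly greater-than n", {
  counter <- structure(list(m1 = c(51L, 50L, 0L, 77L)), M = 100L, k = 5L,
                       class = "atom_counter")
  sel <- select_annotated_atoms(counter, n = 50)
  expect_equal(sel$m1, c(1L, 4L))     # 51 in, 50 out, 0 never
  expect_warning(select_annotated_atoms(counter, n = 100), "no atom")
})

test_that("TP/TN selection honors the quorums and scales them", {
  y <- cbind(t = c(1, 1, 0, 0))
  votes <- c(90, 89, 15, 20)  # positive votes out of 100 models
  preds <- lapply(1:100, function(m)
    cbind(t = as.integer(m <= votes)))
  sel <- select_tp_tn(preds, y)[["t"]]
  expect_equal(sel$tp, 1L)               # 90/100 in, 89/100 out
  expect_equal(sel$tn, 3L)               # 85 negatives required: 85 in, 80 out
  # quorum scaling at M = 10: ceil(90/100*10) = 9, ceil(85/100*10) = 9
  preds10 <- lapply(1:10, function(m) cbind(t = as.integer(m <= c(9, 8, 2, 0))))
  sel10 <- select_tp_tn(preds10, y)[["t"]]
  expect_equal(sel10$tp, 1L)             # 9/10 in, 8/10 out
  expect_equal(sel10$tn, 4L)             # 8 negative votes < 9 excludes row 3
  expect_error(select_tp_tn(preds10, y, tp_quorum = 101), "exceeds")
})

test_that("attention rendering is deterministic and monotone in shade", {
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_attention("CCO", c(0, 0.5, 1), f1)
  render_attention("CCO", c(0, 0.5, 1), f2)
  expect_identical(readLines(f1), readLines(f2))
  svg <- readLines(f1)
  expect_true(any(grepl("<svg", svg)))
  # all-equal values -> identical circle fills
  fe <- withr::local_tempfile(fileext = ".svg")
  render_attention("CCO", c(2, 2, 2), fe)
  fills <- regmatches(readLines(fe), regexpr('fill="rgb[^"]*"', readLines(fe)))
  expect_length(unique(fills), 1)
  # exactly one nonzero value -> exactly one fully shaded circle
  fo <- withr::local_tempfile(fileext = ".svg")
  render_attention("CCO", c(0, 1, 0), fo)
  lines <- grep("circle", readLines(fo), value = TRUE)
  expect_length(grep('fill="rgb(0,102,255)"', lines, fixed = TRUE), 1)
  expect_length(grep('fill="rgb(255,255,255)"', lines, fixed = TRUE), 2)
  expect_error(render_attention("CCO", c(-1, 0, 0), f1), "nonnegative")
  expect_error(render_attention("CCO", c(1, 0), f1), "3 atoms")
})
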