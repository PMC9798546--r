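# splitting, metrics, training loop, randomization test

test_that("5:1 splits have ceiling sizes, are disjoint, and are seeded", {
  s600 <- split_dataset(600, seed = 3)
  expect_length(s600$train, 500)
  expect_length(s600$test, 100)
  s7 <- split_dataset(7, seed = 3)
  expect_length(s7$train, 6)
  expect_length(s7$test, 1)
  expect_setequal(c(s7$train, s7$test), 1:7)
  expect_identical(split_dataset(100, seed = 42), split_dataset(100, seed = 42))
  expect_false(identical(split_dataset(100, seed = 1),
                         split_dataset(100, seed = 2)))
  df <- data.frame(x = 1:12)
  sd <- split_dataset(df, seed = 1)
  expect_equal(nrow(sd$train), 10)
  expect_equal(sort(c(sd$train$x, sd$test$x)), 1:12)
  expect_error(split_dataset(10, ratio = c(-1, 1)), "positive")
})

test_that("F1 metrics follow the counts and aggregate correctly", {
  y <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  perfect <- metrics_report(y, y)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$micro_f1, 1)
  # all-negative predictions with positives present: F1 = 0
  allneg <- metrics_report(y * 0, y)
  expect_equal(allneg$per_target$f1, c(0, 0))
  # counts TP=8, FP=2, FN=2 -> F1 = 0.8
  expect_equal(molattn:::f1_from_counts(8, 2, 2), 0.8)
  # micro == per-target F1 with a single target
  y1 <- cbind(t = c(1, 0, 1, 1, 0))
  p1 <- cbind(t = c(1, 1, 0, 1, 0))
  r1 <- metrics_report(p1, y1)
  expect_equal(r1$micro_f1, r1$per_target$f1[1])
  # all-NA target excluded from the macro mean
  yna <- cbind(a = c(1, 0, 1), b = c(NA, NA, NA))
  rna <- metrics_report(cbind(c(1, 0, 1), c(1, 1, 1)), yna)
  expect_true(is.na(rna$per_target$f1[2]))
  expect_equal(rna$macro_f1, rna$per_target$f1[1])
})

test_that("a separable toy task trains to high validation F1 with decreasing loss", {
  # label = molecule contains sulfur: linear in one identity feature bin
  smi <- withr::with_seed(21, as.character(generate_molecules(
    generator_config(400, seed = 77, target_prevalence = c("S" = 0.4)))))
  data <- prepare_molecules(smi, list(target_spec("has_sulfur", "S")),
                            embed_seed = 7)
  cfg <- molattn_config(n_heads = 2, head_dim = 8, n_encoder_layers = 1,
                        max_epochs = 20, learning_rate = 1e-3,
                        contrastive_weight = 0, batch_size = 32, seed = 2)
  fit <- molattn(data, cfg)
  expect_gte(max(fit$log$val_macro_f1, na.rm = TRUE), 0.99)
  # training loss decreases over the first epochs
  expect_lt(fit$log$total[3], fit$log$total[1])
  # early stopping never returns a checkpoint below a previously seen F1
  expect_equal(fit$best_val_macro_f1, max(fit$log$val_macro_f1, na.rm = TRUE))
})

test_that("training is deterministic for a fixed seed", {
  gs <- fixture_graphs(c("ethanol", "benzene", "ethyl_acetate", "peroxide",
                         "neopentane", "toluene", "acetic", "cysteamine",
                         "isopentane", "chiral"))
  labs <- label_substructures(vapply(gs, `[[`, "", "smiles"),
                              list(target_spec("oxy", "O")))
  d <- list(graphs = gs, labels = labs)
  cfg <- molattn_config(n_heads = 2, head_dim = 4, n_encoder_layers = 1,
                        max_epochs = 3, batch_size = 4,
                        validation_fraction = 0.2, seed = 31)
  f1 <- molattn(d, cfg)
  f2 <- molattn(d, cfg)
  expect_identical(f1$log, f2$log)
  expect_equal(f1$params, f2$params)
})

test_that("randomization test: identity, exhaustive oracle, symmetry, range", {
  y <- cbind(c(1, 0, 1, 0), c(1, 1, 0, 0))
  A <- cbind(c(1, 0, 1, 1), c(1, 0, 0, 0))
  # identical predictions -> p = 1
  expect_equal(approx_randomization_test(A, A, y, n_iter = 99)$p_value, 1)
  B <- cbind(c(1, 0, 0, 0), c(1, 1, 0, 1))
  res <- approx_randomization_test(A, B, y, n_iter = 2000, seed = 5)
  # exhaustive enumeration over the 2^4 swap patterns
  stat <- function(pa, pb) abs(molattn:::macro_f1(pa, y) -
                                 molattn:::macro_f1(pb, y))
  exact <- mean(vapply(0:15, function(m) {
    swap <- as.logical(bitwAnd(m, 2^(0:3)))
    Ai <- A; Bi <- B
    Ai[swap, ] <- B[swap, , drop = FALSE]
    Bi[swap, ] <- A[swap, , drop = FALSE]
    stat(Ai, Bi) >= res$observed - 1e-12
  }, TRUE))
  se <- sqrt(exact * (1 - exact) / res$n_iter)
  expect_lt(abs(res$p_value - exact), 3 * se + 1 / (res$n_iter + 1))
  # p is invariant to exchanging A and B, and lies in (0, 1]
  res_ba <- approx_randomization_test(B, A, y, n_iter = 2000, seed = 5)
  expect_equal(res$p_value, res_ba$p_value)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_error(approx_randomization_test(A, B[1:3, ], y), "dimensions")
})
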