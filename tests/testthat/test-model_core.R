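# attention variants, encoder/decoder forward, gradients

test_that("g(d) is exp(-d) on [0, inf)", {
  expect_equal(g_dist(0), 1)
  expect_equal(g_dist(log(2)), 0.5)
  expect_equal(g_dist(1.5), exp(-1.5))
  expect_error(g_dist(-0.1), "nonnegative")
})

test_that("single atom: adjacency branch is annihilated, dist branch passes V", {
  dm <- 8
  w <- withr::with_seed(1, rand_attn_weights(dm, "proposed", with_wo = FALSE))
  X <- matrix(rnorm(dm), 1, dm)
  out <- encoder_attention(X, matrix(0, 1, 1), matrix(0, 1, 1), w, n_heads = 2,
                           variant = "proposed")
  # softmax of a singleton is 1 and g(0) = 1, so output is V_dist exactly
  expect_equal(out, X %*% w$dist$Wv, tolerance = 1e-12)
})

test_that("a bond-free molecule reduces the dual branch to the distance branch", {
  dm <- 8
  withr::with_seed(2, {
    w <- rand_attn_weights(dm, "proposed", with_wo = FALSE)
    X <- matrix(rnorm(4 * dm), 4, dm)
    gm <- rand_graph_mats(4)
  })
  A0 <- matrix(0, 4, 4)
  both <- encoder_attention(X, A0, gm$D, w, 2, "proposed")
  dist_only <- encoder_attention(X, A0, gm$D, w$dist, 2, "dist_only")
  expect_equal(both, dist_only, tolerance = 1e-12)
})

test_that("all attention variants match the brute-force pairwise oracle", {
  dm <- 8
  for (variant in c("proposed", "mat_attn", "adj_only", "dist_only")) {
    withr::with_seed(7, {
      for (rep in 1:5) {
        n <- sample(2:5, 1)
        X <- matrix(rnorm(n * dm), n, dm)
        gm <- rand_graph_mats(n)
        w <- rand_attn_weights(dm, variant)
        lam <- if (variant == "mat_attn") c(0.5, 0.3, 0.2)
        fast <- encoder_attention(X, gm$A, gm$D, w, 2, variant, lambdas = lam)
        slow <- oracle_encoder_attention(X, gm$A, gm$D, w, 2, variant,
                                         lambdas = lam)
        expect_lt(max(abs(fast - slow)), 1e-6)
      }
    })
  }
})

test_that("MAT attention reduces correctly at extreme lambdas", {
  dm <- 8
  withr::with_seed(3, {
    n <- 4
    X <- matrix(rnorm(n * dm), n, dm)
    gm <- rand_graph_mats(n)
    w <- rand_attn_weights(dm, "adj_only", with_wo = FALSE)
  })
  # lambda = (1,0,0): plain softmax attention = dist_only with g(D) == 1
  plain <- encoder_attention(X, gm$A, matrix(0, n, n), w, 2, "dist_only")
  mat100 <- encoder_attention(X, gm$A, gm$D, w, 2, "mat_attn",
                              lambdas = c(1, 0, 0))
  expect_equal(mat100, plain, tolerance = 1e-10)
  # lambda = (0,0,1) with A = I: output is V
  mat001 <- encoder_attention(X, diag(n), gm$D, w, 2, "mat_attn",
                              lambdas = c(0, 0, 1))
  expect_equal(mat001, X %*% w$Wv, tolerance = 1e-10)
})

test_that("encoder is permutation-equivariant, predictions permutation-invariant", {
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  g <- fixture_graphs("ethyl_acetate")[[1]]
  n <- g$n_atoms
  perm <- withr::with_seed(4, sample(n))
  gp <- g
  gp$features <- g$features[perm, , drop = FALSE]
  gp$adjacency <- g$adjacency[perm, perm]
  gp$distance <- g$distance[perm, perm]
  f1 <- molattn:::molattn_forward(params, build_batch(list(g)), cfg)
  f2 <- molattn:::molattn_forward(params, build_batch(list(gp)), cfg)
  expect_equal(f2$enc, f1$enc[perm, , drop = FALSE], tolerance = 1e-10)
  expect_equal(f2$probs, f1$probs, tolerance = 1e-10)
})

test_that("forward is deterministic with dropout disabled", {
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  b <- fixture_batch()
  f1 <- molattn:::molattn_forward(params, b, cfg, training = TRUE)
  f2 <- molattn:::molattn_forward(params, b, cfg, training = TRUE)
  expect_identical(f1$probs, f2$probs)
})

test_that("decoder attention: singleton, sum-to-one, uniform under equal keys", {
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  # single-atom molecule: all attention on the one atom
  d1 <- decoder_module(matrix(rnorm(cfg$d_model), 1), params, cfg, target = 1)
  expect_equal(as.numeric(d1$attention), rep(1, cfg$n_heads))
  # sums to 1 over real atoms for every layer and head
  fwd <- molattn:::molattn_forward(params, fixture_batch(), cfg)
  for (t in 1:3) {
    P <- fwd$attention[[t]][[1]]
    for (b in seq_len(dim(P)[3]))
      expect_equal(unname(rowSums(P[, , b])), rep(1, cfg$n_heads),
                   tolerance = 1e-6)
  }
  # identical atom attributes -> uniform attention 1/n
  same <- matrix(1, 3, cfg$d_model)
  d3 <- decoder_module(same, params, cfg, target = 2)
  expect_equal(as.numeric(d3$attention), rep(1 / 3, cfg$n_heads * 3),
               tolerance = 1e-10)
  expect_error(decoder_module(same, params, cfg, target = 9), "out of range")
})

test_that("probabilities are in (0,1); duplicates in a batch agree; simplified
          decoder yields no attention", {
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  gs <- fixture_graphs(c("ethanol", "ethanol", "benzene"))
  fwd <- molattn:::molattn_forward(params, build_batch(gs), cfg)
  expect_true(all(fwd$probs > 0 & fwd$probs < 1))
  expect_equal(fwd$probs[1, ], fwd$probs[2, ], tolerance = 1e-12)
  scfg <- tiny_config(variant = "simplified_decoder")
  sparams <- tiny_params(scfg)
  sfwd <- molattn:::molattn_forward(sparams, build_batch(gs), scfg)
  expect_true(all(sfwd$probs > 0 & sfwd$probs < 1))
  expect_length(sfwd$attention[[1]], 0)
})

test_that("analytic gradients match finite differences (spot check)", {
  cfg <- molattn_config(n_heads = 2L, head_dim = 4L, n_encoder_layers = 1L,
                        n_decoder_layers = 1L, dropout = 0, seed = 5L,
                        contrastive_weight = 0.5)
  params <- tiny_params(cfg, n_targets = 2)
  labs <- matrix(c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0), 5, 2)
  b <- fixture_batch(n_targets = 2)
  b$labels <- labs
  w <- c(1.3, 0.8)
  lossfun <- function(pv) {
    p <- molattn:::unflatten_params(params, pv)
    fwd <- molattn:::molattn_forward(p, b, cfg, want_cache = TRUE)
    total_loss(fwd$probs, fwd$cls, labs, w, cfg$tau,
               cfg$contrastive_weight)$total
  }
  pv <- molattn:::flatten_params(params)
  fwd <- molattn:::molattn_forward(params, b, cfg, want_cache = TRUE)
  dlog <- molattn:::bce_grad_logits(fwd$probs, labs, w)
  dcls <- lapply(1:2, function(t)
    molattn:::contrastive_core(fwd$cls[[t]], labs[, t], cfg$tau)$dfeat *
      (cfg$contrastive_weight / 2))
  gv <- molattn:::flatten_params(
    molattn:::molattn_backward(params, b, cfg, fwd, dlog, dcls))
  idx <- withr::with_seed(9, sample(length(pv), 40))
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    a <- pv; a[i] <- a[i] + eps
    c2 <- pv; c2[i] <- c2[i] - eps
    (lossfun(a) - lossfun(c2)) / (2 * eps)
  }, 0)
  expect_lt(max(abs(num - gv[idx])), 1e-6)
})

test_that("checkpoints round-trip and refuse schema mismatches", {
  cfg <- tiny_config()
  obj <- structure(list(params = tiny_params(cfg), config = cfg,
                        target_names = c("a", "b", "c"),
                        schema = molattn:::feature_schema_hash()),
                   class = "molattn")
  path <- withr::local_tempfile(fileext = ".rds")
  save_molattn(obj, path)
  back <- load_molattn(path)
  expect_equal(back$params, obj$params)
  raw <- readRDS(path); raw$schema <- "0"
  saveRDS(raw, path)
  expect_error(load_molattn(path), "schema")
})
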