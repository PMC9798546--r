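# ---- forward pass ------------------------------------------------------------

# Stacked-matrix conventions: see src/attention_kernels.cpp. All dense algebra
# runs on (B*N) x d matrices through BLAS; only the per-molecule attention
# loops live in C++.

add_bias <- function(m, b) m + rep(b, each = nrow(m))

ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = add_bias(xhat * rep(g, each = nrow(x)), b), xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

drop_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix((runif(length(x)) >= rate) / (1 - rate), nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

drop_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

dummy_cube <- function() array(0, c(1, 1, 1))

#' Elementwise distance decay
#'
#' `g(d) = exp(-d)`: strictly decreasing, `g(0) = 1`, range (0, 1] for
#' nonnegative distances. Applied to the Euclidean distance matrix to gate the
#' distance attention branch.
#' @param d Nonnegative distances (angstroms).
#' @return `exp(-d)`.
#' @export
g_dist <- function(d) {
  if (any(d < 0)) stop("distances must be nonnegative")
  exp(-d)
}

# attention sublayer core for one encoder layer; X, outputs stacked (B*N) x dm
enc_attention_core <- function(X, lp, batch, config, want_cache = FALSE) {
  H <- config$n_heads
  nat <- batch$n_atoms
  v <- config$variant
  if (v %in% c("proposed", "simplified_decoder")) {
    QA <- X %*% lp$adj$Wq; KA <- X %*% lp$adj$Wk; VA <- X %*% lp$adj$Wv
    QD <- X %*% lp$dist$Wq; KD <- X %*% lp$dist$Wk; VD <- X %*% lp$dist$Wv
    aA <- .enc_attn_fwd(QA, KA, VA, batch$adjacency, dummy_cube(), nat, H,
                        0L, 0, 0, 0)
    aD <- .enc_attn_fwd(QD, KD, VD, batch$gdist, dummy_cube(), nat, H,
                        0L, 0, 0, 0)
    ctx <- aA$ctx + aD$ctx
    cache <- if (want_cache) list(QA = QA, KA = KA, VA = VA, PA = aA$P,
                                  QD = QD, KD = KD, VD = VD, PD = aD$P)
  } else if (v == "adj_only" || v == "dist_only") {
    Q <- X %*% lp$att$Wq; K <- X %*% lp$att$Wk; V <- X %*% lp$att$Wv
    M <- if (v == "adj_only") batch$adjacency else batch$gdist
    a <- .enc_attn_fwd(Q, K, V, M, dummy_cube(), nat, H, 0L, 0, 0, 0)
    ctx <- a$ctx
    cache <- if (want_cache) list(Q = Q, K = K, V = V, P = a$P)
  } else { # mat_attn
    Q <- X %*% lp$att$Wq; K <- X %*% lp$att$Wk; V <- X %*% lp$att$Wv
    a <- .enc_attn_fwd(Q, K, V, batch$gdist, batch$adjacency, nat, H, 1L,
                       config$lambda1, config$lambda2, config$lambda3)
    ctx <- a$ctx
    cache <- if (want_cache) list(Q = Q, K = K, V = V, P = a$P)
  }
  list(ctx = ctx, cache = cache)
}

enc_layer_fwd <- function(X, lp, batch, config, training, want_cache) {
  att <- enc_attention_core(X, lp, batch, config, want_cache)
  O <- add_bias(att$ctx %*% lp$Wo, lp$bo)
  dO <- drop_fwd(O, config$dropout, training)
  l1 <- ln_fwd(X + dO$y, lp$ln1_g, lp$ln1_b)
  X1 <- l1$y
  pre <- add_bias(X1 %*% lp$W1, lp$b1)
  H1 <- pmax(pre, 0)
  Fo <- add_bias(H1 %*% lp$W2, lp$b2)
  dF <- drop_fwd(Fo, config$dropout, training)
  l2 <- ln_fwd(X1 + dF$y, lp$ln2_g, lp$ln2_b)
  cache <- if (want_cache) {
    list(X = X, att = att$cache, ctx = att$ctx, mask_o = dO$mask, ln1 = l1,
         X1 = X1, pre = pre, H1 = H1, mask_f = dF$mask, ln2 = l2)
  }
  list(X = l2$y, cache = cache)
}

dec_layer_fwd <- function(Yq, K, V, lp, nat, config, training, want_cache) {
  H <- config$n_heads
  Qr <- Yq %*% lp$Wq
  a <- .dec_attn_fwd(Qr, K, V, nat, H)
  O <- add_bias(a$ctx %*% lp$Wo, lp$bo)
  dO <- drop_fwd(O, config$dropout, training)
  l1 <- ln_fwd(Yq + dO$y, lp$ln1_g, lp$ln1_b)
  Y1 <- l1$y
  pre <- add_bias(Y1 %*% lp$W1, lp$b1)
  H1 <- pmax(pre, 0)
  Fo <- add_bias(H1 %*% lp$W2, lp$b2)
  dF <- drop_fwd(Fo, config$dropout, training)
  l2 <- ln_fwd(Y1 + dF$y, lp$ln2_g, lp$ln2_b)
  cache <- if (want_cache) {
    list(Yq = Yq, Qr = Qr, P = a$P, ctx = a$ctx, mask_o = dO$mask, ln1 = l1,
         Y1 = Y1, pre = pre, H1 = H1, mask_f = dF$mask, ln2 = l2)
  }
  list(Y = l2$y, P = a$P, cache = cache)
}

# mask vector over stacked rows (1 = real atom)
stacked_mask <- function(batch) as.numeric(t(batch$atom_mask))

# Full forward pass.
# Returns probs (B x T), logits, cls (list per target of B x dm), attention
# (list per target: list per decoder layer of H x N x B softmax cubes), enc
# (stacked encoder output) and, when requested, the caches for backprop.
molattn_forward <- function(params, batch, config, training = FALSE,
                            want_cache = FALSE) {
  nat <- batch$n_atoms
  Tn <- ncol(params$out$W)
  X <- add_bias(batch$features %*% params$emb$W, params$emb$b)
  enc_caches <- if (want_cache) vector("list", config$n_encoder_layers)
  for (l in seq_len(config$n_encoder_layers)) {
    st <- enc_layer_fwd(X, params$enc[[l]], batch, config, training, want_cache)
    X <- st$X
    if (want_cache) enc_caches[[l]] <- st$cache
  }
  Enc <- X

  cls_feats <- vector("list", Tn)
  attention <- vector("list", Tn)
  logits <- matrix(0, batch$B, Tn)
  dec_caches <- NULL
  kv <- NULL
  pooled <- NULL
  mv <- NULL

  if (config$variant == "simplified_decoder") {
    mv <- stacked_mask(batch)
    pooled <- rowsum(Enc * mv, rep(seq_len(batch$B), each = batch$N))
    for (t in seq_len(Tn)) {
      logits[, t] <- pooled %*% params$out$W[, t] + params$out$b[t]
      cls_feats[[t]] <- pooled
      attention[[t]] <- list()
    }
  } else {
    shared <- config$share_decoder_weights
    if (shared) {
      kv <- lapply(seq_len(config$n_decoder_layers), function(l) {
        lp <- params$dec[[l]]
        list(K = Enc %*% lp$Wk, V = Enc %*% lp$Wv)
      })
    }
    if (want_cache) dec_caches <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      Yq <- matrix(params$cls[t, ], batch$B, config$d_model, byrow = TRUE)
      layer_caches <- if (want_cache) vector("list", config$n_decoder_layers)
      att_t <- vector("list", config$n_decoder_layers)
      for (l in seq_len(config$n_decoder_layers)) {
        lp <- if (shared) params$dec[[l]] else params$dec_t[[t]][[l]]
        if (shared) {
          Kl <- kv[[l]]$K; Vl <- kv[[l]]$V
        } else {
          Kl <- Enc %*% lp$Wk; Vl <- Enc %*% lp$Wv
        }
        st <- dec_layer_fwd(Yq, Kl, Vl, lp, nat, config, training, want_cache)
        Yq <- st$Y
        att_t[[l]] <- st$P
        if (want_cache) layer_caches[[l]] <- st$cache
      }
      cls_feats[[t]] <- Yq
      attention[[t]] <- att_t
      logits[, t] <- Yq %*% params$out$W[, t] + params$out$b[t]
      if (want_cache) dec_caches[[t]] <- layer_caches
    }
  }
  probs <- stats::plogis(logits)
  cache <- if (want_cache) list(enc = enc_caches, dec = dec_caches, Enc = Enc,
                                kv = kv, pooled = pooled, mv = mv)
  list(probs = probs, logits = logits, cls = cls_feats,
       attention = attention, enc = Enc, cache = cache)
}

#' Dual-branch masked encoder attention for one molecule
#'
#' Computes one multi-head attention sublayer exactly as the model defines it.
#' In the dual-branch (`"proposed"`) form, each head computes
#' `(softmax(Q_adj K_adj'/sqrt(d_k)) * A) V_adj +
#'  (softmax(Q_dist K_dist'/sqrt(d_k)) * g(D)) V_dist`,
#' where `*` is the elementwise product applied **after** the softmax with no
#' renormalization; `"adj_only"` and `"dist_only"` keep a single branch, and
#' `"mat_attn"` computes `(l1 softmax(QK'/sqrt(d_k)) + l2 g(D) + l3 A) V`.
#' Heads are concatenated and, if `weights$Wo` is given, linearly mixed.
#'
#' @param X Atom representation matrix (n x d_model).
#' @param A Binary adjacency matrix (zero diagonal).
#' @param D Euclidean distance matrix (angstroms).
#' @param weights For `"proposed"`: `list(adj=list(Wq,Wk,Wv),
#'   dist=list(Wq,Wk,Wv), Wo=, bo=)`; other variants: `list(Wq,Wk,Wv,Wo,bo)`.
#'   `Wo` may be `NULL` to return the raw concatenated head outputs.
#' @param n_heads Number of heads (must divide `ncol(X)`).
#' @param variant Attention variant.
#' @param lambdas Length-3 weights for `"mat_attn"`.
#' @return n x d_model matrix of attention outputs.
#' @export
encoder_attention <- function(X, A, D, weights, n_heads,
                              variant = c("proposed", "mat_attn", "adj_only",
                                          "dist_only"),
                              lambdas = NULL) {
  variant <- match.arg(variant)
  n <- nrow(X)
  if (!all(dim(A) == n) || !all(dim(D) == n)) stop("dimension mismatch")
  if (variant == "mat_attn" && length(lambdas) != 3)
    stop("mat_attn needs three lambda weights")
  cfg <- list(n_heads = n_heads, variant = variant,
              lambda1 = lambdas[1], lambda2 = lambdas[2],
              lambda3 = lambdas[3])
  batch <- list(adjacency = array(A, c(n, n, 1)),
                gdist = array(g_dist(D), c(n, n, 1)),
                n_atoms = n)
  lp <- if (variant == "proposed") list(adj = weights$adj, dist = weights$dist)
        else list(att = weights)
  out <- enc_attention_core(X, lp, batch, cfg)$ctx
  if (!is.null(weights$Wo))
    out <- add_bias(out %*% weights$Wo, weights$bo %||% numeric(ncol(out)))
  out
}

#' Decoder-like module for one molecule
#'
#' Runs the per-target decoder: the target's learnable query vector
#' cross-attends the encoder's atom attributes (no self-attention), followed
#' by the usual feedforward/residual/normalization, for each decoder layer.
#' Each head's attention over real atoms sums to 1.
#'
#' @param atom_attributes Encoder output for one molecule (n x d_model).
#' @param params Model parameters (as stored in a fitted model).
#' @param config A `molattn_config`.
#' @param target Target index (1-based).
#' @return `list(attribute_cls = d_model vector, attention = array
#'   [n_decoder_layers x n_heads x n])`.
#' @export
decoder_module <- function(atom_attributes, params, config, target = 1L) {
  n <- nrow(atom_attributes)
  Tn <- ncol(params$out$W)
  if (target < 1 || target > Tn) stop("target index out of range")
  nat <- n
  Yq <- matrix(params$cls[target, ], 1, config$d_model)
  att <- array(0, c(config$n_decoder_layers, config$n_heads, n))
  for (l in seq_len(config$n_decoder_layers)) {
    lp <- if (config$share_decoder_weights) params$dec[[l]]
          else params$dec_t[[target]][[l]]
    K <- atom_attributes %*% lp$Wk
    V <- atom_attributes %*% lp$Wv
    st <- dec_layer_fwd(Yq, K, V, lp, nat, config, training = FALSE,
                        want_cache = FALSE)
    Yq <- st$Y
    att[l, , ] <- st$P[, seq_len(n), 1]
  }
  list(attribute_cls = drop(Yq), attention = att)
}
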