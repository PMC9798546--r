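# ---- hand-derived backward pass ----------------------------------------------
#
# Mirrors molattn_forward() exactly; validated against finite differences in
# the test suite. Gradients for padded rows are zero by construction (the
# attention kernels only write real-atom rows and every other sublayer is
# rowwise), so padding contributes nothing to any parameter gradient.

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

ffn_bwd <- function(dd, cache, lp, gl, in_mat) {
  # dd: gradient of (input + dropout(FFN out)); returns list(dinput_extra, gl)
  dFo <- drop_bwd(dd, cache$mask_f)
  dH1 <- dFo %*% t(lp$W2)
  gl$W2 <- gl$W2 + t(cache$H1) %*% dFo
  gl$b2 <- gl$b2 + colSums(dFo)
  dpre <- dH1 * (cache$pre > 0)
  gl$W1 <- gl$W1 + t(in_mat) %*% dpre
  gl$b1 <- gl$b1 + colSums(dpre)
  list(dx = dpre %*% t(lp$W1), gl = gl)
}

molattn_backward <- function(params, batch, config, fwd, dlogits,
                             dcls = NULL) {
  grads <- zero_like(params)
  nat <- batch$n_atoms
  H <- config$n_heads
  Tn <- ncol(params$out$W)
  Enc <- fwd$cache$Enc
  dEnc <- matrix(0, nrow(Enc), ncol(Enc))

  if (config$variant == "simplified_decoder") {
    pooled <- fwd$cache$pooled
    grads$out$W <- t(pooled) %*% dlogits
    grads$out$b <- colSums(dlogits)
    dpooled <- dlogits %*% t(params$out$W)
    if (!is.null(dcls)) dpooled <- dpooled + Reduce(`+`, dcls)
    dEnc <- dpooled[rep(seq_len(batch$B), each = batch$N), , drop = FALSE] *
      fwd$cache$mv
  } else {
    shared <- config$share_decoder_weights
    nL <- config$n_decoder_layers
    if (shared) {
      dK_acc <- lapply(seq_len(nL), function(l) dEnc)
      dV_acc <- lapply(seq_len(nL), function(l) dEnc)
    }
    for (t in seq_len(Tn)) {
      Y2 <- fwd$cls[[t]]
      grads$out$W[, t] <- t(Y2) %*% dlogits[, t]
      grads$out$b[t] <- sum(dlogits[, t])
      dY <- dlogits[, t] %o% params$out$W[, t]
      if (!is.null(dcls)) dY <- dY + dcls[[t]]
      for (l in rev(seq_len(nL))) {
        cache <- fwd$cache$dec[[t]][[l]]
        lp <- if (shared) params$dec[[l]] else params$dec_t[[t]][[l]]
        gl <- if (shared) grads$dec[[l]] else grads$dec_t[[t]][[l]]
        l2b <- ln_bwd(dY, cache$ln2, lp$ln2_g)
        gl$ln2_g <- gl$ln2_g + l2b$dg; gl$ln2_b <- gl$ln2_b + l2b$db
        fb <- ffn_bwd(l2b$dx, cache, lp, gl, in_mat = cache$Y1)
        gl <- fb$gl
        dY1 <- l2b$dx + fb$dx
        l1b <- ln_bwd(dY1, cache$ln1, lp$ln1_g)
        gl$ln1_g <- gl$ln1_g + l1b$dg; gl$ln1_b <- gl$ln1_b + l1b$db
        dYq <- l1b$dx
        dO <- drop_bwd(l1b$dx, cache$mask_o)
        dctx <- dO %*% t(lp$Wo)
        gl$Wo <- gl$Wo + t(cache$ctx) %*% dO
        gl$bo <- gl$bo + colSums(dO)
        if (shared) {
          Kl <- fwd$cache$kv[[l]]$K; Vl <- fwd$cache$kv[[l]]$V
        } else {
          Kl <- Enc %*% lp$Wk; Vl <- Enc %*% lp$Wv
        }
        bw <- .dec_attn_bwd(dctx, cache$P, cache$Qr, Kl, Vl, nat, H)
        dYq <- dYq + bw$dQr %*% t(lp$Wq)
        gl$Wq <- gl$Wq + t(cache$Yq) %*% bw$dQr
        if (shared) {
          dK_acc[[l]] <- dK_acc[[l]] + bw$dK
          dV_acc[[l]] <- dV_acc[[l]] + bw$dV
          grads$dec[[l]] <- gl
        } else {
          dEnc <- dEnc + bw$dK %*% t(lp$Wk) + bw$dV %*% t(lp$Wv)
          gl$Wk <- gl$Wk + t(Enc) %*% bw$dK
          gl$Wv <- gl$Wv + t(Enc) %*% bw$dV
          grads$dec_t[[t]][[l]] <- gl
        }
        dY <- dYq
      }
      grads$cls[t, ] <- colSums(dY)
    }
    if (shared) {
      for (l in seq_len(nL)) {
        lp <- params$dec[[l]]
        dEnc <- dEnc + dK_acc[[l]] %*% t(lp$Wk) + dV_acc[[l]] %*% t(lp$Wv)
        grads$dec[[l]]$Wk <- t(Enc) %*% dK_acc[[l]]
        grads$dec[[l]]$Wv <- t(Enc) %*% dV_acc[[l]]
      }
    }
  }

  # encoder
  dX <- dEnc
  for (l in rev(seq_len(config$n_encoder_layers))) {
    cache <- fwd$cache$enc[[l]]
    lp <- params$enc[[l]]
    gl <- grads$enc[[l]]
    l2b <- ln_bwd(dX, cache$ln2, lp$ln2_g)
    gl$ln2_g <- l2b$dg; gl$ln2_b <- l2b$db
    fb <- ffn_bwd(l2b$dx, cache, lp, gl, in_mat = cache$X1)
    gl <- fb$gl
    dX1 <- l2b$dx + fb$dx
    l1b <- ln_bwd(dX1, cache$ln1, lp$ln1_g)
    gl$ln1_g <- l1b$dg; gl$ln1_b <- l1b$db
    dXin <- l1b$dx
    dO <- drop_bwd(l1b$dx, cache$mask_o)
    dctx <- dO %*% t(lp$Wo)
    gl$Wo <- t(cache$ctx) %*% dO
    gl$bo <- colSums(dO)
    X <- cache$X
    ac <- cache$att
    if (config$variant %in% c("proposed", "simplified_decoder")) {
      bwA <- .enc_attn_bwd(dctx, ac$PA, ac$QA, ac$KA, ac$VA, batch$adjacency,
                           dummy_cube(), nat, H, 0L, 0, 0, 0)
      bwD <- .enc_attn_bwd(dctx, ac$PD, ac$QD, ac$KD, ac$VD, batch$gdist,
                           dummy_cube(), nat, H, 0L, 0, 0, 0)
      dXin <- dXin +
        bwA$dQ %*% t(lp$adj$Wq) + bwA$dK %*% t(lp$adj$Wk) +
        bwA$dV %*% t(lp$adj$Wv) +
        bwD$dQ %*% t(lp$dist$Wq) + bwD$dK %*% t(lp$dist$Wk) +
        bwD$dV %*% t(lp$dist$Wv)
      gl$adj$Wq <- t(X) %*% bwA$dQ
      gl$adj$Wk <- t(X) %*% bwA$dK
      gl$adj$Wv <- t(X) %*% bwA$dV
      gl$dist$Wq <- t(X) %*% bwD$dQ
      gl$dist$Wk <- t(X) %*% bwD$dK
      gl$dist$Wv <- t(X) %*% bwD$dV
    } else {
      if (config$variant == "mat_attn") {
        bw <- .enc_attn_bwd(dctx, ac$P, ac$Q, ac$K, ac$V, batch$gdist,
                            batch$adjacency, nat, H, 1L, config$lambda1,
                            config$lambda2, config$lambda3)
      } else {
        M <- if (config$variant == "adj_only") batch$adjacency else batch$gdist
        bw <- .enc_attn_bwd(dctx, ac$P, ac$Q, ac$K, ac$V, M, dummy_cube(),
                            nat, H, 0L, 0, 0, 0)
      }
      dXin <- dXin + bw$dQ %*% t(lp$att$Wq) + bw$dK %*% t(lp$att$Wk) +
        bw$dV %*% t(lp$att$Wv)
      gl$att$Wq <- t(X) %*% bw$dQ
      gl$att$Wk <- t(X) %*% bw$dK
      gl$att$Wv <- t(X) %*% bw$dV
    }
    grads$enc[[l]] <- gl
    dX <- dXin
  }
  grads$emb$W <- t(batch$features) %*% dX
  grads$emb$b <- colSums(dX)
  grads
}
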