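# ---- configuration and parameter initialization -----------------------------

#' Model and training configuration
#'
#' One control object covering architecture, losses and optimization.
#' Defaults match the package's reference experiment (learning rate 7e-5,
#' dropout 0.1, contrastive temperature 0.7, 2 encoder layers of 4 heads x
#' 15 dims) with conventional optimizer settings (Adam, batch size 32, early
#' stopping with patience 10 on validation macro F1).
#'
#' @param n_heads Number of attention heads.
#' @param head_dim Dimension of a single head; model width is
#'   `n_heads * head_dim`.
#' @param n_encoder_layers,n_decoder_layers Encoder / decoder depth.
#' @param variant Attention variant: `"proposed"` (dual-branch masked
#'   attention), `"mat_attn"` (lambda-weighted sum of softmax attention,
#'   exp(-D) and A), `"adj_only"`, `"dist_only"`, or `"simplified_decoder"`
#'   (proposed encoder, decoder replaced by sum pooling).
#' @param lambda1,lambda2,lambda3 MAT attention weights (used by `mat_attn`).
#' @param dropout Dropout rate applied at the end of every attention and
#'   feedforward sublayer.
#' @param share_decoder_weights If `TRUE` (default) decoder layer weights are
#'   shared across targets and only the query vectors are per-target; set
#'   `FALSE` for fully separate decoder modules per target.
#' @param tau Supervised contrastive temperature.
#' @param contrastive_weight Weight of the contrastive term in the total
#'   loss; 0 disables it exactly.
#' @param learning_rate Adam learning rate.
#' @param batch_size,max_epochs,patience,validation_fraction Training loop
#'   controls; early stopping monitors validation macro F1.
#' @param threshold Probability threshold for binarizing predictions.
#' @param embed_seed Conformer embedding seed (recorded for provenance).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return A `molattn_config` list.
#' @export
molattn_config <- function(n_heads = 4L, head_dim = 15L,
                           n_encoder_layers = 2L, n_decoder_layers = 1L,
                           variant = c("proposed", "mat_attn", "adj_only",
                                       "dist_only", "simplified_decoder"),
                           lambda1 = 0.33, lambda2 = 0.33, lambda3 = 0.33,
                           dropout = 0.1, share_decoder_weights = TRUE,
                           tau = 0.7, contrastive_weight = 1.0,
                           learning_rate = 7e-5, batch_size = 32L,
                           max_epochs = 100L, patience = 10L,
                           validation_fraction = 0.1, threshold = 0.5,
                           embed_seed = 42L, seed = 1L) {
  variant <- match.arg(variant)
  if (tau <= 0) stop("tau must be positive")
  if (contrastive_weight < 0) stop("contrastive_weight must be >= 0")
  structure(list(
    n_heads = as.integer(n_heads), head_dim = as.integer(head_dim),
    d_model = as.integer(n_heads) * as.integer(head_dim),
    n_encoder_layers = as.integer(n_encoder_layers),
    n_decoder_layers = as.integer(n_decoder_layers),
    variant = variant,
    lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
    dropout = dropout, share_decoder_weights = share_decoder_weights,
    tau = tau, contrastive_weight = contrastive_weight,
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    validation_fraction = validation_fraction, threshold = threshold,
    embed_seed = as.integer(embed_seed), seed = as.integer(seed)
  ), class = "molattn_config")
}

#' Read a configuration file
#'
#' Reads YAML or JSON whose keys mirror [molattn_config()] argument names.
#' @param path Config file path.
#' @return A `molattn_config`.
#' @export
read_molattn_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(molattn_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(molattn_config, vals[intersect(names(vals), known)])
}

glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -l, l), nin, nout)
}

init_attn_block <- function(dm) list(Wq = glorot(dm, dm), Wk = glorot(dm, dm),
                                     Wv = glorot(dm, dm))

init_common_layer <- function(dm) {
  list(Wo = glorot(dm, dm), bo = numeric(dm),
       W1 = glorot(dm, dm), b1 = numeric(dm),
       W2 = glorot(dm, dm), b2 = numeric(dm),
       ln1_g = rep(1, dm), ln1_b = numeric(dm),
       ln2_g = rep(1, dm), ln2_b = numeric(dm))
}

init_enc_layer <- function(config) {
  dm <- config$d_model
  lp <- init_common_layer(dm)
  if (config$variant %in% c("proposed", "simplified_decoder")) {
    lp$adj <- init_attn_block(dm)
    lp$dist <- init_attn_block(dm)
  } else {
    lp$att <- init_attn_block(dm)
  }
  lp
}

init_dec_layer <- function(config) {
  dm <- config$d_model
  c(init_attn_block(dm), init_common_layer(dm))
}

# Glorot-uniform initialization of all learnable parameters; relies on the
# caller having seeded the RNG.
init_params <- function(config, n_targets, d_f = feature_dim()) {
  dm <- config$d_model
  p <- list(emb = list(W = glorot(d_f, dm), b = numeric(dm)),
            enc = lapply(seq_len(config$n_encoder_layers),
                         function(i) init_enc_layer(config)))
  if (config$variant != "simplified_decoder") {
    # one learnable query vector per target (the affine image of the scalar 1,
    # initialized as a width-1 affine layer would be)
    l <- sqrt(6 / (1 + dm))
    p$cls <- matrix(runif(n_targets * dm, -l, l), n_targets, dm)
    if (config$share_decoder_weights) {
      p$dec <- lapply(seq_len(config$n_decoder_layers),
                      function(i) init_dec_layer(config))
    } else {
      p$dec_t <- lapply(seq_len(n_targets), function(t)
        lapply(seq_len(config$n_decoder_layers),
               function(i) init_dec_layer(config)))
    }
  }
  p$out <- list(W = glorot(dm, n_targets), b = numeric(n_targets))
  p
}

# flatten/unflatten parameter trees (used by the Adam optimizer and tests)
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(skeleton, v) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    x[] <- v[pos + seq_len(n)]
    pos <<- pos + n
    x
  }
  fill(skeleton)
}
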