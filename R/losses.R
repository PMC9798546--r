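# ---- losses ------------------------------------------------------------------

#' Per-target class weights for imbalanced labels
#'
#' The weight of each negative sample is 1 and the weight of a positive
#' sample is `(number of all samples - number of positive samples) /
#' number of positive samples`, computed per target. The weights are
#' scale-invariant: duplicating the dataset leaves them unchanged.
#'
#' @param labels Binary matrix (samples x targets) with named columns.
#' @param min_positives Targets with fewer positives than this raise an error
#'   naming the target (a target with no positives is untrainable).
#' @return Named numeric vector of positive-sample weights.
#' @export
compute_class_weights <- function(labels, min_positives = 1L) {
  labels <- as.matrix(labels)
  n <- nrow(labels)
  pos <- colSums(labels == 1, na.rm = TRUE)
  bad <- which(pos < min_positives)
  if (length(bad)) {
    nm <- colnames(labels)[bad] %||% as.character(bad)
    stop("target(s) with fewer than ", min_positives, " positive samples: ",
         paste(nm, collapse = ", "))
  }
  w <- (n - pos) / pos
  names(w) <- colnames(labels)
  w
}

#' Class-weighted binary cross-entropy
#'
#' Mean over samples and targets of
#' `-(w_t * y * log(p) + (1 - y) * log(1 - p))`. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` for log stability.
#'
#' @param probabilities Matrix of predicted probabilities (samples x targets).
#' @param labels Binary matrix of the same shape.
#' @param class_weights Per-target positive weights (default all 1).
#' @return Scalar loss.
#' @export
weighted_bce <- function(probabilities, labels,
                         class_weights = rep(1, ncol(as.matrix(labels)))) {
  p <- pmin(pmax(as.matrix(probabilities), 1e-7), 1 - 1e-7)
  y <- as.matrix(labels)
  w <- matrix(class_weights, nrow(y), ncol(y), byrow = TRUE)
  mean(-(w * y * log(p) + (1 - y) * log1p(-p)))
}

# gradient of weighted_bce with respect to the logits
bce_grad_logits <- function(probs, labels, class_weights) {
  y <- as.matrix(labels)
  w <- matrix(class_weights, nrow(y), ncol(y), byrow = TRUE)
  (w * y * (probs - 1) + (1 - y) * probs) / length(y)
}

#' Supervised contrastive loss
#'
#' For a batch of unit-length feature vectors `z` with one binary label per
#' sample,
#' `L = sum_i (-1/|P(i)|) sum_{p in P(i)} log( exp(z_i.z_p/tau) /
#'    sum_{a != i} exp(z_i.z_a/tau) )`,
#' where `P(i)` is the set of other samples sharing sample i's label. Samples
#' with an empty positive set contribute 0. Vectors are re-normalized
#' defensively; the loss depends only on inner products, so it is invariant
#' to a common rotation of all vectors.
#'
#' @param z Feature matrix (batch x d); rows are normalized to unit length.
#' @param labels Binary label vector for one target.
#' @param tau Temperature (> 0).
#' @return Scalar loss (0, with a warning, for batches smaller than 2).
#' @export
contrastive_loss <- function(z, labels, tau = 0.7) {
  contrastive_core(z, labels, tau, want_grad = FALSE)$loss
}

contrastive_core <- function(z, labels, tau, want_grad = TRUE) {
  z <- as.matrix(z)
  B <- nrow(z)
  if (tau <= 0) stop("tau must be positive")
  if (B < 2) {
    warning("contrastive loss needs a batch of at least 2; returning 0")
    return(list(loss = 0, dfeat = z * 0))
  }
  r <- sqrt(rowSums(z * z))
  rs <- pmax(r, 1e-12)
  zn <- z / rs
  S <- zn %*% t(zn) / tau
  E <- exp(S)
  diag(E) <- 0
  denom <- rowSums(E)
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  npos <- rowSums(same)
  active <- npos > 0
  loss <- 0
  if (any(active)) {
    pos_sum <- rowSums(S * same)
    loss <- sum((-pos_sum[active] + npos[active] * log(denom[active])) /
                  npos[active])
  }
  if (!want_grad) return(list(loss = loss))
  G <- matrix(0, B, B)
  if (any(active)) {
    Pmat <- E / denom                       # softmax over a != i, rowwise
    G[active, ] <- Pmat[active, , drop = FALSE] -
      same[active, , drop = FALSE] / npos[active]
    diag(G) <- 0
  }
  dz <- (G %*% zn + t(G) %*% zn) / tau
  # through the row normalization z -> z / ||z||
  dfeat <- (dz - zn * rowSums(zn * dz)) / rs
  list(loss = loss, dfeat = dfeat)
}

#' Total training loss
#'
#' Class-weighted binary cross-entropy plus `contrastive_weight` times the
#' mean over targets of the supervised contrastive loss applied per target to
#' that target's (normalized) decoder query features.
#'
#' @param probabilities Samples x targets probability matrix.
#' @param cls_features List (one per target) of samples x d feature matrices.
#' @param labels Binary samples x targets matrix.
#' @param class_weights Per-target positive weights.
#' @param tau,contrastive_weight See [molattn_config()].
#' @return `list(total=, bce=, contrastive=)`.
#' @export
total_loss <- function(probabilities, cls_features, labels,
                       class_weights = rep(1, ncol(as.matrix(labels))),
                       tau = 0.7, contrastive_weight = 1.0) {
  bce <- weighted_bce(probabilities, labels, class_weights)
  con <- 0
  if (contrastive_weight > 0) {
    labels <- as.matrix(labels)
    con <- mean(vapply(seq_len(ncol(labels)), function(t) {
      contrastive_loss(cls_features[[t]], labels[, t], tau)
    }, 0))
  }
  list(total = bce + contrastive_weight * con, bce = bce, contrastive = con)
}
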