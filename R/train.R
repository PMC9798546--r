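# ---- model fitting -----------------------------------------------------------

# group graphs into padded batches; sorting by size keeps padding small
make_batches <- function(graphs, labels, batch_size, sort_by_size = TRUE) {
  ord <- if (sort_by_size) order(vapply(graphs, `[[`, 0L, "n_atoms"))
         else seq_along(graphs)
  chunks <- split(ord, ceiling(seq_along(ord) / batch_size))
  lapply(chunks, function(ix) {
    b <- build_batch(graphs[ix], labels[ix, , drop = FALSE])
    b$orig_index <- ix
    b
  })
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, pvec, gvec, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * gvec
  state$v <- beta2 * state$v + (1 - beta2) * gvec * gvec
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, pvec = pvec - lr * mhat / (sqrt(vhat) + eps))
}

#' Fit the masked-attention molecular Transformer
#'
#' Trains the model on a prepared dataset with Adam, class-weighted binary
#' cross-entropy and (optionally) the supervised contrastive loss. A fraction
#' of the training molecules is held out for early stopping on validation
#' macro F1; the returned model carries the best-validation parameters.
#'
#' @param data A `molattn_data` object from [prepare_molecules()], or a list
#'   with elements `graphs` (list of `mol_graph`) and `labels` (binary
#'   matrix with one row per graph).
#' @param config A [molattn_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `molattn` with `params`, `config`, `log`
#'   (per-epoch loss decomposition and validation F1), `class_weights`,
#'   `target_names`, `best_epoch`.
#' @seealso [predict.molattn()], [evaluate()], [attention_records()]
#' @export
molattn <- function(data, config = molattn_config(), verbose = FALSE) {
  graphs <- data$graphs
  labels <- as.matrix(data$labels)
  if (length(graphs) != nrow(labels)) stop("graphs and labels disagree in length")
  target_names <- colnames(labels) %||% paste0("target_", seq_len(ncol(labels)))
  n <- length(graphs)
  Tn <- ncol(labels)

  set.seed(config$seed)
  n_val <- floor(config$validation_fraction * n)
  val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)

  w <- compute_class_weights(labels[tr_idx, , drop = FALSE])
  params <- init_params(config, Tn)
  pvec <- flatten_params(params)
  opt <- adam_init(length(pvec))

  tr_batches <- make_batches(graphs[tr_idx], labels[tr_idx, , drop = FALSE],
                             config$batch_size)
  val_graphs <- graphs[val_idx]
  val_labels <- labels[val_idx, , drop = FALSE]

  log <- NULL
  best_f1 <- -Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L
  use_con <- config$contrastive_weight > 0

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(tr_batches))
    ep_bce <- ep_con <- 0
    for (bi in ord) {
      batch <- tr_batches[[bi]]
      fwd <- molattn_forward(params, batch, config, training = TRUE,
                             want_cache = TRUE)
      dlogits <- bce_grad_logits(fwd$probs, batch$labels, w)
      bce <- weighted_bce(fwd$probs, batch$labels, w)
      con <- 0
      dcls <- NULL
      if (use_con) {
        dcls <- vector("list", Tn)
        for (t in seq_len(Tn)) {
          cg <- contrastive_core(fwd$cls[[t]], batch$labels[, t], config$tau)
          con <- con + cg$loss / Tn
          dcls[[t]] <- cg$dfeat * (config$contrastive_weight / Tn)
        }
      }
      total <- bce + config$contrastive_weight * con
      if (!is.finite(total))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      grads <- molattn_backward(params, batch, config, fwd, dlogits, dcls)
      st <- adam_step(opt, pvec, flatten_params(grads), config$learning_rate)
      opt <- st$state
      pvec <- st$pvec
      params <- unflatten_params(params, pvec)
      ep_bce <- ep_bce + bce
      ep_con <- ep_con + con
    }
    nb <- length(tr_batches)
    row <- data.frame(epoch = epoch, bce = ep_bce / nb, contrastive = ep_con / nb,
                      total = (ep_bce + config$contrastive_weight * ep_con) / nb,
                      val_macro_f1 = NA_real_)
    if (length(val_idx)) {
      vp <- predict_graphs(params, val_graphs, config, Tn)
      row$val_macro_f1 <- metrics_report(vp, val_labels,
                                         config$threshold)$macro_f1
      if (row$val_macro_f1 > best_f1 + 1e-9) {
        best_f1 <- row$val_macro_f1
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    log <- rbind(log, row)
    if (verbose)
      cat(sprintf("epoch %3d  bce %.4f  con %.4f  val F1 %s\n", epoch,
                  row$bce, row$contrastive,
                  ifelse(is.na(row$val_macro_f1), "-",
                         sprintf("%.4f", row$val_macro_f1))))
    if (length(val_idx) && wait >= config$patience) break
  }
  if (!length(val_idx)) {
    best_params <- params
    best_epoch <- nrow(log)
  }

  structure(list(params = best_params, config = config,
                 target_names = target_names, class_weights = w,
                 log = log, best_epoch = best_epoch,
                 best_val_macro_f1 = if (length(val_idx)) best_f1 else NA_real_,
                 n_train = length(tr_idx), n_val = length(val_idx),
                 schema = feature_schema_hash(), d_f = feature_dim()),
            class = "molattn")
}

# batched inference returning a probability matrix in input order
predict_graphs <- function(params, graphs, config, Tn, batch_size = 64L) {
  batches <- make_batches(graphs,
                          matrix(0L, length(graphs), Tn), batch_size)
  probs <- matrix(NA_real_, length(graphs), Tn)
  for (b in batches) {
    fwd <- molattn_forward(params, b, config, training = FALSE)
    probs[b$orig_index, ] <- fwd$probs
  }
  probs
}

#' @export
print.molattn <- function(x, ...) {
  cfg <- x$config
  cat("molattn model (", cfg$variant, "): ", cfg$n_encoder_layers,
      " encoder x ", cfg$n_heads, " heads x ", cfg$head_dim, " dims",
      if (cfg$variant != "simplified_decoder")
        paste0(", ", cfg$n_decoder_layers, " decoder layer(s)"),
      "\n", sep = "")
  cat("targets:", paste(x$target_names, collapse = ", "), "\n")
  cat(sprintf("trained %d epochs (best %d, val macro F1 %s) on %d molecules\n",
              nrow(x$log), x$best_epoch,
              ifelse(is.na(x$best_val_macro_f1), "-",
                     sprintf("%.4f", x$best_val_macro_f1)), x$n_train))
  invisible(x)
}

#' @export
summary.molattn <- function(object, ...) {
  print(object)
  cat("\nclass weights:\n")
  print(round(object$class_weights, 4))
  cat("\nlast training epochs:\n")
  print(utils::tail(object$log, 5), row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.molattn <- function(object, ...) object$params

#' Plot training curves
#'
#' Loss decomposition per epoch and, when available, validation macro F1.
#' @param x A fitted `molattn` model.
#' @param ... Unused.
#' @export
plot.molattn <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  with(x$log, {
    graphics::plot(epoch, total, type = "l", ylab = "loss", main = "training loss")
    graphics::lines(epoch, bce, lty = 2)
    graphics::legend("topright", c("total", "bce"), lty = 1:2, bty = "n")
    if (any(!is.na(val_macro_f1)))
      graphics::plot(epoch, val_macro_f1, type = "l", ylab = "macro F1",
                     main = "validation")
  })
  invisible(x)
}

#' Predict molecular properties
#'
#' @param object A fitted `molattn` model.
#' @param newdata A `molattn_data`, a list of `mol_graph` objects, or a single
#'   `mol_graph`.
#' @param type `"prob"` (default) for probabilities, `"class"` for 0/1 calls
#'   at the model threshold, `"all"` for probabilities plus per-molecule
#'   attention records and decoder query (cls) features.
#' @param threshold Decision threshold for `type = "class"`.
#' @param ... Unused.
#' @return A samples x targets matrix, or for `type = "all"` a list with
#'   `probabilities`, `attention` (see [attention_records()]) and
#'   `cls_features`.
#' @export
predict.molattn <- function(object, newdata, type = c("prob", "class", "all"),
                            threshold = object$config$threshold, ...) {
  type <- match.arg(type)
  graphs <- as_graph_list(newdata)
  Tn <- length(object$target_names)
  if (type != "all") {
    probs <- predict_graphs(object$params, graphs, object$config, Tn)
    colnames(probs) <- object$target_names
    rownames(probs) <- vapply(graphs, `[[`, "", "id")
    return(if (type == "class") (probs >= threshold) * 1L else probs)
  }
  predict_full(object, graphs)
}

as_graph_list <- function(newdata) {
  if (inherits(newdata, "molattn_data")) newdata$graphs
  else if (inherits(newdata, "mol_graph")) list(newdata)
  else if (is.list(newdata) && !is.null(newdata$graphs)) newdata$graphs
  else newdata
}

predict_full <- function(object, graphs, batch_size = 64L) {
  Tn <- length(object$target_names)
  cfg <- object$config
  batches <- make_batches(graphs, matrix(0L, length(graphs), Tn), batch_size)
  nmol <- length(graphs)
  probs <- matrix(NA_real_, nmol, Tn,
                  dimnames = list(vapply(graphs, `[[`, "", "id"),
                                  object$target_names))
  attention <- vector("list", nmol)
  cls <- lapply(seq_len(Tn), function(t) matrix(NA_real_, nmol, cfg$d_model))
  L <- cfg$n_decoder_layers
  for (b in batches) {
    fwd <- molattn_forward(object$params, b, cfg, training = FALSE)
    probs[b$orig_index, ] <- fwd$probs
    for (t in seq_len(Tn)) cls[[t]][b$orig_index, ] <- fwd$cls[[t]]
    if (cfg$variant != "simplified_decoder") {
      for (k in seq_len(b$B)) {
        i <- b$orig_index[k]
        n <- b$n_atoms[k]
        rec <- lapply(seq_len(Tn), function(t) {
          a <- array(0, c(L, cfg$n_heads, n))
          for (l in seq_len(L)) a[l, , ] <- fwd$attention[[t]][[l]][, seq_len(n), k]
          a
        })
        names(rec) <- object$target_names
        attention[[i]] <- rec
      }
    }
  }
  names(attention) <- rownames(probs)
  names(cls) <- object$target_names
  list(probabilities = probs, attention = attention, cls_features = cls)
}

#' Per-molecule decoder attention records
#'
#' Runs the model over molecules and returns, for each molecule and target,
#' the decoder attention array (`n_decoder_layers x n_heads x n_atoms`). Each
#' `[layer, head]` row over real atoms sums to 1.
#'
#' @param object A fitted `molattn` model (decoder-bearing variant).
#' @param newdata Molecules, as for [predict.molattn()].
#' @return Named list (molecule id) of named lists (target) of arrays.
#' @export
attention_records <- function(object, newdata) {
  if (object$config$variant == "simplified_decoder")
    stop("the simplified_decoder variant has no decoder attention")
  predict_full(object, as_graph_list(newdata))$attention
}

#' Evaluate a fitted model on labeled molecules
#'
#' @param object A fitted `molattn` model.
#' @param data A `molattn_data` (or list with `graphs` and `labels`).
#' @param threshold Decision threshold.
#' @return A [metrics_report()].
#' @export
evaluate <- function(object, data, threshold = object$config$threshold) {
  probs <- predict(object, data)
  metrics_report(probs, as.matrix(data$labels), threshold)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the parameters, the
#' configuration and a feature-schema hash; loading refuses a checkpoint
#' written under a different atom-feature schema.
#' @param object A fitted `molattn` model.
#' @param path Checkpoint path (`.rds`).
#' @export
save_molattn <- function(object, path) {
  saveRDS(unclass(object), path, compress = "gzip")
  invisible(path)
}

#' @rdname save_molattn
#' @export
load_molattn <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, feature_schema_hash()))
    stop("checkpoint feature schema does not match this package version")
  class(obj) <- "molattn"
  obj
}
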