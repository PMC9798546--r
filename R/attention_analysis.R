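# ---- attention summation, localization statistics, ensemble annotation -------

#' Sum decoder attention over layers and heads
#'
#' Collapses one molecule's attention record (array
#' `n_decoder_layers x n_heads x n_atoms`, each `[layer, head]` row summing
#' to 1 over real atoms) to per-atom totals. The total mass over all atoms is
#' therefore `n_heads * n_decoder_layers`.
#'
#' @param record Attention array for one molecule and target, as returned by
#'   [attention_records()].
#' @return Numeric vector of per-atom attention totals.
#' @export
sum_attention <- function(record) {
  if (is.null(record) || !length(record))
    stop("empty attention record (simplified_decoder variant has none)")
  apply(record, 3, sum)
}

#' Attention localization statistics for a target substructure
#'
#' Given a molecule's attention record and the set of atoms belonging to the
#' target substructure, computes: the summed attention mass on the target
#' atoms (`attn_sum`); the normalized localization
#' `attn_sum / (n_heads * n_decoder_layers)`, which lies in `[0, 1]` and
#' equals `|T|/N` under uniform attention; and the variance of the target
#' atoms' attention values about
#' `attn_sum / (|T| * n_heads * n_decoder_layers)`.
#'
#' As printed, the variance's centering term is normalized by
#' `n_heads * n_decoder_layers` while the attention values themselves are
#' not, so it is not the ordinary variance of the per-atom totals;
#' `corrected = TRUE` instead takes the variance of the normalized values
#' `attn(a) / (n_heads * n_decoder_layers)` about their own mean.
#'
#' @param record Attention array (`layers x heads x atoms`).
#' @param target_atoms Nonempty integer vector of 1-based atom indices.
#' @param corrected Use the rescaled variance (default `FALSE`).
#' @return `list(attn_sum=, normalized=, variance=)`.
#' @export
localization_stats <- function(record, target_atoms, corrected = FALSE) {
  totals <- sum_attention(record)
  if (!length(target_atoms)) stop("empty target atom set")
  if (any(target_atoms < 1 | target_atoms > length(totals)))
    stop("target atom index out of range")
  nh_ndc <- dim(record)[1] * dim(record)[2]
  tvals <- totals[target_atoms]
  attn_sum <- sum(tvals)
  normalized <- attn_sum / nh_ndc
  variance <- if (corrected) {
    mean((tvals / nh_ndc - mean(tvals / nh_ndc))^2)
  } else {
    mean((tvals - attn_sum / (length(tvals) * nh_ndc))^2)
  }
  list(attn_sum = attn_sum, normalized = normalized, variance = variance)
}

#' Ensemble top-k attention counters
#'
#' Emulates annotation by repeated training: for each of M models and each
#' molecule, the k atoms with the largest summed attention get their counters
#' incremented (ties broken by the lower atom index; molecules with at most k
#' atoms increment every atom). Counter totals per molecule are
#' `M * min(k, n_atoms)`.
#'
#' @param records List over models; each element is a named list (molecule id)
#'   of per-atom summed-attention vectors (or attention arrays, which are
#'   collapsed with [sum_attention()]). All models must cover the same
#'   molecules.
#' @param k Number of top atoms per model and molecule.
#' @return An `atom_counter`: named list (molecule id) of integer per-atom
#'   counters, with attributes `M`, `k`.
#' @export
ensemble_topk_counts <- function(records, k = 5L) {
  M <- length(records)
  if (!M) stop("no model records")
  ids <- names(records[[1]])
  for (m in seq_len(M)) {
    if (!identical(sort(names(records[[m]])), sort(ids)))
      stop("models cover different molecule sets")
  }
  counters <- lapply(records[[1]], function(v) {
    n <- if (is.array(v)) dim(v)[3] else length(v)
    integer(n)
  })
  names(counters) <- ids
  for (m in seq_len(M)) {
    for (id in ids) {
      v <- records[[m]][[id]]
      if (is.array(v)) v <- sum_attention(v)
      kk <- min(k, length(v))
      top <- order(-v, seq_along(v))[seq_len(kk)]
      counters[[id]][top] <- counters[[id]][top] + 1L
    }
  }
  structure(counters, M = M, k = as.integer(k), class = "atom_counter")
}

#' Select frequently annotated atoms
#'
#' Returns, per molecule, the atoms whose counter value is strictly greater
#' than `n`.
#'
#' @param counter An `atom_counter` from [ensemble_topk_counts()].
#' @param n Count threshold (strict inequality; with M models and `n >= M`
#'   the result is empty and a warning is raised).
#' @return Named list of integer atom-index vectors.
#' @export
select_annotated_atoms <- function(counter, n = 50L) {
  M <- attr(counter, "M")
  if (!is.null(M) && n >= M)
    warning("threshold n >= number of models M; no atom can be selected")
  lapply(unclass(counter), function(v) which(v > n))
}

#' Select consistently predicted TP and TN samples
#'
#' Given per-model binary predictions on the same test samples, returns per
#' target the positive samples predicted positive by at least `tp_quorum` of
#' the models and the negative samples predicted negative by at least
#' `tn_quorum`. The quorums are stated out of 100 models; for other ensemble
#' sizes they scale proportionally, rounded up.
#'
#' @param predictions List over models of binary prediction matrices
#'   (samples x targets), or a 3-d array samples x targets x models.
#' @param labels Binary samples x targets matrix.
#' @param tp_quorum,tn_quorum Agreement quorums per 100 models.
#' @return Named list per target: `list(tp = row indices, tn = row indices)`.
#' @export
select_tp_tn <- function(predictions, labels, tp_quorum = 90L,
                         tn_quorum = 85L) {
  if (is.array(predictions) && length(dim(predictions)) == 3) {
    predictions <- lapply(seq_len(dim(predictions)[3]),
                          function(m) predictions[, , m])
  }
  M <- length(predictions)
  y <- as.matrix(labels)
  scale_q <- function(q) if (M == 100L) q else ceiling(q / 100 * M)
  tq <- scale_q(tp_quorum)
  nq <- scale_q(tn_quorum)
  if (tq > M || nq > M) stop("quorum exceeds the number of models")
  pos_votes <- Reduce(`+`, lapply(predictions, function(p) (as.matrix(p) >= 0.5) * 1L))
  Tn <- ncol(y)
  out <- lapply(seq_len(Tn), function(t) {
    list(tp = which(y[, t] == 1 & pos_votes[, t] >= tq),
         tn = which(y[, t] == 0 & (M - pos_votes[, t]) >= nq))
  })
  names(out) <- colnames(y) %||% paste0("target_", seq_len(Tn))
  out
}

#' Render per-atom attention on a 2D depiction
#'
#' Draws the molecule's 2D structure with one circle per atom whose blue
#' shade increases monotonically with `values / max(values)` (white at 0).
#' The SVG output is deterministic: identical inputs give byte-identical
#' files.
#'
#' @param smiles SMILES of the molecule.
#' @param values Nonnegative per-atom values (one per heavy atom, parse
#'   order).
#' @param path Output path; format follows the extension (`.svg` or `.png`).
#' @param size Canvas size in pixels.
#' @return The output path, invisibly.
#' @export
render_attention <- function(smiles, values, path, size = 400) {
  if (any(values < 0)) stop("attention values must be nonnegative")
  dep <- backend_depict(smiles)
  at <- dep$atoms
  if (nrow(at) != length(values))
    stop("got ", length(values), " values for ", nrow(at), " atoms")
  vmax <- max(values)
  shade <- if (vmax > 0) values / vmax else values * 0
  # map depiction coordinates to the canvas
  pad <- 0.12 * size
  rng <- function(u) {
    r <- range(u)
    if (diff(r) < 1e-9) r + c(-0.5, 0.5) else r
  }
  rx <- rng(at$x); ry <- rng(at$y)
  sc <- min((size - 2 * pad) / diff(rx), (size - 2 * pad) / diff(ry))
  px <- pad + (at$x - rx[1]) * sc
  py <- size - (pad + (at$y - ry[1]) * sc)
  col <- function(s) sprintf("rgb(%d,%d,%d)", round(255 * (1 - s)),
                             round(255 * (1 - 0.6 * s)), 255L)
  fmt <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "svg"
  if (fmt == "png") {
    grDevices::png(path, width = size, height = size)
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::plot.window(c(0, size), c(size, 0), asp = 1)
    for (b in seq_len(nrow(dep$bonds))) {
      i <- dep$bonds$a1[b] + 1L; j <- dep$bonds$a2[b] + 1L
      graphics::segments(px[i], py[i], px[j], py[j], col = "grey30")
    }
    graphics::symbols(px, py, circles = rep(0.035 * size, length(px)),
                      inches = FALSE, add = TRUE,
                      bg = grDevices::rgb(1 - shade, 1 - 0.6 * shade, 1),
                      fg = "grey60")
    graphics::text(px, py, at$symbol, cex = 0.8)
    graphics::par(op)
    grDevices::dev.off()
    return(invisible(path))
  }
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    size, size, size, size),
    sprintf('<rect width="%d" height="%d" fill="white"/>', size, size))
  for (b in seq_len(nrow(dep$bonds))) {
    i <- dep$bonds$a1[b] + 1L; j <- dep$bonds$a2[b] + 1L
    lines <- c(lines, sprintf(
      '<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#444" stroke-width="1.5"/>',
      px[i], py[i], px[j], py[j]))
  }
  for (i in seq_len(nrow(at))) {
    lines <- c(lines, sprintf(
      '<circle cx="%.2f" cy="%.2f" r="%.2f" fill="%s" stroke="#999"/>',
      px[i], py[i], 0.035 * size, col(shade[i])),
      sprintf('<text x="%.2f" y="%.2f" font-size="%.1f" text-anchor="middle" dy="0.35em">%s</text>',
              px[i], py[i], 0.03 * size, at$symbol[i]))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
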