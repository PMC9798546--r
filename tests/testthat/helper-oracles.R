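# Independent brute-force oracles used to validate the package's fast paths.
# These are deliberately naive (explicit loops, recursive search) and share no
# code with the implementation.

# ---- restricted SMARTS parser + brute-force subgraph matcher -----------------
# Supports: single-letter organic atoms (C, N, O, S and aromatic c, n, o, s),
# branches, ring-closure digits, and bond symbols "=" / "#". The default bond
# matches a single or aromatic molecule bond, as in SMARTS.

parse_pattern <- function(smarts) {
  chars <- strsplit(smarts, "")[[1]]
  atoms <- data.frame(elem = character(0), aromatic = logical(0))
  bonds <- data.frame(i = integer(0), j = integer(0), type = character(0))
  stack <- integer(0)
  prev <- 0L
  pending <- "default"
  ring_open <- list()
  k <- 1
  while (k <= length(chars)) {
    ch <- chars[k]
    if (ch %in% c("C", "N", "O", "S", "c", "n", "o", "s")) {
      atoms <- rbind(atoms, data.frame(
        elem = toupper(ch), aromatic = ch %in% c("c", "n", "o", "s")))
      id <- nrow(atoms)
      if (prev > 0L)
        bonds <- rbind(bonds, data.frame(i = prev, j = id, type = pending))
      prev <- id
      pending <- "default"
    } else if (ch == "(") {
      stack <- c(stack, prev)
    } else if (ch == ")") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (ch == "=") {
      pending <- "double"
    } else if (ch == "#") {
      pending <- "triple"
    } else if (grepl("[0-9]", ch)) {
      key <- ch
      if (!is.null(ring_open[[key]])) {
        bonds <- rbind(bonds, data.frame(i = ring_open[[key]], j = prev,
                                         type = "default"))
        ring_open[[key]] <- NULL
      } else ring_open[[key]] <- prev
    } else stop("oracle parser: unsupported SMARTS character: ", ch)
    k <- k + 1
  }
  list(atoms = atoms, bonds = bonds)
}

# molecule description (atoms/bonds frames from the chemistry backend, one
# molecule) -> adjacency with bond classes
mol_for_oracle <- function(atoms, bonds) {
  n <- nrow(atoms)
  list(elem = toupper(atoms$symbol), aromatic = atoms$aromatic == 1,
       bonds = bonds, n = n)
}

oracle_smarts_match <- function(mol, pattern) {
  pa <- pattern$atoms
  pb <- pattern$bonds
  np <- nrow(pa)
  if (np > mol$n) return(FALSE)
  bond_tab <- new.env()
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[r] + 1L
      j <- mol$bonds$a2[r] + 1L
      cls <- if (mol$bonds$aromatic[r] == 1) "aromatic"
             else if (mol$bonds$order[r] == 2) "double"
             else if (mol$bonds$order[r] == 3) "triple" else "single"
      assign(paste(min(i, j), max(i, j)), cls, envir = bond_tab)
    }
  }
  bond_cls <- function(i, j) {
    v <- mget(paste(min(i, j), max(i, j)), envir = bond_tab,
              ifnotfound = list(NULL))[[1]]
    v
  }
  bond_ok <- function(want, have) {
    if (is.null(have)) return(FALSE)
    switch(want,
           default = have %in% c("single", "aromatic"),
           double = have == "double",
           triple = have == "triple")
  }
  atom_ok <- function(p, m) pa$elem[p] == mol$elem[m] &&
    pa$aromatic[p] == mol$aromatic[m]
  assign_next <- function(map) {
    p <- length(map) + 1L
    if (p > np) return(TRUE)
    for (m in seq_len(mol$n)) {
      if (m %in% map || !atom_ok(p, m)) next
      ok <- TRUE
      if (nrow(pb)) {
        for (r in seq_len(nrow(pb))) {
          i <- pb$i[r]; j <- pb$j[r]
          if (max(i, j) != p) next
          other <- map[min(i, j)]
          if (!bond_ok(pb$type[r], bond_cls(other, m))) { ok <- FALSE; break }
        }
      }
      if (ok && assign_next(c(map, m))) return(TRUE)
    }
    FALSE
  }
  assign_next(integer(0))
}

# ---- brute-force masked attention (explicit pairwise loops) ------------------

oracle_encoder_attention <- function(X, A, D, weights, n_heads, variant,
                                     lambdas = NULL) {
  n <- nrow(X)
  dm <- ncol(X)
  dk <- dm %/% n_heads
  gD <- exp(-D)
  out <- matrix(0, n, dm)
  branch <- function(Wq, Wk, Wv, mask, mode = "mask", lam = NULL) {
    Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
    res <- matrix(0, n, dm)
    for (h in seq_len(n_heads)) {
      cols <- (h - 1) * dk + seq_len(dk)
      for (i in seq_len(n)) {
        s <- numeric(n)
        for (j in seq_len(n)) s[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dk)
        p <- exp(s - max(s)); p <- p / sum(p)
        w <- if (mode == "mask") p * mask[i, ]
             else lam[1] * p + lam[2] * gD[i, ] + lam[3] * A[i, ]
        for (j in seq_len(n))
          res[i, cols] <- res[i, cols] + w[j] * V[j, cols]
      }
    }
    res
  }
  if (variant == "proposed") {
    out <- branch(weights$adj$Wq, weights$adj$Wk, weights$adj$Wv, A) +
      branch(weights$dist$Wq, weights$dist$Wk, weights$dist$Wv, gD)
  } else if (variant == "adj_only") {
    out <- branch(weights$Wq, weights$Wk, weights$Wv, A)
  } else if (variant == "dist_only") {
    out <- branch(weights$Wq, weights$Wk, weights$Wv, gD)
  } else if (variant == "mat_attn") {
    out <- branch(weights$Wq, weights$Wk, weights$Wv, NULL, mode = "mat",
                  lam = lambdas)
  }
  if (!is.null(weights$Wo))
    out <- out %*% weights$Wo + rep(weights$bo, each = n)
  out
}

# ---- supervised contrastive loss, double loop --------------------------------

oracle_contrastive <- function(z, labels, tau) {
  z <- z / sqrt(rowSums(z^2))
  B <- nrow(z)
  total <- 0
  for (i in seq_len(B)) {
    P <- setdiff(which(labels == labels[i]), i)
    if (!length(P)) next
    li <- 0
    for (p in P) {
      denom <- 0
      for (a in setdiff(seq_len(B), i))
        denom <- denom + exp(sum(z[i, ] * z[a, ]) / tau)
      li <- li + log(exp(sum(z[i, ] * z[p, ]) / tau) / denom)
    }
    total <- total - li / length(P)
  }
  total
}

# ---- localization statistics, elementwise ------------------------------------

oracle_localization <- function(record, target_atoms) {
  L <- dim(record)[1]; H <- dim(record)[2]
  attn <- numeric(dim(record)[3])
  for (a in seq_along(attn)) {
    s <- 0
    for (l in seq_len(L)) for (h in seq_len(H)) s <- s + record[l, h, a]
    attn[a] <- s
  }
  attn_sum <- sum(attn[target_atoms])
  normalized <- attn_sum / (L * H)
  m <- attn_sum / (length(target_atoms) * L * H)
  variance <- mean((attn[target_atoms] - m)^2)
  list(attn_sum = attn_sum, normalized = normalized, variance = variance)
}

# ---- misc helpers -------------------------------------------------------------

rand_attn_weights <- function(dm, variant, with_wo = TRUE) {
  rw <- function() matrix(rnorm(dm * dm, sd = 0.3), dm, dm)
  w <- if (variant == "proposed") {
    list(adj = list(Wq = rw(), Wk = rw(), Wv = rw()),
         dist = list(Wq = rw(), Wk = rw(), Wv = rw()))
  } else {
    list(Wq = rw(), Wk = rw(), Wv = rw())
  }
  if (with_wo) { w$Wo <- rw(); w$bo <- rnorm(dm, sd = 0.1) }
  w
}

rand_graph_mats <- function(n) {
  A <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1  # path backbone
    extra <- which(upper.tri(A) & A == 0)
    if (length(extra)) {
      on <- extra[runif(length(extra)) < 0.3]
      A[on] <- 1
      A <- pmax(A, t(A))
    }
  }
  P <- matrix(rnorm(3 * n), n, 3)
  D <- as.matrix(dist(P))
  dimnames(D) <- NULL
  list(A = A, D = D)
}
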