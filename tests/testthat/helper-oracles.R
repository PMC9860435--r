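# Independent oracles the implementation is checked against. These are
# deliberately naive (scalar loops, brute force) and share no code with
# the package internals.

# direct 2-D convolution with symmetric-reflect borders
conv2_brute <- function(m, g) {
  h <- (length(g) - 1) / 2
  k2 <- outer(g, g)                 # separable kernel -> full 2-D kernel
  H <- nrow(m); W <- ncol(m)
  reflect <- function(i, n) {
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
    i
  }
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (cl in seq_len(W)) {
      rr <- reflect(r + (-h:h), H)
      cc <- reflect(cl + (-h:h), W)
      out[r, cl] <- sum(k2 * m[rr, cc])
    }
  }
  out
}

# scalar stack-based flood fill, 8-connected, labels in column-major
# first-pixel order (the labelling convention the package documents)
flood_cc <- function(b) {
  H <- nrow(b); W <- ncol(b)
  labels <- matrix(0L, H, W)
  lab <- 0L
  for (idx in which(b != 0)) {
    if (labels[idx] != 0L) next
    lab <- lab + 1L
    stack <- idx
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (labels[p] != 0L) next
      labels[p] <- lab
      r <- (p - 1L) %% H + 1L
      cl <- (p - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- cl + dc
        if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
            b[r2, c2] != 0 && labels[r2, c2] == 0L) {
          stack <- c(stack, (c2 - 1L) * H + r2)
        }
      }
    }
  }
  labels
}

# scalar replicate of the per-pixel mixture update, one pixel, K
# components; mirrors the documented rules step by step
mog_scalar <- function(x_seq, thr, alpha = 1 / 25, K = 3, T_bg = 0.9,
                       s2_init = 225, s2_min = 4, w_new = 0.05) {
  w <- c(1, rep(0, K - 1))
  mu <- c(x_seq[1], rep(0, K - 1))
  s2 <- rep(s2_init, K)
  fg <- numeric(0)
  for (x in x_seq[-1]) {
    sd <- sqrt(s2)
    score <- ifelse(w > 0, w / sd, -1)
    band <- pmax(thr, 2.5 * sd)
    match <- w > 0 & abs(x - mu) <= band
    matched <- if (any(match)) {
      cand <- which(match)
      cand[which.max(score[cand])]
    } else 0L
    background <- FALSE
    if (matched > 0) {
      higher <- which(seq_len(K) != matched & w > 0 &
                        (score > score[matched] |
                           (score == score[matched] & seq_len(K) < matched)))
      background <- sum(w[higher]) < T_bg
    }
    fg <- c(fg, as.numeric(!background))
    if (matched > 0) {
      w <- w + alpha * ((seq_len(K) == matched) - w)
      mu[matched] <- mu[matched] + alpha * (x - mu[matched])
      s2[matched] <- max(s2_min,
                         (1 - alpha) * s2[matched] +
                           alpha * (x - mu[matched])^2)
    } else {
      weakest <- which.min(score)
      w <- w * (1 - alpha)
      w[weakest] <- w_new
      mu[weakest] <- x
      s2[weakest] <- s2_init
    }
    w <- w / sum(w)
  }
  list(fg = fg, w = w, mu = mu, s2 = s2)
}

# brute-force maximum bipartite matching between point triggers and
# tolerance-extended windows (<= 10 events each)
brute_max_matching <- function(trig, lo, hi) {
  n <- length(trig); m <- length(lo)
  best <- 0L
  recurse <- function(i, used) {
    if (i > n) return(0L)
    res <- recurse(i + 1L, used)               # skip trigger i
    for (j in seq_len(m)) {
      if (!used[j] && trig[i] >= lo[j] && trig[i] <= hi[j]) {
        used2 <- used; used2[j] <- TRUE
        res <- max(res, 1L + recurse(i + 1L, used2))
      }
    }
    res
  }
  if (m == 0L || n == 0L) return(0L)
  recurse(1L, logical(m))
}
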