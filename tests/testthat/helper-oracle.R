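# Independent scalar-loop reference implementation of the network equations.
# Everything is computed element by element with explicit loops — no shared
# code with the vectorized implementation under test.

o_sigmoid <- function(x) 1 / (1 + exp(-x))

o_matvec <- function(W, x) {   # t(W) %*% x by explicit loops: W is in x out
  out <- numeric(ncol(W))
  for (k in seq_len(ncol(W))) {
    s <- 0
    for (i in seq_len(nrow(W))) s <- s + x[i] * W[i, k]
    out[k] <- s
  }
  out
}

o_dot <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + a[i] * b[i]
  s
}

o_softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# One GRU update h_t = GRU(h_{t-1}, x_t), scalar form.
o_gru_step <- function(par, h_prev, x) {
  h <- length(h_prev)
  z <- r <- hh <- hn <- numeric(h)
  for (k in seq_len(h)) {
    z[k] <- o_sigmoid(par$bz[k] + o_dot(x, par$Wz[, k]) + o_dot(h_prev, par$Uz[, k]))
    r[k] <- o_sigmoid(par$br[k] + o_dot(x, par$Wr[, k]) + o_dot(h_prev, par$Ur[, k]))
  }
  rh <- r * h_prev
  for (k in seq_len(h)) {
    hh[k] <- tanh(par$bh[k] + o_dot(x, par$Wh[, k]) + o_dot(rh, par$Uh[, k]))
    hn[k] <- (1 - z[k]) * h_prev[k] + z[k] * hh[k]
  }
  hn
}

o_gru_pars <- function(params, side, dir) {
  nm <- function(x) params[[paste("gru", side, dir, x, sep = ".")]]
  list(Wz = nm("Wz"), Uz = nm("Uz"), bz = nm("bz"),
       Wr = nm("Wr"), Ur = nm("Ur"), br = nm("br"),
       Wh = nm("Wh"), Uh = nm("Uh"), bh = nm("bh"))
}

# Encode the L k-mer ids of one site: BiGRU + k-mer attention -> w, alpha.
o_encode_site <- function(ids, side, params, cfg) {
  L <- length(ids); h <- cfg$h
  x <- lapply(seq_len(L), function(t) params$E[ids[t] + 1L, ])
  pf <- o_gru_pars(params, side, "fwd")
  pb <- o_gru_pars(params, side, "bwd")
  hf <- vector("list", L); hb <- vector("list", L)
  hprev <- numeric(h)
  for (t in seq_len(L)) { hf[[t]] <- o_gru_step(pf, hprev, x[[t]]); hprev <- hf[[t]] }
  hprev <- numeric(h)
  for (t in rev(seq_len(L))) { hb[[t]] <- o_gru_step(pb, hprev, x[[t]]); hprev <- hb[[t]] }
  Wt <- params[[paste0("kmer.", side, ".Wt")]]
  bt <- params[[paste0("kmer.", side, ".bt")]]
  ts <- params[[paste0("kmer.", side, ".ts")]]
  hcat <- lapply(seq_len(L), function(t) c(hf[[t]], hb[[t]]))
  scores <- numeric(L)
  for (t in seq_len(L)) {
    g <- tanh(bt + o_matvec(Wt, hcat[[t]]))
    scores[t] <- o_dot(g, ts)
  }
  alpha <- o_softmax(scores)
  w <- numeric(2 * h)
  for (t in seq_len(L)) w <- w + alpha[t] * hcat[[t]]
  list(w = w, alpha = alpha)
}

# Full forward pass for one record given its m x L id matrices.
oracle_forward_record <- function(acc_ids, don_ids, params, cfg) {
  m <- nrow(acc_ids)
  enc_a <- lapply(seq_len(m), function(i) o_encode_site(acc_ids[i, ], "a", params, cfg))
  enc_d <- lapply(seq_len(m), function(j) o_encode_site(don_ids[j, ], "d", params, cfg))
  wa <- lapply(enc_a, `[[`, "w"); wd <- lapply(enc_d, `[[`, "w")
  # cross-attention
  beta_a <- matrix(0, m, m); beta_d <- matrix(0, m, m)
  for (i in seq_len(m))
    beta_a[i, ] <- o_softmax(vapply(seq_len(m), function(j) o_dot(wa[[i]], wd[[j]]), 0))
  for (j in seq_len(m))
    beta_d[j, ] <- o_softmax(vapply(seq_len(m), function(i) o_dot(wd[[j]], wa[[i]]), 0))
  va <- lapply(seq_len(m), function(i) {
    v <- numeric(2 * cfg$h)
    for (j in seq_len(m)) v <- v + beta_a[i, j] * wd[[j]]
    v
  })
  vd <- lapply(seq_len(m), function(j) {
    v <- numeric(2 * cfg$h)
    for (i in seq_len(m)) v <- v + beta_d[j, i] * wa[[i]]
    v
  })
  # site attention
  site_r <- function(v, side) {
    Wc <- params[[paste0("site.", side, ".Wc")]]
    bc <- params[[paste0("site.", side, ".bc")]]
    cs <- params[[paste0("site.", side, ".cs")]]
    sc <- vapply(v, function(vi) o_dot(tanh(bc + o_matvec(Wc, vi)), cs), 0)
    gamma <- o_softmax(sc)
    r <- numeric(2 * cfg$h)
    for (i in seq_along(v)) r <- r + gamma[i] * v[[i]]
    list(r = r, gamma = gamma)
  }
  ra <- site_r(va, "a"); rd <- site_r(vd, "d")
  # head
  z1 <- pmax(params$head.br + o_matvec(params$head.Wr, c(ra$r, rd$r)), 0)
  logit <- params$head.bp + o_dot(z1, drop(params$head.wp))
  list(score = o_sigmoid(logit),
       alpha_a = t(vapply(enc_a, `[[`, numeric(cfg$L), "alpha")),
       alpha_d = t(vapply(enc_d, `[[`, numeric(cfg$L), "alpha")),
       beta_a = beta_a, beta_d = beta_d,
       gamma_a = ra$gamma, gamma_d = rd$gamma)
}

# Element-wise BCE + L2 loss oracle.
oracle_loss <- function(scores, labels, params = NULL, lambda = 0) {
  tot <- 0
  for (i in seq_along(scores)) {
    p <- min(max(scores[i], 1e-7), 1 - 1e-7)
    tot <- tot - (labels[i] * log(p) + (1 - labels[i]) * log(1 - p))
  }
  l2 <- 0
  if (lambda > 0) for (w in params) l2 <- l2 + sum(w * w)
  tot / length(scores) + lambda * l2
}

# Exhaustive pairwise AUC oracle: fraction of (pos, neg) pairs ranked
# correctly, ties counting one half.
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (if (p > n) 1 else if (p == n) 0.5 else 0)
  tot / (length(pos) * length(neg))
}
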