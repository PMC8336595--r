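#' Model configuration
#'
#' Hyperparameters of the junction-attention network. Defaults are the
#' published operating point: 3-mers embedded in 128 dimensions, flanking
#' windows of L = 4 positions, GRU hidden size 128 per direction, attention
#' vectors of size 16 and a 128-unit pre-output layer.
#'
#' @param K k-mer size.
#' @param l k-mer embedding dimension.
#' @param L Flanking-window length.
#' @param h GRU hidden size per direction (site embeddings are 2h).
#' @param a_dim Size of all attention vectors.
#' @param f_dim Hidden units of the pre-output fully connected layer.
#' @param lambda_l2 L2-regularization weight on all trainable parameters.
#' @return A \code{model_config} list.
#' @export
model_config <- function(K = 3L, l = 128L, L = 4L, h = 128L, a_dim = 16L,
                         f_dim = 128L, lambda_l2 = 1e-3) {
  cfg <- list(K = as.integer(K), l = as.integer(l), L = as.integer(L),
              h = as.integer(h), a_dim = as.integer(a_dim),
              f_dim = as.integer(f_dim), lambda_l2 = as.numeric(lambda_l2))
  stopifnot(all(vapply(cfg[1:6], function(x) x >= 1L, logical(1))), cfg$lambda_l2 >= 0)
  structure(cfg, class = "model_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Decorrelate RNG streams by purpose: two internal uses given the same user
# seed must not replay the same stream (e.g. a group shuffle reproducing the
# label-assignment permutation), so each use salts the seed with a label.
mix_seed <- function(seed, salt) {
  s <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.double(seed) * 7919 + s * 104729) %% 2147483629)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

gru_param_names <- c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wh", "Uh", "bh")

init_gru <- function(l, h) {
  list(Wz = glorot(l, h), Uz = glorot(h, h), bz = numeric(h),
       Wr = glorot(l, h), Ur = glorot(h, h), br = numeric(h),
       Wh = glorot(l, h), Uh = glorot(h, h), bh = numeric(h))
}

#' Initialize model parameters
#'
#' Dense and recurrent weights use fan-based (Glorot) uniform initialization,
#' biases start at zero, attention vectors are free learned vectors. The pad
#' k-mer (index \code{4^K}) has its own trainable embedding row.
#'
#' @param cfg A \code{\link{model_config}}.
#' @param seed Integer RNG seed; initialization is fully reproducible.
#' @return Flat named list of parameter arrays (class \code{model_params}).
#' @export
init_params <- function(cfg, seed = 1L) {
  with_seed(seed, {
    p <- list()
    p$E <- glorot(4L^cfg$K + 1L, cfg$l)
    for (side in c("a", "d")) for (dir in c("fwd", "bwd")) {
      g <- init_gru(cfg$l, cfg$h)
      for (nm in gru_param_names) p[[paste("gru", side, dir, nm, sep = ".")]] <- g[[nm]]
    }
    for (side in c("a", "d")) {
      p[[paste0("kmer.", side, ".Wt")]] <- glorot(2L * cfg$h, cfg$a_dim)
      p[[paste0("kmer.", side, ".bt")]] <- numeric(cfg$a_dim)
      p[[paste0("kmer.", side, ".ts")]] <- stats::runif(cfg$a_dim, -sqrt(6 / (cfg$a_dim + 1)),
                                                        sqrt(6 / (cfg$a_dim + 1)))
      p[[paste0("site.", side, ".Wc")]] <- glorot(2L * cfg$h, cfg$a_dim)
      p[[paste0("site.", side, ".bc")]] <- numeric(cfg$a_dim)
      p[[paste0("site.", side, ".cs")]] <- stats::runif(cfg$a_dim, -sqrt(6 / (cfg$a_dim + 1)),
                                                        sqrt(6 / (cfg$a_dim + 1)))
    }
    p$head.Wr <- glorot(4L * cfg$h, cfg$f_dim)
    p$head.br <- numeric(cfg$f_dim)
    p$head.wp <- glorot(cfg$f_dim, 1L)
    p$head.bp <- 0
    structure(p, class = "model_params", config = cfg, seed = as.integer(seed))
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with max subtraction for stability.
row_softmax <- function(x) {
  e <- exp(x - x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))])
  e / rowSums(e)
}

# One GRU pass over a stacked input matrix Xall ((L*N) x l; rows of position
# t are (t-1)*N + 1:N), in the given order of positions. The three input
# projections are fused into one matmul; each step needs two more.
gru_run <- function(Xall, par, order, N, L, h) {
  XP <- Xall %*% cbind(par$Wz, par$Wr, par$Wh)
  XP <- XP + rep(c(par$bz, par$br, par$bh), each = nrow(XP))  # bias folded in once
  Ucat2 <- cbind(par$Uz, par$Ur)
  iz <- seq_len(h); ir <- h + iz; ih <- 2L * h + iz
  H <- vector("list", L)
  cache <- vector("list", L)
  H_prev <- matrix(0, N, h)
  for (t in order) {
    rows <- (t - 1L) * N + seq_len(N)
    P2 <- H_prev %*% Ucat2
    Z <- sigmoid(XP[rows, iz, drop = FALSE] + P2[, iz, drop = FALSE])
    Rt <- sigmoid(XP[rows, ir, drop = FALSE] + P2[, ir, drop = FALSE])
    RH <- Rt * H_prev
    Hh <- tanh(XP[rows, ih, drop = FALSE] + RH %*% par$Uh)
    Ht <- (1 - Z) * H_prev + Z * Hh
    H[[t]] <- Ht
    cache[[t]] <- list(Z = Z, Rt = Rt, Hh = Hh, H_prev = H_prev, RH = RH)
    H_prev <- Ht
  }
  list(H = H, cache = cache)
}

get_gru <- function(params, side, dir) {
  out <- lapply(gru_param_names, function(nm) params[[paste("gru", side, dir, nm, sep = ".")]])
  names(out) <- gru_param_names
  out
}

# Encode one side's flanking windows: embedding -> BiGRU -> k-mer attention.
# ids: N x L matrix of 0-based vocabulary indices.
encode_side <- function(ids, side, params, cfg) {
  L <- ncol(ids); N <- nrow(ids); h <- cfg$h
  Xall <- params$E[as.vector(ids) + 1L, , drop = FALSE]   # (L*N) x l, step-major
  fw <- gru_run(Xall, get_gru(params, side, "fwd"), seq_len(L), N, L, h)
  bw <- gru_run(Xall, get_gru(params, side, "bwd"), rev(seq_len(L)), N, L, h)
  Hcat_all <- matrix(0, L * N, 2L * h)
  for (t in seq_len(L))
    Hcat_all[(t - 1L) * N + seq_len(N), ] <- cbind(fw$H[[t]], bw$H[[t]])
  Wt <- params[[paste0("kmer.", side, ".Wt")]]
  bt <- params[[paste0("kmer.", side, ".bt")]]
  ts <- params[[paste0("kmer.", side, ".ts")]]
  Gall <- tanh(Hcat_all %*% Wt + rep(bt, each = L * N))
  s <- matrix(Gall %*% ts, N, L)
  alpha <- row_softmax(s)
  W <- matrix(0, N, 2L * h)
  for (t in seq_len(L))
    W <- W + alpha[, t] * Hcat_all[(t - 1L) * N + seq_len(N), , drop = FALSE]
  list(ids = ids, Xall = Xall, fw = fw, bw = bw, Hcat_all = Hcat_all,
       Gall = Gall, alpha = alpha, W = W)
}

# Masked softmax of a score vector restricted to the first m entries (the
# unmasked sites); callers slice to unmasked rows before calling, so this is
# a plain stable softmax.
vec_softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Encode junction flanking windows into site embeddings
#'
#' Embedding lookup, bidirectional GRU over the L window positions, and
#' k-mer attention pooling, for one side (acceptor or donor). Acceptor and
#' donor encoders use disjoint parameters.
#'
#' @param ids Integer matrix \code{[M x L]} of 0-based k-mer vocabulary
#'   indices (one row per site).
#' @param side \code{"a"} (acceptor) or \code{"d"} (donor).
#' @param params,cfg Model parameters and configuration.
#' @return List with \code{W} \code{[M x 2h]} site embeddings and
#'   \code{alpha} \code{[M x L]} k-mer attention weights.
#' @export
encode_junctions <- function(ids, side = c("a", "d"), params, cfg) {
  side <- match.arg(side)
  ids <- as.matrix(ids)
  if (ncol(ids) != cfg$L) stop("ids must have L = ", cfg$L, " columns")
  if (any(ids < 0L) || any(ids > 4L^cfg$K))
    stop("k-mer indices must lie in [0, 4^K]")
  enc <- encode_side(ids, side, params, cfg)
  list(W = enc$W, alpha = enc$alpha)
}

#' Cross-attention between acceptor and donor site embeddings
#'
#' Single-head dot-product attention in both directions: each acceptor
#' attends over all donors (weights \code{beta_a}) and each donor over all
#' acceptors (\code{beta_d}); the cross-attentive embeddings are the
#' weight-averaged embeddings of the opposite side.
#'
#' @param W_a Acceptor embeddings \code{[m x 2h]}.
#' @param W_d Donor embeddings \code{[n x 2h]}.
#' @return List with \code{V_a} \code{[m x 2h]}, \code{V_d} \code{[n x 2h]},
#'   \code{beta_a} \code{[m x n]} and \code{beta_d} \code{[n x m]}.
#' @export
cross_attention <- function(W_a, W_d) {
  W_a <- as.matrix(W_a); W_d <- as.matrix(W_d)
  if (nrow(W_a) < 1L || nrow(W_d) < 1L) stop("need >= 1 unmasked site per side")
  if (ncol(W_a) != ncol(W_d)) stop("embedding dimensions differ")
  S <- W_a %*% t(W_d)
  beta_a <- row_softmax(S)
  beta_d <- row_softmax(t(S))
  list(V_a = beta_a %*% W_d, V_d = beta_d %*% W_a,
       beta_a = beta_a, beta_d = beta_d)
}

#' Site attention pooling over cross-attentive embeddings
#'
#' Scores each site by the inner product of \code{tanh(F_c(v_i))} with the
#' learned attention vector, softmax-normalizes over sites, and returns the
#' weighted average embedding.
#'
#' @param V Cross-attentive site embeddings \code{[M x 2h]}.
#' @param side \code{"a"} or \code{"d"} (disjoint parameters per side).
#' @param params Model parameters.
#' @return List with \code{r} (length-2h representation), \code{gamma}
#'   (\code{[M]} site weights) and the projected scores matrix \code{C}.
#' @export
site_attention <- function(V, side = c("a", "d"), params) {
  side <- match.arg(side)
  V <- as.matrix(V)
  if (nrow(V) < 1L) stop("need >= 1 unmasked site")
  Wc <- params[[paste0("site.", side, ".Wc")]]
  bc <- params[[paste0("site.", side, ".bc")]]
  cs <- params[[paste0("site.", side, ".cs")]]
  C <- tanh(V %*% Wc + rep(bc, each = nrow(V)))
  gamma <- vec_softmax(drop(C %*% cs))
  list(r = drop(crossprod(V, gamma)), gamma = gamma, C = C)
}

#' Forward pass of the junction-attention network
#'
#' Runs the full network on a padded batch: k-mer embedding, bidirectional GRU
#' junction encoders with k-mer attention (per side), cross-attention between
#' each gene's acceptor and donor site embeddings, site attention, and the
#' sigmoid prediction head. Padded sites are excluded exactly (sliced out
#' before cross-attention), so scores are invariant to pad content.
#'
#' @param batch A \code{junction_batch} from \code{\link{build_batch}}.
#' @param params Model parameters from \code{\link{init_params}}.
#' @param cfg The matching \code{\link{model_config}}.
#' @param keep \code{"none"} for scores only, \code{"maps"} to also return
#'   per-record attention maps, \code{"cache"} for all backward-pass caches.
#' @return List with \code{scores} (vector in (0,1)), \code{logits}, and
#'   optionally \code{maps} (per record: \code{alpha_a}, \code{alpha_d}
#'   \code{[m x L]}, \code{beta_a}, \code{beta_d} \code{[m x m]},
#'   \code{gamma_a}, \code{gamma_d} \code{[m]}) and \code{cache}.
#' @export
model_forward <- function(batch, params, cfg, keep = c("none", "maps", "cache")) {
  keep <- match.arg(keep)
  dims <- dim(batch$acceptor_ids)
  B <- dims[1L]; M <- dims[2L]; L <- dims[3L]
  N <- B * M; h <- cfg$h
  acc_ids <- matrix(batch$acceptor_ids, N, L)
  don_ids <- matrix(batch$donor_ids, N, L)
  enc_a <- encode_side(acc_ids, "a", params, cfg)
  enc_d <- encode_side(don_ids, "d", params, cfg)

  Rcat <- matrix(0, B, 4L * h)
  rec <- vector("list", B)
  maps <- if (keep != "none") vector("list", B) else NULL
  for (b in seq_len(B)) {
    m <- batch$n_exons[b]
    if (m < 1L) stop("record ", b, ": all sites masked")
    idx <- b + (seq_len(m) - 1L) * B
    Wa <- enc_a$W[idx, , drop = FALSE]
    Wd <- enc_d$W[idx, , drop = FALSE]
    ca <- cross_attention(Wa, Wd)
    sa <- site_attention(ca$V_a, "a", params)
    sd <- site_attention(ca$V_d, "d", params)
    Rcat[b, ] <- c(sa$r, sd$r)
    rec[[b]] <- list(idx = idx, m = m, Wa = Wa, Wd = Wd, beta_a = ca$beta_a,
                     beta_d = ca$beta_d, Va = ca$V_a, Vd = ca$V_d,
                     Ca = sa$C, Cd = sd$C, gamma_a = sa$gamma, gamma_d = sd$gamma)
    if (keep != "none") {
      maps[[b]] <- list(id = batch$ids[b],
                        alpha_a = enc_a$alpha[idx, , drop = FALSE],
                        alpha_d = enc_d$alpha[idx, , drop = FALSE],
                        beta_a = ca$beta_a, beta_d = ca$beta_d,
                        gamma_a = sa$gamma, gamma_d = sd$gamma)
    }
  }
  A1 <- sweep(Rcat %*% params$head.Wr, 2L, params$head.br, "+")
  Z1 <- pmax(A1, 0)
  logits <- drop(Z1 %*% params$head.wp) + params$head.bp
  scores <- sigmoid(logits)
  out <- list(scores = scores, logits = logits)
  if (keep != "none") out$maps <- maps
  if (keep == "cache") {
    out$cache <- list(enc_a = enc_a, enc_d = enc_d, rec = rec, Rcat = Rcat,
                      A1 = A1, Z1 = Z1, B = B, M = M, L = L, N = N,
                      acc_ids = acc_ids, don_ids = don_ids)
  }
  out
}

clamp01 <- function(x, eps = 1e-7) pmin(pmax(x, eps), 1 - eps)

#' Binary cross-entropy loss with L2 regularization
#'
#' Mean over the batch of \eqn{-[y \log \hat y + (1-y)\log(1-\hat y)]} plus
#' \eqn{\lambda \lVert\theta\rVert^2} over all trainable parameters. Scores
#' are clamped to \code{[1e-7, 1 - 1e-7]} inside the logs.
#'
#' @param scores Predicted probabilities in (0,1).
#' @param labels Binary labels.
#' @param params Model parameters (for the L2 term); may be \code{NULL} when
#'   \code{lambda_l2 = 0}.
#' @param lambda_l2 L2 weight.
#' @return Non-negative finite scalar.
#' @export
model_loss <- function(scores, labels, params = NULL, lambda_l2 = 0) {
  if (any(!is.finite(scores)) || any(!is.finite(labels))) stop("NaN/Inf in loss inputs")
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  p <- clamp01(scores)
  bce <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  l2 <- 0
  if (lambda_l2 > 0) {
    stopifnot(!is.null(params))
    l2 <- lambda_l2 * sum(vapply(params, function(w) sum(w^2), numeric(1)))
  }
  bce + l2
}
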