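# Hand-written reverse-mode differentiation of the forward pass. Every block
# mirrors a forward block in model.R; gradient correctness is property-tested
# against central finite differences (see tests).

zero_like <- function(params) lapply(params, function(w) w * 0)

# Backward through one GRU pass in the stacked layout. dH_ext: list per
# position of external gradients on the hidden states. The per-step gate
# gradients are written into one (L*N) x 3h matrix so the input-projection
# parameter gradients and dXall need a single crossprod / matmul each.
gru_backward <- function(Xall, par, order, run, dH_ext, N, L, h) {
  Wcat <- cbind(par$Wz, par$Wr, par$Wh)
  Ucat2 <- cbind(par$Uz, par$Ur)
  dAall <- matrix(0, L * N, 3L * h)
  gUz <- par$Uz * 0; gUr <- par$Ur * 0; gUh <- par$Uh * 0
  dH_carry <- matrix(0, N, h)
  for (t in rev(order)) {
    cc <- run$cache[[t]]
    dH <- dH_ext[[t]] + dH_carry
    dZ <- dH * (cc$Hh - cc$H_prev)
    dHh <- dH * cc$Z
    dH_prev <- dH * (1 - cc$Z)
    dAh <- dHh * (1 - cc$Hh^2)
    dRH <- dAh %*% t(par$Uh)
    dRt <- dRH * cc$H_prev
    dH_prev <- dH_prev + dRH * cc$Rt
    dAr <- dRt * cc$Rt * (1 - cc$Rt)
    dAz <- dZ * cc$Z * (1 - cc$Z)
    dAzr <- cbind(dAz, dAr)
    rows <- (t - 1L) * N + seq_len(N)
    dAall[rows, seq_len(2L * h)] <- dAzr
    dAall[rows, 2L * h + seq_len(h)] <- dAh
    gU2 <- crossprod(cc$H_prev, dAzr)
    gUz <- gUz + gU2[, seq_len(h), drop = FALSE]
    gUr <- gUr + gU2[, h + seq_len(h), drop = FALSE]
    gUh <- gUh + crossprod(cc$RH, dAh)
    # H_prev reaches Ah only through RH = Rt * H_prev (handled via dRH above)
    dH_carry <- dH_prev + dAzr %*% t(Ucat2)
  }
  gW <- crossprod(Xall, dAall)
  gb <- colSums(dAall)
  iz <- seq_len(h); ir <- h + iz; ih <- 2L * h + iz
  g <- list(Wz = gW[, iz, drop = FALSE], Uz = gUz, bz = gb[iz],
            Wr = gW[, ir, drop = FALSE], Ur = gUr, br = gb[ir],
            Wh = gW[, ih, drop = FALSE], Uh = gUh, bh = gb[ih])
  list(g = g, dXall = dAall %*% t(Wcat))
}

# Backward through one side's encoder given dW on the site embeddings.
encode_side_backward <- function(enc, dW, side, params, cfg, grads) {
  L <- ncol(enc$alpha); h <- cfg$h; N <- nrow(dW)
  Wt <- params[[paste0("kmer.", side, ".Wt")]]
  ts <- params[[paste0("kmer.", side, ".ts")]]
  alpha <- enc$alpha
  # w = sum_t alpha_t * Hcat_t
  dalpha <- matrix(0, N, L)
  dHcat_all <- matrix(0, L * N, 2L * h)
  for (t in seq_len(L)) {
    rows <- (t - 1L) * N + seq_len(N)
    dalpha[, t] <- rowSums(dW * enc$Hcat_all[rows, , drop = FALSE])
    dHcat_all[rows, ] <- alpha[, t] * dW
  }
  ds <- alpha * (dalpha - rowSums(alpha * dalpha))
  dsall <- as.vector(ds)                          # step-major, matches Gall
  dAall <- (dsall %o% ts) * (1 - enc$Gall^2)
  key <- function(x) paste0("kmer.", side, ".", x)
  grads[[key("Wt")]] <- grads[[key("Wt")]] + crossprod(enc$Hcat_all, dAall)
  grads[[key("bt")]] <- grads[[key("bt")]] + colSums(dAall)
  grads[[key("ts")]] <- grads[[key("ts")]] + drop(crossprod(enc$Gall, dsall))
  dHcat_all <- dHcat_all + dAall %*% t(Wt)
  # split into GRU direction gradients, per position
  dHfw <- vector("list", L); dHbw <- vector("list", L)
  for (t in seq_len(L)) {
    rows <- (t - 1L) * N + seq_len(N)
    dHfw[[t]] <- dHcat_all[rows, seq_len(h), drop = FALSE]
    dHbw[[t]] <- dHcat_all[rows, h + seq_len(h), drop = FALSE]
  }
  bf <- gru_backward(enc$Xall, get_gru(params, side, "fwd"), seq_len(L), enc$fw,
                     dHfw, N, L, h)
  bb <- gru_backward(enc$Xall, get_gru(params, side, "bwd"), rev(seq_len(L)), enc$bw,
                     dHbw, N, L, h)
  for (nm in gru_param_names) {
    kf <- paste("gru", side, "fwd", nm, sep = ".")
    kb <- paste("gru", side, "bwd", nm, sep = ".")
    grads[[kf]] <- grads[[kf]] + bf$g[[nm]]
    grads[[kb]] <- grads[[kb]] + bb$g[[nm]]
  }
  # embedding gradients: scatter-add stacked dX rows by vocabulary id
  rs <- rowsum(bf$dXall + bb$dXall, group = as.vector(enc$ids))
  rows <- as.integer(rownames(rs)) + 1L
  grads$E[rows, ] <- grads$E[rows, , drop = FALSE] + rs
  grads
}

softmax_rows_backward <- function(P, dP) P * (dP - rowSums(P * dP))

#' Backward pass: gradients of the loss with respect to all parameters
#'
#' Given a forward cache and the gradient of the (mean) loss with respect to
#' the pre-sigmoid logits, accumulates gradients through the head, site
#' attention, cross-attention, k-mer attention, BiGRUs and the embedding
#' table. L2 gradients are not included here (the training step adds
#' \code{2 lambda theta}).
#'
#' @param fwd Output of \code{model_forward(..., keep = "cache")}.
#' @param batch The batch passed to the forward pass.
#' @param params Model parameters.
#' @param cfg Model configuration.
#' @param dlogits Gradient of the loss w.r.t. each record's logit.
#' @return Named list of gradients matching \code{params}.
#' @export
model_backward <- function(fwd, batch, params, cfg, dlogits) {
  cache <- fwd$cache
  stopifnot(!is.null(cache))
  grads <- zero_like(params)
  h <- cfg$h; B <- cache$B

  # head
  dZ1 <- dlogits %o% drop(params$head.wp)
  grads$head.wp <- crossprod(cache$Z1, dlogits)
  grads$head.bp <- sum(dlogits)
  dA1 <- dZ1 * (cache$A1 > 0)
  grads$head.Wr <- crossprod(cache$Rcat, dA1)
  grads$head.br <- colSums(dA1)
  dRcat <- dA1 %*% t(params$head.Wr)

  N <- cache$N
  dW_a <- matrix(0, N, 2L * h)
  dW_d <- matrix(0, N, 2L * h)

  for (b in seq_len(B)) {
    rc <- cache$rec[[b]]
    m <- rc$m
    dra <- dRcat[b, seq_len(2L * h)]
    drd <- dRcat[b, 2L * h + seq_len(2L * h)]

    # site attention backward, acceptor side: ra = t(Va) gamma_a
    site_bwd <- function(dr, V, C, gamma, Wc_key, bc_key, cs_key) {
      Wc <- params[[Wc_key]]; cs <- params[[cs_key]]
      dV <- gamma %o% dr
      dgamma <- drop(V %*% dr)
      dsc <- gamma * (dgamma - sum(gamma * dgamma))
      dA <- (dsc %o% cs) * (1 - C^2)
      grads[[Wc_key]] <<- grads[[Wc_key]] + crossprod(V, dA)
      grads[[bc_key]] <<- grads[[bc_key]] + colSums(dA)
      grads[[cs_key]] <<- grads[[cs_key]] + drop(crossprod(C, dsc))
      dV + dA %*% t(Wc)
    }
    dVa <- site_bwd(dra, rc$Va, rc$Ca, rc$gamma_a, "site.a.Wc", "site.a.bc", "site.a.cs")
    dVd <- site_bwd(drd, rc$Vd, rc$Cd, rc$gamma_d, "site.d.Wc", "site.d.bc", "site.d.cs")

    # cross-attention backward
    dbeta_a <- dVa %*% t(rc$Wd)
    dWd_b <- crossprod(rc$beta_a, dVa)
    dbeta_d <- dVd %*% t(rc$Wa)
    dWa_b <- crossprod(rc$beta_d, dVd)
    dS <- softmax_rows_backward(rc$beta_a, dbeta_a) +
      t(softmax_rows_backward(rc$beta_d, dbeta_d))
    dWa_b <- dWa_b + dS %*% rc$Wd
    dWd_b <- dWd_b + t(dS) %*% rc$Wa
    dW_a[rc$idx, ] <- dW_a[rc$idx, , drop = FALSE] + dWa_b
    dW_d[rc$idx, ] <- dW_d[rc$idx, , drop = FALSE] + dWd_b
  }

  grads <- encode_side_backward(cache$enc_a, dW_a, "a", params, cfg, grads)
  grads <- encode_side_backward(cache$enc_d, dW_d, "d", params, cfg, grads)
  grads
}

#' Loss value and parameter gradients for one batch
#'
#' Convenience wrapper combining forward, BCE gradient at the logits
#' (\code{(score - y) / B}), backward pass and L2 gradients.
#'
#' @inheritParams model_backward
#' @param lambda_l2 L2 weight; adds \code{2 lambda theta} to every gradient.
#' @return List with \code{loss}, \code{scores} and \code{grads}.
#' @export
model_loss_grads <- function(batch, params, cfg, lambda_l2 = cfg$lambda_l2) {
  fwd <- model_forward(batch, params, cfg, keep = "cache")
  y <- batch$labels
  loss <- model_loss(fwd$scores, y, params, lambda_l2)
  dlogits <- (fwd$scores - y) / length(y)
  grads <- model_backward(fwd, batch, params, cfg, dlogits)
  if (lambda_l2 > 0)
    grads <- Map(function(g, w) g + 2 * lambda_l2 * w, grads, params)
  list(loss = loss, scores = fwd$scores, grads = grads)
}
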