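#' Training configuration
#'
#' Defaults follow the published setup: AMSGrad with learning rate 1e-3,
#' decay rates (0.9, 0.999), batch size 64 and L2 weight 1e-3. "Trained until
#' convergence" is operationalized as early stopping on validation loss with
#' a configurable patience over a group-aware validation carve-out.
#'
#' @param learning_rate AMSGrad step size.
#' @param beta1,beta2 Exponential decay rates of the first/second moments.
#' @param amsgrad Use the non-decreasing second-moment maximum (AMSGrad);
#'   plain Adam when \code{FALSE}.
#' @param batch_size Minibatch size.
#' @param lambda_l2 L2-regularization weight.
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience in epochs on validation loss.
#' @param val_fraction Fraction of the training records (group-aware) held out
#'   for early stopping.
#' @param seed RNG seed governing the validation split, shuffling and
#'   parameter initialization.
#' @param deterministic Use R's internal matrix product instead of BLAS for
#'   bit-identical reruns (BLAS kernels can differ by 1 ulp depending on heap
#'   alignment and threading); roughly 1.5x slower.
#' @return A \code{train_config} list.
#' @export
train_config <- function(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         amsgrad = TRUE, batch_size = 64L, lambda_l2 = 1e-3,
                         max_epochs = 100L, patience = 5L, val_fraction = 0.1,
                         seed = 1L, deterministic = FALSE) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            batch_size >= 1L, max_epochs >= 0L, val_fraction >= 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 amsgrad = isTRUE(amsgrad), batch_size = as.integer(batch_size),
                 lambda_l2 = lambda_l2, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), val_fraction = val_fraction,
                 seed = as.integer(seed), deterministic = isTRUE(deterministic)),
            class = "train_config")
}

# Evaluate expr with the fully deterministic internal matrix product.
with_deterministic <- function(expr) {
  old <- options(matprod = "internal")
  on.exit(options(old))
  force(expr)
}

amsgrad_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), vhat = zero_like(params), t = 0L)
}

amsgrad_step <- function(params, grads, state, tc, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - tc$beta1^state$t
  bc2 <- 1 - tc$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- tc$beta1 * state$m[[nm]] + (1 - tc$beta1) * g
    state$v[[nm]] <- tc$beta2 * state$v[[nm]] + (1 - tc$beta2) * g^2
    vv <- if (tc$amsgrad) {
      state$vhat[[nm]] <- pmax(state$vhat[[nm]], state$v[[nm]])
      state$vhat[[nm]]
    } else state$v[[nm]]
    params[[nm]] <- params[[nm]] -
      tc$learning_rate * (state$m[[nm]] / bc1) / (sqrt(vv / bc2) + eps)
  }
  list(params = params, state = state)
}

# Subset a featurized batch by record indices (keeps the global M_max so
# records can be featurized once and sliced per minibatch).
slice_batch <- function(batch, idx) {
  structure(list(acceptor_ids = batch$acceptor_ids[idx, , , drop = FALSE],
                 donor_ids = batch$donor_ids[idx, , , drop = FALSE],
                 site_mask = batch$site_mask[idx, , drop = FALSE],
                 labels = batch$labels[idx], n_exons = batch$n_exons[idx],
                 ids = batch$ids[idx], L = batch$L, K = batch$K,
                 pad_index = batch$pad_index),
            class = "junction_batch")
}

# Group-aware holdout: greedily assigns shuffled groups to the holdout until
# it reaches `fraction` of the records. Returns logical holdout mask.
group_holdout <- function(groups, fraction, seed) {
  n <- length(groups)
  if (fraction <= 0) return(rep(FALSE, n))
  tab <- split(seq_len(n), groups)
  ord <- with_seed(mix_seed(seed, "group-holdout"), sample.int(length(tab)))
  hold <- rep(FALSE, n)
  target <- fraction * n
  taken <- 0L
  for (gi in ord) {
    if (taken >= target) break
    hold[tab[[gi]]] <- TRUE
    taken <- taken + length(tab[[gi]])
  }
  hold
}

#' Train the junction-attention model
#'
#' Minibatch AMSGrad on binary cross-entropy with L2 regularization. A
#' group-aware fraction of the training records is carved out for early
#' stopping on validation loss; the parameters at the best validation loss
#' are returned. Fully reproducible given the seed.
#'
#' @param dataset A labeled \code{junction_dataset} with both classes present.
#' @param model_cfg A \code{\link{model_config}}.
#' @param tc A \code{\link{train_config}}.
#' @param quiet Suppress per-epoch messages.
#' @return List with \code{params} (best), \code{log} (data frame: epoch,
#'   train_loss, val_loss, val_acc, val_auc), \code{best_epoch},
#'   \code{model_cfg} and \code{train_cfg}.
#' @export
train_model <- function(dataset, model_cfg, tc = train_config(), quiet = TRUE) {
  if (tc$deterministic) {
    old <- options(matprod = "internal")
    on.exit(options(old), add = TRUE)
  }
  labs <- dataset_labels(dataset)
  if (any(is.na(labs))) stop("all records must be labeled for training")
  if (length(unique(labs)) < 2L) stop("training requires both classes")
  fc <- feat_config(L = model_cfg$L, K = model_cfg$K)
  full <- build_batch(dataset, fc)
  groups <- dataset_groups(dataset)
  val_mask <- group_holdout(groups, tc$val_fraction, seed = tc$seed + 1L)
  if (all(val_mask)) stop("validation carve-out consumed all records")
  tr_idx <- which(!val_mask); va_idx <- which(val_mask)
  params <- init_params(model_cfg, seed = tc$seed)
  if (tc$max_epochs == 0L)
    return(list(params = params, log = data.frame(), best_epoch = 0L,
                model_cfg = model_cfg, train_cfg = tc))
  state <- amsgrad_init(params)
  va_batch <- if (length(va_idx)) slice_batch(full, va_idx) else NULL
  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- vector("list", tc$max_epochs)
  bad_epochs <- 0L
  for (epoch in seq_len(tc$max_epochs)) {
    ord <- with_seed(mix_seed(tc$seed, paste0("epoch-", epoch)), sample(tr_idx))
    n_batches <- ceiling(length(ord) / tc$batch_size)
    tl <- 0
    for (k in seq_len(n_batches)) {
      idx <- ord[((k - 1L) * tc$batch_size + 1L):min(k * tc$batch_size, length(ord))]
      res <- model_loss_grads(slice_batch(full, idx), params, model_cfg, tc$lambda_l2)
      step <- amsgrad_step(params, res$grads, state, tc)
      params <- step$params; state <- step$state
      tl <- tl + res$loss * length(idx)
    }
    tl <- tl / length(ord)
    if (!is.null(va_batch)) {
      vs <- model_forward(va_batch, params, model_cfg)$scores
      vl <- model_loss(vs, va_batch$labels, params, tc$lambda_l2)
      vy <- va_batch$labels
      vacc <- mean((vs > 0.5) == (vy == 1))
      vauc <- if (length(unique(vy)) == 2L) auc_rank(vy, vs) else NA_real_
    } else {
      vl <- tl; vacc <- NA_real_; vauc <- NA_real_
    }
    log[[epoch]] <- data.frame(epoch = epoch, train_loss = tl, val_loss = vl,
                               val_acc = vacc, val_auc = vauc)
    if (!quiet) message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                                epoch, tl, vl, vacc))
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = params, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= tc$patience) break
    }
  }
  list(params = best$params, log = do.call(rbind, log[!vapply(log, is.null, logical(1))]),
       best_epoch = best$epoch, model_cfg = model_cfg, train_cfg = tc)
}

#' Score a dataset with a trained model
#'
#' @param fit A fit from \code{\link{train_model}} (or a list with
#'   \code{params} and \code{model_cfg}).
#' @param dataset A \code{junction_dataset}.
#' @param keep Passed to \code{\link{model_forward}} (\code{"maps"} to get
#'   attention maps for discovery).
#' @param deterministic Use the bit-reproducible internal matrix product.
#' @return The forward-pass result with record \code{ids} attached.
#' @export
predict_model <- function(fit, dataset, keep = "none", deterministic = FALSE) {
  if (deterministic) {
    old <- options(matprod = "internal")
    on.exit(options(old), add = TRUE)
  }
  fc <- feat_config(L = fit$model_cfg$L, K = fit$model_cfg$K)
  batch <- build_batch(dataset, fc)
  out <- model_forward(batch, fit$params, fit$model_cfg, keep = keep)
  out$ids <- batch$ids
  out
}

#' Grouped k-fold cross-validation splits
#'
#' Groups (paralog clusters) are atomic: all records of a group land in the
#' same fold. Records without a group id form singleton groups. Groups are
#' assigned greedily (largest first, seeded shuffle among ties) to the
#' currently smallest fold, balancing fold sizes at group granularity.
#'
#' @param dataset A \code{junction_dataset} (or character vector of group ids).
#' @param k Number of folds (>= 2).
#' @param seed RNG seed for the shuffle.
#' @return List of k lists with integer \code{train_idx} and \code{test_idx}.
#' @export
grouped_kfold <- function(dataset, k = 5L, seed = 1L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  groups <- if (inherits(dataset, "junction_dataset")) dataset_groups(dataset)
            else as.character(dataset)
  tab <- split(seq_along(groups), groups)
  if (length(tab) < k) stop("fewer groups (", length(tab), ") than folds (", k, ")")
  ord <- with_seed(mix_seed(seed, "kfold"), sample.int(length(tab)))
  sizes <- lengths(tab)[ord]
  ord <- ord[order(-sizes)]              # largest groups first, shuffled ties
  fold_of <- integer(length(tab))
  fold_sizes <- integer(k)
  for (gi in ord) {
    f <- which.min(fold_sizes)
    fold_of[gi] <- f
    fold_sizes[f] <- fold_sizes[f] + length(tab[[gi]])
  }
  lapply(seq_len(k), function(f) {
    test <- sort(unlist(tab[fold_of == f], use.names = FALSE))
    list(train_idx = setdiff(seq_along(groups), test), test_idx = test)
  })
}

#' Run grouped k-fold cross-validation end to end
#'
#' Trains one model per fold and evaluates it on the held-out fold,
#' reporting per-fold metrics plus their mean and standard deviation.
#'
#' @param dataset Labeled \code{junction_dataset}.
#' @param model_cfg,tc Model and training configuration.
#' @param k Number of folds.
#' @param seed Seed for fold assignment; fold f trains with seed
#'   \code{tc$seed + f}.
#' @param quiet Passed to \code{\link{train_model}}.
#' @return List with \code{folds} (data frame of per-fold metrics) and
#'   \code{summary} (mean and sd rows per metric).
#' @export
cross_validate <- function(dataset, model_cfg, tc = train_config(), k = 5L,
                           seed = 1L, quiet = TRUE) {
  splits <- grouped_kfold(dataset, k = k, seed = seed)
  rows <- lapply(seq_along(splits), function(f) {
    sp <- splits[[f]]
    tcf <- tc; tcf$seed <- tc$seed + f
    fit <- train_model(subset_dataset(dataset, sp$train_idx), model_cfg, tcf, quiet = quiet)
    test <- subset_dataset(dataset, sp$test_idx)
    scores <- predict_model(fit, test)$scores
    met <- evaluate_binary(dataset_labels(test), scores)
    data.frame(fold = f, accuracy = met$accuracy, precision = met$precision,
               sensitivity = met$sensitivity, specificity = met$specificity,
               f1 = met$f1, mcc = met$mcc, auc = met$auc)
  })
  folds <- do.call(rbind, rows)
  metric_cols <- setdiff(names(folds), "fold")
  summary <- data.frame(metric = metric_cols,
                        mean = vapply(folds[metric_cols], mean, numeric(1)),
                        sd = vapply(folds[metric_cols], stats::sd, numeric(1)))
  list(folds = folds, summary = summary)
}
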