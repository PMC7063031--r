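# Training loops: standard aggregate training and the multi-domain
# adversarial procedure (ADANN).
#
# ADANN, per epoch: every participant takes a turn as the *source* domain
# (label 0). Each source batch is paired with a *target* batch (label 1)
# drawn from one uniformly chosen other participant. The two batches pass
# through the network consecutively, each under its own participant's
# batch-norm statistics; only source batches update the stored running
# statistics. The total loss is Ly + lambda * Ld (gesture and domain
# cross-entropy); at the point where the domain head joins the shared
# trunk, its backpropagated gradient is multiplied by a negative reversal
# constant, pushing shared weights toward domain-invariant features while
# the head itself still learns to discriminate domains. Target batches
# contribute only to Ld; their gesture labels are never used.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with initial learning
#' rate 0.0404709, batch size 512, domain-loss weight lambda = 0.1,
#' gradient-reversal constant -1, learning-rate annealing by a factor of 5
#' with patience 15, early stopping after 2 consecutive annealings without
#' a better validation loss.
#'
#' @param lr initial learning rate.
#' @param batch_size windows per batch.
#' @param lambda domain-loss weight (>= 0).
#' @param reversal_constant multiplier applied to the domain-head gradient
#'   at the reversal point.
#' @param anneal_factor learning-rate division factor.
#' @param patience epochs without validation improvement before annealing.
#' @param max_epochs hard cap on epochs.
#' @param seed controls all sampling (shuffling, target-domain choice,
#'   dropout).
#' @export
train_config <- function(lr = 0.0404709, batch_size = 512, lambda = 0.1,
                         reversal_constant = -1, anneal_factor = 5,
                         patience = 15, max_epochs = 100, seed = 1L) {
  .assert(lambda >= 0, "lambda must be >= 0")
  .assert(batch_size >= 1, "batch_size must be >= 1")
  list(lr = lr, batch_size = batch_size, lambda = lambda,
       reversal_constant = reversal_constant, anneal_factor = anneal_factor,
       patience = patience, max_epochs = max_epochs, seed = as.integer(seed))
}

# ---- Adam ----------------------------------------------------------------

.adam_new <- function(params) {
  list(m = .zero_grads(params), v = .zero_grads(params), t = 0)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^state$t)
      vhat <- v / (1 - beta2^state$t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- upd(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# ---- loss + gradient of one batch ---------------------------------------

# Computes Ly + lambda * Ld on one batch and the full parameter gradient.
# domain_label: 0 (source) or 1 (target); include_class: whether gesture
# labels contribute (FALSE for target batches).
.batch_grads <- function(model, windows, labels, participant, cfgt,
                         domain_label = 0L, include_class = TRUE,
                         update_stats = TRUE) {
  fw <- forward(model, windows, participant = participant, mode = "train",
                update_stats = update_stats, keep = "full")
  model <- fw$model
  nb <- nrow(fw$class_logits)
  grads <- .zero_grads(model$params)
  loss_y <- 0
  dh <- matrix(0, nb, model$config$head_in)
  if (include_class) {
    ce <- .ce_loss_grad(fw$class_logits, labels)
    loss_y <- ce$loss
    grads$head_class$W <- crossprod(fw$h, ce$grad)
    grads$head_class$b <- colSums(ce$grad)
    dh <- dh + ce$grad %*% t(model$params$head_class$W)
  }
  loss_d <- 0
  if (cfgt$lambda > 0) {
    cd <- .ce_loss_grad(fw$domain_logits, rep(as.integer(domain_label), nb))
    loss_d <- cd$loss
    gd <- cd$grad * cfgt$lambda
    grads$head_domain$W <- crossprod(fw$h, gd)
    grads$head_domain$b <- colSums(gd)
    # gradient reversal: the trunk sees the domain gradient negated
    dh <- dh + cfgt$reversal_constant * (gd %*% t(model$params$head_domain$W))
  }
  bk <- .backward_blocks(model, fw, dh, mode = "train")
  grads$blocks <- bk$block_grads
  list(model = model, grads = grads, loss_y = loss_y, loss_d = loss_d)
}

# mean gesture cross-entropy over a set of windows, eval mode
.eval_loss <- function(model, dataset, idx, participant, batch_size = 512) {
  tot <- 0; n <- 0
  for (s in split(idx, ceiling(seq_along(idx) / batch_size))) {
    fw <- forward(model, dataset$windows[, , s, drop = FALSE],
                  participant = participant, mode = "eval")
    ce <- .ce_loss_grad(fw$class_logits, dataset$meta$gesture[s])
    tot <- tot + ce$loss * length(s)
    n <- n + length(s)
  }
  tot / n
}

# annealing / early-stopping bookkeeping shared by both loops
.lr_controller <- function(cfgt) {
  env <- new.env()
  env$best <- Inf; env$wait <- 0; env$lr <- cfgt$lr; env$strikes <- 0
  env$update <- function(val_loss) {
    if (val_loss < env$best - 1e-12) {
      env$best <- val_loss; env$wait <- 0; env$strikes <- 0
      return("improved")
    }
    env$wait <- env$wait + 1
    if (env$wait > cfgt$patience) {
      env$lr <- env$lr / cfgt$anneal_factor
      env$wait <- 0
      env$strikes <- env$strikes + 1
      if (env$strikes >= 2) return("stop")
      return("annealed")
    }
    "waiting"
  }
  env
}

#' Standard aggregate training
#'
#' Cross-entropy training on the gesture labels, pooling every
#' participant's training windows together under a single shared
#' batch-norm bank (key `"aggregate"`).
#'
#' @param model an `emg_model`.
#' @param dataset an `emg_dataset` with train/val cycles in its split.
#' @param cfgt a [train_config()].
#' @param verbose print a per-epoch line.
#' @return the trained model (best-validation weights) with a `history`
#'   attribute (data frame: epoch, train loss, val loss, lr).
#' @export
train_standard <- function(model, dataset, cfgt = train_config(),
                           verbose = FALSE) {
  tr <- split_indices(dataset, "train")
  va <- split_indices(dataset, "val")
  .assert(length(tr) > 0 && length(va) > 0, "empty train or validation split")
  model <- ensure_bank(model, "aggregate")
  opt <- .adam_new(model$params)
  ctl <- .lr_controller(cfgt)
  hist <- data.frame()
  best_params <- model$params
  best_bn <- model$bn
  .with_seed(cfgt$seed, {
    for (epoch in seq_len(cfgt$max_epochs)) {
      ord <- sample(tr)
      tl <- 0; nb <- 0
      for (s in split(ord, ceiling(seq_along(ord) / cfgt$batch_size))) {
        bg <- .batch_grads(model, dataset$windows[, , s, drop = FALSE],
                           dataset$meta$gesture[s], "aggregate",
                           # standard training has no paired domains
                           utils::modifyList(cfgt, list(lambda = 0)))
        model <- bg$model
        st <- .adam_step(model$params, bg$grads, opt, ctl$lr)
        model$params <- st$params; opt <- st$state
        tl <- tl + bg$loss_y; nb <- nb + 1
      }
      vl <- .eval_loss(model, dataset, va, "aggregate")
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / nb,
                                     val_loss = vl, lr = ctl$lr))
      if (verbose) message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                                   epoch, tl / nb, vl, ctl$lr))
      act <- ctl$update(vl)
      if (act == "improved") { best_params <- model$params; best_bn <- model$bn }
      if (act == "stop") break
    }
  })
  model$params <- best_params
  model$bn <- best_bn
  attr(model, "history") <- hist
  model
}

#' Multi-domain adversarial training (ADANN)
#'
#' See the file header for the procedure. Falls back to [train_standard()]
#' with a warning when the training split holds a single participant.
#'
#' @inheritParams train_standard
#' @export
train_adann <- function(model, dataset, cfgt = train_config(),
                        verbose = FALSE) {
  tr <- split_indices(dataset, "train")
  va <- split_indices(dataset, "val")
  .assert(length(tr) > 0 && length(va) > 0, "empty train or validation split")
  parts <- sort(unique(dataset$meta$participant[tr]))
  if (length(parts) < 2) {
    warning("single participant: falling back to standard training")
    return(train_standard(model, dataset, cfgt, verbose))
  }
  by_part <- lapply(parts, function(p) tr[dataset$meta$participant[tr] == p])
  names(by_part) <- as.character(parts)
  for (p in parts) model <- ensure_bank(model, p)
  opt <- .adam_new(model$params)
  ctl <- .lr_controller(cfgt)
  hist <- data.frame()
  best_params <- model$params
  best_bn <- model$bn
  .with_seed(cfgt$seed, {
    for (epoch in seq_len(cfgt$max_epochs)) {
      tly <- 0; tld <- 0; nb <- 0
      for (p in sample(parts)) {                     # every participant is a source
        ord <- sample(by_part[[as.character(p)]])
        for (s in split(ord, ceiling(seq_along(ord) / cfgt$batch_size))) {
          q <- sample(setdiff(parts, p), 1)          # target domain
          qi <- by_part[[as.character(q)]]
          qs <- sample(qi, min(length(s), length(qi)))
          bs <- .batch_grads(model, dataset$windows[, , s, drop = FALSE],
                             dataset$meta$gesture[s], p, cfgt,
                             domain_label = 0L, include_class = TRUE,
                             update_stats = TRUE)
          model <- bs$model
          bt <- .batch_grads(model, dataset$windows[, , qs, drop = FALSE],
                             NULL, q, cfgt,
                             domain_label = 1L, include_class = FALSE,
                             update_stats = FALSE)
          model <- bt$model
          st <- .adam_step(model$params, .add_grads(bs$grads, bt$grads), opt,
                           ctl$lr)
          model$params <- st$params; opt <- st$state
          tly <- tly + bs$loss_y
          tld <- tld + bs$loss_d + bt$loss_d
          nb <- nb + 1
        }
      }
      # validation: each participant's own statistics, averaged
      vl <- mean(vapply(parts, function(p) {
        vi <- va[dataset$meta$participant[va] == p]
        if (length(vi) == 0) return(NA_real_)
        .eval_loss(model, dataset, vi, p)
      }, numeric(1)), na.rm = TRUE)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tly / nb,
                                     domain_loss = tld / nb, val_loss = vl,
                                     lr = ctl$lr))
      if (verbose) message(sprintf("epoch %3d  Ly %.4f  Ld %.4f  val %.4f  lr %.2e",
                                   epoch, tly / nb, tld / nb, vl, ctl$lr))
      act <- ctl$update(vl)
      if (act == "improved") { best_params <- model$params; best_bn <- model$bn }
      if (act == "stop") break
    }
  })
  model$params <- best_params
  model$bn <- best_bn
  attr(model, "history") <- hist
  model
}

#' Write a training history to CSV
#' @param model a trained model carrying a `history` attribute.
#' @param path output CSV path.
#' @export
write_training_log <- function(model, path) {
  utils::write.csv(attr(model, "history"), path, row.names = FALSE)
  invisible(path)
}

# average the running statistics over a model's stored banks
.mean_bank <- function(model) {
  banks <- model$bn
  .assert(length(banks) > 0, "model has no batch-norm statistics")
  out <- banks[[1]]
  if (length(banks) > 1) {
    for (b in seq_along(out)) {
      out[[b]]$mean <- rowMeans(sapply(banks, function(bk) bk[[b]]$mean))
      out[[b]]$var <- rowMeans(sapply(banks, function(bk) bk[[b]]$var))
    }
  }
  out
}

#' Recompute batch-norm statistics for a new domain (AdaBN)
#'
#' Runs the unlabeled windows through the network in statistics-collection
#' mode and stores the resulting running statistics under `key`. No weight
#' is ever updated.
#'
#' @param model an `emg_model`.
#' @param windows array `channels x len x n` of unlabeled windows.
#' @param key bank key to (re)create.
#' @param batch_size forward batch size.
#' @export
adapt_bn <- function(model, windows, key, batch_size = 512) {
  key <- as.character(key)
  model$bn[[key]] <- .new_bank(model$config)
  n <- dim(windows)[3]
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  # train-mode normalisation uses batch statistics, so each chunk's batch
  # statistics are independent of the bank; their weighted average over
  # chunks is the AdaBN estimate.
  for (i in seq_along(chunks)) {
    fw <- forward(model, windows[, , chunks[[i]], drop = FALSE],
                  participant = key, mode = "train", update_stats = TRUE,
                  dropout = FALSE)
    w <- length(chunks[[i]]) / n
    for (b in seq_along(model$bn[[key]])) {
      new <- fw$model$bn[[key]][[b]]
      old <- model$bn[[key]][[b]]
      # forward() applied momentum 0.1; recover the chunk statistics
      bm <- (new$mean - 0.9 * old$mean) / 0.1
      bv <- (new$var - 0.9 * old$var) / 0.1
      if (i == 1) { model$bn[[key]][[b]]$mean <- bm * w
                    model$bn[[key]][[b]]$var <- bv * w }
      else { model$bn[[key]][[b]]$mean <- old$mean + bm * w
             model$bn[[key]][[b]]$var <- old$var + bv * w }
    }
  }
  model
}

#' Cross-subject evaluation
#'
#' Computes gesture accuracy on the test cycles of each participant.
#' `adaptation = "adabn"` first recomputes batch-norm statistics from the
#' participant's unlabeled test windows ([adapt_bn()]); `"none"` uses the
#' average of the stored training banks (or the aggregate bank if
#' present). Weights are never updated.
#'
#' @param model a trained `emg_model`.
#' @param dataset an `emg_dataset`.
#' @param participants participants to evaluate (default: all in the test
#'   split).
#' @param adaptation `"adabn"` or `"none"`.
#' @param batch_size forward batch size.
#' @return named numeric vector of per-participant accuracies.
#' @export
evaluate_cross_subject <- function(model, dataset, participants = NULL,
                                   adaptation = c("adabn", "none"),
                                   batch_size = 512) {
  adaptation <- match.arg(adaptation)
  te <- split_indices(dataset, "test")
  if (is.null(participants)) participants <- sort(unique(dataset$meta$participant[te]))
  acc <- vapply(participants, function(p) {
    idx <- te[dataset$meta$participant[te] == p]
    key <- as.character(p)
    m <- model
    if (adaptation == "adabn") {
      key <- paste0("adapt_", p)
      m <- adapt_bn(m, dataset$windows[, , idx, drop = FALSE], key,
                    batch_size = batch_size)
    } else {
      m$bn[[key]] <- if (!is.null(model$bn[["aggregate"]])) {
        model$bn[["aggregate"]]
      } else .mean_bank(model)
    }
    correct <- 0
    for (s in split(idx, ceiling(seq_along(idx) / batch_size))) {
      fw <- forward(m, dataset$windows[, , s, drop = FALSE], participant = key,
                    mode = "eval")
      pred <- max.col(fw$class_logits) - 1L
      correct <- correct + sum(pred == dataset$meta$gesture[s])
    }
    correct / length(idx)
  }, numeric(1))
  stats::setNames(acc, participants)
}

#' Paired comparison of two training methods
#'
#' Two-sided Wilcoxon signed-rank test (exact when no ties/zeros permit)
#' on paired per-participant accuracies, plus Cohen's d computed as the
#' mean difference over the pooled standard deviation.
#'
#' @param acc_a,acc_b equal-length paired accuracy vectors (n >= 5).
#' @return list with `p_value`, `cohens_d`, `mean_diff`.
#' @export
compare_training_methods <- function(acc_a, acc_b) {
  .assert(length(acc_a) == length(acc_b), "paired samples must match in length")
  .assert(length(acc_a) >= 5, "need at least 5 pairs")
  p <- stats::wilcox.test(acc_a, acc_b, paired = TRUE)$p.value
  pooled <- sqrt((stats::var(acc_a) + stats::var(acc_b)) / 2)
  md <- mean(acc_a) - mean(acc_b)
  d <- if (pooled < .EPS) {
    if (abs(md) < .EPS) 0 else sign(md) * Inf
  } else md / pooled
  list(p_value = p, cohens_d = d, mean_diff = md)
}
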