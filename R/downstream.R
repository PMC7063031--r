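# Downstream probes of feature quality: linear discriminant analysis of
# single features / feature groups, and regression heads that predict a
# handcrafted feature from a block's learned feature maps.

# ---- compact LDA ---------------------------------------------------------
# Gaussian classes with a shared covariance, empirical priors. If the
# pooled covariance is singular it is ridge-shrunk toward
# mean(diag(S)) * I, escalating until invertible (logged via message).

#' Fit a linear discriminant classifier
#'
#' @param x numeric matrix (observations x features).
#' @param y class labels (any atomic type).
#' @return object of class `emg_lda`.
#' @export
lda_fit <- function(x, y) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  n <- nrow(x); p <- ncol(x)
  means <- t(sapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE])))
  if (p == 1) means <- matrix(means, ncol = 1)
  s <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    xc <- sweep(x[y == classes[i], , drop = FALSE], 2, means[i, ])
    s <- s + crossprod(xc)
  }
  s <- s / max(n - length(classes), 1)
  alpha <- 0
  repeat {
    sr <- s + alpha * mean(diag(s)) * diag(p)
    inv <- tryCatch(solve(sr), error = function(e) NULL)
    if (!is.null(inv) && all(is.finite(inv))) break
    alpha <- if (alpha == 0) 1e-6 else alpha * 10
    if (alpha > 1) { inv <- diag(p) / max(mean(diag(s)), .EPS); break }
  }
  if (alpha > 0) message(sprintf("lda_fit: singular covariance, shrinkage %g applied", alpha))
  priors <- as.numeric(table(factor(y, levels = classes))) / n
  structure(list(classes = classes, means = means, sigma_inv = inv,
                 log_priors = log(priors), shrinkage = alpha),
            class = "emg_lda")
}

#' Predict with a fitted LDA
#' @param object an `emg_lda`.
#' @param newdata matrix of observations.
#' @param ... unused.
#' @export
predict.emg_lda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  a <- object$means %*% object$sigma_inv             # C x p
  const <- -0.5 * rowSums(a * object$means) + object$log_priors
  scores <- sweep(newdata %*% t(a), 2, const, "+")
  object$classes[max.col(scores)]
}

# ---- single-feature / group LDA evaluation -------------------------------

# columns of the LDA design for one handcrafted feature: its 10 channel
# values. For one learned feature: the first principal component of its
# 10 channel values (fit on the training rows).
.feature_design <- function(table, id, train_rows, learned, symmetric_pc1) {
  v <- table$values[, , id]                      # windows x channels
  if (learned || symmetric_pc1) {
    mu <- colMeans(v[train_rows, , drop = FALSE])
    vc <- sweep(v, 2, mu)
    pc <- stats::prcomp(vc[train_rows, , drop = FALSE], center = FALSE)
    matrix(vc %*% pc$rotation[, 1], ncol = 1)
  } else {
    v
  }
}

#' Linear discriminant evaluation of features
#'
#' Cross-subject protocol: the classifier is fit on the training cycles of
#' all participants and tested on the test cycles; no test window is ever
#' seen in training. A single handcrafted feature enters as its 10
#' per-channel values; a single learned feature is first summarised by the
#' first principal component of its 10 channel values (components fit on
#' the training set). Groups/blocks concatenate the designs of all member
#' features.
#'
#' @param table a `feature_table` (handcrafted or learned).
#' @param dataset the `emg_dataset` the table was computed on (provides
#'   labels and the cycle split).
#' @param features feature id(s) (names from [feature_ids()]) or a group /
#'   block label (e.g. `"SAP"`, `"B3"`) to evaluate jointly.
#' @param learned treat features as learned (PC1 summarisation).
#' @param symmetric_pc1 apply PC1 summarisation to handcrafted features
#'   too (symmetric variant).
#' @return object of class `eval_result`: `accuracy`, `confusion` (rows =
#'   true class), `features`.
#' @export
lda_eval <- function(table, dataset, features, learned = FALSE,
                     symmetric_pc1 = FALSE) {
  ids <- feature_ids(table)
  if (length(features) == 1 && features %in% unique(table$groups)) {
    features <- ids[table$groups == features]
  }
  .assert(all(features %in% ids), "unknown feature id")
  tr <- split_indices(dataset, "train")
  te <- split_indices(dataset, "test")
  design <- do.call(cbind, lapply(features, function(f) {
    .feature_design(table, f, tr, learned, symmetric_pc1)
  }))
  y <- dataset$meta$gesture
  fit <- lda_fit(design[tr, , drop = FALSE], y[tr])
  pred <- predict(fit, design[te, , drop = FALSE])
  classes <- sort(unique(y))
  conf <- table(factor(y[te], levels = classes),
                factor(pred, levels = classes))
  structure(list(accuracy = mean(pred == y[te]),
                 confusion = unclass(conf), features = features,
                 n_test = length(te)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: accuracy %.3f (n = %d)\n",
              paste(x$features[seq_len(min(3, length(x$features)))],
                    collapse = ","), x$accuracy, x$n_test))
  invisible(x)
}

# ---- regression probe ----------------------------------------------------

# probe input: flattened first-channel slice of a block's post-activation
# maps -> matrix n_windows x (maps * t_block)
.probe_inputs <- function(model, dataset, block, batch_size = 256) {
  cfg <- model$config
  nw <- n_windows(dataset)
  out <- NULL
  parts <- dataset$meta$participant
  for (pk in unique(parts)) {
    idx <- which(parts == pk)
    key <- if (as.character(pk) %in% names(model$bn)) pk else "aggregate"
    for (s in split(idx, ceiling(seq_along(idx) / batch_size))) {
      fw <- forward(model, dataset$windows[, , s, drop = FALSE],
                    participant = key, mode = "eval", keep = "acts")
      act <- fw$acts[[block]]
      # rows of act$mat: (t-1)*n + seq, with seq = (window-1)*C + channel;
      # channel 1 of window w is seq (w-1)*C + 1
      n <- act$n; tt <- act$t; m <- ncol(act$mat)
      ch1 <- as.vector(outer((seq_along(s) - 1) * cfg$n_channels + 1,
                             (seq_len(tt) - 1) * n, "+"))
      x <- act$mat[ch1, , drop = FALSE]            # (n_win*t) x m, window-fastest
      x <- matrix(x, length(s))                    # n_win x (t*m)
      if (is.null(out)) out <- matrix(0, nw, ncol(x))
      out[s, ] <- x
    }
  }
  out
}

# regression target: the feature's first-channel value; multi-output
# methods are summarised by the first principal component
.probe_target <- function(table, feature, train_rows, per_phase_pca = FALSE) {
  ids <- feature_ids(table)
  cols <- if (feature %in% ids) feature else ids[startsWith(ids, feature) &
    grepl(paste0("^", feature, "[0-9]+$"), ids)]
  .assert(length(cols) >= 1, sprintf("unknown feature '%s'", feature))
  v <- table$values[, 1, cols, drop = FALSE]       # first channel
  v <- matrix(v, nrow = dim(table$values)[1])
  if (ncol(v) == 1) return(as.vector(v))
  if (per_phase_pca) {
    # per-phase PCA (training and test sets decomposed independently)
    out <- numeric(nrow(v))
    for (rows in list(train_rows, setdiff(seq_len(nrow(v)), train_rows))) {
      pc <- stats::prcomp(v[rows, , drop = FALSE], center = TRUE)
      out[rows] <- pc$x[, 1]
    }
    out
  } else {
    pc <- stats::prcomp(v[train_rows, , drop = FALSE], center = TRUE)
    as.vector(sweep(v, 2, pc$center) %*% pc$rotation[, 1])
  }
}

#' Regression probe from a block's learned features to a handcrafted
#' feature
#'
#' A single linear output neuron reads the flattened first-channel slice
#' of the block's post-activation feature maps and is trained (Adam, MSE)
#' to predict the handcrafted feature's first-channel value, all other
#' weights frozen. Targets are z-scored on training statistics.
#' Repetitions differ in head initialisation and batch order; the result
#' is the mean test MSE over repetitions and participants.
#'
#' @param model a trained `emg_model`.
#' @param table a handcrafted `feature_table` on the same dataset.
#' @param dataset the `emg_dataset`.
#' @param block block (1-based) whose maps feed the head.
#' @param feature feature method name (e.g. `"MAV"`, `"AR"`).
#' @param reps training repetitions.
#' @param epochs,lr,batch_size head-training parameters.
#' @param per_phase_pca decompose training and test sets independently
#'   when building multi-output targets (the literal protocol), instead
#'   of the default leakage-free train-fit / test-apply.
#' @param seed base seed.
#' @return object of class `regression_result` with the mean test MSE,
#'   the per-(rep, participant) MSE matrix, block and feature.
#' @export
regression_probe <- function(model, table, dataset, block, feature,
                             reps = 20, epochs = 30, lr = 0.01,
                             batch_size = 128, per_phase_pca = FALSE,
                             seed = 1L) {
  if (length(model$bn) == 0) {
    warning("regression probe on an untrained model")
    model <- ensure_bank(model, "aggregate")
  }
  tr <- split_indices(dataset, "train")
  te <- split_indices(dataset, "test")
  x <- .probe_inputs(model, dataset, block)
  # standardise the probe inputs on training statistics so one learning
  # rate fits every block
  xm <- colMeans(x[tr, , drop = FALSE])
  xs <- pmax(apply(x[tr, , drop = FALSE], 2, stats::sd), .EPS)
  x <- sweep(sweep(x, 2, xm), 2, xs, "/")
  yv <- .probe_target(table, feature, tr, per_phase_pca)
  mu <- mean(yv[tr]); sdv <- max(stats::sd(yv[tr]), .EPS)
  yv <- (yv - mu) / sdv
  parts <- sort(unique(dataset$meta$participant[te]))
  mse <- matrix(NA_real_, reps, length(parts),
                dimnames = list(NULL, parts))
  p <- ncol(x)
  for (r in seq_len(reps)) {
    .with_seed(seed + r - 1, {
      # near-zero init + SGD with momentum: gradient-proportional steps
      # decay cleanly on easy targets and keep the weights in the row
      # space of the training design (an adaptive optimiser such as Adam
      # never settles below learning-rate amplitude when the optimum has
      # zero gradient). Repetition randomness: init noise + batch order.
      w <- stats::rnorm(p, 0, 0.01 / sqrt(p)); b <- 0
      mw <- numeric(p); mb <- 0
      for (ep in seq_len(epochs)) {
        for (s in split(sample(tr), ceiling(seq_along(tr) / batch_size))) {
          pred <- x[s, , drop = FALSE] %*% w + b
          g <- 2 * (pred - yv[s]) / length(s)
          gw <- crossprod(x[s, , drop = FALSE], g)[, 1]
          gb <- sum(g)
          mw <- 0.9 * mw + gw; mb <- 0.9 * mb + gb
          w <- w - lr * mw
          b <- b - lr * mb
        }
      }
      for (pi in seq_along(parts)) {
        ti <- te[dataset$meta$participant[te] == parts[pi]]
        pred <- x[ti, , drop = FALSE] %*% w + b
        mse[r, pi] <- mean((pred - yv[ti])^2)
      }
    })
  }
  structure(list(mean_mse = mean(mse), mse = mse, block = block,
                 feature = feature, reps = reps),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s from block %d: mean test MSE %.4f (%d reps)\n",
              x$feature, x$block, x$mean_mse, x$reps))
  invisible(x)
}
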