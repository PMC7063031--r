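# A small feed-forward engine for the channel-independent EMG ConvNet.
#
# The network consumes 10 x 151 windows. Because every convolution kernel
# has height 1, the 10 electrode channels never mix before the heads:
# internally each (window, channel) pair is treated as an independent
# 1-D sequence, and activations are stored as matrices of shape
# (n_seq * T) x maps with rows ordered sequence-fastest, time-slowest.
# This makes convolution an im2col matrix product and batch normalisation
# a per-column operation.
#
# Blocks: conv (valid padding, stride 1) -> batch norm -> leaky ReLU ->
# dropout. Two linear heads (gesture, domain) read the time-averaged,
# (map, channel)-flattened output of the last block. Batch-norm affine
# parameters are shared weights; the running mean / variance are kept in
# per-participant "banks" so that one set of weights can serve many
# domains (the AdaBN convention).

#' Architecture configuration
#'
#' Defaults reproduce the 6-block, 64-map network for 10 x 151 inputs
#' (543,629 trainable parameters). `n_blocks * (kernel_time - 1)` must not
#' exceed `input_len - 1` so the final time length is at least 1.
#'
#' @param n_blocks number of conv blocks.
#' @param feature_maps feature maps per conv layer.
#' @param kernel_time kernel width along the time axis (height is 1).
#' @param leaky_slope negative slope of the leaky ReLU.
#' @param dropout drop probability.
#' @param n_classes gesture classes.
#' @param n_domain_outputs outputs of the adversarial domain head.
#' @param n_channels,input_len input window shape.
#' @export
architecture_config <- function(n_blocks = 6, feature_maps = 64,
                                kernel_time = 26, leaky_slope = 0.1,
                                dropout = 0.35, n_classes = 11,
                                n_domain_outputs = 2, n_channels = 10,
                                input_len = 151) {
  t_final <- input_len - n_blocks * (kernel_time - 1)
  if (t_final < 1) {
    stop("configuration error: blocks consume more time samples than the input has",
         call. = FALSE)
  }
  list(n_blocks = n_blocks, feature_maps = feature_maps,
       kernel_time = kernel_time, leaky_slope = leaky_slope,
       dropout = dropout, n_classes = n_classes,
       n_domain_outputs = n_domain_outputs, n_channels = n_channels,
       input_len = input_len, t_final = t_final,
       head_in = feature_maps * n_channels)
}

# He-style initialisation for one conv tensor [m_out, m_in, K]
.init_conv <- function(m_out, m_in, k) {
  array(stats::rnorm(m_out * m_in * k, 0, sqrt(2 / (m_in * k))),
        dim = c(m_out, m_in, k))
}

#' Build a model
#'
#' @param config an [architecture_config()].
#' @param seed seed for the weight initialisation.
#' @return object of class `emg_model`: shared parameters plus an (empty)
#'   per-participant bank of batch-norm running statistics.
#' @export
build_model <- function(config = architecture_config(), seed = 1L) {
  .with_seed(seed, {
    blocks <- vector("list", config$n_blocks)
    m <- config$feature_maps
    for (b in seq_len(config$n_blocks)) {
      m_in <- if (b == 1) 1L else m
      blocks[[b]] <- list(W = .init_conv(m, m_in, config$kernel_time),
                          b = numeric(m), gamma = rep(1, m), beta = numeric(m))
    }
    hin <- config$head_in
    params <- list(
      blocks = blocks,
      head_class = list(W = matrix(stats::rnorm(hin * config$n_classes,
                                                0, sqrt(1 / hin)),
                                   hin, config$n_classes),
                        b = numeric(config$n_classes)),
      head_domain = list(W = matrix(stats::rnorm(hin * config$n_domain_outputs,
                                                 0, sqrt(1 / hin)),
                                    hin, config$n_domain_outputs),
                         b = numeric(config$n_domain_outputs)))
    structure(list(config = config, params = params, bn = list()),
              class = "emg_model")
  })
}

#' @export
print.emg_model <- function(x, ...) {
  cat(sprintf("<emg_model> %d blocks x %d maps, %s parameters, %d BN bank(s)\n",
              x$config$n_blocks, x$config$feature_maps,
              format(count_parameters(x), big.mark = ","), length(x$bn)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Brute-force sum over every trainable tensor (conv kernels and biases,
#' batch-norm affine parameters, head weights). Running statistics are not
#' parameters.
#'
#' @param model an `emg_model`.
#' @param per_part if `TRUE`, return a named per-component breakdown.
#' @export
count_parameters <- function(model, per_part = FALSE) {
  p <- model$params
  blocks <- vapply(p$blocks, function(bl) {
    length(bl$W) + length(bl$b) + length(bl$gamma) + length(bl$beta)
  }, numeric(1))
  parts <- c(stats::setNames(blocks, paste0("block", seq_along(blocks))),
             head_class = length(p$head_class$W) + length(p$head_class$b),
             head_domain = length(p$head_domain$W) + length(p$head_domain$b))
  if (per_part) parts else sum(parts)
}

# fresh running statistics (mean 0, var 1 per map per block)
.new_bank <- function(config) {
  lapply(seq_len(config$n_blocks), function(b) {
    list(mean = numeric(config$feature_maps),
         var = rep(1, config$feature_maps))
  })
}

#' Ensure a participant has a batch-norm bank, creating one if needed
#' @param model an `emg_model`.
#' @param participant participant id (or `"aggregate"`).
#' @export
ensure_bank <- function(model, participant) {
  key <- as.character(participant)
  if (is.null(model$bn[[key]])) model$bn[[key]] <- .new_bank(model$config)
  model
}

# windows array [C, L, nb] -> input activation matrix [(nb*C)*L, 1]
.input_matrix <- function(windows) {
  d <- dim(windows)
  matrix(as.vector(aperm(windows, c(1, 3, 2))), ncol = 1)
}

# conv weight tensor [m_out, m_in, K] -> matrix [m_in*K, m_out] whose
# k-th row block is the [m_in x m_out] slice for kernel position k
.wmat <- function(w) {
  d <- dim(w)
  matrix(aperm(w, c(2, 3, 1)), d[2] * d[3], d[1])
}

.wmat_inv <- function(wm, m_out, m_in, k) {
  aperm(array(wm, dim = c(m_in, k, m_out)), c(3, 1, 2))
}

# fast per-column scale / shift (sweep() is too slow in the hot path)
.cmul <- function(x, v) x * rep(v, each = nrow(x))
.cadd <- function(x, v) x + rep(v, each = nrow(x))

# one block forward; returns output matrix + caches for backward
.block_forward <- function(amat, n, t, bl, stats, cfg, training, update_stats,
                           dropout_on) {
  k <- cfg$kernel_time
  t_out <- t - k + 1
  z <- conv_fwd_cpp(amat, .wmat(bl$W), n, t, k)
  z <- .cadd(z, bl$b)
  if (training) {
    mu <- colMeans(z)
    va <- colMeans(z^2) - mu^2
    if (update_stats) {
      mom <- 0.1
      stats$mean <- (1 - mom) * stats$mean + mom * mu
      stats$var <- (1 - mom) * stats$var + mom * va
    }
  } else {
    mu <- stats$mean
    va <- stats$var
  }
  invstd <- 1 / sqrt(va + 1e-5)
  xhat <- .cmul(.cadd(z, -mu), invstd)
  y <- .cadd(.cmul(xhat, bl$gamma), bl$beta)
  a <- y
  neg <- y < 0
  a[neg] <- cfg$leaky_slope * y[neg]
  mask <- NULL
  if (dropout_on && cfg$dropout > 0) {
    mask <- matrix(stats::runif(length(a)) >= cfg$dropout, nrow(a), ncol(a))
    a <- a * mask / (1 - cfg$dropout)
  }
  list(out = a, n = n, t = t_out, stats = stats,
       cache = list(amat = amat, n = n, t = t, xhat = xhat, invstd = invstd,
                    y = y, mask = mask, batch_mode = training))
}

# backward through one block. mode: "train" (batch statistics),
# "eval" (fixed statistics) or "guided" (eval statistics + guided ReLU).
.block_backward <- function(da, bl, cache, cfg, mode) {
  if (!is.null(cache$mask)) da <- da * cache$mask / (1 - cfg$dropout)
  if (mode == "guided") {
    da[cache$y <= 0] <- 0
    da[da < 0] <- 0
    dy <- da
  } else {
    dy <- da
    neg <- cache$y < 0
    dy[neg] <- cfg$leaky_slope * da[neg]
  }
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- .cmul(dy, bl$gamma)
  if (cache$batch_mode) {
    dz <- .cadd(dxhat, -colMeans(dxhat)) -
      .cmul(cache$xhat, colMeans(dxhat * cache$xhat))
    dz <- .cmul(dz, cache$invstd)
  } else {
    dz <- .cmul(dxhat, cache$invstd)
  }
  k <- cfg$kernel_time
  m_in <- ncol(cache$amat)
  cb <- conv_bwd_cpp(cache$amat, .wmat(bl$W), dz, cache$n, cache$t, k)
  list(damat = cb$dA,
       grads = list(W = .wmat_inv(cb$dW, dim(bl$W)[1], m_in, k),
                    b = colSums(dz), gamma = dgamma, beta = dbeta))
}

# pooled head input: time-average each sequence, arrange (map, channel)
# row-major per window -> H [n_win, maps * channels]
.head_input <- function(amat, n, t, n_channels) {
  m <- ncol(amat)
  pooled <- rowsum(amat, group = rep(seq_len(n), t), reorder = FALSE) / t
  n_win <- n / n_channels
  matrix(aperm(array(pooled, dim = c(n_channels, n_win, m)), c(2, 1, 3)),
         nrow = n_win)
}

.head_input_backward <- function(dh, n, t, n_channels, m) {
  n_win <- n / n_channels
  dpool_arr <- aperm(array(dh, dim = c(n_win, n_channels, m)), c(2, 1, 3))
  dpooled <- matrix(dpool_arr, n, m)
  dpooled[rep(seq_len(n), t), , drop = FALSE] / t
}

#' Forward pass
#'
#' @param model an `emg_model`.
#' @param windows array `channels x len x n` (or a single window matrix).
#' @param participant participant id selecting the batch-norm bank, or
#'   `"aggregate"`.
#' @param mode `"train"` (batch statistics, dropout on) or `"eval"`
#'   (running statistics, dropout off, deterministic).
#' @param update_stats in train mode, whether this batch updates the
#'   participant's running statistics.
#' @param keep caches / activations to retain: `"none"`, `"acts"`
#'   (post-activation of every block, for feature extraction) or `"full"`
#'   (everything needed for backward).
#' @param dropout whether dropout is active; defaults to train mode.
#'   Statistics-collection passes (AdaBN) run train-mode normalisation
#'   with dropout off.
#' @return list with `class_logits` (n x n_classes), `domain_logits`
#'   (n x n_domain_outputs), the possibly-updated `model`, and caches.
#' @export
forward <- function(model, windows, participant = "aggregate",
                    mode = c("eval", "train"), update_stats = (mode == "train"),
                    keep = "none", dropout = (mode == "train")) {
  mode <- match.arg(mode)
  cfg <- model$config
  if (is.matrix(windows)) windows <- array(windows, dim = c(dim(windows), 1))
  key <- as.character(participant)
  if (is.null(model$bn[[key]])) {
    if (mode == "eval") {
      stop(sprintf("no batch-norm statistics for participant '%s'; train on them or use an adaptation policy", key),
           call. = FALSE)
    }
    model <- ensure_bank(model, key)
  }
  d <- dim(windows)
  n_win <- d[3]
  n <- n_win * cfg$n_channels
  amat <- .input_matrix(windows)
  t <- cfg$input_len
  caches <- vector("list", cfg$n_blocks)
  acts <- vector("list", cfg$n_blocks)
  training <- mode == "train"
  for (b in seq_len(cfg$n_blocks)) {
    res <- .block_forward(amat, n, t, model$params$blocks[[b]],
                          model$bn[[key]][[b]], cfg, training,
                          training && update_stats, dropout_on = dropout)
    model$bn[[key]][[b]] <- res$stats
    amat <- res$out
    t <- res$t
    if (keep == "full") caches[[b]] <- res$cache
    if (keep != "none") acts[[b]] <- list(mat = amat, n = n, t = t)
  }
  h <- .head_input(amat, n, t, cfg$n_channels)
  cl <- .cadd(h %*% model$params$head_class$W, model$params$head_class$b)
  dl <- .cadd(h %*% model$params$head_domain$W, model$params$head_domain$b)
  list(class_logits = cl, domain_logits = dl, model = model,
       h = h, final_t = t, n_seq = n, caches = caches, acts = acts)
}

# softmax cross-entropy; labels are 0-based class ids
.softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

.ce_loss_grad <- function(logits, labels) {
  p <- .softmax(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], .EPS)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / n)
}

# zero-filled gradient structure matching the parameter tree
.zero_grads <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

.add_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- .add_grads(a[[nm]], b[[nm]])
    a
  } else a + b
}

.scale_grads <- function(a, s) rapply(a, function(x) x * s, how = "replace")

# full backward from head gradients dh through every block.
# Returns parameter gradients (blocks only) and the input-space gradient.
.backward_blocks <- function(model, fw, dh, mode = "train", to_block = 0L) {
  cfg <- model$config
  da <- .head_input_backward(dh, fw$n_seq, fw$final_t, cfg$n_channels,
                             cfg$feature_maps)
  grads <- vector("list", cfg$n_blocks)
  for (b in rev(seq_len(cfg$n_blocks))) {
    if (b <= to_block) break
    res <- .block_backward(da, model$params$blocks[[b]], fw$caches[[b]], cfg,
                           mode)
    grads[[b]] <- res$grads
    da <- res$damat
  }
  list(block_grads = grads, damat = da)
}

#' Extract learned features from a dataset
#'
#' For each requested block, each of the feature maps is summarised per
#' channel by averaging its post-activation values over time, yielding
#' `maps x channels` scalars per window (the "learned features"). With the
#' default 6-block, 64-map network this gives 6 x 64 = 384 learned feature
#' ids.
#'
#' @param model a trained `emg_model`.
#' @param dataset an `emg_dataset`.
#' @param blocks blocks to extract (default all).
#' @param participant_bank `"own"` to use each window's participant
#'   statistics, or a single bank key (e.g. `"aggregate"`).
#' @param batch_size forward batch size.
#' @return a `feature_table` with ids `B<block>M<map>` and group labels
#'   `B<block>`.
#' @export
extract_learned_features <- function(model, dataset,
                                     blocks = seq_len(model$config$n_blocks),
                                     participant_bank = "own",
                                     batch_size = 256) {
  cfg <- model$config
  .assert(all(blocks >= 1 & blocks <= cfg$n_blocks), "block out of range")
  nw <- n_windows(dataset)
  nf <- length(blocks) * cfg$feature_maps
  ids <- unlist(lapply(blocks, function(b) sprintf("B%dM%d", b,
                                                   seq_len(cfg$feature_maps))))
  vals <- array(NA_real_, dim = c(nw, cfg$n_channels, nf),
                dimnames = list(NULL, NULL, ids))
  groups <- rep(paste0("B", blocks), each = cfg$feature_maps)
  parts <- if (identical(participant_bank, "own")) {
    dataset$meta$participant
  } else rep(participant_bank, nw)
  for (pk in unique(parts)) {
    idx <- which(parts == pk)
    for (s in split(idx, ceiling(seq_along(idx) / batch_size))) {
      fw <- forward(model, dataset$windows[, , s, drop = FALSE],
                    participant = pk, mode = "eval", keep = "acts")
      off <- 0
      for (b in blocks) {
        act <- fw$acts[[b]]
        pooled <- rowsum(act$mat, group = rep(seq_len(act$n), act$t),
                         reorder = FALSE) / act$t
        # rows of `pooled` are (window, channel) with channel fastest
        arr <- array(pooled, dim = c(cfg$n_channels, length(s),
                                     cfg$feature_maps))
        vals[s, , (off + 1):(off + cfg$feature_maps)] <- aperm(arr, c(2, 1, 3))
        off <- off + cfg$feature_maps
      }
    }
  }
  feature_table(vals, dataset$meta, groups)
}

#' Save a model checkpoint as versioned JSON
#'
#' Stores the configuration, every weight tensor and the complete
#' per-participant batch-norm bank in plain text (full double precision).
#'
#' @param model an `emg_model`.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  enc <- function(x) list(dim = if (is.null(dim(x))) length(x) else dim(x),
                          data = as.vector(x))
  payload <- list(format = "emglens-checkpoint", version = 1L,
                  config = model$config,
                  params = rapply(model$params, enc, how = "replace",
                                  classes = c("numeric", "array", "matrix")),
                  bn = model$bn)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a checkpoint written by [save_model()]
#' @param path checkpoint file.
#' @export
load_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .assert(identical(p$format, "emglens-checkpoint"), "not a checkpoint file")
  dec <- function(x) {
    if (is.list(x) && identical(sort(names(x)), c("data", "dim"))) {
      d <- unlist(x$dim)
      v <- as.numeric(unlist(x$data))
      if (length(d) > 1) array(v, dim = d) else v
    } else if (is.list(x)) {
      lapply(x, dec)
    } else x
  }
  bn <- lapply(p$bn, function(bank) {
    lapply(bank, function(st) list(mean = as.numeric(unlist(st$mean)),
                                   var = as.numeric(unlist(st$var))))
  })
  structure(list(config = p$config, params = dec(p$params), bn = bn),
            class = "emg_model")
}
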