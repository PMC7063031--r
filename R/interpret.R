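# Guided Grad-CAM for EMG windows.
#
# Four steps: (1) seed the output gradient with 1 at the requested class;
# (2) guided backpropagation -- negative activations are zeroed, and at
# every backward activation step negative gradients are zeroed again,
# yielding a non-negative input-space map; (3) Grad-CAM -- the class
# gradient at a chosen block's post-activation maps is globally average
# pooled into per-map weights w_i, and ReLU(sum_i w_i F_i) gives a coarse
# class-discriminative spatial map; (4) the Grad-CAM map is broadcast
# along time and fused with the guided-backprop map by point-wise
# multiplication. All saliency is computed in eval mode (dropout off,
# per-participant batch-norm statistics).

# one-hot output gradient -> gradient at the head input
.seed_class_grad <- function(model, fw, class) {
  cfg <- model$config
  .assert(class >= 0 && class < cfg$n_classes, "class out of range")
  dlog <- matrix(0, nrow(fw$class_logits), cfg$n_classes)
  dlog[, class + 1] <- 1
  dlog %*% t(model$params$head_class$W)
}

#' Guided backpropagation map
#'
#' @param model a trained `emg_model`.
#' @param window a window (matrix `channels x len` or an `emg_window`).
#' @param class 0-based gesture class whose output neuron is seeded.
#' @param participant batch-norm bank to use.
#' @return non-negative `channels x len` matrix.
#' @export
guided_backprop <- function(model, window, class, participant = "aggregate") {
  if (inherits(window, "emg_window")) window <- window$data
  fw <- forward(model, window, participant = participant, mode = "eval",
                keep = "full")
  dh <- .seed_class_grad(model, fw, class)
  bk <- .backward_blocks(model, fw, dh, mode = "guided")
  g <- matrix(bk$damat, model$config$n_channels, model$config$input_len)
  pmax(g, 0)                     # the final propagation step is rectified too
}

#' Grad-CAM map
#'
#' @inheritParams guided_backprop
#' @param block block whose post-activation maps are weighted (default:
#'   the last block, spatial size `channels x 1` for the full
#'   architecture).
#' @return non-negative `channels x t_block` matrix.
#' @export
grad_cam <- function(model, window, class, participant = "aggregate",
                     block = model$config$n_blocks) {
  if (inherits(window, "emg_window")) window <- window$data
  cfg <- model$config
  .assert(block >= 1 && block <= cfg$n_blocks, "block out of range")
  fw <- forward(model, window, participant = participant, mode = "eval",
                keep = "full")
  dh <- .seed_class_grad(model, fw, class)
  bk <- .backward_blocks(model, fw, dh, mode = "eval", to_block = block)
  fmat <- fw$acts[[block]]$mat               # post-activation maps
  w <- colMeans(bk$damat)                    # global average pooled gradient
  cam <- as.vector(fmat %*% w)
  matrix(pmax(cam, 0), cfg$n_channels)
}

#' Guided Grad-CAM saliency map
#'
#' Fusion of [grad_cam()] (broadcast along the time axis) and
#' [guided_backprop()] by point-wise multiplication.
#'
#' @inheritParams grad_cam
#' @return object of class `saliency_map` with non-negative `relevance`
#'   (`channels x len`), the `gesture` class and the input window.
#' @export
guided_grad_cam <- function(model, window, class, participant = "aggregate",
                            block = model$config$n_blocks) {
  if (inherits(window, "emg_window")) window <- window$data
  gb <- guided_backprop(model, window, class, participant)
  cam <- grad_cam(model, window, class, participant, block)
  len <- ncol(gb)
  camb <- if (ncol(cam) == 1) {
    cam[, rep(1, len)]
  } else {
    t(apply(cam, 1, function(r) {
      stats::approx(seq(1, len, length.out = length(r)), r, xout = seq_len(len),
                    rule = 2)$y
    }))
  }
  structure(list(relevance = gb * camb, gesture = as.integer(class),
                 window = window),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> class %d, max relevance %.3g\n",
              x$gesture, max(x$relevance)))
  invisible(x)
}

#' Write a saliency map as CSV
#' @param map a `saliency_map`.
#' @param path output path.
#' @export
write_saliency <- function(map, path) {
  utils::write.table(map$relevance, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Gaussian-noise saliency probe
#'
#' Feeds a pure-noise window (zero mean, standard deviation `sigma`,
#' matched to the amplitude scale of the recordings) to the network and
#' reports, per class, the maximum Guided Grad-CAM relevance. Comparing
#' against the same quantity on real windows shows how much weaker the
#' "evidence" for a gesture is when it is not actually present.
#'
#' @param model a trained `emg_model`.
#' @param sigma noise standard deviation.
#' @param classes classes to probe (default: all).
#' @param seed seed for the noise window.
#' @param participant batch-norm bank.
#' @return named numeric vector of per-class maximum saliency magnitudes.
#' @export
noise_probe <- function(model, sigma = 450,
                        classes = seq_len(model$config$n_classes) - 1L,
                        seed = 1L, participant = "aggregate") {
  w <- generate_noise_window(sigma = sigma, seed = seed,
                             channels = model$config$n_channels,
                             window_len = model$config$input_len)
  mag <- vapply(classes, function(cl) {
    max(guided_grad_cam(model, w, cl, participant)$relevance)
  }, numeric(1))
  stats::setNames(mag, paste0("class", classes))
}
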