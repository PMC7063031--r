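# Architecture: parameter counts, shape recursion, channel independence,
# batch-norm banks, learned-feature extraction, checkpointing, and the
# compiled convolution against a literal im2col oracle.

test_that("default architecture has exactly 543,629 parameters", {
  m <- build_model(architecture_config())
  expect_equal(count_parameters(m), 543629)
  parts <- count_parameters(m, per_part = TRUE)
  expect_equal(unname(parts["block1"]), 1856)
  expect_true(all(parts[paste0("block", 2:6)] == 106688))
  expect_equal(unname(parts["head_class"]), 7051)
  expect_equal(unname(parts["head_domain"]), 1282)
  # brute-force: sum over every trainable tensor
  brute <- sum(unlist(rapply(m$params, length, how = "unlist")))
  expect_equal(brute, 543629)
})

test_that("time-length recursion and final map geometry", {
  cfg <- architecture_config()
  m <- ensure_bank(build_model(cfg, seed = 2), "p")
  set.seed(1)
  w <- array(rnorm(10 * 151 * 2), dim = c(10, 151, 2))
  fw <- forward(m, w, "p", mode = "eval", keep = "acts")
  for (b in 1:6) expect_equal(fw$acts[[b]]$t, 151 - 25 * b)
  expect_equal(fw$final_t, 1)            # block-6 maps are 10 x 1
  expect_equal(dim(fw$class_logits), c(2, 11))
  expect_equal(dim(fw$domain_logits), c(2, 2))
  expect_error(architecture_config(n_blocks = 7), "configuration error")
})

test_that("compiled convolution equals the literal im2col oracle", {
  set.seed(3)
  n <- 4; m_in <- 3; m_out <- 5; tt <- 12; k <- 4
  a_arr <- array(rnorm(n * m_in * tt), dim = c(n, m_in, tt))
  w <- array(rnorm(m_out * m_in * k), dim = c(m_out, m_in, k))
  bias <- rnorm(m_out)
  # package path: rows sequence-fastest, time-slowest
  amat <- matrix(0, n * tt, m_in)
  for (c in seq_len(m_in)) amat[, c] <- as.vector(a_arr[, c, ])
  z <- emglens:::conv_fwd_cpp(amat, emglens:::.wmat(w), n, tt, k)
  z <- z + rep(bias, each = nrow(z))
  ref <- oracle_conv(a_arr, w, bias)
  t_out <- tt - k + 1
  for (j in seq_len(m_out)) {
    expect_equal(matrix(z[, j], n, t_out), ref[, j, ], tolerance = 1e-12)
  }
})

test_that("channels never mix: permuting input channels permutes outputs", {
  cfg <- architecture_config(n_blocks = 2, feature_maps = 6, n_classes = 3)
  m <- ensure_bank(build_model(cfg, seed = 5), "p")
  set.seed(6)
  w <- array(rnorm(10 * 151 * 3), dim = c(10, 151, 3))
  perm <- sample(10)
  fw1 <- forward(m, w, "p", mode = "eval", keep = "acts")
  fw2 <- forward(m, w[perm, , , drop = FALSE], "p", mode = "eval",
                 keep = "acts")
  for (b in 1:2) {
    a1 <- fw1$acts[[b]]; a2 <- fw2$acts[[b]]
    # reshape to [maps x channels x windows x time] and compare channels
    r1 <- array(t(a1$mat), c(ncol(a1$mat), 10, 3, a1$t))
    r2 <- array(t(a2$mat), c(ncol(a2$mat), 10, 3, a2$t))
    expect_equal(r2, r1[, perm, , , drop = FALSE], tolerance = 1e-12)
  }
})

test_that("eval mode is deterministic; train dropout is not a no-op", {
  m <- ensure_bank(build_model(architecture_config(n_blocks = 2,
                                                   feature_maps = 4)), "p")
  set.seed(7)
  w <- array(rnorm(10 * 151 * 3), dim = c(10, 151, 3))
  f1 <- forward(m, w, "p", mode = "eval")
  f2 <- forward(m, w, "p", mode = "eval")
  expect_identical(f1$class_logits, f2$class_logits)
  set.seed(1); g1 <- forward(m, w, "p", mode = "train", update_stats = FALSE)
  set.seed(2); g2 <- forward(m, w, "p", mode = "train", update_stats = FALSE)
  expect_false(identical(g1$class_logits, g2$class_logits))
})

test_that("per-participant banks are independent and drive the output", {
  cfg <- architecture_config(n_blocks = 2, feature_maps = 4)
  m <- build_model(cfg, seed = 9)
  set.seed(10)
  w <- array(rnorm(10 * 151 * 8), dim = c(10, 151, 8))
  # train-mode forwards on shifted data diverge the two banks
  m <- forward(m, w, "pA", mode = "train")$model
  m <- forward(m, w * 3 + 1, "pB", mode = "train")$model
  expect_false(isTRUE(all.equal(m$bn[["pA"]][[1]]$mean,
                                m$bn[["pB"]][[1]]$mean)))
  fa <- forward(m, w[, , 1], "pA", mode = "eval")
  fb <- forward(m, w[, , 1], "pB", mode = "eval")
  expect_false(isTRUE(all.equal(fa$class_logits, fb$class_logits)))
  # unknown participant in eval mode is an explicit error
  expect_error(forward(m, w, "stranger", mode = "eval"), "statistics")
})

test_that("learned features: shape, block-6 identity, 384 ids", {
  m <- fix_model()
  ds <- subset_dataset(fix_dataset(), 1:5)
  lf <- extract_learned_features(m, ds)
  expect_equal(dim(lf$values), c(5, 10, 2 * 8))
  # full-depth architecture yields 6 x 64 = 384 learned feature ids
  full <- ensure_bank(build_model(architecture_config(), seed = 1), "1")
  ds1 <- subset_dataset(fix_dataset(), 1)
  lf6 <- extract_learned_features(full, ds1, participant_bank = "1")
  expect_equal(length(feature_ids(lf6)), 384)
  expect_equal(sum(table(lf6$groups)), 384)
  # block 6 has time length 1: time-average is the map value itself
  fw <- forward(full, ds1$windows[, , 1], "1", mode = "eval", keep = "acts")
  a6 <- fw$acts[[6]]
  expect_equal(a6$t, 1)
  pooled <- matrix(lf6$values[1, , 321:384], nrow = 10)  # channels x maps
  direct <- matrix(a6$mat[, ], a6$n, ncol(a6$mat))
  expect_equal(pooled, direct, tolerance = 1e-12)
  expect_error(extract_learned_features(m, ds, blocks = 9), "out of range")
})

test_that("checkpoint round-trip preserves weights, banks and outputs", {
  dir <- withr::local_tempdir()
  m <- fix_model()
  path <- file.path(dir, "model.json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  expect_setequal(names(m2$bn), names(m$bn))
  w <- fix_dataset()$windows[, , 1:3]
  f1 <- forward(m, w, "1", mode = "eval")
  f2 <- forward(m2, w, "1", mode = "eval")
  expect_equal(f1$class_logits, f2$class_logits, tolerance = 1e-12)
})
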