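# Training loops: gradient reversal, batch-norm statistics conservation,
# the lambda = 0 reduction, annealing / early-stopping bookkeeping,
# cross-subject evaluation and the paired statistical comparison.

test_that("gradient reversal flips only the trunk gradient of Ld", {
  cfg <- architecture_config(n_blocks = 2, feature_maps = 4, dropout = 0,
                             n_classes = 3)
  m <- ensure_bank(build_model(cfg, seed = 1), "p")
  set.seed(2)
  w <- array(rnorm(10 * 151 * 4), dim = c(10, 151, 4))
  y <- c(0L, 1L, 2L, 0L)
  g_rev <- emglens:::.batch_grads(m, w, y, "p",
                                  train_config(lambda = 1, reversal_constant = -1),
                                  update_stats = FALSE)
  g_fwd <- emglens:::.batch_grads(m, w, y, "p",
                                  train_config(lambda = 1, reversal_constant = 1),
                                  update_stats = FALSE)
  g_cls <- emglens:::.batch_grads(m, w, y, "p",
                                  train_config(lambda = 0),
                                  update_stats = FALSE)
  # domain-head gradients are identical (reversal acts below the head)
  expect_equal(g_rev$grads$head_domain, g_fwd$grads$head_domain,
               tolerance = 1e-12)
  # trunk: g_rev = g_cls - g_dom, g_fwd = g_cls + g_dom
  # => (g_rev + g_fwd) / 2 = g_cls and the domain parts are exact negatives
  for (b in 1:2) {
    avg <- (g_rev$grads$blocks[[b]]$W + g_fwd$grads$blocks[[b]]$W) / 2
    expect_equal(avg, g_cls$grads$blocks[[b]]$W, tolerance = 1e-10)
    dom_rev <- g_rev$grads$blocks[[b]]$W - g_cls$grads$blocks[[b]]$W
    dom_fwd <- g_fwd$grads$blocks[[b]]$W - g_cls$grads$blocks[[b]]$W
    expect_equal(dom_rev, -dom_fwd, tolerance = 1e-10)
    expect_gt(max(abs(dom_fwd)), 0)      # the domain loss does reach the trunk
  }
})

test_that("batch-norm statistics update only when serving as source", {
  cfg <- architecture_config(n_blocks = 2, feature_maps = 4, n_classes = 3)
  m <- ensure_bank(ensure_bank(build_model(cfg, seed = 3), "src"), "tgt")
  before <- m$bn
  set.seed(4)
  w <- array(rnorm(10 * 151 * 4), dim = c(10, 151, 4))
  bs <- emglens:::.batch_grads(m, w, c(0L, 1L, 2L, 0L), "src",
                               train_config(), domain_label = 0L,
                               update_stats = TRUE)
  bt <- emglens:::.batch_grads(bs$model, w, NULL, "tgt", train_config(),
                               domain_label = 1L, include_class = FALSE,
                               update_stats = FALSE)
  after <- bt$model$bn
  expect_false(isTRUE(all.equal(before[["src"]], after[["src"]])))
  expect_identical(before[["tgt"]], after[["tgt"]])
})

test_that("lambda = 0 detaches the domain head", {
  cfg <- architecture_config(n_blocks = 2, feature_maps = 4, n_classes = 3)
  m0 <- build_model(cfg, seed = 5)
  ds <- fix_dataset()
  m1 <- train_adann(m0, ds, train_config(lambda = 0, batch_size = 64,
                                         max_epochs = 1, seed = 1))
  expect_identical(m1$params$head_domain, m0$params$head_domain)
  expect_false(isTRUE(all.equal(m1$params$head_class, m0$params$head_class)))
})

test_that("training is deterministic given the seed and reduces the loss", {
  cfg <- architecture_config(n_blocks = 2, feature_maps = 4, n_classes = 3)
  tc <- train_config(batch_size = 64, max_epochs = 2, seed = 123)
  m1 <- train_standard(build_model(cfg, seed = 6), fix_dataset(), tc)
  m2 <- train_standard(build_model(cfg, seed = 6), fix_dataset(), tc)
  h1 <- attr(m1, "history"); h2 <- attr(m2, "history")
  expect_identical(h1$val_loss, h2$val_loss)
  expect_lt(h1$train_loss[2], h1$train_loss[1])
  expect_identical(m1$params, m2$params)
})

test_that("single-participant ADANN falls back to standard training", {
  ds <- subset_dataset(fix_dataset(), which(fix_dataset()$meta$participant == 1))
  cfg <- architecture_config(n_blocks = 2, feature_maps = 4, n_classes = 3)
  expect_warning(
    m <- train_adann(build_model(cfg, seed = 7), ds,
                     train_config(batch_size = 64, max_epochs = 1)),
    "single participant")
  expect_true("aggregate" %in% names(m$bn))
})

test_that("annealing and early stopping fire at the documented schedule", {
  ctl <- emglens:::.lr_controller(train_config(patience = 2, anneal_factor = 5,
                                               lr = 1))
  expect_equal(ctl$update(1.0), "improved")
  expect_equal(ctl$update(1.1), "waiting")
  expect_equal(ctl$update(1.1), "waiting")
  expect_equal(ctl$update(1.1), "annealed")   # patience 2 exceeded
  expect_equal(ctl$lr, 1 / 5)
  expect_equal(ctl$update(0.9), "improved")   # improvement resets strikes
  expect_equal(ctl$strikes, 0)
  for (i in 1:3) ctl$update(2)
  expect_equal(ctl$lr, 1 / 25)
  r <- NULL
  for (i in 1:3) r <- ctl$update(2)
  expect_equal(r, "stop")                     # 2nd annealing without a best
})

test_that("cross-subject evaluation: trained accuracy and chance level", {
  m <- fix_model()
  ds <- fix_dataset()
  acc <- evaluate_cross_subject(m, ds, adaptation = "adabn")
  # participants seen in training, evaluated on held-out cycles: the tiny
  # trained fixture should be far above the 1/3 chance level
  expect_gt(mean(acc), 0.8)
  # label permutation: accuracy collapses to ~chance
  ds_perm <- ds
  set.seed(1)
  ds_perm$meta$gesture <- sample(ds_perm$meta$gesture)
  acc_p <- evaluate_cross_subject(m, ds_perm, adaptation = "adabn")
  expect_lt(abs(mean(acc_p) - 1 / 3), 0.12)
  # adaptation = "none" also runs (average-bank path)
  acc_n <- evaluate_cross_subject(m, ds, participants = 1,
                                  adaptation = "none")
  expect_true(is.finite(acc_n))
})

test_that("Wilcoxon signed-rank p matches exhaustive enumeration; Cohen's d", {
  # 6 fixed pairs without ties or zeros
  a <- c(0.81, 0.74, 0.69, 0.90, 0.66, 0.77)
  b <- c(0.72, 0.70, 0.71, 0.80, 0.60, 0.70)
  r <- compare_training_methods(a, b)
  expect_equal(r$p_value, oracle_signed_rank_p(a - b), tolerance = 1e-12)
  # constant +1 shift with n = 22 is maximally significant (tied absolute
  # differences force the normal approximation, hence the suppression)
  set.seed(2)
  base <- runif(22)
  r2 <- suppressWarnings(compare_training_methods(base + 1, base))
  expect_lt(r2$p_value, 0.001)
  # identical vectors: d = 0
  expect_equal(suppressWarnings(compare_training_methods(base, base))$cohens_d, 0)
  # hand-computed pooled-SD d
  expect_equal(r$cohens_d, mean(a - b) / sqrt((var(a) + var(b)) / 2),
               tolerance = 1e-12)
  expect_error(compare_training_methods(a[1:4], b[1:4]), "at least 5")
})
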