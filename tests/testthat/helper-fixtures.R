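# Shared fixtures, built once per test run and cached.
#
# Everything is generated in code (no binary fixtures); sizes are kept
# small so the whole non-acceptance suite stays in the minutes range.

.fixture_env <- new.env()

.fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small multi-participant dataset: 3 participants x 3 gestures x 8 cycles
# of 1 s -> 17 windows per recording, 1224 windows total
fix_dataset <- function() {
  .fixture("dataset", function() {
    generate_dataset(synth_config(participants = 3, gestures = 3,
                                  cycle_s = 1, cycles = 8, seed = 42))
  })
}

# an even smaller dataset for feature tables (192 windows)
fix_tiny_dataset <- function() {
  .fixture("tiny_dataset", function() {
    generate_dataset(synth_config(participants = 2, gestures = 3,
                                  cycle_s = 0.35, cycles = 8, seed = 11))
  })
}

fix_registry <- function() .fixture("registry", feature_registry)

# handcrafted feature table on the tiny dataset
fix_features <- function() {
  .fixture("features", function() compute_all(fix_tiny_dataset(), fix_registry()))
}

# a reduced ConvNet trained briefly on the small dataset (enough to be
# far above chance within-domain)
fix_model <- function() {
  .fixture("model", function() {
    acfg <- architecture_config(n_blocks = 2, feature_maps = 8, n_classes = 3)
    train_adann(build_model(acfg, seed = 1), fix_dataset(),
                train_config(batch_size = 64, max_epochs = 2, patience = 2,
                             seed = 1))
  })
}

# learned-feature table of the trained fixture on the tiny dataset
fix_learned <- function() {
  .fixture("learned", function() {
    m <- fix_model()
    extract_learned_features(m, fix_tiny_dataset(), participant_bank = "own")
  })
}

# one full Mapper scenario-A run on the handcrafted table, shared by the
# end-to-end and export tests
fix_scenarioA <- function() {
  .fixture("scenarioA", function() {
    run_scenario(list(handcrafted = fix_features()), "A", seed = 7)
  })
}

# ---- independent oracles -------------------------------------------------

# literal im2col convolution, independent of the package's kernels
oracle_conv <- function(a_arr, w, bias) {
  # a_arr: [n, m_in, T]; w: [m_out, m_in, K]
  n <- dim(a_arr)[1]; m_in <- dim(a_arr)[2]; tt <- dim(a_arr)[3]
  m_out <- dim(w)[1]; k <- dim(w)[3]
  t_out <- tt - k + 1
  out <- array(0, dim = c(n, m_out, t_out))
  for (i in seq_len(n)) {
    for (j in seq_len(m_out)) {
      for (t in seq_len(t_out)) {
        acc <- bias[j]
        for (c in seq_len(m_in)) {
          for (kk in seq_len(k)) {
            acc <- acc + a_arr[i, c, t + kk - 1] * w[j, c, kk]
          }
        }
        out[i, j, t] <- acc
      }
    }
  }
  out
}

# brute-force Mapper steps 3-5 on a 2-D lens: vectorised nowhere, loops
# everywhere, cell-centred k x k cover, Ward + first-gap cut via the
# package's partial_cluster is NOT used -- clustering callback is
# injected so graph assembly is tested independently of the cut.
oracle_mapper <- function(lens_xy, high_pts, k, overlap, cluster_fun) {
  lo <- c(min(lens_xy[, 1]), min(lens_xy[, 2]))
  hi <- c(max(lens_xy[, 1]), max(lens_xy[, 2]))
  h <- (hi - lo) / k
  d_half <- h / (1 - overlap) / 2
  nodes <- list()
  for (ix in seq_len(k)) {
    for (iy in seq_len(k)) {
      cx <- lo[1] + h[1] * (ix - 0.5)
      cy <- lo[2] + h[2] * (iy - 0.5)
      mem <- c()
      for (p in seq_len(nrow(lens_xy))) {
        if (abs(lens_xy[p, 1] - cx) <= d_half[1] + 1e-12 &&
            abs(lens_xy[p, 2] - cy) <= d_half[2] + 1e-12) mem <- c(mem, p)
      }
      if (length(mem) == 0) next
      cl <- cluster_fun(high_pts[mem, , drop = FALSE])
      for (g in sort(unique(cl))) {
        nodes[[length(nodes) + 1]] <- sort(mem[cl == g])
      }
    }
  }
  nn <- length(nodes)
  edges <- matrix(integer(0), ncol = 2)
  if (nn > 1) {
    for (i in 1:(nn - 1)) {
      for (j in (i + 1):nn) {
        if (length(intersect(nodes[[i]], nodes[[j]])) > 0) {
          edges <- rbind(edges, c(i, j))
        }
      }
    }
  }
  list(nodes = nodes, edges = edges)
}

# exact two-sided signed-rank p-value by enumerating all sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  ev <- n * (n + 1) / 4
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
}
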