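# The handcrafted feature bank: registry structure, closed-form examples,
# oracle recomputations and scaling properties.

test_that("registry has the documented structure", {
  reg <- fix_registry()
  s <- registry_summary(reg)
  expect_equal(s$n_methods, 56)
  expect_equal(s$n_outputs, 79)
  expect_equal(as.numeric(s$group_counts), c(25, 5, 6, 7, 13))
  expect_false(anyDuplicated(names(reg$entries)) > 0)
  # multi-output expansions
  no <- vapply(reg$entries, `[[`, numeric(1), "n_outputs")
  expect_equal(unname(no[c("AR", "CC", "DAR", "DCC", "HIST", "MHW", "MTW",
                           "TSPSD")]),
               c(4, 4, 4, 4, 3, 3, 3, 6))
})

test_that("closed-form examples", {
  reg <- fix_registry()
  alt <- rep(c(1, -1), length.out = 151)
  expect_equal(compute_feature(reg$entries$MAV, alt), 1)
  expect_equal(compute_feature(reg$entries$ZC, alt), 150)
  expect_equal(compute_feature(reg$entries$RMS, rep(-2.5, 151)), 2.5)
  expect_equal(compute_feature(reg$entries$WL, 0:150), 150)
  expect_equal(compute_feature(reg$entries$IEMG, alt), 151)
  expect_equal(compute_feature(reg$entries$MAX, c(rep(0.1, 150), -7)), 7)
  expect_error(compute_feature(reg$entries$MAV, c(rep(0, 150), NA)),
               "input error")
})

test_that("AR coefficients recover a simulated AR(1) process", {
  set.seed(7)
  x <- as.numeric(stats::filter(rnorm(10000), 0.5, method = "recursive"))
  phi <- ar_coefficients(x, 4)
  expect_equal(phi[1], 0.5, tolerance = 0.1)
  expect_lt(max(abs(phi[2:4])), 0.1)
})

test_that("cepstral recursion identity holds exactly", {
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(151)
    phi <- ar_coefficients(x, 4)
    cc <- cepstral_from_ar(phi)
    expect_identical(cc[1], phi[1])      # c1 = -a1 with a1 = -phi1
    # full recursion against a direct evaluation
    a <- -phi
    c2 <- -a[2] - (1 / 2) * cc[1] * a[1]
    c3 <- -a[3] - (1 / 3) * cc[1] * a[2] - (2 / 3) * cc[2] * a[1]
    expect_equal(cc[2:3], c(c2, c3), tolerance = 1e-12)
  }
})

test_that("spectral moment identities for VCF and OHM", {
  reg <- fix_registry()
  set.seed(9)
  x <- rnorm(151)
  # oracle: moments recomputed from scratch with a raw FFT
  n <- length(x)                         # odd: no Nyquist bin, fold 2..nh+1
  nh <- floor(n / 2)
  p <- Mod(stats::fft(x)[1:(nh + 1)])^2 / n
  p[2:(nh + 1)] <- 2 * p[2:(nh + 1)]
  fr <- (0:nh) * 1000 / n
  m <- function(k) sum(fr[-1]^k * p[-1])
  expect_equal(compute_feature(reg$entries$VCF, x),
               m(2) / m(0) - (m(1) / m(0))^2, tolerance = 1e-10)
  expect_equal(compute_feature(reg$entries$OHM, x),
               sqrt(m(2) / m(0)) / (m(1) / m(0)), tolerance = 1e-10)
})

test_that("difference-series features equal base features of diff(x)", {
  reg <- fix_registry()
  set.seed(10)
  x <- rnorm(151, 0, 40)
  d <- diff(x)
  pairs <- list(c("DAMV", "MAV"), c("DLD", "LD"), c("DVARV", "VAR"),
                c("DV", "V"), c("DTM", "TM"))
  for (p in pairs) {
    expect_equal(compute_feature(reg$entries[[p[1]]], x),
                 compute_feature(reg$entries[[p[2]]], d), tolerance = 1e-12,
                 label = p[1])
  }
  expect_equal(compute_feature(reg$entries$DAR, x),
               compute_feature(reg$entries$AR, d), tolerance = 1e-12)
  expect_equal(compute_feature(reg$entries$DCC, x),
               compute_feature(reg$entries$CC, d), tolerance = 1e-12)
  expect_equal(compute_feature(reg$entries$DASDV, x),
               sqrt(mean(d^2)), tolerance = 1e-12)
})

test_that("sample entropy separates noise from a sine", {
  reg <- fix_registry()
  set.seed(11)
  noise <- rnorm(151)
  sine <- sin(2 * pi * 7 * (0:150) / 151)
  expect_gt(compute_feature(reg$entries$SAMPEN, noise),
            compute_feature(reg$entries$SAMPEN, sine))
  expect_gt(compute_feature(reg$entries$APEN, noise),
            compute_feature(reg$entries$APEN, sine))
})

test_that("amplitude scaling: SAP features scale, thresholdless counters do not", {
  reg <- fix_registry()
  set.seed(12)
  x <- rnorm(151, 0, 30)
  g <- 4.2
  for (f in c("MAV", "RMS", "WL", "IEMG", "MAX", "DAMV")) {
    expect_equal(compute_feature(reg$entries[[f]], g * x),
                 g * compute_feature(reg$entries[[f]], x), tolerance = 1e-9,
                 label = f)
  }
  for (f in c("ZC", "SSC", "BC", "KATZ")) {
    expect_equal(compute_feature(reg$entries[[f]], g * x),
                 compute_feature(reg$entries[[f]], x), tolerance = 1e-9,
                 label = f)
  }
})

test_that("degenerate windows stay finite", {
  reg <- fix_registry()
  for (x in list(rep(0, 151), rep(2.5, 151), c(rep(0, 150), 1))) {
    v <- unlist(lapply(reg$entries, compute_feature, x = x))
    expect_true(all(is.finite(v)))
  }
})

test_that("compute_all: shape, determinism, channel independence", {
  ds <- subset_dataset(fix_tiny_dataset(), 1:6)
  reg <- fix_registry()
  ft <- compute_all(ds, reg)
  expect_equal(dim(ft$values), c(6, 10, 79))
  expect_true(all(is.finite(ft$values)))
  # duplicate window -> identical rows
  ds2 <- ds; ds2$windows[, , 2] <- ds2$windows[, , 1]
  ft2 <- compute_all(ds2, reg)
  expect_identical(ft2$values[1, , ], ft2$values[2, , ])
  # permuting channels permutes feature rows identically
  perm <- c(3, 1, 2, 5, 4, 7, 6, 9, 10, 8)
  ds3 <- ds; ds3$windows <- ds3$windows[perm, , , drop = FALSE]
  ft3 <- compute_all(ds3, reg)
  expect_equal(ft3$values, ft$values[, perm, ], tolerance = 1e-12)
})

test_that("feature table export and registry schema are written", {
  dir <- withr::local_tempdir()
  ft <- compute_all(subset_dataset(fix_tiny_dataset(), 1:3), fix_registry())
  f1 <- write_feature_table(ft, file.path(dir, "ft.csv"))
  tab <- utils::read.csv(f1)
  expect_equal(nrow(tab), 3)
  expect_equal(ncol(tab), 3 + 790)
  f2 <- write_registry_schema(fix_registry(), file.path(dir, "reg.json"))
  sch <- jsonlite::fromJSON(f2)
  expect_equal(nrow(sch), 56)
})
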