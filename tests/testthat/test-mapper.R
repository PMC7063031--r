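# Mapper pipeline: point-cloud construction, PCA reduction, the t-SNE
# lens, cover geometry, Ward partial clustering, graph assembly (against
# a brute-force oracle) and end-to-end invariances.

test_that("scenario point counts: A = 79, B = 384, C = 463", {
  hc <- fix_features()
  tables <- list(handcrafted = hc, learned = fix_learned())
  a <- build_point_cloud(tables, "A")
  expect_equal(nrow(a$points), 79)
  expect_equal(ncol(a$points), n_windows(fix_tiny_dataset()) * 10)
  # full-width learned table (6 blocks x 64 maps) on one window
  full <- ensure_bank(build_model(architecture_config(), seed = 1), "agg")
  ds1 <- subset_dataset(fix_tiny_dataset(), 1:2)
  lf <- extract_learned_features(full, ds1, participant_bank = "agg")
  b <- build_point_cloud(list(learned = lf), "B")
  expect_equal(nrow(b$points), 384)
  hc2 <- compute_all(ds1, fix_registry())
  cc <- build_point_cloud(list(handcrafted = hc2, learned = lf), "C")
  expect_equal(nrow(cc$points), 79 + 384)
  # rows are z-scored
  expect_equal(unname(apply(a$points[1:5, ], 1, mean)), rep(0, 5),
               tolerance = 1e-9)
  # mismatched window sets are rejected
  expect_error(build_point_cloud(list(handcrafted = hc, learned = lf), "C"),
               "different window sets")
})

test_that("PCA reduction honours the variance target", {
  set.seed(1)
  # points exactly on a 2-D plane embedded in 30-D
  basis <- matrix(rnorm(60), 2, 30)
  pts <- matrix(rnorm(40), 20, 2) %*% basis
  cloud <- structure(list(points = pts, ids = as.character(1:20),
                          labels = rep("x", 20)), class = "point_cloud")
  red <- reduce_pca(cloud, 0.99)
  expect_equal(red$n_components, 2)
  # reconstruction error bounded by the discarded variance
  pc <- prcomp(pts)
  rec <- pc$x[, 1:2] %*% t(pc$rotation[, 1:2])
  resid <- sum((scale(pts, scale = FALSE) - rec)^2)
  expect_lt(resid / sum(scale(pts, scale = FALSE)^2), 0.01)
  # isotropic cloud: about 99% of the dimensions are needed
  iso <- structure(list(points = matrix(rnorm(300 * 50), 300), ids = NULL,
                        labels = NULL), class = "point_cloud")
  k <- reduce_pca(iso, 0.99)$n_components
  expect_gt(k, 0.9 * 50)
})

test_that("t-SNE lens: deterministic, separates blobs, warns when small", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(40 * 5), 40), matrix(rnorm(40 * 5) + 12, 40))
  cloud <- structure(list(points = pts, ids = as.character(1:80),
                          labels = rep(c("a", "b"), each = 40)),
                     class = "point_cloud")
  l1 <- suppressWarnings(tsne_lens(cloud, perplexity = 10, seed = 5,
                                   max_iter = 400))
  l2 <- suppressWarnings(tsne_lens(cloud, perplexity = 10, seed = 5,
                                   max_iter = 400))
  expect_identical(l1$coords, l2$coords)
  expect_true(is.finite(l1$kl) && l1$kl >= 0)
  # between/within distance ratio of the two blobs
  ctr_a <- colMeans(l1$coords[1:40, ]); ctr_b <- colMeans(l1$coords[41:80, ])
  between <- sqrt(sum((ctr_a - ctr_b)^2))
  within <- mean(c(sqrt(rowSums(sweep(l1$coords[1:40, ], 2, ctr_a)^2)),
                   sqrt(rowSums(sweep(l1$coords[41:80, ], 2, ctr_b)^2))))
  expect_gt(between / within, 2)
  expect_warning(
    expect_warning(tsne_lens(cloud, perplexity = 100, seed = 1, max_iter = 5),
                   "clamping"),
    "unstable")
})

test_that("cover geometry: 25 regions, full coverage, overlap behaviour", {
  set.seed(3)
  lens <- structure(list(coords = matrix(runif(200), 100, 2),
                         ids = NULL, labels = NULL), class = "mapper_lens")
  cov <- build_cover(lens, k = 5, overlap = 0.65)
  expect_equal(nrow(cov$centers), 25)
  mem <- cover_membership(cov, lens)
  counts <- tabulate(unlist(mem), 100)
  expect_true(all(counts >= 1))                  # every point covered
  # points near cell centres lie in more than one region at 65% overlap
  ctr_pt <- which.min(rowSums((lens$coords -
    matrix(cov$centers[13, ], 100, 2, byrow = TRUE))^2))
  expect_gt(counts[ctr_pt], 1)
  # zero overlap partitions the box (up to shared boundaries)
  cov0 <- build_cover(lens, k = 5, overlap = 0)
  mem0 <- cover_membership(cov0, lens)
  expect_true(all(tabulate(unlist(mem0), 100) >= 1))
  interior <- table(unlist(mem0))
  expect_gt(mean(interior == 1), 0.9)
  expect_error(build_cover(lens, overlap = 1), "overlap")
  # vertex-centred variant has (k+1)^2 regions
  expect_equal(nrow(build_cover(lens, k = 5, overlap = 0.65,
                                vertex_centered = TRUE)$centers), 36)
})

test_that("Ward partial clustering with the first-gap cut", {
  expect_equal(partial_cluster(matrix(1, 4, 2)), rep(1L, 4))
  expect_equal(partial_cluster(matrix(rnorm(2), 1, 2)), 1L)
  # two far-separated tight pairs -> 2 clusters
  pts <- rbind(c(0, 0), c(0, 0.1), c(50, 50), c(50, 50.1))
  cl <- partial_cluster(pts)
  expect_equal(length(unique(cl)), 2)
  expect_equal(cl[1], cl[2])
  expect_equal(cl[3], cl[4])
  expect_false(cl[1] == cl[3])
})

test_that("graph assembly matches a brute-force oracle on a toy instance", {
  set.seed(4)
  # 20 points in 3 loose groups; high-dim coordinates = lens + noise dims
  lens_xy <- rbind(matrix(rnorm(14, 0, 0.4), 7, 2),
                   matrix(rnorm(14, 3, 0.4), 7, 2),
                   cbind(rnorm(6, 1.5, 0.4), rnorm(6, 3, 0.4)))
  high <- cbind(lens_xy, matrix(rnorm(40, 0, 0.1), 20, 2))
  lens <- structure(list(coords = lens_xy, ids = as.character(1:20),
                         labels = rep(c("g1", "g2", "g3"), c(7, 7, 6))),
                    class = "mapper_lens")
  cov <- build_cover(lens, k = 3, overlap = 0.5)
  mem <- cover_membership(cov, lens)
  cls <- lapply(mem, function(i) partial_cluster(high[i, , drop = FALSE]))
  g <- assemble_graph(mem, cls, labels = lens$labels, ids = lens$ids)
  ref <- oracle_mapper(lens_xy, high, k = 3, overlap = 0.5,
                       cluster_fun = partial_cluster)
  expect_equal(length(g$nodes), length(ref$nodes))
  got <- lapply(g$nodes, function(n) sort(n$members))
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  vapply(ref$nodes, paste, character(1), collapse = ","))
  # edge sets agree after mapping node indices by member sets
  key <- vapply(got, paste, character(1), collapse = ",")
  rkey <- vapply(ref$nodes, paste, character(1), collapse = ",")
  map <- match(key, rkey)
  e1 <- apply(g$edges, 1, function(e) paste(sort(map[e]), collapse = "-"))
  e2 <- apply(ref$edges, 1, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(e1, e2)
  # every clustered point appears in at least one node
  expect_setequal(sort(unique(unlist(got))), 1:20)
})

test_that("identical points produce a complete graph across regions", {
  lens <- structure(list(coords = matrix(1, 6, 2), ids = as.character(1:6),
                         labels = rep("x", 6)), class = "mapper_lens")
  cov <- build_cover(lens, k = 2, overlap = 0.5)
  mem <- cover_membership(cov, lens)
  cls <- lapply(mem, function(i) rep(1L, length(i)))
  g <- assemble_graph(mem, cls)
  nn <- length(g$nodes)
  expect_equal(nrow(g$edges), nn * (nn - 1) / 2)
})

test_that("end-to-end scenario A: determinism, coverage, composition", {
  tables <- list(handcrafted = fix_features())
  r1 <- fix_scenarioA()
  r2 <- run_scenario(tables, "A", seed = 7)
  expect_equal(r1$report, r2$report)
  expect_identical(lapply(r1$graph$nodes, `[[`, "members"),
                   lapply(r2$graph$nodes, `[[`, "members"))
  expect_equal(r1$report$n_points, 79)
  # member union covers all clustered points
  expect_setequal(unique(unlist(lapply(r1$graph$nodes, `[[`, "members"))),
                  1:79)
  # node compositions are valid fractions
  for (nd in r1$graph$nodes) {
    expect_equal(sum(unlist(nd$composition)), 1, tolerance = 1e-9)
  }
  # same-group concentration: mean max composition should comfortably beat
  # a label permutation
  conc <- function(g) {
    mean(vapply(g$nodes, function(nd) max(unlist(nd$composition)), numeric(1)))
  }
  obs <- conc(r1$graph)
  set.seed(1)
  perm_vals <- replicate(5, {
    mem <- r1$memberships; cls <- r1$clusterings
    pl <- sample(r1$cloud$labels)
    gp <- assemble_graph(mem, cls, labels = pl, ids = r1$cloud$ids)
    conc(gp)
  })
  expect_gt(obs, mean(perm_vals))
})

test_that("uniform translation and scaling leave node membership unchanged", {
  # the pipeline is deformation-invariant whenever the deformed
  # coordinates are exactly representable, so snap the cloud to a
  # 1/256 grid: x * 2 and x + 5 are then exact in double precision
  tables <- list(handcrafted = fix_features())
  cloud <- build_point_cloud(tables, "A")
  red <- reduce_pca(cloud)
  red$points <- round(red$points * 256) / 256
  run_from <- function(pts) {
    cl <- red; cl$points <- pts
    lens <- suppressWarnings(tsne_lens(cl, seed = 3))
    cov <- build_cover(lens)
    mem <- cover_membership(cov, lens)
    cls <- lapply(mem, function(i) partial_cluster(pts[i, , drop = FALSE]))
    lapply(assemble_graph(mem, cls)$nodes,
           function(n) sort(unname(n$members)))
  }
  base <- run_from(red$points)
  moved <- run_from(red$points * 2 + 5)
  expect_identical(base, moved)
})

test_that("graph and lens exports are well formed", {
  dir <- withr::local_tempdir()
  r <- fix_scenarioA()
  j <- jsonlite::fromJSON(write_graph_json(r$graph, file.path(dir, "g.json")),
                          simplifyVector = FALSE)
  expect_length(j$nodes, length(r$graph$nodes))
  gml <- readLines(write_graphml(r$graph, file.path(dir, "g.graphml")))
  expect_true(any(grepl("graphml", gml)))
  expect_equal(sum(grepl("<node ", gml)), length(r$graph$nodes))
  lcsv <- utils::read.csv(write_lens_csv(r$lens, file.path(dir, "l.csv")))
  expect_equal(nrow(lcsv), 79)
})
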