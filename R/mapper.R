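# Mapper topological data analysis over feature point clouds.
#
# Pipeline: (1) prepare -- each feature id becomes one point, its
# coordinates the feature's values over all (window, channel) pairs,
# z-scored; (2) PCA to 99% variance; (3) a 2-D t-SNE lens (perplexity 30);
# (4) a cover of 5 x 5 axis-aligned regions overlapping by 65%;
# (5) Ward partial clustering inside each region (in the PCA space);
# (6) clusters become nodes, and nodes sharing a member feature are
# connected. Scenario A uses the 79 handcrafted features, B the 384
# learned features (6 blocks x 64 maps), C their union (463 points).

#' Build a feature point cloud
#'
#' @param tables named list of `feature_table`s; `handcrafted` is required
#'   for scenarios A and C, `learned` for B and C. Tables must be computed
#'   on the same windows.
#' @param scenario `"A"` (handcrafted), `"B"` (learned) or `"C"` (both).
#' @return object of class `point_cloud`: `points` (M x N*C matrix, one
#'   z-scored row per feature), `ids`, `labels` (functional group or
#'   block).
#' @export
build_point_cloud <- function(tables, scenario = c("A", "B", "C")) {
  scenario <- match.arg(scenario)
  use <- switch(scenario, A = "handcrafted", B = "learned",
                C = c("handcrafted", "learned"))
  .assert(all(use %in% names(tables)),
          sprintf("scenario %s needs tables: %s", scenario,
                  paste(use, collapse = ", ")))
  if (length(use) > 1) {
    m1 <- tables[[use[1]]]$meta; m2 <- tables[[use[2]]]$meta
    .assert(nrow(m1) == nrow(m2) && all(m1 == m2),
            "feature tables computed on different window sets")
  }
  rows <- list(); ids <- c(); labels <- c()
  for (nm in use) {
    tb <- tables[[nm]]
    d <- dim(tb$values)
    for (m in seq_len(d[3])) {
      # order: window-major, channel within window
      v <- as.vector(t(tb$values[, , m]))
      s <- stats::sd(v)
      rows[[length(rows) + 1]] <- if (s < .EPS) v * 0 else (v - mean(v)) / s
    }
    ids <- c(ids, feature_ids(tb))
    labels <- c(labels, tb$groups)
  }
  structure(list(points = do.call(rbind, rows), ids = ids, labels = labels),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d features x %d coordinates\n",
              nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' First dimensionality reduction: PCA to a variance target
#'
#' Keeps the smallest number of principal components whose cumulative
#' variance reaches `variance`.
#'
#' @param cloud a `point_cloud`.
#' @param variance cumulative-variance target in (0, 1].
#' @return the cloud with `points` replaced by PC scores and
#'   `n_components` recorded.
#' @export
reduce_pca <- function(cloud, variance = 0.99) {
  .assert(nrow(cloud$points) >= 2, "need at least two points")
  pc <- stats::prcomp(cloud$points, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= variance)[1]
  cloud$points <- pc$x[, seq_len(k), drop = FALSE]
  cloud$n_components <- k
  cloud
}

# ---- exact t-SNE ---------------------------------------------------------
# Small point clouds (M <= a few hundred) allow the exact O(M^2)
# algorithm. Implemented here because the reference configuration uses
# perplexity 30 on as few as 79 points, which common implementations
# refuse (they require perplexity < (M-1)/3).

.tsne_p_matrix <- function(d2, perplexity) {
  n <- nrow(d2)
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .EPS) { h <- 0 } else {
        pr <- w / sw
        h <- -sum(pr * log(pmax(pr, .EPS)))
      }
      if (abs(h - target) < 1e-6) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p[i, -i] <- w / max(sum(w), .EPS)
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

#' Second reduction: 2-D t-SNE lens
#'
#' Exact t-SNE with early exaggeration, momentum and a fixed iteration
#' count; deterministic given `seed`. The final Kullback-Leibler
#' divergence is reported as an embedding-quality diagnostic.
#'
#' @param cloud a (PCA-reduced) `point_cloud`.
#' @param perplexity t-SNE perplexity; if `perplexity >= M` it is clamped
#'   to `M - 1` with a warning, and a warning is also raised when
#'   `M <= 3 * perplexity` (small clouds give diffuse embeddings).
#' @param dims embedding dimensionality.
#' @param seed controls the random initialisation.
#' @param max_iter gradient-descent iterations.
#' @return object of class `mapper_lens`: `coords` (M x dims), `kl`
#'   (final divergence), `ids`, `labels`.
#' @export
tsne_lens <- function(cloud, perplexity = 30, dims = 2, seed = 1L,
                      max_iter = 600) {
  x <- cloud$points
  n <- nrow(x)
  if (perplexity >= n) {
    warning("perplexity >= number of points; clamping")
    perplexity <- n - 1
  }
  if (n <= 3 * perplexity) {
    warning("fewer than 3 * perplexity points; the lens may be unstable")
  }
  d2 <- as.matrix(stats::dist(x))^2
  # normalising by the mean squared distance makes the affinities exactly
  # invariant to uniform translation / scaling of the cloud
  d2 <- d2 / max(mean(d2), .EPS)
  p <- .tsne_p_matrix(d2, perplexity)
  .with_seed(seed, {
    y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
    gain <- matrix(1, n, dims)
    inc <- matrix(0, n, dims)
    exag <- 12
    lr <- max(n / exag / 4, 50)
    kl <- NA_real_
    for (it in seq_len(max_iter)) {
      pp <- if (it <= 100) p * exag else p
      num <- 1 / (1 + as.matrix(stats::dist(y))^2)
      diag(num) <- 0
      q <- pmax(num / sum(num), 1e-12)
      mult <- (pp - q) * num
      grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
      mom <- if (it < 250) 0.5 else 0.8
      gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
      gain[gain < 0.01] <- 0.01
      inc <- mom * inc - lr * gain * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
      if (it == max_iter) kl <- sum(p * log(p / q))
    }
    structure(list(coords = y, kl = kl, ids = cloud$ids,
                   labels = cloud$labels),
              class = "mapper_lens")
  })
}

#' @export
print.mapper_lens <- function(x, ...) {
  cat(sprintf("<mapper_lens> %d points in %d-D, final KL divergence %.3f\n",
              nrow(x$coords), ncol(x$coords), x$kl))
  invisible(x)
}

#' Build the overlapping cover of a lens
#'
#' The lens bounding box is split into `k` cells per dimension of side
#' `H`; each region is the cell expanded symmetrically to side
#' `D = H / (1 - overlap)`, so adjacent regions share a fraction
#' `overlap` of their extent. Every lens point lies in at least one
#' region. With `vertex_centered = TRUE` the regions are instead centred
#' on the `(k+1)^dims` cell vertices (the textbook formulation); the
#' default cell-centred `k^dims` grid is the convention used in practice.
#'
#' @param lens a `mapper_lens`.
#' @param k divisions per dimension.
#' @param overlap overlap fraction in [0, 1).
#' @param vertex_centered use the `(k+1)^dims` vertex-centred variant.
#' @return object of class `mapper_cover`: region centres and half-sides.
#' @export
build_cover <- function(lens, k = 5, overlap = 0.65, vertex_centered = FALSE) {
  if (overlap >= 1) stop("overlap fraction must be < 1", call. = FALSE)
  .assert(nrow(lens$coords) > 0, "empty lens")
  dims <- ncol(lens$coords)
  lo <- apply(lens$coords, 2, min)
  hi <- apply(lens$coords, 2, max)
  h <- (hi - lo) / k
  centers1d <- lapply(seq_len(dims), function(j) {
    if (vertex_centered) lo[j] + h[j] * (0:k) else lo[j] + h[j] * (seq_len(k) - 0.5)
  })
  grid <- as.matrix(expand.grid(centers1d))
  dimnames(grid) <- NULL
  half <- h / (1 - overlap) / 2
  structure(list(centers = grid, half = half, k = k, overlap = overlap,
                 bbox = rbind(lo, hi), dims = dims),
            class = "mapper_cover")
}

#' Region membership of lens points
#'
#' @param cover a `mapper_cover`.
#' @param lens a `mapper_lens`.
#' @return list (one element per region) of point indices; every point
#'   appears in at least one region.
#' @export
cover_membership <- function(cover, lens) {
  lapply(seq_len(nrow(cover$centers)), function(r) {
    inside <- rep(TRUE, nrow(lens$coords))
    for (j in seq_len(cover$dims)) {
      inside <- inside &
        abs(lens$coords[, j] - cover$centers[r, j]) <= cover$half[j] + 1e-12
    }
    which(inside)
  })
}

#' Ward partial clustering of one region
#'
#' Ward hierarchical clustering of the region's points (in the
#' PCA-reduced space), cut by the first-gap heuristic: merge heights are
#' histogrammed into `ceiling(sqrt(n))` bins over [0, max height]; the
#' dendrogram is cut at the first empty bin. If no gap exists the region
#' stays a single cluster.
#'
#' @param points numeric matrix of the region's points (rows).
#' @return integer cluster assignment of each row.
#' @export
partial_cluster <- function(points) {
  n <- nrow(points)
  if (n <= 1) return(rep(1L, n))
  hc <- stats::hclust(stats::dist(points), method = "ward.D2")
  hts <- hc$height
  if (max(hts) < .EPS) return(rep(1L, n))
  # at least 3 bins: with sqrt(n) bins alone, a 4-point region with two
  # tight far-apart pairs has no empty bin and the gap is invisible
  nb <- max(3, ceiling(sqrt(n)))
  breaks <- seq(0, max(hts) * (1 + 1e-9), length.out = nb + 1)
  counts <- graphics::hist(hts, breaks = breaks, plot = FALSE)$counts
  empty <- which(counts == 0)
  if (length(empty) == 0) return(rep(1L, n))
  cut_h <- breaks[empty[1]]
  as.integer(stats::cutree(hc, h = cut_h))
}

#' Assemble the topological graph from per-region clusterings
#'
#' @param memberships list of per-region point-index vectors
#'   ([cover_membership()]).
#' @param clusterings list of per-region cluster assignments
#'   ([partial_cluster()]), aligned with `memberships`.
#' @param labels optional per-point labels used to attach composition
#'   fractions to each node.
#' @param ids optional per-point ids stored in each node's member list.
#' @return object of class `topo_graph`: `nodes` (list with `members`,
#'   `region`, `composition`) and `edges` (2-column matrix of node pairs
#'   sharing at least one member).
#' @export
assemble_graph <- function(memberships, clusterings, labels = NULL,
                           ids = NULL) {
  nodes <- list()
  for (r in seq_along(memberships)) {
    pts <- memberships[[r]]
    if (length(pts) == 0) next
    cl <- clusterings[[r]]
    for (g in sort(unique(cl))) {
      mem <- pts[cl == g]
      comp <- if (!is.null(labels)) {
        tab <- table(labels[mem])
        as.list(tab / sum(tab))
      } else NULL
      nodes[[length(nodes) + 1]] <- list(
        members = mem, region = r, composition = comp,
        member_ids = if (!is.null(ids)) ids[mem] else NULL)
    }
  }
  nn <- length(nodes)
  edges <- matrix(integer(0), ncol = 2)
  if (nn > 1) {
    for (i in seq_len(nn - 1)) {
      for (j in (i + 1):nn) {
        if (length(intersect(nodes[[i]]$members, nodes[[j]]$members)) > 0) {
          edges <- rbind(edges, c(i, j))
        }
      }
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "topo_graph")
}

#' @export
print.topo_graph <- function(x, ...) {
  cat(sprintf("<topo_graph> %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Run a full Mapper scenario
#'
#' @param tables named list of feature tables (see [build_point_cloud()]).
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param variance,perplexity,k,overlap,seed pipeline hyperparameters.
#' @return list with the graph, lens, cover, memberships, clusterings and
#'   a summary report (node/edge counts, per-node composition).
#' @export
run_scenario <- function(tables, scenario = "A", variance = 0.99,
                         perplexity = 30, k = 5, overlap = 0.65, seed = 1L) {
  cloud <- build_point_cloud(tables, scenario)
  red <- reduce_pca(cloud, variance)
  lens <- suppressWarnings(tsne_lens(red, perplexity = perplexity, seed = seed))
  cover <- build_cover(lens, k = k, overlap = overlap)
  mem <- cover_membership(cover, lens)
  cls <- lapply(mem, function(idx) {
    partial_cluster(red$points[idx, , drop = FALSE])
  })
  graph <- assemble_graph(mem, cls, labels = cloud$labels, ids = cloud$ids)
  report <- list(scenario = scenario, n_points = nrow(cloud$points),
                 n_components = red$n_components, kl = lens$kl,
                 n_nodes = length(graph$nodes), n_edges = nrow(graph$edges))
  list(graph = graph, lens = lens, cover = cover, memberships = mem,
       clusterings = cls, cloud = cloud, report = report)
}

#' Export a topological graph as JSON
#' @param graph a `topo_graph`.
#' @param path output path.
#' @export
write_graph_json <- function(graph, path) {
  nodes <- lapply(seq_along(graph$nodes), function(i) {
    nd <- graph$nodes[[i]]
    list(id = i, region = nd$region, members = nd$member_ids,
         member_index = nd$members, composition = nd$composition)
  })
  edges <- if (nrow(graph$edges)) {
    lapply(seq_len(nrow(graph$edges)), function(e) {
      list(source = graph$edges[e, 1], target = graph$edges[e, 2])
    })
  } else list()
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a topological graph as GraphML
#' @param graph a `topo_graph`.
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
               '<key id="members" for="node" attr.name="members" attr.type="string"/>',
               '<graph edgedefault="undirected">'), con)
  for (i in seq_along(graph$nodes)) {
    mem <- graph$nodes[[i]]$member_ids
    if (is.null(mem)) mem <- graph$nodes[[i]]$members
    writeLines(sprintf('<node id="n%d"><data key="members">%s</data></node>',
                       i, paste(mem, collapse = " ")), con)
  }
  if (nrow(graph$edges)) {
    for (e in seq_len(nrow(graph$edges))) {
      writeLines(sprintf('<edge source="n%d" target="n%d"/>',
                         graph$edges[e, 1], graph$edges[e, 2]), con)
    }
  }
  writeLines(c("</graph>", "</graphml>"), con)
  invisible(path)
}

#' Export lens coordinates as CSV
#' @param lens a `mapper_lens`.
#' @param path output path.
#' @export
write_lens_csv <- function(lens, path) {
  df <- data.frame(id = lens$ids, label = lens$labels, lens$coords)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
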