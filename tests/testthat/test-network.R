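test_that("edges are exactly the strict threshold exceedances", {
  v <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  v[1, 2] <- v[2, 1] <- 0.5
  v[1, 3] <- v[3, 1] <- 0.01
  v[2, 3] <- v[3, 2] <- 0.02
  diag(v) <- 1
  m <- mi_matrix(v, h = 0.25, M = 10)
  net <- build_network(m, 0.06)
  expect_identical(nrow(net$edges), 1L)
  expect_setequal(c(net$edges$gene_a, net$edges$gene_b), c("g1", "g2"))

  # threshold above the matrix maximum: nodes retained, no edges
  empty <- build_network(m, 2)
  expect_identical(nrow(empty$edges), 0L)
  expect_length(empty$nodes, 3)

  # threshold -Inf: complete graph, no self loops
  full <- build_network(m, -Inf)
  expect_identical(nrow(full$edges), 3L)
  expect_false(any(full$edges$gene_a == full$edges$gene_b))

  # exhaustive check on a random instance
  set.seed(4)
  a <- matrix(rnorm(64, sd = 0.1), 8); sym <- (a + t(a)) / 2
  dimnames(sym) <- list(paste0("g", 1:8), paste0("g", 1:8))
  mm <- mi_matrix(sym, h = 0.25, M = 10)
  thr <- 0.05
  net <- build_network(mm, thr)
  expected <- sum(sym[upper.tri(sym)] > thr)
  expect_identical(nrow(net$edges), as.integer(expected))
  expect_true(all(net$edges$mi > thr))
})

test_that("permutation threshold dominates its per-repetition null maxima and is reproducible", {
  set.seed(10)
  X <- standardize(matrix(rnorm(40 * 15), 40, 15))
  thr <- permutation_threshold(X, h = 0.25, n_perm = 10, seed = 2)
  maxima <- attr(thr, "maxima")
  expect_length(maxima, 10)
  expect_true(all(as.numeric(thr) >= maxima))
  expect_identical(as.numeric(permutation_threshold(X, h = 0.25, n_perm = 10, seed = 2)),
                   as.numeric(thr))
  # more permutations can only raise the null maximum in distribution;
  # with a shared seed stream the first reps coincide
  thr5 <- permutation_threshold(X, h = 0.25, n_perm = 5, seed = 2)
  expect_gte(as.numeric(thr), as.numeric(thr5))
})

test_that("network files round-trip through edge list and GraphML", {
  set.seed(6)
  X <- standardize(matrix(rnorm(6 * 10), 6, 10,
                          dimnames = list(paste0("G", 1:6), NULL)))
  m <- pairwise_mi(X, 0.25)
  net <- build_network(m, stats::median(m$values[upper.tri(m$values)]),
                       permutation_count = 30L)
  expect_gt(nrow(net$edges), 0)
  dir <- withr::local_tempdir()

  el <- file.path(dir, "edges.tsv")
  write_network(net, el, format = "edgelist")
  lines <- readLines(el)
  expect_identical(sum(!startsWith(lines, "#")) - 1L, nrow(net$edges))
  back <- read_network(el, format = "edgelist")
  expect_identical(back$nodes, net$nodes)
  expect_equal(back$edges$mi, net$edges$mi, tolerance = 1e-9)
  expect_equal(back$threshold, net$threshold)

  gml <- file.path(dir, "net.graphml")
  write_network(net, gml, format = "graphml")
  back <- read_network(gml, format = "graphml")
  expect_setequal(back$nodes, net$nodes)
  key <- function(e) paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
  expect_setequal(key(back$edges), key(net$edges))
  expect_equal(sort(back$edges$mi), sort(net$edges$mi), tolerance = 1e-9)

  # empty network round-trips too
  empty <- build_network(m, 10)
  write_network(empty, el, format = "edgelist")
  expect_identical(nrow(read_network(el)$edges), 0L)
  expect_length(read_network(el)$nodes, 6)
  write_network(empty, gml, format = "graphml")
  expect_identical(nrow(read_network(gml, "graphml")$edges), 0L)
})

test_that("clustering orders identical rows together and recovers planted blocks", {
  # two identical rows merge at height 0
  v <- matrix(c(1, 0.9, 0, 0.9, 1, 0, 0, 0, 1), 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  v[2, ] <- v[1, ]; v[, 2] <- v[, 1]; v <- (v + t(v)) / 2
  co <- cluster_order(mi_matrix(v, 0.25, 5))
  expect_equal(co$hclust$height[1], 0)
  expect_setequal(co$order, paste0("g", 1:3))

  # planted two-block MI structure: blocks contiguous in the leaf order
  blocks <- rep(1:2, each = 5)
  sim <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.8, 0.05))
  set.seed(9)
  sim <- sim + matrix(rnorm(100, sd = 0.01), 10)
  sim <- (sim + t(sim)) / 2; diag(sim) <- 1
  dimnames(sim) <- list(paste0("g", 1:10), paste0("g", 1:10))
  co <- cluster_order(mi_matrix(sim, 0.25, 20))
  pos <- match(paste0("g", 1:10), co$order)
  expect_lt(max(pos[blocks == 1]) - min(pos[blocks == 1]), 5)
  expect_lt(max(pos[blocks == 2]) - min(pos[blocks == 2]), 5)
  expect_setequal(co$order, rownames(sim))
  expect_false(is.unsorted(co$hclust$height))
})

test_that("genes tied to a hub sit closer to it than unrelated genes", {
  # planted topology: a hub correlated with its block, plus independent noise
  gen <- generate_dataset(synthetic_spec(
    n_genes = 30, n_informative = 0, n_samples_per_class = 20,
    n_corr_blocks = 1, block_size = 6, block_rho = 0.85, seed = 12))
  X <- standardize(gen$dataset)$values
  m <- pairwise_mi(X, 0.25)
  thr <- permutation_threshold(X, h = 0.25, n_perm = 10, seed = 3)
  net <- build_network(m, as.numeric(thr))
  g <- as_igraph(net)
  block <- names(gen$block_membership)
  hub <- block[1]
  others <- setdiff(net$nodes, block)
  d <- igraph::distances(g, v = hub)
  expect_lt(mean(d[, setdiff(block, hub)]), mean(d[, others]))
})
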