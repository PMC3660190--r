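test_that("the r heuristic follows max(5, int(500/n + 0.5))", {
  expect_identical(compute_r(28), 18L)
  expect_identical(compute_r(500), 5L)
  expect_identical(compute_r(5), 100L)
  expect_error(compute_r(1), "at least 2")
})

test_that("split plans are stratified, sized by the validation fraction, and reproducible", {
  gen <- toy_dataset(n_genes = 10, n_per_class = 14, seed = 2)
  ds <- gen$dataset
  plans <- plan_splits(ds, 0.3, seed = 5, r = 10)
  expect_length(plans, 10)
  for (p in plans) {
    expect_length(intersect(p$train, p$validation), 0)
    expect_setequal(c(p$train, p$validation), seq_len(28))
    # round(0.3 * 14) = 4 per class held out
    expect_identical(sum(ds$labels[p$validation] == 1), 4L)
    expect_identical(sum(ds$labels[p$validation] == 0), 4L)
    expect_setequal(unique(ds$labels[p$train]), c(0L, 1L))
  }
  expect_identical(plan_splits(ds, 0.3, seed = 5, r = 10), plans)
  expect_error(plan_splits(ds, 0.6, seed = 1), "validation_fraction")
})

test_that("ranking_score averages weights over exactly the subsets containing the gene", {
  subsets <- list(c("a", "b"), c("a", "c"), c("b", "c"))
  weights <- list(c(a = 0.5, b = 1), c(a = 0.3, c = 2), c(b = 4, c = 8))
  expect_equal(ranking_score(subsets, weights, "a"), 0.4)
  expect_equal(ranking_score(subsets, weights, "b"), 2.5)
  expect_error(ranking_score(subsets, weights, "z"), "no subset")

  # brute-force indicator-table oracle on a random instance
  set.seed(6)
  genes <- paste0("g", 1:5)
  subsets <- replicate(3, sample(genes, 3), simplify = FALSE)
  weights <- lapply(subsets, function(s) stats::setNames(runif(3), s))
  for (g in genes) {
    ind <- vapply(subsets, function(s) g %in% s, logical(1))
    if (!any(ind)) next
    num <- sum(vapply(seq_along(subsets), function(i)
      if (ind[i]) weights[[i]][[g]] else 0, numeric(1)))
    expect_lt(abs(ranking_score(subsets, weights, g) - num / sum(ind)), 1e-12)
  }
})

test_that("convergence compares relative squared norms against 0.01", {
  expect_true(converged(c(1, 2, 3), c(1, 2, 3)))          # ratio 0
  expect_false(converged(c(1, 0), c(0, 1)))               # ratio 2
  expect_true(converged(c(10, 10), c(10.1, 10.0)))        # ratio 5e-5
  expect_false(converged(c(0, 0), c(1, 1)))               # degenerate zero norm
})

test_that("rank_stage puts a strongly planted gene first and is seed-stable", {
  firsts <- vapply(1:5, function(s) {
    gen <- toy_dataset(n_genes = 20, n_per_class = 15, n_informative = 1,
                       effect = 3, seed = s)
    X <- t(standardize(gen$dataset)$values)
    set.seed(s)
    ranked <- rank_stage(X, gen$dataset$labels)
    ranked[1] == gen$informative_genes
  }, logical(1))
  expect_gte(sum(firsts), 4)

  gen <- toy_dataset(n_genes = 12, n_per_class = 8, seed = 3)
  X <- t(standardize(gen$dataset)$values)
  set.seed(42); a <- rank_stage(X, gen$dataset$labels)
  set.seed(42); b <- rank_stage(X, gen$dataset$labels)
  expect_identical(a, b)
  expect_identical(attr(a, "scores"), attr(b, "scores"))
  # scores sorted non-increasing within the stage
  expect_false(is.unsorted(rev(attr(a, "scores"))))

  # two-gene boundary: both ranked, ensemble respects m_min
  r2 <- rank_stage(X[, 1:2], gen$dataset$labels)
  expect_setequal(as.character(r2), colnames(X)[1:2])
  expect_gte(attr(r2, "ensemble_size"), 10)
})

test_that("recursive ranking halves stages down to a final three and permutes the input", {
  gen <- toy_dataset(n_genes = 8, n_per_class = 6, seed = 5)
  X <- t(standardize(gen$dataset)$values)
  set.seed(1)
  ranked <- recursive_rank(X, gen$dataset$labels)
  expect_identical(attr(ranked, "stage_sizes"), c(8L, 4L, 3L))
  expect_setequal(as.character(ranked), colnames(X))

  # k = 3 collapses to one effective ranking (initial + final-three stages)
  r3 <- recursive_rank(X[, 1:3], gen$dataset$labels)
  expect_identical(attr(r3, "stage_sizes"), c(3L, 3L))
  expect_setequal(as.character(r3), colnames(X)[1:3])

  # larger input: still a permutation
  gen <- toy_dataset(n_genes = 50, n_per_class = 10, seed = 6)
  X <- t(standardize(gen$dataset)$values)
  set.seed(2)
  ranked <- recursive_rank(X, gen$dataset$labels)
  expect_setequal(as.character(ranked), colnames(X))
  expect_identical(attr(ranked, "stage_sizes")[1:2], c(50L, 25L))
})

test_that("artificial genes preserve marginals and destroy label association", {
  gen <- toy_dataset(n_genes = 100, n_per_class = 10, n_informative = 10,
                     effect = 2, seed = 9)
  aug <- make_artificial_genes(gen$dataset, count = 100, seed = 3)
  expect_identical(dim(aug), c(200L, 20L))
  flags <- attr(aug, "probe_flags")
  expect_identical(sum(flags), 100L)

  # each probe's sorted values equal its source gene's sorted values
  src <- attr(aug, "probe_sources")
  for (p in sample(names(src), 10)) {
    expect_identical(sort(aug$values[p, ]), sort(unname(gen$dataset$values[src[p], ])),
                     ignore_attr = TRUE)
  }

  # probes' class-mean differences are stochastically smaller than the
  # informative genes' (rank-sum)
  md <- abs(rowMeans(aug$values[, aug$labels == 1]) -
            rowMeans(aug$values[, aug$labels == 0]))
  pv <- stats::wilcox.test(md[gen$informative_genes],
                           md[flags], alternative = "greater")$p.value
  expect_lt(pv, 0.01)
})

test_that("gene-indices count the probes ranked strictly above", {
  ranked <- c("p1", "gA", "p2", "p3", "gB")
  flags <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  gi <- assign_gene_indices(ranked, flags)
  expect_equal(gi[["gA"]], 1 / 3)
  expect_equal(gi[["gB"]], 1)
  gi2 <- assign_gene_indices(c("g", paste0("p", 1:10)),
                             c(FALSE, rep(TRUE, 10)))
  expect_equal(unname(gi2), 0)
  gi3 <- assign_gene_indices(c(paste0("p", 1:10), "g"),
                             c(rep(TRUE, 10), FALSE))
  expect_equal(unname(gi3), 1)
  # 10 probes, 4 above
  gi4 <- assign_gene_indices(c(paste0("p", 1:4), "g", paste0("p", 5:10)),
                             c(rep(TRUE, 4), FALSE, rep(TRUE, 6)))
  expect_equal(unname(gi4), 0.4)
  expect_error(assign_gene_indices(c("a", "b"), c(FALSE, FALSE)), "no probes")
  # monotone non-decreasing along the ranked order
  set.seed(7)
  flags <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  flags[1] <- TRUE
  gi <- assign_gene_indices(sprintf("x%02d", 1:50), flags)
  expect_false(is.unsorted(gi))
})

test_that("p* is the first candidate beating baseline, else the max-accuracy candidate", {
  expect_equal(choose_pstar(c(0.1, 0.2, 0.3), c(0.6, 0.9, 0.9), 0.8), 0.2)
  expect_equal(choose_pstar(c(0.1, 0.2, 0.3), c(0.7, 0.75, 0.75), 0.8), 0.2)
  expect_equal(choose_pstar(0.15, 0.9, 0.8), 0.15)
  expect_error(choose_pstar(numeric(0), numeric(0), 0.5), "empty")
})

test_that("select_genes completes on a noise-only dataset and is deterministic", {
  gen <- generate_dataset(synthetic_spec(
    n_genes = 60, n_informative = 0, n_samples_per_class = 10,
    effect_size = 0, seed = 14))
  sel <- select_genes(gen$dataset, seed = 3)
  expect_s3_class(sel, "amfes_selection")
  expect_identical(sel$r, 25L)             # max(5, int(500/20 + 0.5))
  expect_true(sel$p_star >= 0 && sel$p_star <= 1)
  # panel is exactly the genes at or below p* in the final ranking
  expect_setequal(sel$panel,
                  names(sel$final_gene_indices)[sel$final_gene_indices <= sel$p_star])

  sel2 <- select_genes(gen$dataset, seed = 3)
  expect_identical(sel2$panel, sel$panel)
  expect_identical(sel2$p_star, sel$p_star)
  expect_identical(sel2$avg_accuracy, sel$avg_accuracy)
})

test_that("per-stratum selection reports panels and overlap per covariate level", {
  gen <- generate_dataset(synthetic_spec(
    n_genes = 40, n_informative = 5, n_samples_per_class = 12,
    effect_size = 3, seed = 31))
  ds <- gen$dataset
  ds <- expression_dataset(ds$values, ds$labels,
                           covariates = data.frame(sex = rep(c("F", "M"), 12)))
  out <- select_by_stratum(ds, "sex", seed = 4)
  expect_named(out$selections, c("F", "M"))
  expect_identical(out$panel_sizes,
                   vapply(out$selections, function(s) length(s$panel), integer(1)))
  expect_identical(out$overlap,
                   intersect(out$selections$F$panel, out$selections$M$panel))
  expect_error(select_by_stratum(ds, "age"), "unknown covariate")
})
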