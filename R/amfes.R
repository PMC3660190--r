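#' Configuration for AMFES selection
#'
#' Bundles the tunable knobs of the ensemble ranking and subset selection.
#' Defaults: linear kernel with `cost = 1`; random subsets of
#' `max(3, ceiling(sqrt(k)))` genes at a stage of `k` genes; ensemble grown
#' from `m_min = 10` subsets one at a time until the relative change of the
#' score vector drops below `tol = 0.01` (hard cap `m_max = 500`); one probe
#' (artificial gene) per original gene; stratified 30% validation split per
#' training-validation pair.
#'
#' @param cost SVM soft-margin cost C.
#' @param subset_size Genes per random subset, or `NULL` for the
#'   `max(3, ceiling(sqrt(k)))` policy.
#' @param validation_fraction Fraction of learning samples held out per pair,
#'   in `(0, 0.5]`.
#' @param n_probes Number of artificial genes, or `NULL` for one per original
#'   gene.
#' @param m_min,m_max Minimum / maximum ensemble size per ranking stage.
#' @param tol Convergence threshold on
#'   `||theta_{m-1} - theta_m||^2 / ||theta_{m-1}||^2`.
#' @param test_fraction Fraction of samples held out entirely (testing
#'   samples) before learning begins; 0 keeps every sample as learning.
#' @return An `amfes_config` list.
#' @export
amfes_config <- function(cost = 1, subset_size = NULL,
                         validation_fraction = 0.3, n_probes = NULL,
                         m_min = 10L, m_max = 500L, tol = 0.01,
                         test_fraction = 0) {
  stopifnot(cost > 0, m_min >= 2, m_max >= m_min, tol > 0,
            test_fraction >= 0, test_fraction < 1)
  if (validation_fraction <= 0 || validation_fraction > 0.5) {
    stop("validation_fraction must be in (0, 0.5]")
  }
  if (!is.null(subset_size)) stopifnot(subset_size >= 2)
  structure(list(cost = cost, subset_size = subset_size,
                 validation_fraction = validation_fraction,
                 n_probes = n_probes, m_min = as.integer(m_min),
                 m_max = as.integer(m_max), tol = tol,
                 test_fraction = test_fraction),
            class = "amfes_config")
}

#' Number of training-validation pairs for n learning samples
#'
#' The heuristic `r = max(5, int(500 / n + 0.5))` balances validation
#' reliability against run time: small studies get many resampled pairs,
#' large ones few.
#'
#' @param n Number of learning samples (>= 2).
#' @return Integer r.
#' @export
compute_r <- function(n) {
  if (n < 2) stop("need at least 2 learning samples")
  max(5L, as.integer(500 / n + 0.5))
}

#' Plan stratified training-validation splits
#'
#' Draws `r` independent class-stratified partitions of the samples of `ds`
#' into a training part and a validation part.
#'
#' @param ds An `expression_dataset`.
#' @param validation_fraction Fraction of each class held out, in `(0, 0.5]`.
#' @param seed Integer seed.
#' @param r Number of pairs; defaults to `compute_r(n_samples)`.
#' @return List of `r` lists with integer vectors `train` and `validation`.
#' @export
plan_splits <- function(ds, validation_fraction, seed = 1L, r = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (validation_fraction <= 0 || validation_fraction > 0.5) {
    stop("validation_fraction must be in (0, 0.5]")
  }
  n_per_class <- table(factor(ds$labels, levels = c(0L, 1L)))
  if (any(n_per_class < 2L)) stop("each class needs at least 2 samples")
  if (is.null(r)) r <- compute_r(length(ds$labels))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx0 <- which(ds$labels == 0L)
  idx1 <- which(ds$labels == 1L)
  k0 <- max(1L, round(validation_fraction * length(idx0)))
  k1 <- max(1L, round(validation_fraction * length(idx1)))
  lapply(seq_len(r), function(i) {
    val <- c(sample(idx0, k0), sample(idx1, k1))
    list(train = setdiff(seq_along(ds$labels), val), validation = sort(val))
  })
}

#' Average objective-change score of a gene over an ensemble
#'
#' `theta_m(g)` is the mean of `weight_i(g)` over exactly those subsets `S_i`
#' that contain `g`:
#' `theta_m(g) = sum_i I(g in S_i) weight_i(g) / sum_i I(g in S_i)`.
#'
#' @param subsets List of character vectors (the gene subsets `S_1..S_m`).
#' @param weights List of named numeric vectors: `weights[[i]][g]` is the
#'   objective-change weight of gene `g` under the classifier trained on
#'   `S_i` (names cover exactly the genes of `S_i`).
#' @param gene Gene identifier.
#' @return The scalar ranking score.
#' @export
ranking_score <- function(subsets, weights, gene) {
  hit <- vapply(subsets, function(s) gene %in% s, logical(1))
  if (!any(hit)) stop("gene '", gene, "' appears in no subset")
  mean(vapply(which(hit), function(i) weights[[i]][[gene]], numeric(1)))
}

#' Ensemble-growth convergence test
#'
#' The ensemble has converged when the score vector stops moving:
#' `||theta_prev - theta_curr||^2 / ||theta_prev||^2 < tol`.
#' A zero-norm previous vector is degenerate and reports not-converged.
#'
#' @param theta_prev,theta_curr Equal-length numeric score vectors.
#' @param tol Relative squared-norm threshold (default 0.01).
#' @return Logical.
#' @export
converged <- function(theta_prev, theta_curr, tol = 0.01) {
  stopifnot(length(theta_prev) == length(theta_curr))
  denom <- sum(theta_prev^2)
  if (denom == 0) return(FALSE)
  sum((theta_prev - theta_curr)^2) / denom < tol
}

# Random gene subsets with guaranteed coverage: genes are dealt round-robin
# within successive random shuffles, so every cycle of ceiling(k/j) subsets
# covers every gene at least once (the final block of a cycle takes the last
# j genes of the shuffle and may overlap its predecessor).
.coverage_subsets <- function(genes, j, n_subsets) {
  k <- length(genes)
  out <- vector("list", n_subsets)
  i <- 1L
  while (i <= n_subsets) {
    ord <- sample(genes)
    starts <- seq(1L, k, by = j)
    for (s in starts) {
      if (i > n_subsets) break
      idx <- if (s + j - 1L <= k) s:(s + j - 1L) else (k - j + 1L):k
      out[[i]] <- ord[idx]
      i <- i + 1L
    }
  }
  out
}

#' Rank one stage of genes by ensemble SVM scores
#'
#' Draws random gene subsets `S_1..S_m`, trains a linear SVM on each, scores
#' every gene by the average objective-change weight over the subsets that
#' contain it, and grows `m` until [converged()] holds (between `m_min`
#' enlarged to one full coverage cycle, and `m_max`).  Ties in the final
#' descending sort are broken by input order (stable sort).
#'
#' @param X Numeric matrix, samples x stage genes (columns named).
#' @param y Binary 0/1 labels.
#' @param config An [amfes_config()].
#' @return Character vector of stage genes in descending score order, with
#'   attributes `scores` (named, same order) and `ensemble_size`.
#' @export
rank_stage <- function(X, y, config = amfes_config()) {
  X <- as.matrix(X)
  k <- ncol(X)
  stopifnot(k >= 2L)
  genes <- colnames(X)
  j <- if (is.null(config$subset_size)) max(3L, ceiling(sqrt(k))) else config$subset_size
  j <- min(j, k)
  # the ensemble grows by full coverage cycles (ceiling(k/j) subsets each):
  # one cycle is the smallest addition that updates every gene's score, so
  # testing convergence between cycles compares genuinely refreshed vectors
  cycle <- ceiling(k / j)
  m0 <- max(config$m_min, cycle)

  wsum <- stats::setNames(numeric(k), genes)
  cnt <- stats::setNames(integer(k), genes)
  add_subsets <- function(n) {
    for (s in .coverage_subsets(genes, j, n)) {
      fit <- fit_svm(X[, s, drop = FALSE], y, cost = config$cost)
      w <- .feature_weights_all(fit)
      wsum[s] <<- wsum[s] + w[s]
      cnt[s] <<- cnt[s] + 1L
    }
  }
  add_subsets(m0)
  theta <- wsum / pmax(cnt, 1L)
  m <- m0
  repeat {
    if (m >= config$m_max) break
    step <- min(cycle, config$m_max - m)
    add_subsets(step)
    m <- m + step
    theta_new <- wsum / cnt
    done <- converged(theta, theta_new, config$tol)
    theta <- theta_new
    if (done) break
  }
  ord <- order(-theta, seq_len(k))
  structure(genes[ord], scores = theta[ord], ensemble_size = m)
}

#' Recursive staged ranking
#'
#' Stage 1 ranks all `k` genes; each subsequent stage re-ranks the current
#' top `ceiling(k'/2)` while the bottom half keeps its order; once the set to
#' re-rank would have three or fewer genes, the top three are ranked once
#' more and the recursion stops.  The output is a total order over the input
#' genes.
#'
#' @inheritParams rank_stage
#' @return Character vector: all genes in final rank order, with attributes
#'   `scores` (score from each gene's deepest ranking stage; comparable
#'   within a stage segment, not across segments) and `stage_sizes`.
#' @export
recursive_rank <- function(X, y, config = amfes_config()) {
  X <- as.matrix(X)
  genes <- colnames(X)
  if (ncol(X) == 1L) {
    return(structure(genes, scores = stats::setNames(0, genes),
                     stage_sizes = 1L))
  }
  ranked <- rank_stage(X, y, config)
  scores <- attr(ranked, "scores")
  sizes <- ncol(X)
  current <- length(ranked)
  repeat {
    top <- min(3L, current)
    if (ceiling(current / 2) > 3L) top <- as.integer(ceiling(current / 2))
    if (top < 2L) break
    sub <- rank_stage(X[, ranked[seq_len(top)], drop = FALSE], y, config)
    ranked[seq_len(top)] <- sub
    scores[seq_len(top)] <- attr(sub, "scores")
    sizes <- c(sizes, top)
    if (top <= 3L) break
    current <- top
  }
  names(scores) <- ranked
  structure(as.character(ranked), scores = scores, stage_sizes = sizes)
}

#' Augment a dataset with artificial (probe) genes
#'
#' Each probe is an independent within-gene permutation of the sample values
#' of a randomly chosen original gene: marginal distributions are preserved,
#' any label association is destroyed.  Probes calibrate relevance — the
#' fraction of probes outranking a gene becomes its gene-index.
#'
#' @param ds An `expression_dataset`.
#' @param count Number of probes (>= 1); default one per original gene.
#' @param seed Integer seed.
#' @return An `expression_dataset` of `n_genes + count` rows; attribute
#'   `probe_flags` is a logical vector (TRUE = probe), attribute
#'   `probe_sources` names each probe's source gene.
#' @export
make_artificial_genes <- function(ds, count = NULL, seed = 1L) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(count)) count <- length(ds$gene_ids)
  count <- as.integer(count)
  stopifnot(count >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  M <- length(ds$sample_ids)
  src <- sample.int(length(ds$gene_ids), count, replace = TRUE)
  probes <- t(vapply(src, function(i) sample(ds$values[i, ]), numeric(M)))
  rownames(probes) <- sprintf("probe%05d", seq_len(count))
  colnames(probes) <- ds$sample_ids
  aug <- expression_dataset(rbind(ds$values, probes), ds$labels, ds$covariates)
  attr(aug, "probe_flags") <- c(rep(FALSE, length(ds$gene_ids)),
                                rep(TRUE, count))
  attr(aug, "probe_sources") <- stats::setNames(ds$gene_ids[src],
                                                rownames(probes))
  aug
}

#' Gene-indices from a ranking of originals and probes
#'
#' For each original gene, the gene-index is the proportion of probes ranked
#' strictly above it — a relevance score in `[0, 1]` where 0 means the gene
#' outranks every probe.
#'
#' @param ranked Character vector: genes in rank order (best first).
#' @param probe_flags Logical vector aligned with `ranked` (TRUE = probe).
#' @return Named numeric vector of gene-indices over the original genes, in
#'   rank order.
#' @export
assign_gene_indices <- function(ranked, probe_flags) {
  stopifnot(length(ranked) == length(probe_flags))
  n_probes <- sum(probe_flags)
  if (n_probes == 0L) stop("ranking contains no probes")
  probes_above <- cumsum(probe_flags) - probe_flags  # strictly above each slot
  idx <- probes_above[!probe_flags] / n_probes
  stats::setNames(idx, ranked[!probe_flags])
}

#' Choose the gene-index cutoff p*
#'
#' Scans candidate cutoffs in ascending order and returns the first whose
#' average validation accuracy strictly exceeds the all-genes baseline; if
#' none does, returns the candidate with maximal average accuracy (ties go
#' to the smaller cutoff).
#'
#' @param candidates Ascending numeric cutoffs `p_i`.
#' @param avg_acc Average validation accuracy `av(p_i)` per candidate.
#' @param baseline Average validation accuracy using all genes.
#' @return The chosen cutoff `p*`.
#' @export
choose_pstar <- function(candidates, avg_acc, baseline) {
  if (!length(candidates)) stop("empty candidate list")
  stopifnot(length(candidates) == length(avg_acc),
            !is.unsorted(candidates))
  hit <- which(avg_acc > baseline)
  if (length(hit)) return(candidates[hit[1L]])
  candidates[which.max(avg_acc)]
}

# Standardize columns of a samples x genes matrix using moments estimated on
# the training rows only (population convention; constant columns -> 0).
.standardize_by_train <- function(X, train_rows) {
  mu <- colMeans(X[train_rows, , drop = FALSE])
  cx <- sweep(X, 2L, mu)
  sdev <- sqrt(colMeans(cx[train_rows, , drop = FALSE]^2))
  zero <- sdev == 0
  sdev[zero] <- 1
  out <- sweep(cx, 2L, sdev, "/")
  out[, zero] <- 0
  out
}

# Validation accuracy of a linear SVM trained on `genes` (possibly empty ->
# majority-class prediction).
.pair_accuracy <- function(Xs, y, split, genes, cost) {
  yv <- y[split$validation]
  if (!length(genes)) {
    maj <- as.integer(mean(y[split$train]) >= 0.5)
    return(mean(yv == maj))
  }
  fit <- fit_svm(Xs[split$train, genes, drop = FALSE], y[split$train], cost)
  dv <- svm_decision_values(fit, Xs[split$validation, genes, drop = FALSE])
  mean(as.integer(dv > 0) == yv)
}

#' AMFES: select an optimal biomarker panel
#'
#' Full adaptive selection pipeline.  Learning samples are resampled into
#' `r = max(5, int(500/n + 0.5))` stratified training-validation pairs.  For
#' each pair the training data are augmented with artificial probe genes,
#' recursively ranked by the ensemble SVM score, and every original gene gets
#' a gene-index (fraction of probes outranking it).  Candidate cutoffs `p_i`
#' (the distinct observed gene-index values, plus 0) are evaluated in
#' ascending order by the average validation accuracy `av(p_i)` over the
#' pairs; scanning stops at the first candidate beating the all-genes
#' baseline (see [choose_pstar()]).  Finally, the full learning set is
#' re-ranked with fresh probes and the genes with gene-index `<= p*` form the
#' selected panel.  Deterministic given `seed`.
#'
#' @param ds A labeled `expression_dataset`.
#' @param config An [amfes_config()].
#' @param seed Master seed for all randomness (splits, probes, subsets).
#' @return An `amfes_selection` with fields `p_star`, `panel` (character),
#'   `candidate_values`, `avg_accuracy`, `baseline_accuracy`, `r`,
#'   `pair_seeds`, `final_ranking` (with scores/probe flags),
#'   `final_gene_indices`, `test_samples` (held-out indices, possibly empty),
#'   `seed`, `config`.
#' @export
select_genes <- function(ds, config = amfes_config(), seed = 1L) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (length(unique(ds$labels)) < 2L) stop("both classes required")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n_all <- length(ds$sample_ids)
  test_idx <- integer(0)
  if (config$test_fraction > 0) {
    i0 <- which(ds$labels == 0L); i1 <- which(ds$labels == 1L)
    test_idx <- sort(c(sample(i0, max(1L, round(config$test_fraction * length(i0)))),
                       sample(i1, max(1L, round(config$test_fraction * length(i1))))))
  }
  learn_idx <- setdiff(seq_len(n_all), test_idx)
  learn <- subset_dataset(ds, samples = learn_idx)
  n <- length(learn$sample_ids)
  r <- compute_r(n)
  split_seed <- sample.int(.Machine$integer.max, 1L)
  splits <- plan_splits(learn, config$validation_fraction, seed = split_seed, r = r)
  pair_seeds <- sample.int(.Machine$integer.max, r)
  rank_seeds <- sample.int(.Machine$integer.max, r)

  y <- learn$labels
  X <- t(learn$values)                         # samples x genes
  n_probes <- if (is.null(config$n_probes)) length(learn$gene_ids) else config$n_probes

  # Per pair: rank originals + fresh probes on the training rows, record the
  # pair's gene-index map and its candidate cutoff values.
  pair_indices <- vector("list", r)
  for (p in seq_len(r)) {
    aug <- make_artificial_genes(learn, count = n_probes, seed = pair_seeds[p])
    flags <- attr(aug, "probe_flags")
    Xa <- .standardize_by_train(t(aug$values), splits[[p]]$train)
    set.seed(rank_seeds[p])
    ranked <- recursive_rank(Xa[splits[[p]]$train, , drop = FALSE],
                             y[splits[[p]]$train], config)
    pair_indices[[p]] <- assign_gene_indices(
      ranked, flags[match(ranked, aug$gene_ids)])
  }

  # Standardized view of the original genes for accuracy evaluation.
  Xs_per_pair <- lapply(splits, function(sp) .standardize_by_train(X, sp$train))

  baseline_per_pair <- vapply(seq_len(r), function(p) {
    .pair_accuracy(Xs_per_pair[[p]], y, splits[[p]], learn$gene_ids, config$cost)
  }, numeric(1))
  baseline <- mean(baseline_per_pair)

  candidates <- sort(unique(c(0, unlist(lapply(pair_indices, function(gi)
    unique(gi))))))
  avg_acc <- rep(NA_real_, length(candidates))
  for (ci in seq_along(candidates)) {
    pc <- candidates[ci]
    acc <- vapply(seq_len(r), function(p) {
      genes <- names(pair_indices[[p]])[pair_indices[[p]] <= pc]
      .pair_accuracy(Xs_per_pair[[p]], y, splits[[p]], genes, config$cost)
    }, numeric(1))
    avg_acc[ci] <- mean(acc)
    if (avg_acc[ci] > baseline) break           # first-exceeds rule: stop early
    # perfect accuracy cannot be strictly exceeded and wins any max-av tie at
    # the smallest cutoff, so later candidates cannot change the choice
    if (avg_acc[ci] >= 1) break
  }
  evaluated <- !is.na(avg_acc)
  p_star <- choose_pstar(candidates[evaluated], avg_acc[evaluated], baseline)

  # Final ranking on all learning samples with fresh probes.
  final_seeds <- sample.int(.Machine$integer.max, 2L)
  aug <- make_artificial_genes(learn, count = n_probes, seed = final_seeds[1L])
  flags <- attr(aug, "probe_flags")
  Xa <- .standardize_by_train(t(aug$values), seq_len(n))
  set.seed(final_seeds[2L])
  ranked <- recursive_rank(Xa, y, config)
  ranked_flags <- flags[match(ranked, aug$gene_ids)]
  gene_indices <- assign_gene_indices(ranked, ranked_flags)
  panel <- names(gene_indices)[gene_indices <= p_star]

  structure(
    list(p_star = p_star,
         panel = panel,
         candidate_values = candidates[evaluated],
         avg_accuracy = avg_acc[evaluated],
         baseline_accuracy = baseline,
         r = r,
         pair_seeds = pair_seeds,
         final_ranking = structure(as.character(ranked),
                                   scores = attr(ranked, "scores"),
                                   probe_flags = ranked_flags),
         final_gene_indices = gene_indices,
         test_samples = test_idx,
         seed = seed,
         config = config),
    class = "amfes_selection")
}

#' @export
print.amfes_selection <- function(x, ...) {
  cat(sprintf("amfes_selection: %d genes at p* = %.4g (baseline acc %.3f, r = %d pairs)\n",
              length(x$panel), x$p_star, x$baseline_accuracy, x$r))
  invisible(x)
}

#' Run selection separately per covariate stratum
#'
#' Filters samples on each level of a covariate (e.g. `sex`), runs
#' [select_genes()] per stratum, and reports the panel overlap.
#'
#' @param ds A labeled `expression_dataset` with covariates.
#' @param covariate Covariate column name to stratify on.
#' @param config An [amfes_config()].
#' @param seed Master seed; each stratum gets a derived seed.
#' @return A list with `selections` (named by stratum level), `overlap`
#'   (character vector of genes shared by all strata), and `panel_sizes`.
#' @export
select_by_stratum <- function(ds, covariate, config = amfes_config(), seed = 1L) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$covariates) || !covariate %in% names(ds$covariates)) {
    stop("unknown covariate: ", covariate)
  }
  strata <- as.character(ds$covariates[[covariate]])
  levels_ <- sort(unique(strata))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stratum_seeds <- sample.int(.Machine$integer.max, length(levels_))
  selections <- stats::setNames(vector("list", length(levels_)), levels_)
  for (i in seq_along(levels_)) {
    sub <- subset_dataset(ds, samples = strata == levels_[i])
    selections[[i]] <- select_genes(sub, config, seed = stratum_seeds[i])
  }
  panels <- lapply(selections, `[[`, "panel")
  list(selections = selections,
       overlap = Reduce(intersect, panels),
       panel_sizes = vapply(panels, length, integer(1)))
}
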