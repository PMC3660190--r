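#' Specify a synthetic expression study
#'
#' Describes a two-class microarray-shaped simulation: thousands of genes,
#' tens of samples, a small planted set of label-informative genes, optional
#' correlated gene blocks driven by shared latent factors, and Gaussian noise.
#' Informative genes are disjoint from the correlated blocks by default so
#' ground truth stays unambiguous.
#'
#' @param n_genes Total number of genes.
#' @param n_informative Number of label-informative genes.
#' @param n_samples_per_class Samples per class (case and control).
#' @param effect_size Between-class mean shift for informative genes, in units
#'   of the noise standard deviation.
#' @param n_corr_blocks Number of correlated gene blocks (default 0).
#' @param block_size Genes per correlated block.
#' @param block_rho Target pairwise correlation within a block, in `[0, 1)`.
#' @param noise_sd Standard deviation of the Gaussian noise (default 1).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @param allow_overlap If `TRUE`, correlated blocks may include informative
#'   genes (class shift and block factor then superpose).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes, n_informative, n_samples_per_class,
                           effect_size = 2, n_corr_blocks = 0L,
                           block_size = 0L, block_rho = 0,
                           noise_sd = 1, seed = 1L, allow_overlap = FALSE) {
  stopifnot(n_genes >= 1, n_informative >= 0, n_samples_per_class >= 1,
            effect_size >= 0, n_corr_blocks >= 0, block_size >= 0,
            noise_sd > 0)
  if (block_rho < 0 || block_rho >= 1) stop("block_rho must be in [0, 1)")
  if (n_corr_blocks > 0 && block_size < 2) {
    stop("correlated blocks need block_size >= 2")
  }
  if (!allow_overlap &&
      n_informative + n_corr_blocks * block_size > n_genes) {
    stop("n_informative + n_corr_blocks * block_size exceeds n_genes")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_informative = as.integer(n_informative),
         n_samples_per_class = as.integer(n_samples_per_class),
         effect_size = effect_size,
         n_corr_blocks = as.integer(n_corr_blocks),
         block_size = as.integer(block_size),
         block_rho = block_rho,
         noise_sd = noise_sd,
         seed = as.integer(seed),
         allow_overlap = allow_overlap),
    class = "synthetic_spec")
}

#' Generate a labeled synthetic expression dataset
#'
#' Informative genes get class-dependent means differing by
#' `effect_size * noise_sd`; each correlated block shares a per-sample latent
#' factor, `gene = sqrt(rho) * factor + sqrt(1 - rho) * noise`, giving
#' pairwise correlation `rho` in expectation; all remaining genes are pure
#' noise.  Bit-reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `dataset` (an `expression_dataset`),
#'   `informative_genes` (character), and `block_membership` (named integer
#'   vector: block id per block gene).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n <- spec$n_samples_per_class
  M <- 2L * n
  N <- spec$n_genes
  labels <- rep(c(1L, 0L), each = n)
  gene_ids <- sprintf("g%04d", seq_len(N))
  sample_ids <- sprintf("%s%02d", ifelse(labels == 1L, "case", "ctrl"),
                        c(seq_len(n), seq_len(n)))

  values <- matrix(stats::rnorm(N * M, sd = spec$noise_sd), N, M,
                   dimnames = list(gene_ids, sample_ids))

  info_idx <- seq_len(spec$n_informative)
  if (spec$n_informative > 0) {
    shift <- spec$effect_size * spec$noise_sd / 2
    values[info_idx, labels == 1L] <- values[info_idx, labels == 1L] + shift
    values[info_idx, labels == 0L] <- values[info_idx, labels == 0L] - shift
  }

  block_membership <- integer(0)
  if (spec$n_corr_blocks > 0) {
    start <- if (spec$allow_overlap) 1L else spec$n_informative + 1L
    rho <- spec$block_rho
    for (b in seq_len(spec$n_corr_blocks)) {
      idx <- start + (b - 1L) * spec$block_size + seq_len(spec$block_size) - 1L
      factor_b <- stats::rnorm(M, sd = spec$noise_sd)
      values[idx, ] <- sqrt(rho) * matrix(factor_b, spec$block_size, M,
                                          byrow = TRUE) +
        sqrt(1 - rho) * values[idx, ]
      block_membership <- c(block_membership,
                            stats::setNames(rep.int(b, spec$block_size),
                                            gene_ids[idx]))
    }
  }

  list(dataset = expression_dataset(values, labels),
       informative_genes = gene_ids[info_idx],
       block_membership = block_membership)
}

#' Draw a correlated bivariate Gaussian sample
#'
#' Standard bivariate normal with correlation `rho`; used as a fixture whose
#' mutual information has the closed form `-0.5 * log(1 - rho^2)` nats.
#'
#' @param rho Correlation in `(-1, 1)`.
#' @param M Sample size, at least 2.
#' @param seed Integer seed.
#' @return List with numeric vectors `x` and `y` of length `M`.
#' @export
generate_bivariate_gaussian <- function(rho, M, seed = 1L) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  stopifnot(M >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z1 <- stats::rnorm(M)
  z2 <- stats::rnorm(M)
  list(x = z1, y = rho * z1 + sqrt(1 - rho^2) * z2)
}

# Save/restore the global RNG state so seeded generators are pure functions
# that do not perturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
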