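#' Gaussian-KDE mutual information between two vectors (naive path)
#'
#' Plug-in estimate of `I(X, Y)` in nats from Gaussian kernel density
#' estimates of the joint and the marginals.  The normalization constants of
#' the kernels cancel, leaving
#' \deqn{I = \frac{1}{M}\sum_w \log\frac{M \sum_u e^{-((x_w-x_u)^2+(y_w-y_u)^2)/2h^2}}
#'   {\sum_u e^{-(x_w-x_u)^2/2h^2}\;\sum_u e^{-(y_w-y_u)^2/2h^2}}.}
#' The estimate can legitimately be negative (small-sample bias); it is never
#' clamped.  This reference path recomputes every kernel term from scratch
#' and serves as the oracle for the loop-reordered [pairwise_mi()].
#'
#' @param x,y Numeric vectors of equal length `M >= 2`.  The default
#'   bandwidth assumes standardized inputs.
#' @param h Kernel bandwidth, > 0 (default 0.25).
#' @return Scalar mutual information in nats.
#' @export
kde_mi_naive <- function(x, y, h = 0.25) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  M <- length(x)
  if (M < 2L) stop("need at least 2 samples")
  if (h <= 0) stop("bandwidth h must be > 0")
  Kx <- exp(-outer(x, x, "-")^2 / (2 * h^2))
  Ky <- exp(-outer(y, y, "-")^2 / (2 * h^2))
  joint <- rowSums(Kx * Ky)
  mean(log(M * joint / (rowSums(Kx) * rowSums(Ky))))
}

#' Construct an MI matrix container
#'
#' @param values Symmetric numeric matrix with gene ids as dimnames.
#' @param h Bandwidth used.
#' @param M Sample count used.
#' @return An `mi_matrix` with fields `gene_ids`, `values`, `h`, `M`.
#' @export
mi_matrix <- function(values, h, M) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- sprintf("g%d", seq_len(nrow(values)))
  }
  if (max(abs(values - t(values))) > 1e-12) stop("MI matrix must be symmetric")
  structure(list(gene_ids = rownames(values), values = values,
                 h = h, M = as.integer(M)),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat(sprintf("mi_matrix: %d genes, h = %g, M = %d samples\n",
              length(x$gene_ids), x$h, x$M))
  invisible(x)
}

#' All pairwise KDE-MI values of a gene matrix (fast path)
#'
#' Computes the `N x N` matrix of Gaussian-KDE mutual-information estimates
#' for all gene pairs of a genes-by-samples matrix.  Each gene's `M x M`
#' kernel matrix and marginal row sums are computed once and reused for every
#' pair, and the per-sample summation is hoisted to the outer loop (the
#' loop-nest optimization), so each sample-pair kernel distance is evaluated
#' once per gene rather than once per gene pair.  Numerically identical to
#' [kde_mi_naive()] applied pair by pair; the diagonal holds the self-MI
#' `I(X, X) > 0`.
#'
#' @param values Numeric genes x samples matrix (rows named), or an
#'   `expression_dataset`.
#' @param h Kernel bandwidth (default 0.25; meant for standardized rows).
#' @return An [mi_matrix()].
#' @export
pairwise_mi <- function(values, h = 0.25) {
  if (inherits(values, "expression_dataset")) values <- values$values
  values <- as.matrix(values)
  N <- nrow(values); M <- ncol(values)
  if (N < 2L) stop("need at least 2 genes")
  if (M < 2L) stop("need at least 2 samples")
  if (h <= 0) stop("bandwidth h must be > 0")
  # K[w, u, g] = exp(-(v_gw - v_gu)^2 / 2h^2); stored as an M x M x N array.
  K <- array(0, dim = c(M, M, N))
  for (g in seq_len(N)) {
    K[, , g] <- exp(-outer(values[g, ], values[g, ], "-")^2 / (2 * h^2))
  }
  logS <- log(apply(K, 3L, colSums))           # M x N marginal log row sums
  acc <- matrix(0, N, N)
  for (w in seq_len(M)) {
    Aw <- matrix(K[w, , ], M, N)               # kernel row w across genes
    acc <- acc + log(crossprod(Aw))            # log sum_u K_x[w,u] K_y[w,u]
  }
  mi <- acc / M + log(M) - (matrix(colMeans(logS), N, N) +
                            matrix(colMeans(logS), N, N, byrow = TRUE))
  mi <- (mi + t(mi)) / 2                       # exact symmetry
  dimnames(mi) <- list(rownames(values), rownames(values))
  mi_matrix(mi, h = h, M = M)
}

#' Summary statistics of an MI matrix
#'
#' Mean, standard deviation, sign counts, and extrema over all `N^2` entries,
#' diagonal included; exact zeros land in neither the positive nor the
#' negative bucket.
#'
#' @param m An `mi_matrix`.
#' @return An `mi_summary` list with `mean`, `sd`, `n_positive`,
#'   `n_negative`, `n_zero`, `min`, `max`, `n_genes`.
#' @export
mi_summary <- function(m) {
  stopifnot(inherits(m, "mi_matrix"))
  v <- as.vector(m$values)
  structure(list(mean = mean(v), sd = stats::sd(v),
                 n_positive = sum(v > 0), n_negative = sum(v < 0),
                 n_zero = sum(v == 0), min = min(v), max = max(v),
                 n_genes = length(m$gene_ids)),
            class = "mi_summary")
}

#' @export
print.mi_summary <- function(x, ...) {
  cat(sprintf(paste0("mi_summary over %d^2 entries: mean %.4g, sd %.4g, ",
                     "%d positive / %d negative, range [%.4g, %.4g]\n"),
              x$n_genes, x$mean, x$sd, x$n_positive, x$n_negative,
              x$min, x$max))
  invisible(x)
}
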