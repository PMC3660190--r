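#' Construct an expression dataset
#'
#' Container for a genes-by-samples real-valued expression matrix with binary
#' sample labels (case = 1, control = 0) and optional per-sample covariates.
#' Values are assumed already normalized; the package treats them as given.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.  Row and
#'   column names are used as gene and sample identifiers; generated
#'   (`g1..`, `s1..`) when absent.
#' @param labels Integer/numeric vector of 0/1 per sample (case = 1).
#' @param covariates Optional data frame of per-sample covariates (one row per
#'   sample, e.g. a `sex` column).
#' @return An object of class `expression_dataset` with fields `values`
#'   (genes x samples matrix), `gene_ids`, `sample_ids`, `labels`,
#'   `covariates`.
#' @export
expression_dataset <- function(values, labels, covariates = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  }
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) {
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  }
  if (anyNA(values)) {
    stop("expression matrix contains missing values; ",
         "impute at ingestion (see read_expression_table(impute=)) or drop")
  }
  labels <- as.integer(labels)
  if (length(labels) != ncol(values)) {
    stop("length(labels) must equal the number of samples")
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 (control) or 1 (case)")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(values)) {
      stop("covariates must have one row per sample")
    }
    rownames(covariates) <- sample_ids
  }
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = labels, covariates = covariates),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d case / %d control)\n",
              length(x$gene_ids), length(x$sample_ids),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  if (!is.null(x$covariates)) {
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Subset an expression dataset by genes and/or samples
#'
#' @param ds An `expression_dataset`.
#' @param genes Gene identifiers or indices to keep (default all).
#' @param samples Sample identifiers, indices, or a logical mask (default all).
#' @return The subsetted `expression_dataset`.
#' @export
subset_dataset <- function(ds, genes = NULL, samples = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(genes)) genes <- seq_along(ds$gene_ids)
  if (is.null(samples)) samples <- seq_along(ds$sample_ids)
  if (is.character(genes)) {
    missing <- setdiff(genes, ds$gene_ids)
    if (length(missing)) {
      stop("unknown gene id(s): ", paste(utils::head(missing, 5), collapse = ", "))
    }
    genes <- match(genes, ds$gene_ids)
  }
  if (is.logical(samples)) samples <- which(samples)
  if (is.character(samples)) samples <- match(samples, ds$sample_ids)
  cov <- if (is.null(ds$covariates)) NULL else ds$covariates[samples, , drop = FALSE]
  expression_dataset(ds$values[genes, samples, drop = FALSE],
                     ds$labels[samples], cov)
}

#' Read a delimited expression table
#'
#' Ingests a tab-separated expression table (one header row, first column =
#' identifiers) plus a two-column labels table (`sample_id<TAB>label`).
#' The canonical orientation is genes in rows, samples in columns; pass
#' `orientation = "samples-in-rows"` for the transpose.
#'
#' @param path Path to the expression TSV.
#' @param labels_path Path to the labels TSV (no header required; a header
#'   line `sample_id<TAB>label` is tolerated).
#' @param orientation `"genes-in-rows"` (default) or `"samples-in-rows"`.
#' @param label_map Named vector mapping label strings to 0/1; default maps
#'   `AD` to 1 and `normal` to 0; numeric labels 0/1 pass through.
#' @param impute If `TRUE`, missing cells are replaced by the per-gene median;
#'   by default missing values are a hard error.
#' @return An `expression_dataset`.
#' @export
read_expression_table <- function(path, labels_path,
                                  orientation = c("genes-in-rows", "samples-in-rows"),
                                  label_map = c(AD = 1, normal = 0),
                                  impute = FALSE) {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(tab[, -1L, drop = FALSE], 2L, function(col) {
      suppressWarnings(all(!is.na(as.numeric(col)) | is.na(col)))
    }))
    for (jj in bad) {
      col <- tab[[jj + 1L]]
      ii <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   ii, colnames(tab)[jj + 1L], col[ii]))
    }
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate identifier(s) in first column: ", paste(dup, collapse = ", "))
  }
  if (orientation == "samples-in-rows") m <- t(m)
  if (anyNA(m)) {
    if (!impute) {
      idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at gene '%s', sample '%s' (use impute=TRUE for per-gene median imputation)",
                   rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
    }
    for (i in which(rowSums(is.na(m)) > 0L)) {
      m[i, is.na(m[i, ])] <- stats::median(m[i, ], na.rm = TRUE)
    }
  }
  lab <- read_labels(labels_path, label_map)
  missing <- setdiff(colnames(m), names(lab))
  if (length(missing)) {
    stop("samples without labels: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  expression_dataset(m, lab[colnames(m)])
}

#' Read a two-column sample label table
#'
#' @inheritParams read_expression_table
#' @return Named integer vector of 0/1 labels.
#' @export
read_labels <- function(labels_path, label_map = c(AD = 1, normal = 0)) {
  lt <- utils::read.delim(labels_path, header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(as.character(lt[1L, 1L])), "sample_id")) {
    lt <- lt[-1L, , drop = FALSE]
  }
  raw <- as.character(lt[[2L]])
  lab <- ifelse(raw %in% names(label_map), unname(label_map[raw]),
                suppressWarnings(as.numeric(raw)))
  if (anyNA(lab)) {
    stop("unmappable label value(s): ",
         paste(unique(raw[is.na(lab)]), collapse = ", "))
  }
  stats::setNames(as.integer(lab), as.character(lt[[1L]]))
}

#' Write an expression dataset to TSV
#'
#' Writes the expression matrix (genes in rows) and, optionally, a companion
#' labels TSV.  Inverse of [read_expression_table()].
#'
#' @param ds An `expression_dataset`.
#' @param path Output TSV path for the matrix.
#' @param labels_path Optional output path for the two-column labels TSV.
#' @export
write_expression_table <- function(ds, path, labels_path = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(gene_id = ds$gene_ids, ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.table(
      data.frame(sample_id = ds$sample_ids, label = ds$labels),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(path)
}

#' Standardize expression values gene-wise
#'
#' Centers every gene row to mean 0 and scales to variance 1 using the
#' population convention (denominator `M`, not `M - 1`).  Constant genes
#' cannot be scaled; their rows become all zeros and their identifiers are
#' recorded in the `constant_genes` attribute.  The operation is idempotent.
#'
#' @param x An `expression_dataset` or a numeric matrix with variables in rows.
#' @return Object of the same class with standardized rows; attribute
#'   `constant_genes` lists flagged zero-variance rows.
#' @export
standardize <- function(x) UseMethod("standardize")

#' @export
standardize.default <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  cx <- x - mu
  sdev <- sqrt(rowMeans(cx^2))
  const <- sdev == 0
  sdev[const] <- 1
  out <- cx / sdev
  out[const, ] <- 0
  attr(out, "constant_genes") <-
    if (is.null(rownames(x))) which(const) else rownames(x)[const]
  out
}

#' @export
standardize.expression_dataset <- function(x) {
  v <- standardize.default(x$values)
  out <- expression_dataset(v, x$labels, x$covariates)
  attr(out, "constant_genes") <- attr(v, "constant_genes")
  out
}

#' Read / write gene panels
#'
#' A panel file holds one gene identifier per line; lines starting with `#`
#' carry free-text provenance and are ignored on read.
#'
#' @param panel Character vector of gene ids (for writing).
#' @param path File path.
#' @param provenance Optional free-text provenance written as `#` comments.
#' @return `read_panel` returns a character vector with a `provenance`
#'   attribute.
#' @export
write_panel <- function(panel, path, provenance = NULL) {
  stopifnot(!anyDuplicated(panel))
  lines <- character(0)
  if (!is.null(provenance)) lines <- paste0("# ", provenance)
  writeLines(c(lines, as.character(panel)), path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  prov <- sub("^#\\s*", "", lines[startsWith(lines, "#")])
  genes <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s) in panel file: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  structure(genes, provenance = if (length(prov)) prov else NULL)
}

#' Read / write a mutual-information matrix as TSV
#'
#' Gene identifiers appear as both the header row and the first column.
#'
#' @param m An `mi_matrix` (for writing).
#' @param path File path.
#' @return `read_mi_matrix` returns an `mi_matrix`; bandwidth and sample
#'   count are restored from `#`-prefixed metadata lines when present.
#' @export
write_mi_matrix <- function(m, path) {
  stopifnot(inherits(m, "mi_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# h=%.17g M=%d", m$h, m$M), con)
  df <- data.frame(gene_id = m$gene_ids, m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mi_matrix
#' @export
read_mi_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  h <- NA_real_; M <- NA_integer_
  if (startsWith(first, "#")) {
    h <- as.numeric(sub(".*h=([^ ]+).*", "\\1", first))
    M <- as.integer(sub(".*M=([0-9]+).*", "\\1", first))
  }
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  v <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(v) <- as.character(tab[[1L]])
  mi_matrix(v, h = h, M = M)
}
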