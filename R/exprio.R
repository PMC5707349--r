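#' Read an expression matrix from TSV or MatrixMarket files
#'
#' TSV layout: header row of sample ids, first column gene ids, tab separated,
#' '.' decimal. MTX layout: MatrixMarket coordinate real general with 1-based
#' indices, plus companion files `<prefix>.genes.txt` and
#' `<prefix>.samples.txt` (one name per line), where `<prefix>` is the `.mtx`
#' path without its extension.
#'
#' @param path file path (`.tsv`-style table or `.mtx`).
#' @param format "tsv" or "mtx"; guessed from the extension by default.
#' @param sample_meta optional sample metadata data.frame or path to a TSV
#'   with columns `sample_id`, `time`, `stage`, `modality`.
#' @return an [expr_matrix()].
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "mtx"),
                        sample_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (is.character(sample_meta)) sample_meta <- read_sample_meta(sample_meta)
  if (format == "tsv") {
    tab <- tryCatch(
      utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
    if (ncol(tab) < 2) stop("parse error in ", path, ": expected gene id column plus samples")
    ids <- as.character(tab[[1]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) stop("duplicated gene id(s) in ", path, ": ",
                          paste(utils::head(dup, 5), collapse = ", "))
    v <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.vector(v)))) &
                     !is.na(as.vector(v)))[1]
      line <- if (length(bad)) ((bad - 1) %% nrow(v)) + 2 else NA
      stop("parse error in ", path, ": non-numeric value near line ", line)
    }
    storage.mode(v) <- "double"
    rownames(v) <- ids
  } else {
    prefix <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    gf <- paste0(prefix, ".genes.txt"); sf <- paste0(prefix, ".samples.txt")
    if (!file.exists(gf)) stop("companion gene name file not found: ", gf)
    if (!file.exists(sf)) stop("companion sample name file not found: ", sf)
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
    v <- as.matrix(m)
    storage.mode(v) <- "double"  # zero-entry files read back as pattern matrices
    rn <- readLines(gf); cn <- readLines(sf)
    if (length(rn) != nrow(v)) stop("gene name file length does not match matrix rows")
    if (length(cn) != ncol(v)) stop("sample name file length does not match matrix columns")
    dimnames(v) <- list(rn, cn)
  }
  expr_matrix(v, sample_meta)
}

#' Write an expression matrix to TSV or MatrixMarket files
#'
#' @param x an [expr_matrix()].
#' @param path output path; for "mtx" the companion name files are written
#'   next to it.
#' @param format "tsv" or "mtx".
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(gene_id = rownames(x$values), x$values,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(x$values, sparse = TRUE), "generalMatrix"), path)
    prefix <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    writeLines(rownames(x$values), paste0(prefix, ".genes.txt"))
    writeLines(colnames(x$values), paste0(prefix, ".samples.txt"))
  }
  invisible(path)
}

#' Read per-sample metadata
#'
#' @param path TSV with columns `sample_id`, `time`, `stage`, `modality`.
#' @return data.frame.
#' @export
read_sample_meta <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("sample metadata must have a `sample_id` column: ", path)
  tab
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto a common reference distribution: the
#' per-rank mean of the column-wise order statistics. Ties within a column
#' receive the mean of the reference values over the tied rank positions
#' (average-rank convention).
#'
#' @param x an [expr_matrix()] with at least 2 samples; a single-sample
#'   matrix is returned unchanged with a warning.
#' @return a quantile-normalized `expr_matrix`.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (ncol(v) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(x)
  }
  ref <- rowMeans(apply(v, 2, sort, method = "radix"))
  out <- v
  for (j in seq_len(ncol(v))) {
    ord <- order(v[, j], method = "radix")
    sorted <- v[ord, j]
    # tied values share the mean reference value over their rank positions
    assigned <- stats::ave(ref, match(sorted, unique(sorted)), FUN = mean)
    out[ord, j] <- assigned
  }
  expr_matrix(out, x$sample_meta)
}

#' Filter to expressed genes
#'
#' Keeps genes whose expression is strictly greater than `min_level` in at
#' least `min_samples` samples (the RPKM > 0.5 in >= 8 cells convention).
#'
#' @param x an [expr_matrix()].
#' @param min_level expression threshold (strict inequality).
#' @param min_samples minimum number of samples exceeding the threshold.
#' @return the filtered `expr_matrix`; errors if no gene survives.
#' @export
filter_expressed <- function(x, min_level = 0.5, min_samples = 8) {
  stopifnot(inherits(x, "expr_matrix"))
  if (min_samples > ncol(x$values))
    stop("`min_samples` (", min_samples, ") exceeds the number of samples (",
         ncol(x$values), ")")
  keep <- rowSums(x$values > min_level) >= min_samples
  if (!any(keep))
    stop("no gene passes expression > ", min_level, " in >= ", min_samples,
         " samples; consider relaxing the thresholds")
  x[keep, ]
}

#' log10(x + 1) transform
#'
#' @param x an [expr_matrix()] with non-negative values.
#' @return the transformed `expr_matrix`.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  expr_matrix(log10(x$values + 1), x$sample_meta)
}

#' Drop zero-variance genes
#'
#' Genes constant across all samples carry no correlation signal and are
#' removed before any correlation-based step; the number removed is reported.
#'
#' @param x an [expr_matrix()].
#' @return `expr_matrix` without constant genes.
#' @export
drop_zero_variance <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  keep <- matrixStats_rowVars(v) > 0
  n_drop <- sum(!keep)
  if (n_drop) message("dropping ", n_drop, " zero-variance gene(s)")
  if (!any(keep)) stop("all genes have zero variance")
  x[keep, ]
}

# row variances without an extra dependency
matrixStats_rowVars <- function(v) {
  n <- ncol(v)
  if (n < 2) return(rep(0, nrow(v)))
  mu <- rowMeans(v)
  rowSums((v - mu)^2) / (n - 1)
}

#' Preprocess per modality
#'
#' Single-cell matrices are quantile-normalized, filtered to expressed genes
#' and log10(x+1) transformed, in that order; bulk matrices skip the
#' normalization unless `normalize_bulk = TRUE`.
#'
#' @param x an [expr_matrix()].
#' @param min_level,min_samples see [filter_expressed()].
#' @param normalize_bulk also quantile-normalize bulk matrices.
#' @param log apply the log10(x+1) transform.
#' @return preprocessed `expr_matrix`.
#' @export
preprocess_matrix <- function(x, min_level = 0.5, min_samples = 8,
                              normalize_bulk = FALSE, log = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  modality <- unique(stats::na.omit(x$sample_meta$modality))
  is_sc <- length(modality) == 1 && identical(modality, "sc")
  if (is_sc || normalize_bulk) x <- quantile_normalize(x)
  x <- filter_expressed(x, min_level = min_level,
                        min_samples = min(min_samples, ncol(x$values)))
  if (log) x <- log_transform(x)
  x
}
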