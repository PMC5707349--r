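#' Expression matrix container
#'
#' A light container for a genes-by-samples non-negative expression matrix
#' (RPKM or simulated counts) together with per-sample metadata. Bulk
#' (cell-population) time courses carry a `time` column in hours or days (one
#' consistent unit across an analysis); single-cell matrices may additionally
#' carry a `true_time` column when simulated.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names. All values must be finite and >= 0.
#' @param sample_meta optional data.frame with columns among `sample_id`,
#'   `time`, `stage`, `modality` ("bulk" or "sc") and any extras. Rows are
#'   matched to columns of `values` by `sample_id` (or taken in order when
#'   the column is absent).
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   and `sample_meta`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' x <- expr_matrix(m, data.frame(sample_id = c("s1", "s2"), time = c(0, 24)))
#' dim(x)
#' @export
expr_matrix <- function(values, sample_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicated gene id(s): ", paste(utils::head(dup_g, 5), collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(utils::head(dup_s, 5), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (any(values < 0))
    stop("expression values must be non-negative")
  meta <- .norm_sample_meta(sample_meta, colnames(values))
  structure(list(values = values, sample_meta = meta), class = "expr_matrix")
}

.norm_sample_meta <- function(sample_meta, sample_ids) {
  n <- length(sample_ids)
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = sample_ids)
  }
  if (!is.data.frame(sample_meta)) stop("`sample_meta` must be a data.frame")
  if (!"sample_id" %in% names(sample_meta)) {
    if (nrow(sample_meta) != n)
      stop("`sample_meta` rows do not match the number of samples")
    sample_meta$sample_id <- sample_ids
  }
  idx <- match(sample_ids, sample_meta$sample_id)
  if (anyNA(idx))
    stop("`sample_meta` is missing sample(s): ",
         paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "))
  sample_meta <- sample_meta[idx, , drop = FALSE]
  rownames(sample_meta) <- NULL
  for (col in c("time", "stage", "modality"))
    if (!col %in% names(sample_meta)) sample_meta[[col]] <- NA
  sample_meta
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' Subset an expression matrix
#'
#' @param x an [expr_matrix()].
#' @param i,j gene / sample indices (numeric, logical or character).
#' @param ... ignored.
#' @return an `expr_matrix` restricted to the selected genes and samples.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  keep <- match(colnames(v), x$sample_meta$sample_id)
  expr_matrix(v, x$sample_meta[keep, , drop = FALSE])
}

#' @export
print.expr_matrix <- function(x, ...) {
  mod <- unique(stats::na.omit(x$sample_meta$modality))
  cat(sprintf("<expr_matrix> %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (length(mod)) paste0(" [", paste(mod, collapse = "/"), "]") else ""))
  has_time <- sum(!is.na(x$sample_meta$time))
  if (has_time) cat(sprintf("  collection time available for %d sample(s)\n", has_time))
  invisible(x)
}

#' Collection times of the samples
#'
#' @param x an [expr_matrix()].
#' @param require logical; error when any time is missing.
#' @return numeric vector of per-sample collection times.
#' @export
sample_times <- function(x, require = TRUE) {
  tt <- suppressWarnings(as.numeric(x$sample_meta$time))
  if (require && anyNA(tt))
    stop("collection time missing for sample(s): ",
         paste(utils::head(x$sample_meta$sample_id[is.na(tt)], 5), collapse = ", "))
  tt
}
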