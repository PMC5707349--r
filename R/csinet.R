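#' Connection specificity index (CSI) co-expression network
#'
#' For a gene set G and a sample window, computes the absolute pairwise
#' Pearson correlation matrix and from it the CSI: for a pair (A, B),
#' the fraction of third-party genes C whose correlation with both A and B
#' falls below `pcc(A, B) - margin`,
#' `CSI(A,B) = #\{C != A,B : pcc(A,C) < pcc(A,B) - margin and
#'  pcc(B,C) < pcc(A,B) - margin\} / (|G| - 2)`.
#' A high CSI marks pairs whose co-expression is specific to each other
#' rather than shared with the rest of the set. Edges are called at
#' `CSI > cutoff`.
#'
#' @param x_cp bulk [expr_matrix()].
#' @param genes gene ids (>= 3 usable after dropping genes constant in the
#'   window, which are removed with a message).
#' @param window_samples sample ids (>= 3); defaults to all samples.
#' @param margin specificity margin on the |PCC| scale (0.05).
#' @param cutoff edge threshold on the CSI scale (0.6, strict >).
#' @param stage optional per-gene stage annotation (named vector).
#' @return object of class `csi_result`: `genes`, `pcc_matrix`,
#'   `csi_matrix`, `edges` (data.frame a, b, pcc, csi), `stage`, and the
#'   `margin`/`cutoff` used.
#' @export
csi_from_expression <- function(x_cp, genes, window_samples = NULL,
                                margin = 0.05, cutoff = 0.6, stage = NULL) {
  stopifnot(inherits(x_cp, "expr_matrix"))
  if (is.null(window_samples)) window_samples <- colnames(x_cp$values)
  if (length(window_samples) < 3) stop("window needs >= 3 samples")
  genes <- intersect(genes, rownames(x_cp$values))
  v <- x_cp$values[genes, window_samples, drop = FALSE]
  con <- matrixStats_rowVars(v) == 0
  if (any(con)) {
    message("dropping ", sum(con), " gene(s) constant in the window")
    v <- v[!con, , drop = FALSE]
  }
  genes <- rownames(v)
  ng <- length(genes)
  if (ng < 3) stop("need >= 3 usable genes for CSI")
  pcc <- abs(stats::cor(t(v)))
  csi <- matrix(0, ng, ng, dimnames = dimnames(pcc))
  for (i in seq_len(ng - 1)) {
    for (j in (i + 1):ng) {
      thr <- pcc[i, j] - margin
      below <- pcc[i, ] < thr & pcc[j, ] < thr
      below[c(i, j)] <- FALSE
      csi[i, j] <- csi[j, i] <- sum(below) / (ng - 2)
    }
  }
  ut <- which(upper.tri(csi) & csi > cutoff, arr.ind = TRUE)
  edges <- data.frame(a = genes[ut[, 1]], b = genes[ut[, 2]],
                      pcc = pcc[ut], csi = csi[ut],
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, pcc_matrix = pcc, csi_matrix = csi,
                 edges = edges, stage = stage, margin = margin,
                 cutoff = cutoff), class = "csi_result")
}

#' @export
print.csi_result <- function(x, ...) {
  cat(sprintf("<csi_result> %d genes, %d edge(s) at CSI > %g (margin %g)\n",
              length(x$genes), nrow(x$edges), x$cutoff, x$margin))
  invisible(x)
}

#' Merge per-transition CSI networks
#'
#' Unions the edge lists of several CSI networks (e.g. one per stage
#' transition) into one display network. A duplicate edge keeps its maximum
#' CSI; nodes are annotated with the stage in which their pathway is active.
#'
#' @param results list of `csi_result` objects.
#' @param stage_labels named character vector, gene id -> stage.
#' @return list with `edges` (a, b, csi, pcc) and `nodes` (gene, stage).
#' @export
merge_transition_networks <- function(results, stage_labels = NULL) {
  stopifnot(length(results) >= 1)
  edges <- do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "csi_result"))
    r$edges
  }))
  if (nrow(edges)) {
    lo <- pmin(edges$a, edges$b); hi <- pmax(edges$a, edges$b)
    edges$a <- lo; edges$b <- hi
    key <- paste(edges$a, edges$b, sep = "\r")
    edges <- edges[order(key, -edges$csi), , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$a, edges$b, sep = "\r")), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- unique(c(edges$a, edges$b))
  stage <- if (is.null(stage_labels)) rep(NA_character_, length(nodes))
           else unname(stage_labels[nodes])
  list(edges = edges,
       nodes = data.frame(gene = nodes, stage = stage,
                          stringsAsFactors = FALSE))
}
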