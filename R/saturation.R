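#' Sampling-saturation analysis against a bulk reference
#'
#' Quantifies how the average expression profile of k randomly chosen single
#' cells converges to the matched bulk (cell-population) reference as k grows.
#' For each subset size k = 1..n, up to `max_combos` distinct cell subsets are
#' drawn (all combinations are enumerated when there are no more than
#' `max_combos` of them, removing Monte-Carlo noise at the extremes), the
#' subset-average profile is computed, lowly expressed genes are removed, and
#' the Pearson correlation between the log10(x+1) average and the log10(x+1)
#' reference is recorded.
#'
#' The reference is library-size rescaled to the averaged profile's total
#' before the log/correlation step, so a subset reproducing the reference's
#' exact mixing proportions scores PCC = 1 to machine precision.
#'
#' @param x_sc single-cell [expr_matrix()] (linear RPKM scale).
#' @param reference named per-gene bulk profile (linear scale), covering the
#'   gene universe of `x_sc`.
#' @param max_combos cap on the number of subsets per size (default 30).
#' @param min_level expression threshold for the filter (strict >).
#' @param min_samples cells required above `min_level` for a gene to enter
#'   the analysis universe (applied to the full single-cell matrix when it
#'   has at least `min_samples` cells).
#' @param filter_rule "union" keeps genes passing the threshold in the
#'   averaged profile or in the reference; "sc_only" uses the averaged
#'   profile alone.
#' @param seed integer seed; subset draws are reproducible.
#' @param reference_id label stored in the result (e.g. the stage or
#'   timepoint the reference represents).
#' @return an object of class `saturation_result`: list with `subset_sizes`,
#'   `pcc_samples` (list of per-size correlation vectors), `mean_pcc`,
#'   `sd_pcc`, `n_combos`, `genes_used` and `reference_id`.
#' @export
sampling_saturation <- function(x_sc, reference, max_combos = 30,
                                min_level = 0.5, min_samples = 8,
                                filter_rule = c("union", "sc_only"),
                                seed = 1, reference_id = "reference") {
  stopifnot(inherits(x_sc, "expr_matrix"))
  filter_rule <- match.arg(filter_rule)
  if (max_combos < 1) stop("`max_combos` must be >= 1")
  n <- ncol(x_sc$values)
  if (n < 1) stop("need at least one cell")
  if (is.null(names(reference))) stop("`reference` must be a named vector")
  common <- intersect(rownames(x_sc$values), names(reference))
  if (!length(common)) stop("no genes shared between cells and reference")
  v <- x_sc$values[common, , drop = FALSE]
  ref <- reference[common]
  # analysis universe: genes expressed in enough cells of the full matrix
  if (n >= min_samples) {
    keep <- rowSums(v > min_level) >= min_samples
    if (any(keep)) { v <- v[keep, , drop = FALSE]; ref <- ref[keep] }
  }

  pcc_samples <- vector("list", n)
  with_seed_local(seed, {
    for (k in seq_len(n)) {
      n_comb <- choose(n, k)
      subsets <- if (n_comb <= max_combos) {
        asplit(utils::combn(n, k), 2)
      } else {
        seen <- character(0); out <- list()
        while (length(out) < max_combos) {
          s <- sort(sample(n, k))
          key <- paste(s, collapse = ",")
          if (!key %in% seen) { seen <- c(seen, key); out[[length(out) + 1]] <- s }
        }
        out
      }
      pcc_samples[[k]] <- vapply(subsets, function(s) {
        avg <- rowMeans(v[, s, drop = FALSE])
        sel <- if (filter_rule == "union") (avg > min_level | ref > min_level)
               else avg > min_level
        if (sum(sel) < 3) return(NA_real_)
        ref_scaled <- ref[sel] * sum(avg[sel]) / sum(ref[sel])
        stats::cor(log10(avg[sel] + 1), log10(ref_scaled + 1))
      }, 0)
    }
  })
  if (all(vapply(pcc_samples, function(p) all(is.na(p)), TRUE)))
    stop("no genes survive filtering at any subset size; relax `min_level`")
  structure(list(
    reference_id = reference_id,
    subset_sizes = seq_len(n),
    pcc_samples = pcc_samples,
    mean_pcc = vapply(pcc_samples, mean, 0, na.rm = TRUE),
    sd_pcc = vapply(pcc_samples, stats::sd, 0, na.rm = TRUE),
    n_combos = lengths(pcc_samples),
    genes_used = rownames(v)), class = "saturation_result")
}

#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf("<saturation_result> reference %s, sizes 1..%d\n",
              x$reference_id, max(x$subset_sizes)))
  cat(sprintf("  mean PCC at n = %d cells: %.4f (saturation point at eps=0.01: %d)\n",
              max(x$subset_sizes), x$mean_pcc[length(x$mean_pcc)],
              saturation_point(x)))
  invisible(x)
}

#' Saturation point of a sampling-saturation curve
#'
#' Smallest subset size whose mean correlation is within `epsilon` of the
#' full-sample (plateau) correlation.
#'
#' @param result a `saturation_result` from [sampling_saturation()].
#' @param epsilon plateau tolerance on the PCC scale.
#' @return integer subset size.
#' @export
saturation_point <- function(result, epsilon = 0.01) {
  stopifnot(inherits(result, "saturation_result"))
  m <- result$mean_pcc
  if (!length(m)) stop("empty saturation result")
  plateau <- m[length(m)]
  k <- which(m >= plateau - epsilon)
  result$subset_sizes[if (length(k)) min(k) else length(m)]
}

#' Write a saturation curve as TSV
#'
#' @param result a `saturation_result`.
#' @param path output TSV path (columns k, mean_pcc, sd_pcc, n_combos).
#' @param per_draw optional path for the long-format per-draw table.
#' @return `path`, invisibly.
#' @export
write_saturation <- function(result, path, per_draw = NULL) {
  stopifnot(inherits(result, "saturation_result"))
  utils::write.table(
    data.frame(k = result$subset_sizes, mean_pcc = result$mean_pcc,
               sd_pcc = result$sd_pcc, n_combos = result$n_combos),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(per_draw)) {
    long <- do.call(rbind, lapply(result$subset_sizes, function(k)
      data.frame(k = k, draw = seq_along(result$pcc_samples[[k]]),
                 pcc = result$pcc_samples[[k]])))
    utils::write.table(long, per_draw, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
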