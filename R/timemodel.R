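#' Fit a PLS differentiation-time model on bulk data
#'
#' Fits a two-component PLS1 regression (NIPALS with X-deflation) of sample
#' collection time on bulk expression, restricted to the intersection of the
#' bulk differentially expressed genes and the single-cell expressed genes.
#' Each latent component score is a linear projection of the (centered,
#' optionally unit-variance scaled) expression profile; components are
#' sign-oriented so that every score correlates non-negatively with time.
#' An ordinary least-squares fit of time on the first two scores defines the
#' model time `T = q1*PLSC1 + q2*PLSC2 + e`.
#'
#' @param x_cp bulk [expr_matrix()] with collection times in `sample_meta$time`
#'   (use log-scale expression).
#' @param sc_expressed_genes,cp_deg_genes optional gene id vectors; when
#'   given, the model genes are their intersection with the matrix rows.
#' @param n_components number of latent components (2).
#' @param scale z-score genes to unit variance before PLS (default TRUE).
#' @return an object of class `time_model`: gene list, centering/scaling
#'   vectors, weight matrix `W`, loadings `P`, projection (rotation) matrix
#'   `R` with `scores = X %*% R`, regression coefficients `q1`, `q2`,
#'   intercept `e`, per-sample `scores`, `train_time`, `fitted_T` and
#'   `diag_pcc = cor(fitted_T, train_time)`.
#' @export
fit_pls_time <- function(x_cp, sc_expressed_genes = NULL, cp_deg_genes = NULL,
                         n_components = 2, scale = TRUE) {
  stopifnot(inherits(x_cp, "expr_matrix"))
  time <- sample_times(x_cp)
  n <- length(time)
  if (n < 3) stop("need at least 3 bulk samples with collection times")
  if (n < n_components + 1)
    stop("need more samples than components: ", n, " samples for ",
         n_components, " components")
  if (stats::sd(time) == 0) stop("collection times have zero variance")

  genes <- rownames(x_cp$values)
  if (!is.null(cp_deg_genes)) genes <- intersect(genes, cp_deg_genes)
  if (!is.null(sc_expressed_genes)) genes <- intersect(genes, sc_expressed_genes)
  if (!length(genes)) stop("empty gene intersection; no genes to fit")
  v <- x_cp$values[genes, , drop = FALSE]
  gvar <- matrixStats_rowVars(v)
  if (any(gvar == 0)) {
    message("dropping ", sum(gvar == 0), " zero-variance gene(s) before PLS")
    v <- v[gvar > 0, , drop = FALSE]
    genes <- rownames(v)
  }
  if (!length(genes)) stop("all candidate genes have zero variance")

  X <- t(v)                         # samples x genes
  center <- colMeans(X)
  scl <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2, center), 2, scl, "/")
  yc <- time - mean(time)

  A <- n_components
  W <- matrix(0, ncol(Xc), A); P <- matrix(0, ncol(Xc), A)
  S <- matrix(0, n, A)
  Xd <- Xc; yd <- yc
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) stop("degenerate component ", a,
                          ": no covariance with time remains")
    w <- w / nw
    s <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, s)) / sum(s^2)
    if (stats::cor(s, time) < 0) { w <- -w; s <- -s; p <- -p }
    W[, a] <- w; P[, a] <- p; S[, a] <- s
    Xd <- Xd - tcrossprod(s, p)
    yd <- yd - s * sum(s * yd) / sum(s^2)
  }
  R <- W %*% solve(crossprod(P, W))  # scores = Xc %*% R exactly
  rownames(W) <- rownames(P) <- rownames(R) <- genes
  colnames(W) <- colnames(P) <- colnames(R) <- colnames(S) <-
    paste0("PLSC", seq_len(A))

  fit <- stats::lm.fit(cbind(1, S[, 1:2, drop = FALSE]), time)
  coefs <- fit$coefficients
  fitted_T <- drop(cbind(1, S[, 1:2, drop = FALSE]) %*% coefs)
  structure(list(
    version = 1L,
    gene_list = genes, center = center, scale = scl, scaled = scale,
    W = W, P = P, R = R,
    q1 = unname(coefs[2]), q2 = unname(coefs[3]), e = unname(coefs[1]),
    scores = S, train_time = time,
    train_samples = colnames(x_cp$values),
    fitted_T = stats::setNames(fitted_T, colnames(x_cp$values)),
    diag_pcc = stats::cor(fitted_T, time)), class = "time_model")
}

#' @export
print.time_model <- function(x, ...) {
  cat(sprintf("<time_model> %d genes, %d components, %d training samples\n",
              length(x$gene_list), ncol(x$W), length(x$train_time)))
  cat(sprintf("  T = %.4g*PLSC1 + %.4g*PLSC2 + %.4g;  PCC(T, time) = %.4f\n",
              x$q1, x$q2, x$e, x$diag_pcc))
  invisible(x)
}

# project new profiles (genes x samples) through a fitted model
project_scores <- function(model, values) {
  miss <- setdiff(model$gene_list, rownames(values))
  if (length(miss))
    message(length(miss), " model gene(s) absent from the matrix; ",
            "imputed at the training center")
  X <- matrix(rep(model$center, each = ncol(values)),
              ncol(values), length(model$gene_list),
              dimnames = list(colnames(values), model$gene_list))
  present <- intersect(model$gene_list, rownames(values))
  X[, present] <- t(values[present, , drop = FALSE])
  Xc <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Xc %*% model$R
}

#' Predict single-cell differentiation time from a bulk-trained model
#'
#' Projects single-cell expression profiles onto the bulk PLS components,
#' evaluates the model time `raw_T = q1*PLSC1 + q2*PLSC2 + e`, then corrects
#' the bulk-to-single-cell batch offset with the linear calibration
#' `t = a*raw_T + b`. Calibration coefficients come from regressing `raw_T`
#' on the cells' collection times and inverting, so `t` is reported on the
#' real collection-time scale. Genes missing from the single-cell matrix are
#' imputed at the bulk training center (contributing zero after centering).
#'
#' @param model a [fit_pls_time()] model.
#' @param x_sc single-cell [expr_matrix()] on the same expression scale as
#'   the training data.
#' @param sc_collection_times per-cell collection times; defaults to
#'   `sample_meta$time`. If all cells share one time (or none is available)
#'   calibration is skipped with a warning (`a = 1, b = 0`).
#' @return data.frame with `cell_id`, `raw_T`, `t`, `PLSC1`, `PLSC2`;
#'   attribute `calibration` holds `a` and `b`.
#' @export
predict_sc_time <- function(model, x_sc, sc_collection_times = NULL) {
  stopifnot(inherits(model, "time_model"), inherits(x_sc, "expr_matrix"))
  S <- project_scores(model, x_sc$values)
  raw_T <- drop(model$e + S[, 1] * model$q1 + S[, 2] * model$q2)
  times <- if (is.null(sc_collection_times)) sample_times(x_sc, require = FALSE)
           else sc_collection_times
  if (all(is.na(times)) || length(unique(times[!is.na(times)])) < 2) {
    warning("no usable spread in collection times; calibration skipped (a = 1, b = 0)")
    a <- 1; b <- 0
  } else {
    ok <- !is.na(times)
    cal <- stats::lm.fit(cbind(1, times[ok]), raw_T[ok])
    a_prime <- cal$coefficients[2]; b_prime <- cal$coefficients[1]
    if (!is.finite(a_prime) || abs(a_prime) < 1e-10) {
      warning("degenerate calibration slope; falling back to a mean offset")
      a <- 1; b <- mean(times[ok]) - mean(raw_T[ok])
    } else {
      a <- 1 / a_prime; b <- -b_prime / a_prime
    }
  }
  out <- data.frame(cell_id = colnames(x_sc$values), raw_T = raw_T,
                    t = a * raw_T + b, PLSC1 = S[, 1], PLSC2 = S[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "calibration") <- c(a = unname(a), b = unname(b))
  out
}

# all permutations of 1..n as an (n! x n) matrix; n must stay small
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# |PCC| of each gene row against each permuted time column
abs_cor_perms <- function(values, perm_times) {
  suppressWarnings(abs(stats::cor(t(values), perm_times)))
}

# permutation matrix (n_samples x n_used): exhaustive when n! <= n_perm
time_permutations <- function(time_vector, n_perm, seed) {
  n <- length(time_vector)
  if (factorial(n) <= n_perm) {
    pm <- all_permutations(n)
    list(perms = apply(pm, 1, function(ix) time_vector[ix]), exhaustive = TRUE)
  } else {
    p <- with_seed_local(seed,
      vapply(seq_len(n_perm), function(i) sample(time_vector), numeric(n)))
    list(perms = p, exhaustive = FALSE)
  }
}

#' Randomization p-value for a gene-time correlation
#'
#' Two-sided permutation p-value for a Pearson correlation, obtained by
#' permuting the time vector. Uses the add-one estimator
#' `p = (1 + #(|PCC_perm| >= |observed|)) / (n_perm + 1)` for sampled
#' permutations, or the exact fraction when all `n!` permutations are
#' enumerated (`n! <= n_perm`).
#'
#' @param observed_pcc the observed correlation.
#' @param gene_values,time_vector paired numeric vectors.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
randomization_pvalue <- function(observed_pcc, gene_values, time_vector,
                                 n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  tp <- time_permutations(time_vector, n_perm, seed)
  null_abs <- drop(abs_cor_perms(matrix(gene_values, 1), tp$perms))
  hits <- sum(null_abs >= abs(observed_pcc) - 1e-12, na.rm = TRUE)
  if (tp$exhaustive) hits / ncol(tp$perms) else (1 + hits) / (n_perm + 1)
}

#' Timer-gene detection
#'
#' Correlates every gene with a (model or collection) time vector and calls
#' "timer" genes at a conjunction of an absolute-correlation cutoff and a
#' sample-randomization p-value cutoff. Conventional thresholds: bulk
#' T-genes |PCC| > 0.6 with p < 0.003; single-cell t-genes |PCC| > 0.4 with
#' p < 0.001; per-stage t1-4 sets p < 0.05.
#'
#' @param x an [expr_matrix()].
#' @param time_vector per-sample time (defaults to `sample_meta$time`).
#' @param pcc_cutoff absolute-correlation threshold (selection is
#'   `|pcc| >= pcc_cutoff`, matching a strict `>` on data with continuous
#'   correlations).
#' @param p_cutoff randomization p-value threshold (`p <= p_cutoff`).
#' @param n_perm permutations for the randomization p (exhaustive when
#'   `n! <= n_perm`).
#' @param seed integer seed (one shared permutation set across genes).
#' @param class_label label recorded for selected genes ("T-gene",
#'   "t-gene", "t1".."t4").
#' @return data.frame `gene_id`, `pcc`, `p_value`, `selected`, `class`
#'   (NA for unselected genes), `threshold_used`; constant genes are dropped
#'   with a message.
#' @export
timer_genes <- function(x, time_vector = NULL, pcc_cutoff = 0.6,
                        p_cutoff = 0.003, n_perm = 1000, seed = 1,
                        class_label = "T-gene") {
  stopifnot(inherits(x, "expr_matrix"))
  time <- if (is.null(time_vector)) sample_times(x) else time_vector
  if (length(time) != ncol(x$values))
    stop("`time_vector` length must match the number of samples")
  if (length(time) < 4) stop("need at least 4 samples")
  v <- x$values
  con <- matrixStats_rowVars(v) == 0
  if (any(con)) {
    message("dropping ", sum(con), " constant gene(s)")
    v <- v[!con, , drop = FALSE]
  }
  if (!nrow(v)) stop("all genes are constant")
  pcc <- drop(stats::cor(t(v), time))
  tp <- time_permutations(time, n_perm, seed)
  null_abs <- abs_cor_perms(v, tp$perms)     # genes x perms
  hits <- rowSums(null_abs >= abs(pcc) - 1e-12, na.rm = TRUE)
  p <- if (tp$exhaustive) hits / ncol(tp$perms) else (1 + hits) / (n_perm + 1)
  selected <- abs(pcc) >= pcc_cutoff & p <= p_cutoff
  data.frame(gene_id = rownames(v), pcc = pcc, p_value = p,
             selected = selected,
             class = ifelse(selected, class_label, NA_character_),
             threshold_used = pcc_cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

# mean silhouette width under an integer labelling; x is a coordinate
# matrix (rows = points), distances euclidean
mean_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(0)
  s <- vapply(seq_len(nrow(d)), function(i) {
    own <- which(labels == labels[i])
    if (length(own) < 2) return(0)
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ks, labels[i]),
                    function(k) mean(d[i, labels == k]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Branch detection in the (t, scPLS2) plane
#'
#' Displays cells in the plane of predicted time against the second
#' single-cell PLS score (which captures the largest expression variance not
#' already aligned with time) and looks for branching among the late-time
#' half of the cells by clustering their scPLS2 coordinate with k in
#' \{1, 2, 3\}, chosen by mean silhouette width (k = 1 when no k > 1 reaches
#' `sil_cutoff`).
#'
#' @param model a [fit_pls_time()] model (unused beyond validation; scores
#'   come from `predictions`).
#' @param predictions output of [predict_sc_time()].
#' @param x_sc the single-cell [expr_matrix()] behind `predictions`.
#' @param sil_cutoff minimum mean silhouette to accept a split. A forced
#'   k-means split of an unbranched (unimodal) cloud scores about 0.33 in
#'   this plane, so the default 0.4 sits above that noise floor; genuinely
#'   separated branches score well above it.
#' @param seed integer seed for k-means starts.
#' @return data.frame `cell_id`, `t`, `scPLS2`, `branch` (0 = early trunk
#'   cell when a split is found; 1..k = branch); with fewer than 6 cells
#'   branch detection is refused and all labels are 0.
#' @export
detect_branches <- function(model, predictions, x_sc, sil_cutoff = 0.4,
                            seed = 1) {
  stopifnot(inherits(model, "time_model"), is.data.frame(predictions))
  out <- data.frame(cell_id = predictions$cell_id, t = predictions$t,
                    scPLS2 = predictions$PLSC2, branch = 0L,
                    stringsAsFactors = FALSE)
  n <- nrow(out)
  if (n < 6) {
    warning("fewer than 6 cells; branch detection refused (labels all 0)")
    return(out)
  }
  late <- out$t >= stats::median(out$t)
  y <- out$scPLS2[late]
  # clusters are defined along scPLS2; their quality is judged by the mean
  # silhouette in the standardized (t, scPLS2) plane, so a split of an
  # unbranched point cloud (which stays contiguous along t) scores low
  coords <- scale(cbind(out$t[late], y))
  best_k <- 1L; best_sil <- -Inf; best_labels <- rep(1L, length(y))
  for (k in 2:3) {
    if (length(unique(y)) < k) next
    km <- with_seed_local(seed, stats::kmeans(y, centers = k, nstart = 10))
    sil <- mean_silhouette(coords, km$cluster)
    if (sil > best_sil) { best_sil <- sil; best_k <- k; best_labels <- km$cluster }
  }
  if (best_sil < sil_cutoff) { best_k <- 1L; best_labels <- rep(1L, length(y)) }
  if (best_k == 1L) {
    out$branch <- 1L
  } else {
    out$branch[late] <- as.integer(best_labels)
  }
  out
}

#' Compare two cell orderings
#'
#' @param t,other equal-length numeric vectors (length >= 3).
#' @return list with `spearman_rcc` (average-tie ranks), `pearson_pcc` and
#'   `flagged` (TRUE when either input is constant, correlations NA).
#' @export
compare_orderings <- function(t, other) {
  if (length(t) != length(other) || length(t) < 3)
    stop("inputs must have equal length >= 3")
  if (stats::sd(t) == 0 || stats::sd(other) == 0)
    return(list(spearman_rcc = NA_real_, pearson_pcc = NA_real_, flagged = TRUE))
  list(spearman_rcc = stats::cor(t, other, method = "spearman"),
       pearson_pcc = stats::cor(t, other),
       flagged = FALSE)
}

#' Serialize a time model to versioned JSON
#'
#' @param model a [fit_pls_time()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_time_model <- function(model, path) {
  stopifnot(inherits(model, "time_model"))
  payload <- model
  class(payload) <- NULL
  # doubles serialized as %.17g strings so deserialization is bit-identical
  fmt <- function(x) {
    out <- sprintf("%.17g", x)
    if (is.matrix(x)) list(values = out, dim = dim(x)) else out
  }
  for (f in c("center", "scale", "W", "P", "R", "q1", "q2", "e", "scores",
              "train_time", "fitted_T", "diag_pcc"))
    payload[[f]] <- fmt(payload[[f]])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized time model
#'
#' @param path JSON path written by [write_time_model()].
#' @return a `time_model`.
#' @export
read_time_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$version) || p$version != 1L)
    stop("unsupported time model version in ", path)
  for (f in c("center", "scale", "q1", "q2", "e", "train_time", "fitted_T",
              "diag_pcc"))
    p[[f]] <- as.numeric(p[[f]])
  for (m in c("W", "P", "R", "scores"))
    p[[m]] <- matrix(as.numeric(p[[m]]$values), p[[m]]$dim[1], p[[m]]$dim[2])
  rownames(p$W) <- rownames(p$P) <- rownames(p$R) <- p$gene_list
  names(p$center) <- names(p$scale) <- p$gene_list
  names(p$fitted_T) <- p$train_samples
  structure(p, class = "time_model")
}
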