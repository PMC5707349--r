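# shared fixture builders; everything is generated in code

make_em <- function(values, time = NULL, modality = NA) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  meta <- data.frame(sample_id = colnames(values))
  if (!is.null(time)) meta$time <- time
  meta$modality <- modality
  expr_matrix(values, meta)
}

# random expression matrix with exponential-ish positive values
random_em <- function(n_genes, n_samples, seed = 1, time = NULL,
                      modality = NA) {
  set.seed(seed)
  v <- matrix(rexp(n_genes * n_samples, 1 / 5), n_genes, n_samples)
  make_em(v, time = time, modality = modality)
}

# solve a flow problem with scipy's linprog (independent LP oracle)
lp_oracle_objective <- function(problem) {
  arcs <- problem$arcs
  payload <- jsonlite::toJSON(
    list(from = arcs$from, to = arcs$to, cost = arcs$cost, cap = arcs$cap,
         gamma = problem$gamma),
    auto_unbox = TRUE, digits = NA)
  script <- test_path("lp_oracle.py")
  out <- system2("python", shQuote(script), input = as.character(payload),
                 stdout = TRUE, stderr = FALSE)
  res <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_identical(res$status, 0L)
  res$objective
}

# random small weighted network + terminals for flow tests
random_flow_problem <- function(seed, n_max = 10, gamma = NULL) {
  set.seed(seed)
  repeat {
    n <- sample(4:n_max, 1)
    genes <- paste0("n", seq_len(n))
    ed <- t(utils::combn(n, 2))
    ed <- ed[runif(nrow(ed)) < 0.6, , drop = FALSE]
    if (nrow(ed) < 2) next
    we <- data.frame(a = genes[ed[, 1]], b = genes[ed[, 2]],
                     weight = runif(nrow(ed), 0.1, 1),
                     stringsAsFactors = FALSE)
    srcs <- sample(genes, 2)
    tgts <- sample(setdiff(genes, srcs), 2)
    g <- if (is.null(gamma)) runif(1, 0.5, 4) else gamma
    prob <- try(suppressWarnings(build_flow_problem(we, srcs, tgts, gamma = g)),
                silent = TRUE)
    if (!inherits(prob, "try-error")) return(prob)
  }
}

# brute-force CSI (triple loop, no vectorization): the independent oracle
csi_brute_force <- function(pcc, margin) {
  ng <- nrow(pcc)
  csi <- matrix(0, ng, ng, dimnames = dimnames(pcc))
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    if (i == j) next
    cnt <- 0
    for (k in seq_len(ng)) {
      if (k == i || k == j) next
      if (pcc[i, k] < pcc[i, j] - margin && pcc[j, k] < pcc[i, j] - margin)
        cnt <- cnt + 1
    }
    csi[i, j] <- cnt / (ng - 2)
  }
  csi
}

# exact hypergeometric upper tail from explicit binomial coefficients
hyper_tail_brute <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# permutation enumerator for brute-force oracles
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
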