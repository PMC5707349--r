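test_that("genes affine in time give an exact fit and exact recovery", {
  time <- rep(c(0, 12, 24, 36, 48, 60), each = 2)
  set.seed(51)
  slopes <- runif(40, -2, 2); inter <- runif(40, 150, 250)
  v <- t(outer(time, slopes) + rep(inter, each = length(time)))
  dimnames(v) <- list(sprintf("g%02d", 1:40), sprintf("s%02d", seq_along(time)))
  x <- make_em(v, time = time, modality = "bulk")
  m <- fit_pls_time(x)
  expect_gt(m$diag_pcc, 1 - 1e-9)
  # training samples fed through the prediction path reproduce fitted_T
  pred <- suppressWarnings(predict_sc_time(m, x, sc_collection_times = time))
  expect_equal(pred$raw_T, unname(m$fitted_T), tolerance = 1e-9)
  expect_equal(cor(pred$t, time, method = "spearman"), 1)
})

test_that("first PLS weight matches the eigen-decomposition oracle", {
  set.seed(52)
  v <- matrix(rexp(3 * 4, 1 / 5), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  time <- c(0, 10, 20, 30)
  x <- make_em(v, time = time, modality = "bulk")
  m <- fit_pls_time(x, n_components = 2, scale = TRUE)
  # oracle: dominant eigenvector of X'yy'X (X column-scaled as in the fit)
  X <- scale(t(v))
  yc <- time - mean(time)
  M <- crossprod(X, yc) %*% crossprod(yc, X)
  ev <- eigen(M)$vectors[, 1]
  ev <- ev / sqrt(sum(ev^2))
  expect_equal(abs(drop(crossprod(m$W[, 1], ev))), 1, tolerance = 1e-9)
})

test_that("components are sign-oriented and scores reproducible from R", {
  sim <- simulate_trajectory(trajectory_sim_spec(seed = 9))
  m <- suppressMessages(fit_pls_time(sim$bulk))
  expect_gte(cor(m$scores[, 1], m$train_time), 0)
  expect_gte(cor(m$scores[, 2], m$train_time), 0)
  # stored rotation reproduces the training scores exactly
  X <- t(sim$bulk$values[m$gene_list, ])
  Xc <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
  expect_equal(unname(Xc %*% m$R), unname(m$scores), tolerance = 1e-9)
})

test_that("PLS fit agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  sim <- simulate_trajectory(trajectory_sim_spec(seed = 10))
  m <- suppressMessages(fit_pls_time(sim$bulk))
  X <- t(sim$bulk$values[m$gene_list, ])
  ref <- mixOmics::pls(X, m$train_time, ncomp = 2, scale = TRUE,
                       mode = "regression")
  for (comp in 1:2) {
    r <- abs(cor(m$scores[, comp], ref$variates$X[, comp]))
    expect_gt(r, 1 - 1e-6)
  }
})

test_that("prediction is invariant to gene order and missing-gene imputation", {
  sim <- simulate_trajectory(trajectory_sim_spec(seed = 11))
  m <- suppressMessages(fit_pls_time(sim$bulk))
  p1 <- predict_sc_time(m, sim$sc)
  # permute gene order
  perm <- sample(nrow(sim$sc$values))
  x_perm <- expr_matrix(sim$sc$values[perm, ], sim$sc$sample_meta)
  p2 <- predict_sc_time(m, x_perm)
  expect_equal(p1$t, p2$t, tolerance = 1e-12)
  # dropping a model gene imputes the training center (warning-free, logged)
  keep <- setdiff(rownames(sim$sc$values), m$gene_list[1:5])
  p3 <- suppressMessages(
    predict_sc_time(m, expr_matrix(sim$sc$values[keep, ], sim$sc$sample_meta)))
  expect_equal(cor(p1$t, p3$t), 1, tolerance = 1e-3)
})

test_that("calibration maps raw model time onto the collection-time scale", {
  sim <- simulate_trajectory(trajectory_sim_spec(seed = 12))
  m <- suppressMessages(fit_pls_time(sim$bulk))
  pred <- predict_sc_time(m, sim$sc)
  cal <- attr(pred, "calibration")
  expect_equal(pred$t, cal["a"] * pred$raw_T + cal["b"],
               ignore_attr = TRUE)
  # degenerate case: a single shared collection time skips calibration
  sub <- sim$sc$sample_meta$time == sim$sc$sample_meta$time[1]
  x_one <- expr_matrix(sim$sc$values[, sub], sim$sc$sample_meta[sub, ])
  expect_warning(p_one <- predict_sc_time(m, x_one), "calibration skipped")
  expect_equal(p_one$t, p_one$raw_T)
})

test_that("randomization p-values match exhaustive enumeration at n = 4", {
  set.seed(53)
  g <- rnorm(4); tv <- c(1, 2, 3, 4)
  obs <- cor(g, tv)
  p <- randomization_pvalue(obs, g, tv, n_perm = 1000, seed = 1)
  # brute force over all 24 orderings
  perms <- combinat_perms(4)
  null_abs <- apply(perms, 1, function(ix) abs(cor(g, tv[ix])))
  expect_equal(p, mean(null_abs >= abs(obs) - 1e-12))
  # sampled mode lower bound: perfect correlation cannot beat 1/(N+1)
  p_perf <- randomization_pvalue(1, tv, tv, n_perm = 999, seed = 1)
  expect_gte(p_perf, 1 / 1000)
})

test_that("timer gene calling enforces the conjunction of both thresholds", {
  set.seed(54)
  time <- rep(seq(0, 70, by = 10), each = 2)
  n <- length(time)
  v <- matrix(rnorm(300 * n), 300, n)
  v[1, ] <- time + rnorm(n, 0, 1e-3)          # near-perfect timer
  v[2, ] <- rep(5, n)                          # constant: dropped
  dimnames(v) <- list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:n))
  x <- make_em(v + 100, time = time)
  expect_message(tab <- timer_genes(x, pcc_cutoff = 0.6, p_cutoff = 0.003,
                                    n_perm = 1000, seed = 2), "constant")
  expect_false("g002" %in% tab$gene_id)
  expect_true(tab$selected[tab$gene_id == "g001"])
  expect_identical(tab$class[tab$gene_id == "g001"], "T-gene")
  # selection respects |pcc| >= cutoff AND p <= cutoff jointly
  expect_true(all(abs(tab$pcc[tab$selected]) >= 0.6))
  expect_true(all(tab$p_value[tab$selected] <= 0.003))
})

test_that("timer selection rate under an i.i.d. null tracks the p cutoff", {
  set.seed(55)
  n_genes <- 2000
  time <- rep(1:8, each = 2)
  v <- matrix(rnorm(n_genes * 16), n_genes, 16,
              dimnames = list(sprintf("g%04d", 1:n_genes),
                              sprintf("s%02d", 1:16)))
  x <- make_em(v + 10, time = time)
  alpha <- 0.05
  tab <- timer_genes(x, pcc_cutoff = 0, p_cutoff = alpha, n_perm = 500,
                     seed = 3)
  rate <- mean(tab$selected)
  expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / n_genes) + 0.01)
})

test_that("orderings comparison matches a hand-computed rank oracle", {
  expect_equal(compare_orderings(1:5, 1:5)$spearman_rcc, 1)
  expect_equal(compare_orderings(1:5, 5:1)$spearman_rcc, -1)
  a <- c(3.2, 1.5, 4.4, 2.2, 9.0)
  b <- c(10, 40, 20, 35, 15)
  got <- compare_orderings(a, b)
  # brute-force rank correlation with average ties
  rk <- function(z) rank(z, ties.method = "average")
  expect_equal(got$spearman_rcc, cor(rk(a), rk(b)))
  expect_equal(got$pearson_pcc, cor(a, b))
  expect_true(compare_orderings(rep(1, 5), 1:5)$flagged)
})

test_that("branch detection separates two planted late lineages", {
  set.seed(56)
  sim <- simulate_trajectory(trajectory_sim_spec(seed = 13))
  m <- suppressMessages(fit_pls_time(sim$bulk))
  pred <- predict_sc_time(m, sim$sc)
  # plant two lineages after the midpoint by shifting scPLS2 coordinates
  late <- pred$t >= median(pred$t)
  lineage <- integer(nrow(pred))
  lineage[late] <- rep_len(c(1L, 2L), sum(late))
  spread <- 6 * sd(pred$PLSC2)
  pred$PLSC2[lineage == 1] <- pred$PLSC2[lineage == 1] + spread
  pred$PLSC2[lineage == 2] <- pred$PLSC2[lineage == 2] - spread
  br <- detect_branches(m, pred, sim$sc)
  got <- br$branch[late]
  truth <- lineage[late]
  agree <- max(mean(got == truth), mean((3L - got) == truth))
  expect_gte(agree, 0.9)
  # a single linear trajectory yields one branch for all cells
  br1 <- detect_branches(m, predict_sc_time(m, sim$sc), sim$sc)
  expect_true(all(br1$branch == 1L))
  # too few cells: refused
  few <- pred[1:5, ]
  expect_warning(br_few <- detect_branches(m, few, sim$sc), "refused")
  expect_true(all(br_few$branch == 0L))
})

test_that("a serialized model round-trips with bit-identical predictions", {
  sim <- simulate_trajectory(trajectory_sim_spec(seed = 14))
  m <- suppressMessages(fit_pls_time(sim$bulk))
  path <- withr::local_tempfile(fileext = ".json")
  write_time_model(m, path)
  m2 <- read_time_model(path)
  p1 <- predict_sc_time(m, sim$sc)
  p2 <- predict_sc_time(m2, sim$sc)
  expect_identical(p1$t, p2$t)
  expect_identical(p1$raw_T, p2$raw_T)
})

test_that("degenerate fits are rejected with informative errors", {
  x <- random_em(10, 3, seed = 57, time = c(1, 2, 3))
  expect_error(fit_pls_time(x, n_components = 3), "components")
  x0 <- random_em(10, 4, seed = 58, time = rep(2, 4))
  expect_error(fit_pls_time(x0), "zero variance")
  x1 <- random_em(10, 4, seed = 59, time = 1:4)
  expect_error(fit_pls_time(x1, cp_deg_genes = "not_a_gene"), "intersection")
})
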