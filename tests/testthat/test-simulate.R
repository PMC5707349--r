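test_that("mixture profiles are weighted sums and expose the cell multiset", {
  v <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("g1", "g2"), c("A", "B")))
  x <- make_em(v)
  mix <- simulate_cp_from_sc(x, c("A", "B"), c(1, 2))
  expect_equal(unname(mix$profile), c(1, 2))
  expect_identical(mix$cell_slots, c("A", "B", "B"))

  # 1:2:3 over three cells implies six cell slots
  x3 <- random_em(10, 3, seed = 31)
  mix3 <- simulate_cp_from_sc(x3, colnames(x3$values), c(1, 2, 3))
  expect_length(mix3$cell_slots, 6)

  # identity: a single cell at ratio 1 is the cell itself
  m1 <- simulate_cp_from_sc(x3, colnames(x3$values)[1], 1)
  expect_equal(m1$profile, x3$values[, 1])

  # linearity: profiles add when ratios add
  pa <- simulate_cp_from_sc(x3, colnames(x3$values), c(1, 2, 3))$profile
  pb <- simulate_cp_from_sc(x3, colnames(x3$values), c(2, 1, 1))$profile
  pc <- simulate_cp_from_sc(x3, colnames(x3$values), c(3, 3, 4))$profile
  expect_equal(pa + pb, pc)

  expect_error(simulate_cp_from_sc(x3, colnames(x3$values), c(1, 0, 2)),
               "positive")
})

test_that("read downsampling conserves depth and reproduces proportions", {
  set.seed(32)
  profile <- setNames(rexp(100, 1 / 10), sprintf("g%03d", 1:100))
  ds <- downsample_reads(profile, gene_lengths_kb = 1, depth = 1e6, seed = 5)
  expect_equal(sum(ds$counts), 1e6)
  # chi-square goodness of fit against the expected read proportions
  p_exp <- profile / sum(profile)
  gof <- suppressWarnings(chisq.test(ds$counts, p = p_exp))
  expect_gt(gof$p.value, 0.01)
  # determinism
  ds2 <- downsample_reads(profile, gene_lengths_kb = 1, depth = 1e6, seed = 5)
  expect_identical(ds$counts, ds2$counts)

  # one expressed gene takes all reads
  one <- c(a = 0, b = 7, c = 0)
  expect_equal(unname(downsample_reads(one, depth = 500, seed = 1)$counts),
               c(0, 500, 0))
  expect_error(downsample_reads(c(a = 0, b = 0), depth = 10), "all zero")
})

test_that("re-derived RPKM converges to the input profile at high depth", {
  set.seed(33)
  profile <- setNames(rexp(50, 1 / 5), sprintf("g%03d", 1:50))
  ds <- downsample_reads(profile, gene_lengths_kb = 1, depth = 1e7, seed = 6)
  big <- profile >= 1
  ratio <- ds$rpkm[big] / profile[big]
  ratio <- ratio / mean(ratio)  # up to a global scale
  expect_lt(max(abs(ratio - 1)), 0.02)
})

test_that("subtype simulation plants exact proportions and DE fractions", {
  spec <- subtype_sim_spec(n_cells_total = 2000,
                           proportions = c(0.35, 0.35, 0.25, 0.05),
                           n_genes = 300, de_fraction = 0.2, seed = 3)
  sim <- simulate_subtypes(spec)
  expect_identical(sim$counts_per_subtype, c(700L, 700L, 500L, 100L))
  expect_identical(as.integer(table(sim$labels)), sim$counts_per_subtype)
  expect_identical(dim(sim$x$values), c(300L, 2000L))
  # planted DE fraction is exact by construction
  expect_length(sim$de_genes, 60)
  expect_identical(sort(unique(which(rowSums(sim$de_factors != 1) > 0))),
                   match(sim$de_genes, rownames(sim$x$values)))
  # bit-reproducible
  sim2 <- simulate_subtypes(spec)
  expect_identical(sim$x$values, sim2$x$values)

  # largest-remainder apportionment totals are exact
  expect_identical(sum(popclock:::largest_remainder(c(1, 1, 1) / 3, 20000)), 20000L)
  expect_error(subtype_sim_spec(proportions = c(0.5, 0.4)), "sum to 1")
})

test_that("null subtypes (de_fraction = 0) reject at the nominal rate", {
  spec <- subtype_sim_spec(n_cells_total = 400, proportions = c(0.5, 0.5),
                           n_genes = 400, de_fraction = 0, seed = 4)
  sim <- simulate_subtypes(spec)
  g1 <- sim$labels == 1
  pvals <- apply(sim$x$values, 1, function(r) {
    if (sd(r) == 0) return(NA)
    suppressWarnings(wilcox.test(r[g1], r[!g1])$p.value)
  })
  rate <- mean(pvals < 0.05, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 0.035)
})

test_that("expansion time course follows its composition schedule exactly", {
  spec <- expansion_sim_spec(cells_per_timepoint = 20, n_genes = 200, seed = 5)
  sim <- simulate_expansion_timecourse(spec)
  expect_equal(sim$composition[1, ], c(major = 0.5, minor = 0.5))
  expect_equal(sim$composition[5, ], c(major = 0.95, minor = 0.05))
  # geometric in the expanding proportion
  expect_equal(diff(log(sim$composition[, "major"])),
               rep(log(0.95 / 0.5) / 4, 4))
  # planted change-gene sets have the specified size exactly
  expect_identical(lengths(sim$changed_genes), rep(2L, 4))  # 1% of 200
  # no-expansion schedule stays at 50/50
  ne <- simulate_expansion_timecourse(
    expansion_sim_spec(cells_per_timepoint = 20, n_genes = 200, seed = 5,
                       final_composition = c(0.5, 0.5)))
  expect_true(all(ne$composition == 0.5))
  # matched bulk equals the composition-weighted population means: check
  # by construction at t1 where both populations are at baseline
  expect_identical(dim(sim$bulk$values), c(200L, 5L))
})

test_that("trajectory generator plants recoverable monotone timer genes", {
  sim0 <- simulate_trajectory(
    trajectory_sim_spec(noise_sd = 0, dropout_rate = 0, seed = 7))
  tt <- sim0$sc$sample_meta$true_time
  pcc <- abs(cor(t(sim0$sc$values[sim0$timer_genes, ]), tt))
  lin <- sim0$timer_shape == "linear"
  expect_equal(max(abs(pcc[lin] - 1)), 0, tolerance = 1e-12)
  expect_gt(min(pcc[!lin]), 0.98)

  # design mirrors 8 timepoints x 8 cells = 64 single cells
  expect_identical(ncol(sim0$sc$values), 64L)
  expect_identical(length(unique(sim0$sc$sample_meta$time)), 8L)

  # reproducibility
  sim0b <- simulate_trajectory(
    trajectory_sim_spec(noise_sd = 0, dropout_rate = 0, seed = 7))
  expect_identical(sim0$sc$values, sim0b$sc$values)
})

test_that("planted timer genes are recovered at noise_sd = 0.3", {
  sim <- simulate_trajectory(trajectory_sim_spec(seed = 8))  # 0.3 / 0.1
  tab <- timer_genes(sim$sc, time_vector = sim$sc$sample_meta$true_time,
                     pcc_cutoff = 0.4, p_cutoff = 0.001, n_perm = 1000,
                     seed = 1, class_label = "t-gene")
  found <- tab$gene_id[tab$selected]
  sensitivity <- mean(sim$timer_genes %in% found)
  expect_gte(sensitivity, 0.9)
})
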