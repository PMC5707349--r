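#' Simulate a bulk (cell-population) profile from single-cell mixtures
#'
#' Builds a linear-mixture bulk profile by summing single-cell RPKM vectors
#' at a given integer ratio, e.g. three cells at ratio 1:2:3 represent a
#' six-cell population.
#'
#' @param x_sc single-cell [expr_matrix()].
#' @param cell_ids cells entering the mixture, same length as `ratio`.
#' @param ratio positive integer weights.
#' @return list with `profile` (named per-gene vector, the weighted sum) and
#'   `cell_slots` (the implied cell multiset, one id per slot).
#' @export
simulate_cp_from_sc <- function(x_sc, cell_ids, ratio) {
  stopifnot(inherits(x_sc, "expr_matrix"))
  if (length(cell_ids) != length(ratio))
    stop("`cell_ids` and `ratio` must have equal length")
  if (any(ratio <= 0) || any(ratio != round(ratio)))
    stop("`ratio` entries must be positive integers")
  miss <- setdiff(cell_ids, colnames(x_sc$values))
  if (length(miss)) stop("unknown cell id(s): ", paste(miss, collapse = ", "))
  profile <- drop(x_sc$values[, cell_ids, drop = FALSE] %*% ratio)
  names(profile) <- rownames(x_sc$values)
  list(profile = profile, cell_slots = rep(cell_ids, times = ratio))
}

#' Downsample a profile to a fixed read depth
#'
#' Converts an RPKM profile to expected read masses (RPKM x gene length),
#' draws `depth` reads multinomially and re-derives RPKM from the sampled
#' counts, emulating shallow sequencing of the same library.
#'
#' @param profile non-negative per-gene RPKM vector (named).
#' @param gene_lengths_kb per-gene transcript length in kb (scalar recycled).
#' @param depth total reads to draw (>= 1), e.g. `1e5` for 0.1 M.
#' @param seed integer seed.
#' @return list with `counts` (integer reads per gene, summing to `depth`)
#'   and `rpkm` (re-derived RPKM).
#' @export
downsample_reads <- function(profile, gene_lengths_kb = 1, depth, seed = 1) {
  if (any(profile < 0)) stop("`profile` must be non-negative")
  if (all(profile == 0)) stop("`profile` is all zero; nothing to sample")
  if (depth < 1) stop("`depth` must be >= 1")
  gene_lengths_kb <- rep_len(gene_lengths_kb, length(profile))
  if (any(gene_lengths_kb <= 0)) stop("gene lengths must be positive")
  mass <- profile * gene_lengths_kb
  counts <- with_seed_local(seed, drop(stats::rmultinom(1, size = depth,
                                                        prob = mass / sum(mass))))
  rpkm <- counts / (gene_lengths_kb * depth / 1e6)
  names(counts) <- names(rpkm) <- names(profile)
  list(counts = counts, rpkm = rpkm)
}

#' Specification for the discrete-subtype simulator
#'
#' @param n_cells_total total number of cells (e.g. 20000 or 50000).
#' @param proportions per-subtype proportions summing to 1; a rare subtype is
#'   conventionally 0.05.
#' @param n_genes number of genes.
#' @param de_fraction fraction of genes carrying subtype-specific expression
#'   factors (0.20 emulates "20% of genes differ").
#' @param seed integer seed.
#' @param gamma_shape,gamma_scale gamma prior on gene mean expression.
#' @param lib_sdlog lognormal sd of per-cell library size factors.
#' @param de_meanlog,de_sdlog lognormal location/scale of the multiplicative
#'   DE factors (sign-symmetric: factor or its reciprocal with equal
#'   probability).
#' @return validated spec object.
#' @export
subtype_sim_spec <- function(n_cells_total = 20000,
                             proportions = c(0.35, 0.35, 0.25, 0.05),
                             n_genes = 2000, de_fraction = 0.20, seed = 1,
                             gamma_shape = 0.6, gamma_scale = 2,
                             lib_sdlog = 0.35, de_meanlog = 0.1, de_sdlog = 0.4) {
  if (abs(sum(proportions) - 1) > 1e-9) stop("`proportions` must sum to 1")
  if (any(proportions <= 0)) stop("all proportions must be > 0")
  if (de_fraction < 0 || de_fraction >= 1) stop("`de_fraction` must be in [0, 1)")
  structure(as.list(environment()), class = "subtype_sim_spec")
}

# largest-remainder apportionment: counts sum exactly to n
largest_remainder <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate discrete cell subtypes (gamma-Poisson hierarchy)
#'
#' Per-gene mean expression drawn from a gamma distribution, per-cell library
#' size factors lognormal, subtype identity applying multiplicative DE
#' factors to a fixed fraction of genes; counts are Poisson.
#'
#' @param spec a [subtype_sim_spec()].
#' @return list with `x` (counts [expr_matrix()]), `labels` (per-cell subtype
#'   integer), `counts_per_subtype`, and `de_genes` / `de_factors` (the
#'   planted truth).
#' @export
simulate_subtypes <- function(spec) {
  stopifnot(inherits(spec, "subtype_sim_spec"))
  n_sub <- length(spec$proportions)
  counts_per <- largest_remainder(spec$proportions, spec$n_cells_total)
  with_seed_local(spec$seed, {
    gene_mean <- stats::rgamma(spec$n_genes, shape = spec$gamma_shape,
                               scale = spec$gamma_scale)
    n_de <- round(spec$de_fraction * spec$n_genes)
    de_genes <- sort(sample(spec$n_genes, n_de))
    de_factors <- matrix(1, spec$n_genes, n_sub)
    if (n_de > 0) for (s in seq_len(n_sub)) {
      f <- stats::rlnorm(n_de, meanlog = spec$de_meanlog, sdlog = spec$de_sdlog)
      flip <- sample(c(TRUE, FALSE), n_de, replace = TRUE)
      f[flip] <- 1 / f[flip]
      de_factors[de_genes, s] <- f
    }
    labels <- rep(seq_len(n_sub), times = counts_per)
    lib <- stats::rlnorm(spec$n_cells_total, 0, spec$lib_sdlog)
    v <- matrix(0L, spec$n_genes, spec$n_cells_total)
    for (s in seq_len(n_sub)) {
      idx <- which(labels == s)
      lam <- outer(gene_mean * de_factors[, s], lib[idx])
      v[, idx] <- stats::rpois(length(lam), lam)
    }
    dimnames(v) <- list(sprintf("g%04d", seq_len(spec$n_genes)),
                        sprintf("cell%05d", seq_len(spec$n_cells_total)))
    storage.mode(v) <- "double"
    meta <- data.frame(sample_id = colnames(v), modality = "sc",
                       subtype = labels)
    list(x = expr_matrix(v, meta), labels = labels,
         counts_per_subtype = counts_per,
         de_genes = rownames(v)[de_genes], de_factors = de_factors)
  })
}

#' Specification for the expanding two-population time course
#'
#' Two subpopulations that differ in `de_fraction` of genes at the first
#' timepoint; at each later timepoint a fresh `per_timepoint_change_fraction`
#' of genes shifts persistently in both populations (the shared temporal
#' signal), while the composition moves from `initial_composition` to
#' `final_composition` on a geometric schedule in the expanding population's
#' proportion.
#'
#' @param n_timepoints number of timepoints (>= 2; 5 in the reference design).
#' @param per_timepoint_change_fraction fraction of genes acquiring a new
#'   persistent temporal shift at each timepoint after the first (0.01).
#' @param initial_composition,final_composition length-2 proportions
#'   (major, minor), each summing to 1; `c(0.5, 0.5)` to `c(0.95, 0.05)`
#'   reproduces the strong-expansion scenario.
#' @param cells_per_timepoint single cells sampled at each timepoint.
#' @param n_genes number of genes.
#' @param de_fraction fraction of genes distinguishing the two populations at
#'   baseline (0.20).
#' @param noise_sdlog lognormal cell-level noise (log-scale sd).
#' @param bulk_noise_sdlog optional lognormal technical noise on the bulk
#'   samples (log-scale sd). The default 0 treats the bulk as the
#'   composition-weighted expectation over a very large cell population,
#'   where sampling noise has averaged out.
#' @param seed integer seed.
#' @return validated spec object.
#' @export
expansion_sim_spec <- function(n_timepoints = 5,
                               per_timepoint_change_fraction = 0.01,
                               initial_composition = c(0.5, 0.5),
                               final_composition = c(0.95, 0.05),
                               cells_per_timepoint = 40, n_genes = 2000,
                               de_fraction = 0.20, noise_sdlog = 0.3,
                               bulk_noise_sdlog = 0, seed = 1) {
  if (n_timepoints < 2) stop("`n_timepoints` must be >= 2")
  for (comp in list(initial_composition, final_composition))
    if (length(comp) != 2 || abs(sum(comp) - 1) > 1e-9 || any(comp <= 0))
      stop("compositions must be length-2 positive vectors summing to 1")
  structure(as.list(environment()), class = "expansion_sim_spec")
}

#' Simulate an expanding two-population time course
#'
#' @param spec an [expansion_sim_spec()].
#' @return list with `sc` (single-cell [expr_matrix()], metadata columns
#'   `time` and `population`), `bulk` (one composition-weighted bulk sample
#'   per timepoint), `composition` (per-timepoint major/minor proportions)
#'   and `changed_genes` (per-timepoint planted temporal-shift gene sets).
#' @export
simulate_expansion_timecourse <- function(spec) {
  stopifnot(inherits(spec, "expansion_sim_spec"))
  tp <- seq_len(spec$n_timepoints)
  # geometric schedule in the expanding (major) population's proportion
  p0 <- spec$initial_composition[1]; p1 <- spec$final_composition[1]
  major <- p0 * (p1 / p0)^((tp - 1) / (spec$n_timepoints - 1))
  comp <- cbind(major = major, minor = 1 - major)

  with_seed_local(spec$seed, {
    g_ids <- sprintf("g%04d", seq_len(spec$n_genes))
    base <- stats::rlnorm(spec$n_genes, meanlog = 1, sdlog = 1)
    # population B baseline factors on the DE gene subset
    n_de <- round(spec$de_fraction * spec$n_genes)
    de_genes <- sample(spec$n_genes, n_de)
    pop_factor <- rep(1, spec$n_genes)
    f <- stats::rlnorm(n_de, meanlog = 0, sdlog = 0.8)
    flip <- sample(c(TRUE, FALSE), n_de, replace = TRUE)
    f[flip] <- 1 / f[flip]
    pop_factor[de_genes] <- f

    # persistent temporal shifts, planted in fresh gene sets at t2..tn
    n_chg <- round(spec$per_timepoint_change_fraction * spec$n_genes)
    pool <- setdiff(seq_len(spec$n_genes), integer(0))
    changed <- list()
    shift <- matrix(1, spec$n_genes, spec$n_timepoints) # cumulative factors
    for (i in tp[-1]) {
      gs <- sample(pool, n_chg)
      pool <- setdiff(pool, gs)
      s <- stats::rlnorm(n_chg, meanlog = 0, sdlog = 0.6)
      flip <- sample(c(TRUE, FALSE), n_chg, replace = TRUE)
      s[flip] <- 1 / s[flip]
      shift[, i] <- shift[, i - 1]
      shift[gs, i] <- shift[gs, i - 1] * s
      changed[[i - 1]] <- g_ids[sort(gs)]
    }
    mean_major <- function(i) base * shift[, i]
    mean_minor <- function(i) base * pop_factor * shift[, i]

    n_minor <- vapply(tp, function(i)
      largest_remainder(comp[i, c(2, 1)], spec$cells_per_timepoint)[1], 1L)
    cells <- list(); meta <- list()
    for (i in tp) {
      n_min <- n_minor[i]; n_maj <- spec$cells_per_timepoint - n_min
      mu <- cbind(matrix(mean_major(i), spec$n_genes, n_maj),
                  matrix(mean_minor(i), spec$n_genes, n_min))
      noise <- matrix(stats::rlnorm(length(mu), 0, spec$noise_sdlog),
                      nrow = spec$n_genes)
      cells[[i]] <- mu * noise
      meta[[i]] <- data.frame(
        time = i, population = rep(c("major", "minor"), c(n_maj, n_min)))
    }
    v <- do.call(cbind, cells)
    dimnames(v) <- list(g_ids, sprintf("cell%04d", seq_len(ncol(v))))
    meta <- do.call(rbind, meta)
    meta <- data.frame(sample_id = colnames(v), time = meta$time,
                       modality = "sc", population = meta$population)

    bulk <- vapply(tp, function(i)
      comp[i, 1] * mean_major(i) + comp[i, 2] * mean_minor(i),
      numeric(spec$n_genes))
    bulk <- bulk * matrix(stats::rlnorm(length(bulk), 0, spec$bulk_noise_sdlog),
                          nrow = spec$n_genes)
    dimnames(bulk) <- list(g_ids, sprintf("bulk_t%d", tp))
    bulk_meta <- data.frame(sample_id = colnames(bulk), time = tp,
                            modality = "bulk")
    list(sc = expr_matrix(v, meta),
         bulk = expr_matrix(bulk, bulk_meta),
         composition = comp, changed_genes = changed)
  })
}

#' Specification for the matched bulk/single-cell trajectory simulator
#'
#' Emulates a multi-stage differentiation time course observed in parallel by
#' bulk RNA-seq (replicated, at fixed collection times) and single cells
#' (drawing a true latent time jittered around their collection timepoint).
#' A subset of "timer" genes follows gene-specific monotone functions of time
#' (an equal mix of linear and gentle sigmoidal response curves, random
#' direction); the remaining genes are time-independent noise.
#'
#' @param timepoints strictly increasing collection times (hours); the
#'   default, 8 timepoints, mirrors an 8-stage sampling design.
#' @param bulk_replicates_per_timepoint bulk samples per timepoint.
#' @param cells_per_timepoint single cells per timepoint (8 x 8 = 64 default).
#' @param n_genes,n_timer_genes gene totals (timer genes <= total).
#' @param noise_sd Gaussian noise sd as a fraction of each timer gene's
#'   signal sd (non-timer genes receive noise at the median timer signal sd).
#' @param dropout_rate single-cell dropout probability scale; realized
#'   per-entry dropout decreases with expression magnitude.
#' @param time_jitter_sd sd of the latent-time jitter around the collection
#'   time, as a fraction of the median inter-timepoint gap.
#' @param seed integer seed.
#' @return validated spec object.
#' @export
trajectory_sim_spec <- function(timepoints = seq(0, 84, by = 12),
                                bulk_replicates_per_timepoint = 3,
                                cells_per_timepoint = 8,
                                n_genes = 2000, n_timer_genes = 300,
                                noise_sd = 0.3, dropout_rate = 0.1,
                                time_jitter_sd = 0.25, seed = 1) {
  if (any(diff(timepoints) <= 0)) stop("`timepoints` must be strictly increasing")
  if (n_timer_genes > n_genes) stop("`n_timer_genes` must be <= `n_genes`")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("`dropout_rate` must be in [0, 1)")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(as.list(environment()), class = "trajectory_sim_spec")
}

#' Simulate a matched bulk + single-cell differentiation trajectory
#'
#' @param spec a [trajectory_sim_spec()].
#' @return list with `bulk` ([expr_matrix()], collection times in metadata),
#'   `sc` ([expr_matrix()], metadata columns `time` (collection) and
#'   `true_time` (latent)), `timer_genes` (planted timer ids) and
#'   `timer_shape` ("linear"/"sigmoid" per timer gene). Values are on a
#'   log10-like non-negative scale.
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_sim_spec"))
  tps <- spec$timepoints
  u_of <- function(t) (t - min(tps)) / (max(tps) - min(tps)) # unit time
  with_seed_local(spec$seed, {
    ng <- spec$n_genes; nt <- spec$n_timer_genes
    g_ids <- sprintf("g%04d", seq_len(ng))
    timer_idx <- seq_len(nt) # planted at the head; callers see shuffled? keep ordered
    shape <- rep(c("linear", "sigmoid"), length.out = nt)
    base <- stats::runif(ng, 0.5, 2.0)
    amp <- stats::runif(nt, 0.8, 2.0) * sample(c(-1, 1), nt, replace = TRUE)
    # keep down-regulated timer signals non-negative (no zero-clipping,
    # which would bend the planted monotone curves)
    base[timer_idx] <- base[timer_idx] + pmax(0, -amp)
    center <- stats::runif(nt, 0.25, 0.75)
    # gentle sigmoid: scale 0.25 on unit time keeps curves strictly monotone
    # and close to linear over the sampled range
    signal_at <- function(t) {
      u <- u_of(t)
      s <- matrix(base, ng, length(t))
      lin <- shape == "linear"
      s[timer_idx[lin], ] <- s[timer_idx[lin], ] +
        amp[lin] %o% u
      sig <- !lin
      s[timer_idx[sig], ] <- s[timer_idx[sig], ] +
        (amp[sig] %o% rep(1, length(t))) *
        stats::plogis(outer(-center[sig], u, function(c0, uu) (uu + c0) / 0.25))
      s
    }
    # per-gene signal sd over the design, for noise scaling
    sig_grid <- signal_at(tps)
    sig_sd <- apply(sig_grid, 1, stats::sd)
    noise_scale <- rep(stats::median(sig_sd[timer_idx]), ng)
    noise_scale[timer_idx] <- sig_sd[timer_idx]
    noise_scale <- spec$noise_sd * noise_scale

    # bulk: replicates at exact collection times
    nb <- spec$bulk_replicates_per_timepoint
    bulk_t <- rep(tps, each = nb)
    bulk <- signal_at(bulk_t) +
      matrix(stats::rnorm(ng * length(bulk_t), 0, noise_scale), ng)
    bulk <- pmax(bulk, 0)
    dimnames(bulk) <- list(g_ids, sprintf("cp_t%02d_r%d",
                                          rep(seq_along(tps), each = nb),
                                          rep(seq_len(nb), length(tps))))
    bulk_meta <- data.frame(sample_id = colnames(bulk), time = bulk_t,
                            stage = rep(seq_along(tps), each = nb),
                            modality = "bulk")

    # single cells: latent time jittered around the collection time
    nc <- spec$cells_per_timepoint
    coll_t <- rep(tps, each = nc)
    gap <- stats::median(diff(tps))
    true_t <- coll_t + stats::rnorm(length(coll_t), 0, spec$time_jitter_sd * gap)
    true_t <- pmin(pmax(true_t, min(tps)), max(tps))
    sc <- signal_at(true_t) +
      matrix(stats::rnorm(ng * length(true_t), 0, noise_scale), ng)
    sc <- pmax(sc, 0)
    dimnames(sc) <- list(g_ids, sprintf("sc_t%02d_c%02d",
                                        rep(seq_along(tps), each = nc),
                                        rep(seq_len(nc), length(tps))))
    if (spec$dropout_rate > 0) {
      m <- mean(sc)
      p_drop <- spec$dropout_rate * exp(-sc / m)
      sc[matrix(stats::runif(length(sc)), nrow(sc)) < p_drop] <- 0
    }
    sc_meta <- data.frame(sample_id = colnames(sc), time = coll_t,
                          stage = rep(seq_along(tps), each = nc),
                          modality = "sc", true_time = true_t)
    list(bulk = expr_matrix(bulk, bulk_meta),
         sc = expr_matrix(sc, sc_meta),
         timer_genes = g_ids[timer_idx],
         timer_shape = stats::setNames(shape, g_ids[timer_idx]))
  })
}
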