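#' Gene-set collection
#'
#' @param sets named list of gene id vectors.
#' @param universe gene id universe; sets are intersected with it
#'   (harmonization), and sets left empty are flagged with a message.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)), length(universe) > 0)
  universe <- unique(universe)
  harmonized <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- names(harmonized)[lengths(harmonized) == 0]
  if (length(empty))
    message("empty set(s) after harmonization with the universe: ",
            paste(empty, collapse = ", "))
  structure(list(sets = harmonized, universe = universe),
            class = "gene_set_collection")
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member ids, tab
#'   separated).
#' @param universe optional universe; defaults to the union of all members.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                          vapply(parts, `[`, "", 1))
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe)
}

#' Fisher / hypergeometric enrichment of a query gene set
#'
#' One-sided (enrichment) hypergeometric tail per term, Bonferroni-corrected
#' across the terms tested in the call. The conventional decision threshold
#' is Bonferroni p < 0.05.
#'
#' @param query gene ids (must be non-empty within the universe).
#' @param collection a [gene_set_collection()].
#' @return data.frame with `term`, `k` (overlap), `K` (set size), `n`
#'   (query size), `N` (universe size), `odds_ratio`, `p_raw`,
#'   `p_bonferroni`.
#' @export
fisher_enrichment <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- intersect(unique(query), collection$universe)
  if (!length(query)) stop("empty query after harmonization with the universe")
  N <- length(collection$universe)
  n <- length(query)
  n_terms <- length(collection$sets)
  out <- lapply(names(collection$sets), function(term) {
    set <- collection$sets[[term]]
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / max((K - k) * (n - k), .Machine$double.eps)
    data.frame(term = term, k = k, K = K, n = n, N = N, odds_ratio = or,
               p_raw = p, p_bonferroni = min(1, p * n_terms),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$p_raw), ]
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
gsea_es <- function(ranked_names, scores, gene_set, weight) {
  hit <- ranked_names %in% gene_set
  if (!any(hit)) return(NA_real_)
  inc <- abs(scores)^weight * hit
  denom_hit <- sum(inc)
  if (denom_hit == 0) { inc <- as.numeric(hit); denom_hit <- sum(inc) }
  miss <- !hit
  running <- cumsum(inc / denom_hit - miss / sum(miss))
  running[which.max(abs(running))]
}

#' Gene-set enrichment analysis (weighted KS statistic)
#'
#' Walks the ranked list accumulating `|score|^weight` at gene-set hits and
#' a uniform decrement at misses; the enrichment score (ES) is the running
#' sum's maximum deviation from zero. The null is gene-set permutation:
#' random same-size sets drawn from the ranked universe. NES is the ES
#' divided by the mean absolute null ES of the same sign, and the reported
#' FDR q-value is the same-sign permutation tail probability (single-set
#' call).
#'
#' @param ranked_scores named numeric vector of per-gene scores; sorted
#'   decreasingly internally.
#' @param gene_set gene ids (must intersect the ranking).
#' @param n_perm gene-set permutations (>= 1).
#' @param seed integer seed.
#' @param weight hit-increment exponent (1 = classic weighted; 0 makes the
#'   statistic rank-only).
#' @return one-row data.frame `term`, `size`, `es`, `nes`, `p_perm`,
#'   `fdr_q`.
#' @export
gsea <- function(ranked_scores, gene_set, n_perm = 1000, seed = 1,
                 weight = 1) {
  if (is.null(names(ranked_scores))) stop("`ranked_scores` must be named")
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  ord <- order(ranked_scores, decreasing = TRUE)
  scores <- ranked_scores[ord]
  nm <- names(scores)
  in_rank <- intersect(gene_set, nm)
  if (!length(in_rank)) stop("gene set has no member in the ranking")
  es <- gsea_es(nm, scores, in_rank, weight)
  size <- length(in_rank)
  null_es <- with_seed_local(seed, vapply(seq_len(n_perm), function(i)
    gsea_es(nm, scores, sample(nm, size), weight), 0))
  same_sign <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(null_es[sign(null_es) == sign(es)]) >= abs(es))) /
    (1 + length(same_sign))
  data.frame(term = "gene_set", size = size, es = es, nes = nes,
             p_perm = p, fdr_q = p, stringsAsFactors = FALSE)
}

#' Pathway-activation calls per stage
#'
#' A pathway is called active in a stage iff (i) its member genes are
#' enriched in the stage-specific gene set (hypergeometric test, Bonferroni
#' p < `fisher_cutoff`), and (ii) its upregulated target genes are enriched
#' by GSEA against the stage's expression-ranked gene list
#' (FDR < `gsea_fdr_cutoff`). A pathway without a target set is reported
#' untestable, not inactive.
#'
#' @param stage_genes named list: stage -> stage-specific gene ids (e.g.
#'   rank-product DE at pfp < 0.05).
#' @param pathway_members [gene_set_collection()] of pathway member sets.
#' @param pathway_up_targets [gene_set_collection()] of pathway upregulated
#'   target sets (same pathway names).
#' @param stage_expression_rank named list: stage -> named score vector
#'   (e.g. stage-mean z-scored expression) to rank for GSEA.
#' @param fisher_cutoff Bonferroni threshold for the member test (0.05).
#' @param gsea_fdr_cutoff FDR threshold for the target test (0.05 by
#'   default; 0.25 is a common permissive alternative).
#' @param n_perm,seed GSEA permutation settings.
#' @return data.frame with one row per stage x pathway: enrichment
#'   statistics of both tests and `status` in
#'   \{"active", "inactive", "untestable"\}.
#' @export
pathway_activation <- function(stage_genes, pathway_members,
                               pathway_up_targets, stage_expression_rank,
                               fisher_cutoff = 0.05, gsea_fdr_cutoff = 0.05,
                               n_perm = 1000, seed = 1) {
  stopifnot(inherits(pathway_members, "gene_set_collection"),
            inherits(pathway_up_targets, "gene_set_collection"))
  rows <- list()
  for (stage in names(stage_genes)) {
    fish <- fisher_enrichment(stage_genes[[stage]], pathway_members)
    for (pw in names(pathway_members$sets)) {
      frow <- fish[fish$term == pw, ]
      targets <- pathway_up_targets$sets[[pw]]
      if (is.null(targets) || !length(targets)) {
        rows[[length(rows) + 1]] <- data.frame(
          stage = stage, pathway = pw, member_p_bonferroni = frow$p_bonferroni,
          target_es = NA_real_, target_fdr = NA_real_, status = "untestable",
          stringsAsFactors = FALSE)
        next
      }
      g <- tryCatch(gsea(stage_expression_rank[[stage]], targets,
                         n_perm = n_perm, seed = seed),
                    error = function(e) NULL)
      if (is.null(g)) {
        rows[[length(rows) + 1]] <- data.frame(
          stage = stage, pathway = pw, member_p_bonferroni = frow$p_bonferroni,
          target_es = NA_real_, target_fdr = NA_real_, status = "untestable",
          stringsAsFactors = FALSE)
        next
      }
      active <- frow$p_bonferroni < fisher_cutoff &&
        !is.na(g$es) && g$es > 0 && g$fdr_q < gsea_fdr_cutoff
      rows[[length(rows) + 1]] <- data.frame(
        stage = stage, pathway = pw, member_p_bonferroni = frow$p_bonferroni,
        target_es = g$es, target_fdr = g$fdr_q,
        status = if (active) "active" else "inactive",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Permutation test for between-set network connectivity
#'
#' Tests whether two gene sets are linked by more network edges than
#' expected for random same-size sets drawn from the network's node
#' universe. `p = (1 + #(perm >= observed)) / (n_perm + 1)`.
#'
#' @param network data.frame of undirected edges (columns `a`/`b` or
#'   `from`/`to`).
#' @param set_x,set_y gene sets (within the node universe).
#' @param n_perm number of permutations (1000 by convention).
#' @param seed integer seed.
#' @return list with `observed` (edge count between the sets), `p_value`
#'   and `null_mean`.
#' @export
permutation_interaction_test <- function(network, set_x, set_y,
                                         n_perm = 1000, seed = 1) {
  aa <- if ("from" %in% names(network)) network$from else network$a
  bb <- if ("to" %in% names(network)) network$to else network$b
  universe <- unique(c(aa, bb))
  bad <- setdiff(c(set_x, set_y), universe)
  if (length(bad)) stop("gene(s) outside the network universe: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  count_between <- function(x, y)
    sum((aa %in% x & bb %in% y) | (aa %in% y & bb %in% x))
  observed <- count_between(set_x, set_y)
  nx <- length(unique(set_x)); ny <- length(unique(set_y))
  null <- with_seed_local(seed, vapply(seq_len(n_perm), function(i)
    count_between(sample(universe, nx), sample(universe, ny)), 0))
  list(observed = observed,
       p_value = (1 + sum(null >= observed)) / (n_perm + 1),
       null_mean = mean(null))
}

#' Fold enrichment of a feature among a query set
#'
#' `(|query & feature| / |query|) / (|background & feature| / |background|)`,
#' e.g. cell-cycle genes among hub interactors versus all network genes.
#'
#' @param query,feature_set,background gene id vectors; `background` must be
#'   non-empty and contain the query.
#' @return the fold enrichment, or `NA` with a warning when the background
#'   rate is zero.
#' @export
fold_enrichment <- function(query, feature_set, background) {
  query <- unique(query); background <- unique(background)
  if (!length(background)) stop("`background` must be non-empty")
  if (length(setdiff(query, background)))
    stop("`query` must be contained in `background`")
  bg_rate <- length(intersect(background, feature_set)) / length(background)
  if (bg_rate == 0) {
    warning("background feature rate is zero; fold enrichment undefined")
    return(NA_real_)
  }
  q_rate <- length(intersect(query, feature_set)) / length(query)
  q_rate / bg_rate
}
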