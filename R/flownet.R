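#' Load a protein-interaction template network
#'
#' Reads one or more edge files and unions them into a single undirected
#' template. Two formats are auto-detected per file: SIF
#' (`a interaction b`, whitespace separated) and 2/3-column TSV
#' (`gene_a gene_b [score]`). Edges carrying a confidence score are kept only
#' when the score is strictly greater than `min_confidence` (the STRING
#' "> 600" convention); score-free edges pass unconditionally. Self-loops
#' are removed and duplicate edges merged keeping the maximum confidence.
#'
#' @param paths character vector of edge files.
#' @param min_confidence confidence floor for score-bearing edges (strict >).
#' @param ortholog_map optional 2-column data.frame (or TSV path) mapping
#'   source ids to target ids, applied before the union; edges touching an
#'   untranslatable node are dropped with a message.
#' @return data.frame of class `template_network` with columns `a`, `b`
#'   (canonically ordered), `score` (NA when absent) and `provenance`.
#' @export
load_template <- function(paths, min_confidence = 600, ortholog_map = NULL) {
  if (is.character(ortholog_map))
    ortholog_map <- utils::read.delim(ortholog_map, header = FALSE,
                                      stringsAsFactors = FALSE)
  pieces <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    tab <- utils::read.table(p, header = FALSE, stringsAsFactors = FALSE,
                             fill = TRUE, col.names = paste0("V", 1:3),
                             colClasses = "character")
    if (ncol(tab) < 2 || !nrow(tab)) stop("malformed edge file: ", p)
    third <- tab$V3[tab$V3 != "" & !is.na(tab$V3)]
    numeric_third <- length(third) && !anyNA(suppressWarnings(as.numeric(third)))
    if (length(third) && !numeric_third) {
      # SIF: middle column is the interaction type
      out <- data.frame(a = tab$V1, b = tab$V3, score = NA_real_,
                        stringsAsFactors = FALSE)
    } else {
      out <- data.frame(a = tab$V1, b = tab$V2,
                        score = if (numeric_third)
                          suppressWarnings(as.numeric(tab$V3)) else NA_real_,
                        stringsAsFactors = FALSE)
    }
    out$provenance <- basename(p)
    out
  })
  edges <- do.call(rbind, pieces)
  scored <- !is.na(edges$score)
  edges <- edges[!scored | edges$score > min_confidence, , drop = FALSE]
  if (!is.null(ortholog_map)) {
    map <- stats::setNames(as.character(ortholog_map[[2]]),
                           as.character(ortholog_map[[1]]))
    a2 <- unname(map[edges$a]); b2 <- unname(map[edges$b])
    drop <- is.na(a2) | is.na(b2)
    if (any(drop)) message("dropping ", sum(drop),
                           " edge(s) with untranslatable node(s)")
    edges <- edges[!drop, , drop = FALSE]
    edges$a <- a2[!drop]; edges$b <- b2[!drop]
  }
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  if (!nrow(edges)) stop("template union is empty")
  lo <- pmin(edges$a, edges$b); hi <- pmax(edges$a, edges$b)
  edges$a <- lo; edges$b <- hi
  key <- paste(edges$a, edges$b, sep = "\r")
  ord <- order(key, -ifelse(is.na(edges$score), -Inf, edges$score))
  edges <- edges[ord, , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$a, edges$b, sep = "\r")), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("template_network", "data.frame")
  edges
}

#' Weight template edges by co-expression over a transition window
#'
#' Sets each edge's weight to the absolute Pearson correlation of its two
#' genes' bulk expression across the samples flanking a stage transition.
#' Edges with a gene absent or constant in the window, or with zero
#' correlation, are dropped.
#'
#' @param template a [load_template()] network.
#' @param x_cp bulk [expr_matrix()].
#' @param window_samples sample ids of the transition window (>= 3).
#' @return data.frame `a`, `b`, `weight` in (0, 1].
#' @export
weight_edges <- function(template, x_cp, window_samples) {
  stopifnot(inherits(x_cp, "expr_matrix"))
  if (length(window_samples) < 3) stop("transition window needs >= 3 samples")
  miss <- setdiff(window_samples, colnames(x_cp$values))
  if (length(miss)) stop("unknown window sample(s): ", paste(miss, collapse = ", "))
  v <- x_cp$values[, window_samples, drop = FALSE]
  usable <- rownames(v)[matrixStats_rowVars(v) > 0]
  keep <- template$a %in% usable & template$b %in% usable
  if (sum(!keep)) message("dropping ", sum(!keep),
                          " edge(s) with absent/constant gene(s) in the window")
  edges <- template[keep, c("a", "b"), drop = FALSE]
  if (!nrow(edges)) stop("no template edge has both genes usable in the window")
  w <- vapply(seq_len(nrow(edges)), function(i)
    abs(stats::cor(v[edges$a[i], ], v[edges$b[i], ])), 0)
  edges$weight <- w
  edges <- edges[edges$weight > 0, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Assemble a source-to-target flow problem
#'
#' Builds the directed flow network: a super-source S feeds every source
#' gene (capacity 1, cost 0), every target gene drains into a super-sink K
#' (capacity 1, cost 0), and each undirected weighted template edge becomes
#' two antiparallel arcs with cost `-log(weight)` and unit capacity. `gamma`
#' is the reward per unit of total flow; larger gamma pulls more (and
#' costlier) paths into the solution.
#'
#' @param weighted_edges output of [weight_edges()] (columns a, b, weight
#'   in (0, 1]).
#' @param sources source gene ids (bulk-expressed, single-cell-undetected
#'   timer genes); sources also present in `targets` are removed with a
#'   warning.
#' @param targets target gene ids (single-cell timer genes of the flanking
#'   stages).
#' @param gamma flow reward (>= 0).
#' @param edge_capacity capacity of gene-gene arcs.
#' @return object of class `flow_problem`.
#' @export
build_flow_problem <- function(weighted_edges, sources, targets, gamma,
                               edge_capacity = 1) {
  if (gamma < 0) stop("`gamma` must be >= 0")
  if (any(weighted_edges$weight <= 0 | weighted_edges$weight > 1))
    stop("edge weights must lie in (0, 1]")
  overlap <- intersect(sources, targets)
  if (length(overlap)) {
    warning("removing ", length(overlap),
            " gene(s) present in both sources and targets from the sources ",
            "(sources should be single-cell-undetectable): ",
            paste(utils::head(overlap, 5), collapse = ", "))
    sources <- setdiff(sources, overlap)
  }
  nodes <- unique(c(weighted_edges$a, weighted_edges$b))
  sources <- intersect(sources, nodes)
  targets <- intersect(targets, nodes)
  if (!length(sources)) stop("no source gene is present in the network")
  if (!length(targets)) stop("no target gene is present in the network")
  cost <- -log(weighted_edges$weight)
  arcs <- rbind(
    data.frame(from = "__S__", to = sources, cost = 0, cap = 1,
               weight = NA_real_, kind = "source", stringsAsFactors = FALSE),
    data.frame(from = weighted_edges$a, to = weighted_edges$b, cost = cost,
               cap = edge_capacity, weight = weighted_edges$weight,
               kind = "edge", stringsAsFactors = FALSE),
    data.frame(from = weighted_edges$b, to = weighted_edges$a, cost = cost,
               cap = edge_capacity, weight = weighted_edges$weight,
               kind = "edge", stringsAsFactors = FALSE),
    data.frame(from = targets, to = "__K__", cost = 0, cap = 1,
               weight = NA_real_, kind = "target", stringsAsFactors = FALSE))
  structure(list(arcs = arcs, sources = sources, targets = targets,
                 gamma = gamma, nodes = c("__S__", nodes, "__K__")),
            class = "flow_problem")
}

#' Solve the minimum-cost / maximum-information flow problem
#'
#' Minimizes `sum_e f_e * (-log w_e) - gamma * (total flow out of S)` subject
#' to flow conservation and arc capacities, by successive shortest
#' augmenting paths: while the cheapest residual S-to-K path costs less than
#' `gamma`, a unit of flow is routed along it. Because the constraint matrix
#' is a network matrix this reproduces the optimum of the continuous linear
#' program.
#'
#' @param problem a [build_flow_problem()].
#' @param flow_tol positive-flow threshold for the selected subnetwork.
#' @return object of class `flow_result`: `arcs` (with per-arc `flow`),
#'   `subnetwork` (positive-flow gene-gene edges with weight and flow),
#'   `node_roles` (source/mediator/target for subnetwork nodes),
#'   `total_flow`, `objective`, `unreached_targets`.
#' @export
solve_flow <- function(problem, flow_tol = 1e-6) {
  stopifnot(inherits(problem, "flow_problem"))
  arcs <- problem$arcs
  nodes <- problem$nodes
  ni <- stats::setNames(seq_along(nodes), nodes)
  from <- ni[arcs$from]; to <- ni[arcs$to]
  cost <- arcs$cost; cap <- arcs$cap
  m <- nrow(arcs); nv <- length(nodes)
  # residual arc list: forward arcs 1..m, backward arcs m+1..2m
  r_from <- c(from, to); r_to <- c(to, from); r_cost <- c(cost, -cost)
  flow <- numeric(m)
  s_idx <- ni[["__S__"]]; k_idx <- ni[["__K__"]]
  repeat {
    r_cap <- c(cap - flow, flow)
    active <- which(r_cap > 1e-12)
    dist <- rep(Inf, nv); dist[s_idx] <- 0
    pred <- integer(nv)
    for (iter in seq_len(nv - 1)) {
      changed <- FALSE
      for (e in active) {
        nd <- dist[r_from[e]] + r_cost[e]
        if (nd < dist[r_to[e]] - 1e-12) {
          dist[r_to[e]] <- nd; pred[r_to[e]] <- e; changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (!is.finite(dist[k_idx]) || dist[k_idx] >= problem$gamma - 1e-9) break
    # trace the augmenting path, find the bottleneck, push flow
    path <- integer(0); node <- k_idx
    while (node != s_idx) { e <- pred[node]; path <- c(path, e); node <- r_from[e] }
    bottleneck <- min(r_cap[path])
    for (e in path) {
      if (e <= m) flow[e] <- flow[e] + bottleneck
      else flow[e - m] <- flow[e - m] - bottleneck
    }
  }
  arcs$flow <- flow
  total_flow <- sum(flow[arcs$kind == "source"])
  objective <- sum(flow * cost) - problem$gamma * total_flow
  sel <- arcs$kind == "edge" & arcs$flow > flow_tol
  sub <- arcs[sel, c("from", "to", "weight", "flow"), drop = FALSE]
  rownames(sub) <- NULL
  sub_nodes <- unique(c(sub$from, sub$to))
  roles <- ifelse(sub_nodes %in% problem$sources, "source",
                  ifelse(sub_nodes %in% problem$targets, "target", "mediator"))
  reached <- arcs$to == "__K__" & arcs$flow > flow_tol
  unreached <- setdiff(problem$targets, arcs$from[reached])
  if (length(unreached))
    warning("no flow reached ", length(unreached), " target(s): ",
            paste(utils::head(unreached, 5), collapse = ", "))
  structure(list(arcs = arcs, subnetwork = sub,
                 node_roles = stats::setNames(roles, sub_nodes),
                 total_flow = total_flow, objective = objective,
                 gamma = problem$gamma, flow_tol = flow_tol,
                 unreached_targets = unreached), class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("<flow_result> gamma = %g: total flow %.4g, objective %.6g\n",
              x$gamma, x$total_flow, x$objective))
  cat(sprintf("  subnetwork: %d edge(s), %d node(s)\n",
              nrow(x$subnetwork), length(x$node_roles)))
  invisible(x)
}

#' Check flow conservation of a solved instance
#'
#' @param result a [solve_flow()] result.
#' @return maximum absolute in-minus-out residual over non-terminal nodes.
#' @export
flow_conservation_residual <- function(result) {
  arcs <- result$arcs
  nodes <- setdiff(unique(c(arcs$from, arcs$to)), c("__S__", "__K__"))
  res <- vapply(nodes, function(nd)
    sum(arcs$flow[arcs$to == nd]) - sum(arcs$flow[arcs$from == nd]), 0)
  if (!length(res)) return(0)
  max(abs(res))
}

#' Select gamma on a grid
#'
#' Solves the flow problem across a gamma grid and scores each solution.
#' The default scorer (no literature access) prefers the largest subnetwork
#' whose minimum positive-flow edge weight still exceeds `min_edge_weight`
#' (the |PCC| > 0.6 floor); an alternative scorer — e.g. one based on a
#' literature co-citation index — can be injected as a callback.
#'
#' @param problem a [build_flow_problem()]; its gamma field is overridden.
#' @param gamma_grid non-empty numeric grid.
#' @param scorer optional `function(flow_result) -> numeric`; the gamma with
#'   the highest score wins.
#' @param min_edge_weight weight floor for the default scorer.
#' @return list with `gamma`, `result` (the solution at the chosen gamma)
#'   and `table` (per-gamma edge counts, minimum weights, objectives).
#' @export
select_gamma <- function(problem, gamma_grid, scorer = NULL,
                         min_edge_weight = 0.6) {
  if (!length(gamma_grid)) stop("`gamma_grid` must be non-empty")
  solutions <- lapply(gamma_grid, function(g) {
    problem$gamma <- g
    suppressWarnings(solve_flow(problem))
  })
  n_edges <- vapply(solutions, function(s) nrow(s$subnetwork), 0L)
  min_w <- vapply(solutions, function(s)
    if (nrow(s$subnetwork)) min(s$subnetwork$weight) else NA_real_, 0)
  tab <- data.frame(gamma = gamma_grid, n_edges = n_edges, min_weight = min_w,
                    objective = vapply(solutions, `[[`, 0, "objective"))
  if (is.null(scorer)) {
    ok <- which(!is.na(min_w) & min_w > min_edge_weight & n_edges > 0)
    if (length(ok)) {
      pick <- ok[which.max(n_edges[ok])]
    } else {
      warning("no gamma keeps all selected edge weights above ",
              min_edge_weight, "; returning the smallest-network gamma")
      pick <- which.min(ifelse(n_edges == 0, Inf, n_edges))
      if (!is.finite(n_edges[pick])) pick <- 1L
    }
  } else {
    scores <- vapply(solutions, scorer, 0)
    pick <- which.max(scores)
  }
  list(gamma = gamma_grid[pick], result = solutions[[pick]], table = tab)
}

#' Call hub nodes of a flow subnetwork
#'
#' Hubs are nodes whose degree in the positive-flow subnetwork (undirected
#' sense) is strictly greater than `min_degree`, further capped to the
#' `top_fraction` highest-degree nodes when that cap is the smaller set;
#' boundary ties are all included.
#'
#' @param result a [solve_flow()] result (or any data.frame with columns
#'   `from`/`to` or `a`/`b` describing undirected edges).
#' @param min_degree degree floor (strict >; default 4).
#' @param top_fraction fraction of highest-degree nodes retained (0.05).
#' @return character vector of hub node ids (possibly empty).
#' @export
call_hubs <- function(result, min_degree = 4, top_fraction = 0.05) {
  edges <- if (inherits(result, "flow_result")) result$subnetwork else result
  if (!nrow(edges)) stop("empty subnetwork")
  aa <- if ("from" %in% names(edges)) edges$from else edges$a
  bb <- if ("to" %in% names(edges)) edges$to else edges$b
  und <- unique(data.frame(a = pmin(aa, bb), b = pmax(aa, bb),
                           stringsAsFactors = FALSE))
  deg <- table(c(und$a, und$b))
  deg <- sort(stats::setNames(as.integer(deg), names(deg)), decreasing = TRUE)
  n_top <- ceiling(top_fraction * length(deg))
  thr <- deg[min(n_top, length(deg))]
  names(deg)[deg > min_degree & deg >= thr]
}
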