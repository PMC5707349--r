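test_that("template loading applies the confidence filter and merges edges", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "string.tsv")
  writeLines(c("A\tB\t601", "A\tC\t599", "B\tC\t700", "C\tC\t900"), f1)
  f2 <- file.path(d, "hprd.sif")
  writeLines(c("A interacts B", "C binds D"), f2)
  net <- load_template(c(f1, f2))
  # 599 excluded (strict > 600), self-loop dropped, A-B merged keeping score
  expect_setequal(paste(net$a, net$b), c("A B", "B C", "C D"))
  expect_equal(net$score[net$a == "A" & net$b == "B"], 601)

  # ortholog translation drops untranslatable nodes with a message
  map <- data.frame(from = c("A", "B", "C"), to = c("a1", "b1", "c1"))
  expect_message(net2 <- load_template(c(f1, f2), ortholog_map = map),
                 "untranslatable")
  expect_setequal(paste(net2$a, net2$b), c("a1 b1", "b1 c1"))
  expect_error(load_template(f1, min_confidence = 1e6), "empty")
})

test_that("edge weights are |PCC| over the transition window", {
  v <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 1),
             g4 = c(5, 5, 5, 5), g5 = c(1, 3, 2, 5))
  colnames(v) <- paste0("s", 1:4)
  x <- make_em(v)
  tmpl <- data.frame(a = c("g1", "g1", "g1", "g1"),
                     b = c("g2", "g3", "g4", "g5"),
                     score = NA_real_, provenance = "test")
  class(tmpl) <- c("template_network", "data.frame")
  we <- suppressMessages(weight_edges(tmpl, x, paste0("s", 1:4)))
  # identical profiles: w = 1; anti-correlated: |PCC| = 1 too
  expect_equal(we$weight[we$b == "g2"], 1)
  expect_equal(we$weight[we$b == "g3"], 1)
  # constant gene dropped
  expect_false("g4" %in% we$b)
  # hand-computed correlation
  expect_equal(we$weight[we$b == "g5"], abs(cor(v["g1", ], v["g5", ])))
  expect_error(weight_edges(tmpl, x, c("s1", "s2")), ">= 3")
})

test_that("a single unit path carries full flow with objective -gamma", {
  we <- data.frame(a = c("src", "mid"), b = c("mid", "tgt"), weight = c(1, 1))
  prob <- build_flow_problem(we, "src", "tgt", gamma = 2)
  res <- solve_flow(prob)
  expect_equal(res$total_flow, 1)
  expect_equal(res$objective, -2)
  expect_setequal(res$subnetwork$from, c("src", "mid"))
  expect_lt(flow_conservation_residual(res), 1e-9)
  expect_identical(unname(res$node_roles[c("src", "mid", "tgt")]),
                   c("source", "mediator", "target"))
})

test_that("disconnected targets get zero flow and a warning", {
  we <- data.frame(a = c("src", "x"), b = c("tgt1", "tgt2"),
                   weight = c(0.9, 0.9))
  prob <- build_flow_problem(we, "src", c("tgt1", "tgt2"), gamma = 3)
  expect_warning(res <- solve_flow(prob), "tgt2")
  expect_identical(res$unreached_targets, "tgt2")
  expect_equal(res$total_flow, 1)
})

test_that("solutions match the LP oracle on random small instances", {
  worst <- 0
  for (s in 1:20) {
    prob <- random_flow_problem(seed = 600 + s, n_max = 10)
    res <- suppressWarnings(solve_flow(prob))
    expect_lt(flow_conservation_residual(res), 1e-9)
    expect_true(all(res$arcs$flow <= res$arcs$cap + 1e-9))
    worst <- max(worst, abs(res$objective - lp_oracle_objective(prob)))
  }
  expect_lt(worst, 1e-6)
})

test_that("total flow is non-decreasing in gamma", {
  for (s in 1:10) {
    prob <- random_flow_problem(seed = 700 + s, n_max = 9)
    flows <- vapply(c(0.5, 1, 2, 4, 8), function(g) {
      prob$gamma <- g
      suppressWarnings(solve_flow(prob))$total_flow
    }, 0)
    expect_true(all(diff(flows) >= -1e-9))
  }
})

test_that("removing a zero-flow edge leaves the objective unchanged", {
  prob <- random_flow_problem(seed = 801, n_max = 9, gamma = 2)
  res <- suppressWarnings(solve_flow(prob))
  unused <- which(res$arcs$kind == "edge" & res$arcs$flow <= 1e-12)
  skip_if(length(unused) == 0, "instance has no unused edge")
  # rebuild the problem without one unused undirected edge
  e <- res$arcs[unused[1], ]
  arcs <- res$arcs
  drop <- arcs$kind == "edge" &
    ((arcs$from == e$from & arcs$to == e$to) |
       (arcs$from == e$to & arcs$to == e$from))
  we <- unique(data.frame(a = pmin(arcs$from[arcs$kind == "edge" & !drop],
                                   arcs$to[arcs$kind == "edge" & !drop]),
                          b = pmax(arcs$from[arcs$kind == "edge" & !drop],
                                   arcs$to[arcs$kind == "edge" & !drop]),
                          weight = arcs$weight[arcs$kind == "edge" & !drop]))
  prob2 <- suppressWarnings(build_flow_problem(we, prob$sources, prob$targets,
                                               gamma = prob$gamma))
  res2 <- suppressWarnings(solve_flow(prob2))
  expect_equal(res2$objective, res$objective, tolerance = 1e-9)
})

test_that("gamma selection respects the minimum-edge-weight floor", {
  # cheap strong path plus an extra path through a weak (0.5) edge that
  # only enters at high gamma
  we <- data.frame(a = c("s1", "m1", "s2", "m2"),
                   b = c("m1", "t1", "m2", "t2"),
                   weight = c(0.95, 0.9, 0.5, 0.95))
  prob <- build_flow_problem(we, c("s1", "s2"), c("t1", "t2"), gamma = 1)
  sel <- select_gamma(prob, gamma_grid = c(0.3, 2))
  # at gamma = 2 the weak edge would carry flow; the floor excludes it
  expect_equal(sel$gamma, 0.3)
  expect_true(all(sel$result$subnetwork$weight > 0.6))
  # a grid of one returns that gamma
  sel1 <- suppressWarnings(select_gamma(prob, gamma_grid = 5))
  expect_equal(sel1$gamma, 5)
  # custom scorer wins over the default
  sel2 <- select_gamma(prob, gamma_grid = c(0.3, 2),
                       scorer = function(r) r$total_flow)
  expect_equal(sel2$gamma, 2)
})

test_that("hub calling uses degree > 4 capped to the top fraction", {
  # star with center degree 6
  star <- data.frame(a = rep("hub", 6), b = paste0("leaf", 1:6))
  expect_identical(call_hubs(star, top_fraction = 1), "hub")
  # path graph: all degrees <= 2, no hubs
  path <- data.frame(a = paste0("n", 1:5), b = paste0("n", 2:6))
  expect_length(call_hubs(path), 0)
  # constructed degree sequence vs brute-force percentile computation
  set.seed(81)
  hub_edges <- do.call(rbind, lapply(1:6, function(i)
    data.frame(a = paste0("h", i), b = paste0("x", i, "_", 1:(i + 3)))))
  deg <- table(c(hub_edges$a, hub_edges$b))
  n_top <- ceiling(0.05 * length(deg))
  thr <- sort(as.integer(deg), decreasing = TRUE)[n_top]
  brute <- names(deg)[deg > 4 & deg >= thr]
  expect_setequal(call_hubs(hub_edges, min_degree = 4, top_fraction = 0.05),
                  brute)
  expect_error(call_hubs(data.frame(a = character(0), b = character(0))),
               "empty")
})
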