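test_that("network construction canonicalizes edges", {
  net <- interaction_network(c("a", "b", "B", "c", "c"),
                             c("b", "a", "a", "c", "d"),
                             c(0.6, 0.9, 0.7, 0.5, 0.8))
  # self-loop dropped, duplicate A-B collapsed to max confidence
  expect_equal(nrow(net$edges), 2)
  ab <- net$edges[net$edges$from == "A", ]
  expect_equal(ab$confidence, 0.9)
  expect_setequal(net$nodes, c("A", "B", "C", "D"))
  expect_error(interaction_network("a", "b", 1.5), "confidence")
})

test_that("confidence filtering is strict and keeps isolated nodes", {
  net <- interaction_network(c("a", "b", "c"), c("b", "c", "a"),
                             c(0.5, 0.51, 0.9))
  f <- filter_confidence(net, 0.5)
  expect_equal(nrow(f$edges), 2)            # 0.5 is excluded, strictly >
  expect_equal(length(f$nodes), 3)
  expect_equal(nrow(filter_confidence(net, 0)$edges), 3)
  all_low <- interaction_network(c("a", "b"), c("b", "c"), c(0.4, 0.4))
  empty <- filter_confidence(all_low, 0.5)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(length(empty$nodes), 3)
})

test_that("centralities match hand-enumerated small graphs", {
  # path A-B-C
  path <- interaction_network(c("a", "b"), c("b", "c"), c(1, 1))
  ct <- centralities(path)
  b <- ct[ct$node == "B", ]
  expect_equal(b$degree, 2)
  expect_equal(b$stress, 1)
  expect_equal(b$betweenness, 1)
  # triangle: every pair adjacent, no intermediates
  tri <- interaction_network(c("a", "a", "b"), c("b", "c", "c"), rep(1, 3))
  expect_true(all(centralities(tri)$stress == 0))
  expect_true(all(centralities(tri)$betweenness == 0))
  # 4-cycle: each opposite pair has 2 shortest paths -> betweenness 1/2
  cyc <- interaction_network(c("a", "b", "c", "d"), c("b", "c", "d", "a"),
                             rep(1, 4))
  cc <- centralities(cyc)
  expect_equal(cc$betweenness, rep(0.5, 4))
  expect_equal(cc$stress, rep(1, 4))
})

test_that("centralities agree with the exhaustive path enumerator", {
  for (seed in 1:12) {
    net <- random_toy_network(seed)
    got <- centralities(net)
    want <- brute_centralities(net$nodes, net$edges)
    expect_equal(got$degree, want$degree)
    expect_equal(got$stress, want$stress)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
    # betweenness never exceeds stress
    expect_true(all(got$betweenness <= got$stress + 1e-12))
  }
})

test_that("betweenness cross-checks against igraph on a larger graph", {
  set.seed(31)
  n <- 60
  pairs <- utils::combn(n, 2)
  keep <- runif(ncol(pairs)) < 0.08
  net <- interaction_network(paste0("N", pairs[1, keep]),
                             paste0("N", pairs[2, keep]),
                             runif(sum(keep), 0.5, 1),
                             nodes = paste0("N", 1:n))
  got <- centralities(net)
  g <- as_igraph(net)
  ref <- igraph::betweenness(g, weights = NA)
  expect_equal(got$betweenness, unname(ref[got$node]), tolerance = 1e-9)
  deg <- igraph::degree(g)
  expect_equal(got$degree, unname(deg[got$node]))
})

hub_fixture <- function() {
  # 20 nodes; hubs H1-H3 each wired to 6 spokes at confidence 0.8 and
  # given strong folds; decoys fail exactly one criterion each
  from <- c(rep("H1", 6), rep("H2", 6), rep("H3", 6),
            rep("LOWCONF", 6), rep("LOWDEG", 5), rep("NOFOLD", 6))
  to <- c(paste0("S", 1:6), paste0("S", 3:8), paste0("S", 5:10),
          paste0("S", 1:6), paste0("S", 1:5), paste0("S", 1:6))
  conf <- c(rep(0.8, 18), rep(0.6, 6), rep(0.8, 5), rep(0.8, 6))
  net <- interaction_network(from, to, conf)
  folds <- make_folds(c("H1", "H2", "H3", "LOWCONF", "LOWDEG",
                        paste0("S", 1:10)),
                      c(2.5, 4, 0.3, 3, 3, rep(1, 10)),
                      scale = "mean_normalized")
  list(net = net, folds = folds)
}

test_that("hub extraction applies the printed thresholds strictly", {
  fx <- hub_fixture()
  hubs <- extract_hubs(fx$net, fx$folds, min_degree = 5, conf = 0.7,
                       min_fold = 2)
  expect_setequal(hubs$up, c("H1", "H2"))    # >5 interactants, fold > 2
  expect_equal(hubs$down, "H3")              # fold 0.3 < 1/2
  # LOWCONF drops to degree 0 at conf > 0.7; LOWDEG has only 5 edges;
  # NOFOLD has no fold value
  hubs2 <- extract_hubs(fx$net, fx$folds, min_degree = 5, conf = 0.5,
                        min_fold = 2)
  expect_true("LOWCONF" %in% hubs2$up)
  expect_error(extract_hubs(fx$net, fx$folds, min_degree = 0), "positive")
})

test_that("hub sets are monotone in the thresholds", {
  set.seed(9)
  n <- 40
  pairs <- utils::combn(n, 2)
  keep <- runif(ncol(pairs)) < 0.2
  net <- interaction_network(paste0("N", pairs[1, keep]),
                             paste0("N", pairs[2, keep]),
                             runif(sum(keep), 0.3, 1))
  folds <- make_folds(paste0("N", 1:n), exp(rnorm(n, 0, 1)),
                      scale = "mean_normalized")
  base <- extract_hubs(net, folds, min_degree = 3, conf = 0.5,
                       min_fold = 1.5)
  tighter_conf <- extract_hubs(net, folds, min_degree = 3, conf = 0.7,
                               min_fold = 1.5)
  tighter_fold <- extract_hubs(net, folds, min_degree = 3, conf = 0.5,
                               min_fold = 2.5)
  expect_true(all(tighter_conf$up %in% base$up))
  expect_true(all(tighter_conf$down %in% base$down))
  expect_true(all(tighter_fold$up %in% base$up))
  expect_true(all(tighter_fold$down %in% base$down))
})

test_that("standardized-scale down-hubs use the negative threshold", {
  net <- interaction_network(rep("H", 6), paste0("S", 1:6), rep(0.9, 6))
  folds <- make_folds(c("H", paste0("S", 1:6)), c(-2.5, rep(0, 6)),
                      scale = "standardized")
  hubs <- extract_hubs(net, folds, min_fold = 2)
  expect_equal(hubs$down, "H")
  expect_length(hubs$up, 0)
})

test_that("k-means on connectivity profiles separates disjoint cliques", {
  clique <- function(ids, conf) {
    p <- utils::combn(ids, 2)
    interaction_network(p[1, ], p[2, ], rep(conf, ncol(p)))
  }
  a <- clique(paste0("A", 1:4), 0.9)
  b <- clique(paste0("B", 1:4), 0.9)
  net <- interaction_network(c(a$edges$from, b$edges$from),
                             c(a$edges$to, b$edges$to),
                             c(a$edges$confidence, b$edges$confidence))
  hubs <- c(paste0("A", 1:4), paste0("B", 1:4))
  cl <- cluster_hubs(net, hubs, k = 2, seed = 5)
  expect_equal(length(unique(cl$cluster[paste0("A", 1:4)])), 1)
  expect_equal(length(unique(cl$cluster[paste0("B", 1:4)])), 1)
  expect_false(cl$cluster[["A1"]] == cl$cluster[["B1"]])
  # determinism under the seed; k = 1 puts everything together
  cl2 <- cluster_hubs(net, hubs, k = 2, seed = 5)
  expect_identical(cl$cluster, cl2$cluster)
  expect_true(all(cluster_hubs(net, hubs, k = 1)$cluster == 1))
  expect_error(cluster_hubs(net, hubs, k = 9), "exceeds")
})

test_that("shell is the union of seeds and first neighbors", {
  path <- interaction_network(c("a", "b"), c("b", "c"), c(1, 1))
  expect_setequal(shell(path, "a"), c("A", "B"))
  expect_setequal(shell(path, c("a", "b", "c")), c("A", "B", "C"))
  expect_error(shell(path, character()), "empty")
  # gap-junction style fixture: 4 seeds, 7 distinct neighbors (2 shared)
  from <- c("J1", "J1", "J2", "J2", "J3", "J3", "J4", "J4", "J4")
  to <- c("N1", "N2", "N2", "N3", "N4", "N5", "N5", "N6", "N7")
  net <- interaction_network(from, to, rep(0.9, 9))
  sh <- shell(net, c("J1", "J2", "J3", "J4"))
  expect_length(sh, 11)
  # shells are expansive: shell(shell(S)) contains shell(S)
  sh2 <- shell(net, sh)
  expect_true(all(sh %in% sh2))
  # missing seeds are reported, not fatal
  sh3 <- shell(net, c("J1", "GHOST"))
  expect_equal(attr(sh3, "missing"), "GHOST")
})

test_that("class-stratified centrality ranks the planted dense core", {
  set.seed(12)
  cfg <- synth_config(n_genes = 400, n_network_genes = 400,
                      p_core = 0.25, p_periph = 0.02, p_cross = 0.06,
                      seed = 12)
  d <- generate_dataset(cfg)
  cent <- centralities(filter_confidence(d$network, 0.5))
  res <- centrality_by_class(cent, cent$node, d$annotation)
  means <- res$class_means["degree", ]
  uc_classes <- c("UC_pluri", "UC_only")
  mc_classes <- intersect(c("pluri_only", "neither"), colnames(res$class_means))
  expect_gt(min(means[uc_classes], na.rm = TRUE),
            max(means[mc_classes], na.rm = TRUE))
  # identical centrality across classes -> nothing flagged
  flat <- cent; flat$degree <- 5L; flat$stress <- 2; flat$betweenness <- 1
  res2 <- suppressWarnings(centrality_by_class(flat, flat$node,
                                               d$annotation))
  expect_true(all(vapply(res2$fits,
                         function(f) all(f$flag == "ns"), TRUE)))
})

test_that("STRING edge lists parse in both score dialects", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1 protein2 combined_score",
               "a b 700", "b c 400"), p1)
  net <- read_string_edges(p1)
  expect_equal(sort(net$edges$confidence), c(0.4, 0.7))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "a\tb\t0.7", "b\tc\t0.4"), p2)
  expect_equal(sort(read_string_edges(p2)$edges$confidence), c(0.4, 0.7))
})
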