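test_that("the same seed reproduces the dataset bit-identically", {
  cfg <- synth_config(n_genes = 500, seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$study$values, d2$study$values)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$network$edges, d2$network$edges)
  # a different seed differs
  d3 <- generate_dataset(synth_config(n_genes = 500, seed = 43))
  expect_false(identical(d1$study$values, d3$study$values))
  # generation does not disturb the session RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_dataset(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generated pieces satisfy their structural contracts", {
  d <- generate_dataset(synth_config(n_genes = 800, seed = 3))
  ann <- d$annotation
  expect_true(all(ann$phylostratum %in% 1:17))
  expect_true(all(ann$mgi > 0 & ann$mgi <= 1))
  expect_true(all(ann$stem_score >= pmax(ann$multi_score,
                                         ann$pluri_score)))
  expect_equal(sum(ann$oncofetal), 33)
  expect_setequal(d$truth$uc_genes,
                  ann$gene_id[ann$phylostratum <= 3])
  # positive copy is the exponentiated additive study
  expect_equal(d$study_positive$values, 2^d$study$values)
  expect_equal(unique(d$study$meta$cell_state),
               c("initial", "pgcc", "early_progeny", "late_progeny"))
  # no self-loops in the network
  expect_true(all(d$network$edges$from != d$network$edges$to))
})

test_that("core-periphery limiting cases are exact", {
  # p_core 1, others 0: a UC clique plus isolated MC nodes
  cfg <- synth_config(n_genes = 60, n_network_genes = 60,
                      p_core = 1, p_periph = 0, p_cross = 0, seed = 5)
  net <- generate_network(cfg)
  uc <- net$nodes[attr(net, "is_uc")]
  n_uc <- length(uc)
  expect_equal(nrow(net$edges), choose(n_uc, 2))
  expect_true(all(net$edges$from %in% uc) && all(net$edges$to %in% uc))
  # single gene: edgeless
  net1 <- generate_network(synth_config(n_genes = 1, n_network_genes = 1,
                                        seed = 2))
  expect_equal(nrow(net1$edges), 0)
  expect_equal(length(net1$nodes), 1)
  expect_error(synth_config(p_core = 1.4), "probabilities")
  expect_error(synth_config(p_core = 0.01, p_periph = 0.2), "p_core")
  expect_error(synth_config(noise_sd = 0), "noise_sd")
  expect_error(synth_config(state_effects = list(a = c(delta_uc = 0,
                                                       delta_mc = 0))),
               "every state")
})

test_that("a flat edge probability recovers the binomial mean degree", {
  p <- 0.1; n <- 80
  degs <- numeric(20)
  for (s in 1:20) {
    net <- generate_network(synth_config(n_genes = n, n_network_genes = n,
                                         p_core = p, p_periph = p,
                                         p_cross = p, seed = 100 + s))
    degs[s] <- 2 * nrow(net$edges) / n
  }
  expected <- p * (n - 1)
  se <- sqrt(2 * choose(n, 2) * p * (1 - p)) / n / sqrt(20)
  expect_lt(abs(mean(degs) - expected), 3 * se)
})

test_that("UC nodes are denser than MC nodes under the core model", {
  net <- generate_network(synth_config(n_genes = 400,
                                       n_network_genes = 400,
                                       p_core = 0.2, p_periph = 0.02,
                                       p_cross = 0.06, seed = 8))
  deg <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  tab <- table(c(net$edges$from, net$edges$to))
  deg[names(tab)] <- tab
  expect_gt(mean(deg[attr(net, "is_uc")]), mean(deg[!attr(net, "is_uc")]))
})

test_that("planted effects are recovered as a contrast against the
           unaffected middle strata", {
  # per-sample standardization recentres folds, so the recoverable
  # estimand of delta_uc is UC-bin fold minus middle-bin fold
  deltas <- numeric(50)
  for (s in 1:50) {
    d <- generate_dataset(synth_config(
      n_genes = 10000, seed = 300 + s,
      states = c("initial", "pgcc"),
      state_effects = list(initial = c(delta_uc = 0, delta_mc = 0),
                           pgcc = c(delta_uc = -0.3, delta_mc = 0.3))))
    f <- compute_fold(d$study, "pgcc", "initial")
    ps <- d$annotation$phylostratum[match(f$gene_id,
                                          d$annotation$gene_id)]
    deltas[s] <- mean(f$fold[ps <= 3]) - mean(f$fold[ps >= 4 & ps <= 11])
  }
  expect_lt(abs(mean(deltas) - (-0.3)), 0.05)
})
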