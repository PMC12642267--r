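synthetic_profile_folds <- function(delta, n_per_bin = 500, sd = 1,
                                    seed = 1) {
  # +delta for phylostrata 1-3, -delta for 12-17, noise elsewhere
  set.seed(seed)
  ps <- rep(1:17, each = n_per_bin)
  shift <- ifelse(ps <= 3, delta, ifelse(ps >= 12, -delta, 0))
  gene <- sprintf("g%05d", seq_along(ps))
  ann <- data.frame(gene_id = toupper(gene), phylostratum = ps,
                    stringsAsFactors = FALSE)
  list(folds = make_folds(gene, shift + rnorm(length(ps), 0, sd)),
       ann = ann)
}

test_that("planted UC-shift folds flag the expected strata", {
  fx <- synthetic_profile_folds(delta = 0.5)
  prof <- evolutionary_profile(fx$folds, fx$ann)
  expect_s3_class(prof, "evo_profile")
  expect_true(all(prof$flag[1:3] == "up"))
  expect_true(all(prof$flag[12:17] == "down"))
  expect_equal(classify_three_phase(prof), "UC_SHIFT")
  expect_equal(sum(prof$n), nrow(fx$folds))
})

test_that("zero folds give an all-ns profile and NONE classification", {
  fx <- synthetic_profile_folds(delta = 0, n_per_bin = 5, sd = 0)
  expect_warning(prof <- evolutionary_profile(fx$folds, fx$ann),
                 "zero pooled")
  expect_true(all(prof$flag == "ns"))
  expect_true(all(prof$mean_fold[prof$n > 0] == 0))
  expect_equal(classify_three_phase(prof), "NONE")
})

test_that("cell-cycle exclusion removes exactly the flagged genes", {
  genes <- paste0("G", 1:10)
  ann <- data.frame(gene_id = genes,
                    phylostratum = rep(c(1, 5), 5),
                    stringsAsFactors = FALSE)
  folds <- make_folds(genes, rnorm(10))
  cc <- genes[c(1, 4, 7)]
  prof <- evolutionary_profile(folds, ann, exclude_cell_cycle = TRUE,
                               cell_cycle_genes = cc)
  expect_equal(sum(prof$n), 7)
  expect_equal(attr(prof, "n_cell_cycle_removed"), 3)
  # excluding against a disjoint set leaves the profile bit-identical
  p1 <- evolutionary_profile(folds, ann)
  p2 <- evolutionary_profile(folds, ann, exclude_cell_cycle = TRUE,
                             cell_cycle_genes = "ZZZ")
  expect_equal(p1, p2, ignore_attr = TRUE)
  expect_error(evolutionary_profile(folds, ann, exclude_cell_cycle = TRUE),
               "cell_cycle_genes")
})

test_that("genes without phylostratum are excluded and tallied", {
  ann <- data.frame(gene_id = c("A", "B", "C", "D", "E", "F"),
                    phylostratum = c(1, 1, 5, 5, NA, NA))
  folds <- make_folds(c("A", "B", "C", "D", "E", "F"),
                      c(0.1, 0.2, -0.1, -0.2, 9, 9))
  prof <- evolutionary_profile(folds, ann)
  expect_equal(sum(prof$n), 4)
  expect_equal(attr(prof, "n_excluded"), 2)
  expect_error(evolutionary_profile(make_folds("Z", 1), ann),
               "no annotated genes")
})

test_that("three-phase classification covers every branch", {
  fx <- synthetic_profile_folds(delta = 0.5)
  up <- evolutionary_profile(fx$folds, fx$ann)
  expect_equal(classify_three_phase(up), "UC_SHIFT")
  # mirrored folds give the mirrored label
  down <- fx$folds; down$fold <- -down$fold
  expect_equal(classify_three_phase(evolutionary_profile(down, fx$ann)),
               "MC_SHIFT")
  # contradictory zone flags are ambiguous: both UC and late shifted up
  both <- fx$folds
  ps <- fx$ann$phylostratum[match(both$gene_id, fx$ann$gene_id)]
  both$fold <- abs(both$fold) * ifelse(ps <= 3 | ps >= 12, 1, 0) +
    ifelse(ps <= 3 | ps >= 12, 0.5, 0)
  expect_equal(classify_three_phase(evolutionary_profile(both, fx$ann)),
               "AMBIGUOUS")
})

test_that("TAI matches closed-form hand examples exactly", {
  expect_equal(tai(c(1, 1), c(1, 17)), 9, tolerance = 1e-12)
  expect_equal(tai(c(0, 5), c(1, 17)), 17, tolerance = 1e-12)
  expect_equal(tai(c(2, 1, 1), c(2, 4, 10)), 4.5, tolerance = 1e-12)
  expect_error(tai(c(0, 0), c(1, 2)), "zero")
  expect_error(tai(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("TAI is scale-invariant and monotone in old-gene expression", {
  set.seed(8)
  for (i in 1:10) {
    e <- rexp(50); ps <- sample(1:17, 50, replace = TRUE)
    expect_equal(tai(e, ps), tai(e * runif(1, 0.1, 100), ps),
                 tolerance = 1e-12)
    # raising the expression of an oldest-stratum gene weakly raises TAI
    j <- which.max(ps)
    e2 <- e; e2[j] <- e2[j] * 2
    expect_gte(tai(e2, ps), tai(e, ps) - 1e-12)
  }
})

test_that("UC/MC ratio matches hand arithmetic on an 8-gene fixture", {
  ann <- data.frame(gene_id = paste0("G", 1:8),
                    phylostratum = c(1, 2, 3, 5, 8, 12, 15, 17))
  vals <- cbind(c(4, 2, 6, 1, 2, 3, 1, 1),      # sample 1
                c(8, 4, 12, 2, 4, 6, 2, 2))     # sample 2 = 2x sample 1
  st <- evo_study(vals, ann$gene_id, c("s", "s"))
  # per sample: mean UC = 4 resp. 8; mean MC = 1.6 resp. 3.2 -> ratio 2.5
  expect_equal(uc_mc_ratio(st, ann, "s"), 2.5)
  expect_equal(uc_mc_ratio(st, ann, "s", method = "ratio_of_means"), 2.5)
  # identical expression in both classes -> ratio 1
  flat <- evo_study(matrix(3, 8, 2), ann$gene_id, c("s", "s"))
  expect_equal(uc_mc_ratio(flat, ann, "s"), 1)
  # doubling UC genes doubles the ratio
  dbl <- vals; dbl[1:3, ] <- dbl[1:3, ] * 2
  st2 <- evo_study(dbl, ann$gene_id, c("s", "s"))
  expect_equal(uc_mc_ratio(st2, ann, "s"), 5)
  expect_error(uc_mc_ratio(st, ann, "nope"), "unknown")
  uc_only <- ann; uc_only$phylostratum <- 1
  expect_error(uc_mc_ratio(st, uc_only, "s"), "non-empty")
})
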