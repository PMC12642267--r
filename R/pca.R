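# Gene-wise PCA: genes are the observations, samples the variables.
# The dominant component of processed expression matrices is the shared
# between-gene expression level, common to all cell states; its
# correlation with gene age links the within-genome expression hierarchy
# to evolutionary origin.

#' Mean-normalize the samples of a study
#'
#' Multiplicatively rescales every sample column so that all column means
#' equal the grand mean, preserving relative expression within each
#' sample. The n-sample generalization of pairwise whole-transcriptome
#' mean normalization.
#'
#' @param study An [evo_study()] with positive column means.
#' @return The rescaled `evo_study`.
#' @export
mean_normalize_study <- function(study) {
  stopifnot(inherits(study, "evo_study"))
  cm <- colMeans(study$values)
  if (any(cm <= 0)) {
    stop("mean normalization requires positive sample means", call. = FALSE)
  }
  study$values <- sweep(study$values, 2L, mean(cm) / cm, `*`)
  study
}

#' PCA of a study with genes as observations
#'
#' Covariance-based principal component analysis of the gene x sample
#' matrix, treating genes as observations and samples as variables
#' (columns are centered, not rescaled). Deterministic up to component
#' sign; the sign of PC1 is fixed so that its per-gene scores correlate
#' non-negatively with mean expression.
#'
#' @param study An [evo_study()] with >= 2 samples and >= 3 genes.
#' @param scale `"mean_normalized"` (default; samples rescaled to a
#'   common mean first) or `"standardized"` (per-sample SD units).
#' @return Object of class `evo_pca`: list with `scores` (gene x
#'   component), `loadings` (sample x component), `var_fraction`
#'   (non-negative, descending, sums to 1), `center`, `scale`.
#' @export
pca_genes <- function(study, scale = c("mean_normalized", "standardized")) {
  stopifnot(inherits(study, "evo_study"))
  scale <- match.arg(scale)
  if (ncol(study$values) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (nrow(study$values) < 3L) stop("need >= 3 genes", call. = FALSE)
  study <- switch(scale,
                  mean_normalized = mean_normalize_study(study),
                  standardized = standardize_study(study))
  x <- study$values
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (all(fit$sdev < 1e-12)) stop("rank-0 matrix: no variance", call. = FALSE)
  # fix PC1 sign against mean expression
  mexp <- rowMeans(x)
  r <- suppressWarnings(stats::cor(fit$x[, 1L], mexp))
  if (!is.na(r) && r < 0) {
    fit$x[, 1L] <- -fit$x[, 1L]
    fit$rotation[, 1L] <- -fit$rotation[, 1L]
  }
  structure(
    list(scores = fit$x, loadings = fit$rotation,
         var_fraction = fit$sdev^2 / sum(fit$sdev^2),
         center = fit$center, scale = scale),
    class = "evo_pca"
  )
}

#' @export
print.evo_pca <- function(x, digits = 4, ...) {
  cat("Gene-wise PCA (", nrow(x$scores), " genes x ", nrow(x$loadings),
      " samples, ", x$scale, " scale)\n", sep = "")
  vf <- signif(x$var_fraction, digits)
  cat("variance fractions:", paste(utils::head(vf, 5), collapse = ", "),
      if (length(vf) > 5) "...\n" else "\n")
  invisible(x)
}

#' Correlation of PC1 gene scores with gene age
#'
#' Spearman rank correlation (gene age is ordinal) between the per-gene
#' scores on the first principal component and the phylostratum.
#'
#' @param pca An `evo_pca` fit.
#' @param ps Phylostratum per gene: a named vector (matched by gene id)
#'   or a vector aligned with the score rows. Genes without an age are
#'   dropped; >= 3 aged genes required.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
pc1_age_correlation <- function(pca, ps) {
  stopifnot(inherits(pca, "evo_pca"))
  scores <- pca$scores[, 1L]
  if (!is.null(names(ps))) {
    ps <- ps[match(rownames(pca$scores), .norm_id(names(ps)))]
  } else if (length(ps) != length(scores)) {
    stop("'ps' must be named by gene or aligned with the score rows",
         call. = FALSE)
  }
  keep <- !is.na(ps)
  if (sum(keep) < 3L) stop("need >= 3 genes with a phylostratum",
                           call. = FALSE)
  x <- scores[keep]; y <- ps[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant scores or ages", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n = sum(keep), method = "spearman")
}
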