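# Signature-level fold analysis: member-vs-complement ANOM (the internal
# complementary normalization — on the standardized scale one side going
# up forces the other down within the same gene universe), stemness
# score-bin profiles and per-gene oncofetal comparisons.

#' Signature vs complement fold comparison
#'
#' Two-group ANOM on fold values: the signature's member genes against
#' all remaining genes of the fold universe. Reporting member and
#' complement side by side realizes the internal complementary
#' normalization: the two sides share the grand mean, so a significant
#' rise of one implies a fall of the other.
#'
#' @param folds A `fold_table`.
#' @param members Character vector of member gene ids (subset of the fold
#'   universe; both sides must be non-empty).
#' @param alpha Family-wise significance level.
#' @param label Signature label carried into the result.
#' @return Object of class `signature_fold`: one-row-per-side data.frame
#'   (`side`, `n`, `mean_fold`, `lower`, `upper`, `flag`) with attributes
#'   `label`, `anom`.
#' @export
signature_fold <- function(folds, members, alpha = 0.05,
                           label = "signature") {
  stopifnot(is.data.frame(folds))
  members <- .norm_id(members)
  is_member <- folds$gene_id %in% members
  if (!any(is_member)) stop("signature has no members in the fold universe",
                            call. = FALSE)
  if (all(is_member)) stop("signature complement is empty", call. = FALSE)
  fit <- anom(list(member = folds$fold[is_member],
                   complement = folds$fold[!is_member]), alpha = alpha)
  out <- data.frame(side = fit$group, n = fit$n, mean_fold = fit$mean,
                    lower = fit$lower, upper = fit$upper, flag = fit$flag,
                    stringsAsFactors = FALSE)
  structure(out, class = c("signature_fold", "data.frame"),
            label = label, anom = fit)
}

#' @export
print.signature_fold <- function(x, digits = 4, ...) {
  cat("Signature fold: ", attr(x, "label"), "\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Fold profile across stemness score bins
#'
#' Bins genes by an integer score (e.g. the number of pluripotent or
#' multipotent stem-cell databases containing the gene; score 0 means
#' non-stemness) and fits an ANOM on fold values across bins. Scores
#' above `max_bin` are pooled into the top bin.
#'
#' @param folds A `fold_table`.
#' @param score Named integer vector gene_id -> score, or a numeric
#'   vector aligned with `folds$gene_id`.
#' @param alpha Family-wise significance level.
#' @param max_bin Top bin; larger scores are pooled into it.
#' @return Object of class `score_bin_profile`: data.frame (`score`, `n`,
#'   `mean_fold`, `lower`, `upper`, `flag`) over occupied bins 0..max_bin,
#'   attribute `anom`.
#' @export
score_bin_profile <- function(folds, score, alpha = 0.05, max_bin = 5L) {
  stopifnot(is.data.frame(folds))
  if (!is.null(names(score))) {
    score <- score[match(folds$gene_id, .norm_id(names(score)))]
  } else if (length(score) != nrow(folds)) {
    stop("'score' must be named by gene or aligned with the fold table",
         call. = FALSE)
  }
  keep <- !is.na(score)
  sc <- score[keep]; fold <- folds$fold[keep]
  if (any(sc < 0)) stop("scores must be non-negative", call. = FALSE)
  sc <- pmin(as.integer(sc), as.integer(max_bin))
  groups <- split(fold, factor(sc, levels = 0:max_bin))
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) {
    stop("need at least two occupied score bins (all genes score ",
         names(groups), ")", call. = FALSE)
  }
  fit <- anom(groups, alpha = alpha)
  out <- data.frame(score = as.integer(fit$group), n = fit$n,
                    mean_fold = fit$mean, lower = fit$lower,
                    upper = fit$upper, flag = fit$flag,
                    stringsAsFactors = FALSE)
  structure(out, class = c("score_bin_profile", "data.frame"),
            anom = fit, max_bin = as.integer(max_bin))
}

#' @export
print.score_bin_profile <- function(x, digits = 4, ...) {
  cat("Score-bin fold profile (top bin pooled at ", attr(x, "max_bin"),
      ")\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Per-gene oncofetal comparison between two studies
#'
#' Oncofetal genes are compared individually on absolute expression
#' levels: the two studies are first put on a common scale by pairwise
#' whole-transcriptome mean normalization, then each oncofetal gene gets
#' a two-sample Welch t test (test vs reference samples) with Bonferroni
#' correction over the tested set. The per-gene test choice is recorded
#' in the result's metadata.
#'
#' @param test,ref [evo_study()] objects (>= 2 samples each).
#' @param oncofetal Character vector of oncofetal gene ids.
#' @param alpha Family-wise significance level (Bonferroni over the
#'   tested genes).
#' @return Object of class `oncofetal_result`: data.frame (`gene_id`,
#'   `fold` — ratio of normalized means —, `p`, `p_adj`, `flag` in
#'   up/down/ns), attributes `missing` (requested genes absent from the
#'   data) and `method`.
#' @export
oncofetal_compare <- function(test, ref, oncofetal, alpha = 0.05) {
  stopifnot(inherits(test, "evo_study"), inherits(ref, "evo_study"))
  .check_alpha(alpha)
  if (ncol(test$values) < 2L || ncol(ref$values) < 2L) {
    stop("need >= 2 replicates on each side", call. = FALSE)
  }
  oncofetal <- unique(.norm_id(oncofetal))
  norm <- mean_normalize_pair(test, ref)
  common <- rownames(norm$a$values)
  present <- intersect(oncofetal, common)
  missing <- setdiff(oncofetal, common)
  if (!length(present)) stop("no oncofetal genes present in the data",
                             call. = FALSE)
  res <- lapply(present, function(g) {
    xt <- norm$a$values[g, ]; xr <- norm$b$values[g, ]
    p <- tryCatch(stats::t.test(xt, xr)$p.value, error = function(e) NA_real_)
    mr <- mean(xr)
    data.frame(gene_id = g,
               fold = if (mr != 0) mean(xt) / mr else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- stats::p.adjust(res$p, method = "bonferroni")
  res$flag <- factor(
    ifelse(!is.na(res$p_adj) & res$p_adj < alpha,
           ifelse(res$fold > 1, "up", "down"), "ns"),
    levels = c("down", "ns", "up"))
  structure(res, class = c("oncofetal_result", "data.frame"),
            missing = missing,
            method = "Welch t per gene, Bonferroni over tested set",
            alpha = alpha)
}

#' @export
print.oncofetal_result <- function(x, digits = 4, ...) {
  cat("Oncofetal per-gene comparison (", attr(x, "method"), ")\n",
      sep = "")
  cat(sum(x$flag == "up"), "up,", sum(x$flag == "down"), "down,",
      sum(x$flag == "ns"), "unchanged")
  if (length(attr(x, "missing"))) {
    cat("; missing from data:", paste(attr(x, "missing"), collapse = ", "))
  }
  cat("\n\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
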