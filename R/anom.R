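# Analysis of means (ANOM): simultaneous comparison of each group mean
# against the grand mean with decision limits. This is the package's core
# estimator; evolutionary profiles, signature folds, score-bin profiles
# and class-stratified centrality are all ANOM fits over different
# groupings.
#
# Decision limits use a Bonferroni-adjusted two-sided t critical value at
# alpha/(2k) with pooled degrees of freedom, in place of Nelson's exact h
# (exact tables cover a limited range of k and df; the Bonferroni variant
# is conservative and standard). Monte-Carlo calibration of the
# family-wise error is asserted in the test suite.

#' Analysis of means
#'
#' Compares each group mean against the grand mean (weighted by group
#' size) with simultaneous decision limits
#' \deqn{\mu \pm h \, s \sqrt{(k-1)/(k n_i)}}
#' where `s` is the pooled standard deviation with `sum(n_i - 1)` degrees
#' of freedom and `h` the two-sided t critical value at `alpha/(2k)`.
#' A group is flagged `up` iff its mean exceeds the upper limit and
#' `down` iff it falls below the lower limit; otherwise `ns`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups). Groups of
#'   size 1 carry no degrees of freedom but still receive limits.
#' @param alpha Simultaneous (family-wise) significance level in (0, 1).
#' @return An object of class `anom`: data.frame-backed fit with one row
#'   per group (`group`, `n`, `mean`, `lower`, `upper`, `flag`) and
#'   attributes `grand_mean`, `pooled_sd`, `df`, `alpha`, `h`.
#' @examples
#' set.seed(1)
#' g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 3))
#' fit <- anom(g)
#' fit$flag
#' @export
anom <- function(groups, alpha = 0.05) {
  .check_alpha(alpha)
  if (!is.list(groups) || length(groups) < 2L) {
    stop("ANOM needs at least 2 groups", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  n <- lengths(groups)
  if (any(n < 1L)) stop("every group must contain at least one value",
                        call. = FALSE)
  k <- length(groups)
  means <- vapply(groups, mean, 0)
  grand <- sum(n * means) / sum(n)
  df <- sum(n - 1L)
  if (df < 1L) stop("no residual degrees of freedom (all groups size 1)",
                    call. = FALSE)
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  s <- sqrt(ss / df)
  h <- stats::qt(1 - alpha / (2 * k), df)
  half <- h * s * sqrt((k - 1) / (k * n))
  lower <- grand - half
  upper <- grand + half
  if (s == 0) {
    warning("zero pooled variance: all flags set to 'ns'", call. = FALSE)
    flag <- rep("ns", k)
  } else {
    flag <- ifelse(means > upper, "up", ifelse(means < lower, "down", "ns"))
  }
  out <- data.frame(group = names(groups), n = as.integer(n),
                    mean = unname(means), lower = unname(lower),
                    upper = unname(upper),
                    flag = factor(flag, levels = c("down", "ns", "up")),
                    stringsAsFactors = FALSE)
  structure(out, class = c("anom", "data.frame"),
            grand_mean = grand, pooled_sd = s, df = df,
            alpha = alpha, h = h)
}

#' @export
print.anom <- function(x, digits = 4, ...) {
  cat("Analysis of means (", nrow(x), " groups, alpha = ",
      attr(x, "alpha"), ")\n", sep = "")
  cat("grand mean ", signif(attr(x, "grand_mean"), digits),
      ", pooled SD ", signif(attr(x, "pooled_sd"), digits),
      " on ", attr(x, "df"), " df\n\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.anom <- function(object, ...) {
  sig <- object$group[object$flag != "ns"]
  cat("ANOM fit: ", nrow(object), " groups; ",
      length(sig), " flagged (",
      paste(sprintf("%s:%s", sig,
                    object$flag[object$flag != "ns"]), collapse = ", "),
      ")\n", sep = "")
  invisible(object)
}

#' @export
coef.anom <- function(object, ...) {
  stats::setNames(object$mean, object$group)
}

#' Decision limits of an ANOM fit
#'
#' @param object An `anom` fit.
#' @param parm,level Unused (limits are fixed by the fit's alpha).
#' @param ... Unused.
#' @return Matrix with columns `lower`, `upper`, one row per group.
#' @export
confint.anom <- function(object, parm, level, ...) {
  m <- cbind(lower = object$lower, upper = object$upper)
  rownames(m) <- object$group
  m
}

#' Classic ANOM decision chart
#'
#' Group means with the grand-mean centerline and dotted decision limits;
#' flagged groups are starred.
#'
#' @param x An `anom` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.anom <- function(x, ...) {
  k <- nrow(x)
  ylim <- range(x$mean, x$lower, x$upper)
  graphics::plot(seq_len(k), x$mean, xaxt = "n", xlab = "group",
                 ylab = "mean", ylim = ylim, pch = 19, type = "b", ...)
  graphics::axis(1, at = seq_len(k), labels = x$group, las = 2)
  graphics::abline(h = attr(x, "grand_mean"), lty = 1)
  graphics::lines(seq_len(k), x$lower, lty = 3, col = "red")
  graphics::lines(seq_len(k), x$upper, lty = 3, col = "red")
  sig <- which(x$flag != "ns")
  if (length(sig)) {
    graphics::points(sig, x$mean[sig], pch = 8, col = "red", cex = 1.5)
  }
  invisible(x)
}
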