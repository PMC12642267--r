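# Evolutionary profiles: per-phylostratum ANOM on expression folds,
# three-phase axis classification, Transcriptome Age Index, UC/MC ratio.

#' Per-phylostratum evolutionary profile of expression folds
#'
#' Bins the genes of a fold table by phylostratum (1..17) and fits an
#' ANOM across the occupied bins on the fold values. Genes without a
#' phylostratum are excluded and tallied. Optionally removes mitotic
#' cell-cycle genes first (the proliferation control): pass the
#' propagated member set of GO:0000278 as `cell_cycle_genes`.
#'
#' @param folds A `fold_table` from [compute_fold()].
#' @param ann Annotation table with `gene_id` and `phylostratum`.
#' @param alpha Family-wise significance level for the ANOM limits.
#' @param exclude_cell_cycle Remove `cell_cycle_genes` before binning.
#' @param cell_cycle_genes Character vector of cell-cycle gene ids
#'   (required when `exclude_cell_cycle = TRUE`).
#' @return An object of class `evo_profile`: data.frame with one row per
#'   phylostratum 1..17 (`phylostratum`, `n`, `mean_fold`, `lower`,
#'   `upper`, `flag`; empty bins have `n = 0` and `ns`), attributes
#'   `anom` (the underlying fit), `n_excluded` (genes without
#'   phylostratum), `n_cell_cycle_removed`, `cell_cycle_excluded`,
#'   `alpha`.
#' @export
evolutionary_profile <- function(folds, ann, alpha = 0.05,
                                 exclude_cell_cycle = FALSE,
                                 cell_cycle_genes = NULL) {
  stopifnot(is.data.frame(folds), is.data.frame(ann))
  .check_alpha(alpha)
  ps <- ann$phylostratum[match(folds$gene_id, ann$gene_id)]
  keep <- !is.na(ps)
  n_excluded <- sum(!keep)
  fold <- folds$fold[keep]
  gene <- folds$gene_id[keep]
  ps <- ps[keep]
  n_cc <- 0L
  if (exclude_cell_cycle) {
    if (is.null(cell_cycle_genes)) {
      stop("exclude_cell_cycle = TRUE requires 'cell_cycle_genes'",
           call. = FALSE)
    }
    cc <- gene %in% .norm_id(cell_cycle_genes)
    n_cc <- sum(cc)
    fold <- fold[!cc]; ps <- ps[!cc]; gene <- gene[!cc]
  }
  if (!length(fold)) stop("no annotated genes to profile", call. = FALSE)
  groups <- split(fold, factor(ps, levels = 1:17))
  occupied <- lengths(groups) > 0L
  fit <- anom(groups[occupied], alpha = alpha)
  out <- data.frame(phylostratum = 1:17, n = 0L,
                    mean_fold = NA_real_, lower = NA_real_,
                    upper = NA_real_,
                    flag = factor(rep("ns", 17),
                                  levels = c("down", "ns", "up")),
                    stringsAsFactors = FALSE)
  idx <- as.integer(fit$group)
  out$n[idx] <- fit$n
  out$mean_fold[idx] <- fit$mean
  out$lower[idx] <- fit$lower
  out$upper[idx] <- fit$upper
  out$flag[idx] <- fit$flag
  structure(out, class = c("evo_profile", "data.frame"),
            anom = fit, n_excluded = n_excluded,
            n_cell_cycle_removed = n_cc,
            cell_cycle_excluded = exclude_cell_cycle, alpha = alpha)
}

#' @export
print.evo_profile <- function(x, digits = 4, ...) {
  cat("Evolutionary profile (alpha = ", attr(x, "alpha"), ")\n", sep = "")
  cat(sum(x$n), "genes binned;", attr(x, "n_excluded"),
      "without phylostratum excluded")
  if (attr(x, "cell_cycle_excluded")) {
    cat(";", attr(x, "n_cell_cycle_removed"), "cell-cycle genes removed")
  }
  cat("\nclassification:", classify_three_phase(x), "\n\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
plot.evo_profile <- function(x, ...) {
  occ <- x$n > 0L
  graphics::plot(x$phylostratum[occ], x$mean_fold[occ], type = "b",
                 pch = 19, xlab = "phylostratum",
                 ylab = "mean expression fold (SD units)",
                 ylim = range(x$mean_fold[occ], x$lower[occ], x$upper[occ]),
                 ...)
  graphics::abline(h = attr(attr(x, "anom"), "grand_mean"), lty = 1)
  graphics::lines(x$phylostratum[occ], x$lower[occ], lty = 3, col = "red")
  graphics::lines(x$phylostratum[occ], x$upper[occ], lty = 3, col = "red")
  sig <- which(occ & x$flag != "ns")
  if (length(sig)) {
    graphics::points(x$phylostratum[sig], x$mean_fold[sig], pch = 8,
                     col = "red", cex = 1.5)
  }
  invisible(x)
}

#' Three-phase classification of an evolutionary profile
#'
#' The axis-position readout: a UC shift shows activated unicellular
#' phylostrata (1-3) together with suppressed late multicellular
#' phylostrata, roughly unchanged in between; an MC shift is the mirrored
#' pattern.
#'
#' @param profile An `evo_profile`.
#' @param uc_zone Integer phylostrata counted as the unicellular zone.
#' @param late_zone Integer phylostrata counted as the late-MC zone
#'   (defaults chosen from the characteristic three-phase shape;
#'   configurable).
#' @return `"UC_SHIFT"` (>=1 UC bin up, >=1 late bin down, no
#'   contradictory flags in either zone), `"MC_SHIFT"` (mirror),
#'   `"NONE"` (no flags in either zone) or `"AMBIGUOUS"`.
#' @export
classify_three_phase <- function(profile, uc_zone = 1:3,
                                 late_zone = 12:17) {
  stopifnot(inherits(profile, "evo_profile"))
  f_uc <- profile$flag[profile$phylostratum %in% uc_zone &
                         profile$n > 0L]
  f_late <- profile$flag[profile$phylostratum %in% late_zone &
                           profile$n > 0L]
  uc_up <- any(f_uc == "up"); uc_down <- any(f_uc == "down")
  late_up <- any(f_late == "up"); late_down <- any(f_late == "down")
  if (!uc_up && !uc_down && !late_up && !late_down) return("NONE")
  if (uc_up && late_down && !uc_down && !late_up) return("UC_SHIFT")
  if (uc_down && late_up && !uc_up && !late_down) return("MC_SHIFT")
  "AMBIGUOUS"
}

#' Transcriptome Age Index
#'
#' Expression-weighted mean phylostratum:
#' \deqn{TAI = \sum_i ps_i e_i / \sum_i e_i}
#' bounded in \[1, 17\]. Genes without a phylostratum are dropped;
#' expression must be non-negative with a positive total.
#'
#' @param expression Named (or positional) non-negative numeric vector.
#' @param ps Phylostratum per gene (same length/order, `NA` allowed).
#' @return The TAI, a single number in \[1, 17\].
#' @examples
#' tai(c(1, 1), c(1, 17))   # 9
#' tai(c(2, 1, 1), c(2, 4, 10))  # 4.5
#' @export
tai <- function(expression, ps) {
  if (length(expression) != length(ps)) {
    stop("'expression' and 'ps' must have equal length", call. = FALSE)
  }
  if (any(expression < 0, na.rm = TRUE)) {
    stop("expression must be non-negative for TAI", call. = FALSE)
  }
  keep <- !is.na(ps) & !is.na(expression)
  e <- expression[keep]; p <- ps[keep]
  tot <- sum(e)
  if (!length(e) || tot <= 0) {
    stop("TAI undefined: total expression is zero", call. = FALSE)
  }
  sum(p * e) / tot
}

#' UC/MC expression ratio of a cell state
#'
#' The ratio of mean expression of unicellular-origin genes (phylostrata
#' 1-3) to multicellular-origin genes (4-17); values above 1 indicate a
#' UC bias. With `method = "per_sample_mean"` (default) the ratio is
#' computed per sample and averaged over the state's samples — this form
#' is invariant to per-sample multiplicative scaling, so it is unaffected
#' by whole-transcriptome mean normalization. The alternative
#' `"ratio_of_means"` takes the quotient of the state-wide class means.
#'
#' @param study An [evo_study()] with non-negative expression values.
#' @param ann Annotation table with `gene_id` and `phylostratum`.
#' @param state Cell-state label.
#' @param method Averaging order, see above.
#' @return A single positive number.
#' @export
uc_mc_ratio <- function(study, ann, state,
                        method = c("per_sample_mean", "ratio_of_means")) {
  stopifnot(inherits(study, "evo_study"))
  method <- match.arg(method)
  if (!state %in% study$meta$cell_state) {
    stop("unknown cell state '", state, "'", call. = FALSE)
  }
  cls <- evodevo_class(ann$phylostratum[match(rownames(study$values),
                                              ann$gene_id)])
  uc <- cls == "UC"; mc <- cls == "MC"
  if (!any(uc) || !any(mc)) {
    stop("both UC and MC gene classes must be non-empty", call. = FALSE)
  }
  cols <- which(study$meta$cell_state == state)
  v <- study$values[, cols, drop = FALSE]
  if (method == "per_sample_mean") {
    mc_means <- colMeans(v[mc, , drop = FALSE])
    if (any(mc_means == 0)) stop("zero MC-class mean", call. = FALSE)
    mean(colMeans(v[uc, , drop = FALSE]) / mc_means)
  } else {
    mmc <- mean(v[mc, , drop = FALSE])
    if (mmc == 0) stop("zero MC-class mean", call. = FALSE)
    mean(v[uc, , drop = FALSE]) / mmc
  }
}
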