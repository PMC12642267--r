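# Expression containers and the standardized / mean-normalized scales.
#
# An evo_study holds a gene x sample matrix plus per-sample metadata
# (cell_state, replicate). All axis-position inference happens on the
# per-sample standardized scale (each sample column expressed in SD units
# with mean zero), which removes between-sample differences in location
# and spread; per-gene comparisons of absolute levels (oncofetal genes)
# instead use pairwise whole-matrix mean normalization, which preserves
# relative expression.

#' Construct an expression study
#'
#' @param values Numeric gene x sample matrix.
#' @param gene_id Character vector of row identifiers (unique after
#'   canonicalization).
#' @param cell_state Character vector, one label per sample column
#'   (conventionally `initial`, `pgcc`, `early_progeny`, `late_progeny`,
#'   but any labels are accepted).
#' @param replicate Optional integer replicate index per sample; defaults
#'   to 1..n within each state.
#' @param sample_id Optional sample names; defaults to
#'   `<state>_r<replicate>`.
#' @return An object of class `evo_study`: list with `values` (matrix,
#'   dimnames set) and `meta` (data.frame sample_id / cell_state /
#'   replicate).
#' @export
evo_study <- function(values, gene_id, cell_state, replicate = NULL,
                      sample_id = NULL) {
  values <- as.matrix(values)
  gene_id <- .norm_id(gene_id)
  if (length(gene_id) != nrow(values)) {
    stop("length(gene_id) must equal nrow(values)", call. = FALSE)
  }
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in expression study: ",
         paste(utils::head(gene_id[duplicated(gene_id)], 5), collapse = ", "),
         call. = FALSE)
  }
  cell_state <- as.character(cell_state)
  if (length(cell_state) != ncol(values)) {
    stop("length(cell_state) must equal ncol(values)", call. = FALSE)
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(cell_state), cell_state,
                            FUN = seq_along)
  }
  if (is.null(sample_id)) {
    sample_id <- paste0(cell_state, "_r", replicate)
  }
  dimnames(values) <- list(gene_id, sample_id)
  structure(
    list(values = values,
         meta = data.frame(sample_id = sample_id,
                           cell_state = cell_state,
                           replicate = as.integer(replicate),
                           stringsAsFactors = FALSE)),
    class = "evo_study"
  )
}

#' @export
print.evo_study <- function(x, ...) {
  tab <- table(x$meta$cell_state)
  cat("Expression study:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n  states:",
      paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.evo_study <- function(x) dim(x$values)

#' Read an expression study from delimited files
#'
#' The expression table has `gene_id` as its first column and one column
#' per sample; the metadata table has columns `sample_id`, `cell_state`,
#' `replicate`. Delimiter is auto-detected from the extension (`.csv` =
#' comma, anything else tab).
#'
#' @param expr_path,meta_path File paths.
#' @return An [evo_study()] object.
#' @export
read_expression <- function(expr_path, meta_path) {
  sep_of <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  expr <- utils::read.delim(expr_path, sep = sep_of(expr_path),
                            header = TRUE, stringsAsFactors = FALSE,
                            check.names = FALSE)
  meta <- utils::read.delim(meta_path, sep = sep_of(meta_path),
                            header = TRUE, stringsAsFactors = FALSE)
  gene_id <- expr[[1L]]
  values <- as.matrix(expr[, -1L, drop = FALSE])
  idx <- match(colnames(values), meta$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from metadata: ",
         paste(utils::head(colnames(values)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[idx, , drop = FALSE]
  evo_study(values, gene_id, meta$cell_state,
            replicate = meta$replicate, sample_id = meta$sample_id)
}

#' Standardize a vector to mean zero, sample SD one
#'
#' Expresses values in standard deviations around zero (sample SD,
#' denominator n-1). Constant vectors and vectors shorter than 2 are
#' errors.
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @examples
#' standardize_sample(c(1, 2, 3))  # -1 0 1
#' @export
standardize_sample <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values to standardize",
                           call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zero-variance (constant) vector cannot be standardized",
         call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Standardize every sample (column) of a study
#'
#' @param study An [evo_study()].
#' @return A new `evo_study` whose columns each have mean 0 and SD 1.
#' @export
standardize_study <- function(study) {
  stopifnot(inherits(study, "evo_study"))
  study$values <- apply(study$values, 2L, standardize_sample)
  study
}

#' Pairwise whole-transcriptome normalization by mean
#'
#' Multiplicatively rescales two studies so both whole-matrix means equal
#' the grand mean of the pair, preserving relative within-matrix
#' expression. Used for per-gene comparisons of absolute levels. The gene
#' universes are intersected (count reported via attribute `n_dropped`).
#'
#' @param a,b [evo_study()] objects with non-negative processed values and
#'   positive whole-matrix means.
#' @return List with elements `a` and `b`, the rescaled studies restricted
#'   to the common gene universe.
#' @export
mean_normalize_pair <- function(a, b) {
  stopifnot(inherits(a, "evo_study"), inherits(b, "evo_study"))
  common <- intersect(rownames(a$values), rownames(b$values))
  if (!length(common)) stop("no genes in common", call. = FALSE)
  dropped <- (nrow(a$values) - length(common)) +
             (nrow(b$values) - length(common))
  a$values <- a$values[common, , drop = FALSE]
  b$values <- b$values[common, , drop = FALSE]
  ma <- mean(a$values); mb <- mean(b$values)
  if (ma <= 0 || mb <= 0) {
    stop("mean normalization requires positive whole-matrix means ",
         "(non-negative processed values)", call. = FALSE)
  }
  grand <- mean(c(ma, mb))
  a$values <- a$values * (grand / ma)
  b$values <- b$values * (grand / mb)
  out <- list(a = a, b = b)
  attr(out, "n_dropped") <- dropped
  out
}

#' Per-gene expression fold between two cell states
#'
#' On the `standardized` scale the fold is the difference of state means
#' in per-sample SD units (standardized values can be negative, so a
#' ratio would be undefined; the profile figures plot signed folds around
#' zero). On the `mean_normalized` scale the fold is the ratio of state
#' means, used for absolute-level analyses; genes with zero reference
#' mean are dropped with a warning.
#'
#' @param study An [evo_study()].
#' @param test_state,ref_state Cell-state labels present in the study.
#' @param scale `"standardized"` (default) or `"mean_normalized"`.
#' @return A `fold_table` data.frame with columns `gene_id`, `fold`, in
#'   the study's gene order; attribute `scale` records the scale.
#' @export
compute_fold <- function(study, test_state, ref_state,
                         scale = c("standardized", "mean_normalized")) {
  stopifnot(inherits(study, "evo_study"))
  scale <- match.arg(scale)
  states <- study$meta$cell_state
  for (st in c(test_state, ref_state)) {
    if (!st %in% states) {
      stop("unknown cell state '", st, "'; available: ",
           paste(unique(states), collapse = ", "), call. = FALSE)
    }
  }
  test_idx <- which(states == test_state)
  ref_idx <- which(states == ref_state)
  vals <- study$values
  if (scale == "standardized") {
    vals <- apply(vals, 2L, standardize_sample)
    fold <- rowMeans(vals[, test_idx, drop = FALSE]) -
            rowMeans(vals[, ref_idx, drop = FALSE])
    keep <- rep(TRUE, nrow(vals))
  } else {
    mt <- rowMeans(vals[, test_idx, drop = FALSE])
    mr <- rowMeans(vals[, ref_idx, drop = FALSE])
    keep <- mr != 0
    if (any(!keep)) {
      warning(sum(!keep), " gene(s) dropped: zero reference mean on ratio scale",
              call. = FALSE)
    }
    fold <- mt[keep] / mr[keep]
  }
  out <- data.frame(gene_id = rownames(study$values)[keep],
                    fold = unname(fold), stringsAsFactors = FALSE)
  if (any(!is.finite(out$fold))) {
    stop("non-finite fold values produced", call. = FALSE)
  }
  class(out) <- c("fold_table", "data.frame")
  attr(out, "scale") <- scale
  attr(out, "test_state") <- test_state
  attr(out, "ref_state") <- ref_state
  out
}
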