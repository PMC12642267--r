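# Gene-level evolutionary / stemness annotations.
#
# The annotation table is an ordinary data.frame (one row per gene) carrying
# the phylostratum (ordinal gene age, 1 = cellular organisms ... 17 =
# Hominidae), the multicellularity gene index (MGI, family-level deep
# dating), stemness compendium scores and the oncofetal flag. All
# downstream class memberships (UC vs MC, deep-UC vs MC-family, stem vs
# non-stem) derive from it.

#' Read a gene annotation table
#'
#' Reads a TSV with columns `gene_id`, `phylostratum`, `mgi`,
#' `multi_score`, `pluri_score`, `stem_score`, `oncofetal` (header
#' required; empty cells are missing values). Gene identifiers are
#' whitespace-stripped and case-folded; duplicate identifiers keep the
#' first row with a warning. Validation is as in [validate_annotations()].
#'
#' @param path Path to the annotation TSV.
#' @return A validated annotation `data.frame`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_annotations(ann)
}

#' Validate (and canonicalize) an annotation table
#'
#' Checks the invariants of the annotation table: `phylostratum` in 1..17
#' when present, `0 < mgi <= 1` when present, non-negative integer scores,
#' unique gene identifiers (first kept, warning). The convention
#' `stem_score >= max(multi_score, pluri_score)` is checked with a warning
#' only, since upstream compendia disagree on how the integrated score is
#' formed.
#'
#' @param ann A data.frame with at least a `gene_id` column.
#' @return The canonicalized annotation data.frame.
#' @export
validate_annotations <- function(ann) {
  stopifnot(is.data.frame(ann))
  if (!"gene_id" %in% names(ann)) {
    stop("annotation table must have a 'gene_id' column", call. = FALSE)
  }
  ann$gene_id <- .norm_id(ann$gene_id)
  dup <- duplicated(ann$gene_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate gene_id row(s) dropped (first kept)",
            call. = FALSE)
    ann <- ann[!dup, , drop = FALSE]
  }
  if ("phylostratum" %in% names(ann)) {
    ps <- ann$phylostratum
    bad <- !is.na(ps) & (ps != as.integer(ps) | ps < 1 | ps > 17)
    if (any(bad)) {
      stop("phylostratum values outside 1..17: ",
           paste(utils::head(unique(ps[bad]), 5), collapse = ", "),
           call. = FALSE)
    }
    ann$phylostratum <- as.integer(ps)
  }
  if ("mgi" %in% names(ann)) {
    m <- ann$mgi
    bad <- !is.na(m) & (m <= 0 | m > 1)
    if (any(bad)) {
      stop("mgi values outside (0, 1]: ",
           paste(utils::head(signif(unique(m[bad]), 7), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  for (col in c("multi_score", "pluri_score", "stem_score")) {
    if (col %in% names(ann)) {
      v <- ann[[col]]
      if (any(!is.na(v) & (v < 0 | v != as.integer(v)))) {
        stop("'", col, "' must be non-negative integers", call. = FALSE)
      }
      ann[[col]] <- as.integer(v)
    }
  }
  if (all(c("stem_score", "multi_score", "pluri_score") %in% names(ann))) {
    viol <- !is.na(ann$stem_score) &
      ann$stem_score < pmax(ann$multi_score, ann$pluri_score, na.rm = TRUE)
    if (any(viol, na.rm = TRUE)) {
      warning(sum(viol, na.rm = TRUE),
              " gene(s) violate stem_score >= max(multi, pluri) convention",
              call. = FALSE)
    }
  }
  if ("oncofetal" %in% names(ann)) {
    ann$oncofetal <- as.logical(ann$oncofetal)
  }
  rownames(ann) <- NULL
  ann
}

#' Evolutionary origin class of a gene
#'
#' The first three phylostrata (cellular organisms, Eukaryota,
#' Opisthokonta) predate multicellularity; genes dated there are
#' unicellular-origin (`"UC"`), phylostrata 4 (Metazoa) through 17
#' (Hominidae) are multicellular-origin (`"MC"`). Missing ages map to
#' `"UNKNOWN"`.
#'
#' @param phylostratum Integer vector of gene ages (1..17), `NA` allowed.
#' @return Character vector in `{"UC","MC","UNKNOWN"}`.
#' @examples
#' evodevo_class(c(1, 3, 4, 17, NA))
#' @export
evodevo_class <- function(phylostratum) {
  out <- rep("UNKNOWN", length(phylostratum))
  out[!is.na(phylostratum) & phylostratum <= 3] <- "UC"
  out[!is.na(phylostratum) & phylostratum >= 4] <- "MC"
  out
}

#' Deep gene-family dating class from the multicellularity gene index
#'
#' MGI = 1 means the gene family occurs only in multicellular organisms
#' (`"MC_FAMILY"`); MGI < 1 means the family has a deep unicellular origin
#' (`"DEEP_UC"`). Values outside (0, 1] are a validation error.
#'
#' @param mgi Numeric vector in (0, 1], `NA` allowed.
#' @return Character vector in `{"DEEP_UC","MC_FAMILY","UNKNOWN"}`.
#' @export
mgi_class <- function(mgi) {
  bad <- !is.na(mgi) & (mgi <= 0 | mgi > 1)
  if (any(bad)) {
    stop("mgi values outside (0, 1]: ",
         paste(utils::head(signif(unique(mgi[bad]), 7), 5), collapse = ", "),
         call. = FALSE)
  }
  out <- rep("UNKNOWN", length(mgi))
  out[!is.na(mgi) & mgi == 1] <- "MC_FAMILY"
  out[!is.na(mgi) & mgi < 1] <- "DEEP_UC"
  out
}

#' Stemness flag
#'
#' A gene is a stemness gene iff its integrated stem score is positive;
#' the zero score means non-stemness.
#'
#' @param stem_score Integer vector of integrated stemness scores.
#' @return Logical vector (`NA` where the score is missing).
#' @export
is_stem <- function(stem_score) {
  ifelse(is.na(stem_score), NA, stem_score > 0)
}
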