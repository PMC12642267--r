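# Gene Ontology DAG handling: loading (child/parent TSV or minimal OBO),
# acyclicity validation, ancestor-closure propagation of gene annotations.
# Propagation is needed because many genes are mapped only to specific
# subcategories and not to the general category being scored.

#' Construct a GO DAG from child/parent edges
#'
#' @param child,parent Character vectors of equal length; each pair is one
#'   `child is_a parent` edge.
#' @param terms Optional character vector of known terms; defaults to the
#'   union of edge endpoints. Terms with no parent are roots.
#' @return An object of class `go_dag` with elements `terms`, `edges`
#'   (two-column character matrix), `parents` (named list term -> parent
#'   terms) and `roots`.
#' @export
go_dag <- function(child, parent, terms = NULL) {
  child <- as.character(child)
  parent <- as.character(parent)
  if (length(child) != length(parent)) {
    stop("'child' and 'parent' must have equal length", call. = FALSE)
  }
  terms <- sort(unique(c(terms, child, parent)))
  parents <- split(parent, factor(child, levels = terms))
  parents <- lapply(parents, unique)
  dag <- structure(
    list(terms = terms,
         edges = cbind(child = child, parent = parent),
         parents = parents,
         roots = setdiff(terms, unique(child))),
    class = "go_dag"
  )
  .check_acyclic(dag)
  dag
}

# Kahn topological sort; stops naming one term on a residual cycle.
.check_acyclic <- function(dag) {
  indeg <- vapply(dag$parents, length, 1L)  # edges child -> parent
  names(indeg) <- dag$terms
  # process terms whose all parents are done: reverse orientation is fine
  # for cycle detection, use out-degree (number of parents) as in-degree of
  # the child in the parent->child order.
  remaining <- indeg
  children_of <- split(dag$edges[, "child"], dag$edges[, "parent"])
  queue <- names(remaining)[remaining == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children_of[[t]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(dag$terms)) {
    cyc <- names(remaining)[remaining > 0L]
    stop("GO DAG contains a cycle involving term(s): ",
         paste(utils::head(cyc, 3), collapse = ", "), call. = FALSE)
  }
  invisible(dag)
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO DAG:", length(x$terms), "terms,", nrow(x$edges), "is_a edges,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

#' Read a GO DAG
#'
#' Two dialects are accepted: a two-column `child<TAB>parent` TSV (no
#' header, or a header line starting with `child`), and a minimal OBO
#' parse recognizing `[Term]` stanzas with `id:` and `is_a:` lines only
#' (relationship types other than `is_a` are ignored).
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.obo` vs anything else),
#'   `"tsv"` or `"obo"`.
#' @return A [go_dag()] object.
#' @export
read_go_dag <- function(path, format = c("auto", "tsv", "obo")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.obo$", path, ignore.case = TRUE)) "obo" else "tsv"
  }
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) && grepl("^child\\b", lines[[1L]], ignore.case = TRUE)) {
      lines <- lines[-1L]
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L)) {
      stop("GO DAG TSV must have two tab-separated columns", call. = FALSE)
    }
    child <- vapply(parts, `[[`, "", 1L)
    parent <- vapply(parts, `[[`, "", 2L)
    go_dag(trimws(child), trimws(parent))
  } else {
    lines <- readLines(path)
    child <- character(); parent <- character(); terms <- character()
    cur <- NA_character_
    in_term <- FALSE
    for (ln in lines) {
      ln <- trimws(ln)
      if (ln == "[Term]") { in_term <- TRUE; cur <- NA_character_; next }
      if (grepl("^\\[", ln)) { in_term <- FALSE; next }
      if (!in_term) next
      if (grepl("^id:", ln)) {
        cur <- trimws(sub("^id:", "", ln))
        terms <- c(terms, cur)
      } else if (grepl("^is_a:", ln) && !is.na(cur)) {
        p <- trimws(sub("^is_a:", "", ln))
        p <- trimws(sub("!.*$", "", p))  # strip trailing name comment
        child <- c(child, cur); parent <- c(parent, p)
      }
    }
    go_dag(child, parent, terms = terms)
  }
}

#' Read gene -> GO term annotations
#'
#' Two-column `gene_id<TAB>term_id` TSV (optional header). Returns the
#' direct (unpropagated) annotation map.
#'
#' @param path File path.
#' @return Named list: gene_id -> character vector of directly annotated
#'   terms.
#' @export
read_go_annotations <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("gene_id", "term_id"))
  if (nrow(tab) && .norm_id(tab$gene_id[[1L]]) == "GENE_ID") {
    tab <- tab[-1L, , drop = FALSE]
  }
  split(trimws(tab$term_id), .norm_id(tab$gene_id))
}

# Ancestors (exclusive) of every term, memoized over the whole DAG.
.go_ancestors <- function(dag) {
  anc <- vector("list", length(dag$terms))
  names(anc) <- dag$terms
  done <- logical(length(dag$terms)); names(done) <- dag$terms
  get_anc <- function(t) {
    if (done[[t]]) return(anc[[t]])
    ps <- dag$parents[[t]]
    res <- character()
    for (p in ps) res <- c(res, p, get_anc(p))
    res <- unique(res)
    anc[[t]] <<- res
    done[[t]] <<- TRUE
    res
  }
  for (t in dag$terms) get_anc(t)
  anc
}

#' Propagate gene annotations up the GO DAG
#'
#' A gene is a member of term T iff it is directly annotated to T or to
#' any descendant of T: each gene's term set is closed under `is_a`
#' ancestry. The output is a superset of the direct annotations, and
#' propagation is idempotent.
#'
#' @param dag A [go_dag()] object.
#' @param direct Named list gene_id -> character vector of term ids; every
#'   term must exist in `dag`.
#' @return Named list gene_id -> propagated term set (sorted, unique).
#' @export
propagate_go <- function(dag, direct) {
  stopifnot(inherits(dag, "go_dag"), is.list(direct))
  all_terms <- unique(unlist(direct, use.names = FALSE))
  unknown <- setdiff(all_terms, dag$terms)
  if (length(unknown)) {
    stop("unknown GO term(s) in annotations: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  anc <- .go_ancestors(dag)
  lapply(direct, function(ts) {
    ts <- unique(ts)
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
}

#' Member genes of a GO signature
#'
#' @param propagated Named list gene_id -> propagated term set (from
#'   [propagate_go()]).
#' @param signature_id A term identifier present somewhere in the
#'   propagated map (otherwise an error lists the available terms).
#' @return Character vector of member gene ids.
#' @export
signature_members <- function(propagated, signature_id) {
  stopifnot(is.list(propagated), length(signature_id) == 1L)
  avail <- sort(unique(unlist(propagated, use.names = FALSE)))
  if (length(propagated) && !signature_id %in% avail) {
    stop("unknown signature term '", signature_id, "'; available: ",
         paste(utils::head(avail, 10), collapse = ", "),
         if (length(avail) > 10) ", ..." else "", call. = FALSE)
  }
  names(propagated)[vapply(propagated, function(ts) signature_id %in% ts,
                           logical(1L))]
}
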