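# Protein interactome: confidence-weighted undirected graph, centrality
# measures (degree local; stress and betweenness global), class-stratified
# centrality ANOM, differential-hub extraction, K-means module detection,
# and first-neighbor 'shell' propagation.

#' Construct a protein interaction network
#'
#' Undirected, confidence-weighted. Self-loops are dropped; duplicate
#' edges (in either orientation) keep the maximum confidence.
#'
#' @param from,to Character vectors of interacting node identifiers.
#' @param confidence Numeric vector in (0, 1], one value per edge.
#' @param nodes Optional extra node identifiers (kept even if isolated).
#' @return Object of class `interaction_network`: list with `nodes`
#'   (character) and `edges` (data.frame `from`, `to`, `confidence`,
#'   canonical orientation `from < to`).
#' @export
interaction_network <- function(from, to, confidence, nodes = NULL) {
  from <- .norm_id(from); to <- .norm_id(to)
  confidence <- as.numeric(confidence)
  if (length(from) != length(to) || length(from) != length(confidence)) {
    stop("'from', 'to' and 'confidence' must have equal length",
         call. = FALSE)
  }
  if (any(!is.na(confidence) & (confidence <= 0 | confidence > 1))) {
    stop("edge confidence must lie in (0, 1]", call. = FALSE)
  }
  keep <- from != to
  from <- from[keep]; to <- to[keep]; confidence <- confidence[keep]
  a <- pmin(from, to); b <- pmax(from, to)
  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    conf <- tapply(confidence, key, max)
    parts <- strsplit(names(conf), "\r", fixed = TRUE)
    a <- vapply(parts, `[[`, "", 1L)
    b <- vapply(parts, `[[`, "", 2L)
    confidence <- unname(conf)
  }
  nodes <- sort(unique(c(.norm_id(nodes), a, b)))
  structure(
    list(nodes = nodes,
         edges = data.frame(from = a, to = b, confidence = confidence,
                            stringsAsFactors = FALSE)),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges")
  if (nrow(x$edges)) {
    cat(sprintf(" (confidence %.2f-%.2f)", min(x$edges$confidence),
                max(x$edges$confidence)))
  }
  cat("\n")
  invisible(x)
}

#' Coerce an interaction network to an igraph object
#'
#' Edge confidence is carried as the `weight` edge attribute. Useful for
#' plotting and for independent cross-checks against igraph's own
#' centrality routines.
#'
#' @param net An [interaction_network()].
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  if (nrow(net$edges)) {
    igraph::E(g)$weight <- net$edges$confidence
  }
  g
}

#' Read a STRING-style edge list
#'
#' Columns `protein1`, `protein2`, `combined_score`, whitespace- or
#' tab-separated, header required. The score scale is auto-detected: a
#' maximum above 1 is taken to be the 0-1000 integer dialect and divided
#' by 1000.
#'
#' @param path File path.
#' @return An [interaction_network()].
#' @export
read_string_edges <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) {
    stop("edge list needs 3 columns: protein1, protein2, combined_score",
         call. = FALSE)
  }
  score <- as.numeric(tab[[3L]])
  if (max(score, na.rm = TRUE) > 1) score <- score / 1000
  interaction_network(tab[[1L]], tab[[2L]], score)
}

#' Filter edges by confidence
#'
#' Keeps edges with confidence strictly above `threshold` (the top-half
#' filter of the source database uses > 0.5). Isolated nodes are
#' retained.
#'
#' @param net An [interaction_network()].
#' @param threshold Confidence threshold in \[0, 1).
#' @return A filtered `interaction_network` with the same node set.
#' @export
filter_confidence <- function(net, threshold) {
  stopifnot(inherits(net, "interaction_network"))
  if (threshold < 0 || threshold >= 1) {
    stop("'threshold' must lie in [0, 1)", call. = FALSE)
  }
  net$edges <- net$edges[net$edges$confidence > threshold, , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

# Adjacency index lists for the Brandes sweep.
.adj_list <- function(net) {
  n <- length(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes)
  adj <- vector("list", n)
  if (nrow(net$edges)) {
    fi <- idx[net$edges$from]; ti <- idx[net$edges$to]
    for (e in seq_along(fi)) {
      adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
      adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
    }
  }
  adj
}

#' Centrality measures of an interaction network
#'
#' Degree (number of direct one-step interactions, local), stress (total
#' number of shortest paths between all pairs of other nodes passing
#' through a node, global load) and betweenness (like stress but each
#' pair's paths are weighted by the inverse of the pair's total shortest
#' path count, global brokerage). Shortest paths are unweighted —
#' confidence is a filter, not a distance — and each unordered pair is
#' counted once; node pairs in different components contribute nothing.
#'
#' @param net An [interaction_network()].
#' @return Object of class `centrality_table`: data.frame `node`,
#'   `degree`, `stress`, `betweenness`.
#' @export
centralities <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  n <- length(net$nodes)
  adj <- .adj_list(net)
  degree <- lengths(adj)
  stress <- numeric(n)
  betweenness <- numeric(n)
  for (s in seq_len(n)) {
    # BFS from s: sigma = shortest-path counts, preds = BFS DAG
    dist <- rep(-1L, n); sigma <- numeric(n)
    preds <- vector("list", n)
    dist[s] <- 0L; sigma[s] <- 1
    queue <- integer(n); queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    order_visited <- queue[seq_len(tail)]
    # dependency accumulation in reverse BFS order
    delta_b <- numeric(n)   # betweenness dependency
    npaths <- numeric(n)    # downward DAG path count (stress)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta_b[v] <- delta_b[v] + (sigma[v] / sigma[w]) * (1 + delta_b[w])
        npaths[v] <- npaths[v] + 1 + npaths[w]
      }
      if (w != s) {
        betweenness[w] <- betweenness[w] + delta_b[w]
        stress[w] <- stress[w] + sigma[w] * npaths[w]
      }
    }
  }
  structure(
    data.frame(node = net$nodes, degree = as.integer(degree),
               stress = stress / 2, betweenness = betweenness / 2,
               stringsAsFactors = FALSE),
    class = c("centrality_table", "data.frame")
  )
}

#' Class-stratified centrality comparison
#'
#' Restricts a centrality table to a set of (upregulated) genes,
#' partitions them into four classes — unicellular-origin and
#' pluripotent (`UC_pluri`), UC only (`UC_only`), pluripotent only
#' (`pluri_only`), neither (`neither`; pluripotent means
#' `pluri_score > 0`) — and fits an ANOM per centrality measure across
#' the classes. Empty classes are skipped with a warning (k reduced).
#'
#' @param cent A `centrality_table` from [centralities()].
#' @param upregulated Character vector of gene ids to analyze.
#' @param ann Annotation table with `phylostratum` and `pluri_score`.
#' @param alpha Family-wise significance level.
#' @return Object of class `centrality_anom`: list of `anom` fits (one
#'   per measure) plus `class_means` (measure x class matrix) and
#'   `class_sizes`.
#' @export
centrality_by_class <- function(cent, upregulated, ann, alpha = 0.05) {
  stopifnot(inherits(cent, "centrality_table"))
  upregulated <- .norm_id(upregulated)
  sub <- cent[cent$node %in% upregulated, , drop = FALSE]
  if (!nrow(sub)) stop("no upregulated genes present in the network",
                       call. = FALSE)
  m <- match(sub$node, ann$gene_id)
  uc <- evodevo_class(ann$phylostratum[m]) == "UC"
  pluri <- !is.na(ann$pluri_score[m]) & ann$pluri_score[m] > 0
  cls <- ifelse(uc & pluri, "UC_pluri",
         ifelse(uc, "UC_only",
         ifelse(pluri, "pluri_only", "neither")))
  cls <- factor(cls, levels = c("UC_pluri", "UC_only", "pluri_only",
                                "neither"))
  empty <- levels(cls)[table(cls) == 0L]
  if (length(empty)) {
    warning("empty class(es) skipped: ", paste(empty, collapse = ", "),
            call. = FALSE)
    cls <- droplevels(cls)
  }
  if (nlevels(cls) < 2L) {
    stop("fewer than 2 non-empty classes after stratification",
         call. = FALSE)
  }
  measures <- c("degree", "stress", "betweenness")
  fits <- lapply(measures, function(meas) {
    anom(split(as.numeric(sub[[meas]]), cls), alpha = alpha)
  })
  names(fits) <- measures
  class_means <- vapply(fits, function(f) {
    stats::setNames(f$mean, f$group)[levels(cls)]
  }, numeric(nlevels(cls)))
  structure(
    list(fits = fits, class_means = t(class_means),
         class_sizes = table(cls)),
    class = "centrality_anom"
  )
}

#' @export
print.centrality_anom <- function(x, digits = 4, ...) {
  cat("Class-stratified centrality (n per class: ",
      paste(sprintf("%s=%d", names(x$class_sizes), x$class_sizes),
            collapse = ", "), ")\n", sep = "")
  print(signif(x$class_means, digits))
  for (meas in names(x$fits)) {
    f <- x$fits[[meas]]
    sig <- f$group[f$flag != "ns"]
    cat(meas, ": ",
        if (length(sig)) paste(sprintf("%s %s", sig,
                                       f$flag[f$flag != "ns"]),
                               collapse = ", ") else "no flags", "\n",
        sep = "")
  }
  invisible(x)
}

#' Extract up- and downregulated interaction hubs
#'
#' A hub has more than `min_degree` interactants (strictly: degree
#' `>= min_degree + 1`) in the network filtered at confidence
#' `> conf`, together with a strong expression fold. On the ratio scale
#' an up-hub needs `fold > min_fold` and a down-hub
#' `fold < 1/min_fold`; on the standardized scale the down rule is
#' `fold < -min_fold`. Genes absent from the fold table are excluded.
#'
#' @param net An [interaction_network()].
#' @param folds A `fold_table` (its `scale` attribute selects the down
#'   rule).
#' @param min_degree Minimum interactant count, exceeded strictly.
#' @param conf Edge-confidence threshold, exceeded strictly.
#' @param min_fold Fold threshold, exceeded strictly.
#' @return List with character vectors `up` and `down`, attribute `net`
#'   (the confidence-filtered network).
#' @export
extract_hubs <- function(net, folds, min_degree = 5L, conf = 0.7,
                         min_fold = 2) {
  stopifnot(inherits(net, "interaction_network"), is.data.frame(folds))
  if (min_degree <= 0 || min_fold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  fnet <- filter_confidence(net, conf)
  deg <- stats::setNames(rep(0L, length(fnet$nodes)), fnet$nodes)
  tab <- table(c(fnet$edges$from, fnet$edges$to))
  deg[names(tab)] <- as.integer(tab)
  fold <- stats::setNames(folds$fold, folds$gene_id)[names(deg)]
  scale <- attr(folds, "scale")
  if (is.null(scale)) scale <- "mean_normalized"
  hubby <- !is.na(fold) & deg >= min_degree + 1L
  up <- hubby & fold > min_fold
  down <- if (scale == "standardized") hubby & fold < -min_fold
          else hubby & fold < 1 / min_fold
  structure(list(up = names(deg)[up], down = names(deg)[down]),
            net = fnet, class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat("Hubs:", length(x$up), "up,", length(x$down), "down\n")
  invisible(x)
}

#' Cluster hubs into interactome modules by K-means
#'
#' Each hub's feature vector is its connectivity profile: the row of the
#' hub-subnetwork adjacency matrix weighted by edge confidence. K-means
#' under a fixed seed gives a deterministic assignment.
#'
#' @param net An [interaction_network()] (typically the filtered network
#'   attached to a hub set).
#' @param hubs Character vector of hub gene ids (>= k).
#' @param k Number of clusters.
#' @param seed RNG seed for the K-means starts.
#' @return List with `cluster` (named integer assignment), `tot_withinss`
#'   and `features` description.
#' @export
cluster_hubs <- function(net, hubs, k, seed = 1L) {
  stopifnot(inherits(net, "interaction_network"))
  hubs <- .norm_id(hubs)
  if (k > length(hubs)) stop("k exceeds the number of hubs", call. = FALSE)
  sub <- net$edges[net$edges$from %in% hubs & net$edges$to %in% hubs, ,
                   drop = FALSE]
  adj <- matrix(0, length(hubs), length(hubs),
                dimnames = list(hubs, hubs))
  if (nrow(sub)) {
    adj[cbind(sub$from, sub$to)] <- sub$confidence
    adj[cbind(sub$to, sub$from)] <- sub$confidence
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  fit <- stats::kmeans(adj, centers = k, nstart = 25L, iter.max = 100L)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(cluster = stats::setNames(fit$cluster, hubs),
       tot_withinss = fit$tot.withinss,
       features = "confidence-weighted connectivity profile")
}

#' First-neighbor shell of a seed gene set
#'
#' The seeds plus all their direct interaction partners in the
#' (confidence-filtered) network — the network-propagation neighborhood.
#' Seeds absent from the network are reported via the `missing`
#' attribute.
#'
#' @param net An [interaction_network()].
#' @param seeds Non-empty character vector of seed gene ids.
#' @return Character vector of shell members (seeds union neighbors),
#'   attribute `missing`.
#' @export
shell <- function(net, seeds) {
  stopifnot(inherits(net, "interaction_network"))
  seeds <- unique(.norm_id(seeds))
  if (!length(seeds)) stop("empty seed set", call. = FALSE)
  missing <- setdiff(seeds, net$nodes)
  present <- setdiff(seeds, missing)
  nb <- c(net$edges$to[net$edges$from %in% present],
          net$edges$from[net$edges$to %in% present])
  out <- sort(unique(c(present, nb)))
  attr(out, "missing") <- missing
  out
}
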