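# End-to-end pipeline: profile -> signatures -> score bins -> network ->
# PCA for each requested state pair, with TSV outputs and a
# machine-readable JSON summary. Every threshold actually applied is
# recorded in the summary so any number in it can be reproduced by
# calling the underlying operation directly.

.fnv_hash <- function(x) {
  # tiny stable config fingerprint (no external digest dependency);
  # polynomial rolling hash in double precision to stay exact
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 1e9
  sprintf("%09.0f", h)
}

.write_tsv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# evoaxis ",
                    as.character(utils::packageVersion("evoaxis")),
                    " config-hash ", stamp), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full evodevo-axis analysis
#'
#' Executes, for each test state against the reference state: the
#' standardized fold computation, the per-phylostratum evolutionary
#' profile with three-phase classification, MGI-class and stemness
#' signature folds (plus any GO signatures if a propagated annotation
#' map is supplied), pluripotency / multipotency score-bin profiles,
#' hub extraction with K-means module clustering, class-stratified
#' centrality on the upregulated genes, and finally the study-wide
#' gene-wise PCA with the PC1-age correlation and per-state UC/MC
#' ratios (on the positive-scale study, when given).
#'
#' @param study An [evo_study()] (additive/log-like scale).
#' @param annotation Validated annotation table.
#' @param network Optional [interaction_network()].
#' @param go Optional list with elements `dag` ([go_dag()]) and `direct`
#'   (gene -> term map); enables GO signature folds and the cell-cycle
#'   exclusion control.
#' @param study_positive Optional strictly positive copy of the study for
#'   ratio-scale readouts (UC/MC ratio, TAI).
#' @param test_states Test state labels; default: all non-reference
#'   states in the study.
#' @param ref_state Reference state label.
#' @param alpha Family-wise significance level used throughout.
#' @param min_conf,hub_conf,hub_degree,hub_fold Network thresholds
#'   (confidence filter, hub confidence, hub interactant count, hub
#'   fold).
#' @param upreg_fold Standardized fold above which a gene counts as
#'   upregulated for the class-stratified centrality analysis.
#' @param k_up,k_down K-means cluster counts for up-/down-hub modules.
#' @param seed Seed for the K-means starts.
#' @param out_dir Optional output directory: per-pair profile and
#'   signature TSVs plus `summary.json` are written there; on any stage
#'   error the partial outputs are removed.
#' @return (Invisibly) the report bundle: a list with one entry per test
#'   state (profile, classification, signature folds, score-bin
#'   profiles, hubs, clusters, centrality ANOM) plus `pca`, `pc1_age`,
#'   `uc_mc_ratio`, `tai` and `summary` (the JSON-ready list).
#' @export
run_full <- function(study, annotation, network = NULL, go = NULL,
                     study_positive = NULL, test_states = NULL,
                     ref_state = "initial", alpha = 0.05,
                     min_conf = 0.5, hub_conf = 0.7, hub_degree = 5L,
                     hub_fold = 2, upreg_fold = 0.5,
                     k_up = 4L, k_down = 2L, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(study, "evo_study"))
  .check_alpha(alpha)
  stamp <- .fnv_hash(list(alpha, min_conf, hub_conf, hub_degree, hub_fold,
                          upreg_fold, k_up, k_down, seed))
  if (is.null(test_states)) {
    test_states <- setdiff(unique(study$meta$cell_state), ref_state)
  }
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (length(written)) unlink(written)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  emit <- function(df, fname) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      path <- file.path(out_dir, fname)
      .write_tsv(df, path, stamp)
      written <<- c(written, path)
    }
  }

  propagated <- NULL
  cc_genes <- NULL
  if (!is.null(go)) {
    propagated <- stage("go_propagation", propagate_go(go$dag, go$direct))
    if ("GO:0000278" %in% unlist(propagated, use.names = FALSE)) {
      cc_genes <- signature_members(propagated, "GO:0000278")
    }
  }

  per_pair <- list()
  summary_pairs <- list()
  for (ts in test_states) {
    folds <- stage("fold", compute_fold(study, ts, ref_state,
                                        scale = "standardized"))
    prof <- stage("profile",
                  evolutionary_profile(folds, annotation, alpha = alpha))
    label <- classify_three_phase(prof)
    emit(as.data.frame(prof), paste0("profile_", ts, ".tsv"))

    sigs <- list()
    mgi_cls <- mgi_class(annotation$mgi[match(folds$gene_id,
                                              annotation$gene_id)])
    sig_sets <- list(
      mgi_deep_uc = folds$gene_id[mgi_cls == "DEEP_UC"],
      mgi_mc_family = folds$gene_id[mgi_cls == "MC_FAMILY"],
      stemness = folds$gene_id[
        is_stem(annotation$stem_score[match(folds$gene_id,
                                            annotation$gene_id)])])
    if (!is.null(propagated)) {
      for (nm in names(evoaxis_signatures)) {
        term <- evoaxis_signatures[[nm]]
        if (!is.na(term) &&
            term %in% unlist(propagated, use.names = FALSE)) {
          sig_sets[[nm]] <- signature_members(propagated, term)
        }
      }
    }
    for (nm in names(sig_sets)) {
      mem <- intersect(sig_sets[[nm]], folds$gene_id)
      if (length(mem) && length(mem) < nrow(folds)) {
        sigs[[nm]] <- stage(paste0("signature_", nm),
                            signature_fold(folds, mem, alpha = alpha,
                                           label = nm))
      }
    }
    if (length(sigs)) {
      sig_df <- do.call(rbind, lapply(names(sigs), function(nm) {
        cbind(signature = nm, as.data.frame(sigs[[nm]]))
      }))
      emit(sig_df, paste0("signatures_", ts, ".tsv"))
    }

    score_bins <- list()
    for (sc in c("pluri_score", "multi_score")) {
      s <- stats::setNames(annotation[[sc]], annotation$gene_id)
      score_bins[[sc]] <- stage(paste0("score_bins_", sc),
                                score_bin_profile(folds, s, alpha = alpha))
    }

    netres <- NULL
    if (!is.null(network)) {
      netres <- stage("network", {
        fnet <- filter_confidence(network, min_conf)
        hubs <- extract_hubs(fnet, folds, min_degree = hub_degree,
                             conf = hub_conf, min_fold = hub_fold)
        clusters <- list()
        if (length(hubs$up) >= k_up) {
          clusters$up <- cluster_hubs(attr(hubs, "net"), hubs$up, k_up,
                                      seed = seed)
        }
        if (length(hubs$down) >= k_down) {
          clusters$down <- cluster_hubs(attr(hubs, "net"), hubs$down,
                                        k_down, seed = seed)
        }
        cent <- centralities(fnet)
        upreg <- folds$gene_id[folds$fold > upreg_fold]
        strat <- tryCatch(
          centrality_by_class(cent, upreg, annotation, alpha = alpha),
          error = function(e) NULL)
        list(hubs = hubs, clusters = clusters, centrality = cent,
             stratified = strat)
      })
    }

    per_pair[[ts]] <- list(folds = folds, profile = prof,
                           classification = label, signatures = sigs,
                           score_bins = score_bins, network = netres)
    summary_pairs[[ts]] <- list(
      classification = label,
      profile_flags = stats::setNames(as.character(prof$flag),
                                      prof$phylostratum),
      signature_flags = lapply(sigs, function(s) {
        stats::setNames(as.character(s$flag), s$side)
      }),
      n_hubs_up = if (!is.null(netres)) length(netres$hubs$up) else NA,
      n_hubs_down = if (!is.null(netres)) length(netres$hubs$down) else NA)
  }

  pos <- if (!is.null(study_positive)) study_positive else NULL
  ratios <- NULL; tais <- NULL
  if (!is.null(pos)) {
    states <- unique(pos$meta$cell_state)
    ratios <- stage("uc_mc_ratio", vapply(states, function(st) {
      uc_mc_ratio(pos, annotation, st)
    }, 0))
    ps <- stats::setNames(annotation$phylostratum, annotation$gene_id)
    tais <- stage("tai", vapply(states, function(st) {
      cols <- pos$meta$cell_state == st
      tai(rowMeans(pos$values[, cols, drop = FALSE]),
          ps[rownames(pos$values)])
    }, 0))
  }
  pca <- stage("pca", pca_genes(
    if (!is.null(pos)) pos else study,
    scale = if (!is.null(pos)) "mean_normalized" else "standardized"))
  rho <- stage("pc1_age", pc1_age_correlation(
    pca, stats::setNames(annotation$phylostratum, annotation$gene_id)))

  summary <- list(
    version = as.character(utils::packageVersion("evoaxis")),
    config_hash = stamp,
    thresholds = list(alpha = alpha, min_conf = min_conf,
                      hub_conf = hub_conf, hub_degree = hub_degree,
                      hub_fold = hub_fold, upreg_fold = upreg_fold,
                      k_up = k_up, k_down = k_down, seed = seed),
    ref_state = ref_state, pairs = summary_pairs,
    uc_mc_ratio = as.list(ratios), tai = as.list(tais),
    pc1_variance_fraction = pca$var_fraction[[1L]],
    pc1_age_rho = rho$rho, pc1_age_p = rho$p_value)
  if (!is.null(out_dir)) {
    path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, path)
  }
  invisible(c(per_pair = list(per_pair),
              list(pca = pca, pc1_age = rho, uc_mc_ratio = ratios,
                   tai = tais, summary = summary)))
}
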