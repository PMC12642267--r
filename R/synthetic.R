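# Synthetic study generator: annotation table, core-periphery
# interactome and four-state expression study with planted UC/MC-shift
# effects, so every analysis stage is testable without external data.
#
# Expression is simulated on a log-like additive scale (Gaussian around a
# per-gene baseline); a strictly positive exponentiated copy is returned
# for ratio-scale paths (UC/MC ratio, TAI, oncofetal folds). State
# effects are specified in standardized per-sample SD units and are
# internally scaled by sqrt(baseline_sd^2 + noise_sd^2), so the
# standardized-scale fold recovers the planted delta directly.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Configuration for the synthetic study generator
#'
#' Defaults emulate a four-state polyploid giant cancer cell (PGCC)
#' study: initial cells, PGCC (shifted toward multicellularity), early
#' progeny (the shift enhanced) and late progeny (partial backward
#' movement toward the initial, unicellular-biased position).
#'
#' @param n_genes Number of genes.
#' @param ps_weights Unnormalized phylostratum weights over 1..17
#'   (default: a decreasing age histogram; the first three, unicellular,
#'   strata hold about half the genes, as in human gene dating).
#' @param states Cell-state labels.
#' @param n_rep Replicates per state.
#' @param state_effects Named list state -> c(delta_uc, delta_mc):
#'   planted shifts, in standardized SD units, added to unicellular
#'   (phylostrata 1-3) and late-multicellular (12-17) genes.
#' @param baseline_mean,baseline_sd Per-gene baseline expression
#'   (log2-like units).
#' @param age_slope Linear trend of baseline on phylostratum (default
#'   -0.2 per stratum: older genes are expressed higher).
#' @param noise_sd Replicate noise SD.
#' @param deep_uc_base,deep_uc_decay Probability that a gene's family has
#'   deep unicellular origin (MGI < 1): `min(1, base - decay * (ps - 1))`
#'   floored at 0.05, decreasing with the stratum.
#' @param multi_mean,pluri_mean Poisson means of the multipotency /
#'   pluripotency database counts.
#' @param pluri_uc_enrichment Multiplier on `pluri_mean` for UC genes.
#' @param n_oncofetal Number of genes flagged oncofetal.
#' @param n_network_genes Genes carried into the interactome.
#' @param p_core,p_periph,p_cross Edge probabilities for UC-UC, MC-MC and
#'   cross pairs (core-periphery structure; `p_core >= p_periph`).
#' @param conf_range Edge-confidence range (uniform draw).
#' @param seed RNG seed; the same seed reproduces the dataset
#'   bit-identically.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 10000L,
                         ps_weights = c(30, 18, 10, 9, 8, 7, 6, 5, 4,
                                        3.5, 3, 2.5, 2, 1.8, 1.5, 1.2, 1),
                         states = c("initial", "pgcc", "early_progeny",
                                    "late_progeny"),
                         n_rep = 3L,
                         state_effects = list(
                           initial = c(delta_uc = 0, delta_mc = 0),
                           pgcc = c(delta_uc = -0.3, delta_mc = 0.3),
                           early_progeny = c(delta_uc = -0.45,
                                             delta_mc = 0.45),
                           late_progeny = c(delta_uc = -0.1,
                                            delta_mc = 0.1)),
                         baseline_mean = 8, baseline_sd = 3,
                         age_slope = -0.2, noise_sd = 1,
                         deep_uc_base = 1, deep_uc_decay = 0.06,
                         multi_mean = 0.5, pluri_mean = 0.25,
                         pluri_uc_enrichment = 3,
                         n_oncofetal = 33L,
                         n_network_genes = 300L,
                         p_core = 0.15, p_periph = 0.02, p_cross = 0.05,
                         conf_range = c(0.4, 1), seed = 1L) {
  if (length(ps_weights) != 17L || any(ps_weights < 0)) {
    stop("'ps_weights' must be 17 non-negative weights", call. = FALSE)
  }
  probs <- c(p_core, p_periph, p_cross)
  if (any(probs < 0 | probs > 1)) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  rm(probs)
  if (p_core < p_periph) {
    stop("core-periphery structure requires p_core >= p_periph",
         call. = FALSE)
  }
  if (noise_sd <= 0) stop("'noise_sd' must be positive", call. = FALSE)
  if (!identical(sort(names(state_effects)), sort(states))) {
    stop("'state_effects' must name every state", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic annotation + interactome + expression dataset
#'
#' @param config A [synth_config()].
#' @return List of class `synth_dataset` with elements:
#'   * `annotation` — gene annotation data.frame (phylostratum, mgi,
#'     multi/pluri/stem scores, oncofetal flag);
#'   * `network` — core-periphery [interaction_network()] over a gene
#'     subset;
#'   * `study` — additive-scale [evo_study()] (four states x replicates);
#'   * `study_positive` — the exponentiated (`2^x`) strictly positive
#'     copy for ratio-scale analyses;
#'   * `truth` — ground-truth record (UC / late-MC gene sets, planted
#'     per-state effects in SD units, the internal effect scaling, the
#'     network gene subset) sufficient to score any recovery test.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    n <- as.integer(config$n_genes)
    gene_id <- sprintf("G%05d", seq_len(n))
    ps <- sample.int(17L, n, replace = TRUE,
                     prob = config$ps_weights / sum(config$ps_weights))
    uc <- ps <= 3L
    late <- ps >= 12L
    p_deep <- pmax(0.05, pmin(1, config$deep_uc_base -
                                config$deep_uc_decay * (ps - 1)))
    deep <- stats::runif(n) < p_deep
    mgi <- ifelse(deep, stats::runif(n, 0.2, 0.99), 1)
    pluri_mu <- ifelse(uc, config$pluri_mean * config$pluri_uc_enrichment,
                       config$pluri_mean)
    multi <- stats::rpois(n, config$multi_mean)
    pluri <- stats::rpois(n, pluri_mu)
    onco <- rep(FALSE, n)
    onco[sample.int(n, min(config$n_oncofetal, n))] <- TRUE
    annotation <- data.frame(
      gene_id = gene_id, phylostratum = ps, mgi = mgi,
      multi_score = multi, pluri_score = pluri,
      stem_score = multi + pluri, oncofetal = onco,
      stringsAsFactors = FALSE)

    # expression: baseline with age trend, planted state effects, noise
    baseline <- stats::rnorm(n, config$baseline_mean +
                               config$age_slope * (ps - mean(1:17)),
                             config$baseline_sd)
    eff_scale <- sqrt(config$baseline_sd^2 + config$noise_sd^2)
    states_per_col <- rep(config$states, each = config$n_rep)
    vals <- matrix(NA_real_, n, length(states_per_col))
    for (j in seq_along(states_per_col)) {
      eff <- config$state_effects[[states_per_col[j]]]
      shift <- numeric(n)
      shift[uc] <- eff[["delta_uc"]] * eff_scale
      shift[late] <- eff[["delta_mc"]] * eff_scale
      vals[, j] <- baseline + shift + stats::rnorm(n, 0, config$noise_sd)
    }
    study <- evo_study(vals, gene_id, states_per_col)
    study_pos <- study
    study_pos$values <- 2^study$values

    net <- .generate_network_impl(config, gene_id, uc)

    truth <- list(
      uc_genes = gene_id[uc], late_mc_genes = gene_id[late],
      state_effects = config$state_effects, effect_scale = eff_scale,
      network_genes = net$nodes, seed = config$seed)
    structure(list(annotation = annotation, network = net, study = study,
                   study_positive = study_pos, truth = truth),
              class = "synth_dataset")
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("Synthetic dataset:", nrow(x$annotation), "genes;",
      length(x$truth$uc_genes), "UC /", length(x$truth$late_mc_genes),
      "late-MC;", length(x$network$nodes), "network nodes\n")
  invisible(x)
}

# Core-periphery Bernoulli graph over a gene subset; UC genes form the
# dense ancient core.
.generate_network_impl <- function(config, gene_id, uc) {
  m <- min(as.integer(config$n_network_genes), length(gene_id))
  sel <- sort(sample.int(length(gene_id), m))
  ids <- gene_id[sel]; is_uc <- uc[sel]
  if (m < 2L) {
    return(interaction_network(character(), character(), numeric(),
                               nodes = ids))
  }
  pair <- utils::combn(m, 2L)
  i <- pair[1L, ]; j <- pair[2L, ]
  p <- ifelse(is_uc[i] & is_uc[j], config$p_core,
       ifelse(!is_uc[i] & !is_uc[j], config$p_periph, config$p_cross))
  hit <- stats::runif(length(p)) < p
  conf <- stats::runif(sum(hit), config$conf_range[1L],
                       config$conf_range[2L])
  interaction_network(ids[i[hit]], ids[j[hit]], conf, nodes = ids)
}

#' Generate only the synthetic core-periphery interactome
#'
#' UC-UC pairs connect with probability `p_core`, MC-MC with `p_periph`,
#' cross pairs with `p_cross`; with `p_core > p_cross > p_periph` the
#' expected mean degree of UC nodes exceeds that of MC nodes, emulating
#' the dense ancient unicellular center of the interactome.
#'
#' @param config A [synth_config()].
#' @return An [interaction_network()]; attribute `is_uc` marks the core
#'   nodes.
#' @export
generate_network <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    n <- as.integer(config$n_genes)
    gene_id <- sprintf("G%05d", seq_len(n))
    ps <- sample.int(17L, n, replace = TRUE,
                     prob = config$ps_weights / sum(config$ps_weights))
    net <- .generate_network_impl(config, gene_id, ps <= 3L)
    ps_sel <- ps[match(net$nodes, gene_id)]
    attr(net, "is_uc") <- ps_sel <= 3L
    net
  })
}
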