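#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the analysis the
#' package implements: PC-skeleton alpha 0.05 with conditioning order up to
#' 3, partial-correlation edge threshold 0.1, walktrap step length 4, a
#' 500-tree forest with 2/3 subsampling, 7 top clusters taken forward,
#' tenfold cross-validated elastic net over mixing grid {0.1, 0.5, 0.9},
#' PCA eigenvalue cutoff 2 and loading cutoff 0.40. One global seed fans
#' out to fixed per-stage seeds so toggling a stage never shifts another
#' stage's randomness.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param cohort_dir Directory with `subjects.csv`/`lipids.csv` to load; if
#'   `NULL`, a cohort is simulated from `sim_spec`.
#' @param sim_spec A [cohort_spec()] used when `cohort_dir` is `NULL`.
#' @param stages Stages to run, a subset of `simulate, preprocess, screen,
#'   network, importance, selection, score, pca`; earlier artifacts are
#'   loaded from `out_dir` when a stage is skipped.
#' @param covariates Adjustment covariate names.
#' @param alpha,max_order,threshold,walktrap_steps Network stage parameters.
#' @param n_trees,sample_rate,n_perm,top_k_clusters Importance stage
#'   parameters.
#' @param nfolds,alphas Elastic-net stage parameters.
#' @param eigen_cutoff,loading_cutoff PCA stage parameters.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            cohort_dir = NULL,
                            sim_spec = cohort_spec(),
                            stages = c("simulate", "preprocess", "screen",
                                       "network", "importance", "selection",
                                       "score", "pca"),
                            covariates = default_covariates(),
                            alpha = 0.05, max_order = 3, threshold = 0.1,
                            walktrap_steps = 4,
                            n_trees = 500, sample_rate = 2 / 3, n_perm = 10,
                            top_k_clusters = 7,
                            nfolds = 10, alphas = c(0.1, 0.5, 0.9),
                            eigen_cutoff = 2, loading_cutoff = 0.40,
                            seed = 1L) {
  all_stages <- c("simulate", "preprocess", "screen", "network",
                  "importance", "selection", "score", "pca")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, cohort_dir = cohort_dir,
                 sim_spec = sim_spec, stages = stages,
                 covariates = covariates, alpha = alpha,
                 max_order = max_order, threshold = threshold,
                 walktrap_steps = walktrap_steps, n_trees = n_trees,
                 sample_rate = sample_rate, n_perm = n_perm,
                 top_k_clusters = top_k_clusters, nfolds = nfolds,
                 alphas = alphas, eigen_cutoff = eigen_cutoff,
                 loading_cutoff = loading_cutoff, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML map onto [pipeline_config()] arguments; a
#' `sim_spec` sub-map maps onto [cohort_spec()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim_spec)) raw$sim_spec <- do.call(cohort_spec, raw$sim_spec)
  do.call(pipeline_config, raw)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

write_matrix_tsv <- function(m, path, id_col = "subject_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_stage_tsv(df, path)
}

#' Run the full matched lipidomics pipeline
#'
#' Executes preprocess (half-min imputation, Blom, strata deviations) ->
#' per-lipid screen -> split-half PC network with robust edges and walktrap
#' clusters -> grouped-permutation cluster importance -> nested elastic-net
#' selection -> LOOCV multilipid score -> varimax PCA factor pathway,
#' writing every stage's artifact plus a manifest under `config$out_dir`.
#' Identical config and seed give byte-identical numeric outputs, and
#' stages skipped via `config$stages` are reloaded from their saved
#' artifacts, so rerunning downstream stages reproduces the single-shot
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a bundle (list) with all in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 8)
  names(seeds) <- c("simulate", "preprocess", "screen", "network",
                    "importance", "selection", "score", "pca")
  on <- function(stage) stage %in% config$stages
  bundle <- list(config = config, stage_log = character(0))
  note <- function(stage, msg) {
    bundle$stage_log <<- c(bundle$stage_log, paste0(stage, ": ", msg))
    message("[", stage, "] ", msg)
  }

  # --- cohort -------------------------------------------------------------
  cohort_dir <- file.path(out, "cohort")
  if (on("simulate")) {
    if (!is.null(config$cohort_dir)) {
      cohort <- read_cohort(config$cohort_dir)
      note("simulate", paste("loaded cohort from", config$cohort_dir))
    } else {
      spec <- config$sim_spec
      spec$seed <- as.integer(seeds[["simulate"]] %% .Machine$integer.max)
      cohort <- generate_cohort(spec)
      note("simulate", paste("generated", nrow(cohort$subjects),
                             "subjects in",
                             length(unique(cohort$subjects$stratum_id)),
                             "strata"))
    }
    write_cohort(cohort, cohort_dir)
  } else {
    cohort <- read_cohort(cohort_dir)
  }
  validate_cohort(cohort)
  bundle$cohort <- cohort
  s <- cohort$subjects

  # --- preprocess ---------------------------------------------------------
  blom_path <- file.path(out, "transformed_blom.tsv")
  dev_path <- file.path(out, "deviations.tsv")
  if (on("preprocess")) {
    blom <- blom_transform(impute_half_min(cohort$lipids))
    dev <- strata_deviation(blom, s$stratum_id)
    write_matrix_tsv(blom, blom_path)
    write_matrix_tsv(dev, dev_path)
    note("preprocess", "half-min imputation -> Blom -> strata deviations")
  } else {
    blom <- if (file.exists(blom_path)) read_matrix_tsv(blom_path) else NULL
    dev <- if (file.exists(dev_path)) read_matrix_tsv(dev_path) else NULL
  }
  bundle$blom <- blom
  bundle$deviations <- dev

  # --- screen -------------------------------------------------------------
  screen_path <- file.path(out, "screen.tsv")
  if (on("screen")) {
    scr <- screen_lipids(cohort, blom, config$covariates)
    write_stage_tsv(as.data.frame(scr), screen_path)
    note("screen", paste(sum(scr$p_raw < 0.05, na.rm = TRUE),
                         "of", nrow(scr), "lipids nominally associated;",
                         sum(scr$p_by < 0.05, na.rm = TRUE),
                         "after BY adjustment"))
    bundle$screen <- scr
  } else if (file.exists(screen_path)) {
    bundle$screen <- utils::read.delim(screen_path, stringsAsFactors = FALSE)
  }

  # --- network ------------------------------------------------------------
  edge_path <- file.path(out, "network_edges.tsv")
  part_path <- file.path(out, "network_partition.tsv")
  if (on("network")) {
    halves <- split_half_skeletons(blom, s$stratum_id, config$alpha,
                                   config$max_order,
                                   seed = seeds[["network"]])
    net <- robust_edges(halves$a, halves$b, blom, config$threshold,
                        config$max_order)
    net <- walktrap_clusters(net, config$walktrap_steps)
    write_network(net, edge_path, part_path,
                  graphml_path = file.path(out, "network.graphml"))
    note("network", paste(nrow(net$edges), "robust edges,",
                          max(net$partition), "walktrap clusters"))
    partition <- net$partition
    bundle$network <- net
  } else if (file.exists(part_path)) {
    pt <- utils::read.delim(part_path, stringsAsFactors = FALSE)
    partition <- stats::setNames(as.integer(pt$cluster_id), pt$feature)
  } else partition <- NULL
  bundle$partition <- partition

  # --- importance ---------------------------------------------------------
  imp_path <- file.path(out, "importance.tsv")
  if (on("importance")) {
    imp <- rank_clusters(dev, s$is_case, partition,
                         n_trees = config$n_trees,
                         sample_rate = config$sample_rate,
                         n_perm = config$n_perm,
                         seed = seeds[["importance"]])
    write_stage_tsv(imp$table, imp_path)
    note("importance", paste("baseline OOB error",
                             round(imp$baseline_oob_error, 4),
                             "; top cluster",
                             imp$table$cluster_id[imp$table$rank == 1]))
    tops <- top_clusters(imp, config$top_k_clusters)
    bundle$importance <- imp
  } else if (file.exists(imp_path)) {
    it <- utils::read.delim(imp_path, stringsAsFactors = FALSE)
    tops <- utils::head(it$cluster_id[order(it$rank)],
                        config$top_k_clusters)
  } else tops <- NULL
  bundle$top_clusters <- tops

  # --- selection ----------------------------------------------------------
  sel_path <- file.path(out, "selection.json")
  if (on("selection")) {
    within <- enet_within_clusters(dev, s$is_case, partition, tops,
                                   alphas = config$alphas,
                                   nfolds = config$nfolds,
                                   seed = seeds[["selection"]])
    cand <- unique(unlist(within))
    sel <- enet_across_clusters(dev, s$is_case, cand,
                                within_cluster_selected = within,
                                alphas = config$alphas,
                                nfolds = config$nfolds,
                                seed = seeds[["selection"]] + 1L)
    jsonlite::write_json(
      list(within_cluster_selected = within,
           across_cluster_selected = sel$across_cluster_selected,
           enet_coefficients = as.list(sel$enet_coefficients)),
      sel_path, auto_unbox = TRUE, digits = NA)
    note("selection", paste(length(sel$across_cluster_selected),
                            "network-wide predictors"))
    selected <- sel$across_cluster_selected
    bundle$selection <- sel
  } else if (file.exists(sel_path)) {
    sj <- jsonlite::read_json(sel_path, simplifyVector = TRUE)
    selected <- as.character(sj$across_cluster_selected)
  } else selected <- NULL
  bundle$selected <- selected

  # --- score --------------------------------------------------------------
  score_path <- file.path(out, "score_summary.json")
  if (on("score")) {
    if (length(selected)) {
      sm <- build_loocv_score(cohort, blom, selected, config$covariates)
      write_stage_tsv(sm$subject_scores, file.path(out, "scores.tsv"))
      wt <- data.frame(feature = names(sm$weight_medians),
                       loocv_median_weight = as.numeric(sm$weight_medians),
                       stringsAsFactors = FALSE)
      write_stage_tsv(wt, file.path(out, "weights.tsv"))
      jsonlite::write_json(
        list(or_per_sd = sm$or_per_sd, ci_low = sm$ci95[1],
             ci_high = sm$ci95[2], p = sm$p,
             interaction_p = if (is.null(sm$interaction_wald)) NA else
               sm$interaction_wald$p,
             n_failed_folds = length(sm$failed_strata)),
        score_path, auto_unbox = TRUE, digits = NA)
      note("score", sprintf("OR per SD %.3f (%.3f-%.3f)", sm$or_per_sd,
                            sm$ci95[1], sm$ci95[2]))
      bundle$score <- sm
    } else {
      jsonlite::write_json(list(or_per_sd = NA, note = "no predictors selected"),
                           score_path, auto_unbox = TRUE)
      note("score", "no predictors selected; score skipped")
    }
  }

  # --- pca ----------------------------------------------------------------
  if (on("pca")) {
    fm <- fit_pca_controls(blom, s$is_case == 0, config$eigen_cutoff,
                           config$loading_cutoff)
    bundle$factor_model <- fm
    if (fm$retained >= 1) {
      write_matrix_tsv(fm$loadings, file.path(out, "pca_loadings.tsv"),
                       id_col = "feature")
      fs <- project_scores(fm, blom)
      rownames(fs) <- s$subject_id
      write_matrix_tsv(fs, file.path(out, "factor_scores.tsv"))
      qa <- quartile_association(cohort, fs, config$covariates)
      write_stage_tsv(qa, file.path(out, "factor_assoc.tsv"))
      note("pca", paste(fm$retained, "factors retained explaining",
                        sprintf("%.1f%%", 100 * fm$variance_explained),
                        "of variance"))
      bundle$factor_scores <- fs
      bundle$factor_assoc <- qa
    } else {
      note("pca", "no factor retained (all eigenvalues <= cutoff)")
    }
  }

  manifest <- list(
    seed = config$seed,
    stage_seeds = as.list(seeds),
    config_hash = {
      cfg <- unclass(config)[setdiff(names(config), "out_dir")]
      cfg$sim_spec <- unclass(cfg$sim_spec)
      object_hash(cfg)
    },
    stages_run = config$stages,
    n_subjects = nrow(s),
    n_strata = length(unique(s$stratum_id)),
    n_features = length(cohort$feature_names),
    stage_log = bundle$stage_log
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  bundle$manifest <- manifest
  invisible(bundle)
}

#' Render a human-readable summary of a pipeline run
#'
#' Reads the stage artifacts under `out_dir` and renders the cluster
#' ranking, the selected predictors with their LOOCV median weights, the
#' score OR/CI and intervention interaction, and the per-factor quartile
#' ORs; sections whose artifacts are missing are flagged as gaps.
#'
#' @param out_dir A pipeline output directory.
#' @param truth Optional ground-truth list (e.g. `cohort$truth`) to
#'   cross-reference the top-ranked cluster against a planted signal.
#' @return The report lines, invisibly; printed to the console.
#' @export
make_report <- function(out_dir, truth = NULL) {
  lines <- c("== Matched lipidomics pipeline report ==", "")
  add <- function(...) lines <<- c(lines, ...)

  sp <- file.path(out_dir, "screen.tsv")
  if (file.exists(sp)) {
    scr <- utils::read.delim(sp, stringsAsFactors = FALSE)
    n_nom <- sum(scr$p_raw < 0.05, na.rm = TRUE)
    n_by <- sum(scr$p_by < 0.05, na.rm = TRUE)
    add(sprintf("Per-lipid screen: %d/%d nominally associated (p < 0.05); %s",
                n_nom, nrow(scr),
                if (n_by == 0) "none FDR-significant after BY adjustment"
                else paste(n_by, "FDR-significant after BY adjustment")), "")
  } else add("[screen: artifact missing]", "")

  ip <- file.path(out_dir, "importance.tsv")
  if (file.exists(ip)) {
    imp <- utils::read.delim(ip, stringsAsFactors = FALSE)
    imp <- imp[order(imp$rank), ]
    add("Most important lipid clusters (grouped OOB permutation):")
    for (r in seq_len(min(7, nrow(imp))))
      add(sprintf("  rank %d  cluster %s  error increase %+.4f  [%s]",
                  imp$rank[r], imp$cluster_id[r],
                  imp$oob_error_increase[r], imp$member_features[r]))
    if (!is.null(truth) && length(truth$effects)) {
      planted <- unique(truth$clusters[names(truth$effects)])
      hit <- imp$cluster_id[imp$rank == 1] %in% planted
      add(sprintf("  (planted signal cluster%s recovered at rank 1: %s)",
                  if (length(planted) > 1) "s" else "",
                  if (hit) "yes" else "no"))
    }
    add("")
  } else add("[importance: artifact missing]", "")

  wp <- file.path(out_dir, "weights.tsv")
  sp2 <- file.path(out_dir, "score_summary.json")
  if (file.exists(sp2)) {
    sm <- jsonlite::read_json(sp2, simplifyVector = TRUE)
    if (!is.null(sm$note)) {
      add(paste("Multilipid score:", sm$note), "")
    } else {
      if (file.exists(wp)) {
        wt <- utils::read.delim(wp, stringsAsFactors = FALSE)
        add("Selected predictors (LOOCV median weights):")
        for (r in seq_len(nrow(wt)))
          add(sprintf("  %-12s %+.3f", wt$feature[r],
                      wt$loocv_median_weight[r]))
      }
      add(sprintf("Multilipid score: OR per SD %.2f (95%% CI %.2f-%.2f), p = %.3g",
                  sm$or_per_sd, sm$ci_low, sm$ci_high, sm$p))
      if (!is.null(sm$interaction_p) && !is.na(sm$interaction_p))
        add(sprintf("  intervention interaction Wald p = %.3f%s",
                    sm$interaction_p,
                    if (sm$interaction_p > 0.05)
                      " (no evidence of effect modification)" else ""))
      add("")
    }
  } else add("[score: artifact missing]", "")

  fp <- file.path(out_dir, "factor_assoc.tsv")
  if (file.exists(fp)) {
    qa <- utils::read.delim(fp, stringsAsFactors = FALSE)
    add("PCA factor quartile associations (Q4 vs Q1, controls-based cuts):")
    for (r in seq_len(nrow(qa)))
      add(sprintf("  %s  OR %.2f (%.2f-%.2f), trend p = %.3f",
                  qa$factor[r], qa$or_q4[r], qa$ci_low_q4[r],
                  qa$ci_high_q4[r], qa$p_trend[r]))
    add("")
  } else add("[pca: artifact missing]", "")

  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
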