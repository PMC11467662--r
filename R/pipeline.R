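# End-to-end orchestration: preprocess -> screen -> DEG selection -> three
# modelling arms (plain / autoencoder latent / MixUp-augmented) -> grid-CV
# random forest and gradient boosting per arm -> explainability on the best
# arm -> volcano + consensus reports, with a run manifest tying artifacts
# together.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the package defaults. The
#' configuration round-trips losslessly through YAML via
#' \code{\link{write_pipeline_config}} / \code{\link{read_pipeline_config}}.
#'
#' @param sf_mode Size-factor mode (\code{"unit_sum"} or \code{"deseq"}).
#' @param min_total,nzv_freq_ratio,nzv_unique_pct Gene-filter thresholds.
#' @param n_pca Genes kept by the PCA screen.
#' @param n_deg Genes kept by differential-expression selection.
#' @param var_target PCA cumulative-variance target.
#' @param autoencoder Named list of \code{\link{autoencoder_spec}}
#'   overrides (\code{input_dim} is set from \code{n_deg}).
#' @param mixup Named list of \code{\link{mixup_config}} overrides.
#' @param split Named list of \code{\link{split_spec}} overrides.
#' @param rf_grid,xgb_grid Hyperparameter grids (\code{NULL} = defaults of
#'   \code{\link{grid_spec}}).
#' @param cv_folds Cross-validation folds.
#' @param xai Named list: \code{k}, \code{min_methods}, \code{n_perturb}
#'   (LIME), \code{shap_n_mc} (sampling-SHAP permutations).
#' @param volcano Named list: \code{fc_cut}, \code{p_cut},
#'   \code{use_adjusted}.
#' @param seed Global seed from which all stage seeds derive.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sf_mode = "unit_sum", min_total = 10,
                            nzv_freq_ratio = 19, nzv_unique_pct = 10,
                            n_pca = 2000, n_deg = 200, var_target = 0.90,
                            autoencoder = list(), mixup = list(),
                            split = list(), rf_grid = NULL,
                            xgb_grid = NULL, cv_folds = 5,
                            xai = list(), volcano = list(), seed = 1L) {
  ae_defaults <- list(encoder_dims = 128, bottleneck_dim = 72,
                      epochs = 200, batch_size = 32, learning_rate = 1e-3)
  mix_defaults <- list(alpha = 0.2, mode = "full_double")
  split_defaults <- list(test_fraction = 0.20, stratified = TRUE)
  xai_defaults <- list(k = 10, min_methods = 2, n_perturb = 500,
                       shap_n_mc = 50)
  volcano_defaults <- list(fc_cut = 1, p_cut = 0.05, use_adjusted = FALSE)
  structure(
    list(sf_mode = sf_mode, min_total = min_total,
         nzv_freq_ratio = nzv_freq_ratio, nzv_unique_pct = nzv_unique_pct,
         n_pca = n_pca, n_deg = n_deg, var_target = var_target,
         autoencoder = utils::modifyList(ae_defaults, autoencoder),
         mixup = utils::modifyList(mix_defaults, mixup),
         split = utils::modifyList(split_defaults, split),
         rf_grid = rf_grid, xgb_grid = xgb_grid,
         cv_folds = cv_folds,
         xai = utils::modifyList(xai_defaults, xai),
         volcano = utils::modifyList(volcano_defaults, volcano),
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#' @param config A \code{\link{pipeline_config}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path A file written by \code{\link{write_pipeline_config}} (or
#'   hand-edited; missing fields fall back to defaults).
#' @return A \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# tiny polynomial rolling hash so the manifest can fingerprint its
# configuration without extra dependencies
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

shape_string <- function(rows, cols) sprintf("(%dx%d)", rows, cols)

#' Run the full classification pipeline
#'
#' Executes preprocessing (filter, size factors, normalization, VST), the
#' PCA gene screen, DEG selection, a stratified train/test split shared by
#' all arms, the three modelling arms (\code{plain}: the selected genes;
#' \code{autoencoder}: latent features fitted on the training split;
#' \code{mixup}: training split augmented, test split untouched), grid-CV
#' training of a random forest and a gradient-boosted model per arm,
#' explainability (SHAP, LIME, variable importance and their consensus) on
#' the arm/model with the best test accuracy (ties prefer the MixUp arm,
#' then boosting), and volcano classification with the gray-zone check.
#'
#' Dataset shape strings count the feature columns plus one label column.
#'
#' @param counts Genes x samples count matrix, or path to a counts TSV.
#' @param labels Per-sample two-class vector (aligned with columns), or
#'   path to a labels CSV.
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Optional directory; when given, every table the run
#'   produces is written there and listed in the manifest.
#' @return A manifest list: \code{metrics} (one row per arm x model),
#'   \code{best} (arm/model), \code{deg_table}, \code{consensus},
#'   \code{venn}, \code{volcano}, \code{gray_check}, \code{rankings},
#'   \code{shapes}, \code{config_hash}, \code{seed}, \code{artifacts}.
#' @export
run_pipeline <- function(counts, labels, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(counts) && length(counts) == 1) {
    counts <- read_counts(counts)
  }
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    labels <- read_labels(labels)
  }
  if (!is.null(names(labels)) && !is.null(colnames(counts))) {
    if (!all(colnames(counts) %in% names(labels))) {
      stop("labels missing for some samples")
    }
    labels <- labels[colnames(counts)]
  }
  if (length(unique(as.character(labels))) != 2) {
    stop("labels must be two-class")
  }
  seed <- config$seed
  stage <- "preprocess"
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   artifacts = character(0))
  res <- tryCatch({
    prep <- preprocess_counts(counts, sf_mode = config$sf_mode,
                              min_total = config$min_total,
                              nzv_freq_ratio = config$nzv_freq_ratio,
                              nzv_unique_pct = config$nzv_unique_pct)

    stage <- "reduce"
    screen <- pca_gene_screen(prep$vst, n_pca = config$n_pca,
                              var_target = config$var_target)
    vst_scr <- prep$vst[screen$kept_genes, , drop = FALSE]
    deg <- de_test(vst_scr, labels)
    n_deg <- min(config$n_deg, nrow(deg))
    genes <- select_top_degs(deg, n_deg)
    features <- t(prep$vst[genes, , drop = FALSE])

    stage <- "split"
    sp <- do.call(split_spec, c(config$split, list(seed = seed)))
    parts <- train_test_split(features, as.character(labels), sp)

    stage <- "arms"
    arms <- list()
    arms$plain <- list(train_x = parts$train$x, train_y = parts$train$y,
                       test_x = parts$test$x, test_y = parts$test$y)

    ae_args <- c(list(input_dim = ncol(features), seed = seed),
                 config$autoencoder)
    ae_spec <- do.call(autoencoder_spec, ae_args)
    ae <- fit_autoencoder(parts$train$x, ae_spec)
    arms$autoencoder <- list(train_x = encode(ae, parts$train$x),
                             train_y = parts$train$y,
                             test_x = encode(ae, parts$test$x),
                             test_y = parts$test$y)

    mix_cfg <- do.call(mixup_config, c(config$mixup, list(seed = seed)))
    aug <- mixup_augment(parts$train$x, parts$train$y, mix_cfg)
    arms$mixup <- list(train_x = aug$features, train_y = aug$labels,
                       test_x = parts$test$x, test_y = parts$test$y)

    stage <- "train"
    models <- c("random_forest", "xgboost")
    rows <- list()
    fits <- list()
    for (arm in names(arms)) {
      a <- arms[[arm]]
      for (mdl in models) {
        gs <- grid_spec(mdl,
                        grid = if (mdl == "random_forest") config$rf_grid
                               else config$xgb_grid,
                        cv_folds = config$cv_folds)
        t0 <- proc.time()[["elapsed"]]
        fit <- grid_search_fit(a$train_x, a$train_y, gs, seed = seed)
        ev <- evaluate_model(fit, a$test_x, a$test_y)
        wall <- proc.time()[["elapsed"]] - t0
        fits[[paste(arm, mdl, sep = ".")]] <- fit
        m <- ev$metrics
        rows[[length(rows) + 1]] <- data.frame(
          arm = arm, model = mdl,
          accuracy = m$accuracy, precision = m$precision_ppv,
          npv = m$npv, recall = m$recall_sensitivity,
          specificity = m$specificity, f1 = m$f1,
          wall_time_s = wall,
          dataset_shape = shape_string(nrow(a$train_x),
                                       ncol(a$train_x) + 1),
          stringsAsFactors = FALSE)
      }
    }
    metrics <- do.call(rbind, rows)

    stage <- "xai"
    # best test accuracy; ties prefer the MixUp arm, then boosting
    arm_pref <- ifelse(metrics$arm == "mixup", 0, 1)
    model_pref <- ifelse(metrics$model == "xgboost", 0, 1)
    best_i <- order(-metrics$accuracy, arm_pref, model_pref)[1]
    best_arm <- metrics$arm[best_i]
    best_model <- metrics$model[best_i]
    best_fit <- fits[[paste(best_arm, best_model, sep = ".")]]
    a <- arms[[best_arm]]
    shap <- shap_ranking(best_fit, background = a$train_x,
                         explain_set = a$test_x,
                         n_mc = config$xai$shap_n_mc, seed = seed)
    lime <- lime_ranking(best_fit, explain_set = a$test_x,
                         n_perturb = config$xai$n_perturb, seed = seed)
    varimp <- varimp_ranking(best_fit)
    consensus <- consensus_features(list(shap, lime, varimp),
                                    k = config$xai$k,
                                    min_methods = config$xai$min_methods)

    stage <- "report"
    volcano <- volcano_classify(deg, fc_cut = config$volcano$fc_cut,
                                p_cut = config$volcano$p_cut,
                                use_adjusted = config$volcano$use_adjusted,
                                consensus = consensus)
    # latent features are not genes; the gray-zone check only applies when
    # the explained features are gene-named
    gray_check <- if (best_arm == "autoencoder") {
      list(violations = character(0), ok = NA)
    } else {
      check_consensus_not_gray(volcano, consensus)
    }

    list(prep = prep, screen = screen, deg = deg, genes = genes,
         metrics = metrics, best = list(arm = best_arm, model = best_model),
         rankings = list(shap = shap, lime = lime, varimp = varimp),
         consensus = consensus, volcano = volcano, gray_check = gray_check,
         arms = arms)
  }, error = function(e) {
    e$stage <- stage
    e$partial_manifest <- manifest
    stop(errorCondition(sprintf("pipeline failed at stage '%s': %s",
                                stage, conditionMessage(e)),
                        stage = stage, partial_manifest = manifest,
                        class = "pipeline_error"))
  })

  manifest$metrics <- res$metrics
  manifest$best <- res$best
  manifest$deg_table <- res$deg
  manifest$selected_genes <- res$genes
  manifest$rankings <- res$rankings
  manifest$consensus <- res$consensus
  manifest$venn <- res$consensus$venn
  manifest$volcano <- res$volcano
  manifest$gray_check <- res$gray_check
  manifest$shapes <- stats::setNames(res$metrics$dataset_shape,
                                     paste(res$metrics$arm,
                                           res$metrics$model, sep = "."))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name, writer) {
      path <- file.path(out_dir, name)
      writer(obj, path)
      manifest$artifacts <<- c(manifest$artifacts, path)
    }
    csv <- function(obj, path) utils::write.csv(obj, path,
                                                row.names = FALSE)
    wr(data.frame(sample_id = names(res$prep$size_factors$s),
                  s = unname(res$prep$size_factors$s)),
       "size_factors.csv", csv)
    wr(data.frame(
         gene_id = c(res$prep$filter_report$removed_low_count,
                     res$prep$filter_report$removed_nzv,
                     res$prep$filter_report$kept),
         status = rep(c("removed_low_count", "removed_nzv", "kept"),
                      c(length(res$prep$filter_report$removed_low_count),
                        length(res$prep$filter_report$removed_nzv),
                        length(res$prep$filter_report$kept)))),
       "filter_report.csv", csv)
    wr(res$prep$vst, "vst.tsv", function(m, p) write_counts(m, p))
    wr(as.data.frame(res$deg), "deg_table.csv", csv)
    wr(res$metrics, "metrics.csv", csv)
    for (nm in names(res$rankings)) {
      wr(res$rankings[[nm]]$scores, paste0("ranking_", nm, ".csv"), csv)
    }
    wr(res$consensus$features, "consensus.csv", csv)
    wr(data.frame(region = names(res$consensus$venn),
                  count = unname(res$consensus$venn)),
       "venn_counts.csv", csv)
    wr(as.data.frame(res$volcano), "volcano.csv", csv)
    manifest_out <- manifest[c("config_hash", "seed", "best", "shapes",
                               "artifacts")]
    manifest_out$metrics <- res$metrics
    jsonlite::write_json(manifest_out,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$artifacts <- c(manifest$artifacts,
                            file.path(out_dir, "manifest.json"))
  }
  class(manifest) <- "pipeline_manifest"
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("pipeline_manifest (seed %d, config %s)\n", x$seed,
              x$config_hash))
  cat(sprintf("  best arm/model: %s / %s\n", x$best$arm, x$best$model))
  print(x$metrics[, c("arm", "model", "accuracy", "f1", "dataset_shape")])
  invisible(x)
}
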