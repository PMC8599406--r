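#' Configuration for a full constraint-determinants analysis
#'
#' Bundles the inputs and every tunable of the end-to-end pipeline. Inputs
#' may be in-memory objects (a [feature_table()], [load_string_edges()]
#' networks) or file paths in the corresponding text formats. Defaults follow
#' the study design: a 30% holdout on the primary response with the same
#' held-out genes reused for the second response, STRING score threshold
#' 0.400, 10-fold cross-validation, a 500-tree forest with mtry = p/3, and
#' Bonferroni-adjusted significance at 0.05.
#'
#' @param table feature_table, or path to a TSV readable by
#'   [load_feature_table()].
#' @param functional,physical interaction_network objects or paths to
#'   STRING-format links files.
#' @param schema schema data.frame (needed when \code{table} is a path).
#' @param responses response column names; the first is the primary response
#'   whose gene universe defines the train/test split. Default: all response
#'   columns of the table.
#' @param gene_col gene ID column when loading from TSV.
#' @param test_fraction holdout fraction (default 0.30).
#' @param min_score STRING combined-score threshold (default 0.400).
#' @param strip_prefix taxon prefix stripped from network protein IDs.
#' @param n_folds CV folds for component selection (default 10).
#' @param max_components cap on the number of latent components evaluated.
#' @param n_trees,mtry_fraction random-forest baseline size (500, 1/3).
#' @param include_forest run the forest baseline stage (default TRUE).
#' @param alpha significance level for adjusted partial correlations.
#' @param log_expression log2(x+1)-transform expression variables before
#'   modelling (default FALSE).
#' @param impute_exclude groups excluded from imputation; NULL = default
#'   (GO and amino-acid composition).
#' @param seeds named list of integer seeds: \code{split}, \code{cv},
#'   \code{imputation}, \code{forest}.
#' @return object of class \code{analysis_config}.
#' @export
analysis_config <- function(table, functional, physical, schema = NULL,
                            responses = NULL, gene_col = "gene",
                            test_fraction = 0.30, min_score = 0.400,
                            strip_prefix = NULL, n_folds = 10L,
                            max_components = NULL, n_trees = 500L,
                            mtry_fraction = 1 / 3, include_forest = TRUE,
                            alpha = 0.05, log_expression = FALSE,
                            impute_exclude = NULL,
                            seeds = list(split = 1L, cv = 2L,
                                         imputation = 3L, forest = 4L)) {
  if (!(test_fraction > 0 && test_fraction < 1))
    stopf("test_fraction must be in (0,1)")
  for (s in c("split", "cv", "imputation", "forest"))
    seeds[[s]] <- as.integer(seeds[[s]] %||% match(s, c("split", "cv",
                                                        "imputation", "forest")))
  structure(list(table = table, functional = functional, physical = physical,
                 schema = schema, responses = responses, gene_col = gene_col,
                 test_fraction = test_fraction, min_score = min_score,
                 strip_prefix = strip_prefix, n_folds = as.integer(n_folds),
                 max_components = max_components, n_trees = as.integer(n_trees),
                 mtry_fraction = mtry_fraction,
                 include_forest = isTRUE(include_forest), alpha = alpha,
                 log_expression = isTRUE(log_expression),
                 impute_exclude = impute_exclude, seeds = seeds),
            class = "analysis_config")
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full constraint-determinants analysis
#'
#' Executes, in order: load -> one-hot encoding -> amino-acid proportion
#' scaling -> (optional log-expression transform) -> network centrality merge
#' -> imputation -> train/test split on the primary response -> per-response
#' centring/scaling on the training genes -> cross-validated component
#' selection -> PLS and PCR fits -> holdout scoring -> VIP scores and PCR
#' variance decomposition -> grouped Spearman partial correlations on the
#' full table -> random-forest baseline. Progress is logged to standard
#' error; the returned report contains no timestamps, so identical
#' configuration and seeds reproduce it exactly.
#'
#' @param config an [analysis_config()].
#' @return object of class \code{analysis_report}: per-response model
#'   metrics, importance tables and partial-correlation tables, plus
#'   provenance (variable counts, dropped variables, configuration echo).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))

  table <- run_stage("load", {
    if (inherits(config$table, "feature_table")) config$table
    else load_feature_table(config$table, schema = config$schema,
                            response_names = config$responses %||% character(),
                            gene_col = config$gene_col)
  })
  responses <- config$responses %||% colnames(table$responses)
  if (!length(responses)) stopf("no response columns configured")
  missing_r <- setdiff(responses, colnames(table$responses))
  if (length(missing_r))
    stopf("response(s) absent from table: %s", paste(missing_r, collapse = ", "))
  primary <- responses[1]
  n_vars_input <- ncol(table$data)

  table <- run_stage("one_hot", one_hot_encode(table))
  table <- run_stage("aa_scaling", scale_aa_composition(table))
  if (config$log_expression) {
    expr_vars <- names(table$group)[table$group == "expression"]
    for (v in expr_vars) table$data[[v]] <- log2(table$data[[v]] + 1)
  }

  table <- run_stage("centrality", {
    load_net <- function(x, kind)
      if (inherits(x, "interaction_network")) x
      else load_string_edges(x, min_score = config$min_score,
                             id_prefix_strip = config$strip_prefix,
                             kind = kind)
    add_centrality_features(table,
                            load_net(config$functional, "functional"),
                            load_net(config$physical, "physical"))
  })

  table <- run_stage("impute",
    impute_missing(table, exclude_groups = config$impute_exclude,
                   seed = config$seeds$imputation))

  split <- run_stage("split",
    split_train_test(table, test_fraction = config$test_fraction,
                     seed = config$seeds$split, response = primary))

  pp_all <- run_stage("preprocess_all", preprocess(table))

  results <- list()
  pcor <- list()
  for (ri in seq_along(responses)) {
    r <- responses[ri]
    yfull <- stats::setNames(table$responses[[r]], table$gene_ids)
    universe <- table$gene_ids[!is.na(yfull)]
    test_r <- intersect(split$test, universe)
    train_r <- setdiff(universe, split$test)
    if (length(train_r) < config$n_folds || length(test_r) < 2)
      stopf("too few genes with response '%s' for the configured split", r)

    pp <- run_stage(paste0("preprocess_", r), preprocess(table, fit_on = train_r))
    X <- as.matrix(pp$table)
    Xtr <- X[train_r, , drop = FALSE]
    Xte <- X[test_r, , drop = FALSE]
    ytr <- yfull[train_r]
    yte <- yfull[test_r]

    sel_pls <- run_stage(paste0("select_pls_", r),
      select_components(Xtr, ytr, max_A = config$max_components,
                        n_folds = config$n_folds,
                        seed = derive_seed(config$seeds$cv, ri), method = "pls"))
    sel_pcr <- run_stage(paste0("select_pcr_", r),
      select_components(Xtr, ytr, max_A = config$max_components,
                        n_folds = config$n_folds,
                        seed = derive_seed(config$seeds$cv, ri), method = "pcr"))

    A_pls <- max(1L, sel_pls$selected_A)
    A_pcr <- max(1L, sel_pcr$selected_A)
    pls <- run_stage(paste0("fit_pls_", r), fit_pls(Xtr, ytr, A_pls))
    pcr <- run_stage(paste0("fit_pcr_", r), fit_pcr(Xtr, ytr, A_pcr))

    metrics <- list(pls = score_predictions(yte, predict(pls, Xte)),
                    pcr = score_predictions(yte, predict(pcr, Xte)))
    rf_oob <- NULL
    if (config$include_forest) {
      rf <- run_stage(paste0("rf_", r),
        fit_rf_baseline(Xtr, ytr, n_trees = config$n_trees,
                        mtry_fraction = config$mtry_fraction,
                        seed = derive_seed(config$seeds$forest, ri)))
      metrics$rf <- score_predictions(yte, predict(rf, Xte))
      rf_oob <- rf$oob_r2
    }

    results[[r]] <- list(
      n_train = length(train_r), n_test = length(test_r),
      selected_components = list(pls = sel_pls$selected_A,
                                 pcr = sel_pcr$selected_A),
      metrics = metrics,
      rf_oob_r2 = rf_oob,
      vip = vip_scores(pls),
      pcr_pct_variance = pcr_variance_decomposition(pcr),
      train_r2 = list(pls = pls$r2_train, pcr = pcr$r2_train),
      dropped_variables = pp$state$dropped)

    pcor[[r]] <- run_stage(paste0("pcor_", r),
      grouped_partial_correlations(pp_all$table, r, alpha = config$alpha))
  }

  cfg_echo <- config[setdiff(names(config), c("table", "functional",
                                              "physical", "schema"))]
  structure(list(primary_response = primary,
                 gene_ids = table$gene_ids,
                 n_variables_input = n_vars_input,
                 n_variables_modelled = ncol(pp_all$table$data),
                 variable_group = table$group,
                 test_genes = split$test,
                 responses = results,
                 partial_correlations = pcor,
                 config = cfg_echo),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report: %d genes, %d variables modelled\n",
              length(x$gene_ids), x$n_variables_modelled))
  for (r in names(x$responses)) {
    res <- x$responses[[r]]
    line <- sprintf("  %s: PLS %.1f%% / PCR %.1f%%", r,
                    100 * res$metrics$pls$variance_explained,
                    100 * res$metrics$pcr$variance_explained)
    if (!is.null(res$metrics$rf))
      line <- sprintf("%s / RF %.1f%%", line,
                      100 * res$metrics$rf$variance_explained)
    cat(line, sprintf("of holdout variance explained (A = %d / %d)\n",
                      res$selected_components$pls,
                      res$selected_components$pcr))
  }
  invisible(x)
}

#' Importance table of an analysis report
#'
#' @param report analysis_report.
#' @param response response name (default the primary response).
#' @return data.frame \code{variable, group, vip, pct_variance} sorted by
#'   VIP, combining the PLS and PCR importance measures.
#' @export
importance_table <- function(report, response = NULL) {
  response <- response %||% report$primary_response
  res <- report$responses[[response]]
  if (is.null(res)) stopf("no such response in report: %s", response)
  vars <- names(res$vip)
  out <- data.frame(variable = vars,
                    group = unname(report$variable_group[vars]),
                    vip = unname(res$vip),
                    pct_variance = unname(res$pcr_pct_variance[vars]),
                    stringsAsFactors = FALSE)
  out[order(-out$vip), ]
}

#' Serialize an analysis report to JSON
#'
#' Fully numeric, timestamp-free rendering: identical configurations and
#' seeds produce byte-identical JSON.
#'
#' @param report analysis_report.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
report_json <- function(report, path = NULL) {
  stripped <- unclass(report)
  stripped$responses <- lapply(stripped$responses, function(res) {
    res$metrics <- lapply(res$metrics, unclass)
    res$vip <- as.list(res$vip)
    res$pcr_pct_variance <- as.list(res$pcr_pct_variance)
    res
  })
  js <- jsonlite::toJSON(stripped, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "columns", na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
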