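#' Construct a gene-by-variable feature table
#'
#' The central data container: one row per gene, one column per predictor
#' variable, with per-variable group labels (e.g. \code{"expression"},
#' \code{"amino_acid_composition"}, \code{"GO_component"},
#' \code{"network_centrality"}) and kinds, plus one or more response vectors
#' (e.g. \code{dN}, a per-gene phyloP average) kept strictly apart from the
#' predictors.
#'
#' @param data data.frame of predictor columns (numeric, or character for
#'   not-yet-encoded categorical/membership columns), one row per gene.
#' @param gene_ids character vector of distinct gene identifiers, one per row.
#' @param group named character vector mapping every variable to a group label.
#' @param kind named character vector mapping every variable to one of
#'   \code{"continuous"}, \code{"binary"}, \code{"categorical"}.
#' @param responses data.frame (or named list) of numeric response vectors
#'   over the same genes; missing values allowed.
#' @param standardized logical; set by [preprocess()] on its output (binary
#'   columns are then no longer 0/1 and are not validated as such).
#' @return An object of class \code{feature_table}.
#' @export
feature_table <- function(data, gene_ids, group, kind,
                          responses = NULL, standardized = FALSE) {
  data <- as.data.frame(data, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(gene_ids)
  if (nrow(data) != length(gene_ids))
    stopf("data has %d rows but %d gene ids were given", nrow(data), length(gene_ids))
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stopf("duplicate gene IDs: %s", paste(dup, collapse = ", "))
  vn <- colnames(data)
  if (anyDuplicated(vn))
    stopf("duplicate variable names: %s",
          paste(unique(vn[duplicated(vn)]), collapse = ", "))
  if (!all(vn %in% names(group)))
    stopf("variables without a group label: %s",
          paste(setdiff(vn, names(group)), collapse = ", "))
  if (!all(vn %in% names(kind)))
    stopf("variables without a kind: %s",
          paste(setdiff(vn, names(kind)), collapse = ", "))
  group <- group[vn]
  kind <- kind[vn]
  bad <- !kind %in% c("continuous", "binary", "categorical")
  if (any(bad))
    stopf("invalid variable kind for: %s", paste(vn[bad], collapse = ", "))
  if (!standardized) {
    for (v in vn[kind == "binary"]) {
      vals <- data[[v]]
      if (!all(is.na(vals) | vals %in% c(0, 1)))
        stopf("binary variable '%s' contains values outside {0,1}", v)
    }
  }
  if (is.null(responses)) {
    responses <- data.frame(row.names = seq_along(gene_ids))
  } else {
    responses <- as.data.frame(responses, check.names = FALSE)
    if (nrow(responses) != length(gene_ids))
      stopf("responses have %d rows but there are %d genes",
            nrow(responses), length(gene_ids))
  }
  clash <- intersect(colnames(responses), vn)
  if (length(clash))
    stopf("responses also appear among predictors: %s", paste(clash, collapse = ", "))
  structure(list(data = data, gene_ids = gene_ids, group = group, kind = kind,
                 responses = responses, standardized = standardized),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d genes x %d variables\n",
              length(x$gene_ids), ncol(x$data)))
  tg <- table(x$group)
  cat("  groups:", paste(sprintf("%s (%d)", names(tg), tg), collapse = ", "), "\n")
  if (ncol(x$responses))
    cat("  responses:", paste(colnames(x$responses), collapse = ", "), "\n")
  if (isTRUE(x$standardized)) cat("  (standardized)\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) c(length(x$gene_ids), ncol(x$data))

#' Predictor matrix of a feature table
#'
#' @param x feature_table.
#' @param ... unused.
#' @return numeric matrix (genes x variables) with gene IDs as row names.
#'   Errors if categorical columns remain (one-hot encode them first).
#' @export
as.matrix.feature_table <- function(x, ...) {
  cat_left <- names(x$kind)[x$kind == "categorical"]
  if (length(cat_left))
    stopf("categorical variables not yet one-hot encoded: %s",
          paste(cat_left, collapse = ", "))
  m <- as.matrix(as.data.frame(lapply(x$data, as.numeric),
                               check.names = FALSE, optional = TRUE))
  dimnames(m) <- list(x$gene_ids, colnames(x$data))
  m
}

#' Load a feature table from a TSV file
#'
#' Reads a tab-separated table with a header row and one gene per row.
#' Empty cells, \code{"NA"} and \code{"NaN"} (case-insensitive) are treated as
#' missing; unparseable numeric cells become missing rather than zero.
#'
#' @param path TSV file path.
#' @param schema data.frame with columns \code{column}, \code{group},
#'   \code{kind} declaring each predictor column. Columns absent from the
#'   schema default to continuous variables in group \code{"other"}.
#' @param response_names character vector of response column names; these are
#'   split out of the predictor matrix.
#' @param gene_col name of the gene identifier column (default \code{"gene"}).
#' @return A [feature_table()].
#' @export
load_feature_table <- function(path, schema = NULL, response_names = character(),
                               gene_col = "gene") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "", comment.char = "",
                           fileEncoding = "UTF-8")
  if (!gene_col %in% colnames(raw))
    stopf("gene ID column '%s' not found in %s", gene_col, path)
  gene_ids <- trimws(raw[[gene_col]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stopf("duplicate gene IDs in %s: %s", path, paste(dup, collapse = ", "))
  missing_resp <- setdiff(response_names, colnames(raw))
  if (length(missing_resp))
    stopf("response column(s) absent: %s", paste(missing_resp, collapse = ", "))
  responses <- lapply(raw[response_names], parse_numeric)
  responses <- as.data.frame(responses, check.names = FALSE,
                             row.names = seq_along(gene_ids))

  pred_cols <- setdiff(colnames(raw), c(gene_col, response_names))
  if (!is.null(schema)) {
    schema <- as.data.frame(schema, stringsAsFactors = FALSE)
    stopifnot(all(c("column", "group", "kind") %in% colnames(schema)))
  }
  group <- kind <- stats::setNames(character(length(pred_cols)), pred_cols)
  data <- vector("list", length(pred_cols))
  names(data) <- pred_cols
  for (v in pred_cols) {
    i <- if (!is.null(schema)) match(v, schema$column) else NA_integer_
    g <- if (!is.na(i)) schema$group[i] else "other"
    k <- if (!is.na(i)) schema$kind[i] else "continuous"
    group[v] <- g
    kind[v] <- k
    if (k == "categorical") {
      col <- trimws(raw[[v]])
      col[is_missing_token(col)] <- NA_character_
      data[[v]] <- col
    } else {
      data[[v]] <- parse_numeric(raw[[v]])
    }
  }
  data <- as.data.frame(data, check.names = FALSE, optional = TRUE)
  if (length(pred_cols) == 0) data <- data.frame(row.names = seq_along(gene_ids))
  feature_table(data, gene_ids, group, kind, responses)
}

#' Write a feature table to TSV
#'
#' Inverse of [load_feature_table()]: the gene column, predictors and
#' responses are written tab-separated with \code{NA} for missing entries.
#'
#' @param table feature_table.
#' @param path output file path.
#' @param gene_col name for the gene identifier column.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(table, path, gene_col = "gene") {
  out <- cbind(stats::setNames(data.frame(table$gene_ids,
                                          stringsAsFactors = FALSE), gene_col),
               table$data, table$responses)
  # fixed-notation full precision so that load() round-trips values exactly
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) out[[j]] <- formatC(out[[j]], format = "g", digits = 17)
  out[] <- lapply(out, function(x) ifelse(is.na(x) | x == "NA", "NA", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Schema of a feature table
#'
#' @param table feature_table.
#' @return data.frame with columns \code{column}, \code{group}, \code{kind},
#'   suitable as the \code{schema} argument of [load_feature_table()].
#' @export
table_schema <- function(table) {
  data.frame(column = names(table$group), group = unname(table$group),
             kind = unname(table$kind), stringsAsFactors = FALSE)
}

#' One-hot encode categorical or membership columns
#'
#' Each level (or set member) of the named columns becomes a binary variable
#' \code{<column>.<level>} with values in \{0,1\}; the source column is
#' removed and the new variables inherit its group. All levels are kept (no
#' reference level is dropped): downstream latent-variable models tolerate the
#' resulting collinearity, and each GO slim or chromosome then has its own
#' interpretable column. Cells may contain several members separated by
#' \code{","}, \code{";"} or \code{"|"}; an empty cell means no membership
#' (all zeros) while a missing cell yields missing values across the derived
#' columns.
#'
#' @param table feature_table.
#' @param columns character vector of columns to encode; defaults to every
#'   column of kind \code{"categorical"}.
#' @return feature_table with the encoded binary columns appended.
#' @export
one_hot_encode <- function(table, columns = NULL) {
  columns <- columns %||% names(table$kind)[table$kind == "categorical"]
  if (!length(columns)) return(table)
  miss <- setdiff(columns, colnames(table$data))
  if (length(miss)) stopf("no such column(s): %s", paste(miss, collapse = ", "))
  data <- table$data
  group <- table$group
  kind <- table$kind
  for (v in columns) {
    cells <- as.character(data[[v]])
    sets <- strsplit(cells, "[,;|]")
    sets <- lapply(sets, function(s) {
      s <- trimws(s)
      s[nzchar(s)]
    })
    levels <- sort(unique(unlist(sets)))
    if (!length(levels))
      stopf("column '%s' has no non-missing levels to encode", v)
    newnames <- paste(v, levels, sep = ".")
    clash <- intersect(newnames, setdiff(colnames(data), v))
    if (length(clash))
      stopf("one-hot name collision with existing variable(s): %s",
            paste(clash, collapse = ", "))
    enc <- matrix(0, nrow(data), length(levels),
                  dimnames = list(NULL, newnames))
    for (i in seq_along(sets)) {
      if (is.na(cells[i])) enc[i, ] <- NA_real_
      else enc[i, match(sets[[i]], levels)] <- 1
    }
    src_group <- group[[v]]
    data[[v]] <- NULL
    group <- group[names(group) != v]
    kind <- kind[names(kind) != v]
    data <- cbind(data, as.data.frame(enc, check.names = FALSE))
    group[newnames] <- src_group
    kind[newnames] <- "binary"
  }
  feature_table(data, table$gene_ids, group, kind, table$responses,
                standardized = table$standardized)
}

#' Scale amino-acid counts to proportions of the protein
#'
#' Divides each gene's amino-acid columns by their row sum so the block sums
#' to 1 per gene; already-proportional rows are left unchanged (up to
#' normalization). Composition then reflects residue usage independently of
#' protein length, which enters separately through the size group.
#'
#' @param table feature_table.
#' @param aa_columns the amino-acid count columns; defaults to all variables
#'   in group \code{"amino_acid_composition"}.
#' @return feature_table with proportions in place of counts.
#' @export
scale_aa_composition <- function(table, aa_columns = NULL) {
  aa_columns <- aa_columns %||%
    names(table$group)[table$group == "amino_acid_composition"]
  if (!length(aa_columns)) return(table)
  miss <- setdiff(aa_columns, colnames(table$data))
  if (length(miss)) stopf("no such amino-acid column(s): %s",
                          paste(miss, collapse = ", "))
  block <- as.matrix(table$data[aa_columns])
  if (anyNA(block))
    stopf("missing values in amino-acid columns of gene(s): %s",
          paste(table$gene_ids[apply(is.na(block), 1, any)], collapse = ", "))
  if (any(block < 0))
    stopf("negative amino-acid counts for gene(s): %s",
          paste(unique(table$gene_ids[which(block < 0, arr.ind = TRUE)[, 1]]),
                collapse = ", "))
  rs <- rowSums(block)
  zero <- rs == 0
  if (any(zero))
    stopf("all-zero amino-acid row for gene(s): %s",
          paste(table$gene_ids[zero], collapse = ", "))
  block <- block / rs
  data <- table$data
  data[aa_columns] <- as.data.frame(block, check.names = FALSE)
  feature_table(data, table$gene_ids, table$group, table$kind,
                table$responses, standardized = table$standardized)
}

#' Centre and scale predictors, dropping zero-variance variables
#'
#' Per-variable means and standard deviations are computed on the
#' \code{fit_on} genes only and applied to all genes, so that held-out genes
#' are transformed with training statistics and no information leaks into
#' holdout scoring. Variables whose sample variance on \code{fit_on} is zero
#' (within \code{tol}) or undefined are removed and recorded. Responses are
#' left untouched.
#'
#' @param table feature_table with all-numeric predictors (one-hot encode
#'   first).
#' @param fit_on gene IDs to compute statistics on; default all genes.
#' @param tol zero-variance tolerance on the sample variance.
#' @return list with elements \code{table} (transformed feature_table, marked
#'   \code{standardized}) and \code{state} (a \code{preprocess_state}: means,
#'   sds, dropped variables).
#' @export
preprocess <- function(table, fit_on = NULL, tol = 1e-12) {
  fit_on <- fit_on %||% table$gene_ids
  idx <- match(fit_on, table$gene_ids)
  if (anyNA(idx))
    stopf("fit_on gene(s) not in table: %s",
          paste(fit_on[is.na(idx)], collapse = ", "))
  if (length(idx) < 2) stopf("need at least 2 genes in fit_on")
  X <- as.matrix(table)
  mu <- apply(X[idx, , drop = FALSE], 2, mean, na.rm = TRUE)
  sdev <- apply(X[idx, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  drop <- !is.finite(sdev) | sdev^2 <= tol
  dropped <- colnames(X)[drop]
  keep <- colnames(X)[!drop]
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep], "-"),
              2, sdev[keep], "/")
  state <- structure(list(means = mu[keep], sds = sdev[keep],
                          dropped = dropped, fit_on = fit_on),
                     class = "preprocess_state")
  out <- feature_table(as.data.frame(Xs, check.names = FALSE, optional = TRUE),
                       table$gene_ids, table$group[keep], table$kind[keep],
                       table$responses, standardized = TRUE)
  list(table = out, state = state)
}

#' Apply stored preprocessing statistics to a compatible table
#'
#' @param table feature_table holding at least the state's variables.
#' @param state a \code{preprocess_state} from [preprocess()].
#' @return transformed feature_table restricted to the state's variables.
#' @export
apply_preprocess <- function(table, state) {
  keep <- names(state$means)
  miss <- setdiff(keep, colnames(table$data))
  if (length(miss)) stopf("table lacks variable(s): %s", paste(miss, collapse = ", "))
  X <- as.matrix(table)[, keep, drop = FALSE]
  Xs <- sweep(sweep(X, 2, state$means, "-"), 2, state$sds, "/")
  feature_table(as.data.frame(Xs, check.names = FALSE, optional = TRUE),
                table$gene_ids, table$group[keep], table$kind[keep],
                table$responses, standardized = TRUE)
}

#' @export
print.preprocess_state <- function(x, ...) {
  cat(sprintf("preprocess_state: %d variables scaled, %d dropped (zero variance)\n",
              length(x$means), length(x$dropped)))
  invisible(x)
}

#' Serialize a preprocessing state to JSON (provenance record)
#'
#' @param state preprocess_state.
#' @param path optional file to write to.
#' @return JSON string, invisibly if written to file.
#' @export
preprocess_state_json <- function(state, path = NULL) {
  js <- jsonlite::toJSON(list(means = as.list(state$means),
                              sds = as.list(state$sds),
                              dropped = state$dropped),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Impute missing predictor values by iterative k-NN regression
#'
#' Chained model-based imputation in the missForest spirit: missing entries in
#' non-excluded continuous variables are first mean-filled, then each
#' incomplete column in turn is re-predicted by a distance-weighted k-nearest
#' -neighbour regression trained on the other non-excluded predictor columns
#' (using their current imputed values), iterating until successive
#' imputations change by less than \code{tol} in relative L2 norm or
#' \code{max_iter} rounds. Excluded groups (by default GO-slim and amino-acid
#' composition variables) and the responses are never used as inputs and never
#' modified. The procedure is deterministic; \code{seed} is recorded for
#' provenance.
#'
#' @param table feature_table.
#' @param exclude_groups variable groups excluded from imputation (neither
#'   imputed nor used as predictors). Default: groups named
#'   \code{"amino_acid_composition"} or starting with \code{"GO"}.
#' @param seed integer, stored in the result's \code{imputation} attribute.
#' @param k number of neighbours.
#' @param max_iter,tol iteration cap and relative-change stopping tolerance.
#' @return feature_table with missing entries filled; attribute
#'   \code{"imputation"} records seed, iterations and imputed columns.
#' @export
impute_missing <- function(table, exclude_groups = NULL, seed = 1L,
                           k = 10L, max_iter = 10L, tol = 1e-4) {
  groups <- unique(unname(table$group))
  exclude_groups <- exclude_groups %||%
    groups[groups == "amino_acid_composition" | startsWith(groups, "GO")]
  vn <- colnames(table$data)
  included <- vn[!(table$group[vn] %in% exclude_groups) &
                   table$kind[vn] != "categorical"]
  cont <- included[table$kind[included] == "continuous"]
  targets <- cont[vapply(table$data[cont], anyNA, logical(1))]
  all_missing <- targets[vapply(table$data[targets],
                                function(x) all(is.na(x)), logical(1))]
  if (length(all_missing))
    stopf("column(s) entirely missing, cannot impute: %s",
          paste(all_missing, collapse = ", "))
  info <- list(seed = seed, iterations = 0L, columns = targets,
               excluded_groups = exclude_groups)
  if (!length(targets)) {
    attr(table, "imputation") <- info
    return(table)
  }
  M <- as.matrix(as.data.frame(lapply(table$data[included], as.numeric),
                               check.names = FALSE, optional = TRUE))
  obs <- !is.na(M)
  # mean initialisation
  for (j in targets) M[!obs[, j], j] <- mean(M[obs[, j], j])
  # impute columns with least missingness first
  ord <- targets[order(colSums(!obs[, targets, drop = FALSE]))]
  prev_change <- Inf
  for (it in seq_len(max_iter)) {
    old <- M[, targets, drop = FALSE]
    for (j in ord) {
      preds <- setdiff(included, j)
      Z <- M[, preds, drop = FALSE]
      # standardize predictor space so distances are scale-free
      zs <- apply(Z, 2, stats::sd)
      zs[zs == 0 | !is.finite(zs)] <- 1
      Z <- sweep(sweep(Z, 2, colMeans(Z), "-"), 2, zs, "/")
      tr <- which(obs[, j])
      qu <- which(!obs[, j])
      M[qu, j] <- knn_predict(Z[tr, , drop = FALSE], M[tr, j],
                              Z[qu, , drop = FALSE], k = k)
    }
    new <- M[, targets, drop = FALSE]
    delta <- new[!obs[, targets, drop = FALSE]] - old[!obs[, targets, drop = FALSE]]
    rel <- sqrt(sum(delta^2) / max(sum(new[!obs[, targets, drop = FALSE]]^2),
                                   .Machine$double.eps))
    info$iterations <- it
    if (rel < tol || rel >= prev_change) break
    prev_change <- rel
  }
  data <- table$data
  for (j in targets) data[[j]] <- M[, j]
  out <- feature_table(data, table$gene_ids, table$group, table$kind,
                       table$responses, standardized = table$standardized)
  attr(out, "imputation") <- info
  out
}

# Distance-weighted k-NN regression; deterministic (ties broken by row order).
knn_predict <- function(Ztrain, ytrain, Zquery, k) {
  k <- min(k, nrow(Ztrain))
  tn2 <- rowSums(Ztrain^2)
  out <- numeric(nrow(Zquery))
  for (i in seq_len(nrow(Zquery))) {
    d2 <- tn2 - 2 * drop(Ztrain %*% Zquery[i, ]) + sum(Zquery[i, ]^2)
    nn <- order(d2)[seq_len(k)]
    w <- 1 / (sqrt(pmax(d2[nn], 0)) + 1e-8)
    out[i] <- sum(w * ytrain[nn]) / sum(w)
  }
  out
}

#' Split genes into training and test sets on a response
#'
#' The split is taken over genes with a non-missing \code{response}; the test
#' side holds \code{round(test_fraction * n)} genes, drawn reproducibly under
#' \code{seed}. Reusing the returned test set (intersected with the genes
#' having a second response) scores both responses on the same held-out genes.
#'
#' @param table feature_table with at least one response.
#' @param test_fraction fraction in (0,1) of genes held out.
#' @param seed integer RNG seed.
#' @param response response column defining the gene universe; default the
#'   first response.
#' @return list with character vectors \code{train} and \code{test}.
#' @export
split_train_test <- function(table, test_fraction = 0.3, seed = 1L,
                             response = NULL) {
  if (!ncol(table$responses)) stopf("table has no responses")
  response <- response %||% colnames(table$responses)[1]
  if (!response %in% colnames(table$responses))
    stopf("no such response: %s", response)
  if (!(test_fraction > 0 && test_fraction < 1))
    stopf("test_fraction must be in (0,1)")
  universe <- table$gene_ids[!is.na(table$responses[[response]])]
  n <- length(universe)
  n_test <- round(test_fraction * n)
  if (n_test < 1 || n_test >= n)
    stopf("test_fraction %.3f yields an empty train or test side (n = %d)",
          test_fraction, n)
  set.seed(seed)
  test <- sort(sample(universe, n_test))
  list(train = setdiff(universe, test), test = test)
}
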