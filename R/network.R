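#' Build an interaction network from a STRING-format links file
#'
#' Reads whitespace-separated rows \code{protein1 protein2 combined_score}
#' (integer scores 0--999; \code{score/1000} is STRING's probability-like
#' combined score, optional header line, optionally gzip-compressed) and keeps
#' edges with \code{score/1000 >= min_score} (inclusive, so the conventional
#' 0.400 cutoff keeps raw scores >= 400). Reciprocal duplicate rows collapse
#' to a single undirected edge and self-loops are discarded; the resulting
#' graph is simple and unweighted.
#'
#' @param path links file path (plain text or .gz).
#' @param min_score minimum combined score on the 0--1 scale; default 0.400.
#' @param id_prefix_strip optional taxon prefix (e.g. \code{"4896."}) removed
#'   from protein identifiers.
#' @param kind \code{"functional"} or \code{"physical"} (metadata only).
#' @return An \code{interaction_network}: list with the \pkg{igraph} graph,
#'   \code{kind} and \code{score_threshold}.
#' @export
load_string_edges <- function(path, min_score = 0.400, id_prefix_strip = NULL,
                              kind = c("functional", "physical")) {
  kind <- match.arg(kind)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines_trim <- trimws(lines)
  keep <- nzchar(lines_trim)
  fields <- strsplit(lines_trim[keep], "[ \t]+")
  lineno <- which(keep)
  nf <- lengths(fields)
  # optional STRING header line ("protein1 protein2 combined_score")
  start <- 1L
  if (length(fields) && nf[1] == 3 &&
      identical(tolower(fields[[1]]), c("protein1", "protein2",
                                        "combined_score")))
    start <- 2L
  idx <- seq_along(fields)[seq_along(fields) >= start]
  bad <- idx[nf[idx] != 3]
  if (length(bad))
    stopf("malformed row (expected 3 fields) at line %d of %s", lineno[bad[1]], path)
  a <- vapply(fields[idx], `[[`, character(1), 1)
  b <- vapply(fields[idx], `[[`, character(1), 2)
  sc <- suppressWarnings(as.integer(vapply(fields[idx], `[[`, character(1), 3)))
  if (anyNA(sc))
    stopf("non-integer score at line %d of %s", lineno[idx[which(is.na(sc))[1]]], path)
  if (length(sc) && (min(sc) < 0 || max(sc) > 999))
    stopf("combined scores must lie in 0..999 (%s)", path)
  if (!is.null(id_prefix_strip) && nzchar(id_prefix_strip)) {
    strip <- function(x) ifelse(startsWith(x, id_prefix_strip),
                                substring(x, nchar(id_prefix_strip) + 1L), x)
    a <- strip(a)
    b <- strip(b)
  }
  keep_e <- sc / 1000 >= min_score - 1e-12
  a <- a[keep_e]; b <- b[keep_e]
  if (!length(a)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(data.frame(from = a, to = b,
                                                  stringsAsFactors = FALSE),
                                       directed = FALSE)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  }
  structure(list(graph = g, kind = kind, score_threshold = min_score),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network (%s): %d proteins, %d edges (score >= %.3f)\n",
              x$kind, igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$score_threshold))
  invisible(x)
}

#' Node centrality of an interaction network
#'
#' Definitions on the unweighted simple graph:
#' \itemize{
#'  \item \code{degree}: number of direct neighbours (unnormalized).
#'  \item \code{closeness}: inverse average shortest distance to the other
#'    nodes of the node's connected component, \eqn{(r-1)/\sum_u d(v,u)} with
#'    \eqn{r} the component size; isolated nodes score 0.
#'  \item \code{betweenness}: \eqn{\sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}}
#'    over unordered pairs in the node's component, counting shortest paths
#'    with multiplicity; endpoints excluded.
#'  \item \code{eigenvector}: entry of the principal eigenvector of the
#'    adjacency matrix of the whole graph, non-negative, scaled so the largest
#'    entry is 1. Computed by power iteration on \eqn{A + I} (the spectral
#'    shift leaves eigenvectors unchanged and guarantees convergence on
#'    bipartite graphs), all-ones start, sup-norm tolerance 1e-10, at most
#'    1000 iterations.
#' }
#'
#' @param net interaction_network.
#' @param metric one of \code{"degree"}, \code{"closeness"},
#'   \code{"betweenness"}, \code{"eigenvector"}.
#' @return named numeric vector over the network's nodes.
#' @export
compute_centrality <- function(net, metric = c("degree", "closeness",
                                               "betweenness", "eigenvector")) {
  if (!inherits(net, "interaction_network")) stopf("not an interaction_network")
  if (length(metric) == 1 && !metric %in% c("degree", "closeness",
                                            "betweenness", "eigenvector"))
    stopf("unknown centrality metric: %s", metric)
  metric <- match.arg(metric)
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  ids <- igraph::V(g)$name %||% as.character(seq_len(n))
  val <- switch(metric,
    degree = as.numeric(igraph::degree(g)),
    closeness = {
      cl <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
      cl[!is.finite(cl)] <- 0  # isolated nodes
      as.numeric(cl)
    },
    betweenness = as.numeric(igraph::betweenness(g, directed = FALSE)),
    eigenvector = {
      if (n == 0) stopf("eigenvector centrality needs a non-empty network")
      eigencentrality_power(g)
    })
  stats::setNames(val, ids)
}

# Power iteration for the Perron eigenvector of A, run on A + I.
eigencentrality_power <- function(g, tol = 1e-10, max_iter = 1000L) {
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0) return(rep(0, n))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  v <- rep(1, n)
  for (it in seq_len(max_iter)) {
    av <- v + as.numeric(A %*% v)  # the +I shift
    av <- av / max(av)
    if (max(abs(av - v)) < tol) {
      v <- av
      break
    }
    v <- av
  }
  v / max(v)
}

#' Centrality features for a gene list from two networks
#'
#' Computes degree, closeness, betweenness and eigenvector centrality on the
#' functional and the physical interaction network and aligns them with a
#' gene list. Genes absent from a network receive 0 for its four metrics with
#' a presence flag of \code{FALSE}: absence of interaction evidence is treated
#' as informative rather than missing (the flags let users audit this).
#'
#' @param functional,physical interaction_networks.
#' @param gene_ids character vector of gene identifiers (after any prefix
#'   stripping they must be comparable with the networks' node IDs).
#' @return data.frame with 8 centrality columns
#'   (\code{functional_degree}, ..., \code{physical_eigencentrality}) and two
#'   logical presence flags, one row per gene.
#' @export
centrality_profile <- function(functional, physical, gene_ids) {
  gene_ids <- as.character(gene_ids)
  mats <- list(functional = functional, physical = physical)
  out <- data.frame(row.names = seq_along(gene_ids))
  matched_any <- FALSE
  for (nk in names(mats)) {
    net <- mats[[nk]]
    nodes <- if (igraph::vcount(net$graph))
      (igraph::V(net$graph)$name %||% character(0)) else character(0)
    present <- gene_ids %in% nodes
    if (any(present)) matched_any <- TRUE
    for (m in c("degree", "closeness", "betweenness", "eigenvector")) {
      cn <- paste0(nk, "_", if (m == "eigenvector") "eigencentrality" else m)
      vals <- rep(0, length(gene_ids))
      if (igraph::vcount(net$graph)) {
        cv <- compute_centrality(net, m)
        vals[present] <- unname(cv[gene_ids[present]])
      }
      out[[cn]] <- vals
    }
    out[[paste0(nk, "_present")]] <- present
    message(sprintf("centrality: %d/%d genes matched in %s network",
                    sum(present), length(gene_ids), nk))
  }
  if (!matched_any)
    stopf("no genes match either network; check the ID scheme / prefix stripping")
  out
}

#' Append network-centrality variables to a feature table
#'
#' Merges the eight [centrality_profile()] variables into the table under
#' group \code{"network_centrality"}; presence flags are kept as an attribute.
#'
#' @param table feature_table.
#' @param functional,physical interaction_networks.
#' @return feature_table with 8 added continuous variables and attribute
#'   \code{"network_presence"}.
#' @export
add_centrality_features <- function(table, functional, physical) {
  prof <- centrality_profile(functional, physical, table$gene_ids)
  flags <- prof[c("functional_present", "physical_present")]
  vars <- setdiff(colnames(prof), colnames(flags))
  data <- cbind(table$data, prof[vars])
  group <- c(table$group, stats::setNames(rep("network_centrality",
                                              length(vars)), vars))
  kind <- c(table$kind, stats::setNames(rep("continuous", length(vars)), vars))
  out <- feature_table(data, table$gene_ids, group, kind, table$responses,
                       standardized = table$standardized)
  attr(out, "network_presence") <- flags
  out
}
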