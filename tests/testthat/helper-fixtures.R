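# Shared fixture builders; everything is generated in code at test time.

# A tiny well-formed feature table: 3 groups of continuous variables plus a
# response, built from a seeded draw.
tiny_table <- function(n = 30, seed = 42) {
  set.seed(seed)
  data <- data.frame(expr = rnorm(n), len = rnorm(n), gc = rnorm(n))
  feature_table(data,
                gene_ids = sprintf("G%03d", seq_len(n)),
                group = c(expr = "expression", len = "size", gc = "size"),
                kind = c(expr = "continuous", len = "continuous",
                         gc = "continuous"),
                responses = data.frame(dN = rnorm(n)))
}

# Write a STRING-style links file and load it.
make_network <- function(edges, min_score = 0.4, header = TRUE, ...) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  lines <- sprintf("%s %s %d", edges[[1]], edges[[2]], edges[[3]])
  if (header) lines <- c("protein1 protein2 combined_score", lines)
  writeLines(lines, path)
  load_string_edges(path, min_score = min_score, ...)
}

# Brute-force centrality oracles on an edge list (small graphs only):
# all-pairs BFS with shortest-path counting, and a dense eigen-decomposition.
oracle_centralities <- function(nodes, edges) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges[i, 1], edges[i, 2]] <- 1
    A[edges[i, 2], edges[i, 1]] <- 1
  }
  # BFS distances and shortest-path counts from s
  bfs_counts <- function(s) {
    d <- rep(Inf, n); sigma <- rep(0, n)
    d[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(A[v, ] == 1)) {
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
        if (d[w] == d[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
      frontier <- unique(nxt)
    }
    list(d = d, sigma = sigma)
  }
  bfs <- lapply(seq_len(n), bfs_counts)
  D <- t(vapply(bfs, `[[`, numeric(n), "d"))
  degree <- rowSums(A)
  closeness <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(D[v, ]) & seq_len(n) != v)
    if (!length(reach)) 0 else length(reach) / sum(D[v, reach])
  }, numeric(1))
  # betweenness by enumerating shortest paths through v for each (s,t) pair
  count_via <- function(s, t, v) {
    # paths s->t through v = sigma_sv * sigma_vt if d_sv + d_vt == d_st
    if (D[s, v] + D[v, t] != D[s, t]) return(0)
    bfs[[s]]$sigma[v] * bfs[[v]]$sigma[t]
  }
  betweenness <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || is.infinite(D[s, t])) next
      tot <- tot + count_via(s, t, v) / bfs[[s]]$sigma[t]
    }
    tot
  }, numeric(1))
  ev <- eigen(A, symmetric = TRUE)
  v1 <- ev$vectors[, which.max(ev$values)]
  v1 <- abs(v1)  # Perron vector is non-negative up to sign
  eigenvector <- v1 / max(v1)
  list(degree = setNames(degree, nodes),
       closeness = setNames(closeness, nodes),
       betweenness = setNames(betweenness, nodes),
       eigenvector = setNames(eigenvector, nodes))
}

# Random connected graph on k nodes (retry until connected).
random_connected_edges <- function(k, p_edge = 0.5) {
  repeat {
    pairs <- t(combn(k, 2))
    keep <- runif(nrow(pairs)) < p_edge
    if (!any(keep)) next
    el <- pairs[keep, , drop = FALSE]
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g) == k && igraph::is_connected(g)) return(el)
  }
}

small_study <- function(seed = 7, n = 400) {
  generate_synthetic_study(
    synthetic_spec(n_genes = n, n_go = 30, network_genes = round(n * 0.6),
                   missingness = 0.03),
    seed = seed)
}

study_config <- function(ds, dir = withr::local_tempdir(.local_envir = parent.frame()),
                         include_forest = FALSE, ...) {
  paths <- write_synthetic_study(ds, dir)
  analysis_config(table = ds$table, functional = paths[["functional"]],
                  physical = paths[["physical"]], strip_prefix = "4896.",
                  include_forest = include_forest, ...)
}
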