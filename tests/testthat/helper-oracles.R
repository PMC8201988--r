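# Independent oracles and small fixture builders used across test files.

# Dense power-iteration personalized PageRank, written against the adjacency
# matrix directly: dangling vertices hand their mass to the restart vector.
pagerank_oracle <- function(from, to, n, w, damping = 0.85, tol = 1e-14) {
  p <- w / sum(w)
  A <- matrix(0, n, n)
  if (length(from)) A[cbind(from, to)] <- 1
  out <- rowSums(A)
  r <- p
  for (it in 1:100000) {
    push <- ifelse(out > 0, r / out, 0)
    inflow <- as.vector(crossprod(A, push))
    dangling <- sum(r[out == 0])
    rn <- damping * (inflow + dangling * p) + (1 - damping) * p
    if (sum(abs(rn - r)) < tol) return(rn)
    r <- rn
  }
  rn
}

# Bipartite test graph: n_pir PIR vertices E1.. and n_prom promoters P1..
# (gene g1..), edges given as a 2-column matrix of (pir index, prom index).
make_test_graph <- function(n_prom, n_pir, edge_idx, weights) {
  promoters <- data.frame(id = paste0("P", seq_len(n_prom)),
                          gene = paste0("g", seq_len(n_prom)),
                          stringsAsFactors = FALSE)
  pirs <- data.frame(id = paste0("E", seq_len(n_pir), recycle0 = TRUE),
                     stringsAsFactors = FALSE)
  edges <- if (is.null(edge_idx) || nrow(edge_idx) == 0) {
    data.frame(pir_id = character(), promoter_id = character())
  } else {
    data.frame(pir_id = paste0("E", edge_idx[, 1]),
               promoter_id = paste0("P", edge_idx[, 2]),
               stringsAsFactors = FALSE)
  }
  ids <- c(promoters$id, pirs$id)
  scores <- stats::setNames(weights, ids)
  list(graph = build_graph(promoters, pirs, edges, scores),
       promoters = promoters, pirs = pirs, edges = edges, scores = scores)
}

# Oracle PageRank for a graph built by make_test_graph (promoters first).
oracle_for <- function(n_prom, n_pir, edge_idx, weights, damping = 0.85) {
  from <- if (is.null(edge_idx) || nrow(edge_idx) == 0) integer() else
    n_prom + edge_idx[, 1]
  to <- if (is.null(edge_idx) || nrow(edge_idx) == 0) integer() else
    edge_idx[, 2]
  pr <- pagerank_oracle(from, to, n_prom + n_pir, weights, damping)
  stats::setNames(pr, c(paste0("P", seq_len(n_prom), recycle0 = TRUE),
                        paste0("E", seq_len(n_pir), recycle0 = TRUE)))
}

# Small simulation used by several test files.
tiny_sim <- function(n_genes = 40, seed = 7, ...) {
  simulate_epigenome(sim_config(n_genes = n_genes, seed = seed, ...))
}

# Closed-form AUC from the ranks occupied by the set genes.
auc_closed_form <- function(ranks, N) 1 + 1 / N - mean(ranks) / N

# Temp BED writer for reader tests.
write_lines_tmp <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
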