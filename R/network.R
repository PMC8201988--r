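# Weighted directed enhancer->promoter graph, personalized-PageRank score
# propagation, gene ranking, and the degree-preserving rewiring null.

#' Build the enhancer->promoter graph
#'
#' Vertices are promoters (tagged with their gene) and PIRs; edges are
#' directed PIR -> promoter; vertex weights are the element scores from
#' [element_scores()]. Isolated promoters are retained so genes without any
#' linked enhancer are still ranked. Duplicate edges are collapsed.
#'
#' @param promoters Promoter data frame (`id`, `gene`).
#' @param pirs PIR data frame (`id`).
#' @param edges Edge data frame (`pir_id`, `promoter_id`) from
#'   [link_by_interactions()] or [link_by_nearest()].
#' @param scores Named numeric vector of element scores; elements missing
#'   from it get weight 0 with a warning.
#' @return An `igraph` object with vertex attributes `type`
#'   (`"promoter"`/`"pir"`), `gene` (promoters only) and `weight`.
#' @export
build_graph <- function(promoters, pirs, edges, scores) {
  ids <- c(promoters$id, pirs$id)
  if (anyDuplicated(ids)) stop("duplicated element ids across promoters ",
                               "and PIRs", call. = FALSE)
  unknown <- setdiff(c(edges$pir_id, edges$promoter_id), ids)
  if (length(unknown)) {
    stop("edge references unknown element(s): ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  if (!all(edges$pir_id %in% pirs$id) ||
      !all(edges$promoter_id %in% promoters$id)) {
    stop("edges must run from a PIR to a promoter", call. = FALSE)
  }
  w <- unname(scores[ids])
  if (anyNA(w)) {
    warning(sum(is.na(w)), " element(s) missing from the score table; ",
            "weight set to 0")
    w[is.na(w)] <- 0
  }
  if (any(w < 0)) stop("element scores must be nonnegative", call. = FALSE)
  vertices <- data.frame(
    name = ids,
    type = rep(c("promoter", "pir"), c(nrow(promoters), nrow(pirs))),
    gene = c(promoters$gene, rep(NA_character_, nrow(pirs))),
    weight = w,
    stringsAsFactors = FALSE)
  el <- unique(edges[, c("pir_id", "promoter_id")])
  igraph::graph_from_data_frame(el, directed = TRUE, vertices = vertices)
}

#' Propagate element scores with personalized PageRank
#'
#' Runs personalized PageRank on the directed enhancer->promoter graph with
#' restart probabilities proportional to the vertex weights, so a vertex's
#' stationary mass reflects its own differential score plus the scores
#' flowing in from its enhancers. Dangling vertices (promoters, out-degree
#' 0) redistribute their mass according to the same weight-derived restart
#' vector, keeping the steady state a function of element weights only.
#' The meta-gene score of a gene is the summed PageRank of its promoter
#' vertices (switchable to the maximum).
#'
#' @param graph Graph from [build_graph()].
#' @param damping Damping factor in (0, 1); default 0.85.
#' @param gene_agg How PageRank of multiple promoters of one gene is
#'   combined: `"sum"` (mass-conserving, default) or `"max"`.
#' @return Object of class `gene_score_table`: list with `gene` (named
#'   vector of meta-gene scores), `promoter` (data frame `promoter_id`,
#'   `gene`, `pagerank`) and `pagerank` (full per-vertex vector, sums to 1).
#' @export
pagerank_scores <- function(graph, damping = 0.85,
                            gene_agg = c("sum", "max")) {
  gene_agg <- match.arg(gene_agg)
  if (damping <= 0 || damping >= 1) stop("damping must be in (0, 1)",
                                         call. = FALSE)
  w <- igraph::V(graph)$weight
  if (sum(w) <= 0) {
    warning("all vertex weights are zero: uniform personalization used")
    w <- rep(1, length(w))
  }
  pr <- igraph::page_rank(graph, damping = damping, personalized = w,
                          directed = TRUE)$vector
  is_prom <- igraph::V(graph)$type == "promoter"
  prom <- data.frame(promoter_id = igraph::V(graph)$name[is_prom],
                     gene = igraph::V(graph)$gene[is_prom],
                     pagerank = unname(pr[is_prom]),
                     stringsAsFactors = FALSE)
  agg <- if (gene_agg == "sum") sum else max
  gene <- tapply(prom$pagerank, prom$gene, agg)
  gene <- stats::setNames(as.vector(gene), names(gene))
  structure(list(gene = gene[sort(names(gene))],
                 promoter = prom, pagerank = pr),
            class = "gene_score_table")
}

.gene_vector <- function(scores) {
  if (inherits(scores, "gene_score_table")) scores$gene
  else if (is.numeric(scores) && !is.null(names(scores))) scores
  else stop("expected a gene_score_table or a named numeric vector",
            call. = FALSE)
}

#' Rank genes by meta-gene score
#'
#' Descending by score; ties broken lexicographically by gene id so the
#' ranking is deterministic.
#'
#' @param scores A [pagerank_scores()] result or named numeric vector.
#' @return Data frame (`rank`, `gene`, `score`), rank 1 = highest score.
#' @export
rank_genes <- function(scores) {
  g <- .gene_vector(scores)
  if (length(g) == 0L) stop("no genes to rank", call. = FALSE)
  o <- order(-g, names(g))
  data.frame(rank = seq_along(g), gene = names(g)[o],
             score = unname(g[o]), stringsAsFactors = FALSE)
}

#' Promoter-only baseline ranking
#'
#' Ranks genes by the differential score of their promoter elements alone,
#' discarding enhancer contributions. Genes with several promoters combine
#' them by sum (default) or max, mirroring [pagerank_scores()].
#'
#' @param promoters Promoter data frame (`id`, `gene`).
#' @param scores Named numeric vector of element scores.
#' @param gene_agg `"sum"` or `"max"`.
#' @return Data frame (`rank`, `gene`, `score`).
#' @export
promoter_only_ranks <- function(promoters, scores,
                                gene_agg = c("sum", "max")) {
  gene_agg <- match.arg(gene_agg)
  s <- scores[promoters$id]
  if (anyNA(s)) {
    warning(sum(is.na(s)), " promoter(s) missing from the score table; ",
            "score set to 0")
    s[is.na(s)] <- 0
  }
  agg <- if (gene_agg == "sum") sum else max
  g <- tapply(unname(s), promoters$gene, agg)
  g <- stats::setNames(as.vector(g), names(g))
  rank_genes(g[sort(names(g))])
}

#' Degree-preserving rewiring of the enhancer->promoter graph
#'
#' Randomizes edges by repeated double-edge swaps — pick edges (a -> x) and
#' (b -> y), replace with (a -> y) and (b -> x) unless a duplicate edge
#' would result — so every PIR keeps its out-degree and every promoter its
#' in-degree exactly, while the wiring is shuffled. Vertex weights are
#' untouched. This is the connectivity-matched null used by
#' [rewiring_null()].
#'
#' @param graph Graph from [build_graph()].
#' @param n_swaps Number of attempted swaps (default `10 * ecount(graph)`).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers looping over permutations stay reproducible from one
#'   outer seed).
#' @return Rewired graph with identical vertex set, weights, and degree
#'   sequences.
#' @export
rewire_degree_preserving <- function(graph,
                                     n_swaps = 10 * igraph::ecount(graph),
                                     seed = NULL) {
  if (igraph::ecount(graph) < 2L) {
    warning("fewer than 2 edges: graph returned unchanged")
    return(graph)
  }
  if (!is.null(seed)) set.seed(seed)
  igraph::rewire(graph, igraph::keeping_degseq(loops = FALSE,
                                               niter = n_swaps))
}
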