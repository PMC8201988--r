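# End-to-end pipeline: regions -> signal -> dPCA -> graph -> ranked genes.

#' Run the full gene-ranking pipeline
#'
#' Wires the stages together: promoter extension, PIR peak-support
#' filtering, PIR-promoter linkage, signal summarization at 1-kb scale,
#' power transform and within-mark quantile normalization, the
#' between-condition difference matrix, differential PCA element scores,
#' the enhancer->promoter graph, personalized PageRank propagation, and the
#' final ranked gene list together with the promoter-only baseline.
#'
#' @param x Pipeline inputs: a [simulate_epigenome()] result, a
#'   [read_simulation()] result, or any list with components `promoters`,
#'   `pirs`, `interactions` (optional under `linkage = "nearest"`), `peaks`
#'   (optional when `filter_pirs = FALSE`) and `tracks`.
#' @param extension Promoter half-window in bases (default 1000).
#' @param scale Length scale for signal intensity (default 1000; `NULL`
#'   keeps raw coverage-weighted sums).
#' @param power Power-transform exponent (default 0.5).
#' @param quantile Quantile-normalize within marks (default `TRUE`).
#' @param n_dpcs Number of differential components summed into element
#'   scores (default 2).
#' @param damping PageRank damping factor (default 0.85).
#' @param linkage `"interactions"` (chromatin-interaction evidence) or
#'   `"nearest"` (nearest-TSS assignment).
#' @param filter_pirs Apply the peak-support filter (default `TRUE`;
#'   requires `x$peaks`).
#' @param min_peak_samples Minimum supporting samples for a PIR (default 2).
#' @param peak_marks Marks conferring PIR support.
#' @return Object of class `epirank_result`: `ranked` and
#'   `promoter_ranked` data frames, plus the intermediates `graph`,
#'   `gene_scores`, `element_scores`, `dpca`, `D`, `signal`, `edges`,
#'   `promoters`, `pirs`.
#' @export
epirank_run <- function(x, extension = 1000, scale = 1000, power = 0.5,
                        quantile = TRUE, n_dpcs = 2, damping = 0.85,
                        linkage = c("interactions", "nearest"),
                        filter_pirs = TRUE, min_peak_samples = 2,
                        peak_marks = c("H3K4me1", "H3K27ac")) {
  linkage <- match.arg(linkage)
  stopifnot(!is.null(x$promoters), !is.null(x$pirs), !is.null(x$tracks))
  prom <- extend_promoters(x$promoters, extension)
  pirs <- x$pirs
  if (filter_pirs) {
    pirs <- filter_pirs_by_peaks(pirs, x$peaks, marks = peak_marks,
                                 min_samples = min_peak_samples)
  }
  edges <- if (linkage == "interactions") {
    if (is.null(x$interactions)) {
      stop("linkage = 'interactions' requires an interaction table",
           call. = FALSE)
    }
    link_by_interactions(prom, pirs, x$interactions)
  } else {
    link_by_nearest(prom, pirs)
  }
  n_unlinked <- sum(!pirs$id %in% edges$pir_id)
  if (n_unlinked > 0) {
    message(n_unlinked, " PIR(s) linked to no promoter; excluded from the ",
            "graph")
  }
  pirs <- pirs[pirs$id %in% edges$pir_id, , drop = FALSE]
  elements <- rbind(prom[, c("chrom", "start", "end", "id")],
                    pirs[, c("chrom", "start", "end", "id")])
  esm <- summarize_tracks(x$tracks, elements, scale = scale)
  esm <- normalize_signal(esm, power = power, quantile = quantile)
  D <- difference_matrix(esm)
  k_use <- min(n_dpcs, min(dim(D)))
  fit <- dpca(D, k = k_use)
  scores <- element_scores(fit, k = k_use)
  graph <- build_graph(prom, pirs, edges, scores)
  gs <- pagerank_scores(graph, damping = damping)
  structure(list(
    ranked = rank_genes(gs),
    promoter_ranked = promoter_only_ranks(prom, scores),
    graph = graph, gene_scores = gs, element_scores = scores,
    dpca = fit, D = D, signal = esm, edges = edges,
    promoters = prom, pirs = pirs), class = "epirank_result")
}

#' @export
print.epirank_result <- function(x, ...) {
  cat(sprintf(
    "epirank_result: %d genes ranked, %d promoters, %d PIRs, %d edges\n",
    nrow(x$ranked), nrow(x$promoters), nrow(x$pirs), nrow(x$edges)))
  cat("top genes:", paste(utils::head(x$ranked$gene, 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' Persist the main pipeline outputs as tab-separated tables
#'
#' Writes the ranked lists, element scores, dPC loadings and variance
#' explained, and the graph (edge list plus vertex table).
#'
#' @param result An [epirank_run()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "epirank_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(result$ranked, "ranked_genes.tsv")
  wt(result$promoter_ranked, "ranked_genes_promoter_only.tsv")
  wt(data.frame(element_id = names(result$element_scores),
                score = unname(result$element_scores)),
     "element_scores.tsv")
  wt(loadings_report(result$dpca), "dpc_loadings.tsv")
  wt(result$edges, "graph_edges.tsv")
  v <- igraph::as_data_frame(result$graph, what = "vertices")
  names(v)[names(v) == "name"] <- "id"
  wt(v, "graph_vertices.tsv")
  invisible(dir)
}
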