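# Self-contained synthetic epigenome with planted differential signal.
#
# The generator lays genes out on a 2-kb slot grid along toy chromosomes,
# attaches a Poisson number of PIR slots within +/- 1 Mb of each TSS, and
# draws lognormal baseline signal per (element, mark, sample). At a
# designated fraction of marker genes the condition-A signal of activating
# marks is multiplied by the effect size and that of repressive marks is
# divided by it, at the promoter, the linked PIRs, or both.

.SLOT <- 2000L

#' Default mark panel
#'
#' Six commonly profiled histone marks with their regulatory polarity.
#'
#' @return Data frame (`mark`, `polarity`).
#' @export
default_marks <- function() {
  data.frame(
    mark = c("H3K4me3", "H3K27ac", "H3K4me1", "H3K36me3",
             "H3K27me3", "H3K9me3"),
    polarity = c("activating", "activating", "activating", "activating",
                 "repressive", "repressive"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Study conditions for the synthetic epigenome: a two-condition design with
#' `samples_per_condition` replicates per mark, lognormal baseline noise of
#' log-sd `noise_sigma`, and a multiplicative `effect_size` planted at the
#' marker genes' regulatory elements.
#'
#' @param n_genes Number of genes (default 200).
#' @param pirs_per_gene Poisson mean of PIRs linked per gene (default 5).
#' @param marker_fraction Fraction of genes carrying planted signal
#'   (default 0.1).
#' @param marker_mode Where the signal is planted: `"both"`, `"promoter"`,
#'   or `"enhancer"`.
#' @param marks Mark panel ([default_marks()]).
#' @param effect_size Multiplicative shift (>= 1; 1 plants nothing).
#' @param samples_per_condition Replicates per condition per mark
#'   (default 3).
#' @param noise_sigma Lognormal log-sd of sample noise (default 0.3).
#' @param n_chrom Number of toy chromosomes (default 1).
#' @param gene_spacing TSS spacing in bases (default 20000).
#' @param pir_window Maximum PIR distance from its gene's TSS (default
#'   1e6).
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, pirs_per_gene = 5,
                       marker_fraction = 0.1,
                       marker_mode = c("both", "promoter", "enhancer"),
                       marks = default_marks(), effect_size = 4,
                       samples_per_condition = 3, noise_sigma = 0.3,
                       n_chrom = 1, gene_spacing = 20000, pir_window = 1e6,
                       seed = 1) {
  marker_mode <- match.arg(marker_mode)
  stopifnot(n_genes >= 1, pirs_per_gene >= 0,
            marker_fraction > 0, marker_fraction < 1,
            effect_size >= 1, samples_per_condition >= 1,
            noise_sigma >= 0, n_chrom >= 1,
            gene_spacing >= 2 * .SLOT, pir_window >= gene_spacing,
            all(c("mark", "polarity") %in% names(marks)),
            all(marks$polarity %in% c("activating", "repressive")))
  structure(list(n_genes = n_genes, pirs_per_gene = pirs_per_gene,
                 marker_fraction = marker_fraction,
                 marker_mode = marker_mode, marks = marks,
                 effect_size = effect_size,
                 samples_per_condition = samples_per_condition,
                 noise_sigma = noise_sigma, n_chrom = n_chrom,
                 gene_spacing = gene_spacing, pir_window = pir_window,
                 seed = seed), class = "sim_config")
}

#' Generate a synthetic epigenome
#'
#' Produces everything the pipeline consumes: promoters with gene ids, PIRs,
#' a promoter-PIR interaction table, per-sample peak calls for the
#' enhancer-associated marks, per-(mark, sample, condition) block-signal
#' tracks, a sample sheet, and the ground truth (marker genes and planted
#' element effects). Identical seeds give identical output.
#'
#' Peaks are emitted at every element whose H3K4me1/H3K27ac track value
#' exceeds that track's median, so the PIR peak-support filter passes by
#' construction for nearly all PIRs.
#'
#' @param config A [sim_config()].
#' @return List of class `epigenome_sim` with components `promoters`,
#'   `pirs`, `interactions`, `peaks`, `tracks`, `sample_sheet`, `truth`,
#'   `config`.
#' @export
simulate_epigenome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  slot <- .SLOT
  margin_slots <- as.integer(ceiling(config$pir_window / slot)) + 5L
  genes_per_chrom <- ceiling(config$n_genes / config$n_chrom)
  spacing_slots <- as.integer(config$gene_spacing / slot)
  chrom_slots <- 2L * margin_slots + genes_per_chrom * spacing_slots
  chroms <- paste0("chr", seq_len(config$n_chrom))

  # reserve every promoter slot up front so no PIR can land on one
  occupied <- lapply(chroms, function(ch) {
    occ <- logical(chrom_slots)
    occ[margin_slots + (seq_len(genes_per_chrom) - 1L) * spacing_slots + 1L] <-
      TRUE
    occ
  })
  names(occupied) <- chroms
  prom_rows <- vector("list", config$n_genes)
  pir_rows <- list()
  inter_rows <- list()
  pir_owner <- character(0)  # gene owning each pir (parallel to pirs rows)
  max_off <- as.integer(config$pir_window / slot)
  offsets <- c(-max_off:-1, 1:max_off)
  gid <- 0L
  for (ci in seq_len(config$n_chrom)) {
    ch <- chroms[ci]
    n_here <- min(genes_per_chrom, config$n_genes - gid)
    if (n_here <= 0) break
    for (j in seq_len(n_here)) {
      gid <- gid + 1L
      gslot <- margin_slots + (j - 1L) * spacing_slots + 1L
      tss <- (gslot - 1L) * slot + 1000L
      gene <- sprintf("GENE%04d", gid)
      prom_rows[[gid]] <- data.frame(
        chrom = ch, start = tss - 1, end = tss + 1,
        id = paste0("prom_", gene), gene = gene, tss = tss,
        stringsAsFactors = FALSE)
      n_pir <- stats::rpois(1, config$pirs_per_gene)
      k <- 0L
      tries <- 0L
      while (k < n_pir && tries < 50L * n_pir) {
        tries <- tries + 1L
        s <- gslot + sample(offsets, 1L)
        if (s < 1L || s > chrom_slots || occupied[[ch]][s]) next
        occupied[[ch]][s] <- TRUE
        k <- k + 1L
        ps <- (s - 1L) * slot + 200
        pe <- (s - 1L) * slot + 1800
        pid <- sprintf("pir_%s_%d", gene, k)
        pir_rows[[length(pir_rows) + 1L]] <- data.frame(
          chrom = ch, start = ps, end = pe, id = pid,
          support_count = NA_integer_, stringsAsFactors = FALSE)
        pir_owner <- c(pir_owner, gene)
        inter_rows[[length(inter_rows) + 1L]] <- data.frame(
          chrom_a = ch, start_a = ps, end_a = pe,
          chrom_b = ch, start_b = tss - 500, end_b = tss + 500,
          source = "sim", stringsAsFactors = FALSE)
      }
    }
  }
  promoters <- do.call(rbind, prom_rows)
  pirs <- do.call(rbind, pir_rows)
  inter <- do.call(rbind, inter_rows)
  if (is.null(pirs)) {
    pirs <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), id = character(),
                       support_count = integer())
    inter <- data.frame(chrom_a = character(), start_a = numeric(),
                        end_a = numeric(), chrom_b = character(),
                        start_b = numeric(), end_b = numeric(),
                        source = character())
  }

  n_marker <- round(config$marker_fraction * config$n_genes)
  markers <- sort(sample(promoters$gene, n_marker))

  # element table: extended promoter windows carry the signal blocks
  prom_elem <- data.frame(chrom = promoters$chrom,
                          start = promoters$tss - 1000,
                          end = promoters$tss + 1000,
                          id = promoters$id, stringsAsFactors = FALSE)
  elements <- rbind(prom_elem,
                    pirs[, c("chrom", "start", "end", "id")])
  elem_gene <- c(promoters$gene, pir_owner)
  elem_is_prom <- rep(c(TRUE, FALSE), c(nrow(prom_elem), nrow(pirs)))
  planted <- elem_gene %in% markers &
    ((elem_is_prom & config$marker_mode %in% c("both", "promoter")) |
       (!elem_is_prom & config$marker_mode %in% c("both", "enhancer")))

  marks <- config$marks
  S <- config$samples_per_condition
  n_elem <- nrow(elements)
  # element x mark propensity shared by all samples
  base <- matrix(stats::rlnorm(n_elem * nrow(marks), log(10), 0.5),
                 n_elem, nrow(marks))
  tracks <- list()
  sheet <- NULL
  effects <- data.frame(element_id = elements$id[planted],
                        gene = elem_gene[planted],
                        stringsAsFactors = FALSE)
  ord <- order(elements$chrom, elements$start)
  for (mi in seq_len(nrow(marks))) {
    mk <- marks$mark[mi]
    fold <- if (marks$polarity[mi] == "activating") config$effect_size else
      1 / config$effect_size
    for (cond in c("A", "B")) {
      for (s in seq_len(S)) {
        val <- base[, mi] *
          stats::rlnorm(n_elem, 0, config$noise_sigma)
        if (cond == "A") val[planted] <- val[planted] * fold
        sample_id <- paste0(cond, s)
        blocks <- data.frame(chrom = elements$chrom[ord],
                             start = elements$start[ord],
                             end = elements$end[ord],
                             value = val[ord], stringsAsFactors = FALSE)
        tracks[[length(tracks) + 1L]] <- list(
          blocks = blocks, mark = mk, sample_id = sample_id,
          condition = cond)
        sheet <- rbind(sheet, data.frame(
          track_path = sprintf("tracks/%s.%s.bedGraph", mk, sample_id),
          condition = cond, mark = mk, sample_id = sample_id,
          stringsAsFactors = FALSE))
      }
    }
  }

  # peak calls: element exceeds the track median for the enhancer marks
  peak_marks <- intersect(c("H3K4me1", "H3K27ac"), marks$mark)
  peaks <- NULL
  for (tr in tracks) {
    if (!(tr$mark %in% peak_marks)) next
    thr <- stats::median(tr$blocks$value)
    hit <- tr$blocks$value > thr
    if (!any(hit)) next
    peaks <- rbind(peaks, data.frame(
      chrom = tr$blocks$chrom[hit], start = tr$blocks$start[hit],
      end = tr$blocks$end[hit], sample_id = tr$sample_id,
      mark = tr$mark, stringsAsFactors = FALSE))
  }

  structure(list(
    promoters = promoters, pirs = pirs, interactions = inter,
    peaks = peaks, tracks = tracks, sample_sheet = sheet,
    truth = list(markers = markers, effects = effects),
    config = config), class = "epigenome_sim")
}

#' @export
print.epigenome_sim <- function(x, ...) {
  cat(sprintf(
    "epigenome_sim: %d genes, %d PIRs, %d tracks, %d marker genes (mode %s)\n",
    nrow(x$promoters), nrow(x$pirs), length(x$tracks),
    length(x$truth$markers), x$config$marker_mode))
  invisible(x)
}

#' Write a simulation to disk in the formats the pipeline reads
#'
#' BED files for promoters (gene in column 4), PIRs and per-(mark, sample)
#' peaks; bedGraph tracks; tab-separated interaction table, sample sheet and
#' peak manifest; plain-text ground truth.
#'
#' @param sim An [simulate_epigenome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "epigenome_sim"))
  dir.create(file.path(dir, "tracks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  wt <- function(df, path, col.names = FALSE) {
    utils::write.table(df, file.path(dir, path), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = col.names)
  }
  p <- sim$promoters
  wt(data.frame(p$chrom, as.integer(p$start), as.integer(p$end), p$gene),
     "promoters.bed")
  q <- sim$pirs
  wt(data.frame(q$chrom, as.integer(q$start), as.integer(q$end), q$id),
     "pirs.bed")
  i <- sim$interactions
  wt(data.frame(i$chrom_a, as.integer(i$start_a), as.integer(i$end_a),
                i$chrom_b, as.integer(i$start_b), as.integer(i$end_b),
                i$source), "interactions.tsv")
  wt(sim$sample_sheet, "samples.tsv", col.names = TRUE)
  for (tr in sim$tracks) {
    b <- tr$blocks
    wt(data.frame(b$chrom, as.integer(b$start), as.integer(b$end),
                  signif(b$value, 8)),
       sprintf("tracks/%s.%s.bedGraph", tr$mark, tr$sample_id))
  }
  if (!is.null(sim$peaks)) {
    manifest <- NULL
    for (key in unique(paste(sim$peaks$mark, sim$peaks$sample_id))) {
      sub <- sim$peaks[paste(sim$peaks$mark, sim$peaks$sample_id) == key, ]
      path <- sprintf("peaks/%s.%s.bed", sub$mark[1], sub$sample_id[1])
      wt(data.frame(sub$chrom, as.integer(sub$start), as.integer(sub$end)),
         path)
      manifest <- rbind(manifest, data.frame(
        path = path, sample_id = sub$sample_id[1], mark = sub$mark[1],
        stringsAsFactors = FALSE))
    }
    wt(manifest, "peaks.tsv", col.names = TRUE)
  }
  writeLines(sim$truth$markers, file.path(dir, "markers.txt"))
  wt(sim$truth$effects, "planted_effects.tsv", col.names = TRUE)
  cfg <- unclass(sim$config)
  cfg$marks <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a pipeline input directory
#'
#' Reads back the layout written by [write_simulation()] into the in-memory
#' structure consumed by [epirank_run()].
#'
#' @param dir Directory written by [write_simulation()] (or hand-assembled
#'   with the same layout).
#' @return List with `promoters`, `pirs`, `interactions`, `peaks`, `tracks`,
#'   `sample_sheet`, and `truth` when ground-truth files are present.
#' @export
read_simulation <- function(dir) {
  ss <- read_sample_sheet(file.path(dir, "samples.tsv"))
  tracks <- lapply(seq_len(nrow(ss)), function(i) {
    list(blocks = read_bedgraph(file.path(dir, ss$track_path[i])),
         mark = ss$mark[i], sample_id = ss$sample_id[i],
         condition = ss$condition[i])
  })
  peaks <- NULL
  pm <- file.path(dir, "peaks.tsv")
  if (file.exists(pm)) {
    man <- utils::read.table(pm, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    peaks <- read_peaks(file.path(dir, man$path), man$sample_id, man$mark)
  }
  truth <- NULL
  if (file.exists(file.path(dir, "markers.txt"))) {
    truth <- list(markers = readLines(file.path(dir, "markers.txt")))
  }
  list(promoters = read_bed(file.path(dir, "promoters.bed"), "promoter"),
       pirs = read_bed(file.path(dir, "pirs.bed"), "pir"),
       interactions = read_interactions(file.path(dir, "interactions.tsv")),
       peaks = peaks, tracks = tracks, sample_sheet = ss, truth = truth)
}

#' Evaluate a ranking against the planted markers
#'
#' ECDF/AUC enrichment of the simulation's marker genes in a ranked list —
#' the parameter-recovery readout for synthetic data.
#'
#' @param ranked Ranked list from [rank_genes()].
#' @param truth Ground truth (`$truth` of an [simulate_epigenome()] result).
#' @return An [ecdf_curve()] result for the marker set.
#' @export
truth_eval <- function(ranked, truth) {
  ecdf_curve(ranked, truth$markers, name = "planted_markers")
}
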