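# Region ingestion, preprocessing and enhancer->promoter linkage.
#
# All coordinates are 0-based, half-open (BED convention). Regions live in
# plain data frames; GRanges objects are built internally for overlap and
# nearest queries only.

# Read a tab-separated text file, skipping blank lines and header lines
# starting with "#", "track" or "browser". Returns the kept lines together
# with their original line numbers so error messages can point at the file.
.read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

.field <- function(fields, i) vapply(fields, function(f) f[[i]], character(1))

.parse_coord <- function(x, what, lineno, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(v) | v != floor(v))
  if (length(bad)) {
    stop(sprintf("malformed %s '%s' at line %d of %s", what, x[bad[1]],
                 lineno[bad[1]], path), call. = FALSE)
  }
  v
}

# GRanges view of a half-open region data frame (1-based closed internally).
.gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

.auto_id <- function(chrom, start, end) {
  make.unique(sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end)),
              sep = "_")
}

#' Read regions from a BED-like file
#'
#' Parses a tab-separated BED file (>= 3 columns) into a region data frame.
#' Header lines beginning with `#`, `track` or `browser` are skipped.
#' Coordinates are kept 0-based, half-open.
#'
#' For `kind = "promoter"` a fourth column carrying the gene identifier is
#' required; the transcription start site (`tss`) is taken as the record
#' midpoint, which is robust to both near-point TSS annotations and interval
#' promoters. For other kinds an optional fourth column is used as the
#' element id; ids are auto-generated as `chrom:start-end` (made unique)
#' when absent.
#'
#' @param path Path to a BED file.
#' @param kind One of `"promoter"`, `"pir"`, `"peak"`.
#' @return A data frame with columns `chrom`, `start`, `end`, `id`, plus
#'   `gene` and `tss` for promoters and `support_count` (initially `NA`)
#'   for PIRs. Input order is preserved.
#' @export
read_bed <- function(path, kind = c("pir", "promoter", "peak")) {
  kind <- match.arg(kind)
  raw <- .read_tab_lines(path)
  if (length(raw$lines) == 0L) {
    warning("no records in ", path)
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), id = character())
    if (kind == "promoter") { out$gene <- character(); out$tss <- numeric() }
    if (kind == "pir") out$support_count <- integer()
    return(out)
  }
  fields <- strsplit(raw$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (kind == "promoter") 4L else 3L
  bad <- which(nf < need)
  if (length(bad)) {
    stop(sprintf("malformed line %d of %s: expected >= %d tab-separated columns",
                 raw$lineno[bad[1]], path, need), call. = FALSE)
  }
  chrom <- .field(fields, 1L)
  start <- .parse_coord(.field(fields, 2L), "start", raw$lineno, path)
  end   <- .parse_coord(.field(fields, 3L), "end", raw$lineno, path)
  if (any(start < 0)) {
    stop(sprintf("negative start at line %d of %s",
                 raw$lineno[which(start < 0)[1]], path), call. = FALSE)
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop(sprintf("end <= start at line %d of %s", raw$lineno[bad[1]], path),
         call. = FALSE)
  }
  col4 <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else "", character(1)), "")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (kind == "promoter") {
    if (any(!nzchar(col4))) {
      stop(sprintf("empty gene id at line %d of %s",
                   raw$lineno[which(!nzchar(col4))[1]], path), call. = FALSE)
    }
    out$id <- .auto_id(chrom, start, end)
    out$gene <- col4
    out$tss <- floor((start + end) / 2)
  } else {
    out$id <- ifelse(nzchar(col4), col4, .auto_id(chrom, start, end))
    if (anyDuplicated(out$id)) out$id <- make.unique(out$id, sep = "_")
    if (kind == "pir") out$support_count <- NA_integer_
  }
  rownames(out) <- NULL
  out
}

#' Extend promoters around the transcription start site
#'
#' Replaces each promoter region by the window `[tss - extension,
#' tss + extension)` (clamped at 0), where `tss` is the record midpoint
#' assigned by [read_bed()]. An extension of 0 leaves regions unchanged.
#'
#' @param promoters Promoter data frame from [read_bed()].
#' @param extension Half-window size in bases (default 1000, giving 2-kb
#'   promoter windows).
#' @return The promoter data frame with updated `start`/`end`; ids, genes
#'   and `tss` are unchanged.
#' @export
extend_promoters <- function(promoters, extension = 1000) {
  stopifnot(extension >= 0)
  if (extension == 0) return(promoters)
  promoters$start <- pmax(0, promoters$tss - extension)
  promoters$end <- promoters$tss + extension
  promoters
}

#' Filter PIRs by peak support
#'
#' Retains promoter-interacting regions overlapped (>= 1 bp) by a peak of
#' one of the given marks in at least `min_samples` distinct samples, pooled
#' across both conditions. Samples, not peaks, are counted: several peaks
#' from one sample contribute a single unit of support.
#'
#' @param pirs PIR data frame.
#' @param peaks Peak table with columns `chrom`, `start`, `end`,
#'   `sample_id`, `mark` (see [read_peaks()]).
#' @param marks Marks whose peaks confer support (default H3K4me1/H3K27ac,
#'   the canonical enhancer-associated marks).
#' @param min_samples Minimum number of supporting samples (default 2).
#' @return The retained PIRs with `support_count` filled in.
#' @export
filter_pirs_by_peaks <- function(pirs, peaks,
                                 marks = c("H3K4me1", "H3K27ac"),
                                 min_samples = 2L) {
  if (is.null(peaks) || nrow(peaks) == 0L) {
    stop("no peak calls supplied; either provide peaks or disable the PIR ",
         "support filter explicitly (filter_pirs = FALSE)", call. = FALSE)
  }
  pk <- peaks[peaks$mark %in% marks, , drop = FALSE]
  support <- integer(nrow(pirs))
  if (nrow(pk) > 0L && nrow(pirs) > 0L) {
    ov <- GenomicRanges::findOverlaps(.gr(pirs), .gr(pk))
    if (length(ov)) {
      n_by_pir <- tapply(pk$sample_id[S4Vectors::subjectHits(ov)],
                         S4Vectors::queryHits(ov),
                         function(s) length(unique(s)))
      support[as.integer(names(n_by_pir))] <- as.integer(n_by_pir)
    }
  }
  pirs$support_count <- support
  kept <- pirs[support >= min_samples, , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Read peak calls for several samples
#'
#' @param paths BED file paths, one per (sample, mark) track.
#' @param sample_ids,marks Vectors parallel to `paths`.
#' @return One combined peak table (`chrom`, `start`, `end`, `sample_id`,
#'   `mark`).
#' @export
read_peaks <- function(paths, sample_ids, marks) {
  stopifnot(length(paths) == length(sample_ids),
            length(paths) == length(marks))
  out <- lapply(seq_along(paths), function(i) {
    b <- read_bed(paths[i], kind = "peak")
    if (nrow(b) == 0L) return(NULL)
    data.frame(chrom = b$chrom, start = b$start, end = b$end,
               sample_id = sample_ids[i], mark = marks[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read a chromatin interaction table
#'
#' Expects tab-separated records `chromA startA endA chromB startB endB
#' [source]` (BEDPE-compatible). Header lines starting with `#`/`track` are
#' skipped.
#'
#' @param path Path to the interaction file.
#' @return Data frame with columns `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `source`.
#' @export
read_interactions <- function(path) {
  raw <- .read_tab_lines(path)
  if (length(raw$lines) == 0L) {
    warning("no records in ", path)
    return(data.frame(chrom_a = character(), start_a = numeric(),
                      end_a = numeric(), chrom_b = character(),
                      start_b = numeric(), end_b = numeric(),
                      source = character()))
  }
  fields <- strsplit(raw$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad)) {
    stop(sprintf("malformed line %d of %s: expected >= 6 columns",
                 raw$lineno[bad[1]], path), call. = FALSE)
  }
  out <- data.frame(
    chrom_a = .field(fields, 1L),
    start_a = .parse_coord(.field(fields, 2L), "startA", raw$lineno, path),
    end_a   = .parse_coord(.field(fields, 3L), "endA", raw$lineno, path),
    chrom_b = .field(fields, 4L),
    start_b = .parse_coord(.field(fields, 5L), "startB", raw$lineno, path),
    end_b   = .parse_coord(.field(fields, 6L), "endB", raw$lineno, path),
    stringsAsFactors = FALSE)
  out$source <- ifelse(nf >= 7L,
                       vapply(fields, function(f)
                         if (length(f) >= 7L) f[[7L]] else "", character(1)),
                       "")
  if (any(out$end_a <= out$start_a | out$end_b <= out$start_b)) {
    i <- which(out$end_a <= out$start_a | out$end_b <= out$start_b)[1]
    stop(sprintf("end <= start at line %d of %s", raw$lineno[i], path),
         call. = FALSE)
  }
  out
}

#' Read a sample sheet
#'
#' Tab-separated with a header row and columns `track_path`, `condition`,
#' `mark`, `sample_id`. Conditions must be the two labels `A` and `B`; each
#' mark needs at least one sample per condition, and (mark, sample_id,
#' condition) must be unique.
#'
#' @param path Sample sheet path.
#' @return Validated sample sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("track_path", "condition", "mark", "sample_id")
  miss <- setdiff(need, names(ss))
  if (length(miss)) stop("sample sheet lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  validate_sample_sheet(ss)
  ss
}

validate_sample_sheet <- function(ss) {
  if (!all(ss$condition %in% c("A", "B"))) {
    stop("conditions must be labelled 'A' and 'B'", call. = FALSE)
  }
  key <- paste(ss$mark, ss$sample_id, ss$condition)
  if (anyDuplicated(key)) {
    stop("duplicated (mark, sample_id, condition) in sample sheet",
         call. = FALSE)
  }
  tab <- table(ss$mark, ss$condition)
  if (ncol(tab) < 2L || any(tab == 0L)) {
    bad <- rownames(tab)[rowSums(tab == 0L) > 0 | ncol(tab) < 2L][1]
    stop("mark '", bad, "' lacks samples in one condition", call. = FALSE)
  }
  invisible(ss)
}

#' Read gene sets
#'
#' Either one gene per line (a single set named after the file) or
#' two-column tab-separated `set<TAB>gene` records (a named list of sets).
#'
#' @param path Gene set file path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  raw <- .read_tab_lines(path)
  if (length(raw$lines) == 0L) stop("no genes in ", path, call. = FALSE)
  fields <- strsplit(raw$lines, "\t", fixed = TRUE)
  if (all(lengths(fields) >= 2L)) {
    sets <- split(.field(fields, 2L), .field(fields, 1L))
    lapply(sets, unique)
  } else {
    nm <- sub("\\.[^.]*$", "", basename(path))
    stats::setNames(list(unique(.field(fields, 1L))), nm)
  }
}

#' Link PIRs to promoters by chromatin interaction evidence
#'
#' Emits a directed edge (PIR -> promoter) whenever one anchor of an
#' interaction record overlaps (>= 1 bp) a retained PIR and the other anchor
#' overlaps an extended promoter, in either anchor orientation. Duplicate
#' (pir, promoter) pairs are collapsed.
#'
#' @param promoters Extended promoter data frame.
#' @param pirs Retained PIR data frame.
#' @param interactions Interaction table from [read_interactions()].
#' @return Data frame of edges (`pir_id`, `promoter_id`). Records matching
#'   nothing are dropped and their count reported via `message()`.
#' @export
link_by_interactions <- function(promoters, pirs, interactions) {
  if (nrow(interactions) == 0L || nrow(pirs) == 0L || nrow(promoters) == 0L) {
    return(data.frame(pir_id = character(), promoter_id = character()))
  }
  ga <- .gr(data.frame(chrom = interactions$chrom_a,
                       start = interactions$start_a,
                       end = interactions$end_a))
  gb <- .gr(data.frame(chrom = interactions$chrom_b,
                       start = interactions$start_b,
                       end = interactions$end_b))
  gp <- .gr(promoters)
  gq <- .gr(pirs)
  hits <- function(anchors, targets) {
    ov <- GenomicRanges::findOverlaps(anchors, targets)
    data.frame(rec = S4Vectors::queryHits(ov),
               idx = S4Vectors::subjectHits(ov))
  }
  cross <- function(pir_hits, prom_hits) {
    m <- merge(pir_hits, prom_hits, by = "rec",
               suffixes = c("_pir", "_prom"))
    m
  }
  m <- rbind(cross(hits(ga, gq), hits(gb, gp)),
             cross(hits(gb, gq), hits(ga, gp)))
  matched <- unique(m$rec)
  n_drop <- nrow(interactions) - length(matched)
  if (n_drop > 0) {
    message(n_drop, " interaction record(s) matched no PIR-promoter pair")
  }
  edges <- unique(data.frame(pir_id = pirs$id[m$idx_pir],
                             promoter_id = promoters$id[m$idx_prom],
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  edges
}

#' Link each PIR to its nearest promoter
#'
#' Assigns every PIR one edge to the promoter whose TSS is closest to the
#' PIR midpoint on the same chromosome; ties are broken toward the lower
#' TSS coordinate. PIRs on chromosomes carrying no promoter are dropped
#' with a warning.
#'
#' @inheritParams link_by_interactions
#' @return Data frame of edges (`pir_id`, `promoter_id`), one per linkable
#'   PIR.
#' @export
link_by_nearest <- function(promoters, pirs) {
  if (nrow(pirs) == 0L) {
    return(data.frame(pir_id = character(), promoter_id = character()))
  }
  mid <- floor((pirs$start + pirs$end) / 2)
  out <- vector("list", 0L)
  dropped <- 0L
  for (ch in unique(pirs$chrom)) {
    pi <- which(pirs$chrom == ch)
    pj <- which(promoters$chrom == ch)
    if (length(pj) == 0L) { dropped <- dropped + length(pi); next }
    o <- pj[order(promoters$tss[pj], promoters$id[pj])]
    ts <- promoters$tss[o]
    pos <- findInterval(mid[pi], ts)
    left <- ifelse(pos >= 1L, pos, NA_integer_)
    right <- ifelse(pos + 1L <= length(ts), pos + 1L, NA_integer_)
    dl <- ifelse(is.na(left), Inf, mid[pi] - ts[left])
    dr <- ifelse(is.na(right), Inf, ts[right] - mid[pi])
    pick <- ifelse(dl <= dr, left, right)  # tie -> lower tss (left)
    out[[length(out) + 1L]] <- data.frame(
      pir_id = pirs$id[pi],
      promoter_id = promoters$id[o[pick]],
      stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    warning(dropped, " PIR(s) on chromosomes without promoters were dropped")
  }
  edges <- do.call(rbind, out)
  if (is.null(edges)) edges <- data.frame(pir_id = character(),
                                          promoter_id = character())
  rownames(edges) <- NULL
  edges
}
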