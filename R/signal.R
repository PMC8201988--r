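# Signal summarization over regulatory elements, normalization, and the
# between-condition difference matrix D.

#' Read a bedGraph track
#'
#' Four-column tab-separated block values. Values must be finite and
#' nonnegative; blocks must not overlap within a chromosome.
#'
#' @param path bedGraph file path.
#' @return Data frame of blocks (`chrom`, `start`, `end`, `value`),
#'   0-based half-open.
#' @export
read_bedgraph <- function(path) {
  raw <- .read_tab_lines(path)
  if (length(raw$lines) == 0L) {
    warning("no blocks in ", path)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  }
  fields <- strsplit(raw$lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) {
    stop(sprintf("malformed line %d of %s: expected 4 columns",
                 raw$lineno[bad[1]], path), call. = FALSE)
  }
  out <- data.frame(
    chrom = .field(fields, 1L),
    start = .parse_coord(.field(fields, 2L), "start", raw$lineno, path),
    end   = .parse_coord(.field(fields, 3L), "end", raw$lineno, path),
    value = suppressWarnings(as.numeric(.field(fields, 4L))),
    stringsAsFactors = FALSE)
  if (any(!is.finite(out$value) | out$value < 0)) {
    i <- which(!is.finite(out$value) | out$value < 0)[1]
    stop(sprintf("non-finite or negative value at line %d of %s",
                 raw$lineno[i], path), call. = FALSE)
  }
  if (any(out$end <= out$start)) {
    i <- which(out$end <= out$start)[1]
    stop(sprintf("end <= start at line %d of %s", raw$lineno[i], path),
         call. = FALSE)
  }
  o <- order(out$chrom, out$start)
  so <- out[o, ]
  same <- so$chrom[-1] == so$chrom[-nrow(so)]
  if (nrow(so) > 1L && any(same & so$start[-1] < so$end[-nrow(so)])) {
    stop("overlapping blocks in ", path, call. = FALSE)
  }
  out
}

#' Summarize block signal over elements
#'
#' Coverage-weighted sum: for each element, the sum over overlapping blocks
#' of `value * overlapped bases`. This makes the statistic independent of
#' how a track splits identical coverage into blocks. Elements without any
#' overlapping block get 0.
#'
#' @param blocks Block data frame (`chrom`, `start`, `end`, `value`).
#' @param elements Element data frame (`chrom`, `start`, `end`, `id`).
#' @return Named numeric vector, one value per element.
#' @export
summarize_signal <- function(blocks, elements) {
  v <- stats::setNames(numeric(nrow(elements)), elements$id)
  miss <- setdiff(unique(elements$chrom), unique(blocks$chrom))
  if (length(miss)) {
    warning("chromosome(s) absent from track: ", paste(miss, collapse = ", "))
  }
  if (nrow(blocks) == 0L || nrow(elements) == 0L) return(v)
  ge <- .gr(elements)
  gb <- .gr(blocks)
  ov <- GenomicRanges::findOverlaps(ge, gb)
  if (length(ov) == 0L) return(v)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    ge[S4Vectors::queryHits(ov)], gb[S4Vectors::subjectHits(ov)]))
  contrib <- blocks$value[S4Vectors::subjectHits(ov)] * w
  s <- rowsum(contrib, S4Vectors::queryHits(ov))
  v[as.integer(rownames(s))] <- s[, 1]
  v
}

#' Rescale a summarized value to a fixed length scale
#'
#' Converts a coverage-weighted sum over an element into an intensity per
#' `scale` bases (default 1 kb), so elements of different lengths are
#' comparable.
#'
#' @param value Summarized value(s).
#' @param element_length Element length(s) in bases (> 0).
#' @param scale Reference length in bases (default 1000).
#' @return `value * scale / element_length`.
#' @export
bin_to_scale <- function(value, element_length, scale = 1000) {
  if (any(element_length <= 0)) stop("element_length must be > 0",
                                     call. = FALSE)
  value * scale / element_length
}

#' Power-transform nonnegative signal
#'
#' Elementwise `x^exponent` with `exponent` in (0, 1]; monotone and
#' order-preserving per column. The default square root stabilizes the
#' variance of count-like coverage.
#'
#' @param x Nonnegative numeric vector or matrix.
#' @param exponent Power in (0, 1] (default 0.5).
#' @export
power_transform <- function(x, exponent = 0.5) {
  if (exponent <= 0 || exponent > 1) stop("exponent must be in (0, 1]",
                                          call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) stop("negative values in signal matrix",
                                     call. = FALSE)
  x^exponent
}

#' Element-by-sample signal matrix
#'
#' Container pairing a numeric matrix (elements x tracks) with the
#' (mark, sample, condition) annotation of its columns.
#'
#' @param values Numeric matrix; rownames are element ids.
#' @param columns Data frame with columns `mark`, `sample_id`, `condition`,
#'   one row per matrix column.
#' @param normalized Logical flag set by [normalize_signal()].
#' @return An object of class `element_signal_matrix`.
#' @export
element_signal_matrix <- function(values, columns, normalized = FALSE) {
  stopifnot(is.matrix(values), nrow(columns) == ncol(values),
            all(c("mark", "sample_id", "condition") %in% names(columns)))
  if (any(!is.finite(values))) stop("non-finite values in signal matrix",
                                    call. = FALSE)
  colnames(values) <- paste(columns$mark, columns$sample_id, sep = ".")
  structure(list(values = values, columns = columns,
                 normalized = normalized),
            class = "element_signal_matrix")
}

#' @export
print.element_signal_matrix <- function(x, ...) {
  cat(sprintf("element_signal_matrix: %d elements x %d tracks (%d marks)%s\n",
              nrow(x$values), ncol(x$values), length(unique(x$columns$mark)),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Summarize a set of signal tracks over elements
#'
#' Applies [summarize_signal()] to every track and, when `scale` is not
#' `NULL`, rescales each element to per-`scale`-base intensity with
#' [bin_to_scale()].
#'
#' @param tracks List of tracks; each a list with components `blocks`
#'   (block data frame), `mark`, `sample_id`, `condition`.
#' @param elements Element data frame (`chrom`, `start`, `end`, `id`).
#' @param scale Reference length in bases, or `NULL` to keep raw sums.
#' @return An [element_signal_matrix()].
#' @export
summarize_tracks <- function(tracks, elements, scale = 1000) {
  stopifnot(length(tracks) > 0)
  len <- elements$end - elements$start
  vals <- vapply(tracks, function(tr) {
    v <- summarize_signal(tr$blocks, elements)
    if (!is.null(scale)) v <- bin_to_scale(v, len, scale)
    v
  }, numeric(nrow(elements)))
  vals <- matrix(vals, nrow = nrow(elements),
                 dimnames = list(elements$id, NULL))
  columns <- data.frame(
    mark = vapply(tracks, `[[`, character(1), "mark"),
    sample_id = vapply(tracks, `[[`, character(1), "sample_id"),
    condition = vapply(tracks, `[[`, character(1), "condition"),
    stringsAsFactors = FALSE)
  element_signal_matrix(vals, columns)
}

#' Quantile-normalize a signal matrix within each mark
#'
#' Within one mark, all samples of both conditions are mapped so that every
#' column shares the across-column mean of sorted values; ties receive the
#' mean of the reference values at their tied positions
#' (`limma::normalizeQuantiles`). Marks with a single column are returned
#' unchanged with a warning. Normalizing within (never across) marks keeps
#' each mark's dynamic range while leaving between-condition differences
#' intact.
#'
#' @param x An [element_signal_matrix()], or a plain numeric matrix treated
#'   as the samples of one mark.
#' @return Object of the same type with normalized values.
#' @export
quantile_normalize <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) < 2L) {
      warning("single-column matrix: quantile normalization skipped")
      return(x)
    }
    return(limma::normalizeQuantiles(x, ties = TRUE))
  }
  stopifnot(inherits(x, "element_signal_matrix"))
  for (m in unique(x$columns$mark)) {
    idx <- which(x$columns$mark == m)
    if (length(idx) < 2L) {
      warning("mark '", m, "' has a single sample: quantile normalization ",
              "skipped")
      next
    }
    x$values[, idx] <- limma::normalizeQuantiles(
      x$values[, idx, drop = FALSE], ties = TRUE)
  }
  x
}

#' Normalize an element signal matrix
#'
#' Power transform followed by within-mark quantile normalization; sets the
#' `normalized` flag consumed by [difference_matrix()].
#'
#' @param esm An [element_signal_matrix()].
#' @param power Exponent for [power_transform()]; default 0.5.
#' @param quantile Run [quantile_normalize()] (default `TRUE`).
#' @return Normalized [element_signal_matrix()].
#' @export
normalize_signal <- function(esm, power = 0.5, quantile = TRUE) {
  stopifnot(inherits(esm, "element_signal_matrix"))
  esm$values <- power_transform(esm$values, power)
  if (quantile) esm <- quantile_normalize(esm)
  esm$normalized <- TRUE
  esm
}

#' Between-condition mean difference matrix
#'
#' For every mark, `D[g, m]` is the mean normalized signal over condition-A
#' samples minus the mean over condition-B samples at element `g`. This
#' G x M matrix is the input of [dpca()].
#'
#' @param esm A normalized [element_signal_matrix()].
#' @param cond_a,cond_b Condition labels (defaults `"A"`, `"B"`).
#' @return Numeric G x M matrix; rownames element ids, colnames marks.
#' @export
difference_matrix <- function(esm, cond_a = "A", cond_b = "B") {
  stopifnot(inherits(esm, "element_signal_matrix"))
  if (!esm$normalized) {
    warning("signal matrix has not been normalized; D computed on raw values")
  }
  marks <- unique(esm$columns$mark)
  D <- matrix(0, nrow(esm$values), length(marks),
              dimnames = list(rownames(esm$values), marks))
  for (m in marks) {
    ia <- which(esm$columns$mark == m & esm$columns$condition == cond_a)
    ib <- which(esm$columns$mark == m & esm$columns$condition == cond_b)
    if (length(ia) == 0L || length(ib) == 0L) {
      stop("mark '", m, "' is missing samples in one condition",
           call. = FALSE)
    }
    D[, m] <- rowMeans(esm$values[, ia, drop = FALSE]) -
      rowMeans(esm$values[, ib, drop = FALSE])
  }
  D
}
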