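#' Per-cell mCherry:GFP ratios for gated cells
#'
#' Computes `mcherry / gfp` for every event retained by the gate. Cells
#' with non-positive signal in either channel are excluded — not clamped
#' — because a ratio with a non-positive denominator is undefined and
#' clamping would bias the distribution tail; the exclusion count is
#' kept so drop accounting stays exact across the pipeline.
#'
#' @param table An [event_table()].
#' @param gate A [gate_live()] result for `table`, or `NULL` to use all
#'   events (a pass-through gate).
#' @return An object of class `raw_ratios`: `sample_id`, `ratios`
#'   (numeric, one per usable gated cell), `n_gated`,
#'   `n_dropped_nonpositive` (within the gate), with
#'   `n_used = length(ratios) = n_gated - n_dropped_nonpositive`.
#' @export
compute_ratios <- function(table, gate = NULL) {
  if (!inherits(table, "event_table")) {
    stop("`table` must be an event_table", call. = FALSE)
  }
  if (is.null(gate)) {
    mask <- rep(TRUE, nrow(table))
  } else {
    if (!inherits(gate, "gate_result") || length(gate$mask) != nrow(table)) {
      stop("`gate` mask does not match `table`", call. = FALSE)
    }
    mask <- gate$mask
  }
  g <- table$gfp[mask]
  r <- table$mcherry[mask]
  usable <- g > 0 & r > 0
  if (!any(usable)) {
    stop("no gated cell has positive signal in both channels", call. = FALSE)
  }
  structure(list(
    sample_id = attr(table, "sample_id"),
    ratios = r[usable] / g[usable],
    n_gated = sum(mask),
    n_dropped_nonpositive = sum(!usable)
  ), class = "raw_ratios")
}

#' Normalize mutant ratios to the matched wild-type-rescue reference
#'
#' Divides every per-cell mutant ratio by a scalar reference ratio
#' computed from the wild-type-rescue sample of the same knockout
#' background and client. The default reference statistic is the median
#' of the wild-type per-cell ratios: the assay's ratio distributions are
#' strongly right-skewed, and the median is insensitive to that tail
#' (the mean is available as an option). A wild-type sample normalized
#' against itself therefore has central statistic exactly 1.
#'
#' @param mutant_ratios A [compute_ratios()] result (or numeric vector)
#'   for the mutant sample.
#' @param wt_ratios Same, for the matched wild-type reference.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return An object of class `ratio_set`: `sample_id`, `ratios_raw`,
#'   `normalizer`, `ratios_norm = ratios_raw / normalizer`, `n_used`,
#'   `n_dropped_nonpositive`.
#' @export
normalize_to_reference <- function(mutant_ratios, wt_ratios,
                                   statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  mut <- as_raw_ratios(mutant_ratios)
  wt <- as_raw_ratios(wt_ratios)
  if (length(mut$ratios) == 0L || length(wt$ratios) == 0L) {
    stop("both ratio vectors must be non-empty", call. = FALSE)
  }
  normalizer <- switch(statistic,
                       median = stats::median(wt$ratios),
                       mean = mean(wt$ratios))
  if (!is.finite(normalizer) || normalizer <= 0) {
    stop("reference ", statistic, " is not a positive finite number",
         call. = FALSE)
  }
  structure(list(
    sample_id = mut$sample_id,
    ratios_raw = mut$ratios,
    normalizer = normalizer,
    ratios_norm = mut$ratios / normalizer,
    n_used = length(mut$ratios),
    n_dropped_nonpositive = mut$n_dropped_nonpositive
  ), class = "ratio_set")
}

as_raw_ratios <- function(x) {
  if (inherits(x, "raw_ratios")) return(x)
  if (inherits(x, "ratio_set")) {
    return(structure(list(sample_id = x$sample_id, ratios = x$ratios_norm,
                          n_gated = x$n_used,
                          n_dropped_nonpositive = x$n_dropped_nonpositive),
                     class = "raw_ratios"))
  }
  if (is.numeric(x)) {
    return(structure(list(sample_id = "vector", ratios = as.numeric(x),
                          n_gated = length(x), n_dropped_nonpositive = 0L),
                     class = "raw_ratios"))
  }
  stop("expected a raw_ratios object or numeric vector", call. = FALSE)
}

#' @export
print.ratio_set <- function(x, ...) {
  cat(sprintf(
    "<ratio_set> sample '%s': %d cells, normalizer %.4g, median norm %.4g\n",
    x$sample_id, x$n_used, x$normalizer, stats::median(x$ratios_norm)))
  invisible(x)
}

#' Histogram of normalized ratios on a log10 axis
#'
#' Bins normalized per-cell ratios into log10-spaced bins over `range`.
#' Values outside the range are clipped into the edge bins, so counts
#' always sum to the number of cells — nothing silently vanishes from a
#' histogram.
#'
#' @param ratio_set A [normalize_to_reference()] result (or numeric
#'   vector of positive ratios).
#' @param n_bins Number of bins.
#' @param range Length-2 positive numeric, lower and upper ratio bound.
#' @return Data frame with `bin_left`, `bin_right`, `count`.
#' @export
histogram_summary <- function(ratio_set, n_bins = 64L,
                              range = c(1e-2, 1e2)) {
  v <- if (inherits(ratio_set, "ratio_set")) ratio_set$ratios_norm
       else as.numeric(ratio_set)
  if (length(v) == 0L) stop("ratio set is empty", call. = FALSE)
  if (length(range) != 2L || !all(is.finite(range)) || any(range <= 0) ||
      range[2] <= range[1]) {
    stop("`range` must be two increasing positive numbers", call. = FALSE)
  }
  n_bins <- as.integer(check_scalar(n_bins, "n_bins", lower = 1))
  edges <- 10^seq(log10(range[1]), log10(range[2]), length.out = n_bins + 1L)
  lv <- pmin(pmax(log10(v), log10(range[1])), log10(range[2]))
  idx <- findInterval(lv, log10(edges), rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_left = edges[-(n_bins + 1L)], bin_right = edges[-1L],
             count = counts)
}
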