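# Rolling-window compartment enrichment for localization reporter assays.
#
# A sheared-fragment reporter library is expressed in cells grown on a
# porous transwell; RNA is harvested separately from cell bodies and
# projections and sequenced alongside the input plasmid pool. Windows of
# the reference UTR are scored by counting reads that fall entirely within
# each window, normalizing each compartment by the input, and scaling the
# per-window compartment difference so its maximum is 1.

#' Build the rolling window grid
#'
#' Fixed-size windows every `step` nt along the reference; a final partial
#' window is never emitted (every window has length `window_size`).
#'
#' @param ref_length Reference length in nt.
#' @param window_size Window width in nt (default 250).
#' @param step Offset between consecutive window starts in nt (default 5).
#' @param ref_id Reference identifier.
#' @return A `window_grid`: interval data.frame with attributes
#'   `window_size`, `step`, `ref_length`.
#' @examples
#' nrow(make_windows(1500))  # 251 windows
#' @export
make_windows <- function(ref_length, window_size = 250, step = 5,
                         ref_id = "ref") {
  stopifnot(ref_length > 0, step > 0)
  if (window_size <= 0 || window_size > ref_length) {
    stop("window_size must be in (0, ref_length]")
  }
  starts <- seq.int(0L, ref_length - window_size, by = step)
  grid <- intervals(start = starts, end = starts + as.integer(window_size),
                    ref_id = ref_id)
  attr(grid, "window_size") <- as.integer(window_size)
  attr(grid, "step") <- as.integer(step)
  attr(grid, "ref_length") <- as.integer(ref_length)
  class(grid) <- c("window_grid", class(grid))
  grid
}

#' Count reads entirely contained in each window
#'
#' A read counts toward a window only if the window fully contains it
#' (`window.start <= read.start` and `read.end <= window.end`); one read
#' may count toward many overlapping windows, and reads longer than the
#' window size never count. Reads are never clipped.
#'
#' @param reads Interval data.frame of aligned reads.
#' @param grid Window grid from [make_windows()].
#' @return Integer vector of counts, one per window.
#' @export
count_contained <- function(reads, grid) {
  validate_intervals(reads)
  validate_intervals(grid)
  if (nrow(reads) > 0) single_ref(reads, grid)
  if (nrow(reads) == 0) return(integer(nrow(grid)))
  hits <- IRanges::findOverlaps(as_iranges(reads), as_iranges(grid),
                                type = "within")
  tabulate(S4Vectors::subjectHits(hits), nbins = nrow(grid))
}

#' Normalize compartment counts by the input library
#'
#' Per-window compartment counts divided by per-window input counts.
#' Windows whose input count is below `min_input` are masked: the ratio is
#' unstable at near-zero denominators and masked windows are excluded from
#' all downstream maxima.
#'
#' @param sample_counts,input_counts Nonnegative integer vectors of equal
#'   length.
#' @param min_input Minimum input reads for a window to stay unmasked
#'   (default 10).
#' @return List with `norm` (numeric, `NA` where masked) and `mask`
#'   (logical, `TRUE` = valid).
#' @export
normalize_by_input <- function(sample_counts, input_counts, min_input = 10) {
  stopifnot(length(sample_counts) == length(input_counts))
  if (any(sample_counts < 0) || any(input_counts < 0)) {
    stop("counts must be nonnegative")
  }
  mask <- input_counts >= min_input
  norm <- rep(NA_real_, length(sample_counts))
  norm[mask] <- sample_counts[mask] / input_counts[mask]
  list(norm = norm, mask = mask)
}

#' Scale per-window compartment differences to a maximum of 1
#'
#' The enrichment statistic is the per-window difference between the two
#' input-normalized compartments, scaled so that the maximum over unmasked
#' windows equals 1. If no window has a positive difference the track is
#' scaled by the maximum absolute difference instead (with a warning), and
#' an all-zero difference track is returned unscaled.
#'
#' @param norm_num Normalized counts for the compartment given positive
#'   sign (numerator of the contrast; projection under the default sign
#'   convention).
#' @param norm_den Normalized counts for the opposite compartment.
#' @param mask Logical validity per window.
#' @return Numeric vector of scaled enrichments (`NA` where masked).
#' @export
enrichment_scale <- function(norm_num, norm_den, mask) {
  stopifnot(length(norm_num) == length(norm_den),
            length(norm_num) == length(mask))
  if (!any(mask)) stop("all windows are masked; no enrichment to compute")
  diff <- norm_num - norm_den
  diff[!mask] <- NA_real_
  mx <- max(diff, na.rm = TRUE)
  if (mx > 0) {
    diff / mx
  } else if (any(diff != 0, na.rm = TRUE)) {
    warning("no window with positive difference; scaling by max |difference|")
    diff / max(abs(diff), na.rm = TRUE)
  } else {
    diff
  }
}

#' Compute a rolling-window compartment enrichment track
#'
#' End-to-end quantification for one three-sample experiment (input
#' plasmid pool, cell-body compartment, projection compartment): build the
#' window grid, count contained reads per sample, normalize compartments
#' by input, and scale the compartment difference to a maximum of 1.
#'
#' @param input,body,projection Interval data.frames of aligned reads for
#'   the three samples.
#' @param ref_length Reference UTR length in nt.
#' @param window_size,step Window geometry in nt (defaults 250 and 5).
#' @param min_input Input-coverage floor per window (default 10 reads).
#' @param sign `"projection"` (default) scores projection-minus-body so
#'   that positive enrichment means projection-localized; `"body"` flips
#'   the contrast.
#' @param ref_id Reference identifier for the window grid; inferred from
#'   the reads when `NULL`.
#' @return A `slap_track` object: list with the window `grid`, per-window
#'   raw `counts` (3-column matrix), `norm_body`, `norm_projection`,
#'   `mask`, `enrichment`, and the parameters used.
#' @examples
#' truth <- synthetic_truth(seed = 1, n_fragments = 500,
#'                          depths = c(input = 5e3, body = 5e3, projection = 5e3))
#' frags <- generate_fragment_library(truth)
#' reads <- simulate_compartment_reads(truth, frags)
#' tr <- slap_enrichment(reads$input, reads$body, reads$projection,
#'                       ref_length = truth$utr_length)
#' max(tr$enrichment, na.rm = TRUE)  # 1 by construction
#' @export
slap_enrichment <- function(input, body, projection, ref_length,
                            window_size = 250, step = 5, min_input = 10,
                            sign = c("projection", "body"), ref_id = NULL) {
  sign <- match.arg(sign)
  if (is.null(ref_id)) ref_id <- single_ref(input, body, projection)
  grid <- make_windows(ref_length, window_size, step, ref_id = ref_id)
  counts <- cbind(
    input = count_contained(input, grid),
    body = count_contained(body, grid),
    projection = count_contained(projection, grid)
  )
  nb <- normalize_by_input(counts[, "body"], counts[, "input"], min_input)
  np <- normalize_by_input(counts[, "projection"], counts[, "input"], min_input)
  mask <- nb$mask & np$mask
  enr <- if (sign == "projection") {
    enrichment_scale(np$norm, nb$norm, mask)
  } else {
    enrichment_scale(nb$norm, np$norm, mask)
  }
  structure(list(
    grid = grid,
    counts = counts,
    norm_body = nb$norm,
    norm_projection = np$norm,
    mask = mask,
    enrichment = enr,
    sign = sign,
    params = list(window_size = window_size, step = step,
                  min_input = min_input, ref_length = ref_length)
  ), class = "slap_track")
}

#' @export
print.slap_track <- function(x, ...) {
  cat(sprintf("<slap_track> %d windows of %d nt every %d nt on %s (%d nt)\n",
              nrow(x$grid), x$params$window_size, x$params$step,
              x$grid$ref_id[1], x$params$ref_length))
  cat(sprintf("  sign: %s-positive; masked windows: %d of %d\n",
              x$sign, sum(!x$mask), length(x$mask)))
  if (any(x$mask)) {
    i <- which.max(x$enrichment)
    cat(sprintf("  peak window: %d-%d (1-based), enrichment %.3f\n",
                x$grid$start[i] + 1L, x$grid$end[i], x$enrichment[i]))
  }
  invisible(x)
}

#' @export
summary.slap_track <- function(object, ...) {
  cat(sprintf("Rolling-window enrichment over %d windows (%d masked)\n",
              length(object$mask), sum(!object$mask)))
  print(summary(object$enrichment[object$mask]))
  invisible(object)
}

#' @export
as.data.frame.slap_track <- function(x, ...) {
  data.frame(
    ref_id = x$grid$ref_id, start = x$grid$start, end = x$grid$end,
    input = x$counts[, "input"], body = x$counts[, "body"],
    projection = x$counts[, "projection"],
    norm_body = x$norm_body, norm_projection = x$norm_projection,
    mask = x$mask, enrichment = x$enrichment,
    stringsAsFactors = FALSE
  )
}

#' Plot an enrichment track along the reference
#'
#' @param x A `slap_track`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.slap_track <- function(x, ...) {
  mid <- (x$grid$start + x$grid$end) / 2
  graphics::plot(mid, x$enrichment, type = "l",
                 xlab = "position (nt, window midpoint)",
                 ylab = "scaled enrichment", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Call candidate regions from an enrichment track
#'
#' Windows with enrichment at least `threshold_fraction` times the track
#' maximum are selected. With `refine = "union"` overlapping selected
#' windows are merged into maximal intervals (the region covered by any
#' qualifying window). With `refine = "core"` each merged block is reduced
#' to the span common to all of its qualifying windows: since a window is
#' enriched only when it wholly contains the element, the element must lie
#' in that intersection, which delimits candidates to sub-window
#' resolution. A core is only defined while qualifying starts within a
#' block span less than one window; wider blocks fall back to their union.
#'
#' @param track A `slap_track`.
#' @param threshold_fraction Fraction of the track maximum (default 0.5).
#' @param refine `"union"` (default) or `"core"`.
#' @return Interval data.frame of called regions (possibly 0 rows).
#' @export
call_regions <- function(track, threshold_fraction = 0.5,
                         refine = c("union", "core")) {
  stopifnot(inherits(track, "slap_track"))
  refine <- match.arg(refine)
  enr <- track$enrichment
  sel <- which(track$mask & !is.na(enr) &
                 enr >= threshold_fraction * max(enr, na.rm = TRUE))
  if (length(sel) == 0) {
    return(intervals(integer(0), integer(0), ref_id = character(0)))
  }
  win <- track$grid[sel, , drop = FALSE]
  merged <- merge_intervals(win)
  if (refine == "union") return(merged)
  # per merged block, intersect the qualifying windows it contains
  core <- lapply(seq_len(nrow(merged)), function(i) {
    inblk <- win$start >= merged$start[i] & win$end <= merged$end[i]
    s <- max(win$start[inblk])
    e <- min(win$end[inblk])
    if (s < e) c(s, e) else c(merged$start[i], merged$end[i])
  })
  core <- do.call(rbind, core)
  intervals(start = core[, 1], end = core[, 2], ref_id = merged$ref_id)
}

#' Delimit a minimal signal from sufficient and insufficient regions
#'
#' Nucleotides covered by the union of regions shown sufficient for
#' localization but absent from every insufficient region bound the
#' minimal element. A thin wrapper over [interval_set_difference()] that
#' also reports 1-based coordinates and lengths for human consumption.
#'
#' @param positive_regions,negative_regions Interval data.frames.
#' @return Interval data.frame of the difference with extra columns
#'   `first`, `last` (1-based inclusive) and `length`.
#' @examples
#' pos <- from_onebased(c(520, 525), c(770, 775))
#' neg <- from_onebased(c(400, 405), c(650, 655))
#' minimal_signal(pos, neg)  # 1-based 656-775, 120 nt
#' @export
minimal_signal <- function(positive_regions, negative_regions = NULL) {
  if (is.null(negative_regions) || nrow(negative_regions) == 0) {
    res <- merge_intervals(positive_regions)
  } else {
    res <- interval_set_difference(positive_regions, negative_regions)
  }
  ob <- to_onebased(res)
  res$first <- ob$first
  res$last <- ob$last
  res$length <- ob$length
  res
}
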