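#' Construct a set of genomic intervals
#'
#' Intervals are the atom of the pipeline: aligned reporter reads, rolling
#' windows and called regions are all half-open spans `[start, end)` in
#' 0-based coordinates on a single reference UTR (the BED convention).
#' Human-facing annotations use 1-based inclusive coordinates and are
#' converted at the boundary with [from_onebased()] / [to_onebased()].
#'
#' @param start Integer vector of 0-based inclusive start positions.
#' @param end Integer vector of 0-based exclusive end positions
#'   (`end > start` elementwise).
#' @param ref_id Reference sequence identifier(s); recycled to length.
#' @param name Optional labels; recycled.
#' @return A `data.frame` with columns `ref_id`, `start`, `end`, `name`,
#'   one row per interval.
#' @examples
#' intervals(c(0, 10), c(250, 260))
#' @export
intervals <- function(start, end, ref_id = "ref", name = NA_character_) {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(start), length(end), 0L)
  df <- data.frame(
    ref_id = rep_len(as.character(ref_id), n),
    start = rep_len(start, n),
    end = rep_len(end, n),
    name = rep_len(as.character(name), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("ref_id", "start", "end") %in% names(df)))
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("interval coordinates must be non-missing integers")
  }
  if (any(df$start < 0L)) stop("interval start must be >= 0")
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("empty or inverted interval (start >= end) at row %d", bad[1]))
  }
  invisible(df)
}

#' Interval length in nucleotides
#'
#' @param iv Interval data.frame as returned by [intervals()].
#' @return Integer vector `end - start`.
#' @examples
#' interval_length(from_onebased(650, 776))  # the 127-nt packaged annotation
#' @export
interval_length <- function(iv) {
  validate_intervals(iv)
  iv$end - iv$start
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' Published region coordinates (e.g. a "650-776 nt" UTR annotation) are
#' 1-based inclusive; the pipeline stores 0-based half-open spans. The two
#' converters are exact inverses.
#'
#' @param first,last 1-based inclusive first and last nucleotide.
#' @param ref_id,name Passed to [intervals()].
#' @return `from_onebased`: an interval data.frame. `to_onebased`: a
#'   data.frame with columns `ref_id`, `first`, `last`, `length`, `name`.
#' @examples
#' from_onebased(650, 776)            # [649, 776), length 127
#' to_onebased(intervals(649, 776))
#' @export
from_onebased <- function(first, last, ref_id = "ref", name = NA_character_) {
  intervals(start = as.integer(first) - 1L, end = as.integer(last),
            ref_id = ref_id, name = name)
}

#' @rdname from_onebased
#' @param iv Interval data.frame in internal 0-based coordinates.
#' @export
to_onebased <- function(iv) {
  validate_intervals(iv)
  data.frame(
    ref_id = iv$ref_id,
    first = iv$start + 1L,
    last = iv$end,
    length = iv$end - iv$start,
    name = if ("name" %in% names(iv)) iv$name else NA_character_,
    stringsAsFactors = FALSE
  )
}

single_ref <- function(...) {
  ids <- unique(unlist(lapply(list(...), function(df) df$ref_id)))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1) {
    stop("intervals span multiple ref_ids: ", paste(ids, collapse = ", "))
  }
  if (length(ids) == 0) "ref" else ids
}

as_iranges <- function(iv) {
  IRanges::IRanges(start = iv$start + 1L, end = iv$end)
}

from_iranges <- function(ir, ref_id) {
  if (length(ir) == 0) {
    return(intervals(integer(0), integer(0), ref_id = character(0)))
  }
  intervals(start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
            ref_id = ref_id)
}

#' Merge overlapping or bookended intervals
#'
#' @param iv Interval data.frame.
#' @return Sorted, disjoint intervals covering the same nucleotides.
#' @export
merge_intervals <- function(iv) {
  validate_intervals(iv)
  if (nrow(iv) == 0) return(iv[, c("ref_id", "start", "end", "name")])
  rid <- single_ref(iv)
  from_iranges(IRanges::reduce(as_iranges(iv)), rid)
}

#' Nucleotide-level set difference of interval sets
#'
#' Returns the maximal disjoint intervals covering exactly the nucleotides
#' in the union of `positives` but not in the union of `negatives`. This is
#' the delimitation step of the reporter-window comparison: nucleotides
#' covered by sufficient windows but absent from insufficient ones bound
#' the minimal localization element.
#'
#' @param positives,negatives Interval data.frames on the same `ref_id`.
#' @return Sorted disjoint interval data.frame (possibly 0 rows).
#' @examples
#' # sufficient windows minus insufficient windows, in 0-based coordinates
#' interval_set_difference(intervals(519, 775), intervals(399, 655))
#' @export
interval_set_difference <- function(positives, negatives) {
  validate_intervals(positives)
  validate_intervals(negatives)
  rid <- single_ref(positives, negatives)
  res <- IRanges::setdiff(
    IRanges::reduce(as_iranges(positives)),
    IRanges::reduce(as_iranges(negatives))
  )
  from_iranges(res, rid)
}
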