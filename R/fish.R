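# Per-cell smFISH localization and translation-output scoring.
#
# Each segmented cell carries RNA spot positions, a cell-body mask nested
# inside a whole-cell mask (or their precomputed pixel areas and in/out
# spot counts), and a per-cell EGFP intensity. Localization is scored as
# the out/in spot ratio, adjusted for cell morphology by the
# projection-to-body area ratio, then normalized so the negative-control
# median equals 1. Translation output is EGFP intensity per RNA spot.

cell_counts_known <- function(cell) {
  !is.null(cell$n_in) && !is.null(cell$n_out)
}

#' Classify spots as inside or outside the cell body
#'
#' A spot is "in" iff its pixel carries the body label; the mask decides,
#' including at boundary pixels. Spots are (x, y) integer pixel
#' coordinates indexing the label matrices.
#'
#' @param cell A cell record (list) with `spots` (2-column integer
#'   matrix), `body_mask` and `cell_mask` (logical matrices, body subset
#'   of cell), and `cell_id`.
#' @return List with `n_in` and `n_out`; their sum is the spot count.
#' @export
classify_spots <- function(cell) {
  spots <- cell$spots
  if (is.null(spots) || NROW(spots) == 0) return(list(n_in = 0L, n_out = 0L))
  idx <- cbind(spots[, 1], spots[, 2])
  if (!all(cell$cell_mask[idx])) {
    stop("spot outside the cell mask in cell ", cell$cell_id)
  }
  n_in <- sum(cell$body_mask[idx])
  list(n_in = as.integer(n_in), n_out = as.integer(NROW(spots) - n_in))
}

#' Area-adjusted localization score for one cell
#'
#' `raw = n_out / n_in`; `area_ratio = (cell_area - body_area) /
#' body_area` (the projection area is the whole-cell area outside the
#' body); `adjusted = raw / area_ratio`. Cells with no body spots or no
#' projection area are excluded rather than imputed.
#'
#' @param cell A cell record with either masks + spots or precomputed
#'   `n_in`, `n_out`, `body_area`, `cell_area`.
#' @return One-row data frame with `cell_id`, `condition`, `n_in`,
#'   `n_out`, `raw`, `area_ratio`, `adjusted`, `excluded`, `reason`.
#' @export
localization_score <- function(cell) {
  cnt <- if (cell_counts_known(cell)) {
    list(n_in = as.integer(cell$n_in), n_out = as.integer(cell$n_out))
  } else {
    classify_spots(cell)
  }
  body_area <- if (!is.null(cell$body_area)) cell$body_area else sum(cell$body_mask)
  cell_area <- if (!is.null(cell$cell_area)) cell$cell_area else sum(cell$cell_mask)
  if (body_area <= 0 || cell_area < body_area) {
    stop("cell ", cell$cell_id, ": require 0 < body_area <= cell_area")
  }
  area_ratio <- (cell_area - body_area) / body_area
  excluded <- FALSE
  reason <- NA_character_
  raw <- adjusted <- NA_real_
  if (cnt$n_in == 0) {
    excluded <- TRUE
    reason <- "no spots inside cell body"
  } else if (area_ratio <= 0) {
    excluded <- TRUE
    reason <- "zero projection area"
  } else {
    raw <- cnt$n_out / cnt$n_in
    adjusted <- raw / area_ratio
  }
  data.frame(cell_id = cell$cell_id, condition = cell$condition,
             n_in = cnt$n_in, n_out = cnt$n_out, raw = raw,
             area_ratio = area_ratio, adjusted = adjusted,
             excluded = excluded, reason = reason,
             stringsAsFactors = FALSE)
}

#' Score a batch of cells
#'
#' @param cells List of cell records, or a combined data frame in the
#'   form of [read_cells_tsv()].
#' @return Data frame of per-cell scores (excluded cells flagged, not
#'   dropped), with the number of exclusions in attribute `n_excluded`.
#' @export
localization_scores <- function(cells) {
  if (is.data.frame(cells)) {
    cells <- lapply(seq_len(nrow(cells)), function(i) as.list(cells[i, ]))
  }
  out <- do.call(rbind, lapply(cells, localization_score))
  attr(out, "n_excluded") <- sum(out$excluded)
  out
}

#' Normalize localization scores to the negative control
#'
#' Divides every adjusted score by the median adjusted score of the
#' control condition, so that the control median equals 1 exactly.
#' Idempotent: normalizing an already-normalized set changes nothing.
#'
#' @param scores Data frame from [localization_scores()].
#' @param control_label Condition label of the negative control
#'   (e.g. the reporter with no 3' UTR).
#' @return `scores` with a `normalized` column added.
#' @export
normalize_to_control <- function(scores, control_label) {
  ctrl <- scores$condition == control_label & !scores$excluded
  if (!any(ctrl)) stop("no control cells with condition '", control_label,
                       "' and a defined score")
  med <- stats::median(scores$adjusted[ctrl])
  if (!is.finite(med) || med <= 0) {
    stop("control median is not positive; cannot normalize")
  }
  scores$normalized <- scores$adjusted / med
  scores
}

#' Per-cell translation output
#'
#' EGFP fluorescence divided by the number of RNA spots in the cell (a
#' per-molecule translational output proxy). Cells with zero spots are
#' excluded.
#'
#' @param cells List of cell records or combined data frame; each cell
#'   needs `egfp_intensity` and spot counts.
#' @return Data frame with `cell_id`, `condition`, `n_spots`, `signal`,
#'   `excluded`; exclusions counted in attribute `n_excluded`.
#' @export
translation_output <- function(cells) {
  if (is.data.frame(cells)) {
    cells <- lapply(seq_len(nrow(cells)), function(i) as.list(cells[i, ]))
  }
  rows <- lapply(cells, function(cell) {
    n <- if (cell_counts_known(cell)) {
      cell$n_in + cell$n_out
    } else {
      NROW(cell$spots)
    }
    data.frame(cell_id = cell$cell_id, condition = cell$condition,
               n_spots = as.integer(n),
               signal = if (n > 0) cell$egfp_intensity / n else NA_real_,
               excluded = n == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- sum(out$excluded)
  out
}

#' Condition-level medians, fold changes and bootstrap intervals
#'
#' For each condition: the median per-cell signal, the fold change
#' `median(control) / median(condition)` (so a condition that suppresses
#' translation five-fold scores ~5), and a case-resampling bootstrap
#' percentile confidence interval over cells, resampled independently
#' within the control and the condition.
#'
#' @param signals Data frame with `condition` and `signal` columns
#'   (e.g. from [translation_output()]); excluded/NA signals are dropped.
#' @param control_label Control condition label.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return A `fold_change_summary` data frame: one row per condition with
#'   `n_cells`, `median_signal`, `fold_change`, `ci_lo`, `ci_hi`.
#' @export
fold_change_summary <- function(signals, control_label, n_boot = 1000,
                                seed = 1, conf = 0.95) {
  signals <- signals[is.finite(signals$signal), , drop = FALSE]
  conds <- unique(signals$condition)
  if (!control_label %in% conds) {
    stop("control condition '", control_label, "' missing from signals")
  }
  split_sig <- split(signals$signal, signals$condition)
  small <- names(split_sig)[vapply(split_sig, length, integer(1)) < 5]
  if (length(small)) {
    stop("need at least 5 cells per condition; too few in: ",
         paste(small, collapse = ", "))
  }
  ctrl <- split_sig[[control_label]]
  alpha <- (1 - conf) / 2
  set.seed(seed)
  rows <- lapply(conds, function(cond) {
    x <- split_sig[[cond]]
    fc <- stats::median(ctrl) / stats::median(x)
    boot <- vapply(seq_len(n_boot), function(b) {
      stats::median(sample(ctrl, replace = TRUE)) /
        stats::median(sample(x, replace = TRUE))
    }, numeric(1))
    ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
    data.frame(condition = cond, n_cells = length(x),
               median_signal = stats::median(x), fold_change = fc,
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "control") <- control_label
  class(out) <- c("fold_change_summary", class(out))
  out
}

#' @export
print.fold_change_summary <- function(x, ...) {
  cat(sprintf("Translation output by condition (control: %s)\n",
              attr(x, "control")))
  df <- as.data.frame(x)
  df$median_signal <- signif(df$median_signal, 4)
  df$fold_change <- signif(df$fold_change, 4)
  df$ci_lo <- signif(df$ci_lo, 4)
  df$ci_hi <- signif(df$ci_hi, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
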