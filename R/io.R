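# Readers and writers for the plain-text formats the pipeline touches.
# BED and bedGraph are validated line by line so malformed input fails with
# the offending line number rather than propagating NA coordinates.

#' Read aligned reads or regions from a BED file
#'
#' Accepts 3+ column BED (0-based half-open). Column 4, when present, is
#' kept as the interval name; further columns are ignored. `track`,
#' `browser` and `#` comment lines are skipped.
#'
#' @param path Path to a BED file.
#' @param ref_id If non-NULL, require all records to be on this reference.
#' @return Interval data.frame (see [intervals()]).
#' @export
read_bed <- function(path, ref_id = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(intervals(integer(0), integer(0), ref_id = character(0)))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  parse_one <- function(f, lineno) {
    if (length(f) < 3) {
      stop(sprintf("BED parse error at line %d: fewer than 3 columns", lineno))
    }
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("BED parse error at line %d: non-integer coordinates", lineno))
    }
    if (s < 0 || s >= e) {
      stop(sprintf("BED parse error at line %d: require 0 <= start < end", lineno))
    }
    list(chrom = f[1], start = s, end = e,
         name = if (length(f) >= 4) f[4] else NA_character_)
  }
  recs <- mapply(parse_one, fields, idx, SIMPLIFY = FALSE)
  out <- intervals(
    start = vapply(recs, `[[`, integer(1), "start"),
    end = vapply(recs, `[[`, integer(1), "end"),
    ref_id = vapply(recs, `[[`, character(1), "chrom"),
    name = vapply(recs, `[[`, character(1), "name")
  )
  if (!is.null(ref_id) && nrow(out) && !all(out$ref_id == ref_id)) {
    stop("BED records on unexpected reference: expected ", ref_id)
  }
  out
}

#' Write intervals to a BED file
#'
#' @param iv Interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  validate_intervals(iv)
  nm <- if ("name" %in% names(iv)) iv$name else rep(NA_character_, nrow(iv))
  has_name <- !all(is.na(nm))
  cols <- if (has_name) {
    cbind(iv$ref_id, iv$start, iv$end, ifelse(is.na(nm), ".", nm))
  } else {
    cbind(iv$ref_id, iv$start, iv$end)
  }
  writeLines(apply(cols, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Write a per-interval score track as bedGraph
#'
#' One line per unmasked interval: `ref start end score` (0-based
#' half-open). Masked entries are omitted from the data section.
#'
#' @param iv Interval data.frame giving the spans (windows or positions).
#' @param scores Numeric vector, one score per interval.
#' @param path Output path.
#' @param mask Logical vector; `FALSE` entries are omitted. Default all on.
#' @return `path`, invisibly.
#' @export
write_track <- function(iv, scores, path, mask = NULL) {
  validate_intervals(iv)
  if (is.null(mask)) mask <- rep(TRUE, nrow(iv))
  stopifnot(length(scores) == nrow(iv), length(mask) == nrow(iv))
  if (any(!is.finite(scores[mask]))) {
    stop("unmasked track scores must be finite")
  }
  keep <- which(mask)
  lines <- sprintf("%s\t%d\t%d\t%s", iv$ref_id[keep], iv$start[keep],
                   iv$end[keep], format(scores[keep], digits = 15,
                                        scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph score track
#'
#' @param path Path to a bedGraph file written by [write_track()].
#' @return Interval data.frame with an extra numeric `score` column.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    out <- intervals(integer(0), integer(0), ref_id = character(0))
    out$score <- numeric(0)
    return(out)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 4)
  if (length(bad)) {
    stop(sprintf("bedGraph parse error at line %d: fewer than 4 columns",
                 idx[bad[1]]))
  }
  out <- intervals(
    start = as.integer(vapply(fields, `[`, character(1), 2)),
    end = as.integer(vapply(fields, `[`, character(1), 3)),
    ref_id = vapply(fields, `[`, character(1), 1)
  )
  out$score <- as.numeric(vapply(fields, `[`, character(1), 4))
  out
}

#' Read a reference sequence from FASTA
#'
#' The first record is taken as the reference UTR. T and U are both
#' accepted; the sequence is stored as given.
#'
#' @param path Path to a FASTA file.
#' @return A `reference_sequence` object: list with `ref_id`, `bases`
#'   (single string) and `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  reference_sequence(ref_id = sub("\\s.*$", "", names(set)[1]),
                     bases = toupper(as.character(set[[1]])))
}

#' Construct a reference sequence object
#'
#' @param ref_id Identifier.
#' @param bases String over \{A, C, G, T, U\}.
#' @return A `reference_sequence` object.
#' @export
reference_sequence <- function(ref_id, bases) {
  bases <- toupper(bases)
  chars <- strsplit(bases, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "U", "N"))) {
    stop("reference contains characters outside {A,C,G,T,U,N}")
  }
  structure(list(ref_id = ref_id, bases = bases, length = nchar(bases)),
            class = "reference_sequence")
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat(sprintf("<reference_sequence> %s: %d nt\n", x$ref_id, x$length))
  invisible(x)
}

#' Write a reference sequence to FASTA
#'
#' @param ref A `reference_sequence` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "reference_sequence"))
  set <- Biostrings::BStringSet(ref$bases)
  names(set) <- ref$ref_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read / write per-position mutation count tables
#'
#' Tab-separated with header `position base mutations coverage`;
#' `position` is 1-based along the reference.
#'
#' @param path File path.
#' @return Data frame with the four columns above.
#' @export
read_dms_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "base", "mutations", "coverage")
  if (!all(need %in% names(df))) {
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_dms_counts
#' @param counts Data frame with columns `position`, `base`, `mutations`,
#'   `coverage`.
#' @export
write_dms_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write per-cell imaging records as TSV
#'
#' The combined tabular form: one row per cell with precomputed spot
#' counts and pixel areas (`cell_id`, `condition`, `n_in`, `n_out`,
#' `body_area`, `cell_area`, `egfp_intensity`).
#'
#' @param path File path.
#' @return Data frame of per-cell records.
#' @export
read_cells_tsv <- function(path) {
  if (!file.exists(path)) stop("cells file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "condition", "n_in", "n_out", "body_area",
            "cell_area", "egfp_intensity")
  if (!all(need %in% names(df))) {
    stop("cells table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_cells_tsv
#' @param cells Either a data frame in the combined form or a list of cell
#'   records from [simulate_cells()] (converted with [cells_to_table()]).
#' @export
write_cells_tsv <- function(cells, path) {
  if (!is.data.frame(cells)) cells <- cells_to_table(cells)
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
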