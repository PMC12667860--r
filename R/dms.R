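# DMS-MaPseq reactivity normalization.
#
# Dimethyl sulfate methylates accessible (unpaired) adenines and
# cytosines; during reverse transcription the adducts appear as
# mutations, so per-position mutation rates report single-strandedness.
# Raw rates are converted to normalized reactivities with per-base
# boxplot normalization in a sliding 50-nt window. G and U (T) positions
# carry poor signal-to-noise in live-cell DMS data and are always masked.

#' Per-position raw mutation rates with a validity mask
#'
#' @param mutations,coverage Nonnegative integer vectors of equal length
#'   (per-position modification-induced mutation and read coverage
#'   counts).
#' @param coverage_floor Positions with coverage below this are invalid
#'   (default 500 reads; rate estimates below that are noise-dominated at
#'   typical DMS mutation rates).
#' @return List with `raw_rate` (numeric, `NA` where invalid) and `valid`
#'   (logical).
#' @export
mutation_rates <- function(mutations, coverage, coverage_floor = 500) {
  stopifnot(length(mutations) == length(coverage))
  if (any(mutations < 0) || any(coverage < 0)) stop("counts must be nonnegative")
  if (any(mutations > coverage)) {
    stop("mutations exceed coverage at position ",
         which(mutations > coverage)[1])
  }
  valid <- coverage >= coverage_floor
  raw <- rep(NA_real_, length(mutations))
  raw[valid] <- mutations[valid] / coverage[valid]
  list(raw_rate = raw, valid = valid)
}

# Normalization factor for one window of raw rates: drop outliers above
# Q3 + 1.5*IQR (type-7 quantiles), then average the top 10% (at least one
# value) of what remains.
boxplot_factor <- function(rates) {
  q <- stats::quantile(rates, c(0.25, 0.75), type = 7, names = FALSE)
  cut <- q[2] + 1.5 * (q[2] - q[1])
  kept <- rates[rates <= cut]
  if (length(kept) == 0) return(NA_real_)
  kept <- sort(kept, decreasing = TRUE)
  mean(kept[seq_len(max(1L, ceiling(0.1 * length(kept))))])
}

#' Boxplot-normalize raw mutation rates into reactivities
#'
#' Each nucleobase (A and C) is normalized separately. For every valid
#' position, the valid raw rates of the same base within a 50-nt window
#' centered on the position (shifted, not shrunk, at the sequence ends)
#' form the normalization set; outliers above Q3 + 1.5*IQR are removed
#' and the normalization factor is the mean of the top 10% of the
#' remainder. The position's reactivity is its raw rate divided by that
#' factor. Positions whose base is G or U/T, whose window holds fewer
#' than `min_window_n` valid same-base rates, or whose factor is not
#' positive remain invalid. Reactivities are not capped.
#'
#' @param raw_rate Numeric vector of raw mutation rates (`NA` allowed at
#'   invalid positions).
#' @param valid Logical vector from [mutation_rates()].
#' @param bases Character vector of reference bases, one per position.
#' @param window Sliding normalization window in nt (default 50).
#' @param min_window_n Minimum valid same-base rates required in a window
#'   (default 10).
#' @return List with `reactivity` (numeric, `NA` where invalid) and
#'   `valid` (logical, the post-normalization mask).
#' @export
boxplot_normalize <- function(raw_rate, valid, bases, window = 50,
                              min_window_n = 10) {
  n <- length(raw_rate)
  stopifnot(length(valid) == n, length(bases) == n)
  bases <- toupper(bases)
  bases[bases == "U"] <- "T"
  usable <- valid & bases %in% c("A", "C")
  reactivity <- rep(NA_real_, n)
  out_valid <- rep(FALSE, n)
  half <- window %/% 2
  for (i in which(usable)) {
    lo <- min(max(1L, i - (half - 1L)), max(1L, n - window + 1L))
    hi <- min(n, lo + window - 1L)
    in_win <- lo:hi
    same <- in_win[usable[in_win] & bases[in_win] == bases[i]]
    if (length(same) < min_window_n) next
    fac <- boxplot_factor(raw_rate[same])
    if (is.na(fac) || fac <= 0) next
    reactivity[i] <- raw_rate[i] / fac
    out_valid[i] <- TRUE
  }
  list(reactivity = reactivity, valid = out_valid)
}

#' Compute a normalized DMS reactivity profile
#'
#' Wraps [mutation_rates()] and [boxplot_normalize()] for a counts table
#' against its reference sequence.
#'
#' @param counts Data frame with columns `position` (1-based), `base`,
#'   `mutations`, `coverage` (see [read_dms_counts()]).
#' @param reference A `reference_sequence`; bases are cross-checked
#'   against the table where both are given.
#' @param window Sliding normalization window in nt (default 50).
#' @param coverage_floor Minimum coverage per position (default 500).
#' @param min_window_n Minimum valid same-base rates per window.
#' @return A `reactivity_profile` object: list with `reference`,
#'   `position` (1-based), `base`, `raw_rate`, `reactivity`, `valid`, and
#'   the parameters used.
#' @export
dms_reactivity <- function(counts, reference, window = 50,
                           coverage_floor = 500, min_window_n = 10) {
  stopifnot(inherits(reference, "reference_sequence"))
  need <- c("position", "base", "mutations", "coverage")
  stopifnot(all(need %in% names(counts)))
  n <- reference$length
  if (nrow(counts) != n || !all(sort(counts$position) == seq_len(n))) {
    stop("counts table must cover every reference position exactly once")
  }
  counts <- counts[order(counts$position), , drop = FALSE]
  ref_bases <- strsplit(reference$bases, "")[[1]]
  mr <- mutation_rates(counts$mutations, counts$coverage, coverage_floor)
  bn <- boxplot_normalize(mr$raw_rate, mr$valid, ref_bases, window,
                          min_window_n)
  structure(list(
    reference = reference,
    position = counts$position,
    base = ref_bases,
    raw_rate = mr$raw_rate,
    reactivity = bn$reactivity,
    valid = bn$valid,
    params = list(window = window, coverage_floor = coverage_floor,
                  min_window_n = min_window_n, capped = FALSE)
  ), class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat(sprintf("<reactivity_profile> %s: %d nt, %d valid A/C positions\n",
              x$reference$ref_id, x$reference$length, sum(x$valid)))
  if (any(x$valid)) {
    cat(sprintf("  median reactivity %.3f (uncapped), window %d nt\n",
                stats::median(x$reactivity[x$valid]), x$params$window))
  }
  invisible(x)
}

#' @export
as.data.frame.reactivity_profile <- function(x, ...) {
  data.frame(position = x$position, base = x$base, raw_rate = x$raw_rate,
             reactivity = x$reactivity, valid = x$valid,
             stringsAsFactors = FALSE)
}

#' @export
plot.reactivity_profile <- function(x, ...) {
  graphics::plot(x$position, x$reactivity, type = "h",
                 xlab = "position (nt)", ylab = "normalized reactivity", ...)
  invisible(x)
}

#' Concordance between reactivities and a known secondary structure
#'
#' Rank-based probability that a randomly chosen valid unpaired position
#' has a higher reactivity than a randomly chosen valid paired position
#' (the Wilcoxon/AUC concordance, in [0, 1]; ties count one half). Used
#' to validate the normalization stage against the generative structure
#' of synthetic data: accessible bases should score high.
#'
#' @param profile A `reactivity_profile`.
#' @param structure Dot-bracket string of the reference length
#'   (characters `.`, `(`, `)`).
#' @return List with `concordance`, `n_paired`, `n_unpaired`.
#' @export
structure_agreement <- function(profile, structure) {
  stopifnot(inherits(profile, "reactivity_profile"))
  chars <- strsplit(structure, "")[[1]]
  if (length(chars) != profile$reference$length) {
    stop("structure length does not match reference length")
  }
  if (!all(chars %in% c(".", "(", ")"))) {
    stop("structure must be a dot-bracket string over {., (, )}")
  }
  paired <- chars %in% c("(", ")")
  vp <- profile$valid & paired
  vu <- profile$valid & !paired
  if (sum(vp) < 5 || sum(vu) < 5) {
    stop("need at least 5 valid positions in each of the paired and unpaired classes")
  }
  u <- profile$reactivity[vu]
  p <- profile$reactivity[vp]
  r <- rank(c(u, p))
  n1 <- length(u)
  n2 <- length(p)
  ustat <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  list(concordance = ustat / (n1 * n2), n_paired = n2, n_unpaired = n1)
}
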