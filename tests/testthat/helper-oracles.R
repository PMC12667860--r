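# Independent brute-force oracles. Deliberately naive (explicit loops,
# boolean position arrays, hand-written quantile interpolation) and kept
# free of any package internals so they can arbitrate the vectorized /
# IRanges-backed implementations.

# Set difference via a per-nucleotide boolean array.
bf_set_difference <- function(positives, negatives, ref_length) {
  covered <- rep(FALSE, ref_length)
  for (i in seq_len(nrow(positives))) {
    covered[(positives$start[i] + 1):positives$end[i]] <- TRUE
  }
  for (i in seq_len(nrow(negatives))) {
    covered[(negatives$start[i] + 1):negatives$end[i]] <- FALSE
  }
  runs_to_intervals(covered)
}

# Merge via the same boolean-array route.
bf_merge <- function(iv, ref_length) {
  covered <- rep(FALSE, ref_length)
  for (i in seq_len(nrow(iv))) {
    covered[(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  runs_to_intervals(covered)
}

runs_to_intervals <- function(covered) {
  starts <- integer(0)
  ends <- integer(0)
  inside <- FALSE
  for (p in seq_along(covered)) {
    if (covered[p] && !inside) {
      starts <- c(starts, p - 1L)
      inside <- TRUE
    }
    if (!covered[p] && inside) {
      ends <- c(ends, p - 1L)
      inside <- FALSE
    }
  }
  if (inside) ends <- c(ends, length(covered))
  data.frame(start = starts, end = ends)
}

# Containment counting by a double loop.
bf_count_contained <- function(reads, grid) {
  counts <- integer(nrow(grid))
  for (w in seq_len(nrow(grid))) {
    for (r in seq_len(nrow(reads))) {
      if (grid$start[w] <= reads$start[r] && reads$end[r] <= grid$end[w]) {
        counts[w] <- counts[w] + 1L
      }
    }
  }
  counts
}

# Type-7 quantile by explicit linear interpolation on the sorted vector.
bf_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Boxplot normalization by explicit loops; window shifted (not shrunk)
# at the ends, same-base valid rates only.
bf_boxplot_normalize <- function(raw_rate, valid, bases, window = 50,
                                 min_window_n = 10) {
  n <- length(raw_rate)
  bases <- toupper(bases)
  bases[bases == "U"] <- "T"
  reactivity <- rep(NA_real_, n)
  half <- window %/% 2
  for (i in seq_len(n)) {
    if (!valid[i] || !(bases[i] %in% c("A", "C"))) next
    lo <- i - (half - 1)
    if (lo < 1) lo <- 1
    if (lo > n - window + 1) lo <- max(1, n - window + 1)
    hi <- min(n, lo + window - 1)
    vals <- c()
    for (j in lo:hi) {
      if (valid[j] && bases[j] == bases[i] && bases[j] %in% c("A", "C")) {
        vals <- c(vals, raw_rate[j])
      }
    }
    if (length(vals) < min_window_n) next
    q1 <- bf_quantile7(vals, 0.25)
    q3 <- bf_quantile7(vals, 0.75)
    kept <- c()
    for (v in vals) if (v <= q3 + 1.5 * (q3 - q1)) kept <- c(kept, v)
    if (length(kept) == 0) next
    kept <- sort(kept, decreasing = TRUE)
    k <- ceiling(0.1 * length(kept))
    if (k < 1) k <- 1
    fac <- mean(kept[1:k])
    if (fac > 0) reactivity[i] <- raw_rate[i] / fac
  }
  reactivity
}

# Per-cell localization scoring by scalar arithmetic and a per-spot loop.
bf_localization <- function(cell) {
  n_in <- 0L
  n_out <- 0L
  if (!is.null(cell$spots) && nrow(cell$spots) > 0) {
    for (s in seq_len(nrow(cell$spots))) {
      if (cell$body_mask[cell$spots[s, 1], cell$spots[s, 2]]) {
        n_in <- n_in + 1L
      } else {
        n_out <- n_out + 1L
      }
    }
  } else {
    n_in <- cell$n_in
    n_out <- cell$n_out
  }
  body_area <- if (!is.null(cell$body_area)) cell$body_area else sum(cell$body_mask)
  cell_area <- if (!is.null(cell$cell_area)) cell$cell_area else sum(cell$cell_mask)
  if (n_in == 0) return(list(n_in = n_in, n_out = n_out, adjusted = NA_real_))
  raw <- n_out / n_in
  area_ratio <- (cell_area - body_area) / body_area
  if (area_ratio <= 0) return(list(n_in = n_in, n_out = n_out, adjusted = NA_real_))
  list(n_in = n_in, n_out = n_out, raw = raw, area_ratio = area_ratio,
       adjusted = raw / area_ratio)
}

# Concordance by enumerating all unpaired/paired pairs.
bf_concordance <- function(unpaired, paired) {
  wins <- 0
  for (u in unpaired) {
    for (p in paired) {
      if (u > p) wins <- wins + 1 else if (u == p) wins <- wins + 0.5
    }
  }
  wins / (length(unpaired) * length(paired))
}

# Random interval set on [0, ref_length) for property tests.
random_interval_set <- function(n, ref_length, ref_id = "ref") {
  start <- sample.int(ref_length - 1L, n, replace = TRUE) - 1L
  len <- sample.int(ref_length %/% 4, n, replace = TRUE)
  end <- pmin(start + len, ref_length)
  intervals(start = start, end = end, ref_id = ref_id)
}

# Small synthetic truth used where full assay depth is not needed.
small_truth <- function(seed = 1, ...) {
  synthetic_truth(
    n_fragments = 1200,
    depths = c(input = 2e4, body = 2e4, projection = 2e4),
    seed = seed, ...
  )
}

iou <- function(a, b) {
  inter <- max(0, min(a$end, b$end) - max(a$start, b$start))
  inter / (interval_length(a) + interval_length(b) - inter)
}
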