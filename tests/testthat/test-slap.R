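test_that("window grids enumerate fixed-size windows at the stated step", {
  g <- make_windows(260, 250, 5)
  expect_equal(g$start, c(0L, 5L, 10L))
  expect_equal(g$end, c(250L, 255L, 260L))
  expect_equal(nrow(make_windows(250, 250, 5)), 1)
  expect_equal(nrow(make_windows(1500, 250, 5)), 251)  # floor(1250/5)+1
  expect_true(all(interval_length(make_windows(1000)) == 250))
  expect_error(make_windows(200, 250, 5), "window_size")
})

test_that("containment counting is strict and matches the double-loop oracle", {
  g <- make_windows(260, 250, 5)
  expect_equal(count_contained(intervals(10, 200), g)[1], 1L)    # fully inside
  expect_equal(count_contained(intervals(240, 260), g)[1], 0L)   # partial overlap
  expect_equal(count_contained(intervals(240, 260), g)[3], 1L)
  # reads longer than the window never count
  expect_equal(sum(count_contained(intervals(0, 260), g)), 0L)

  set.seed(7)
  grid <- make_windows(1500, 250, 5)
  reads <- random_interval_set(1000, 1500)
  expect_identical(count_contained(reads, grid), bf_count_contained(reads, grid))
})

test_that("input normalization divides and masks below the coverage floor", {
  res <- normalize_by_input(c(10, 7, 3), c(5, 0, 20), min_input = 1)
  expect_equal(res$norm, c(2, NA, 0.15))
  expect_equal(res$mask, c(TRUE, FALSE, TRUE))
  expect_error(normalize_by_input(c(-1, 2), c(1, 1)), "nonnegative")

  set.seed(19)
  s <- rpois(100, 30)
  i <- rpois(100, 20)
  res <- normalize_by_input(s, i, min_input = 10)
  for (w in seq_along(s)) {
    if (i[w] >= 10) expect_equal(res$norm[w], s[w] / i[w]) else expect_true(is.na(res$norm[w]))
  }
})

test_that("enrichment scaling pins the maximum at one", {
  expect_equal(enrichment_scale(c(2, 4), c(1, 1), c(TRUE, TRUE)), c(1 / 3, 1))
  # degenerate: identical compartments stay all-zero, no division blowup
  expect_equal(enrichment_scale(c(1, 2), c(1, 2), c(TRUE, TRUE)), c(0, 0))
  # all-negative track is scaled by max |diff| with a warning
  expect_warning(
    out <- enrichment_scale(c(1, 1), c(2, 5), c(TRUE, TRUE)),
    "positive"
  )
  expect_equal(out, c(-0.25, -1))
  expect_error(enrichment_scale(1, 2, FALSE), "masked")
})

test_that("the track maximum is exactly one on synthetic assays", {
  truth <- small_truth(seed = 3)
  frags <- generate_fragment_library(truth)
  reads <- simulate_compartment_reads(truth, frags)
  tr <- slap_enrichment(reads$input, reads$body, reads$projection,
                        ref_length = truth$utr_length)
  expect_identical(max(tr$enrichment[tr$mask]), 1)
  expect_equal(length(tr$enrichment), 251)
})

test_that("scaled enrichment is invariant to input-depth rescaling", {
  truth <- small_truth(seed = 14)
  frags <- generate_fragment_library(truth)
  reads <- simulate_compartment_reads(truth, frags)
  grid <- make_windows(truth$utr_length, ref_id = "utr")
  ci <- count_contained(reads$input, grid)
  cb <- count_contained(reads$body, grid)
  cp <- count_contained(reads$projection, grid)
  scale_track <- function(i, b, p, min_input = 10) {
    nb <- normalize_by_input(b, i, min_input)
    np <- normalize_by_input(p, i, min_input)
    enrichment_scale(np$norm, nb$norm, nb$mask & np$mask)
  }
  base <- scale_track(ci, cb, cp)
  # input counts x5 (floor stays proportionally satisfied): ratios shrink
  # by 5 but the max-1 rescaling removes the constant exactly
  expect_equal(scale_track(ci * 5L, cb, cp, min_input = 50), base)
  # both compartments x3: difference scales by 3, rescaling removes it
  expect_equal(scale_track(ci, cb * 3L, cp * 3L), base)
})

test_that("the sign flag flips the contrast", {
  truth <- small_truth(seed = 6)
  frags <- generate_fragment_library(truth)
  reads <- simulate_compartment_reads(truth, frags)
  tp <- slap_enrichment(reads$input, reads$body, reads$projection,
                        ref_length = truth$utr_length)
  tb <- suppressWarnings(slap_enrichment(reads$input, reads$body, reads$projection,
                                         ref_length = truth$utr_length, sign = "body"))
  dp <- tp$norm_projection - tp$norm_body
  db <- tb$norm_body - tb$norm_projection
  expect_equal(dp, -db)
})

test_that("region calling selects, merges, and matches the boolean oracle", {
  truth <- small_truth(seed = 3)
  frags <- generate_fragment_library(truth)
  reads <- simulate_compartment_reads(truth, frags)
  tr <- slap_enrichment(reads$input, reads$body, reads$projection,
                        ref_length = truth$utr_length)

  # single qualifying window returns that window's interval
  solo <- call_regions(tr, threshold_fraction = 1)
  expect_equal(nrow(solo), 1)
  expect_equal(interval_length(solo), 250L)

  # randomized tracks: union call equals per-nucleotide boolean merge
  set.seed(91)
  for (i in 1:30) {
    fake <- tr
    fake$enrichment <- runif(length(tr$enrichment), -0.5, 1)
    fake$enrichment <- fake$enrichment / max(fake$enrichment)
    thr <- runif(1, 0.3, 0.9)
    got <- call_regions(fake, thr)
    sel <- which(fake$mask & fake$enrichment >= thr * max(fake$enrichment, na.rm = TRUE))
    want <- bf_merge(fake$grid[sel, ], truth$utr_length)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("adjacent qualifying windows merge into one maximal interval", {
  truth <- small_truth(seed = 3)
  frags <- generate_fragment_library(truth)
  reads <- simulate_compartment_reads(truth, frags)
  tr <- slap_enrichment(reads$input, reads$body, reads$projection,
                        ref_length = truth$utr_length)
  fake <- tr
  fake$enrichment <- rep(0, length(tr$enrichment))
  fake$enrichment[1:2] <- 1  # windows [0,250) and [5,255)
  expect_equal(call_regions(fake, 0.5)[, c("start", "end")],
               data.frame(start = 0L, end = 255L))
  # core refinement keeps only the span common to both windows
  expect_equal(call_regions(fake, 0.5, refine = "core")[, c("start", "end")],
               data.frame(start = 5L, end = 250L))
})

test_that("core refinement contains the true element when the union does not", {
  truth <- small_truth(seed = 9)
  frags <- generate_fragment_library(truth)
  reads <- simulate_compartment_reads(truth, frags)
  tr <- slap_enrichment(reads$input, reads$body, reads$projection,
                        ref_length = truth$utr_length)
  core <- call_regions(tr, refine = "core")
  expect_equal(nrow(core), 1)
  expect_lt(interval_length(core), 250L)
  el <- truth$element
  expect_lte(core$start, el$start)
  expect_gte(core$end, el$end)
})

test_that("minimal_signal reproduces the published window comparison", {
  pos <- from_onebased(c(520, 525), c(770, 775))
  neg <- from_onebased(c(400, 405), c(650, 655))
  ms <- minimal_signal(pos, neg)
  expect_equal(nrow(ms), 1)
  expect_equal(c(ms$first, ms$last, ms$length), c(656L, 775L, 120L))
  # identical sets cancel; no negatives returns the merged positives
  expect_equal(nrow(minimal_signal(pos, pos)), 0)
  expect_equal(minimal_signal(pos)$length, 256L)  # 520-775 merged
})
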