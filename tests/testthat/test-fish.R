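# A hand-built cell: 5x5 grid, body = central 3x3 block, all inside cell.
toy_cell <- function(spots, cell_id = "c1", condition = "mls",
                     egfp = 1000) {
  cell_mask <- matrix(TRUE, 5, 5)
  body_mask <- matrix(FALSE, 5, 5)
  body_mask[2:4, 2:4] <- TRUE
  list(cell_id = cell_id, condition = condition, spots = spots,
       body_mask = body_mask, cell_mask = cell_mask,
       egfp_intensity = egfp)
}

test_that("spot classification is decided by the body label", {
  allin <- toy_cell(cbind(c(2, 3, 4), c(2, 3, 4)))
  expect_equal(classify_spots(allin), list(n_in = 3L, n_out = 0L))
  # boundary pixel (2,2) carries the body label: counted in
  edge <- toy_cell(cbind(2, 2))
  expect_equal(classify_spots(edge)$n_in, 1L)
  mixed <- toy_cell(cbind(c(1, 3, 5), c(1, 3, 5)))
  expect_equal(classify_spots(mixed), list(n_in = 1L, n_out = 2L))
  expect_equal(classify_spots(toy_cell(matrix(integer(0), 0, 2))),
               list(n_in = 0L, n_out = 0L))
})

test_that("spots outside the cell mask name the offending cell", {
  bad <- toy_cell(cbind(3, 3))
  bad$cell_mask[3, 3] <- FALSE
  bad$body_mask[3, 3] <- FALSE
  expect_error(classify_spots(bad), "c1")
})

test_that("localization scores follow the out/in, area-adjusted arithmetic", {
  cell <- list(cell_id = "a", condition = "mls", n_in = 5L, n_out = 10L,
               body_area = 100, cell_area = 300, egfp_intensity = 1)
  sc <- localization_score(cell)
  expect_equal(sc$raw, 2)
  expect_equal(sc$area_ratio, 2)
  expect_equal(sc$adjusted, 1)
  # area_ratio 1 leaves adjusted == raw
  cell$cell_area <- 200
  expect_equal(localization_score(cell)$adjusted,
               localization_score(cell)$raw)
  # no body spots: excluded, not scored
  cell$n_in <- 0L
  sc0 <- localization_score(cell)
  expect_true(sc0$excluded)
  expect_true(is.na(sc0$adjusted))
})

test_that("localization is invariant to uniform image rescaling", {
  cell <- list(cell_id = "a", condition = "mls", n_in = 7L, n_out = 12L,
               body_area = 150, cell_area = 410, egfp_intensity = 1)
  big <- cell
  big$body_area <- cell$body_area * 4
  big$cell_area <- cell$cell_area * 4
  expect_equal(localization_score(big)$adjusted,
               localization_score(cell)$adjusted)
})

test_that("batch scoring matches the scalar oracle on simulated cells", {
  truth <- small_truth(seed = 55)
  cells <- simulate_cells(truth, 15)
  scores <- localization_scores(cells)
  expect_equal(nrow(scores), length(cells))
  for (i in seq_along(cells)) {
    want <- bf_localization(cells[[i]])
    expect_equal(scores$n_in[i], want$n_in)
    expect_equal(scores$n_out[i], want$n_out)
    if (!is.na(want$adjusted)) expect_equal(scores$adjusted[i], want$adjusted)
  }
  expect_equal(attr(scores, "n_excluded"), sum(scores$excluded))
})

test_that("control normalization pins the control median at one and is idempotent", {
  sc <- data.frame(
    cell_id = paste0("c", 1:6),
    condition = c("no_utr", "no_utr", "no_utr", "mls", "mls", "mls"),
    adjusted = c(0.5, 1.0, 2.0, 3, 4, 5),
    excluded = FALSE
  )
  out <- normalize_to_control(sc, "no_utr")
  expect_identical(median(out$normalized[out$condition == "no_utr"]), 1)
  expect_equal(out$normalized, sc$adjusted / 1.0)

  # all-identical scores normalize to all ones
  same <- sc
  same$adjusted <- 2
  expect_equal(normalize_to_control(same, "no_utr")$normalized, rep(1, 6))

  # idempotence
  again <- out
  again$adjusted <- out$normalized
  expect_equal(normalize_to_control(again, "no_utr")$normalized,
               out$normalized)

  # randomized scores match the divide-by-median oracle
  set.seed(60)
  rnd <- sc
  rnd$adjusted <- rlnorm(6)
  out <- normalize_to_control(rnd, "no_utr")
  expect_equal(out$normalized,
               rnd$adjusted / median(rnd$adjusted[rnd$condition == "no_utr"]))

  expect_error(normalize_to_control(sc, "absent"), "control")
})

test_that("translation output is EGFP per spot and ratio-invariant", {
  cell <- list(cell_id = "a", condition = "mls", n_in = 30L, n_out = 20L,
               body_area = 1, cell_area = 2, egfp_intensity = 1000)
  out <- translation_output(list(cell))
  expect_equal(out$signal, 20)
  double <- cell
  double$n_in <- 60L
  double$n_out <- 40L
  double$egfp_intensity <- 2000
  expect_equal(translation_output(list(double))$signal, 20)
  # zero spots: excluded
  none <- cell
  none$n_in <- 0L
  none$n_out <- 0L
  out <- translation_output(list(none))
  expect_true(out$excluded)
  expect_equal(attr(out, "n_excluded"), 1)
})

test_that("fold changes are control-over-condition medians with sane bootstrap CIs", {
  sig <- data.frame(
    condition = rep(c("no_utr", "mls"), each = 6),
    signal = c(rep(20, 6), rep(4, 6))
  )
  fc <- fold_change_summary(sig, "no_utr", n_boot = 200, seed = 4)
  expect_equal(fc$fold_change[fc$condition == "mls"], 5)
  expect_equal(fc$fold_change[fc$condition == "no_utr"], 1)
  # degenerate signals give a width-zero CI at the true value
  expect_equal(fc$ci_lo[fc$condition == "mls"], 5)
  expect_equal(fc$ci_hi[fc$condition == "mls"], 5)

  # a condition identical in law to the control covers 1
  set.seed(5)
  sig2 <- data.frame(condition = rep(c("no_utr", "same"), each = 40),
                     signal = rlnorm(80, log(10), 0.3))
  fc2 <- fold_change_summary(sig2, "no_utr", n_boot = 500, seed = 6)
  row <- fc2[fc2$condition == "same", ]
  expect_lt(row$ci_lo, 1)
  expect_gt(row$ci_hi, 1)

  expect_error(fold_change_summary(sig, "gone"), "missing")
  expect_error(
    fold_change_summary(sig[c(1:6, 7:9), ], "no_utr"), "at least 5"
  )
  # same seed, same intervals
  expect_equal(fold_change_summary(sig2, "no_utr", n_boot = 300, seed = 9),
               fold_change_summary(sig2, "no_utr", n_boot = 300, seed = 9))
})

test_that("conditions with stronger projection placement score above the control", {
  truth <- synthetic_truth(seed = 77)
  tab <- cells_to_table(simulate_cells(truth, 50))
  scores <- normalize_to_control(localization_scores(tab), "no_utr")
  med <- tapply(scores$normalized[!scores$excluded],
                scores$condition[!scores$excluded], median)
  expect_identical(med[["no_utr"]], 1)
  expect_gt(med[["mls"]], 1)     # p_outside 0.40 vs 0.10
  expect_gt(med[["utr_no_mls"]], 1)
  expect_gt(med[["mls"]], med[["utr_no_mls"]])
})
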