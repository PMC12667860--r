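# Seeded generators for every input the pipeline consumes: a random
# reference UTR, a sheared-fragment reporter library with one embedded
# localization element, multinomial compartment reads, structure-driven
# DMS mutation counts, and segmented cells with condition-dependent spot
# placement and translation output. A single root seed derives fixed
# per-generator child seeds so adding one generator never perturbs the
# others.

SEED_OFFSETS <- c(reference = 101L, structure = 202L, fragments = 303L,
                  reads = 404L, dms = 505L, cells = 606L)

child_seed <- function(seed, what) {
  (as.integer(seed) + SEED_OFFSETS[[what]]) %% .Machine$integer.max
}

#' Generative parameters for a synthetic localization experiment
#'
#' Bundles every parameter of the synthetic experiment, mirroring the
#' geometry of a sheared-reporter transwell assay on a ~1.5-kb UTR: a
#' 127-nt localization element embedded at 1-based 650-776, fragment
#' sizes 200-400 nt, an 8-fold projection sampling weight for fragments
#' carrying the whole element, 100k reads per sample, DMS coverage 5000x
#' with paired/unpaired mutation rates 0.005/0.05, and three imaging
#' conditions (a no-UTR negative control, an element-carrying reporter
#' with 5-fold lower translation output and stronger projection spot
#' placement, and an element-deleted UTR with a 2.5-fold reduction).
#'
#' @param utr_length Reference UTR length in nt.
#' @param element True localization element (interval data.frame,
#'   0-based); default 1-based 650-776 (127 nt).
#' @param enrichment_factor Projection sampling weight multiplier for
#'   fragments containing the entire element (>= 1).
#' @param fragment_size_range Sheared-fragment length range in nt.
#' @param n_fragments Number of distinct library fragments.
#' @param depths Named reads-per-sample vector (`input`, `body`,
#'   `projection`).
#' @param structure Dot-bracket string of length `utr_length`; generated
#'   from the seed when `NULL`.
#' @param mu_paired,mu_unpaired Per-position DMS mutation probabilities
#'   for paired and unpaired bases (`0 <= mu_paired < mu_unpaired <= 1`).
#' @param coverage DMS read coverage per position.
#' @param condition_effects Named list of per-condition
#'   `list(p_outside = , translation_scale = )`: the probability a spot
#'   falls outside the cell body and the expected EGFP per RNA.
#' @param control_label Name of the negative-control condition; must be
#'   in `condition_effects`.
#' @param spot_rate Mean RNA spots per cell (Poisson).
#' @param egfp_noise_sd Log-normal sdlog of per-cell EGFP noise.
#' @param seed Root RNG seed.
#' @return A `synthetic_truth` object (list of the above, with the
#'   structure filled in).
#' @export
synthetic_truth <- function(utr_length = 1500,
                            element = from_onebased(650, 776, name = "element"),
                            enrichment_factor = 8,
                            fragment_size_range = c(200, 400),
                            n_fragments = 5000,
                            depths = c(input = 1e5, body = 1e5, projection = 1e5),
                            structure = NULL,
                            mu_paired = 0.005,
                            mu_unpaired = 0.05,
                            coverage = 5000,
                            condition_effects = list(
                              no_utr = list(p_outside = 0.10, translation_scale = 20),
                              mls = list(p_outside = 0.40, translation_scale = 4),
                              utr_no_mls = list(p_outside = 0.15, translation_scale = 8)
                            ),
                            control_label = "no_utr",
                            spot_rate = 40,
                            egfp_noise_sd = 0.3,
                            seed = 1) {
  validate_intervals(element)
  stopifnot(nrow(element) == 1, element$start >= 0, element$end <= utr_length,
            enrichment_factor >= 1,
            mu_paired >= 0, mu_paired < mu_unpaired, mu_unpaired <= 1,
            all(depths > 0), coverage > 0, n_fragments >= 0,
            length(fragment_size_range) == 2,
            fragment_size_range[1] <= fragment_size_range[2])
  stopifnot(all(c("input", "body", "projection") %in% names(depths)))
  if (!control_label %in% names(condition_effects)) {
    stop("condition_effects must include the control condition '",
         control_label, "'")
  }
  if (is.null(structure)) {
    structure <- random_structure(utr_length, seed = child_seed(seed, "structure"))
  }
  if (nchar(structure) != utr_length) {
    stop("structure length must equal utr_length")
  }
  structure(list(
    utr_length = as.integer(utr_length), element = element,
    enrichment_factor = enrichment_factor,
    fragment_size_range = as.integer(fragment_size_range),
    n_fragments = as.integer(n_fragments), depths = depths,
    structure = structure, mu_paired = mu_paired,
    mu_unpaired = mu_unpaired, coverage = as.integer(coverage),
    condition_effects = condition_effects, control_label = control_label,
    spot_rate = spot_rate, egfp_noise_sd = egfp_noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d-nt UTR, element %d-%d (1-based, %d nt), factor %g\n",
              x$utr_length, x$element$start + 1L, x$element$end,
              interval_length(x$element), x$enrichment_factor))
  cat(sprintf("  %d fragments of %d-%d nt; depths %s; seed %d\n",
              x$n_fragments, x$fragment_size_range[1], x$fragment_size_range[2],
              paste(names(x$depths), format(x$depths, scientific = FALSE, trim = TRUE),
                    sep = "=", collapse = " "), x$seed))
  invisible(x)
}

#' Generate a uniform-random reference sequence
#'
#' @param utr_length Sequence length in nt.
#' @param seed RNG seed.
#' @param ref_id Identifier for the FASTA record.
#' @return A `reference_sequence`.
#' @export
generate_reference <- function(utr_length = 1500, seed = 1, ref_id = "utr") {
  stopifnot(utr_length > 0)
  set.seed(seed)
  reference_sequence(ref_id,
                     paste(sample(c("A", "C", "G", "T"), utr_length,
                                  replace = TRUE), collapse = ""))
}

#' Generate a random hairpin secondary structure
#'
#' Tiles the sequence with non-overlapping stem-loops (stems 5-12 bp,
#' loops 4-8 nt) separated by unpaired gaps, yielding roughly half the
#' positions paired — a plausible mix of structured and unstructured
#' stretches for exercising reactivity scoring.
#'
#' @param length Structure length in nt.
#' @param seed RNG seed.
#' @return Dot-bracket string of the requested length.
#' @export
random_structure <- function(length, seed = 1) {
  set.seed(seed)
  chars <- rep(".", length)
  pos <- 1L
  while (pos + 30L <= length) {
    stem <- sample(5:12, 1)
    loop <- sample(4:8, 1)
    span <- 2L * stem + loop
    if (pos + span - 1L > length) break
    chars[pos:(pos + stem - 1L)] <- "("
    chars[(pos + stem + loop):(pos + span - 1L)] <- ")"
    pos <- pos + span + sample(3:15, 1)
  }
  paste(chars, collapse = "")
}

#' Generate a sheared-fragment reporter library
#'
#' Fragment lengths uniform over `fragment_size_range`, starts uniform
#' over the positions where the fragment fits in the UTR.
#'
#' @param truth A `synthetic_truth`.
#' @param ref_id Reference identifier for the fragment intervals.
#' @return Interval data.frame of `n_fragments` fragments.
#' @export
generate_fragment_library <- function(truth, ref_id = "utr") {
  stopifnot(inherits(truth, "synthetic_truth"))
  rng <- truth$fragment_size_range
  if (rng[1] > truth$utr_length) {
    stop("fragment_size_range does not fit inside the UTR")
  }
  set.seed(child_seed(truth$seed, "fragments"))
  n <- truth$n_fragments
  if (n == 0) return(intervals(integer(0), integer(0), ref_id = character(0)))
  len <- sample(seq.int(rng[1], min(rng[2], truth$utr_length)), n,
                replace = TRUE)
  start <- vapply(len, function(l) {
    sample.int(truth$utr_length - l + 1L, 1L) - 1L
  }, integer(1))
  intervals(start = start, end = start + len, ref_id = ref_id,
            name = sprintf("frag%05d", seq_len(n)))
}

fragment_contains_element <- function(fragments, element) {
  fragments$start <= element$start & fragments$end >= element$end
}

#' Simulate compartment reads over a fragment library
#'
#' Each sample's reads are a multinomial draw over fragments at that
#' sample's depth; a read is its fragment's interval. Input and body
#' sampling weights are uniform; in the projection sample, fragments
#' containing the entire localization element carry weight
#' `enrichment_factor`, all others weight 1 (partial overlap confers no
#' advantage, reproducing the sharp sufficiency boundary the window
#' analysis exploits).
#'
#' @param truth A `synthetic_truth`.
#' @param fragments Fragment library from [generate_fragment_library()].
#' @return List of interval data.frames `input`, `body`, `projection`;
#'   the per-fragment draw counts are kept in attribute
#'   `fragment_counts`.
#' @export
simulate_compartment_reads <- function(truth, fragments) {
  stopifnot(inherits(truth, "synthetic_truth"))
  validate_intervals(fragments)
  set.seed(child_seed(truth$seed, "reads"))
  n <- nrow(fragments)
  w_unif <- rep(1, n)
  w_proj <- ifelse(fragment_contains_element(fragments, truth$element),
                   truth$enrichment_factor, 1)
  draw <- function(depth, w) as.vector(stats::rmultinom(1, depth, w))
  counts <- cbind(
    input = draw(truth$depths[["input"]], w_unif),
    body = draw(truth$depths[["body"]], w_unif),
    projection = draw(truth$depths[["projection"]], w_proj)
  )
  expand <- function(k) {
    idx <- rep.int(seq_len(n), k)
    fragments[idx, c("ref_id", "start", "end", "name"), drop = FALSE]
  }
  out <- list(input = expand(counts[, "input"]),
              body = expand(counts[, "body"]),
              projection = expand(counts[, "projection"]))
  attr(out, "fragment_counts") <- counts
  out
}

#' Simulate DMS mutation counts from a known structure
#'
#' Per-position mutation counts are binomial at the paired rate where the
#' generative structure pairs the base and at the unpaired rate
#' elsewhere, at constant coverage.
#'
#' @param truth A `synthetic_truth`.
#' @param reference A `reference_sequence` of length `utr_length`.
#' @return Data frame with `position` (1-based), `base`, `mutations`,
#'   `coverage`.
#' @export
simulate_dms_counts <- function(truth, reference) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(reference, "reference_sequence"))
  chars <- strsplit(truth$structure, "")[[1]]
  if (length(chars) != reference$length) {
    stop("structure length does not match reference length")
  }
  if (!all(chars %in% c(".", "(", ")"))) {
    stop("structure must be a dot-bracket string over {., (, )}")
  }
  set.seed(child_seed(truth$seed, "dms"))
  paired <- chars %in% c("(", ")")
  mu <- ifelse(paired, truth$mu_paired, truth$mu_unpaired)
  data.frame(
    position = seq_len(reference$length),
    base = strsplit(reference$bases, "")[[1]],
    mutations = stats::rbinom(reference$length, truth$coverage, mu),
    coverage = rep.int(truth$coverage, reference$length),
    stringsAsFactors = FALSE
  )
}

# One synthetic segmented cell: concentric disc body and whole-cell masks
# (pixel-count areas), Poisson spot count, spots placed on body pixels or
# projection pixels according to the condition's p_outside, and EGFP
# proportional to spot count with log-normal noise.
make_cell <- function(cell_id, condition, eff, spot_rate, egfp_noise_sd) {
  body_area_target <- stats::rlnorm(1, log(200), 0.25)
  proj_ratio <- stats::rlnorm(1, log(2), 0.25)
  rb <- sqrt(body_area_target / pi)
  rc <- sqrt(body_area_target * (1 + proj_ratio) / pi)
  g <- 2L * as.integer(ceiling(rc)) + 3L
  ctr <- (g + 1) / 2
  d2 <- outer((seq_len(g) - ctr)^2, (seq_len(g) - ctr)^2, `+`)
  cell_mask <- d2 <= rc^2
  body_mask <- d2 <= rb^2
  body_px <- which(body_mask, arr.ind = TRUE)
  proj_px <- which(cell_mask & !body_mask, arr.ind = TRUE)
  n_spots <- stats::rpois(1, spot_rate)
  outside <- stats::runif(n_spots) < eff$p_outside
  pick <- function(px, k) px[sample.int(nrow(px), k, replace = TRUE), ,
                             drop = FALSE]
  spots <- matrix(integer(0), 0, 2)
  if (n_spots > 0) {
    spots <- rbind(
      if (sum(!outside) > 0) pick(body_px, sum(!outside)),
      if (sum(outside) > 0) pick(proj_px, sum(outside))
    )
    colnames(spots) <- c("x", "y")
  }
  list(cell_id = cell_id, condition = condition, spots = spots,
       body_mask = body_mask, cell_mask = cell_mask,
       body_area = sum(body_mask), cell_area = sum(cell_mask),
       egfp_intensity = eff$translation_scale * n_spots *
         stats::rlnorm(1, 0, egfp_noise_sd))
}

#' Simulate segmented cells with condition-dependent localization
#'
#' @param truth A `synthetic_truth` (uses `condition_effects`,
#'   `spot_rate`, `egfp_noise_sd` and the root seed).
#' @param n_cells_per_condition Cells per condition (default 50).
#' @param conditions Condition labels to simulate; defaults to all in
#'   `condition_effects`. Unknown labels are an error.
#' @return List of cell records (see [classify_spots()]).
#' @export
simulate_cells <- function(truth, n_cells_per_condition = 50,
                           conditions = names(truth$condition_effects)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  unknown <- setdiff(conditions, names(truth$condition_effects))
  if (length(unknown)) {
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  }
  set.seed(child_seed(truth$seed, "cells"))
  cells <- list()
  for (cond in conditions) {
    eff <- truth$condition_effects[[cond]]
    for (i in seq_len(n_cells_per_condition)) {
      cells[[length(cells) + 1L]] <-
        make_cell(sprintf("%s_%03d", cond, i), cond, eff,
                  truth$spot_rate, truth$egfp_noise_sd)
    }
  }
  cells
}

#' Flatten cell records to the combined tabular form
#'
#' @param cells List of cell records from [simulate_cells()].
#' @return Data frame with `cell_id`, `condition`, `n_in`, `n_out`,
#'   `body_area`, `cell_area`, `egfp_intensity`.
#' @export
cells_to_table <- function(cells) {
  do.call(rbind, lapply(cells, function(cell) {
    cnt <- classify_spots(cell)
    data.frame(cell_id = cell$cell_id, condition = cell$condition,
               n_in = cnt$n_in, n_out = cnt$n_out,
               body_area = cell$body_area, cell_area = cell$cell_area,
               egfp_intensity = cell$egfp_intensity,
               stringsAsFactors = FALSE)
  }))
}

#' Write a full set of synthetic pipeline inputs to disk
#'
#' Generates and writes: the reference FASTA, one BED of reads per sample,
#' the DMS counts TSV, the per-cell TSV, and a JSON record of the
#' generative truth (element coordinates, structure, parameters) for test
#' harnesses.
#'
#' @param truth A `synthetic_truth`.
#' @param dir Output directory (created if missing).
#' @param n_cells_per_condition Cells per condition.
#' @return Named list of written file paths, invisibly.
#' @export
write_synthetic_inputs <- function(truth, dir, n_cells_per_condition = 50) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(truth$utr_length,
                            seed = child_seed(truth$seed, "reference"))
  fragments <- generate_fragment_library(truth, ref_id = ref$ref_id)
  reads <- simulate_compartment_reads(truth, fragments)
  dms <- simulate_dms_counts(truth, ref)
  cells <- simulate_cells(truth, n_cells_per_condition)
  paths <- list(
    reference = file.path(dir, "reference.fasta"),
    input = file.path(dir, "input.bed"),
    body = file.path(dir, "body.bed"),
    projection = file.path(dir, "projection.bed"),
    dms_counts = file.path(dir, "dms_counts.tsv"),
    cells = file.path(dir, "cells.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(ref, paths$reference)
  write_bed(reads$input, paths$input)
  write_bed(reads$body, paths$body)
  write_bed(reads$projection, paths$projection)
  write_dms_counts(dms, paths$dms_counts)
  write_cells_tsv(cells_to_table(cells), paths$cells)
  truth_rec <- list(
    utr_length = truth$utr_length,
    element = to_onebased(truth$element),
    enrichment_factor = truth$enrichment_factor,
    fragment_size_range = truth$fragment_size_range,
    n_fragments = truth$n_fragments,
    depths = as.list(truth$depths),
    structure = truth$structure,
    mu_paired = truth$mu_paired, mu_unpaired = truth$mu_unpaired,
    coverage = truth$coverage,
    condition_effects = truth$condition_effects,
    control_label = truth$control_label,
    seed = truth$seed
  )
  jsonlite::write_json(truth_rec, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
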