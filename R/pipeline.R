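# End-to-end orchestration: simulate (or load) inputs, run the
# enrichment, reactivity and imaging stages, and emit a machine-readable
# report plus human-facing tracks and tables.

#' Default run configuration
#'
#' Flat list of every tunable the pipeline exposes, with the assay-scale
#' defaults: 250-nt windows every 5 nt, input floor 10 reads/window,
#' region threshold 0.5 of the track maximum, 50-nt reactivity
#' normalization window, coverage floor 500, projection-positive sign,
#' and 1000 bootstrap replicates.
#'
#' @param seed Root RNG seed for simulation and bootstrap.
#' @param ... Overrides for any config entry.
#' @return Named list.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    utr_length = 1500,
    element_first = 650, element_last = 776,
    enrichment_factor = 8,
    fragment_size_min = 200, fragment_size_max = 400,
    n_fragments = 5000,
    depth_input = 1e5, depth_body = 1e5, depth_projection = 1e5,
    coverage = 5000, mu_paired = 0.005, mu_unpaired = 0.05,
    window_size = 250, step = 5, min_input = 10,
    threshold_fraction = 0.5, sign = "projection",
    norm_window = 50, coverage_floor = 500,
    control_label = "no_utr", n_cells = 50, n_boot = 1000
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  num <- c("utr_length", "enrichment_factor", "n_fragments", "depth_input",
           "depth_body", "depth_projection", "coverage", "window_size",
           "step", "threshold_fraction", "norm_window", "n_cells", "n_boot")
  if (any(unlist(cfg[num]) <= 0)) stop("numeric config parameters must be positive")
  cfg
}

truth_from_config <- function(cfg) {
  synthetic_truth(
    utr_length = cfg$utr_length,
    element = from_onebased(cfg$element_first, cfg$element_last,
                            ref_id = "utr", name = "element"),
    enrichment_factor = cfg$enrichment_factor,
    fragment_size_range = c(cfg$fragment_size_min, cfg$fragment_size_max),
    n_fragments = cfg$n_fragments,
    depths = c(input = cfg$depth_input, body = cfg$depth_body,
               projection = cfg$depth_projection),
    mu_paired = cfg$mu_paired, mu_unpaired = cfg$mu_unpaired,
    coverage = cfg$coverage, control_label = cfg$control_label,
    seed = cfg$seed
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the discovery pipeline end to end
#'
#' Either simulates a complete experiment from the config (the default)
#' or consumes user-supplied files, then runs every stage: rolling-window
#' enrichment, region calling (union and core refinement), minimal-signal
#' delimitation, DMS reactivity normalization with structure concordance
#' (when the generative structure is known), per-cell localization and
#' translation scoring, and condition-level fold changes. Identical
#' config and seed give identical outputs.
#'
#' @param config List from [default_config()].
#' @param simulate If `TRUE`, generate all inputs from the config.
#' @param paths When `simulate = FALSE`: named list with `input`, `body`,
#'   `projection` (BED), `reference` (FASTA), and optionally `dms_counts`
#'   and `cells` (TSV).
#' @param outdir Optional directory; when given, tracks, tables and the
#'   JSON report are written there.
#' @return A `locsig_run` object: list with `config`, `truth` (when
#'   simulated), `track`, `regions`, `regions_core`, `minimal`,
#'   `reactivity`, `agreement`, `loc_scores`, `translation`,
#'   `fold_changes` and `report`.
#' @export
run_discovery <- function(config = default_config(), simulate = TRUE,
                          paths = NULL, outdir = NULL) {
  cfg <- config
  truth <- NULL
  if (simulate) {
    truth <- stage("simulate", truth_from_config(cfg))
    ref <- generate_reference(cfg$utr_length,
                              seed = child_seed(cfg$seed, "reference"))
    fragments <- generate_fragment_library(truth, ref_id = ref$ref_id)
    reads <- simulate_compartment_reads(truth, fragments)
    dms <- simulate_dms_counts(truth, ref)
    cells <- stage("simulate", cells_to_table(simulate_cells(truth, cfg$n_cells)))
    structure <- truth$structure
  } else {
    for (p in c("input", "body", "projection", "reference")) {
      if (is.null(paths[[p]]) || !file.exists(paths[[p]])) {
        stop(sprintf("[load] missing %s file: %s", p,
                     if (is.null(paths[[p]])) "<unset>" else paths[[p]]),
             call. = FALSE)
      }
    }
    ref <- stage("load", read_fasta(paths$reference))
    reads <- stage("load", list(input = read_bed(paths$input),
                                body = read_bed(paths$body),
                                projection = read_bed(paths$projection)))
    dms <- if (!is.null(paths$dms_counts)) {
      stage("load", read_dms_counts(paths$dms_counts))
    }
    cells <- if (!is.null(paths$cells)) stage("load", read_cells_tsv(paths$cells))
    structure <- NULL
  }

  track <- stage("enrich", slap_enrichment(
    reads$input, reads$body, reads$projection,
    ref_length = ref$length, window_size = cfg$window_size, step = cfg$step,
    min_input = cfg$min_input, sign = cfg$sign, ref_id = ref$ref_id
  ))
  regions <- stage("enrich", call_regions(track, cfg$threshold_fraction))
  regions_core <- stage("enrich",
                        call_regions(track, cfg$threshold_fraction, refine = "core"))
  minimal <- stage("enrich", minimal_signal(regions_core))

  reactivity <- agreement <- NULL
  if (!is.null(dms)) {
    reactivity <- stage("reactivity", dms_reactivity(
      dms, ref, window = cfg$norm_window, coverage_floor = cfg$coverage_floor
    ))
    if (!is.null(structure)) {
      agreement <- stage("reactivity", structure_agreement(reactivity, structure))
    }
  }

  loc_scores <- translation <- fold_changes <- NULL
  if (!is.null(cells)) {
    loc_scores <- stage("fishscore", normalize_to_control(
      localization_scores(cells), cfg$control_label
    ))
    translation <- stage("fishscore", translation_output(cells))
    fold_changes <- stage("fishscore", fold_change_summary(
      translation, cfg$control_label, n_boot = cfg$n_boot, seed = cfg$seed
    ))
  }

  results <- list(config = cfg, truth = truth, track = track,
                  regions = regions, regions_core = regions_core,
                  minimal = minimal, reactivity = reactivity,
                  agreement = agreement, loc_scores = loc_scores,
                  translation = translation, fold_changes = fold_changes)
  results$report <- make_report(results)
  class(results) <- "locsig_run"
  if (!is.null(outdir)) write_run_outputs(results, outdir)
  results
}

regions_record <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(list())
  ob <- to_onebased(iv)
  lapply(seq_len(nrow(ob)), function(i) {
    list(ref_id = ob$ref_id[i], first = ob$first[i], last = ob$last[i],
         length = ob$length[i])
  })
}

#' Build the machine-readable run report
#'
#' Collects parameters, seed, package version, per-stage headline numbers
#' and every exclusion count (masked windows, excluded cells) into one
#' JSON-serializable list; candidate intervals are reported 1-based with
#' lengths. The report validates against [validate_report()].
#'
#' @param results Named list of stage results (see [run_discovery()]).
#' @return Report list.
#' @export
make_report <- function(results) {
  cfg <- results$config
  track <- results$track
  rep <- list(
    tool = "locsig",
    version = as.character(utils::packageVersion("locsig")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "seed")],
    enrichment = if (!is.null(track)) list(
      n_windows = length(track$mask),
      n_masked = sum(!track$mask),
      max_enrichment = if (any(track$mask)) max(track$enrichment, na.rm = TRUE),
      sign = track$sign
    ),
    regions = regions_record(results$regions),
    regions_core = regions_record(results$regions_core),
    minimal_signal = regions_record(results$minimal),
    reactivity = if (!is.null(results$reactivity)) list(
      n_positions = results$reactivity$reference$length,
      n_valid = sum(results$reactivity$valid),
      capped = results$reactivity$params$capped,
      structure_concordance = if (!is.null(results$agreement)) {
        results$agreement$concordance
      }
    ),
    imaging = if (!is.null(results$loc_scores)) list(
      n_cells = nrow(results$loc_scores),
      n_excluded = sum(results$loc_scores$excluded),
      control_median_normalized = stats::median(
        results$loc_scores$normalized[
          results$loc_scores$condition == cfg$control_label &
            !results$loc_scores$excluded]),
      fold_changes = lapply(seq_len(nrow(results$fold_changes)), function(i) {
        as.list(results$fold_changes[i, c("condition", "n_cells",
                                          "median_signal", "fold_change",
                                          "ci_lo", "ci_hi")])
      })
    )
  )
  validate_report(rep)
  rep
}

#' Validate a run report against the packaged schema
#'
#' The schema (`inst/extdata/report_schema.json`) lists the required
#' top-level fields and their types; nested candidate-interval records
#' must carry 1-based `first`/`last` and `length`.
#'
#' @param report Report list from [make_report()] or parsed from JSON.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("extdata", "report_schema.json",
                             package = "locsig", mustWork = TRUE)
  schema <- jsonlite::read_json(schema_path)
  for (field in names(schema$required)) {
    if (!field %in% names(report)) stop("report missing field: ", field)
    type <- schema$required[[field]]
    ok <- switch(type,
                 string = is.character(report[[field]]),
                 integer = is.numeric(report[[field]]),
                 object = is.list(report[[field]]),
                 list = is.list(report[[field]]) || is.null(report[[field]]),
                 TRUE)
    if (!ok) stop(sprintf("report field '%s' is not of type %s", field, type))
  }
  for (grp in c("regions", "regions_core", "minimal_signal")) {
    for (r in report[[grp]]) {
      if (!all(c("first", "last", "length") %in% names(r))) {
        stop("interval record in '", grp, "' lacks first/last/length")
      }
      if (r$last - r$first + 1 != r$length) {
        stop("interval record in '", grp, "' has inconsistent length")
      }
    }
  }
  invisible(TRUE)
}

write_run_outputs <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  track <- results$track
  write_track(track$grid, track$enrichment,
              file.path(outdir, "enrichment.bedgraph"), mask = track$mask)
  utils::write.table(as.data.frame(track),
                     file.path(outdir, "enrichment_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(results$regions)) {
    write_bed(results$regions, file.path(outdir, "called_regions.bed"))
  }
  if (nrow(results$regions_core)) {
    write_bed(results$regions_core, file.path(outdir, "called_regions_core.bed"))
  }
  if (!is.null(results$reactivity)) {
    utils::write.table(as.data.frame(results$reactivity),
                       file.path(outdir, "reactivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    prof <- results$reactivity
    pos_iv <- intervals(start = prof$position - 1L, end = prof$position,
                        ref_id = prof$reference$ref_id)
    write_track(pos_iv, ifelse(prof$valid, prof$reactivity, NA_real_),
                file.path(outdir, "reactivity.bedgraph"), mask = prof$valid)
  }
  if (!is.null(results$loc_scores)) {
    utils::write.table(results$loc_scores,
                       file.path(outdir, "localization_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(results$fold_changes)) {
    utils::write.table(as.data.frame(results$fold_changes),
                       file.path(outdir, "fold_changes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(results$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.locsig_run <- function(x, ...) {
  cat("<locsig_run>\n")
  print(x$track)
  cat(sprintf("  called regions: %d (union), %d (core)\n",
              nrow(x$regions), nrow(x$regions_core)))
  if (nrow(x$minimal)) {
    cat("  candidate minimal signal (1-based):\n")
    for (i in seq_len(nrow(x$minimal))) {
      cat(sprintf("    %d-%d (%d nt)\n", x$minimal$first[i],
                  x$minimal$last[i], x$minimal$length[i]))
    }
  }
  if (!is.null(x$agreement)) {
    cat(sprintf("  reactivity/structure concordance: %.3f\n",
                x$agreement$concordance))
  }
  if (!is.null(x$fold_changes)) print(x$fold_changes)
  invisible(x)
}

#' Render a human-readable summary from a report
#'
#' @param report Report list or path to a report JSON.
#' @return Character vector of summary lines, invisibly; also printed.
#' @export
report_summary <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  validate_report(report)
  lines <- c(
    sprintf("%s %s run, seed %d", report$tool, report$version, report$seed),
    if (!is.null(report$enrichment)) {
      sprintf("enrichment: %d windows (%d masked), max %.4g, sign %s",
              report$enrichment$n_windows, report$enrichment$n_masked,
              report$enrichment$max_enrichment, report$enrichment$sign)
    },
    if (length(report$minimal_signal)) {
      vapply(report$minimal_signal, function(r) {
        sprintf("candidate signal: %d-%d (1-based, %d nt)",
                r$first, r$last, r$length)
      }, character(1))
    } else "candidate signal: none called"
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
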