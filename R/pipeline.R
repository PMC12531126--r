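# End-to-end per-patient and cohort orchestration.

#' Pipeline thresholds
#'
#' @param detection Minimum identity fraction / MCF for presence calls.
#' @param mcf_tolerance Profile clustering tolerance for deconvolution.
#' @param reciprocal_overlap CNA event-merging threshold.
#' @param exhaustive_limit Exact parsimony search limit (subclones).
#' @param include_relapse Treat anatomically distinct relapse sites as
#'   metastatic.
#' @param vaf_tumor_min,vaf_normal_max,dp_min,mapq_min Variant quality
#'   thresholds.
#' @return List of class `trace_config`.
#' @export
trace_config <- function(detection = 0.05, mcf_tolerance = 0.1,
                         reciprocal_overlap = 0.9, exhaustive_limit = 9L,
                         include_relapse = TRUE, vaf_tumor_min = 0.05,
                         vaf_normal_max = 0.05, dp_min = 20,
                         mapq_min = 50) {
  structure(as.list(environment()), class = "trace_config")
}

#' Trace the metastatic history of one patient
#'
#' The full analysis: per-sample clone-fraction quantification and purity
#' estimation, variant filtering (when calls are supplied), event merging,
#' cross-sample subclonal deconvolution, maximum-parsimony tree
#' reconstruction, and spread-mode classification.
#'
#' @param segments Segment rows for one patient across samples (internal
#'   layout of [read_segment_table()]; `MSF`/`MCF` may be empty).
#' @param metadata Sample metadata for the patient ([read_metadata()]).
#' @param variants Optional variant calls ([read_variant_table()] layout).
#' @param bed Targeted-region `GRanges`; required when `variants` given.
#' @param tcf Optional named vector of known purities per sample,
#'   overriding estimation.
#' @param config A [trace_config()].
#' @return Object of class `patient_trace`: list with `purities`,
#'   `segments` (quantified), `events`, `subclones`, `tree` (annotated
#'   `clone_tree`), `report` (`spread_report`).
#' @export
trace_patient <- function(segments, metadata, variants = NULL, bed = NULL,
                          tcf = NULL, config = trace_config()) {
  patient <- unique(segments$patient)
  if (length(patient) != 1) {
    stop_ct("segments must belong to one patient", "invalid_input")
  }
  metadata <- metadata[metadata$patient == patient, , drop = FALSE]
  samples <- metadata$sample
  quant <- list()
  purities <- list()
  for (s in intersect(samples, unique(segments$sample))) {
    q <- quantify_sample(segments[segments$sample == s, , drop = FALSE],
                         tcf = if (!is.null(tcf)) unname(tcf[s]))
    quant[[s]] <- q$segments
    purities[[s]] <- q$purity
  }
  seg_q <- do.call(rbind, quant)
  seg_q <- calibrate_errors(seg_q, purities)
  if (!is.null(variants) && nrow(variants)) {
    if (is.null(bed)) {
      stop_ct("variants supplied without a BED of targeted regions",
              "configuration_error")
    }
    snv_rows <- filter_patient_variants(
      variants[variants$patient == patient, , drop = FALSE], bed, purities)
    if (nrow(snv_rows)) seg_q <- rbind(seg_q, snv_rows)
  }
  events <- merge_events(seg_q, samples = samples,
                         reciprocal_overlap = config$reciprocal_overlap)
  subclones <- reconcile_subclones(events,
                                   mcf_tolerance = config$mcf_tolerance,
                                   detection = config$detection,
                                   strict = FALSE)
  tree <- max_parsimony_tree(subclones$matrix,
                             exhaustive_limit = config$exhaustive_limit)
  tree <- annotate_tree(tree, metadata,
                        subclones$fractions * subclones$detected,
                        detection = config$detection)
  report <- classify_spread(tree, patient_id = patient,
                            include_relapse = config$include_relapse)
  structure(
    list(patient_id = patient, purities = purities, segments = seg_q,
         events = events, subclones = subclones, tree = tree,
         report = report),
    class = "patient_trace"
  )
}

#' @export
print.patient_trace <- function(x, ...) {
  cat(sprintf("<patient_trace %s> %d samples, %d events, %d subclones\n",
              x$patient_id, length(x$purities), nrow(x$events$events),
              nrow(x$subclones$matrix)))
  print(x$report)
  invisible(x)
}

spread_modes <- c("earlier", "later", "monoclonal", "polyclonal",
                  "monophyletic", "polyphyletic", "intermetastatic")

report_flags <- function(report) {
  inter <- if (is.data.frame(report$intermetastatic)) {
    any(report$intermetastatic$resolved)
  } else NA
  c(earlier = report$earlier, later = report$later,
    monoclonal = report$monoclonal, polyclonal = report$polyclonal,
    monophyletic = identical(report$phyletic, "monophyletic"),
    polyphyletic = identical(report$phyletic, "polyphyletic"),
    intermetastatic = inter)
}

#' Cohort spread-mode grid
#'
#' The presence/absence grid over spread modes (rows) and patients
#' (columns): `"present"`, `"absent"`, or `"not-evaluable"` (gray state;
#' intermetastatic spread cannot be assessed with metastases in a single
#' anatomical location).
#'
#' @param reports List of `spread_report` objects.
#' @return Character matrix, modes x patients.
#' @export
spread_grid <- function(reports) {
  g <- vapply(reports, function(r) {
    fl <- report_flags(r)
    ifelse(is.na(fl), "not-evaluable", ifelse(fl, "present", "absent"))
  }, character(length(spread_modes)))
  rownames(g) <- spread_modes
  colnames(g) <- vapply(reports, function(r) r$patient_id, "")
  g
}

#' Trace a whole cohort
#'
#' Runs [trace_patient()] per patient; failures are isolated (the patient
#' is flagged not-evaluable and the run continues).
#'
#' @param segments,metadata,variants,bed Cohort-level inputs (multiple
#'   patients).
#' @param config A [trace_config()].
#' @return Object of class `cohort_trace`: `patients` (list of
#'   `patient_trace` or `NULL` for failures), `grid`, `igd` (patients x
#'   sample-class matrix), `failed` (character vector).
#' @export
trace_cohort <- function(segments, metadata, variants = NULL, bed = NULL,
                         config = trace_config()) {
  ids <- unique(metadata$patient)
  patients <- list()
  failed <- character()
  for (p in ids) {
    res <- tryCatch(
      trace_patient(segments[segments$patient == p, , drop = FALSE],
                    metadata, variants = variants, bed = bed,
                    config = config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed <- c(failed, p)
      patients[p] <- list(NULL)
    } else {
      patients[[p]] <- res
    }
  }
  ok <- !vapply(patients, is.null, TRUE)
  reports <- lapply(patients[ok], function(x) x$report)
  igd_m <- t(vapply(patients[ok], function(x) x$report$igd,
                    numeric(4)))
  structure(
    list(patients = patients, grid = spread_grid(reports), igd = igd_m,
         failed = failed, config = config),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %d patients (%d failed)\n",
              length(x$patients), length(x$failed)))
  print(x$grid)
  invisible(x)
}

#' Summary statistics and cohort tests
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return List with `counts` (patients showing each mode), `n_evaluable`
#'   (per mode), `igd_tests` (paired t-tests of IGD, primary vs
#'   lymph-node and primary vs distant).
#' @export
summary.cohort_trace <- function(object, ...) {
  g <- object$grid
  counts <- rowSums(g == "present")
  n_eval <- rowSums(g != "not-evaluable")
  tests <- list()
  for (cl in c("lymph-node", "distant")) {
    if (cl %in% colnames(object$igd)) {
      tests[[paste0("primary_vs_", cl)]] <- cohort_tests(
        list(primary = object$igd[, "primary"], met = object$igd[, cl]),
        paired = TRUE
      )
    }
  }
  list(counts = counts, n_evaluable = n_eval, igd_tests = tests)
}

#' Run the full file-based pipeline
#'
#' Reads the interchange files, traces every patient, and writes per
#' patient a quantified segment table, event matrix, Newick tree and
#' spread-report JSON, plus the cohort grid and IGD table.
#'
#' @param segment_file,metadata_file Paths (required).
#' @param variant_file,bed_file Paths (optional, both or neither).
#' @param outdir Output directory (created if missing).
#' @param config A [trace_config()].
#' @return The `cohort_trace`, invisibly.
#' @export
run_pipeline <- function(segment_file, metadata_file, variant_file = NULL,
                         bed_file = NULL, outdir = ".",
                         config = trace_config()) {
  segments <- read_segment_table(segment_file)
  metadata <- read_metadata(metadata_file)
  variants <- if (!is.null(variant_file)) read_variant_table(variant_file)
  bed <- if (!is.null(bed_file)) read_bed(bed_file)
  if (!is.null(variants) && is.null(bed)) {
    stop_ct("variant file supplied without a BED file", "configuration_error")
  }
  ct <- trace_cohort(segments, metadata, variants, bed, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(ct$patients)) {
    tr <- ct$patients[[p]]
    if (is.null(tr)) next
    write_segment_table(tr$segments,
                        file.path(outdir, paste0(p, "_segments.tsv")))
    write_event_matrix(tr$subclones,
                       file.path(outdir, paste0(p, "_event_matrix.tsv")))
    utils::write.table(
      data.frame(subclone = rownames(tr$subclones$fractions),
                 tr$subclones$fractions, check.names = FALSE),
      file.path(outdir, paste0(p, "_subclone_fractions.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_newick(tr$tree, file.path(outdir, paste0(p, ".nwk")))
    jsonlite::write_json(
      report_json(tr$report),
      file.path(outdir, paste0(p, "_spread.json")),
      auto_unbox = TRUE, pretty = TRUE, na = "null"
    )
  }
  utils::write.table(
    data.frame(mode = rownames(ct$grid), ct$grid, check.names = FALSE),
    file.path(outdir, "spread_grid.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(patient = rownames(ct$igd), ct$igd, check.names = FALSE),
    file.path(outdir, "igd.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  writeLines(c(
    paste0("clonetrace ", as.character(utils::packageVersion("clonetrace"))),
    paste0("R ", R.version.string),
    paste0(names(config), " = ",
           vapply(config, function(x) paste(format(x), collapse = ","), "")),
    paste0("patients_failed = ",
           if (length(ct$failed)) paste(ct$failed, collapse = ",") else "none")
  ), file.path(outdir, "run_log.txt"))
  invisible(ct)
}

report_json <- function(report) {
  list(
    patient_id = report$patient_id,
    n_met_sites = report$n_met_sites,
    sites = report$sites,
    earlier = report$earlier, later = report$later,
    monoclonal = report$monoclonal, polyclonal = report$polyclonal,
    phyletic = report$phyletic,
    intermetastatic = if (is.data.frame(report$intermetastatic)) {
      report$intermetastatic
    } else "not-evaluable",
    igd = as.list(report$igd)
  )
}
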