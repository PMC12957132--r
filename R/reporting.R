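#' Mutation-HLA pair heatmap table
#'
#' Long-format counts of matched mutation-allele pairs across a cohort:
#' for each (panel mutation, binding allele) pair, the number of patients
#' in which the pair is matched. A covered patient can contribute several
#' pairs, so the column sum is at least the number of covered patients.
#'
#' @param patients List of `neo_patient` records.
#' @param panel A `neo_panel`.
#' @return Data frame `mutation_id`, `allele`, `n_patients`, sorted by
#'   count descending.
#' @export
pair_heatmap_table <- function(patients, panel) {
  rep <- cohort_coverage(patients, panel)
  if (!nrow(rep$pairs)) {
    return(data.frame(mutation_id = character(), allele = character(),
                      n_patients = integer(), stringsAsFactors = FALSE))
  }
  counts <- stats::aggregate(patient_id ~ mutation_id + allele, rep$pairs,
                             function(x) length(unique(x)))
  names(counts)[3] <- "n_patients"
  counts <- counts[order(-counts$n_patients, counts$mutation_id,
                         counts$allele), , drop = FALSE]
  rownames(counts) <- NULL
  counts
}

#' Long stacked-bar export of per-locus binder counts
#'
#' @param panel A `neo_panel`.
#' @return Data frame `mutation_id`, `frequency`, `locus`, `n_binders`.
#' @export
panel_long_table <- function(panel) {
  if (!nrow(panel)) {
    return(data.frame(mutation_id = character(), frequency = numeric(),
                      locus = character(), n_binders = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    data.frame(mutation_id = panel$mutation_id[i],
               frequency = panel$frequency[i],
               locus = c("A", "B", "C"),
               n_binders = c(panel$count_A[i], panel$count_B[i],
                             panel$count_C[i]),
               stringsAsFactors = FALSE)
  }))
}

#' Assemble the end-of-run JSON report
#'
#' Serializes the run configuration, stage summaries and a file manifest
#' with md5 checksums. The report carries no timestamps, so re-running with
#' the same inputs reproduces identical JSON.
#'
#' @param config Run configuration list (echoed verbatim).
#' @param summaries Named list of stage summaries (catalog size, panel
#'   size, population coverages, cohort coverage, significant pairs,
#'   reactive wells, ...).
#' @param files Character vector of output file paths to fingerprint; all
#'   must exist.
#' @param path Output path for the JSON report.
#' @return The report list, invisibly.
#' @export
emit_report <- function(config, summaries, files, path) {
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop_arg("missing stage output file(s): %s",
             paste(basename(missing), collapse = ", "))
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = unname(file.size(files)),
    stringsAsFactors = FALSE
  )
  report <- list(config = config, summary = summaries, manifest = manifest)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}

#' Verify a run report's file manifest
#'
#' @param report_path Path to a report JSON written by [emit_report()].
#' @param dir Directory holding the output files.
#' @return TRUE invisibly; errors on a checksum mismatch or missing file.
#' @export
verify_report <- function(report_path, dir = dirname(report_path)) {
  rep <- jsonlite::read_json(report_path, simplifyVector = TRUE)
  man <- rep$manifest
  for (i in seq_len(nrow(man))) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f)) stop_arg("manifest file missing: %s", man$file[i])
    if (unname(tools::md5sum(f)) != man$md5[i]) {
      stop_arg("checksum mismatch for %s", man$file[i])
    }
  }
  invisible(TRUE)
}
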