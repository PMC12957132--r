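#' Build the recurrent-mutation catalog
#'
#' Applies the filter cascade used to derive a shared-mutation panel from a
#' cohort mutation table, in order:
#'
#' 1. drop variants with VAF below `min_vaf` (rows without a VAF are kept);
#' 2. keep only genes carrying a cancer-hallmark annotation in
#'    `gene_annotations`;
#' 3. keep only nonsynonymous consequences (missense, nonsense, frameshift);
#' 4. aggregate by mutation id, counting distinct patients;
#' 5. keep mutations recurrent in at least `min_recurrence` patients.
#'
#' Frequencies use the full cohort size as denominator, and a patient
#' carrying the same mutation in several rows counts once.
#'
#' @param variants Data frame of variant rows as returned by [read_maf()].
#' @param gene_annotations Data frame with columns `gene`, `role` (one of
#'   `oncogene`, `TSG`, `dual`, `unclassified`) and `hallmark` (logical);
#'   genes absent from the table are treated as lacking a hallmark
#'   annotation and excluded.
#' @param cohort_size Number of patients in the cohort (denominator for
#'   frequencies); must be at least the number of distinct sample ids.
#' @param min_recurrence Minimum number of distinct patients (>= 2).
#' @param min_vaf Minimum variant allele frequency (default 0.02).
#' @return A data frame of class `neo_catalog`, sorted by frequency
#'   descending (ties broken lexicographically by mutation id), with columns
#'   `mutation_id`, `gene`, `protein_change`, `consequence`, `n_samples`,
#'   `frequency`, `gene_role`, `impact`.
#' @examples
#' ann <- data.frame(gene = "KRAS", role = "oncogene", hallmark = TRUE)
#' v <- data.frame(sample_id = c("p1", "p2", "p3"), gene = "KRAS",
#'                 protein_change = "G12D", consequence = "missense",
#'                 vaf = 0.3, mutation_id = "KRAS_G12D")
#' build_catalog(v, ann, cohort_size = 10)
#' @export
build_catalog <- function(variants, gene_annotations, cohort_size,
                          min_recurrence = 2L, min_vaf = 0.02) {
  if (!is.numeric(cohort_size) || cohort_size <= 0) {
    stop_arg("cohort_size must be a positive integer")
  }
  if (is.null(gene_annotations) || nrow(gene_annotations) == 0) {
    stop_arg("gene_annotations is mandatory (gene, role, hallmark)")
  }
  if (min_recurrence < 2) stop_arg("min_recurrence must be >= 2")
  n_ids <- length(unique(variants$sample_id))
  if (cohort_size < n_ids) {
    stop_arg("cohort_size (%d) smaller than number of distinct samples (%d)",
             cohort_size, n_ids)
  }
  v <- variants
  # (1) VAF filter: rows without a VAF pass through
  v <- v[is.na(v$vaf) | v$vaf >= min_vaf, , drop = FALSE]
  # (2) hallmark / cancer-gene filter
  ann <- gene_annotations
  hall <- ann$gene[as.logical(ann$hallmark)]
  v <- v[v$gene %in% hall, , drop = FALSE]
  # (3) nonsynonymous only
  v <- v[v$consequence %in% c("missense", "nonsense", "frameshift"),
         , drop = FALSE]
  if (nrow(v) == 0) {
    out <- data.frame(mutation_id = character(), gene = character(),
                      protein_change = character(), consequence = character(),
                      n_samples = integer(), frequency = numeric(),
                      gene_role = character(), impact = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("neo_catalog", class(out))
    attr(out, "cohort_size") <- as.integer(cohort_size)
    return(out)
  }
  # (4) aggregate by mutation id over distinct patients
  key <- paste(v$mutation_id, v$sample_id, sep = "\r")
  v <- v[!duplicated(key), , drop = FALSE]
  counts <- table(v$mutation_id)
  first <- v[!duplicated(v$mutation_id), , drop = FALSE]
  rownames(first) <- first$mutation_id
  out <- data.frame(
    mutation_id = names(counts),
    gene = first[names(counts), "gene"],
    protein_change = first[names(counts), "protein_change"],
    consequence = first[names(counts), "consequence"],
    n_samples = as.integer(counts),
    stringsAsFactors = FALSE
  )
  # (5) recurrence filter
  out <- out[out$n_samples >= min_recurrence, , drop = FALSE]
  out$frequency <- out$n_samples / cohort_size
  role <- ann$role[match(out$gene, ann$gene)]
  out$gene_role <- ifelse(is.na(role), "unclassified", role)
  out$impact <- c(missense = "moderate", nonsense = "high",
                  frameshift = "high")[out$consequence]
  out <- out[order(-out$frequency, out$mutation_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("neo_catalog", class(out))
  attr(out, "cohort_size") <- as.integer(cohort_size)
  out
}

#' @export
print.neo_catalog <- function(x, ...) {
  cat(sprintf("Recurrent-mutation catalog: %d mutation(s) in %d gene(s), cohort n = %s\n",
              nrow(x), length(unique(x$gene)),
              attr(x, "cohort_size") %||% "?"))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Patient-by-mutation membership map
#'
#' @param variants Variant rows (with `sample_id`, `mutation_id`).
#' @param mutation_ids Optional restriction to these mutation ids.
#' @return Named list: patient id -> character vector of mutation ids.
#' @export
patient_mutation_map <- function(variants, mutation_ids = NULL) {
  v <- variants
  if (!is.null(mutation_ids)) {
    v <- v[v$mutation_id %in% mutation_ids, , drop = FALSE]
  }
  lapply(split(v$mutation_id, v$sample_id), unique)
}

#' Cumulative patient-coverage curve
#'
#' For each prefix of the catalog (ordered by descending frequency), the
#' fraction of patients carrying at least one of the first `k` mutations.
#' The curve is non-decreasing and its final point is the fraction of
#' patients with any catalog mutation.
#'
#' @param catalog A `neo_catalog` (or data frame with `mutation_id` ordered
#'   by descending frequency).
#' @param patient_mutations Named list: patient -> mutation-id vector. All
#'   patients in the list form the denominator.
#' @return Data frame with columns `k`, `mutation_id` (the mutation added at
#'   step `k`) and `covered_fraction`.
#' @export
cumulative_coverage <- function(catalog, patient_mutations) {
  if (!length(patient_mutations)) stop_arg("patient map is empty")
  ids <- catalog$mutation_id
  n <- length(patient_mutations)
  covered <- rep(FALSE, n)
  frac <- numeric(length(ids))
  for (k in seq_along(ids)) {
    hit <- vapply(patient_mutations, function(m) ids[k] %in% m, logical(1))
    covered <- covered | hit
    frac[k] <- sum(covered) / n
  }
  data.frame(k = seq_along(ids), mutation_id = ids,
             covered_fraction = frac, stringsAsFactors = FALSE)
}

#' Oncoplot-style 0/1 membership matrix
#'
#' @param patient_mutations Named list: patient -> mutation ids.
#' @param catalog Catalog whose mutations form the rows.
#' @return Integer matrix, mutations x patients, 1 where carried.
#' @export
oncoplot_matrix <- function(patient_mutations, catalog) {
  ids <- catalog$mutation_id
  m <- vapply(patient_mutations,
              function(mu) as.integer(ids %in% mu),
              integer(length(ids)))
  if (length(ids) == 1L) m <- matrix(m, nrow = 1)
  rownames(m) <- ids
  colnames(m) <- names(patient_mutations)
  m
}
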