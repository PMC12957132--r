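#' Matched mutation-HLA pairs for one patient
#'
#' A patient is covered by the panel only through a mutation-HLA pair: a
#' panel mutation the tumor carries together with a patient allele
#' predicted to bind one of its neoepitopes. Mutation presence alone does
#' not count. Genotypes are treated as presence sets, so a homozygous locus
#' contributes one distinct allele.
#'
#' @param patient A `neo_patient` (see [make_patient()]).
#' @param panel A `neo_panel` with its `binding_alleles` list column.
#' @return Data frame of matched pairs (`mutation_id`, `allele`); zero rows
#'   means not covered.
#' @export
patient_covered <- function(patient, panel) {
  if (!length(patient$hla_genotype)) {
    log_msg("warn", "patient ", patient$patient_id,
            " has an empty HLA genotype: cannot be covered")
  }
  rows <- list()
  idx <- which(panel$mutation_id %in% patient$mutations)
  for (i in idx) {
    hits <- intersect(panel$binding_alleles[[i]], patient$hla_genotype)
    if (length(hits)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mutation_id = panel$mutation_id[i], allele = hits,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mutation_id = character(), allele = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Cohort-level panel coverage
#'
#' Aggregates [patient_covered()] over a cohort: a patient counts as
#' covered when it has at least one matched mutation-HLA pair.
#'
#' @param patients List of `neo_patient` records.
#' @param panel A `neo_panel`.
#' @return A list of class `coverage_report`: `n_patients`, `n_covered`,
#'   `fraction`, `pairs` (long data frame `patient_id`, `mutation_id`,
#'   `allele`) and `per_mutation` (contribution counts: patients covered
#'   via each mutation).
#' @export
cohort_coverage <- function(patients, panel) {
  if (!length(patients)) stop_arg("empty cohort")
  pair_rows <- list()
  covered <- logical(length(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    pairs <- patient_covered(p, panel)
    covered[i] <- nrow(pairs) > 0
    if (nrow(pairs)) {
      pairs <- cbind(patient_id = p$patient_id, pairs,
                     stringsAsFactors = FALSE)
      pair_rows[[length(pair_rows) + 1L]] <- pairs
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(patient_id = character(), mutation_id = character(),
               allele = character(), stringsAsFactors = FALSE)
  per_mut <- if (nrow(pairs)) {
    u <- unique(pairs[, c("patient_id", "mutation_id")])
    as.data.frame(table(mutation_id = u$mutation_id),
                  responseName = "n_patients", stringsAsFactors = FALSE)
  } else data.frame(mutation_id = character(), n_patients = integer(),
                    stringsAsFactors = FALSE)
  structure(list(
    n_patients = length(patients),
    n_covered = sum(covered),
    fraction = sum(covered) / length(patients),
    covered = stats::setNames(covered, vapply(patients, `[[`, character(1),
                                              "patient_id")),
    pairs = pairs,
    per_mutation = per_mut
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Cohort coverage: %d/%d patients (%.2f%%) with >=1 mutation-HLA pair\n",
              x$n_covered, x$n_patients, 100 * x$fraction))
  invisible(x)
}

#' Microsatellite-instability classification from marker calls
#'
#' Five mononucleotide markers (BAT-25, BAT-26, MONO-27, NR-21, NR-24) are
#' scored for instability; tumors with two or more unstable markers are
#' MSI-high, those with one or none are microsatellite stable.
#'
#' @param markers Logical vector of length 5 (TRUE = unstable).
#' @return `"MSI-H"` or `"MSS"`.
#' @examples
#' msi_classify(c(TRUE, TRUE, FALSE, FALSE, FALSE))  # "MSI-H"
#' @export
msi_classify <- function(markers) {
  if (length(markers) != 5 || any(is.na(as.logical(markers)))) {
    stop_arg("exactly 5 logical marker calls required")
  }
  if (sum(as.logical(markers)) >= 2) "MSI-H" else "MSS"
}

#' Association between MSI status and panel-mutation carriage
#'
#' Builds the 2x2 table of (MSI-H vs MSS) against (carries at least one
#' panel mutation vs none) over patients with known MSI status and applies
#' the two-sided Fisher's exact test.
#'
#' @param patients List of `neo_patient` records.
#' @param panel A `neo_panel` (or character vector of panel mutation ids).
#' @return List with `table` (named 2x2 counts), `odds_ratio`, `p_value`.
#' @export
msi_panel_association <- function(patients, panel) {
  ids <- if (is.character(panel)) panel else panel$mutation_id
  status <- vapply(patients, `[[`, character(1), "msi_status")
  known <- status %in% c("MSI-H", "MSS")
  if (!any(known)) stop_arg("no patient with known MSI status")
  has_mut <- vapply(patients, function(p) any(p$mutations %in% ids),
                    logical(1))
  msi <- status[known] == "MSI-H"
  mut <- has_mut[known]
  if (all(msi) || !any(msi)) {
    stop_arg("degenerate MSI margin (all %s): association not testable",
             if (all(msi)) "MSI-H" else "MSS")
  }
  a <- sum(msi & mut); b <- sum(msi & !mut)
  cc <- sum(!msi & mut); d <- sum(!msi & !mut)
  ft <- fisher_exact_two_sided(a, b, cc, d)
  list(table = c(msi_mut = a, msi_nomut = b, mss_mut = cc, mss_nomut = d),
       odds_ratio = ft$odds_ratio, p_value = ft$p_value)
}

#' Spearman rank correlation with mid-ranks and t approximation
#'
#' Computes rho as the Pearson correlation of mid-ranks (ties receive
#' average ranks) and a two-sided p-value from the large-sample t
#' approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom, flagged approximate for `n < 10`.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return List with `rho`, `p_value`, `n`, `approximate`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_arg("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop_arg("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_arg("constant vector: rho undefined")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, approximate = n < 10)
}

#' ELISpot mutant vs wild-type reactivity call
#'
#' The fold change is mutant spots over wild-type spots; when the wild-type
#' well has zero spots a pseudocount of 1 is added to both wells. A well
#' pair is reactive when the fold change exceeds `fold_threshold` (default
#' 2) and the mutant well reaches `min_spots` (default 10), the floor
#' guarding against 2-spots-vs-1 artifacts.
#'
#' @param mut_spots,wt_spots Non-negative spot counts.
#' @param min_spots Minimum mutant spot count for a positive call.
#' @param fold_threshold Fold-change threshold (strict).
#' @return List with `fold_change` and `reactive`.
#' @examples
#' elispot_reactivity(50, 20)  # fold 2.5, reactive
#' elispot_reactivity(40, 0)   # fold 41, reactive (pseudocount)
#' @export
elispot_reactivity <- function(mut_spots, wt_spots, min_spots = 10,
                               fold_threshold = 2) {
  if (any(c(mut_spots, wt_spots) < 0)) stop_arg("spot counts must be >= 0")
  fold <- if (wt_spots == 0) (mut_spots + 1) / (wt_spots + 1)
          else mut_spots / wt_spots
  list(fold_change = fold,
       reactive = (fold > fold_threshold) && (mut_spots >= min_spots))
}
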