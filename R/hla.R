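#' Aggregate country-level HLA frequencies into population tables
#'
#' For each population group and (locus, allele), the aggregate frequency is
#' the sample-size-weighted mean over the group's countries,
#' `sum(n_c f_c) / sum(n_c)`, where a country that does not report the
#' allele contributes frequency 0 with its full weight (or the unweighted
#' mean under `weighting = "uniform"`). Aggregation is invariant to scaling
#' all sample sizes by a constant.
#'
#' @param rows Per-country rows as returned by [read_allele_frequencies()].
#' @param weighting `"sample_size"` (default) or `"uniform"`.
#' @return A data frame of class `allele_freq_table` with columns
#'   `population`, `locus`, `allele`, `frequency`, `n_eff` (summed sample
#'   size of the contributing countries).
#' @export
aggregate_population <- function(rows, weighting = c("sample_size", "uniform")) {
  weighting <- match.arg(weighting)
  need <- c("population_group", "country", "locus", "allele",
            "frequency", "sample_size")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop_arg("rows lack column(s): %s",
                             paste(miss, collapse = ", "))
  if (nrow(rows) == 0) stop_arg("no frequency rows supplied")
  dupkey <- paste(rows$population_group, rows$country, rows$allele, sep = "\r")
  if (anyDuplicated(dupkey)) {
    dups <- unique(paste0(rows$country, ":", rows$allele)[duplicated(dupkey)])
    stop_arg("conflicting duplicate (country, allele) rows: %s",
             paste(dups, collapse = ", "))
  }
  out <- list()
  for (popn in unique(rows$population_group)) {
    sub <- rows[rows$population_group == popn, , drop = FALSE]
    for (loc in unique(sub$locus)) {
      ls <- sub[sub$locus == loc, , drop = FALSE]
      countries <- unique(ls$country)
      # every country typed at this locus weighs in, reported allele or not
      wts <- vapply(countries, function(co)
        ls$sample_size[match(co, ls$country)], numeric(1))
      if (weighting == "uniform") wts[] <- 1
      for (al in sort(unique(ls$allele))) {
        f_by_country <- vapply(countries, function(co) {
          i <- which(ls$country == co & ls$allele == al)
          if (length(i)) ls$frequency[i] else 0
        }, numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          population = popn, locus = loc, allele = al,
          frequency = sum(wts * f_by_country) / sum(wts),
          n_eff = sum(vapply(countries, function(co)
            ls$sample_size[match(co, ls$country)], numeric(1))),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$population, tab$locus, -tab$frequency, tab$allele),
             , drop = FALSE]
  rownames(tab) <- NULL
  # per-locus sums cannot exceed 1
  sums <- tapply(tab$frequency, paste(tab$population, tab$locus), sum)
  if (any(sums > 1 + 1e-9)) {
    stop_arg("aggregated per-locus frequency sum exceeds 1 for: %s",
             paste(names(sums)[sums > 1 + 1e-9], collapse = ", "))
  }
  class(tab) <- c("allele_freq_table", class(tab))
  tab
}

.table_for_population <- function(table, population = NULL) {
  if (!is.null(population) && "population" %in% names(table)) {
    table <- table[table$population == population, , drop = FALSE]
  }
  table
}

#' Population coverage of an HLA allele set
#'
#' Two coverage models are supported.
#'
#' * `allelic`: the summed frequency of the selected alleles across loci,
#'   capped at 1 — the expected fraction of the population's allele pool
#'   captured by the set.
#' * `genotypic` (Hardy-Weinberg): `1 - prod_l (1 - S_l)^2` over loci `l`
#'   with selected-allele frequency sum `S_l` — the probability a random
#'   diploid individual carries at least one selected allele at at least
#'   one locus, assuming Hardy-Weinberg proportions and independent loci.
#'
#' @param allele_set Character vector of allele names (e.g. `"A*11:01"`).
#' @param table An `allele_freq_table` (optionally filtered to one
#'   population via `population`).
#' @param model `"genotypic"` (default) or `"allelic"`.
#' @param population Optional population label to filter `table`.
#' @return Coverage fraction in \[0, 1\].
#' @examples
#' tab <- data.frame(population = "Asian", locus = "A", allele = "A*11:01",
#'                   frequency = 0.5, n_eff = 100)
#' population_coverage("A*11:01", tab, model = "genotypic")  # 0.75
#' @export
population_coverage <- function(allele_set, table,
                                model = c("genotypic", "allelic"),
                                population = NULL) {
  model <- match.arg(model)
  table <- .table_for_population(table, population)
  allele_set <- unique(normalize_allele(allele_set))
  missing <- setdiff(allele_set, table$allele)
  if (length(missing)) {
    log_msg("warn", "allele(s) absent from table treated as frequency 0: ",
            paste(missing, collapse = ", "))
  }
  freqs <- table$frequency[match(allele_set, table$allele)]
  freqs[is.na(freqs)] <- 0
  if (model == "allelic") {
    return(min(1, sum(freqs)))
  }
  loci <- allele_locus(allele_set)
  s <- tapply(freqs, factor(loci, levels = c("A", "B", "C")), sum)
  s[is.na(s)] <- 0
  1 - prod((1 - s)^2)
}

#' Greedy selection of an HLA allele set for target coverage
#'
#' Adds alleles in order of descending aggregate frequency (ties broken by
#' allele name) across all loci until the coverage under the requested model
#' reaches `target`, or the table is exhausted (then the achieved coverage
#' is returned with a warning).
#'
#' @param table An `allele_freq_table`, optionally filtered via `population`.
#' @param target Target coverage fraction in (0, 1].
#' @param model `"genotypic"` (default) or `"allelic"`.
#' @param population Optional population label.
#' @return A list of class `allele_set` with elements `alleles` (data frame:
#'   `locus`, `allele`, `frequency`, `running_coverage`), `coverage`,
#'   `model`, `target`, `population`.
#' @export
select_allele_set <- function(table, target = 0.9,
                              model = c("genotypic", "allelic"),
                              population = NULL) {
  model <- match.arg(model)
  if (!is.numeric(target) || target <= 0 || target > 1) {
    stop_arg("target must lie in (0, 1]")
  }
  table <- .table_for_population(table, population)
  if (nrow(table) == 0) stop_arg("empty allele-frequency table")
  ord <- order(-table$frequency, table$allele)
  tab <- table[ord, , drop = FALSE]
  chosen <- integer()
  cov <- 0
  running <- numeric()
  for (i in seq_len(nrow(tab))) {
    chosen <- c(chosen, i)
    cov <- population_coverage(tab$allele[chosen], table, model = model)
    running <- c(running, cov)
    if (cov >= target) break
  }
  if (cov < target) {
    log_msg("warn", sprintf(
      "table exhausted at coverage %.4f (< target %.4f, %s model)",
      cov, target, model))
  }
  structure(list(
    alleles = data.frame(locus = tab$locus[chosen],
                         allele = tab$allele[chosen],
                         frequency = tab$frequency[chosen],
                         running_coverage = running,
                         stringsAsFactors = FALSE),
    coverage = cov, model = model, target = target,
    population = population %||% unique(tab$population)[1]
  ), class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat(sprintf(
    "HLA allele set (%s, %s model): %d allele(s), coverage %.1f%% (target %.0f%%)\n",
    x$population, x$model, nrow(x$alleles), 100 * x$coverage, 100 * x$target))
  counts <- table(x$alleles$locus)
  cat("  per locus:", paste(names(counts), counts, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
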