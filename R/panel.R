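#' Population neoantigen frequency of a mutation
#'
#' For a mutation with cohort frequency `f_m` and predicted binding alleles
#' `a_1..a_n` (percentile rank below the binder threshold), the population
#' neoantigen frequency is the mean of the products of mutation frequency
#' and allele frequency: `(1/n) * sum_i f_m * freq(a_i)`. Alleles missing
#' from the frequency table contribute 0 with a warning.
#'
#' @param mutation_frequency Cohort fraction carrying the mutation.
#' @param binding_alleles Non-empty character vector of binding alleles.
#' @param table An `allele_freq_table` (optionally filtered via
#'   `population`).
#' @param population Optional population label.
#' @return The neoantigen frequency (fraction).
#' @examples
#' tab <- data.frame(population = "Asian", locus = "A",
#'                   allele = c("A*11:01", "A*24:02"),
#'                   frequency = c(0.2, 0.1), n_eff = 100)
#' neoantigen_frequency(0.06, c("A*11:01", "A*24:02"), tab)  # 0.009
#' @export
neoantigen_frequency <- function(mutation_frequency, binding_alleles, table,
                                 population = NULL) {
  if (!length(binding_alleles)) {
    stop_arg("binding_alleles is empty: neoantigen frequency undefined")
  }
  table <- .table_for_population(table, population)
  alleles <- normalize_allele(binding_alleles)
  freqs <- table$frequency[match(alleles, table$allele)]
  if (any(is.na(freqs))) {
    log_msg("warn", "allele(s) missing from frequency table treated as 0: ",
            paste(alleles[is.na(freqs)], collapse = ", "))
    freqs[is.na(freqs)] <- 0
  }
  mean(mutation_frequency * freqs)
}

#' Assemble the off-the-shelf neoantigen panel
#'
#' Combines the recurrent-mutation catalog with per-(mutation, allele) best
#' binding ranks. Under `mode = "any_binder"` a catalog mutation enters the
#' panel when it has at least one binder (rank below `binder_rank`) among
#' the alleles of every requested population table. Under
#' `mode = "extended"` mutations with cohort frequency of at least
#' `min_panel_freq` and at least one strong binder (rank below
#' `strong_rank`) are additionally admitted.
#'
#' @param catalog A `neo_catalog`.
#' @param binding_calls Data frame with columns `mutation_id`, `allele`,
#'   `rank` (best rank per pair is taken if duplicated).
#' @param tables Named list of `allele_freq_table`s, one per population (or
#'   a single table; a table with a `population` column covering several
#'   labels is split).
#' @param mode `"any_binder"` (default) or `"extended"`.
#' @param binder_rank,strong_rank Percentile-rank thresholds (2 and 0.5).
#' @param min_panel_freq Recurrence floor for the extended rule (0.01).
#' @return A data frame of class `neo_panel` sorted by mutation frequency
#'   descending: `mutation_id`, `gene`, `frequency`, `n` (number of binding
#'   alleles), `count_A`, `count_B`, `count_C`, one `neo_freq_<population>`
#'   column per table, `extended_only` flag, and a `binding_alleles` list
#'   column used by the coverage accounting.
#' @export
build_panel <- function(catalog, binding_calls, tables,
                        mode = c("any_binder", "extended"),
                        binder_rank = 2, strong_rank = 0.5,
                        min_panel_freq = 0.01) {
  mode <- match.arg(mode)
  if (is.data.frame(tables)) {
    tables <- split(as.data.frame(tables), tables$population)
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop_arg("tables must be a named list (one allele table per population)")
  }
  bc <- binding_calls
  bc <- bc[bc$mutation_id %in% catalog$mutation_id, , drop = FALSE]
  if (nrow(bc) == 0) {
    log_msg("warn", "no binding calls for any catalog mutation: empty panel")
  }
  if (nrow(bc)) {
    bc$allele <- normalize_allele(bc$allele)
    bc <- bc[order(bc$mutation_id, bc$allele, bc$rank), , drop = FALSE]
    bc <- bc[!duplicated(bc[, c("mutation_id", "allele")]), , drop = FALSE]
  }
  pop_alleles <- lapply(tables, function(t) unique(t$allele))
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    mid <- catalog$mutation_id[i]
    calls <- bc[bc$mutation_id == mid, , drop = FALSE]
    binders <- calls[calls$rank < binder_rank, , drop = FALSE]
    if (nrow(binders) == 0) next
    in_all_pops <- all(vapply(pop_alleles, function(al)
      any(binders$allele %in% al), logical(1)))
    strong_n <- sum(binders$rank < strong_rank)
    keep <- in_all_pops
    extended_only <- FALSE
    if (!keep && mode == "extended" &&
        catalog$frequency[i] >= min_panel_freq && strong_n >= 1) {
      keep <- TRUE
      extended_only <- TRUE
    }
    if (!keep) next
    loci <- allele_locus(binders$allele)
    row <- data.frame(
      mutation_id = mid, gene = catalog$gene[i],
      frequency = catalog$frequency[i],
      n = nrow(binders),
      count_A = sum(loci == "A"), count_B = sum(loci == "B"),
      count_C = sum(loci == "C"),
      n_strong = strong_n, extended_only = extended_only,
      stringsAsFactors = FALSE
    )
    for (popn in names(tables)) {
      pop_binders <- binders$allele[binders$allele %in% pop_alleles[[popn]]]
      row[[paste0("neo_freq_", popn)]] <- if (length(pop_binders)) {
        neoantigen_frequency(catalog$frequency[i], pop_binders,
                             tables[[popn]])
      } else NA_real_
    }
    row$binding_alleles <- I(list(binders$allele))
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    base <- data.frame(mutation_id = character(), gene = character(),
                       frequency = numeric(), n = integer(),
                       count_A = integer(), count_B = integer(),
                       count_C = integer(), n_strong = integer(),
                       extended_only = logical(), stringsAsFactors = FALSE)
    for (popn in names(tables)) base[[paste0("neo_freq_", popn)]] <- numeric()
    base$binding_alleles <- I(list())
    base
  }
  out <- out[order(-out$frequency, out$mutation_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("neo_panel", class(out))
  attr(out, "mode") <- mode
  attr(out, "binder_rank") <- binder_rank
  attr(out, "strong_rank") <- strong_rank
  out
}

#' @export
print.neo_panel <- function(x, ...) {
  cat(sprintf("Neoantigen panel (%s): %d mutation(s), binder counts A/B/C = %d/%d/%d\n",
              attr(x, "mode"), nrow(x),
              sum(x$count_A), sum(x$count_B), sum(x$count_C)))
  if (nrow(x)) {
    show <- as.data.frame(x)[, setdiff(names(x), "binding_alleles")]
    print.data.frame(utils::head(show, 10))
    if (nrow(x) > 10) cat("...\n")
  }
  invisible(x)
}

#' Per-locus binder counts of a panel candidate
#'
#' @param binding_alleles Character vector of binding alleles for one
#'   mutation.
#' @return Named integer vector `c(A = , B = , C = )`; the counts partition
#'   the number of binding alleles.
#' @export
per_locus_counts <- function(binding_alleles) {
  loci <- factor(allele_locus(binding_alleles), levels = c("A", "B", "C"))
  counts <- table(loci)
  stats::setNames(as.integer(counts), names(counts))
}
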