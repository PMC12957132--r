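#' Path to the shipped synthetic HLA allele-frequency table
#'
#' A constructed per-country HLA-A/B/C frequency table for an Asian and a
#' Caucasian population group with realistic common-allele frequencies. It
#' is a synthetic stand-in shaped like curated population-database exports,
#' not measured data.
#'
#' @return File path of the TSV inside the installed package.
#' @export
default_hla_table_path <- function() {
  system.file("extdata", "hla_frequencies_synthetic.tsv",
              package = "otsneo", mustWork = TRUE)
}

#' Default run configuration
#'
#' Thresholds used across the pipeline, in one place: binder and
#' strong-binder percentile ranks (2 and 0.5), minimum recurrence (2
#' patients), minimum VAF (2%), extended-rule recurrence floor (1%),
#' ELISpot fold threshold (2) and spot floor (10), target HLA population
#' coverage (90%) and the coverage model.
#'
#' @param seed Integer seed for every stochastic component of a run.
#' @return A named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    binder_rank = 2, strong_rank = 0.5,
    min_recurrence = 2L, min_vaf = 0.02,
    min_panel_freq = 0.01,
    elispot_fold = 2, elispot_min_spots = 10,
    target_hla_coverage = 0.9,
    coverage_model = "genotypic",
    fdr_threshold = 0.05,
    panel_mode = "any_binder",
    peptide_lengths = 8:11
  )
}

.validate_config <- function(cfg) {
  stopifnot(cfg$strong_rank > 0, cfg$strong_rank < cfg$binder_rank,
            cfg$min_recurrence >= 2,
            cfg$target_hla_coverage > 0, cfg$target_hla_coverage <= 1,
            cfg$coverage_model %in% c("genotypic", "allelic"))
  cfg
}

#' Write a complete simulated input directory
#'
#' Emits everything [run_pipeline()] consumes, with planted ground truth:
#'
#' * `discovery_maf.tsv` — discovery-cohort variants (TCGA MAF dialect);
#' * `gene_annotations.tsv` — cancer-gene roles and hallmark flags;
#' * `hla_frequencies.tsv` — per-country allele frequencies;
#' * `proteins.fasta` / `frameshift_tails.tsv` — wild-type proteins
#'   consistent with the spectrum and novel frameshift tails;
#' * `predictions.tsv` — NetMHCpan-style percentile ranks over all mutant
#'   peptides and the selected population allele sets, with planted strong
#'   binders and planted/unplanted separation;
#' * `patients.tsv` — validation cohort with diploid genotypes and MSI
#'   marker calls;
#' * `elispot.tsv` — mutant/wild-type well pairs for tested patients;
#' * `config.json` and `truth.json`.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer master seed.
#' @param n_discovery Discovery cohort size (default 308).
#' @param n_validation Validation cohort size (default 67).
#' @param config Run configuration (default [default_config()]).
#' @param hla_path Per-country allele-frequency TSV (default the shipped
#'   synthetic table).
#' @param spectrum Mutation spectrum (default
#'   [default_mutation_spectrum()]).
#' @param planted_per_mutation Number of planted binder alleles per
#'   peptide-bearing mutation (default 2).
#' @return The truth list, invisibly.
#' @export
simulate_inputs <- function(dir, seed, n_discovery = 308L,
                            n_validation = 67L,
                            config = default_config(seed),
                            hla_path = default_hla_table_path(),
                            spectrum = default_mutation_spectrum(),
                            planted_per_mutation = 4L) {
  cfg <- .validate_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- read_allele_frequencies(hla_path)
  file.copy(hla_path, file.path(dir, "hla_frequencies.tsv"), overwrite = TRUE)
  tables <- aggregate_population(rows)
  populations <- unique(tables$population)
  # allele sets at the configured target coverage; their union is the
  # prediction space, mirroring a predictor run over both panels
  sets <- lapply(populations, function(p)
    select_allele_set(tables, target = cfg$target_hla_coverage,
                      model = cfg$coverage_model, population = p))
  names(sets) <- populations
  all_alleles <- sort(unique(unlist(lapply(sets, function(s) s$alleles$allele))))

  # proteins + peptides
  prot <- simulate_proteins(spectrum, seed = seed + 1L)
  write_proteins_fasta(prot$proteins, file.path(dir, "proteins.fasta"))
  tails_df <- data.frame(mutation_id = names(prot$tails),
                         tail = unname(prot$tails), stringsAsFactors = FALSE)
  write_tsv(tails_df, file.path(dir, "frameshift_tails.tsv"))
  peptides <- do.call(rbind, lapply(seq_len(nrow(spectrum)), function(i) {
    mid <- spectrum$mutation_id[i]
    mutation_peptides(prot$proteins[[spectrum$gene[i]]],
                      spectrum$protein_change[i],
                      frameshift_tail = if (mid %in% names(prot$tails))
                        prot$tails[[mid]] else NULL,
                      lengths = cfg$peptide_lengths, mutation_id = mid)
  }))

  # planted binders: for each peptide-bearing mutation, a deterministic
  # frequency-weighted draw of alleles from the union set
  pep_muts <- unique(peptides$mutation_id)
  planted <- with_seed(seed + 2L, {
    do.call(rbind, lapply(pep_muts, function(mid) {
      k <- min(planted_per_mutation, length(all_alleles))
      wts <- tables$frequency[match(all_alleles, tables$allele)]
      wts[is.na(wts) | wts <= 0] <- 1e-6
      data.frame(mutation_id = mid,
                 allele = sample(all_alleles, k, prob = wts),
                 stringsAsFactors = FALSE)
    }))
  })
  calls <- simulate_binding(peptides, all_alleles, planted = planted,
                            seed = seed + 3L,
                            binder_rank = cfg$binder_rank,
                            strong_rank = cfg$strong_rank)
  # NetMHCpan-style table: one row per (peptide, allele), best rank at the
  # peptide level regenerated so the file is parseable by the adapter
  pred <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    peps <- peptides$mut_peptide[peptides$mutation_id == calls$mutation_id[i]]
    data.frame(Peptide = peps[1], MHC = paste0("HLA-", calls$allele[i]),
               `%Rank` = calls$rank[i], check.names = FALSE,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(pred, file.path(dir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tsv(calls, file.path(dir, "binding_calls.tsv"))

  # discovery cohort
  disc_spec <- simulation_spec(n_patients = n_discovery, spectrum = spectrum,
                               seed = seed + 4L)
  disc <- simulate_cohort(disc_spec)
  write_maf(disc$variants, file.path(dir, "discovery_maf.tsv"))
  write_tsv(default_gene_annotations(spectrum),
            file.path(dir, "gene_annotations.tsv"))

  # validation cohort with genotypes from the first population's table
  val_tab <- tables[tables$population == populations[1], , drop = FALSE]
  val_spec <- simulation_spec(n_patients = n_validation, spectrum = spectrum,
                              genotype_table = val_tab, seed = seed + 5L)
  val <- simulate_cohort(val_spec)
  write_patients(val$patients, file.path(dir, "patients.tsv"))

  # ELISpot wells: mutation-bearing validation patients, truly reactive
  # with probability 0.15
  wells <- list()
  with_mut <- Filter(function(p) length(p$mutations) > 0, val$patients)
  tested <- utils::head(with_mut, 7L)
  wi <- 0L
  for (p in tested) {
    for (mid in p$mutations) {
      wi <- wi + 1L
      reactive <- with_seed(seed + 6L + wi, stats::runif(1) < 0.15)
      counts <- simulate_elispot(reactive, seed = seed + 600L + wi)
      wells[[wi]] <- data.frame(patient_id = p$patient_id, mutation_id = mid,
                                mut_spots = counts$mut_spots,
                                wt_spots = counts$wt_spots,
                                truly_reactive = reactive,
                                stringsAsFactors = FALSE)
    }
  }
  elispot <- if (length(wells)) do.call(rbind, wells) else
    data.frame(patient_id = character(), mutation_id = character(),
               mut_spots = integer(), wt_spots = integer(),
               truly_reactive = logical(), stringsAsFactors = FALSE)
  write_tsv(elispot, file.path(dir, "elispot.tsv"))

  cfg$n_discovery <- n_discovery
  cfg$n_validation <- n_validation
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  truth <- list(
    planted_binders = planted,
    discovery_carriage = disc$truth$carriage,
    validation_msi_h = val$truth$msi_h,
    elispot_truth = elispot[, c("patient_id", "mutation_id",
                                "truly_reactive")],
    spectrum = spectrum
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

#' Run the full panel-construction and cohort-validation pipeline
#'
#' Reads an input directory (as produced by [simulate_inputs()], or
#' assembled from real files in the same formats), executes every stage —
#' recurrent-mutation catalog, cumulative coverage, co-mutation screen,
#' population allele-set selection, epitope enumeration, binder
#' classification, panel assembly, patient-level coverage, MSI association,
#' frequency correlation, ELISpot reactivity — and writes deterministic
#' TSV outputs plus a JSON report to `out_dir`.
#'
#' @param in_dir Input directory.
#' @param out_dir Output directory (created if absent).
#' @param config Run configuration; defaults to `config.json` in `in_dir`
#'   when present, else [default_config()].
#' @return A list of stage results, invisibly (`catalog`, `screen`,
#'   `allele_sets`, `panel`, `coverage`, `report`, ...).
#' @export
run_pipeline <- function(in_dir, out_dir, config = NULL) {
  if (is.null(config)) {
    cfg_path <- file.path(in_dir, "config.json")
    config <- if (file.exists(cfg_path)) {
      jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    } else default_config()
  }
  cfg <- .validate_config(config)
  if (is.numeric(cfg$peptide_lengths)) {
    cfg$peptide_lengths <- as.integer(cfg$peptide_lengths)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(out_dir, f)

  # --- catalog ---------------------------------------------------------
  variants <- read_maf(file.path(in_dir, "discovery_maf.tsv"), "tcga")
  ann <- read_tsv(file.path(in_dir, "gene_annotations.tsv"))
  cohort_size <- cfg$n_discovery %||% length(unique(variants$sample_id))
  catalog <- build_catalog(variants, ann, cohort_size,
                           min_recurrence = cfg$min_recurrence,
                           min_vaf = cfg$min_vaf)
  write_tsv(as.data.frame(catalog), outfile("catalog.tsv"))
  pm <- patient_mutation_map(variants)
  # patients without any retained variant are absent from the MAF but still
  # belong in coverage and contingency denominators
  n_absent <- cohort_size - length(pm)
  if (n_absent > 0) {
    empty <- stats::setNames(rep(list(character()), n_absent),
                             sprintf("UNMUTATED%04d", seq_len(n_absent)))
    pm <- c(pm, empty)
  }
  curve <- cumulative_coverage(catalog, pm)
  write_tsv(curve, outfile("coverage_curve.tsv"))
  onco <- oncoplot_matrix(pm, catalog)
  write_tsv(cbind(data.frame(mutation_id = rownames(onco),
                             stringsAsFactors = FALSE),
                  as.data.frame(onco)), outfile("oncoplot_matrix.tsv"))

  # --- co-mutation screen ----------------------------------------------
  screen <- comutation_screen(catalog, pm, fdr_threshold = cfg$fdr_threshold)
  write_tsv(as.data.frame(screen), outfile("comutation.tsv"))
  cm <- comutation_matrix(screen)
  write_tsv(cbind(data.frame(mutation_id = rownames(cm),
                             stringsAsFactors = FALSE), as.data.frame(cm)),
            outfile("comutation_matrix.tsv"))

  # --- HLA population tables and allele sets ---------------------------
  rows <- read_allele_frequencies(file.path(in_dir, "hla_frequencies.tsv"))
  tables <- aggregate_population(rows)
  write_tsv(as.data.frame(tables), outfile("population_frequencies.tsv"))
  populations <- unique(tables$population)
  sets <- lapply(populations, function(p)
    select_allele_set(tables, target = cfg$target_hla_coverage,
                      model = cfg$coverage_model, population = p))
  names(sets) <- populations
  for (p in populations) {
    write_tsv(sets[[p]]$alleles, outfile(paste0("allele_set_", p, ".tsv")))
  }

  # --- epitopes + binding ----------------------------------------------
  proteins <- read_proteins_fasta(file.path(in_dir, "proteins.fasta"))
  tails_df <- read_tsv(file.path(in_dir, "frameshift_tails.tsv"))
  tails <- stats::setNames(tails_df$tail, tails_df$mutation_id)
  peptides <- do.call(rbind, lapply(seq_len(nrow(catalog)), function(i) {
    mid <- catalog$mutation_id[i]
    g <- catalog$gene[i]
    if (!g %in% names(proteins)) return(NULL)
    mutation_peptides(proteins[[g]], catalog$protein_change[i],
                      frameshift_tail = if (mid %in% names(tails))
                        tails[[mid]] else NULL,
                      lengths = cfg$peptide_lengths, mutation_id = mid)
  }))
  write_tsv(peptides, outfile("peptides.tsv"))
  preds <- parse_predictor_output(file.path(in_dir, "predictions.tsv"))
  # join predictions to mutations through the peptide sequence
  idx <- match(preds$peptide, peptides$mut_peptide)
  calls <- data.frame(mutation_id = peptides$mutation_id[idx],
                      allele = preds$allele, rank = preds$rank,
                      stringsAsFactors = FALSE)
  calls <- calls[!is.na(calls$mutation_id), , drop = FALSE]
  calls$class <- classify_binder(calls$rank, cfg$strong_rank, cfg$binder_rank)
  write_tsv(calls, outfile("binding_calls.tsv"))

  # --- panel ------------------------------------------------------------
  tab_list <- split(as.data.frame(tables), tables$population)
  panel <- build_panel(catalog, calls, tab_list, mode = cfg$panel_mode,
                       binder_rank = cfg$binder_rank,
                       strong_rank = cfg$strong_rank,
                       min_panel_freq = cfg$min_panel_freq)
  write_tsv(as.data.frame(panel), outfile("panel.tsv"))
  write_tsv(panel_long_table(panel), outfile("panel_long.tsv"))

  # --- cohort validation -----------------------------------------------
  patients <- read_patients(file.path(in_dir, "patients.tsv"))
  coverage <- cohort_coverage(patients, panel)
  write_tsv(coverage$pairs, outfile("cohort_pairs.tsv"))
  write_tsv(data.frame(patient_id = names(coverage$covered),
                       covered = unname(coverage$covered),
                       stringsAsFactors = FALSE),
            outfile("cohort_coverage.tsv"))
  heat <- pair_heatmap_table(patients, panel)
  write_tsv(heat, outfile("pair_heatmap.tsv"))
  msi <- tryCatch(msi_panel_association(patients, panel),
                  error = function(e) NULL)

  # frequency vs neoantigen-frequency correlation per population
  cors <- list()
  for (p in populations) {
    col <- paste0("neo_freq_", p)
    ok <- !is.na(panel[[col]])
    if (sum(ok) >= 3) {
      ct <- spearman_correlation(panel$frequency[ok], panel[[col]][ok])
      cors[[p]] <- data.frame(population = p, rho = ct$rho,
                              p_value = ct$p_value, n = ct$n,
                              stringsAsFactors = FALSE)
    }
  }
  cors <- if (length(cors)) do.call(rbind, cors) else
    data.frame(population = character(), rho = numeric(),
               p_value = numeric(), n = integer(), stringsAsFactors = FALSE)
  write_tsv(cors, outfile("correlations.tsv"))

  # --- ELISpot reactivity ----------------------------------------------
  eli_path <- file.path(in_dir, "elispot.tsv")
  reactivity <- NULL
  if (file.exists(eli_path)) {
    eli <- read_tsv(eli_path)
    if (nrow(eli)) {
      res <- lapply(seq_len(nrow(eli)), function(i)
        elispot_reactivity(eli$mut_spots[i], eli$wt_spots[i],
                           min_spots = cfg$elispot_min_spots,
                           fold_threshold = cfg$elispot_fold))
      reactivity <- cbind(eli[, c("patient_id", "mutation_id",
                                  "mut_spots", "wt_spots")],
                          fold_change = vapply(res, `[[`, numeric(1),
                                               "fold_change"),
                          reactive = vapply(res, `[[`, logical(1),
                                            "reactive"))
      write_tsv(reactivity, outfile("reactivity.tsv"))
    }
  }

  # --- report -----------------------------------------------------------
  summaries <- list(
    cohort_size = cohort_size,
    catalog_size = nrow(catalog),
    catalog_cumulative_coverage =
      if (nrow(curve)) curve$covered_fraction[nrow(curve)] else 0,
    n_pairs_tested = nrow(screen),
    n_significant_pairs = sum(screen$significant),
    panel_size = nrow(panel),
    population_coverage = lapply(sets, function(s) s$coverage),
    n_validation_patients = coverage$n_patients,
    cohort_coverage_fraction = coverage$fraction,
    msi_association_p = if (is.null(msi)) NA else msi$p_value,
    n_reactive_wells = if (is.null(reactivity)) 0L
                       else sum(reactivity$reactive)
  )
  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  report <- emit_report(cfg, summaries, files, outfile("report.json"))
  invisible(list(catalog = catalog, curve = curve, screen = screen,
                 tables = tables, allele_sets = sets, peptides = peptides,
                 calls = calls, panel = panel, patients = patients,
                 coverage = coverage, msi = msi, correlations = cors,
                 reactivity = reactivity, report = report, config = cfg))
}
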