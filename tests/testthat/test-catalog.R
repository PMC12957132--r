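make_variants <- function(sample_id, gene, protein_change, consequence,
                          vaf = NA_real_) {
  data.frame(sample_id = sample_id, gene = gene,
             protein_change = protein_change, consequence = consequence,
             vaf = vaf, mutation_id = paste0(gene, "_", protein_change),
             stringsAsFactors = FALSE)
}

ann_all <- function(genes) data.frame(gene = genes, role = "oncogene",
                                      hallmark = TRUE,
                                      stringsAsFactors = FALSE)

test_that("catalog applies recurrence, VAF and gene filters in order", {
  v <- rbind(
    make_variants(c("p1", "p2", "p3"), "KRAS", "G12D", "missense", 0.3),
    make_variants("p4", "KRAS", "G12V", "missense", 0.3),      # singleton
    make_variants(c("p5", "p6"), "TP53", "R175H", "missense", 0.01), # low VAF
    make_variants(c("p7", "p8"), "NOCGC", "A5V", "missense", 0.3),   # no hallmark
    make_variants(c("p1", "p2"), "KRAS", "A59T", "other", 0.3)       # synonymous-ish
  )
  cat <- build_catalog(v, ann_all(c("KRAS", "TP53")), cohort_size = 10)
  expect_equal(cat$mutation_id, "KRAS_G12D")
  expect_equal(cat$n_samples, 3L)
  expect_equal(cat$frequency, 0.3)
  expect_equal(cat$gene_role, "oncogene")
})

test_that("a multi-row patient counts once and errors are raised for bad args", {
  v <- make_variants(c("p1", "p1", "p2"), "KRAS", "G12D", "missense", 0.3)
  cat <- build_catalog(v, ann_all("KRAS"), cohort_size = 5)
  expect_equal(cat$n_samples, 2L)
  expect_error(build_catalog(v, ann_all("KRAS"), cohort_size = 0),
               "cohort_size")
  expect_error(build_catalog(v, ann_all("KRAS")[0, ], cohort_size = 5),
               "annotation")
  expect_error(build_catalog(v, ann_all("KRAS"), cohort_size = 5,
                             min_recurrence = 1), "min_recurrence")
  expect_error(build_catalog(v, ann_all("KRAS"), cohort_size = 1),
               "smaller")
})

test_that("randomized catalogs equal the brute-force set-comprehension oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n_pat <- sample(10:200, 1)
    n_mut <- sample(5:50, 1)
    genes <- paste0("G", seq_len(n_mut))
    rows <- list()
    for (j in seq_len(n_mut)) {
      carriers <- sample(n_pat, rbinom(1, n_pat, runif(1, 0.01, 0.15)))
      if (!length(carriers)) next
      rows[[length(rows) + 1L]] <- make_variants(
        sprintf("p%03d", carriers), genes[j], "A10V", "missense",
        round(runif(length(carriers), 0, 0.6), 3))
    }
    if (!length(rows)) next
    v <- do.call(rbind, rows)
    hall <- sample(genes, ceiling(n_mut * 0.8))
    got <- build_catalog(v, ann_all(hall), cohort_size = n_pat)
    want <- oracle_catalog(v, hall, n_pat)
    expect_equal(got$mutation_id, want$mutation_id)
    expect_equal(got$n_samples, want$n_samples)
    expect_equal(got$frequency, want$frequency)
  }
})

test_that("cumulative coverage matches hand counts and union oracle, and is monotone", {
  pm <- list(p1 = "m1", p2 = c("m1", "m2"), p3 = "m2")
  cat <- data.frame(mutation_id = c("m1", "m2"))
  curve <- cumulative_coverage(cat, pm)
  expect_equal(curve$covered_fraction, c(2 / 3, 1))
  expect_error(cumulative_coverage(cat, list()), "empty")

  set.seed(7)
  for (rep in 1:10) {
    ids <- paste0("m", 1:12)
    pm <- replicate(60, sample(ids, rpois(1, 2), replace = FALSE),
                    simplify = FALSE)
    names(pm) <- paste0("p", seq_along(pm))
    curve <- cumulative_coverage(data.frame(mutation_id = ids), pm)
    expect_equal(curve$covered_fraction, oracle_coverage_curve(ids, pm))
    expect_true(all(diff(curve$covered_fraction) >= 0))
  }
})

test_that("final curve point equals the fraction of patients with any catalog mutation", {
  set.seed(8)
  ids <- paste0("m", 1:8)
  pm <- replicate(40, sample(ids, rbinom(1, 3, 0.5)), simplify = FALSE)
  names(pm) <- paste0("p", seq_along(pm))
  curve <- cumulative_coverage(data.frame(mutation_id = ids), pm)
  any_frac <- mean(vapply(pm, function(m) length(m) > 0, logical(1)))
  expect_equal(curve$covered_fraction[length(ids)], any_frac)
  # conservation against the pair-rule coverage when every allele matches
  alleles <- c("A*11:01")
  patients <- lapply(names(pm), function(p)
    make_patient(p, pm[[p]], alleles))
  panel <- toy_panel(ids, setNames(rep(list(alleles), length(ids)), ids))
  rep_cov <- cohort_coverage(patients, panel)
  expect_equal(rep_cov$fraction, curve$covered_fraction[length(ids)])
})

test_that("estimated catalog frequencies recover planted carrier probabilities", {
  spec <- simulation_spec(n_patients = 2000, seed = 303)
  sim <- simulate_cohort(spec)
  cat <- build_catalog(sim$variants,
                       default_gene_annotations(spec$spectrum),
                       cohort_size = 2000, min_vaf = 0)
  misses <- 0L
  for (i in seq_len(nrow(cat))) {
    p <- spec$spectrum$carrier_prob[
      spec$spectrum$mutation_id == cat$mutation_id[i]]
    ci <- binom_ci99(cat$n_samples[i], 2000)
    if (p < ci[1] || p > ci[2]) misses <- misses + 1L
  }
  # with m simultaneous 99% intervals a few misses are expected by design;
  # bound the count at its 99.9% binomial quantile
  expect_lte(misses, qbinom(0.999, nrow(cat), 0.01))
})
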