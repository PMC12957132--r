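pop_tab <- function(pop = "Asian", alleles = c("A*11:01", "A*24:02",
                                               "B*07:02", "C*07:02"),
                    freqs = c(0.2, 0.1, 0.12, 0.15)) {
  data.frame(population = pop, locus = allele_locus(alleles),
             allele = alleles, frequency = freqs, n_eff = 500,
             stringsAsFactors = FALSE)
}

test_that("neoantigen frequency is the mean of mutation-allele frequency products", {
  tab <- pop_tab()
  expect_equal(neoantigen_frequency(0.06, c("A*11:01", "A*24:02"), tab),
               0.009)
  expect_equal(neoantigen_frequency(0.05, "B*07:02", tab), 0.05 * 0.12)
  expect_error(neoantigen_frequency(0.05, character(), tab), "empty")
  expect_message(
    v <- neoantigen_frequency(0.1, c("A*11:01", "A*99:01"), tab),
    "missing")
  expect_equal(v, (0.1 * 0.2 + 0) / 2)
})

test_that("fuzzed neoantigen frequencies equal the independent mean-of-products oracle", {
  set.seed(20)
  tab <- simulate_allele_table(seed = 55)
  for (rep in 1:200) {
    mf <- runif(1)
    alleles <- sample(tab$allele, sample(1:8, 1))
    freqs <- tab$frequency[match(alleles, tab$allele)]
    expect_equal(neoantigen_frequency(mf, alleles, tab),
                 oracle_neofreq(mf, freqs), tolerance = 1e-12)
    # linearity in mutation frequency and the product upper bound
    expect_equal(neoantigen_frequency(2 * mf, alleles, tab),
                 2 * neoantigen_frequency(mf, alleles, tab),
                 tolerance = 1e-12)
    expect_lte(neoantigen_frequency(mf, alleles, tab),
               mf * max(freqs) + 1e-15)
  }
})

make_catalog <- function(ids, freqs) {
  out <- data.frame(mutation_id = ids, gene = sub("_.*", "", ids),
                    protein_change = sub(".*_", "", ids),
                    consequence = "missense",
                    n_samples = pmax(2L, round(freqs * 100)),
                    frequency = freqs, gene_role = "oncogene",
                    impact = "moderate", stringsAsFactors = FALSE)
  class(out) <- c("neo_catalog", class(out))
  out
}

test_that("panel keeps mutations with binders and drops rank-only-above-threshold ones", {
  cat <- make_catalog(c("KRAS_G12D", "TP53_R175H", "APC_R1450X"),
                      c(0.06, 0.04, 0.02))
  calls <- data.frame(
    mutation_id = c("KRAS_G12D", "KRAS_G12D", "TP53_R175H", "APC_R1450X"),
    allele = c("A*11:01", "B*07:02", "A*24:02", "C*07:02"),
    rank = c(0.3, 1.5, 3.0, 1.9), stringsAsFactors = FALSE)
  panel <- build_panel(cat, calls, list(Asian = pop_tab()))
  expect_setequal(panel$mutation_id, c("KRAS_G12D", "APC_R1450X"))
  k <- panel[panel$mutation_id == "KRAS_G12D", ]
  expect_equal(k$n, 2)
  expect_equal(c(k$count_A, k$count_B, k$count_C), c(1, 1, 0))
  expect_equal(k$neo_freq_Asian, (0.06 * 0.2 + 0.06 * 0.12) / 2)
})

test_that("extended mode admits recurrent strong binders missing from a population set", {
  cat <- make_catalog(c("KRAS_G12D", "BRAF_V600E"), c(0.06, 0.012))
  # BRAF's only binder allele is absent from the population table
  calls <- data.frame(mutation_id = c("KRAS_G12D", "BRAF_V600E"),
                      allele = c("A*11:01", "B*57:01"),
                      rank = c(0.3, 0.2), stringsAsFactors = FALSE)
  p_any <- build_panel(cat, calls, list(Asian = pop_tab()))
  expect_equal(p_any$mutation_id, "KRAS_G12D")
  p_ext <- build_panel(cat, calls, list(Asian = pop_tab()),
                       mode = "extended")
  expect_setequal(p_ext$mutation_id, c("KRAS_G12D", "BRAF_V600E"))
  expect_true(p_ext$extended_only[p_ext$mutation_id == "BRAF_V600E"])
  # below the recurrence floor the extended rule does not apply
  cat2 <- make_catalog(c("KRAS_G12D", "BRAF_V600E"), c(0.06, 0.008))
  p_ext2 <- build_panel(cat2, calls, list(Asian = pop_tab()),
                        mode = "extended")
  expect_equal(p_ext2$mutation_id, "KRAS_G12D")
})

test_that("panel membership is monotone: adding a binder never removes a mutation", {
  cat <- make_catalog(c("KRAS_G12D", "TP53_R175H"), c(0.06, 0.04))
  calls <- data.frame(mutation_id = "KRAS_G12D", allele = "A*11:01",
                      rank = 0.3, stringsAsFactors = FALSE)
  p1 <- build_panel(cat, calls, list(Asian = pop_tab()))
  calls2 <- rbind(calls, data.frame(mutation_id = "TP53_R175H",
                                    allele = "A*24:02", rank = 1.0))
  p2 <- build_panel(cat, calls2, list(Asian = pop_tab()))
  expect_true(all(p1$mutation_id %in% p2$mutation_id))
})

test_that("per-locus counts partition the number of binding alleles", {
  expect_equal(per_locus_counts(c("A*11:01", "A*24:02", "B*40:01")),
               c(A = 2L, B = 1L, C = 0L))
  expect_equal(sum(per_locus_counts(character())), 0L)
  set.seed(30)
  for (rep in 1:20) {
    alleles <- sprintf("%s*%02d:01",
                       sample(c("A", "B", "C"), sample(1:12, 1),
                              replace = TRUE), sample(1:20, 12)[1])
    counts <- per_locus_counts(alleles)
    expect_equal(sum(counts), length(alleles))
  }
})

test_that("planted binder recovery: the panel equals the planted mutation set", {
  set.seed(40)
  n_mut <- 20
  ids <- sprintf("GENE%02d_A50V", 1:n_mut)
  cat <- make_catalog(ids, round(runif(n_mut, 0.02, 0.2), 3))
  tab <- simulate_allele_table(seed = 61)
  planted_ids <- sort(sample(ids, 12))
  planted <- do.call(rbind, lapply(planted_ids, function(m)
    data.frame(mutation_id = m, allele = sample(tab$allele, 2),
               stringsAsFactors = FALSE)))
  peptides <- data.frame(
    mutation_id = rep(ids, each = 3),
    mut_peptide = replicate(3 * n_mut, paste(sample(strsplit(
      "ACDEFGHIKLMNPQRSTVWY", "")[[1]], 9, replace = TRUE), collapse = "")),
    stringsAsFactors = FALSE)
  calls <- simulate_binding(peptides, tab$allele, planted = planted,
                            seed = 71)
  panel <- build_panel(cat, calls, list(Sim = tab))
  expect_setequal(panel$mutation_id, planted_ids)
  # the strong-binder set is exactly the planted pair set
  strong <- calls[calls$rank < 0.5, c("mutation_id", "allele")]
  expect_setequal(paste(strong$mutation_id, strong$allele),
                  paste(planted$mutation_id, planted$allele))
})

test_that("mutation and neoantigen frequency correlate positively under independent binding", {
  set.seed(50)
  tab <- simulate_allele_table(seed = 81)
  n_mut <- 30
  ids <- sprintf("G%02d_A10V", 1:n_mut)
  freqs <- sort(runif(n_mut, 0.01, 0.3), decreasing = TRUE)
  cat <- make_catalog(ids, freqs)
  calls <- do.call(rbind, lapply(ids, function(m) {
    k <- sample(2:6, 1)
    data.frame(mutation_id = m, allele = sample(tab$allele, k),
               rank = runif(k, 0.1, 1.9), stringsAsFactors = FALSE)
  }))
  panel <- build_panel(cat, calls, list(Sim = tab))
  ct <- spearman_correlation(panel$frequency, panel$neo_freq_Sim)
  expect_gt(ct$rho, 0)
})
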