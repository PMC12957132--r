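test_that("a patient is covered only through a matched mutation-HLA pair", {
  panel <- toy_panel("KRAS_G12D",
                     list(KRAS_G12D = c("A*11:01", "B*07:02")))
  covered <- make_patient("p1", "KRAS_G12D",
                          c("A*11:01", "A*24:02", "C*07:02"))
  pairs <- patient_covered(covered, panel)
  expect_equal(pairs$allele, "A*11:01")

  # mutation without a binding allele in the genotype: not covered
  no_allele <- make_patient("p2", "KRAS_G12D", c("A*02:01", "B*08:01"))
  expect_equal(nrow(patient_covered(no_allele, panel)), 0)

  # binding allele without the mutation: not covered
  no_mut <- make_patient("p3", character(), "A*11:01")
  expect_equal(nrow(patient_covered(no_mut, panel)), 0)

  expect_message(
    empty <- patient_covered(make_patient("p4", "KRAS_G12D"), panel),
    "empty HLA genotype")
  expect_equal(nrow(empty), 0)
})

test_that("cohort coverage counts patients with any pair and matches the triple-loop oracle", {
  binding <- list(m1 = c("A*11:01"), m2 = c("B*07:02", "C*07:02"))
  panel <- toy_panel(c("m1", "m2"), binding)
  patients <- list(
    make_patient("p1", "m1", "A*11:01"),
    make_patient("p2", "m2", "B*07:02"),
    make_patient("p3", "m1", "B*07:02"))
  rep <- cohort_coverage(patients, panel)
  expect_equal(rep$n_covered, 2)
  expect_equal(rep$fraction, 2 / 3)
  expect_error(cohort_coverage(list(), panel), "empty")

  set.seed(60)
  alleles <- sprintf("%s*%02d:01", rep(c("A", "B", "C"), each = 6), 1:6)
  for (trial in 1:25) {
    ids <- sprintf("m%02d", 1:sample(3:12, 1))
    binding <- setNames(lapply(ids, function(i)
      sample(alleles, sample(1:4, 1))), ids)
    panel <- toy_panel(ids, binding)
    patients <- lapply(1:sample(10:100, 1), function(i)
      make_patient(paste0("p", i),
                   mutations = ids[runif(length(ids)) < 0.2],
                   hla_genotype = rand_genotype(alleles)))
    rep <- cohort_coverage(patients, panel)
    expect_equal(rep$fraction,
                 oracle_cohort_coverage(patients, ids, binding))
  }
})

test_that("coverage never decreases when a mutation or allele joins the panel", {
  set.seed(61)
  alleles <- sprintf("A*%02d:01", 1:8)
  patients <- lapply(1:50, function(i)
    make_patient(paste0("p", i), mutations = c("m1", "m2")[runif(2) < 0.4],
                 hla_genotype = sample(alleles, 2)))
  p_small <- toy_panel("m1", list(m1 = alleles[1]))
  p_more_alleles <- toy_panel("m1", list(m1 = alleles[1:3]))
  p_more_muts <- toy_panel(c("m1", "m2"),
                           list(m1 = alleles[1], m2 = alleles[4]))
  base <- cohort_coverage(patients, p_small)$fraction
  expect_gte(cohort_coverage(patients, p_more_alleles)$fraction, base)
  expect_gte(cohort_coverage(patients, p_more_muts)$fraction, base)
})

test_that("MSI classification follows the two-marker rule", {
  expect_equal(msi_classify(c(TRUE, TRUE, FALSE, FALSE, FALSE)), "MSI-H")
  expect_equal(msi_classify(c(TRUE, FALSE, FALSE, FALSE, FALSE)), "MSS")
  expect_equal(msi_classify(rep(FALSE, 5)), "MSS")
  expect_equal(msi_classify(rep(TRUE, 5)), "MSI-H")
  expect_error(msi_classify(c(TRUE, FALSE)), "5")
})

test_that("MSI-panel association builds the right table and uses the exact test", {
  panel <- toy_panel("m1", list(m1 = "A*01:01"))
  mk <- function(id, msi_h, has_mut) {
    make_patient(id, if (has_mut) "m1" else character(), "A*01:01",
                 msi_markers = c(rep(TRUE, if (msi_h) 3 else 0),
                                 rep(FALSE, if (msi_h) 2 else 5)))
  }
  # constructed 2x2 (3,7,5,52)
  patients <- c(lapply(1:3, function(i) mk(paste0("a", i), TRUE, TRUE)),
                lapply(1:7, function(i) mk(paste0("b", i), TRUE, FALSE)),
                lapply(1:5, function(i) mk(paste0("c", i), FALSE, TRUE)),
                lapply(1:52, function(i) mk(paste0("d", i), FALSE, FALSE)))
  res <- msi_panel_association(patients, panel)
  expect_equal(unname(res$table), c(3, 7, 5, 52))
  expect_equal(res$p_value, oracle_fisher_p(3, 7, 5, 52), tolerance = 1e-12)

  # perfectly balanced table gives p = 1
  bal <- c(lapply(1:2, function(i) mk(paste0("e", i), TRUE, TRUE)),
           lapply(1:2, function(i) mk(paste0("f", i), TRUE, FALSE)),
           lapply(1:2, function(i) mk(paste0("g", i), FALSE, TRUE)),
           lapply(1:2, function(i) mk(paste0("h", i), FALSE, FALSE)))
  expect_equal(msi_panel_association(bal, panel)$p_value, 1)

  all_mss <- lapply(1:5, function(i) mk(paste0("i", i), FALSE, TRUE))
  expect_error(msi_panel_association(all_mss, panel), "degenerate")
})

test_that("Spearman correlation handles monotone, tied and degenerate inputs", {
  x <- 1:10
  expect_equal(spearman_correlation(x, x + 3)$rho, 1)
  expect_equal(spearman_correlation(x, -2 * x)$rho, -1)
  expect_error(spearman_correlation(x, rep(1, 10)), "constant")
  expect_error(spearman_correlation(1:3, 1:4), "equal length")

  set.seed(70)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- sample(1:8, n, replace = TRUE) + 0.1 * x
    if (sd(x) == 0 || sd(y) == 0) next
    got <- spearman_correlation(x, y)
    expect_equal(got$rho, oracle_spearman(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("ELISpot reactivity uses fold > 2 with a spot floor and zero-well pseudocount", {
  r <- elispot_reactivity(50, 20)
  expect_equal(r$fold_change, 2.5)
  expect_true(r$reactive)
  r <- elispot_reactivity(30, 20)
  expect_equal(r$fold_change, 1.5)
  expect_false(r$reactive)
  r <- elispot_reactivity(40, 0)
  expect_equal(r$fold_change, 41)
  expect_true(r$reactive)
  # floor: a 9-spot well is never called reactive
  expect_false(elispot_reactivity(9, 1)$reactive)
  expect_error(elispot_reactivity(-1, 5), ">= 0")
})

test_that("null MSI association p-values are approximately uniform", {
  set.seed(71)
  panel <- toy_panel("m1", list(m1 = "A*01:01"))
  pvals <- replicate(200, {
    msi_h <- runif(40) < 0.3
    has <- runif(40) < 0.4
    patients <- lapply(1:40, function(i)
      make_patient(paste0("p", i), if (has[i]) "m1" else character(),
                   "A*01:01",
                   msi_markers = c(rep(TRUE, if (msi_h[i]) 2 else 0),
                                   rep(FALSE, if (msi_h[i]) 3 else 5))))
    tryCatch(msi_panel_association(patients, panel)$p_value,
             error = function(e) NA_real_)
  })
  pvals <- pvals[!is.na(pvals)]
  # exact-test p-values are super-uniform: P(p <= t) <= t under the null
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pvals <= t), t + 3 * sqrt(t * (1 - t) / length(pvals)))
  }
})
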