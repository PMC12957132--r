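# Independent brute-force oracles. These deliberately re-derive results by
# direct definition (set comprehension, exhaustive enumeration, explicit
# loops) and stay separate from the package's code paths.

# Exact two-sided Fisher p-value by full hypergeometric enumeration using
# integer-valued binomial coefficients (exact in doubles for totals <= 40;
# tie comparison is on integer numerators, so no floating-point tolerance).
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  m1 <- a + b
  k1 <- a + c
  lo <- max(0, k1 - (n - m1))
  hi <- min(m1, k1)
  avals <- lo:hi
  num <- choose(m1, avals) * choose(n - m1, k1 - avals)  # common denom choose(n, k1)
  obs <- num[avals == a]
  sum(num[num <= obs]) / choose(n, k1)
}

# Literal quadratic-time Benjamini-Hochberg definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    mins <- Inf
    for (j in i:m) {
      cand <- m / j * p[ord[j]]
      if (cand < mins) mins <- cand
    }
    q[ord[i]] <- min(1, mins)
  }
  q
}

# Direct set-comprehension catalog: filter rows, group, count distinct
# patients, threshold.
oracle_catalog <- function(variants, hallmark_genes, cohort_size,
                           min_recurrence = 2, min_vaf = 0.02) {
  keep <- (is.na(variants$vaf) | variants$vaf >= min_vaf) &
    variants$gene %in% hallmark_genes &
    variants$consequence %in% c("missense", "nonsense", "frameshift")
  v <- variants[keep, , drop = FALSE]
  ids <- unique(v$mutation_id)
  res <- lapply(ids, function(id) {
    n <- length(unique(v$sample_id[v$mutation_id == id]))
    if (n >= min_recurrence) data.frame(mutation_id = id, n_samples = n,
                                        frequency = n / cohort_size,
                                        stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(mutation_id = character(),
                                      n_samples = integer(),
                                      frequency = numeric()))
  out[order(-out$frequency, out$mutation_id), , drop = FALSE]
}

# Explicit union counting for the cumulative coverage curve.
oracle_coverage_curve <- function(ids, patient_mutations) {
  vapply(seq_along(ids), function(k) {
    hit <- vapply(patient_mutations,
                  function(m) length(intersect(ids[seq_len(k)], m)) > 0,
                  logical(1))
    mean(hit)
  }, numeric(1))
}

# Triple loop over patients x panel x alleles for cohort coverage.
oracle_cohort_coverage <- function(patients, panel_ids, binding_alleles) {
  covered <- 0L
  for (p in patients) {
    hit <- FALSE
    for (m in panel_ids) {
      if (!(m %in% p$mutations)) next
      for (a in binding_alleles[[m]]) {
        if (a %in% p$hla_genotype) hit <- TRUE
      }
    }
    if (hit) covered <- covered + 1L
  }
  covered / length(patients)
}

# Mid-rank Spearman by explicit rank-then-Pearson arithmetic.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Direct mean-of-products population neoantigen frequency.
oracle_neofreq <- function(mut_freq, allele_freqs) {
  total <- 0
  for (f in allele_freqs) total <- total + mut_freq * f
  total / length(allele_freqs)
}

# Analytic clipped window count: windows of length k inside [1, L]
# covering position p.
oracle_window_count <- function(L, p, k) {
  if (k > L) return(0L)
  max(0L, min(p, L - k + 1L) - max(1L, p - k + 1L) + 1L)
}

# Brute-force string scan: all k-windows of the mutant protein that differ
# from the same-coordinate wild-type window.
oracle_missense_windows <- function(wt, mut, k) {
  L <- nchar(mut)
  out <- character()
  for (s in seq_len(max(0L, L - k + 1L))) {
    mw <- substr(mut, s, s + k - 1L)
    ww <- substr(wt, s, s + k - 1L)
    if (mw != ww) out <- c(out, mw)
  }
  out
}

# Clopper-Pearson exact binomial interval.
binom_ci99 <- function(x, n) {
  lo <- if (x == 0) 0 else qbeta(0.005, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(0.995, x + 1, n - x)
  c(lo, hi)
}

# Small helper to build a minimal panel object for coverage tests without
# going through binding-call assembly.
toy_panel <- function(ids, binding_alleles, frequency = NULL) {
  out <- data.frame(mutation_id = ids, gene = sub("_.*", "", ids),
                    frequency = frequency %||% seq(0.5, 0.1,
                                                   length.out = length(ids)),
                    stringsAsFactors = FALSE)
  out$binding_alleles <- I(unname(binding_alleles[ids]))
  class(out) <- c("neo_panel", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Draw a valid diploid genotype (at most two alleles per locus) from a pool.
rand_genotype <- function(alleles, loci = c("A", "B", "C")) {
  by_locus <- split(alleles, sub("\\*.*$", "", alleles))
  unlist(lapply(loci, function(l) {
    pool <- by_locus[[l]]
    if (is.null(pool)) return(character())
    sample(pool, min(2, length(pool)))
  }), use.names = FALSE)
}
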