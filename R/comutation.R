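#' 2x2 contingency table for a mutation pair
#'
#' Cross-classifies every patient by carriage of two mutations.
#'
#' @param mutA,mutB Distinct mutation ids.
#' @param patient_mutations Named list: patient -> mutation-id vector.
#' @return Integer vector `c(a, b, c, d)`: both, A only, B only, neither;
#'   cells sum to the number of patients.
#' @examples
#' pm <- list(p1 = c("m1", "m2"), p2 = "m1", p3 = "m2", p4 = character())
#' contingency_table("m1", "m2", pm)  # 1 1 1 1
#' @export
contingency_table <- function(mutA, mutB, patient_mutations) {
  if (identical(mutA, mutB)) stop_arg("mutA and mutB must differ")
  hasA <- vapply(patient_mutations, function(m) mutA %in% m, logical(1))
  hasB <- vapply(patient_mutations, function(m) mutB %in% m, logical(1))
  c(a = sum(hasA & hasB), b = sum(hasA & !hasB),
    c = sum(!hasA & hasB), d = sum(!hasA & !hasB))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The p-value is the minimum-likelihood two-sided rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table (a relative
#' tolerance of 1e-7 absorbs floating-point ties, the convention used by
#' standard exact-test implementations). The odds ratio is the sample
#' cross-product `ad/bc`: `Inf` when `bc = 0` and `ad > 0`, `0` when
#' `ad = 0` and `bc > 0`, and `NaN` when both products vanish.
#'
#' @param a,b,c,d Non-negative integer cell counts (`a` = both present).
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact_two_sided(2, 0, 0, 2)  # OR = Inf, p = 1/3
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop_arg("cells must be non-negative integers")
  }
  n <- a + b + c + d
  if (n < 1) stop_arg("table total must be >= 1")
  ad <- a * d; bc <- b * c
  or <- if (bc == 0 && ad == 0) NaN else if (bc == 0) Inf else ad / bc
  m1 <- a + b           # margin: carriers of A
  k1 <- a + c           # margin: carriers of B
  lo <- max(0L, k1 - (n - m1))
  hi <- min(m1, k1)
  support <- lo:hi
  dens <- stats::dhyper(support, m1, n - m1, k1)
  obs <- dens[support == a]
  p <- sum(dens[dens <= obs * (1 + 1e-7)])
  list(odds_ratio = or, p_value = min(1, max(0, p)))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (a validated wrapper around
#' `stats::p.adjust(method = "BH")`): sort ascending, take
#' `q_(i) = min_{j >= i} (m/j) p_(j)`, clamp at 1, return in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_arg("p-values must lie in [0,1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Pairwise co-occurrence / mutual-exclusivity screen
#'
#' Runs the exact test over every unordered pair of catalog mutations (or
#' their genes), adjusts p-values jointly by Benjamini-Hochberg, and labels
#' each pair's direction: odds ratio above 1 indicates co-occurrence, below
#' 1 mutual exclusivity.
#'
#' @param catalog A `neo_catalog`, or a character vector of mutation ids.
#' @param patient_mutations Named list: patient -> mutation-id vector.
#' @param fdr_threshold Significance cut-off on adjusted p-values
#'   (default 0.05).
#' @param key `"mutation"` (default) screens mutation pairs; `"gene"`
#'   collapses mutation ids to genes first.
#' @return Data frame of class `comut_screen`, one row per unordered pair,
#'   with cells `a,b,c,d`, `odds_ratio`, `p_value`, `fdr`, `direction` and
#'   `significant`; sorted by `fdr` then `p_value`.
#' @export
comutation_screen <- function(catalog, patient_mutations,
                              fdr_threshold = 0.05,
                              key = c("mutation", "gene")) {
  key <- match.arg(key)
  ids <- if (is.character(catalog)) catalog else catalog$mutation_id
  pm <- patient_mutations
  if (key == "gene") {
    ids <- unique(sub("_.*$", "", ids))
    pm <- lapply(pm, function(m) unique(sub("_.*$", "", m)))
  }
  ids <- sort(unique(ids))
  if (length(ids) < 2) stop_arg("need >= 2 mutations to screen")
  # carriage matrix once, then cells by vector arithmetic per pair
  carriage <- vapply(pm, function(m) ids %in% m, logical(length(ids)))
  if (length(ids) == 1L) carriage <- matrix(carriage, nrow = 1)
  pairs <- utils::combn(seq_along(ids), 2)
  n <- ncol(carriage)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    a <- sum(carriage[i1, ] & carriage[i2, ])
    b <- sum(carriage[i1, ] & !carriage[i2, ])
    cc <- sum(!carriage[i1, ] & carriage[i2, ])
    d <- n - a - b - cc
    ft <- fisher_exact_two_sided(a, b, cc, d)
    data.frame(mut1 = ids[i1], mut2 = ids[i2], a = a, b = b, c = cc, d = d,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p_value)
  out$direction <- ifelse(is.nan(out$odds_ratio), "none",
                   ifelse(out$odds_ratio > 1, "co_occurring",
                   ifelse(out$odds_ratio < 1, "mutually_exclusive", "none")))
  out$significant <- out$fdr < fdr_threshold
  out <- out[order(out$fdr, out$p_value, out$mut1, out$mut2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("comut_screen", class(out))
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "key") <- key
  out
}

#' @export
print.comut_screen <- function(x, ...) {
  cat(sprintf("Co-mutation screen (%s pairs): %d tested, %d significant at FDR < %g\n",
              attr(x, "key"), nrow(x), sum(x$significant),
              attr(x, "fdr_threshold")))
  sig <- x[x$significant, , drop = FALSE]
  if (nrow(sig)) print.data.frame(utils::head(as.data.frame(sig), 10))
  invisible(x)
}

#' Triangular co-mutation matrix for heatmap export
#'
#' Square matrix keyed by mutation, with log-transformed odds ratios in the
#' upper triangle and FDR-adjusted p-values in the lower triangle. Infinite
#' log odds ratios are mapped to +/- (max finite |log OR| + 1) so plotting
#' files stay finite; the raw values remain in the screen table.
#'
#' @param screen A `comut_screen`.
#' @return Numeric matrix with NA diagonal.
#' @export
comutation_matrix <- function(screen) {
  ids <- sort(unique(c(screen$mut1, screen$mut2)))
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  lor <- log(screen$odds_ratio)
  finite <- lor[is.finite(lor)]
  cap <- if (length(finite)) max(abs(finite)) + 1 else 1
  lor[lor == Inf] <- cap
  lor[lor == -Inf] <- -cap
  lor[is.nan(lor)] <- 0
  for (r in seq_len(nrow(screen))) {
    i <- match(screen$mut1[r], ids); j <- match(screen$mut2[r], ids)
    lo <- min(i, j); hi <- max(i, j)
    m[lo, hi] <- lor[r]          # upper triangle: log OR
    m[hi, lo] <- screen$fdr[r]   # lower triangle: FDR
  }
  m
}
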