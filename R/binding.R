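#' Classify peptide-HLA binding from a percentile rank
#'
#' Percentile-rank thresholds are strict: ranks below `strong_rank`
#' (default 0.5) are strong binders, ranks below `binder_rank` (default 2)
#' are weak binders, and everything else — including ranks exactly at a
#' threshold — is a non-binder.
#'
#' @param rank Numeric vector of positive percentile ranks (% scale).
#' @param strong_rank Strong-binder threshold (default 0.5).
#' @param binder_rank Binder threshold (default 2); must exceed
#'   `strong_rank`.
#' @return Character vector in `c("non", "weak", "strong")`.
#' @examples
#' classify_binder(c(0.4, 1.9, 2.0))  # strong, weak, non
#' @export
classify_binder <- function(rank, strong_rank = 0.5, binder_rank = 2) {
  if (!(strong_rank > 0 && strong_rank < binder_rank)) {
    stop_arg("need 0 < strong_rank < binder_rank")
  }
  if (any(is.na(rank)) || any(rank <= 0)) {
    stop_arg("percentile ranks must be positive")
  }
  ifelse(rank < strong_rank, "strong",
         ifelse(rank < binder_rank, "weak", "non"))
}

# 31-bit multiplicative string hash (Lehmer multiplier), exact in doubles
.hash_mod <- 2147483647
.hash_string <- function(s, h0) {
  h <- h0 %% .hash_mod
  for (code in utf8ToInt(s)) {
    h <- (h * 48271 + code) %% .hash_mod
  }
  h
}

#' Deterministic synthetic percentile-rank predictor
#'
#' A stand-in predictor that makes every downstream stage testable without
#' an external binding-prediction tool. The rank is a pure hash of
#' (peptide, allele, seed), uniform on (0, 100]; it is position-agnostic
#' and encodes no binding motifs by design. Pairs listed in `planted`
#' (matched by `mutation_id` + allele) instead receive a deterministic rank
#' inside (0, `strong_rank`), providing recoverable ground truth.
#'
#' @param peptide Character vector of peptides.
#' @param allele Allele name(s), recycled against `peptide`.
#' @param seed Integer seed entering the hash.
#' @param mutation_id Optional mutation id(s) for planted matching.
#' @param planted Optional data frame with columns `mutation_id`, `allele`
#'   naming the planted binder pairs.
#' @param strong_rank Upper bound for planted ranks (default 0.5).
#' @param salt Extra integer mixed into the hash; used by the simulator to
#'   re-draw ranks.
#' @return Numeric vector of percentile ranks.
#' @export
synthetic_predict <- function(peptide, allele, seed, mutation_id = NULL,
                              planted = NULL, strong_rank = 0.5, salt = 0L) {
  n <- max(length(peptide), length(allele))
  peptide <- rep_len(peptide, n)
  allele <- rep_len(allele, n)
  bad <- !vapply(strsplit(peptide, ""), function(ch) all(ch %in% .AA),
                 logical(1))
  if (any(bad)) stop_arg("peptide(s) outside amino-acid alphabet")
  h0 <- (abs(as.numeric(seed)) + 1000003 * abs(as.numeric(salt)))
  is_planted <- rep(FALSE, n)
  if (!is.null(planted) && !is.null(mutation_id)) {
    mutation_id <- rep_len(mutation_id, n)
    key <- paste(mutation_id, normalize_allele(allele), sep = "|")
    pkey <- paste(planted$mutation_id, normalize_allele(planted$allele),
                  sep = "|")
    is_planted <- key %in% pkey
  }
  u <- vapply(seq_len(n), function(i) {
    h <- .hash_string(paste(peptide[i], allele[i], sep = "|"), h0)
    (h + 0.5) / .hash_mod
  }, numeric(1))
  rank <- u * 100
  rank[is_planted] <- u[is_planted] * strong_rank * 0.98 + 0.001
  rank
}

#' Multi-tool mutant vs wild-type concordance call
#'
#' A tool supports a neoepitope when the mean prediction score of the
#' mutant peptides strictly exceeds the mean score of the matched wild-type
#' peptides; equal means are negative. The pooling scope (which peptides'
#' scores enter each mean) is whatever the caller supplies per tool.
#'
#' @param tool_scores A list; each element a list with `tool` (label),
#'   `mut_scores` and `wt_scores` (non-empty numeric vectors).
#' @return List with `positive` (named logical per tool) and
#'   `supported_count`.
#' @examples
#' concordance_call(list(list(tool = "toolA",
#'                            mut_scores = c(0.6, 0.8),
#'                            wt_scores = c(0.5, 0.7))))
#' @export
concordance_call <- function(tool_scores) {
  if (!length(tool_scores)) stop_arg("no tool scores supplied")
  positive <- vapply(tool_scores, function(ts) {
    if (!length(ts$mut_scores) || !length(ts$wt_scores)) {
      stop_arg("tool '%s' has an empty score list", ts$tool %||% "?")
    }
    mean(ts$mut_scores) > mean(ts$wt_scores)
  }, logical(1))
  names(positive) <- vapply(tool_scores, function(ts)
    as.character(ts$tool %||% ""), character(1))
  list(positive = positive, supported_count = sum(positive))
}
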