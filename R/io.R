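#' Normalize HLA class I allele names
#'
#' Strips a leading `"HLA-"` prefix and truncates to two-field
#' (`LOCUS*GG:PP`) resolution; class I binding prediction operates at
#' two-field resolution, so higher typing resolution is collapsed before
#' aggregation.
#'
#' @param allele Character vector of allele names (e.g. `"HLA-A*11:01:01"`).
#' @return Character vector in `LOCUS*GG:PP` form (e.g. `"A*11:01"`).
#' @export
normalize_allele <- function(allele) {
  a <- sub("^HLA-", "", as.character(allele))
  bad <- !grepl("^[A-Z]+[0-9]*\\*[0-9]+(:[0-9]+)*$", a)
  if (any(bad)) {
    stop_arg("unparseable HLA allele name(s): %s",
             paste(utils::head(unique(a[bad]), 5), collapse = ", "))
  }
  locus <- sub("\\*.*$", "", a)
  fields <- sub("^[A-Z]+[0-9]*\\*", "", a)
  parts <- strsplit(fields, ":", fixed = TRUE)
  two <- vapply(parts, function(p) paste(p[seq_len(min(2L, length(p)))],
                                         collapse = ":"), character(1))
  paste0(locus, "*", two)
}

#' Locus of an HLA allele name
#' @param allele Character vector like `"A*11:01"`.
#' @return Character vector of loci (`"A"`, `"B"`, `"C"`).
#' @export
allele_locus <- function(allele) sub("\\*.*$", "", sub("^HLA-", "", allele))

.maf_class_map <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Frame_Shift_Del   = "frameshift",
  Frame_Shift_Ins   = "frameshift"
)

#' Read a somatic mutation table (MAF or simple TSV dialect)
#'
#' Two dialects are supported. `"tcga"` expects the standard MAF columns
#' `Hugo_Symbol`, `Tumor_Sample_Barcode`, `HGVSp_Short` and
#' `Variant_Classification` (an optional `t_alt_count`/`t_depth` pair or a
#' `VAF` column supplies variant allele frequencies). `"simple"` expects
#' `sample_id`, `gene`, `protein_change` and optionally `vaf`.
#'
#' Consequence classes are mapped from `Variant_Classification`
#' (`Missense_Mutation` -> missense, `Nonsense_Mutation` -> nonsense,
#' `Frame_Shift_Del`/`Frame_Shift_Ins` -> frameshift, anything else ->
#' other); in the simple dialect they are derived from the protein change.
#' Rows whose protein change cannot be parsed are retained with consequence
#' `other` and `flagged = TRUE`.
#'
#' @param path Path to the mutation table.
#' @param dialect `"tcga"` or `"simple"`.
#' @return A data frame of variant rows with columns `sample_id`, `gene`,
#'   `protein_change` (normalized where parseable), `consequence`, `vaf`
#'   (NA when absent), `impact` and `flagged`.
#' @export
read_maf <- function(path, dialect = c("tcga", "simple")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  if (nrow(df) == 0) {
    log_msg("warn", "empty mutation table: ", path)
    return(.empty_variants())
  }
  need <- if (dialect == "tcga") {
    c("Hugo_Symbol", "Tumor_Sample_Barcode", "HGVSp_Short",
      "Variant_Classification")
  } else c("sample_id", "gene", "protein_change")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_arg("mutation table %s lacks mandatory column(s): %s",
             path, paste(miss, collapse = ", "))
  }
  if (dialect == "tcga") {
    vaf <- rep(NA_real_, nrow(df))
    if (all(c("t_alt_count", "t_depth") %in% names(df))) {
      vaf <- suppressWarnings(as.numeric(df$t_alt_count) /
                                as.numeric(df$t_depth))
    } else if ("VAF" %in% names(df)) {
      vaf <- suppressWarnings(as.numeric(df$VAF))
    }
    cons <- unname(.maf_class_map[df$Variant_Classification])
    cons[is.na(cons)] <- "other"
    out <- data.frame(
      sample_id = as.character(df$Tumor_Sample_Barcode),
      gene = as.character(df$Hugo_Symbol),
      protein_change = sub("^p\\.", "", as.character(df$HGVSp_Short)),
      consequence = cons, vaf = vaf, stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      sample_id = as.character(df$sample_id),
      gene = as.character(df$gene),
      protein_change = as.character(df$protein_change),
      consequence = NA_character_,
      vaf = if ("vaf" %in% names(df))
        suppressWarnings(as.numeric(df$vaf)) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (any(!nzchar(out$sample_id)) || any(!nzchar(out$gene))) {
    stop_arg("mutation table %s has empty sample_id or gene values", path)
  }
  bad_vaf <- !is.na(out$vaf) & (out$vaf < 0 | out$vaf > 1)
  if (any(bad_vaf)) stop_arg("VAF outside [0,1] at row(s) %s",
                             paste(which(bad_vaf), collapse = ", "))
  pc <- parse_protein_change(out$protein_change)
  out$flagged <- !pc$parsed
  if (dialect == "simple") {
    out$consequence <- pc$consequence
  } else {
    out$consequence[out$flagged] <- "other"
  }
  out$protein_change <- ifelse(pc$parsed, pc$normalized, out$protein_change)
  out$mutation_id <- paste0(out$gene, "_", out$protein_change)
  out$impact <- c(missense = "moderate", nonsense = "high",
                  frameshift = "high", other = "modifier")[out$consequence]
  out$impact[is.na(out$impact)] <- "unknown"
  if (any(out$flagged)) {
    log_msg("warn", sum(out$flagged),
            " row(s) with unparseable protein change retained as 'other'")
  }
  out
}

.empty_variants <- function() {
  data.frame(sample_id = character(), gene = character(),
             protein_change = character(), consequence = character(),
             vaf = numeric(), flagged = logical(),
             mutation_id = character(), impact = character(),
             stringsAsFactors = FALSE)
}

#' Read a per-country HLA allele-frequency table
#'
#' Expects a TSV with columns `population_group`, `country`, `locus`
#' (`A`/`B`/`C`), `allele`, `frequency` and `sample_size`. Class II loci are
#' rejected — the pipeline is restricted to HLA class I. Allele names are
#' normalized to two-field resolution.
#'
#' @param path Path to the TSV.
#' @return A validated data frame of raw per-country rows.
#' @export
read_allele_frequencies <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  df <- read_tsv(path)
  need <- c("population_group", "country", "locus", "allele",
            "frequency", "sample_size")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_arg("allele-frequency table lacks column(s): %s",
                             paste(miss, collapse = ", "))
  bad_locus <- !(df$locus %in% c("A", "B", "C"))
  if (any(bad_locus)) {
    stop_arg("non-class-I locus at row(s) %s (only HLA-A/B/C supported): %s",
             paste(which(bad_locus), collapse = ", "),
             paste(unique(df$locus[bad_locus]), collapse = ", "))
  }
  df$frequency <- as.numeric(df$frequency)
  bad_f <- is.na(df$frequency) | df$frequency < 0 | df$frequency > 1
  if (any(bad_f)) stop_arg("frequency outside [0,1] at row(s): %s",
                           paste(which(bad_f), collapse = ", "))
  df$sample_size <- as.numeric(df$sample_size)
  if (any(is.na(df$sample_size) | df$sample_size <= 0)) {
    stop_arg("sample_size must be positive for every row")
  }
  df$allele <- normalize_allele(df$allele)
  if (any(allele_locus(df$allele) != df$locus)) {
    stop_arg("allele name does not match its stated locus")
  }
  df
}

#' Parse NetMHCpan-style binding prediction output
#'
#' Reads a whitespace- or tab-delimited prediction table and extracts one
#' binding call per (peptide, allele). The header row is auto-detected as
#' the first line containing a peptide column, an allele (MHC/HLA) column
#' and a percentile-rank column (named like `%Rank`, `Rank`, `%Rank_EL` or
#' `percentile_rank`). Duplicate (peptide, allele) rows — predictors emit one
#' row per length context — are collapsed to the minimum (best) rank.
#'
#' @param path Path to the prediction table.
#' @return A data frame with columns `peptide`, `allele` (normalized) and
#'   `rank`; binder class is not assigned here (see [classify_binder()]).
#' @export
parse_predictor_output <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    log_msg("warn", "empty prediction file: ", path)
    return(data.frame(peptide = character(), allele = character(),
                      rank = numeric(), stringsAsFactors = FALSE))
  }
  is_rank <- function(tok) grepl("^%?Rank(_EL|_BA)?$|^percentile_rank$",
                                 tok, ignore.case = TRUE)
  is_pep <- function(tok) grepl("^Peptide$", tok, ignore.case = TRUE)
  is_all <- function(tok) grepl("^(MHC|HLA|Allele)$", tok, ignore.case = TRUE)
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (any(is_rank(toks)) && any(is_pep(toks)) && any(is_all(toks))) {
      header_at <- i; break
    }
  }
  if (is.na(header_at)) {
    stop_arg("no recognizable header (peptide / allele / %%Rank) in %s", path)
  }
  toks <- strsplit(trimws(lines[header_at]), "[ \t]+")[[1]]
  ip <- which(is_pep(toks))[1]; ia <- which(is_all(toks))[1]
  ir <- which(is_rank(toks))[1]
  body <- lines[-seq_len(header_at)]
  body <- body[!grepl("^[-#]", body)]
  if (!length(body)) {
    return(data.frame(peptide = character(), allele = character(),
                      rank = numeric(), stringsAsFactors = FALSE))
  }
  rows <- strsplit(trimws(body), "[ \t]+")
  keep <- vapply(rows, length, integer(1)) >= max(ip, ia, ir)
  rows <- rows[keep]
  out <- data.frame(
    peptide = vapply(rows, `[[`, character(1), ip),
    allele = normalize_allele(vapply(rows, `[[`, character(1), ia)),
    rank = as.numeric(vapply(rows, `[[`, character(1), ir)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$rank))) stop_arg("non-numeric %%Rank values in %s", path)
  n0 <- nrow(out)
  out <- out[order(out$peptide, out$allele, out$rank), , drop = FALSE]
  dup <- duplicated(out[, c("peptide", "allele")])
  if (any(dup)) {
    log_msg("info", "collapsed ", sum(dup),
            " duplicate (peptide, allele) prediction row(s) to best rank")
  }
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a patient genotype table
#'
#' Expects a TSV with columns `patient_id`, `mutations`
#' (semicolon-separated mutation ids, empty allowed), `A1`,`A2`,`B1`,`B2`,
#' `C1`,`C2` (HLA class I alleles; empty for untyped loci) and optionally
#' five microsatellite marker columns `BAT25`, `BAT26`, `MONO27`, `NR21`,
#' `NR24` (0/1 instability calls).
#'
#' @param path Path to the TSV.
#' @return A list of patient records as produced by [make_patient()].
#' @export
read_patients <- function(path) {
  df <- read_tsv(path)
  need <- c("patient_id", "mutations", "A1", "A2", "B1", "B2", "C1", "C2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_arg("patient table lacks column(s): %s",
                             paste(miss, collapse = ", "))
  markers_cols <- c("BAT25", "BAT26", "MONO27", "NR21", "NR24")
  has_markers <- all(markers_cols %in% names(df))
  lapply(seq_len(nrow(df)), function(i) {
    muts <- df$mutations[i]
    muts <- if (is.na(muts) || !nzchar(muts)) character() else
      strsplit(muts, ";", fixed = TRUE)[[1]]
    alleles <- unlist(df[i, c("A1", "A2", "B1", "B2", "C1", "C2")],
                      use.names = FALSE)
    alleles <- alleles[!is.na(alleles) & nzchar(alleles)]
    markers <- if (has_markers)
      as.logical(as.integer(unlist(df[i, markers_cols]))) else NULL
    make_patient(df$patient_id[i], muts, normalize_allele(alleles), markers)
  })
}

#' Construct a patient record
#'
#' @param patient_id Patient identifier.
#' @param mutations Character vector of mutation ids carried by the tumor.
#' @param hla_genotype Up to six class I alleles (two per locus, homozygous
#'   loci may repeat an allele); matching treats the genotype as a presence
#'   set, so a homozygous locus contributes one distinct allele.
#' @param msi_markers Optional logical vector of length 5: instability calls
#'   for BAT-25, BAT-26, MONO-27, NR-21, NR-24.
#' @return A list with class `neo_patient`; `msi_status` is derived from the
#'   markers via [msi_classify()] when present, otherwise `"unknown"`.
#' @export
make_patient <- function(patient_id, mutations = character(),
                         hla_genotype = character(), msi_markers = NULL) {
  if (length(hla_genotype)) {
    hla_genotype <- normalize_allele(hla_genotype)
    cnt <- table(allele_locus(hla_genotype))
    if (any(cnt > 2)) stop_arg("patient %s has >2 alleles at a locus",
                               patient_id)
  }
  structure(list(
    patient_id = as.character(patient_id),
    mutations = unique(as.character(mutations)),
    hla_genotype = unique(hla_genotype),
    msi_markers = msi_markers,
    msi_status = if (is.null(msi_markers)) "unknown"
                 else msi_classify(msi_markers)
  ), class = "neo_patient")
}

#' @export
print.neo_patient <- function(x, ...) {
  cat(sprintf("<patient %s: %d mutation(s), %d HLA allele(s), MSI %s>\n",
              x$patient_id, length(x$mutations), length(x$hla_genotype),
              x$msi_status))
  invisible(x)
}

#' Write patients to the TSV dialect read by [read_patients()]
#' @param patients List of patient records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  rows <- lapply(patients, function(p) {
    g <- p$hla_genotype
    by_locus <- split(g, allele_locus(g))
    slot <- function(loc, k) {
      a <- by_locus[[loc]] %||% character()
      if (length(a) >= k) a[k] else if (length(a) == 1 && k == 2) a[1] else ""
    }
    out <- data.frame(
      patient_id = p$patient_id,
      mutations = paste(p$mutations, collapse = ";"),
      A1 = slot("A", 1), A2 = slot("A", 2),
      B1 = slot("B", 1), B2 = slot("B", 2),
      C1 = slot("C", 1), C2 = slot("C", 2),
      stringsAsFactors = FALSE
    )
    if (!is.null(p$msi_markers)) {
      out[c("BAT25", "BAT26", "MONO27", "NR21", "NR24")] <-
        as.list(as.integer(p$msi_markers))
    }
    out
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read wild-type protein sequences from FASTA
#'
#' Headers are taken as gene symbols (first whitespace-delimited token).
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid strings.
#' @export
read_proteins_fasta <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- vapply(strsplit(names(aa), "[ \t]"), `[[`, character(1), 1)
  out
}

#' Write protein sequences to FASTA
#'
#' @param proteins Named character vector of amino-acid strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
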