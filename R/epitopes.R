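.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_protein <- function(x, what = "protein") {
  if (!is.character(x) || length(x) != 1 || !nzchar(x)) {
    stop_arg("%s must be a non-empty string", what)
  }
  chars <- strsplit(x, "")[[1]]
  if (!all(chars %in% .AA)) {
    stop_arg("%s contains characters outside the 20-letter amino-acid alphabet",
             what)
  }
  invisible(chars)
}

#' Apply a protein-level mutation to a wild-type sequence
#'
#' Missense mutations substitute a single residue; nonsense mutations
#' truncate the protein before the stop position; frameshifts keep the
#' prefix up to `pos - 1` and append the supplied novel tail (translated
#' downstream sequence, which must come from the caller or the simulator —
#' no CDS-level translation is attempted here).
#'
#' @param wt_protein Wild-type amino-acid string.
#' @param mutation A single protein change, either a string (e.g. `"G12D"`,
#'   `"K39*"`, `"G659X"`) or one row of [parse_protein_change()] output.
#' @param frameshift_tail Novel downstream amino-acid string; required for
#'   frameshift mutations.
#' @return The mutant protein string.
#' @examples
#' apply_mutation("MKT", "K2R")                         # "MRT"
#' apply_mutation("MKT", "K2*")                         # "M"
#' apply_mutation("MKT", "K2X", frameshift_tail = "QLW") # "MQLW"
#' @export
apply_mutation <- function(wt_protein, mutation, frameshift_tail = NULL) {
  chars <- .check_protein(wt_protein, "wt_protein")
  if (is.character(mutation)) mutation <- parse_protein_change(mutation)[1, ]
  if (!isTRUE(mutation$parsed)) {
    stop_arg("unparseable protein change: %s", mutation$input)
  }
  pos <- mutation$pos
  if (pos > length(chars)) {
    stop_arg("position %d beyond protein length %d", pos, length(chars))
  }
  if (chars[pos] != mutation$ref) {
    stop_arg("reference mismatch at position %d: expected %s, protein has %s",
             pos, mutation$ref, chars[pos])
  }
  switch(mutation$consequence,
    missense = {
      chars[pos] <- mutation$alt
      paste(chars, collapse = "")
    },
    nonsense = paste(chars[seq_len(pos - 1L)], collapse = ""),
    frameshift = {
      if (is.null(frameshift_tail)) {
        stop_arg("frameshift mutation %s requires frameshift_tail",
                 mutation$normalized)
      }
      .check_protein(frameshift_tail, "frameshift_tail")
      paste0(paste(chars[seq_len(pos - 1L)], collapse = ""), frameshift_tail)
    },
    stop_arg("cannot apply consequence '%s'", mutation$consequence)
  )
}

#' Enumerate matched mutant / wild-type candidate peptides
#'
#' Emits every window of each requested length that lies fully within the
#' mutant protein and overlaps at least one altered position (windows are
#' clipped at the termini). For substitutions the paired wild-type peptide
#' is the same-coordinate window of the wild-type protein; for frameshifts
#' (where downstream coordinates no longer correspond) no wild-type peptide
#' is attached. Duplicate mutant sequences arising from different offsets
#' are de-duplicated, keeping the first window's provenance and a copy
#' count.
#'
#' @param wt_protein Wild-type protein string (may be `NA` for pure
#'   frameshift tails).
#' @param mut_protein Mutant protein string.
#' @param altered_positions 1-based positions in the mutant protein that
#'   differ from wild type (a single position for missense; the novel-tail
#'   positions for frameshift).
#' @param lengths Peptide lengths, each in 8..25 (default 8:11).
#' @param mutation_id Optional id copied into the output.
#' @return Data frame of peptide pairs: `mutation_id`, `length`, `start`
#'   (1-based in the mutant protein), `mut_peptide`, `wt_peptide` (`NA` for
#'   frameshift), `mut_offset` (1-based position of the first altered
#'   residue within the peptide), `n_copies`.
#' @export
enumerate_peptides <- function(wt_protein, mut_protein, altered_positions,
                               lengths = 8:11, mutation_id = NA_character_) {
  mchars <- .check_protein(mut_protein, "mut_protein")
  if (!length(altered_positions)) stop_arg("altered_positions is empty")
  if (any(lengths < 8 | lengths > 25)) {
    stop_arg("peptide lengths must lie in 8..25")
  }
  has_wt <- !is.na(wt_protein)
  wchars <- if (has_wt) .check_protein(wt_protein, "wt_protein") else NULL
  L <- length(mchars)
  altered <- sort(unique(as.integer(altered_positions)))
  if (any(altered < 1 | altered > L)) {
    stop_arg("altered position outside mutant protein")
  }
  rows <- list()
  for (k in lengths) {
    if (k > L) next
    for (s in seq_len(L - k + 1L)) {
      e <- s + k - 1L
      hit <- altered[altered >= s & altered <= e]
      if (!length(hit)) next
      mut_pep <- paste(mchars[s:e], collapse = "")
      wt_pep <- NA_character_
      if (has_wt) {
        # same-coordinate wild-type window; only valid when coordinates
        # correspond (substitutions) — caller passes wt = NA for frameshift
        if (e <= length(wchars)) {
          wt_pep <- paste(wchars[s:e], collapse = "")
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mutation_id = mutation_id, length = k, start = s,
        mut_peptide = mut_pep, wt_peptide = wt_pep,
        mut_offset = hit[1] - s + 1L, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(mutation_id = character(), length = integer(),
                      start = integer(), mut_peptide = character(),
                      wt_peptide = character(), mut_offset = integer(),
                      n_copies = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  # de-duplicate identical mutant sequences, keeping provenance of the first
  copies <- as.integer(table(out$mut_peptide)[out$mut_peptide])
  out$n_copies <- copies
  out <- out[!duplicated(out$mut_peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peptide pairs for a mutation against a wild-type protein
#'
#' Convenience wrapper combining [apply_mutation()] and
#' [enumerate_peptides()]. Nonsense mutations create no novel residues and
#' yield an empty pair table (they are catalogued but peptide-less);
#' frameshifts enumerate all windows overlapping the novel tail, with no
#' wild-type pairing.
#'
#' @param wt_protein Wild-type protein string.
#' @param mutation Protein-change string or parsed row.
#' @param frameshift_tail Novel tail for frameshifts.
#' @param lengths Peptide lengths (default 8:11).
#' @param mutation_id Optional id for the output.
#' @return Data frame as from [enumerate_peptides()].
#' @export
mutation_peptides <- function(wt_protein, mutation, frameshift_tail = NULL,
                              lengths = 8:11, mutation_id = NA_character_) {
  if (is.character(mutation)) mutation <- parse_protein_change(mutation)[1, ]
  mut_protein <- apply_mutation(wt_protein, mutation, frameshift_tail)
  if (mutation$consequence == "nonsense") {
    return(enumerate_peptides(wt_protein, wt_protein, 1L,
                              lengths)[0, , drop = FALSE])
  }
  if (mutation$consequence == "frameshift") {
    altered <- seq.int(mutation$pos, nchar(mut_protein))
    return(enumerate_peptides(NA_character_, mut_protein, altered, lengths,
                              mutation_id))
  }
  enumerate_peptides(wt_protein, mut_protein, mutation$pos, lengths,
                     mutation_id)
}

#' Long stimulation peptide centred on the altered residue
#'
#' Returns a window of `length` residues (default 25) from the mutant
#' protein with the altered residue centred (at offset 13 of 25), shifted
#' minimally when the mutation lies within 12 residues of a terminus, and
#' shorter than requested only when the whole protein is shorter.
#'
#' @param mut_protein Mutant protein string.
#' @param altered_position 1-based altered position.
#' @param length Window length (default 25).
#' @return List with `peptide`, `start` and `mut_offset`.
#' @export
long_peptide <- function(mut_protein, altered_position, length = 25L) {
  chars <- .check_protein(mut_protein, "mut_protein")
  L <- length(chars)
  p <- as.integer(altered_position)
  if (p < 1 || p > L) stop_arg("altered_position outside protein")
  k <- as.integer(length)
  if (L < k) {
    log_msg("warn", sprintf(
      "protein shorter (%d) than requested window (%d); whole protein returned",
      L, k))
    return(list(peptide = paste(chars, collapse = ""), start = 1L,
                mut_offset = p))
  }
  half <- (k - 1L) %/% 2L            # 12 for a 25-mer: altered residue at 13
  s <- min(max(1L, p - half), L - k + 1L)
  list(peptide = paste(chars[s:(s + k - 1L)], collapse = ""),
       start = s, mut_offset = p - s + 1L)
}
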