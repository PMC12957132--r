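#' Parse and normalize an HGVS-p short protein change
#'
#' Accepts short-form protein changes such as `"G12D"`, `"p.G12D"`,
#' `"K39*"`, `"G659fs"`, `"G659Vfs*41"` or the truncation-group shorthand
#' `"G659X"`. A leading `"p."` is stripped. The consequence class is derived
#' from the suffix:
#'
#' * single substituted residue -> `missense`
#' * trailing `*` -> `nonsense` (stop gain)
#' * `fs` suffix or trailing `X` -> `frameshift` (truncation group, keyed by
#'   gene + position, so e.g. `G659Vfs*41` and `G659fs` normalize to `G659X`)
#'
#' Anything unparseable is retained with consequence `other` and
#' `parsed = FALSE` so that upstream readers can keep and flag the row.
#'
#' @param x Character vector of protein changes.
#' @return A data frame with columns `input`, `normalized`, `ref` (reference
#'   residue), `pos` (1-based protein position), `alt` (alternate residue or
#'   `"*"`/`"X"`), `consequence` (one of `missense`, `nonsense`,
#'   `frameshift`, `other`) and `parsed` (logical).
#' @examples
#' parse_protein_change(c("G12D", "p.K39*", "G659Vfs*41", "G659X", "?"))
#' @export
parse_protein_change <- function(x) {
  stopifnot(is.character(x))
  raw <- x
  x <- sub("^p\\.", "", x)
  n <- length(x)
  out <- data.frame(
    input = raw, normalized = NA_character_, ref = NA_character_,
    pos = NA_integer_, alt = NA_character_,
    consequence = rep("other", n), parsed = FALSE,
    stringsAsFactors = FALSE
  )
  aa <- "[A-Z]"
  # missense: ref, position, single alt residue (X excluded: truncation code)
  mis <- regmatches(x, regexec(sprintf("^(%s)([0-9]+)(%s)$", aa, aa), x))
  # nonsense: trailing stop
  non <- regmatches(x, regexec(sprintf("^(%s)([0-9]+)\\*$", aa), x))
  # frameshift: fs with optional new residue / extension, e.g. G659fs, G659Vfs*41
  fs <- regmatches(x, regexec(sprintf("^(%s)([0-9]+)%s?fs(\\*[0-9]*)?$", aa, aa),
                              x))
  for (i in seq_len(n)) {
    m <- mis[[i]]; s <- non[[i]]; f <- fs[[i]]
    if (length(f)) {
      out$ref[i] <- f[2]; out$pos[i] <- as.integer(f[3]); out$alt[i] <- "X"
      out$consequence[i] <- "frameshift"
      out$normalized[i] <- paste0(f[2], f[3], "X"); out$parsed[i] <- TRUE
    } else if (length(s)) {
      out$ref[i] <- s[2]; out$pos[i] <- as.integer(s[3]); out$alt[i] <- "*"
      out$consequence[i] <- "nonsense"
      out$normalized[i] <- paste0(s[2], s[3], "*"); out$parsed[i] <- TRUE
    } else if (length(m)) {
      out$ref[i] <- m[2]; out$pos[i] <- as.integer(m[3]); out$alt[i] <- m[4]
      if (m[4] == "X") {
        # truncation-group shorthand used in recurrent-mutation labels
        out$consequence[i] <- "frameshift"
      } else {
        out$consequence[i] <- "missense"
      }
      out$normalized[i] <- paste0(m[2], m[3], m[4]); out$parsed[i] <- TRUE
    }
  }
  out
}

#' Mutation identity key
#'
#' Mutations are identified throughout the pipeline by
#' `<gene>_<normalized protein change>`, e.g. `"KRAS_G12D"` or the
#' truncation group `"RNF43_G659X"`.
#'
#' @param gene Gene symbol vector.
#' @param protein_change Protein change vector (normalized or raw; raw values
#'   are normalized first).
#' @return Character vector of mutation ids.
#' @export
mutation_id <- function(gene, protein_change) {
  pc <- parse_protein_change(as.character(protein_change))
  norm <- ifelse(pc$parsed, pc$normalized, pc$input)
  paste0(gene, "_", norm)
}
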