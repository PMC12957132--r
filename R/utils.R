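#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulation helpers never
#' disturb the caller's random-number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# stderr logging with levels; threshold set via options(otsneo.log_level=)
.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

log_msg <- function(level, ...) {
  threshold <- getOption("otsneo.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}

#' Write a data frame as UTF-8 TSV
#'
#' All tabular pipeline outputs go through this writer so that files are
#' tab-delimited, unquoted and byte-stable across runs.
#'
#' @param x A data frame. List columns are collapsed with `;`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (j in seq_along(x)) {
    if (is.list(x[[j]])) {
      x[[j]] <- vapply(x[[j]], function(v) paste(v, collapse = ";"), character(1))
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA",
                    fileEncoding = "UTF-8")
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)
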