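#' Normalize gene symbols
#'
#' Symbols are stripped of surrounding whitespace, optionally passed through an
#' alias map, and uppercased. Normalization is idempotent: applying it twice
#' gives the same result as applying it once.
#'
#' @param x Character vector of gene symbols.
#' @param alias Optional two-column data frame (`from`, `to`); exact matches of
#'   the trimmed raw symbol against `from` are replaced by `to` before
#'   uppercasing. No other alias resolution is attempted.
#' @return Character vector of normalized symbols.
#' @export
normalize_gene_symbols <- function(x, alias = NULL) {
  x <- trimws(as.character(x))
  if (!is.null(alias)) {
    stopifnot(is.data.frame(alias), ncol(alias) >= 2)
    hit <- match(x, trimws(as.character(alias[[1]])))
    x[!is.na(hit)] <- trimws(as.character(alias[[2]]))[hit[!is.na(hit)]]
  }
  toupper(x)
}

# Read a TSV as a list of character vectors (one per line), keeping track of
# 1-based line numbers so schema errors can name the offending line.
read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*$", lines)
  list(fields = lapply(lines[keep], function(l) strsplit(l, "\t", fixed = TRUE)[[1]]),
       lineno = which(keep))
}

# Does a row of cells look like a header for the given vocabulary of tokens?
looks_like_header <- function(cells, tokens) {
  any(tolower(trimws(cells)) %in% tokens)
}

#' Write a result table as a deterministic report
#'
#' Reports are TSV (default) or JSON depending on the file extension. Output is
#' UTF-8 with LF newlines; numeric columns are rounded to 6 significant digits
#' before writing so that writing and re-reading a report reproduces the
#' in-memory object exactly.
#'
#' @param result A data frame.
#' @param path Output path; a `.json` extension selects JSON, anything else TSV.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(result, path) {
  stopifnot(is.data.frame(result))
  out <- result
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
    if (nrow(out)) {
      cells <- vapply(seq_along(out), function(j) {
        col <- out[[j]]
        if (is.numeric(col) && !is.integer(col)) {
          ifelse(is.na(col), "NA", formatC(col, digits = 6, format = "g"))
        } else {
          ifelse(is.na(col), "NA", as.character(col))
        }
      }, character(nrow(out)))
      if (nrow(out) == 1L) cells <- matrix(cells, nrow = 1L)
      writeLines(apply(cells, 1L, paste, collapse = "\t"), con, sep = "\n")
    }
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path Path to a `.tsv` or `.json` report.
#' @return A data frame.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- jsonlite::fromJSON(path)
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA", quote = "")
}

# Deterministic lexicographic sort used for every reported gene/term set.
sort_c <- function(x) sort(unique(x), method = "radix")
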