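#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse ISO-8601 date strings strictly
#'
#' Empty strings (and any configured unknown-value aliases) become `NA`;
#' anything else that does not parse as `YYYY-MM-DD` is an error rather than
#' a silent `NA`.
#'
#' @param x character vector.
#' @param what label used in error messages.
#' @param na_aliases strings treated as unknown.
#' @return a `Date` vector.
#' @keywords internal
parse_date_strict <- function(x, what = "date", na_aliases = "") {
  x <- as.character(x)
  x[x %in% na_aliases] <- NA_character_
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("unparseable %s value(s): %s (expected YYYY-MM-DD)",
                 what, paste(utils::head(unique(x[bad]), 5), collapse = ", ")),
         call. = FALSE)
  }
  out
}

# Split a ";"-joined id cell into a character vector (empty -> character(0)).
split_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

join_ids <- function(x) {
  if (length(x) == 0) return("")
  paste(x, collapse = ";")
}

# Stable key for an unordered pair of ids.
dyad_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "|")
}

stop_invalid <- function(table, rows, msg) {
  stop(sprintf("invalid %s (row %s): %s", table,
               paste(utils::head(rows, 10), collapse = ", "), msg),
       call. = FALSE)
}
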