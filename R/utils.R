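# Shared helpers: status vocabulary, id-string handling, TSV conventions.

#' Trait status levels
#'
#' The three-valued status vocabulary used throughout the package:
#' `present`, `putative` (pathway evidence above threshold but a required
#' marker missing, or a flagged partial pathway), and `absent`.
#'
#' @return Character vector of the three status levels, in order.
#' @export
trait_statuses <- function() c("present", "putative", "absent")

STATUS_CODE <- c(present = "P", putative = "U", absent = "A")
CODE_STATUS <- c(P = "present", U = "putative", A = "absent")

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_status <- function(x, what = "status") {
  bad <- setdiff(unique(x), trait_statuses())
  if (length(bad) > 0)
    stop_fmt("invalid %s value(s): %s", what, paste(bad, collapse = ", "))
  invisible(x)
}

# Semicolon-separated id fields ("K00123;PF00765"); empty string -> character(0)
split_ids <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

collapse_ids <- function(ids) paste(ids, collapse = ";")

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = character(0), ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop_fmt("file '%s' is missing required column(s): %s",
             path, paste(missing, collapse = ", "))
  invisible(df)
}

is_kegg_id <- function(x) grepl("^K[0-9]{5}$", x)
is_pfam_id <- function(x) grepl("^PF[0-9]{5}$", x)
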