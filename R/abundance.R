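# Consortium-level relative abundance from per-sample read counts.

#' Read a sample-by-genome count table
#'
#' TSV with a `sample` column followed by one column per genome;
#' counts are non-negative integers.
#'
#' @param path Input TSV path.
#' @return data.frame with `sample` plus numeric genome columns.
#' @export
read_count_table <- function(path) {
  df <- read_tsv(path)
  require_columns(df, "sample", path)
  for (col in setdiff(names(df), "sample")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(is.na(df[[col]])) || any(df[[col]] < 0))
      stop_fmt("count table '%s': column '%s' contains negative or non-numeric counts",
               path, col)
  }
  df
}

#' Per-sample relative abundance with cross-sample summary
#'
#' Converts read counts to per-sample fractions (each sample sums to 1)
#' and summarizes each genome as mean +/- sd of its per-sample fractions —
#' the form in which dominant-member abundances such as "71% +/- 6 of
#' reads" are reported. Scale-invariant per sample.
#'
#' @param counts data.frame as returned by [read_count_table()], or a
#'   numeric matrix (samples x genomes).
#' @return List with `fractions` (data.frame, samples x genomes) and
#'   `summary` (data.frame: genome_id, mean_fraction, sd_fraction).
#' @export
relative_abundance <- function(counts) {
  if (is.matrix(counts)) {
    samples <- rownames(counts) %||% paste0("S", seq_len(nrow(counts)))
    mat <- counts
  } else {
    require_columns(counts, "sample", "count table")
    samples <- counts$sample
    mat <- as.matrix(counts[, setdiff(names(counts), "sample"),
                            drop = FALSE])
  }
  totals <- rowSums(mat)
  zero <- which(totals <= 0)
  if (length(zero) > 0)
    stop_fmt("sample '%s' has zero total counts", samples[zero[1]])
  frac <- sweep(mat, 1, totals, "/")
  summary <- data.frame(
    genome_id = colnames(mat),
    mean_fraction = colMeans(frac),
    sd_fraction = apply(frac, 2, stats::sd),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  fractions <- data.frame(sample = samples, frac, check.names = FALSE,
                          stringsAsFactors = FALSE)
  list(fractions = fractions, summary = summary)
}
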