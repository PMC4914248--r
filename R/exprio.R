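#' Read a series-matrix style expression file
#'
#' Parses the tab-delimited dialect used by GEO series-matrix distributions:
#' metadata lines prefixed with `!`, a numeric probe x sample table bracketed
#' by `!series_matrix_table_begin` / `!series_matrix_table_end`, a header row
#' of sample identifiers and a first column of probe identifiers. Identifiers
#' may be double-quoted; quotes are stripped. Cells equal to `NA`, `null`,
#' `NULL` or the empty string become missing values.
#'
#' @param path Path to the file.
#' @return A list with components `matrix` (numeric, probes x samples, with
#'   dimnames) and `annotations` (a named list: one character vector of
#'   values per metadata line, named by the key after the `!` sigil).
#' @seealso [write_series_matrix()]
#' @examples
#' f <- tempfile(fileext = ".txt")
#' m <- matrix(1:6 / 2, 3, 2,
#'             dimnames = list(c("P1", "P2", "P3"), c("S1", "S2")))
#' write_series_matrix(m, f)
#' read_series_matrix(f)$matrix
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  begin <- which(lines == "!series_matrix_table_begin")
  end <- which(lines == "!series_matrix_table_end")
  if (length(begin) != 1L)
    stop("format error: missing '!series_matrix_table_begin' marker in ", path,
         call. = FALSE)
  if (length(end) != 1L || end <= begin + 1L)
    stop("format error: missing or misplaced '!series_matrix_table_end' marker in ",
         path, call. = FALSE)

  meta_lines <- lines[seq_len(begin - 1L)]
  meta_lines <- meta_lines[startsWith(meta_lines, "!")]
  annotations <- list()
  for (ln in meta_lines) {
    fields <- unquote_fields(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    key <- sub("^!", "", fields[1L])
    annotations[[length(annotations) + 1L]] <- fields[-1L]
    names(annotations)[length(annotations)] <- key
  }

  table_lines <- lines[(begin + 1L):(end - 1L)]
  header <- unquote_fields(strsplit(table_lines[1L], "\t", fixed = TRUE)[[1L]])
  sample_ids <- header[-1L]
  if (length(sample_ids) == 0L)
    stop("format error: table header has no sample columns", call. = FALSE)

  body <- table_lines[-1L]
  if (length(body) == 0L)
    stop("format error: table has no probe rows", call. = FALSE)
  probe_ids <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    fields <- unquote_fields(strsplit(body[i], "\t", fixed = TRUE)[[1L]])
    if (length(fields) != length(sample_ids) + 1L)
      stop("format error: row ", i, " has ", length(fields) - 1L,
           " values, expected ", length(sample_ids), call. = FALSE)
    probe_ids[i] <- fields[1L]
    cells <- fields[-1L]
    missing <- cells %in% c("NA", "null", "NULL", "")
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & !missing)
    if (length(bad))
      stop("parse error: non-numeric value '", cells[bad[1L]], "' at probe '",
           probe_ids[i], "', sample '", sample_ids[bad[1L]], "'", call. = FALSE)
    values[i, ] <- num
  }
  if (anyDuplicated(probe_ids))
    stop("format error: duplicated probe identifiers", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("format error: duplicated sample identifiers", call. = FALSE)
  dimnames(values) <- list(probe_ids, sample_ids)
  list(matrix = values, annotations = annotations)
}

unquote_fields <- function(x) {
  gsub('^"|"$', "", x)
}

#' Write an expression matrix in series-matrix format
#'
#' Emits a file that [read_series_matrix()] parses back to an equal matrix.
#' All identifiers are double-quoted on output; identifiers containing tabs,
#' double quotes or newlines are rejected rather than escaped (documented
#' rule: the dialect has no escape convention). Values are written with full
#' double precision so the round trip is exact; missing cells are written as
#' `NA`.
#'
#' @param matrix Numeric probes x samples matrix with unique, nonempty
#'   rownames (probes) and colnames (samples).
#' @param path Output file path.
#' @param annotations Optional named list of character vectors written as
#'   `!key<TAB>values...` metadata lines before the table.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(matrix, path, annotations = NULL) {
  validate_expression_matrix(matrix)
  ids <- c(rownames(matrix), colnames(matrix))
  if (any(grepl('[\t"\n\r]', ids)))
    stop("identifiers containing tab, double-quote or newline characters ",
         "cannot be written to series-matrix format", call. = FALSE)
  quote_id <- function(x) paste0('"', x, '"')
  lines <- character(0)
  if (!is.null(annotations)) {
    if (is.null(names(annotations)) || any(names(annotations) == ""))
      stop("'annotations' must be a fully named list", call. = FALSE)
    for (key in names(annotations))
      lines <- c(lines, paste(c(paste0("!", key),
                                quote_id(as.character(annotations[[key]]))),
                              collapse = "\t"))
  }
  lines <- c(lines, "!series_matrix_table_begin",
             paste(c(quote_id("ID_REF"), quote_id(colnames(matrix))),
                   collapse = "\t"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  for (i in seq_len(nrow(matrix)))
    lines <- c(lines, paste(c(quote_id(rownames(matrix)[i]), fmt(matrix[i, ])),
                            collapse = "\t"))
  lines <- c(lines, "!series_matrix_table_end")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

validate_expression_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (nrow(matrix) == 0L || ncol(matrix) == 0L)
    stop("expression matrix must have at least one probe and one sample",
         call. = FALSE)
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix must carry probe rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(matrix)))
    stop("probe identifiers must be unique", call. = FALSE)
  if (anyDuplicated(colnames(matrix)))
    stop("sample identifiers must be unique", call. = FALSE)
  invisible(matrix)
}

#' Read / write a survival annotation table
#'
#' A 3-column tab-delimited file with header `sample_id`, `time`, `event`;
#' `time` non-negative, `event` coded 0 (censored) / 1 (event observed).
#'
#' @param path File path.
#' @return `read_survival_table()` returns a data.frame with those columns.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table must have columns sample_id, time, event", call. = FALSE)
  df <- df[need]
  validate_survival_table(df)
  df
}

#' @rdname read_survival_table
#' @param table Data frame with columns `sample_id`, `time`, `event`.
#' @export
write_survival_table <- function(table, path) {
  validate_survival_table(table)
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(table[c("sample_id", "time", "event")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_survival_table <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("survival table must be a nonempty data.frame", call. = FALSE)
  if (!all(c("sample_id", "time", "event") %in% names(table)))
    stop("survival table must have columns sample_id, time, event", call. = FALSE)
  if (anyDuplicated(table$sample_id))
    stop("survival table sample_id values must be unique", call. = FALSE)
  if (!is.numeric(table$time) || any(is.na(table$time)) || any(table$time < 0))
    stop("input error: survival times must be non-negative and non-missing",
         call. = FALSE)
  if (any(is.na(table$event)) || !all(table$event %in% c(0, 1)))
    stop("input error: event indicator must be 0 or 1", call. = FALSE)
  invisible(table)
}

#' Rank-transform an expression matrix to a per-sample 0-100 scale
#'
#' Within each sample (column), expression values are replaced by rank scores
#' `100 * (rank - 1) / (N - 1)`, where `rank` is the midrank (average rank,
#' ties shared) among the sample's `N` non-missing probes. The smallest value
#' in a sample scores 0 and the largest 100; a score of 55 means 55% of the
#' sample's other probes have lower expression. Ranking is per sample, so the
#' transform is invariant under any strictly increasing per-sample
#' transformation of the raw values, and Pearson correlation of rank scores
#' equals Spearman correlation of the raw values. Missing cells stay missing
#' and are excluded from `N`.
#'
#' @param matrix Numeric probes x samples matrix with dimnames; every sample
#'   needs at least 2 non-missing probes.
#' @return A matrix of the same shape and dimnames with values in \[0, 100\].
#' @examples
#' m <- matrix(c(1, 2, 2, 9), ncol = 1,
#'             dimnames = list(paste0("P", 1:4), "S1"))
#' rank_transform(m)  # 0, 50, 50, 100
#' @export
rank_transform <- function(matrix) {
  validate_expression_matrix(matrix)
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    n_obs <- sum(!is.na(x))
    if (n_obs < 2L)
      stop("degenerate sample: '", colnames(matrix)[j],
           "' has fewer than 2 non-missing probes", call. = FALSE)
    r <- rank(x, na.last = "keep", ties.method = "average")
    out[, j] <- 100 * (r - 1) / (n_obs - 1)
  }
  out
}

#' Construct a gene-pair rank profile
#'
#' Aligned rank (or expression) vectors of two genes over a shared sample
#' list — the object the greedy cohort partition operates on.
#'
#' @param a_values,b_values Equal-length numeric vectors without missing
#'   values.
#' @param sample_ids Unique sample identifiers of the same length; defaults
#'   to names of `a_values` or `S1..Sn`.
#' @param probe_a,probe_b Optional probe labels carried for reporting.
#' @param n_dropped Number of samples excluded upstream for missingness.
#' @return A list of class `"pair_profile"` with fields `sample_ids`,
#'   `a_values`, `b_values`, `probe_a`, `probe_b`, `n_dropped`.
#' @export
pair_profile <- function(a_values, b_values, sample_ids = NULL,
                         probe_a = "gene_a", probe_b = "gene_b",
                         n_dropped = 0L) {
  if (!is.numeric(a_values) || !is.numeric(b_values))
    stop("pair values must be numeric", call. = FALSE)
  if (length(a_values) != length(b_values))
    stop("pair vectors must have equal length", call. = FALSE)
  if (anyNA(a_values) || anyNA(b_values))
    stop("pair profile must not contain missing values", call. = FALSE)
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(names(a_values))) names(a_values)
                  else paste0("S", seq_along(a_values))
  if (length(sample_ids) != length(a_values))
    stop("sample_ids length must match the pair vectors", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique", call. = FALSE)
  structure(
    list(sample_ids = as.character(sample_ids),
         a_values = as.numeric(a_values), b_values = as.numeric(b_values),
         probe_a = probe_a, probe_b = probe_b,
         n_dropped = as.integer(n_dropped)),
    class = "pair_profile"
  )
}

#' @export
print.pair_profile <- function(x, ...) {
  cat("pair_profile: ", x$probe_a, " vs ", x$probe_b, ", ",
      length(x$sample_ids), " samples", sep = "")
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " dropped for missingness)", sep = "")
  cat("\n")
  invisible(x)
}

#' Extract the aligned profile of two probes from a rank matrix
#'
#' Restricts to samples where both probes are non-missing and records how
#' many were dropped.
#'
#' @param ranks Matrix from [rank_transform()] (any numeric probes x samples
#'   matrix with dimnames works).
#' @param probe_a,probe_b Probe identifiers; an unknown probe raises a lookup
#'   error listing near-matches.
#' @param samples Optional sample identifiers to restrict to.
#' @return A [pair_profile()].
#' @export
extract_gene_pair <- function(ranks, probe_a, probe_b, samples = NULL) {
  validate_expression_matrix(ranks)
  for (p in c(probe_a, probe_b)) {
    if (!p %in% rownames(ranks)) {
      near <- utils::head(agrep(p, rownames(ranks), value = TRUE,
                                ignore.case = TRUE, max.distance = 0.2), 5L)
      stop("lookup error: probe '", p, "' not found",
           if (length(near)) paste0("; near matches: ",
                                    paste(near, collapse = ", ")),
           call. = FALSE)
    }
  }
  if (is.null(samples)) samples <- colnames(ranks)
  missing_samples <- setdiff(samples, colnames(ranks))
  if (length(missing_samples))
    stop("lookup error: samples not found: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  a <- ranks[probe_a, samples]
  b <- ranks[probe_b, samples]
  keep <- !is.na(a) & !is.na(b)
  pair_profile(a[keep], b[keep], sample_ids = samples[keep],
               probe_a = probe_a, probe_b = probe_b,
               n_dropped = sum(!keep))
}
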