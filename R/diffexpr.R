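#' Two-group differential expression with BH correction
#'
#' Per probe, a two-sample t test between `group_a` and `group_b` columns,
#' with Benjamini-Hochberg step-up adjustment across all tested probes and a
#' linear-scale fold change. Standard microarray practice is followed: the
#' test runs on log-scale values and the fold change is reported as a ratio
#' of linear-scale group means.
#'
#' With `values = "log2"` (default) the matrix is taken to be log2 expression
#' already: the test uses the values as-is and the fold change is
#' `2^(mean_a - mean_b)` (ratio of geometric means). With
#' `values = "linear"` the matrix must be strictly positive; the test runs on
#' `log2(values)` and the fold change is the ratio of the linear group means.
#' Fold changes are direction-signed on the larger/smaller convention:
#' magnitude >= 1, positive when group A is higher, negative when lower.
#'
#' Probes with zero variance in both groups and equal means get `p = 1` by
#' convention (no evidence of change); zero variance with unequal means gives
#' `p = 0`.
#'
#' @param matrix Numeric probes x samples matrix with dimnames.
#' @param group_a,group_b Disjoint sets of sample (column) identifiers, each
#'   of size >= 2.
#' @param values `"log2"` or `"linear"`; see Details.
#' @param var_equal Use the pooled-variance Student t (default, the classical
#'   microarray choice); `FALSE` gives Welch's t.
#' @return A data.frame, one row per probe in input order: `probe_id`,
#'   `mean_a`, `mean_b` (on the input scale), `fold_change` (signed linear
#'   ratio), `p_value`, `q_value` (BH), and `passes` — the default filter
#'   `q <= 0.05 & |fold_change| > 2` (recompute with [filter_hits()] for
#'   other thresholds).
#' @examples
#' m <- matrix(rnorm(60), 10, 6,
#'             dimnames = list(paste0("P", 1:10), paste0("S", 1:6)))
#' de <- differential_expression(m, paste0("S", 1:3), paste0("S", 4:6))
#' head(de)
#' @export
differential_expression <- function(matrix, group_a, group_b,
                                    values = c("log2", "linear"),
                                    var_equal = TRUE) {
  validate_expression_matrix(matrix)
  values <- match.arg(values)
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)))
    stop("input error: groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "), call. = FALSE)
  absent <- setdiff(c(group_a, group_b), colnames(matrix))
  if (length(absent))
    stop("input error: samples not in matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("input error: each group needs at least 2 samples", call. = FALSE)

  A <- matrix[, group_a, drop = FALSE]
  B <- matrix[, group_b, drop = FALSE]
  if (anyNA(A) || anyNA(B))
    stop("input error: differential expression requires complete values",
         call. = FALSE)

  if (values == "linear") {
    if (any(A <= 0) || any(B <= 0))
      stop("input error: values = \"linear\" requires strictly positive ",
           "expression (log-transform is applied for the test)", call. = FALSE)
    tA <- log2(A); tB <- log2(B)
  } else {
    tA <- A; tB <- B
  }

  na <- ncol(A); nb <- ncol(B)
  mA <- rowMeans(tA); mB <- rowMeans(tB)
  vA <- rowSums((tA - mA)^2) / (na - 1)
  vB <- rowSums((tB - mB)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * vA + (nb - 1) * vB) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(A))
  } else {
    se <- sqrt(vA / na + vB / nb)
    df <- (vA / na + vB / nb)^2 /
      ((vA / na)^2 / (na - 1) + (vB / nb)^2 / (nb - 1))
  }
  tstat <- (mA - mB) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero_var <- se == 0
  p[zero_var & mA == mB] <- 1      # no variation, no difference: p = 1
  p[zero_var & mA != mB] <- 0

  if (values == "linear") {
    la <- rowMeans(A); lb <- rowMeans(B)
    ratio <- la / lb
    mean_a <- la; mean_b <- lb
  } else {
    ratio <- 2^(mA - mB)
    mean_a <- mA; mean_b <- mB
  }
  fold_change <- ifelse(ratio >= 1, ratio, -1 / ratio)

  q <- stats::p.adjust(p, method = "BH")
  data.frame(probe_id = rownames(matrix),
             mean_a = mean_a, mean_b = mean_b,
             fold_change = fold_change,
             p_value = p, q_value = q,
             passes = q <= 0.05 & abs(fold_change) > 2,
             stringsAsFactors = FALSE)
}

#' Filter differential-expression records on significance and fold change
#'
#' Keeps records with adjusted (default) or raw p-value at or below
#' `p_threshold` — the cutoff is inclusive — and absolute fold change
#' strictly greater than `fc_threshold`. Input order is preserved.
#'
#' @param records Output of [differential_expression()].
#' @param p_threshold Significance cutoff in \[0, 1\], inclusive. Default 0.05.
#' @param fc_threshold Fold-change cutoff, exceeded strictly. Default 2.
#' @param use_adjusted Apply `p_threshold` to the BH `q_value` (default) or
#'   to the raw `p_value`.
#' @return The kept subset of `records`, with `passes` set to `TRUE`.
#' @export
filter_hits <- function(records, p_threshold = 0.05, fc_threshold = 2,
                        use_adjusted = TRUE) {
  need <- c("probe_id", "fold_change", "p_value", "q_value")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("'records' must come from differential_expression()", call. = FALSE)
  if (!is.numeric(p_threshold) || p_threshold < 0 || p_threshold > 1)
    stop("'p_threshold' must be a probability", call. = FALSE)
  if (!is.numeric(fc_threshold) || fc_threshold < 1)
    stop("'fc_threshold' must be a ratio >= 1", call. = FALSE)
  pv <- if (use_adjusted) records$q_value else records$p_value
  keep <- pv <= p_threshold & abs(records$fold_change) > fc_threshold
  out <- records[keep, , drop = FALSE]
  out$passes <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Gene-set enrichment odds ratio with Fisher exact p-value
#'
#' Builds the 2x2 table of hit status against gene-set membership over a
#' stated universe and returns the cross-product odds ratio
#' `(a*d) / (b*c)` — cells: a = in-set hits, b = in-set non-hits, c = out-set
#' hits, d = out-set non-hits — together with the two-sided Fisher exact
#' p-value. When any cell is zero the Haldane-Anscombe correction (0.5 added
#' to every cell) is applied to the odds ratio and the result is flagged via
#' `continuity_corrected`; the p-value is always computed on the uncorrected
#' table.
#'
#' @param hits Identifiers called significant; must be a subset of
#'   `universe`.
#' @param pathway Identifiers of the gene set; must be a subset of
#'   `universe`.
#' @param universe All identifiers tested.
#' @return A list of class `"enrichment_result"`: `counts` (named 2x2
#'   matrix), `odds_ratio`, `p_value`, `continuity_corrected`.
#' @examples
#' enrichment_odds_ratio(hits = paste0("g", 1:15),
#'                       pathway = paste0("g", c(1:10, 901:995)),
#'                       universe = paste0("g", 1:1000))
#' @export
enrichment_odds_ratio <- function(hits, pathway, universe) {
  hits <- unique(as.character(hits))
  pathway <- unique(as.character(pathway))
  universe <- unique(as.character(universe))
  bad_h <- setdiff(hits, universe)
  if (length(bad_h))
    stop("input error: hits not in universe: ",
         paste(utils::head(bad_h, 10L), collapse = ", "), call. = FALSE)
  bad_p <- setdiff(pathway, universe)
  if (length(bad_p))
    stop("input error: pathway members not in universe: ",
         paste(utils::head(bad_p, 10L), collapse = ", "), call. = FALSE)

  a <- length(intersect(pathway, hits))
  b <- length(pathway) - a
  c <- length(hits) - a
  d <- length(universe) - a - b - c
  counts <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                   dimnames = list(c("in_set", "out_set"),
                                   c("hit", "non_hit")))
  corrected <- any(counts == 0)
  or <- if (corrected) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  p <- stats::fisher.test(counts)$p.value
  structure(list(counts = counts, odds_ratio = or, p_value = p,
                 continuity_corrected = corrected),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Gene-set enrichment (Fisher exact)\n")
  print(x$counts)
  cat(sprintf("  odds ratio: %.3f%s   p = %.3g\n", x$odds_ratio,
              if (x$continuity_corrected) " (Haldane-Anscombe corrected)" else "",
              x$p_value))
  invisible(x)
}

#' Read gene sets from a plain-list or GMT file
#'
#' Plain lists carry one identifier per line and yield a single set named
#' after the file. GMT files (detected by tab characters) carry one set per
#' line: name, description, then members, tab-delimited.
#'
#' @param path File path.
#' @return A named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("format error: gene-set file is empty", call. = FALSE)
  if (any(grepl("\t", lines, fixed = TRUE))) {
    sets <- list()
    for (ln in lines) {
      fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(fields) < 3L)
        stop("format error: GMT line needs name, description and >= 1 member",
             call. = FALSE)
      sets[[fields[1L]]] <- unique(fields[-(1:2)])
    }
    sets
  } else {
    stats::setNames(list(unique(trimws(lines))),
                    tools::file_path_sans_ext(basename(path)))
  }
}
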