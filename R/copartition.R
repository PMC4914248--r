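#' Pearson product-moment correlation with strict input checks
#'
#' Plain Pearson correlation, computed on mean-centered vectors for
#' numerical stability. Unlike [stats::cor()] it refuses degenerate inputs:
#' fewer than 3 paired observations is a sample-size error and a constant
#' vector an undefined-correlation error, so the cohort-partition loop never
#' silently propagates `NA`.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, no missing values,
#'   neither constant.
#' @return The correlation, a single number in \[-1, 1\].
#' @examples
#' pearson_r(1:4, c(1, 3, 2, 4))
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("correlation inputs must be numeric vectors", call. = FALSE)
  if (length(x) != length(y))
    stop("correlation inputs must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("sample-size error: correlation needs at least 3 paired values",
         call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("correlation inputs must not contain missing values", call. = FALSE)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  syy <- sum(yc^2)
  if (sxx == 0 || syy == 0)
    stop("undefined-correlation error: constant vector", call. = FALSE)
  r <- sum(xc * yc) / sqrt(sxx * syy)
  min(1, max(-1, r))
}

# Leave-one-out correlations for all current members, O(n) via sum downdates
# on globally centered values. Returns list(r_full, r_loo) where r_loo[i] is
# the correlation of members \ {i}; -Inf marks removals that leave a
# (numerically) constant vector.
loo_correlations <- function(x, y) {
  m <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  if (sxx == 0 || syy == 0)
    stop("undefined-correlation error: constant vector", call. = FALSE)
  r_full <- min(1, max(-1, sxy / sqrt(sxx * syy)))
  # after removing i: raw sums over centered values are Sx' = -xc[i], etc.
  m1 <- m - 1
  num <- m1 * (sxy - xc * yc) - xc * yc
  vx <- m1 * (sxx - xc^2) - xc^2
  vy <- m1 * (syy - yc^2) - yc^2
  # variance terms scale with m * var; treat tiny/negative as constant
  tol_x <- 1e-12 * sxx
  tol_y <- 1e-12 * syy
  ok <- vx > tol_x & vy > tol_y
  r_loo <- rep(-Inf, m)
  r_loo[ok] <- pmin(1, pmax(-1, num[ok] / sqrt(vx[ok] * vy[ok])))
  list(r_full = r_full, r_loo = r_loo)
}

#' Leave-one-out correlation deltas for a cohort
#'
#' For each member sample `s`, the change in the pair's Pearson correlation
#' if `s` were removed: `delta(s) = r(members \ s) - r(members)`. Samples
#' whose removal would leave one of the two vectors constant get
#' `delta = -Inf`, so the greedy step can never select them.
#'
#' @param pair A [pair_profile()].
#' @param members Sample identifiers forming the current cohort (default all
#'   samples in `pair`); at least 4 so each leave-one-out correlation is
#'   defined.
#' @return A data.frame with columns `sample_id`, `r_loo` (correlation
#'   without that sample) and `delta`, in `members` order.
#' @examples
#' pp <- pair_profile(c(1, 2, 3, 10), c(1, 2, 3, -5))
#' loo_correlation_deltas(pp)
#' @export
loo_correlation_deltas <- function(pair, members = NULL) {
  stopifnot(inherits(pair, "pair_profile"))
  if (is.null(members)) members <- pair$sample_ids
  idx <- match(members, pair$sample_ids)
  if (anyNA(idx))
    stop("lookup error: members not in pair profile: ",
         paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
  if (length(idx) < 4L)
    stop("sample-size error: need at least 4 members for leave-one-out deltas",
         call. = FALSE)
  res <- loo_correlations(pair$a_values[idx], pair$b_values[idx])
  data.frame(sample_id = pair$sample_ids[idx],
             r_loo = res$r_loo,
             delta = res$r_loo - res$r_full,
             stringsAsFactors = FALSE)
}

#' Greedy cohort partition maximizing a gene pair's positive correlation
#'
#' Implements the iterative cohort-splitting procedure: all samples start in
#' cohort 1; at each step the leave-one-out correlation of every cohort-1
#' sample is evaluated and the sample whose removal yields the maximal
#' increase in the pair's positive Pearson correlation is moved to cohort 2.
#' The loop stops when no removal increases the correlation (maximal delta
#' not exceeding `tol`) or cohort 1 has shrunk to `min_cohort` samples. The
#' procedure is one-pass greedy: removed samples are never re-admitted.
#'
#' The returned `r_final` is maximized by construction (selection-biased);
#' it must not be read as an unbiased estimate of the pair's correlation in
#' an independent cohort. The partition itself uses expression only — never
#' survival — so downstream survival comparisons are not circular.
#'
#' @param pair A [pair_profile()] (typically rank scores from
#'   [rank_transform()]; any real vectors are accepted).
#' @param min_cohort Minimum cohort-1 size, at least 3 (Pearson correlation
#'   needs 3 points). Default 3.
#' @param tie_rule How to break exact ties in the maximal delta:
#'   `"lowest-index"` (default) keeps the first such sample in input order,
#'   `"highest-index"` the last. Both are deterministic.
#' @param tol Absolute tolerance a delta must exceed to count as an increase
#'   (guards against float-noise-driven removals). Default `1e-12`.
#' @return A list of class `"partition_result"`: `cohort1` and `cohort2`
#'   (sample identifiers), `r_initial`, `r_final`, `trace` (a data.frame of
#'   removal steps: `step`, `sample_id`, `r_before`, `r_after`),
#'   `min_cohort`, `tie_rule`, and a `note` flagging the selection bias.
#' @examples
#' set.seed(1)
#' a <- rnorm(20); b <- a + rnorm(20, sd = 0.3)
#' greedy_partition(pair_profile(a, b))
#' @export
greedy_partition <- function(pair, min_cohort = 3L,
                             tie_rule = c("lowest-index", "highest-index"),
                             tol = 1e-12) {
  stopifnot(inherits(pair, "pair_profile"))
  tie_rule <- match.arg(tie_rule)
  if (length(min_cohort) != 1L || !is.numeric(min_cohort) ||
      min_cohort != round(min_cohort) || min_cohort < 3)
    stop("'min_cohort' must be a single integer >= 3", call. = FALSE)
  min_cohort <- as.integer(min_cohort)
  n <- length(pair$sample_ids)
  if (n < min_cohort)
    stop("sample-size error: pair has ", n, " samples, fewer than min_cohort = ",
         min_cohort, call. = FALSE)

  members <- seq_len(n)   # indices into pair vectors, input order preserved
  removed <- integer(0)
  x <- pair$a_values
  y <- pair$b_values
  r_initial <- pearson_r(x, y)
  r_current <- r_initial
  trace <- list()
  step <- 0L

  while (length(members) > min_cohort) {
    res <- loo_correlations(x[members], y[members])
    r_current <- res$r_full
    deltas <- res$r_loo - r_current
    best <- max(deltas)
    if (!is.finite(best) || best <= tol) break
    hit <- which(deltas == best)
    pick <- if (tie_rule == "lowest-index") hit[1L] else hit[length(hit)]
    step <- step + 1L
    trace[[step]] <- data.frame(step = step,
                                sample_id = pair$sample_ids[members[pick]],
                                r_before = r_current,
                                r_after = res$r_loo[pick],
                                stringsAsFactors = FALSE)
    removed <- c(removed, members[pick])
    members <- members[-pick]
    r_current <- res$r_loo[pick]
  }

  trace <- if (step > 0L) do.call(rbind, trace)
           else data.frame(step = integer(0), sample_id = character(0),
                           r_before = numeric(0), r_after = numeric(0),
                           stringsAsFactors = FALSE)
  structure(
    list(cohort1 = pair$sample_ids[sort(members)],
         cohort2 = pair$sample_ids[removed],
         r_initial = r_initial,
         r_final = r_current,
         trace = trace,
         min_cohort = min_cohort,
         tie_rule = tie_rule,
         note = paste("cohort-1 correlation is maximized by construction",
                      "(selection-biased); do not read r_final as an unbiased",
                      "estimate")),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Greedy correlation-maximizing partition\n")
  cat(sprintf("  cohort 1 (positive-correlation): %d samples\n", length(x$cohort1)))
  cat(sprintf("  cohort 2 (removed):              %d samples\n", length(x$cohort2)))
  cat(sprintf("  Pearson r: %.4f (all samples) -> %.4f (cohort 1, selection-biased)\n",
              x$r_initial, x$r_final))
  cat(sprintf("  removals: %d; min_cohort = %d; tie rule: %s\n",
              nrow(x$trace), x$min_cohort, x$tie_rule))
  invisible(x)
}

#' Serialize a partition result to delimited reports
#'
#' Writes a per-sample report (`sample_id`, `cohort`, `removal_step`,
#' `r_after`) and returns the machine-readable run summary. `removal_step`
#' and `r_after` are `NA` for samples retained in cohort 1.
#'
#' @param partition A [greedy_partition()] result.
#' @param path Output path for the tab-delimited per-sample report.
#' @return Invisibly, a list summarizing the run (`r_initial`, `r_final`,
#'   `n1`, `n2`, `min_cohort`, `tie_rule`, `note`).
#' @export
write_partition_report <- function(partition, path) {
  stopifnot(inherits(partition, "partition_result"))
  all_ids <- c(partition$cohort1, partition$cohort2)
  rep_df <- data.frame(sample_id = all_ids,
                       cohort = rep(c(1L, 2L), c(length(partition$cohort1),
                                                 length(partition$cohort2))),
                       stringsAsFactors = FALSE)
  tr <- partition$trace
  rep_df$removal_step <- tr$step[match(rep_df$sample_id, tr$sample_id)]
  rep_df$r_after <- tr$r_after[match(rep_df$sample_id, tr$sample_id)]
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(rep_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(r_initial = partition$r_initial,
                 r_final = partition$r_final,
                 n1 = length(partition$cohort1),
                 n2 = length(partition$cohort2),
                 min_cohort = partition$min_cohort,
                 tie_rule = partition$tie_rule,
                 note = partition$note))
}
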