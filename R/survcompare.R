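#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator of the survival function under right
#' censoring. Ties between censoring and events at the same time use the
#' standard convention that censoring happens after the events, so censored
#' subjects still count as at risk at that time.
#'
#' @param table Survival data.frame with columns `sample_id`, `time` (>= 0)
#'   and `event` (0/1).
#' @return An object of class `"km_curve"`: a data.frame with one row per
#'   distinct event time — `time`, `n_risk`, `n_event`, `survival` — plus
#'   attributes `n` (subjects) and `n_events` (total events). With no events
#'   the curve is empty and survival is constant at 1.
#' @examples
#' km_estimate(data.frame(sample_id = 1:4, time = 1:4, event = 1))
#' @export
km_estimate <- function(table) {
  validate_survival_table(table)
  time <- table$time
  event <- table$event
  te <- sort(unique(time[event == 1]))
  n_risk <- vapply(te, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(te, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = te, n_risk = n_risk, n_event = n_event,
                    survival = surv)
  rownames(out) <- NULL
  structure(out, class = c("km_curve", "data.frame"),
            n = nrow(table), n_events = sum(event))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, %d distinct event times\n",
              attr(x, "n"), attr(x, "n_events"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot one or more Kaplan-Meier curves
#'
#' Step-function survival curves starting at S(0) = 1.
#'
#' @param x A `"km_curve"` or a list of them (named for the legend).
#' @param col Line colors, recycled.
#' @param xlab,ylab,main Usual graphics labels.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.km_curve <- function(x, col = c("#B2182B", "#2166AC"),
                          xlab = "Time", ylab = "Survival probability",
                          main = "Kaplan-Meier estimate", ...) {
  curves <- if (inherits(x, "km_curve")) list(x) else x
  xmax <- max(1, unlist(lapply(curves, function(k) k$time)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, main = main, ...)
  col <- rep_len(col, length(curves))
  for (i in seq_along(curves)) {
    k <- curves[[i]]
    graphics::lines(stats::stepfun(k$time, c(1, k$survival)), col = col[i],
                    do.points = FALSE, lwd = 2)
  }
  if (!is.null(names(curves)) && length(curves) > 1L)
    graphics::legend("topright", legend = names(curves),
                     col = col[seq_along(curves)], lwd = 2, bty = "n")
  invisible(x)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' At each distinct pooled event time a 2x2 table of events against group is
#' formed; the test compares the observed event count of group A with its
#' expectation under the hypergeometric null and sums the variance across
#' times, giving a chi-square statistic on 1 degree of freedom.
#'
#' @param table_a,table_b Survival data.frames (columns `sample_id`, `time`,
#'   `event`) for the two groups; sample ids must be disjoint and at least
#'   one event must be observed overall.
#' @return A list of class `"logrank_result"`: `statistic`, `df`, `p_value`,
#'   `observed` and `expected` (length-2, groups A and B), `n` (group sizes).
#' @examples
#' a <- data.frame(sample_id = paste0("a", 1:4), time = c(1, 3, 5, 7), event = 1)
#' b <- data.frame(sample_id = paste0("b", 1:4), time = c(2, 4, 6, 8), event = 1)
#' logrank(a, b)
#' @export
logrank <- function(table_a, table_b) {
  validate_survival_table(table_a)
  validate_survival_table(table_b)
  if (length(intersect(table_a$sample_id, table_b$sample_id)))
    stop("input error: groups share sample ids", call. = FALSE)
  time <- c(table_a$time, table_b$time)
  event <- c(table_a$event, table_b$event)
  grp1 <- rep(c(TRUE, FALSE), c(nrow(table_a), nrow(table_b)))
  if (sum(event) == 0)
    stop("degenerate-test error: no events observed in either group",
         call. = FALSE)
  te <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in te) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  d_tot <- sum(event)
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  structure(
    list(statistic = stat, df = 1L,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         observed = c(o1, d_tot - o1),
         expected = c(e1, d_tot - e1),
         n = c(nrow(table_a), nrow(table_b))),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Two-group log-rank (Mantel-Cox) test\n")
  df <- data.frame(N = x$n, Observed = x$observed,
                   Expected = round(x$expected, 2),
                   row.names = c("group A", "group B"))
  print(df)
  cat(sprintf("  chi-square = %.3f on 1 df, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Compare survival between the two partition cohorts
#'
#' Labels the survival table with the cohorts of a [greedy_partition()]
#' result, estimates both Kaplan-Meier curves and runs the log-rank test.
#' Because the partition is driven by expression alone, the downstream
#' log-rank p-value is not invalidated by the selection step under the null
#' of no expression-survival association.
#'
#' @param partition A `"partition_result"`.
#' @param table Survival data.frame covering the partitioned samples.
#' @param allow_missing If `TRUE`, cohort samples absent from `table` are
#'   dropped (with accounting); otherwise their absence is a mapping error.
#' @return A list of class `"cohort_survival"`: `km1`, `km2` (curves for
#'   cohort 1 and 2), `logrank`, `n` and `events` per cohort, `dropped`
#'   (per-cohort counts of unmapped samples), and the partition's selection
#'   `note`.
#' @export
compare_partition_survival <- function(partition, table, allow_missing = FALSE) {
  stopifnot(inherits(partition, "partition_result"))
  validate_survival_table(table)
  map_cohort <- function(ids, label) {
    present <- ids %in% table$sample_id
    if (!all(present) && !allow_missing)
      stop("mapping error: ", sum(!present), " ", label,
           " sample(s) absent from the survival table: ",
           paste(utils::head(ids[!present], 5L), collapse = ", "),
           call. = FALSE)
    list(table = table[match(ids[present], table$sample_id), , drop = FALSE],
         dropped = sum(!present))
  }
  c1 <- map_cohort(partition$cohort1, "cohort-1")
  c2 <- map_cohort(partition$cohort2, "cohort-2")
  if (nrow(c2$table) == 0L)
    stop("degenerate-test error: cohort 2 is empty, nothing to compare",
         call. = FALSE)
  if (nrow(c1$table) == 0L)
    stop("degenerate-test error: cohort 1 is empty after mapping", call. = FALSE)
  lr <- logrank(c1$table, c2$table)
  structure(
    list(km1 = km_estimate(c1$table),
         km2 = km_estimate(c2$table),
         logrank = lr,
         n = c(cohort1 = nrow(c1$table), cohort2 = nrow(c2$table)),
         events = c(cohort1 = sum(c1$table$event), cohort2 = sum(c2$table$event)),
         dropped = c(cohort1 = c1$dropped, cohort2 = c2$dropped),
         note = partition$note),
    class = "cohort_survival"
  )
}

#' @export
print.cohort_survival <- function(x, ...) {
  cat("Cohort survival comparison\n")
  cat(sprintf("  cohort 1: n = %d, events = %d\n", x$n[1], x$events[1]))
  cat(sprintf("  cohort 2: n = %d, events = %d\n", x$n[2], x$events[2]))
  if (any(x$dropped > 0))
    cat(sprintf("  dropped (no survival record): %d / %d\n",
                x$dropped[1], x$dropped[2]))
  cat(sprintf("  log-rank chi-square = %.3f, p = %.4g\n",
              x$logrank$statistic, x$logrank$p_value))
  cat("  note:", x$note, "\n")
  invisible(x)
}
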