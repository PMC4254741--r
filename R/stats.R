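#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric probabilities of
#' every table whose probability does not exceed that of the observed table
#' (the conventional "small-p" two-sided rule). A table with a zero margin
#' carries no information and returns p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome / no outcome), or a length-4 vector `(a, b, c, d)`
#'   filling the table by row.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (any(table < 0) || any(table != round(table))) stop("counts must be non-negative integers")
  if (sum(table) == 0) stop("empty table")
  a <- table[1, 1]
  m <- sum(table[1, ])   # row 1 margin
  n2 <- sum(table[2, ])  # row 2 margin
  k <- sum(table[, 1])   # column 1 margin
  if (m == 0 || n2 == 0 || k == 0 || sum(table[, 2]) == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Attrition summary over a set of automation records
#'
#' Per-step rejection counts and fractions of the total processed
#' population, cumulative percentages of worms remaining after each step,
#' and the overall success fraction. Counts conserve: successes plus the
#' per-step rejections partition the population.
#'
#' @param records list of `automation_record` from [run_worm_cycle()].
#' @return A `run_summary`: `n_processed`, `n_success`, `success_fraction`,
#'   `rejections` (named counts), `rejection_fractions`,
#'   `remaining_percent` (after each step), and `durations` (per-step mean
#'   and SD of the simulated durations).
#' @export
attrition_summary <- function(records) {
  if (length(records) == 0) stop("no records")
  n <- length(records)
  outcome <- vapply(records, `[[`, "", "outcome")
  step <- vapply(records, `[[`, "", "step_reached")
  rej <- vapply(step_names, function(s) sum(outcome == "flushed" & step == s),
                integer(1))
  n_success <- sum(outcome == "success")
  stopifnot(n_success + sum(rej) == n)
  remaining <- 100 * (1 - cumsum(rej) / n)
  dur <- sapply(paste0("step", 1:4), function(s) {
    d <- vapply(records, function(r) {
      v <- tryCatch(r$durations[[s]], error = function(e) NULL)
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    c(mean = mean(d, na.rm = TRUE), sd = sd(d, na.rm = TRUE))
  })
  structure(list(n_processed = n, n_success = n_success,
                 success_fraction = n_success / n,
                 rejections = rej, rejection_fractions = rej / n,
                 remaining_percent = setNames(remaining, step_names),
                 durations = dur),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> %d processed, %d successes (%.1f%%)\n",
              x$n_processed, x$n_success, 100 * x$success_fraction))
  for (s in names(x$rejections))
    cat(sprintf("  flushed at %-12s %4d (%.1f%%) -> %.1f%% remaining\n", s,
                x$rejections[[s]], 100 * x$rejection_fractions[[s]],
                x$remaining_percent[[s]]))
  invisible(x)
}

#' Compare reconnection rates between two groups
#'
#' Rates are successes/total exactly; the two-sided p-value comes from
#' [fisher_exact_2x2()]; significance is flagged at alpha = 0.05. Display
#' rounding follows the field convention: integer percent rates, two-decimal
#' p.
#'
#' @param group_a,group_b `(successes, total)` per group.
#' @param labels group names for the report.
#' @return A `reconnection_report` with `rates`, `counts`, `p_value`,
#'   `significant`.
#' @export
summarize_reconnection <- function(group_a, group_b,
                                   labels = c("manual", "on_chip")) {
  stopifnot(length(group_a) == 2, length(group_b) == 2,
            group_a[1] <= group_a[2], group_b[1] <= group_b[2])
  if (group_a[2] == 0 || group_b[2] == 0) stop("group totals must be > 0")
  tab <- matrix(c(group_a[1], group_a[2] - group_a[1],
                  group_b[1], group_b[2] - group_b[1]), 2, 2, byrow = TRUE)
  p <- fisher_exact_2x2(tab)
  structure(list(
    counts = setNames(list(group_a, group_b), labels),
    rates = setNames(c(group_a[1] / group_a[2], group_b[1] / group_b[2]), labels),
    p_value = p, significant = p < 0.05), class = "reconnection_report")
}

#' @export
print.reconnection_report <- function(x, ...) {
  for (g in names(x$rates))
    cat(sprintf("  %-10s %d/%d = %d%%\n", g, x$counts[[g]][1], x$counts[[g]][2],
                round(100 * x$rates[[g]])))
  cat(sprintf("  p = %.2f (Fisher's exact), %ssignificant at 0.05\n",
              round(x$p_value, 2), if (x$significant) "" else "not "))
  invisible(x)
}
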