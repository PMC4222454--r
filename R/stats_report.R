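#' Summarise per-cell particle counts for one condition and time point
#'
#' Per-cell totals are the unit of analysis in uptake experiments; each
#' condition/time point is reported as mean ± SEM over its cells.
#'
#' @param counts integer vector of per-cell particle counts.
#' @param condition condition label.
#' @param time_h incubation time in hours.
#' @return a `condition_summary` one-row data frame: `condition`, `time_h`,
#'   `n_cells`, `mean_count`, `sd_count`, `sem_count` (sample sd with n-1
#'   denominator over sqrt(n); `NA` for a single cell, where the SEM is
#'   undefined).
#' @examples
#' summarize_condition(c(1, 2, 3, 4, 5), "silica 3h", 3)  # mean 3, SEM 0.7071
#' @export
summarize_condition <- function(counts, condition = "cond", time_h = NA_real_) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) stop("no per-cell counts supplied")
  n <- length(counts)
  s <- if (n > 1) stats::sd(counts) else NA_real_
  out <- data.frame(condition = condition, time_h = time_h, n_cells = n,
                    mean_count = mean(counts), sd_count = s,
                    sem_count = if (n > 1) s / sqrt(n) else NA_real_)
  class(out) <- c("condition_summary", class(out))
  out
}

#' Significance stars at the conventional thresholds
#'
#' `"**"` for p < 0.01 (highly statistically different), `"*"` for
#' 0.01 <= p < 0.05 (statistically different), `"ns"` otherwise.
#'
#' @param p p-value(s).
#' @return character vector of `"ns"`, `"*"`, `"**"`.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
}

#' Unpaired two-sample Student's t-test on per-cell counts
#'
#' Classical pooled-variance Student's t-test (two-sided) between two groups
#' of cells, with Welch's correction available behind a flag. Two degenerate
#' zero-variance groups with equal means are reported as t = 0, p = 1 by
#' convention.
#'
#' @param a,b numeric vectors of per-cell counts (each of length >= 2).
#' @param welch use Welch's unequal-variance test instead (default FALSE).
#' @return a `pairwise_test` list: `t_statistic`, `df`, `p_value`, `stars`,
#'   `mean_a`, `mean_b`, `welch`.
#' @examples
#' t_test_unpaired(c(110, 120, 95, 130), c(210, 260, 240, 280))
#' @export
t_test_unpaired <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(a) + length(b) - 2),
                 p.value = 1)
    } else {
      tt <- list(statistic = c(t = sign(mean(a) - mean(b)) * Inf),
                 parameter = c(df = length(a) + length(b) - 2), p.value = 0)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = !welch)
    tt <- list(statistic = ht$statistic, parameter = ht$parameter,
               p.value = ht$p.value)
  }
  structure(list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, stars = significance_stars(tt$p.value),
                 mean_a = mean(a), mean_b = mean(b), welch = welch),
            class = "pairwise_test")
}

#' @export
print.pairwise_test <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4g (df %.4g), p = %.4g [%s]; means %.4g vs %.4g\n",
              if (x$welch) "Welch" else "Student", x$t_statistic, x$df,
              x$p_value, x$stars, x$mean_a, x$mean_b))
  invisible(x)
}

#' Summarise a per-cell count table across conditions and time points
#'
#' @param counts data frame with columns `condition`, `time_h`, `count`
#'   (e.g. from [generate_kinetics_dataset()] or collected reports).
#' @return data frame of one [summarize_condition()] row per
#'   condition/time combination, ordered by condition then time.
#' @export
summarize_design <- function(counts) {
  stopifnot(all(c("condition", "time_h", "count") %in% names(counts)))
  grp <- split(counts, list(counts$condition, counts$time_h), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g)
    summarize_condition(g$count, g$condition[1], g$time_h[1])))
  out <- out[order(out$condition, out$time_h), ]
  rownames(out) <- NULL
  out
}

#' Bar chart of mean ± SEM per-cell counts over time
#'
#' @param summaries output of [summarize_design()].
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot_uptake_kinetics <- function(summaries, ...) {
  m <- tapply(summaries$mean_count, list(summaries$condition, summaries$time_h),
              identity)
  s <- tapply(summaries$sem_count, list(summaries$condition, summaries$time_h),
              identity)
  ylim <- c(0, 1.15 * max(m + ifelse(is.na(s), 0, s)))
  bp <- graphics::barplot(m, beside = TRUE, ylim = ylim,
                          legend.text = rownames(m),
                          xlab = "incubation time (h)",
                          ylab = "particles per cell (mean ± SEM)", ...)
  ok <- !is.na(s)
  graphics::arrows(bp[ok], (m - s)[ok], bp[ok], (m + s)[ok],
                   angle = 90, code = 3, length = 0.04)
  invisible(bp)
}
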