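# ROI summaries and the comparison procedures: per-direction D* means
# with SEM, paired t-tests, percent-change effects.

#' Mean of a scalar map over an ROI
#'
#' Arithmetic mean over masked voxels, excluding NA (invalid fits).
#'
#' @param map numeric matrix/array.
#' @param mask logical array of the same shape.
#' @return Scalar mean.
#' @export
roi_mean <- function(map, mask) {
  stopifnot(identical(dim(map), dim(mask)))
  v <- map[mask]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty ROI (no valid voxels in mask)",
                            call. = FALSE)
  mean(v)
}

#' ROI summary across subjects
#'
#' @param per_subject_means numeric vector, one ROI mean per subject.
#' @param roi_name label.
#' @return Object of class `roi_stats` with mean and SEM
#'   (sd / sqrt(n); n >= 2 required for SEM, else NA).
#' @export
roi_stats <- function(per_subject_means, roi_name = "roi") {
  n <- length(per_subject_means)
  sem <- if (n >= 2) stats::sd(per_subject_means) / sqrt(n) else NA_real_
  structure(list(roi_name = roi_name, n_subjects = n,
                 per_subject_means = per_subject_means,
                 mean = mean(per_subject_means), sem = sem),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("%s: mean %.4g (SEM %.2g), n = %d\n",
              x$roi_name, x$mean, x$sem, x$n_subjects))
  invisible(x)
}

#' Paired t-test
#'
#' Classical paired t statistic t = mean(d) / (sd(d)/sqrt(n)) with
#' n - 1 degrees of freedom, d = a - b. Two-sided by default; the
#' one-sided alternative tests mean(d) > 0.
#'
#' @param a,b per-subject values, equal length n >= 2.
#' @param alternative "two.sided" (default) or "greater".
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate` (TRUE
#'   when the difference variance is zero, in which case t and p are NA
#'   unless all differences are zero, giving t = 0, p = 1).
#' @examples
#' paired_t(c(2, 3, 4), c(1, 1, 1))  # t = 3.464, p = 0.074
#' @export
paired_t <- function(a, b, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("a and b must have equal length",
                                   call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0,
                  degenerate = TRUE))
    }
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (sdd / sqrt(n))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(t), df = n - 1),
    greater = stats::pt(t, df = n - 1, lower.tail = FALSE)
  )
  list(t = t, df = n - 1L, p = p, mean_diff = mean(d), degenerate = FALSE)
}

#' Percent change from baseline
#'
#' 100 * (post - baseline) / baseline.
#'
#' @param baseline reference value (non-zero).
#' @param post comparison value.
#' @return Percent change.
#' @examples
#' percent_change(354, 519)  # 46.6 (heart-rate example)
#' @export
percent_change <- function(baseline, post) {
  if (any(baseline == 0)) stop("baseline must be non-zero", call. = FALSE)
  100 * (post - baseline) / baseline
}

#' Assemble a results table
#'
#' Long-format results table (one row per ROI/direction/scenario cell)
#' suitable for CSV export.
#'
#' @param rows list of named lists with fields roi, direction, scenario,
#'   mean, sem, t, p, n (missing fields become NA).
#' @return data.frame with those columns.
#' @export
results_table <- function(rows) {
  cols <- c("roi", "direction", "scenario", "mean", "sem", "t", "p", "n")
  do.call(rbind, lapply(rows, function(r) {
    r <- r[cols]
    names(r) <- cols
    r[vapply(r, is.null, TRUE)] <- NA
    as.data.frame(r)
  }))
}
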