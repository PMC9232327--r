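#' Two-group summary of a metric
#'
#' Sample mean, sample SD (n-1 denominator) and size per group, plus the
#' signed mean difference `mean_A - mean_B`.
#'
#' @param values_by_group named list with numeric elements `A` and `B`,
#'   each of length >= 2.
#' @param metric optional metric id carried through.
#' @return List with `summary` (data.frame: metric, group, mean, sd, n)
#'   and `difference` (mean_A - mean_B).
#' @export
group_summary <- function(values_by_group, metric = NA_character_) {
  for (g in c("A", "B")) {
    v <- values_by_group[[g]]
    if (is.null(v) || length(v) < 2L) {
      stop_invalid("group ", g, " needs at least 2 values")
    }
  }
  a <- values_by_group$A
  b <- values_by_group$B
  list(
    summary = data.frame(
      metric = metric, group = c("A", "B"),
      mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b)),
      n = c(length(a), length(b)), stringsAsFactors = FALSE
    ),
    difference = mean(a) - mean(b)
  )
}

#' Independent-samples t-test with significance flags
#'
#' Two-sided independent-samples t-test between two groups, Student's
#' pooled-variance variant by default (Welch selectable). Flags follow the
#' conventional thresholds: `significant_05` for p < 0.05 and
#' `significant_01` for p < 0.01 (very significant). If both groups have
#' zero variance and equal means the statistic is undefined; the result is
#' reported non-significant with `t = NA` and a warning.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @param metric optional metric id carried through.
#' @return A one-row data.frame: `metric`, `t`, `df`, `p`,
#'   `significant_05`, `significant_01`.
#' @export
independent_t_test <- function(a, b, variant = c("student", "welch"),
                               metric = NA_character_) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) {
    stop_invalid("each group needs at least 2 values")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      warning("zero variance in both groups with equal means: t undefined, reported non-significant",
              call. = FALSE)
      return(data.frame(metric = metric, t = NA_real_, df = NA_real_,
                        p = NA_real_, significant_05 = FALSE,
                        significant_01 = FALSE, stringsAsFactors = FALSE))
    }
  }
  fit <- t.test(a, b, var.equal = (variant == "student"))
  p <- fit$p.value
  data.frame(
    metric = metric, t = unname(fit$statistic), df = unname(fit$parameter),
    p = p, significant_05 = p < 0.05, significant_01 = p < 0.01,
    stringsAsFactors = FALSE
  )
}

#' Grade an absolute correlation
#'
#' Maps `|r|` to a qualitative grade using configurable band edges:
#' below the first edge `none`, then `weak`, `moderate`, `strong`.
#'
#' @param r correlation coefficient.
#' @param bands increasing length-3 numeric thresholds on `|r|`.
#' @return One of `"none"`, `"weak"`, `"moderate"`, `"strong"`.
#' @export
correlation_grade <- function(r, bands = c(0.1, 0.3, 0.7)) {
  stopifnot(length(bands) == 3L, !is.unsorted(bands))
  c("none", "weak", "moderate", "strong")[
    findInterval(abs(r), bands) + 1L
  ]
}

#' Pearson correlation with grade
#'
#' Pearson product-moment correlation with a two-sided p value and a
#' qualitative grade from [correlation_grade()].
#'
#' @param x,y paired numeric vectors, length >= 3, nonzero variance.
#' @param bands grade band edges on `|r|`.
#' @param pair optional variable-pair label carried through.
#' @return A one-row data.frame: `pair`, `r`, `p`, `grade`.
#' @export
pearson_correlation <- function(x, y, bands = c(0.1, 0.3, 0.7),
                                pair = NA_character_) {
  if (length(x) != length(y)) stop_invalid("`x` and `y` must be paired")
  if (length(x) < 3L) stop_invalid("correlation needs at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_invalid("zero variance: correlation undefined")
  }
  fit <- cor.test(x, y, method = "pearson")
  r <- unname(fit$estimate)
  data.frame(pair = pair, r = r, p = fit$p.value,
             grade = correlation_grade(r, bands), stringsAsFactors = FALSE)
}

#' Correlation panel: track length vs standardized EMG
#'
#' All three pairwise Pearson correlations among per-subject track length,
#' standardized RMS and standardized iEMG, computed within each group.
#' Undefined correlations (a constant metric within a group) are surfaced
#' per pair as `NA` rows with a warning rather than aborting the panel.
#'
#' @param data data.frame with columns `group`, `track_length`, `rms_pct`,
#'   `iemg_pct` (one row per subject).
#' @param bands grade band edges on `|r|`.
#' @return A data.frame with one row per group x pair: `group`, `pair`,
#'   `r`, `p`, `grade`.
#' @export
correlation_panel <- function(data, bands = c(0.1, 0.3, 0.7)) {
  needed <- c("group", "track_length", "rms_pct", "iemg_pct")
  if (!all(needed %in% names(data))) {
    stop_invalid("`data` must have columns ", paste(needed, collapse = ", "))
  }
  pairs <- list(
    c("track_length", "rms_pct"),
    c("track_length", "iemg_pct"),
    c("rms_pct", "iemg_pct")
  )
  rows <- list()
  for (g in unique(data$group)) {
    d <- data[data$group == g, ]
    for (pr in pairs) {
      label <- paste(pr, collapse = "~")
      res <- tryCatch(
        pearson_correlation(d[[pr[1]]], d[[pr[2]]], bands, pair = label),
        error = function(e) {
          warning(sprintf("group %s, %s: %s", g, label, conditionMessage(e)),
                  call. = FALSE)
          data.frame(pair = label, r = NA_real_, p = NA_real_,
                     grade = NA_character_, stringsAsFactors = FALSE)
        }
      )
      rows[[length(rows) + 1L]] <- cbind(group = g, res)
    }
  }
  do.call(rbind, rows)
}
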