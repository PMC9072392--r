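# Group-level comparison of per-ROI feature distributions: classical
# equal-variance two-sample t-tests with significance stars, box summaries,
# and an optional global one-way ANOVA.

#' Significance stars for a p-value
#'
#' Maps a p-value to the star labels used in the figure captions of the
#' underlying study: \code{p < 0.1} gives \code{"*"}, \code{p < 0.01}
#' \code{"**"}, \code{p < 0.001} \code{"***"}, otherwise \code{""}. Note
#' the deliberately permissive one-star threshold of 0.1.
#'
#' @param p p-value(s) in \code{[0, 1]}.
#' @param thresholds decreasing vector of the three star thresholds.
#' @return character vector of star labels.
#' @examples
#' star_label(c(0.5, 0.05, 0.005, 0.0005))
#' @export
star_label <- function(p, thresholds = c(0.1, 0.01, 0.001)) {
  stopifnot(length(thresholds) == 3, all(diff(thresholds) < 0))
  vapply(p, function(pv) {
    if (is.na(pv)) return(NA_character_)
    if (pv < thresholds[3]) "***"
    else if (pv < thresholds[2]) "**"
    else if (pv < thresholds[1]) "*"
    else ""
  }, character(1))
}

#' Compare one feature between two groups
#'
#' Classical unpaired two-tailed Student's t-test with pooled (equal)
#' variance on the per-ROI values of \code{feature_name}. Missing values are
#' dropped and their count recorded. When both groups are constant and
#' equal, the test statistic is defined as 0 (no difference).
#'
#' @param records data frame with a \code{group} column and one column per
#'   feature (e.g. the \code{features} table of \code{\link{run_pipeline}}).
#' @param feature_name name of the feature column to compare.
#' @param group_a,group_b the two group labels.
#' @param star_thresholds passed to \code{\link{star_label}}.
#' @return An object of class \code{group_comparison}: a one-row data frame
#'   with \code{feature}, \code{group_a}, \code{group_b}, \code{n_a},
#'   \code{n_b}, \code{n_dropped}, \code{t_statistic}, \code{df},
#'   \code{p_value}, \code{stars}.
#' @export
compare_groups <- function(records, feature_name, group_a, group_b,
                           star_thresholds = c(0.1, 0.01, 0.001)) {
  if (!feature_name %in% names(records))
    stop("unknown feature: ", feature_name, call. = FALSE)
  if (!"group" %in% names(records))
    stop("'records' needs a 'group' column", call. = FALSE)
  xa <- records[[feature_name]][records$group == group_a]
  xb <- records[[feature_name]][records$group == group_b]
  n_dropped <- sum(!is.finite(xa)) + sum(!is.finite(xb))
  xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
  if (length(xa) < 2)
    stop(sprintf("group '%s' has fewer than 2 observations", group_a),
         call. = FALSE)
  if (length(xb) < 2)
    stop(sprintf("group '%s' has fewer than 2 observations", group_b),
         call. = FALSE)
  df <- length(xa) + length(xb) - 2
  if (sd(xa) == 0 && sd(xb) == 0 && mean(xa) == mean(xb)) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(xa, xb, var.equal = TRUE,
                        alternative = "two.sided")
  }
  out <- data.frame(feature = feature_name,
                    group_a = group_a, group_b = group_b,
                    n_a = length(xa), n_b = length(xb),
                    n_dropped = n_dropped,
                    t_statistic = unname(tt$statistic),
                    df = df,
                    p_value = unname(tt$p.value),
                    stars = star_label(unname(tt$p.value), star_thresholds),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Global one-way ANOVA across all groups
#'
#' Optional companion to the pairwise t-tests: a one-way fixed-effects
#' F-test of equality of the group means of one feature.
#'
#' @inheritParams compare_groups
#' @return list with \code{f_statistic}, \code{df1}, \code{df2},
#'   \code{p_value}.
#' @export
anova_groups <- function(records, feature_name) {
  x <- records[[feature_name]]
  g <- factor(records$group)
  keep <- is.finite(x)
  fit <- stats::oneway.test(x[keep] ~ g[keep], var.equal = TRUE)
  list(f_statistic = unname(fit$statistic),
       df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]),
       p_value = unname(fit$p.value))
}

#' Box summary of one feature distribution
#'
#' Quartiles by the linear-interpolation convention (R quantile type 7),
#' whiskers at 1.5 times the interquartile range beyond the quartiles,
#' clipped to the data range — the statistics drawn by the beeswarm box
#' plots of the study.
#'
#' @param values numeric vector; missing values are dropped, at least one
#'   finite value is required.
#' @return An object of class \code{box_summary}: list with \code{median},
#'   \code{q25}, \code{q75}, \code{whisker_low}, \code{whisker_high},
#'   \code{n}.
#' @examples
#' unlist(box_summary(c(1, 2, 3, 4, 5))[c("q25", "median", "q75")])
#' @export
box_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0)
    stop("no finite values to summarize", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  structure(list(median = q[2], q25 = q[1], q75 = q[3],
                 whisker_low = max(q[1] - 1.5 * iqr, min(values)),
                 whisker_high = min(q[3] + 1.5 * iqr, max(values)),
                 n = length(values)),
            class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf(
    "<box_summary> median %.4g [q25 %.4g, q75 %.4g], whiskers [%.4g, %.4g], n = %d\n",
    x$median, x$q25, x$q75, x$whisker_low, x$whisker_high, x$n))
  invisible(x)
}

#' All configured pairwise comparisons for a feature table
#'
#' Runs \code{\link{compare_groups}} for every feature, either each group
#' against the control group (\code{mode = "vs-control"}, the study's
#' reading) or all pairs.
#'
#' @inheritParams compare_groups
#' @param features character vector of feature column names.
#' @param mode \code{"vs-control"} or \code{"all-pairs"}.
#' @param control control group label; default: first group encountered.
#' @param strict if \code{FALSE}, a pair that cannot be tested (fewer than
#'   two finite values in a group, e.g. all-degenerate ROIs) yields a row
#'   with missing statistics instead of an error.
#' @return data frame of \code{group_comparison} rows.
#' @export
compare_all_groups <- function(records, features,
                               mode = c("vs-control", "all-pairs"),
                               control = NULL,
                               star_thresholds = c(0.1, 0.01, 0.001),
                               strict = TRUE) {
  mode <- match.arg(mode)
  groups <- unique(records$group)
  control <- control %||% groups[1]
  pairs <- if (mode == "vs-control") {
    others <- setdiff(groups, control)
    if (length(others) == 0) stop("only one group present", call. = FALSE)
    cbind(control, others)
  } else {
    t(utils::combn(groups, 2))
  }
  rows <- list()
  for (f in features) {
    for (k in seq_len(nrow(pairs))) {
      row <- if (strict) {
        compare_groups(records, f, pairs[k, 1], pairs[k, 2],
                       star_thresholds = star_thresholds)
      } else {
        tryCatch(
          compare_groups(records, f, pairs[k, 1], pairs[k, 2],
                         star_thresholds = star_thresholds),
          error = function(e) data.frame(
            feature = f, group_a = pairs[k, 1], group_b = pairs[k, 2],
            n_a = NA_integer_, n_b = NA_integer_, n_dropped = NA_integer_,
            t_statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
            stars = NA_character_, stringsAsFactors = FALSE))
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}
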