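#' One-way analysis of variance
#'
#' Classic fixed-effects F test computed from sums of squares:
#' `F = (SS_between / df_between) / (SS_within / df_within)` with
#' `df_between = groups - 1`, `df_within = N - groups`, and the p value from
#' the upper tail of the F distribution. Implemented directly so that the
#' degenerate cases are reported explicitly: zero within-group variance with
#' non-zero between-group variance yields `p = 0` with a flag, and fully
#' constant data yields an undefined F with a flag.
#'
#' @param groups list of numeric vectors, one per group; at least two groups
#'   with at least two values each.
#' @return An object of class `anova1` with fields `F`, `df_between`,
#'   `df_within`, `p`, `means`, `sds`, `n`, `flag` (`"ok"`,
#'   `"zero-within-variance"` or `"degenerate"`).
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3, df (2, 6)
#' @export
one_way_anova <- function(groups) {
  check_that(
    "at least two groups required" = is.list(groups) && length(groups) >= 2,
    "each group needs at least two values" =
      all(vapply(groups, length, integer(1)) >= 2),
    "group values must be finite numerics" =
      all(vapply(groups, function(g) is.numeric(g) && all(is.finite(g)),
                 logical(1)))
  )
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(k),
                          function(i) sum((groups[[i]] - means[i])^2),
                          numeric(1)))
  df_b <- k - 1L
  df_w <- N - k
  if (ss_within == 0) {
    if (ss_between == 0) {
      res <- list(F = NA_real_, p = NA_real_, flag = "degenerate")
    } else {
      res <- list(F = Inf, p = 0, flag = "zero-within-variance")
    }
  } else {
    Fstat <- (ss_between / df_b) / (ss_within / df_w)
    res <- list(F = Fstat,
                p = stats::pf(Fstat, df_b, df_w, lower.tail = FALSE),
                flag = "ok")
  }
  structure(
    list(F = res$F, df_between = df_b, df_within = df_w, p = res$p,
         means = means, sds = sds, n = n, flag = res$flag),
    class = "anova1"
  )
}

#' @export
print.anova1 <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %s, p = %s%s\n",
              x$df_between, x$df_within,
              if (is.na(x$F)) "NA" else format(x$F, digits = 4),
              if (is.na(x$p)) "NA" else format.pval(x$p, digits = 3),
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Select the EEG rhythms responsive to the time course
#'
#' Runs a one-way ANOVA across the time points on the per-subject mean MI
#' for every rhythm x condition combination, and selects the combinations
#' with `p < 0.05`. On the default synthetic fatigue trajectory the expected
#' selection is alpha1 in the task state by construction.
#'
#' @param mi_table data frame with columns `rhythm`, `condition`, `subject`,
#'   `time_point`, `mean_mi`, complete over all cells.
#' @param alpha significance level of the selection rule (default 0.05).
#' @return A data frame of class `rhythm_selection` with one row per rhythm
#'   x condition (`F`, `df_between`, `df_within`, `p`, `selected`), all
#'   combinations reported regardless of significance; the selected subset
#'   is also available via `attr(, "selected")`.
#' @export
select_rhythm <- function(mi_table, alpha = 0.05) {
  need <- c("rhythm", "condition", "subject", "time_point", "mean_mi")
  check_that(
    "mi_table must contain rhythm, condition, subject, time_point, mean_mi" =
      is.data.frame(mi_table) && all(need %in% names(mi_table)),
    "mean_mi must be complete" = all(is.finite(mi_table$mean_mi))
  )
  combos <- unique(mi_table[, c("rhythm", "condition")])
  tps <- unique(mi_table$time_point)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- mi_table[mi_table$rhythm == combos$rhythm[i] &
                      mi_table$condition == combos$condition[i], ]
    groups <- lapply(tps, function(tp) sub$mean_mi[sub$time_point == tp])
    if (any(vapply(groups, length, integer(1)) !=
              length(groups[[1]]))) {
      stop("incomplete mean-MI table for ", combos$rhythm[i], "/",
           combos$condition[i], call. = FALSE)
    }
    aov1 <- one_way_anova(groups)
    data.frame(rhythm = combos$rhythm[i], condition = combos$condition[i],
               F = aov1$F, df_between = aov1$df_between,
               df_within = aov1$df_within, p = aov1$p,
               selected = !is.na(aov1$p) && aov1$p < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "selected") <- out[out$selected, c("rhythm", "condition")]
  class(out) <- c("rhythm_selection", "data.frame")
  out
}
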