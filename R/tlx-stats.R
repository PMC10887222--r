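# Inferential statistics on the NASA-TLX ratings: one-way ANOVA across the
# three task block types (PW is excluded: it carries no task load), followed
# by Tukey's Honestly Significant Difference test on all class pairs.
# Implemented from the balanced one-way formulas (and the studentized-range
# quantile computed numerically) rather than via a model-fitting routine, so
# standard ANOVA fits remain an independent cross-check.

#' One-way ANOVA + Tukey HSD over TLX classes
#'
#' For each requested variable (and optionally the mean of the workload
#' variables), tests LL vs ML vs HL with a one-way ANOVA and, pairwise, with
#' Tukey's HSD: a pair differs significantly exactly when the absolute mean
#' difference exceeds the HSD threshold
#' `qtukey(1 - alpha, 3, N - 3) * sqrt(MSW / n)`. PW rows are dropped before
#' the analysis. The balanced design (equal per-class counts) is required;
#' unbalanced input falls back to Tukey-Kramer with a flag.
#'
#' @param tlx TLX tibble (rows = administrations) with `block_type`.
#' @param variables Variables to test.
#' @param include_mean Also test the mean of `variables` as `"mean"`.
#' @param alpha Significance level.
#' @return A `tlx_test_result`: tibble with one row per (variable, pair)
#'   carrying `F`, `p`, `hsd_threshold`, `diff`, `significant`, plus the
#'   per-variable ANOVA table in attribute `anova`.
#' @export
tlx_anova_tukey <- function(tlx,
                            variables = c("mental_demand", "temporal_demand",
                                          "effort", "frustration"),
                            include_mean = TRUE, alpha = 0.05) {
  d <- tlx[tlx$block_type != "PW", , drop = FALSE]
  groups <- c("LL", "ML", "HL")
  if (!all(d$block_type %in% groups)) stop("unexpected block type in TLX table")
  if (length(unique(d$block_type)) != 3) stop("need all three task classes")
  vars <- variables
  data_cols <- lapply(vars, function(v) as.numeric(d[[v]]))
  names(data_cols) <- vars
  if (include_mean) {
    data_cols$mean <- rowMeans(do.call(cbind, data_cols[variables]))
    vars <- c(vars, "mean")
  }
  g <- factor(d$block_type, levels = groups)
  n_g <- table(g)
  balanced <- length(unique(n_g)) == 1
  N <- length(g); k <- 3
  pairs <- list(c("LL", "ML"), c("ML", "HL"), c("LL", "HL"))
  anova_rows <- list(); pair_rows <- list()
  for (v in vars) {
    y <- data_cols[[v]]
    means <- tapply(y, g, mean)
    grand <- mean(y)
    ssb <- sum(n_g * (means - grand)^2)
    ssw <- sum((y - means[g])^2)
    msb <- ssb / (k - 1); msw <- ssw / (N - k)
    f_stat <- if (msw > 0) msb / msw else ifelse(msb > 0, Inf, 0)
    p <- pf(f_stat, k - 1, N - k, lower.tail = FALSE)
    q_crit <- qtukey(1 - alpha, k, N - k)
    anova_rows[[v]] <- tibble::tibble(variable = v, F = f_stat, p = p,
                                      msw = msw, balanced = balanced)
    for (pr in pairs) {
      diff <- unname(means[pr[2]] - means[pr[1]])
      hsd <- if (balanced) {
        unname(q_crit * sqrt(msw / n_g[1]))
      } else {
        unname(q_crit * sqrt(msw / 2 * (1 / n_g[pr[1]] + 1 / n_g[pr[2]])))
      }
      pair_rows[[paste(v, pr[1], pr[2])]] <- tibble::tibble(
        variable = v, pair = paste(pr, collapse = "-"), diff = diff,
        hsd_threshold = unname(hsd),
        significant = abs(diff) > hsd, F = f_stat, p = p)
    }
  }
  out <- do.call(rbind, pair_rows)
  attr(out, "anova") <- do.call(rbind, anova_rows)
  attr(out, "balanced") <- balanced
  attr(out, "alpha") <- alpha
  class(out) <- c("tlx_test_result", class(out))
  out
}
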