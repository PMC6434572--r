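# Variant and season comparisons of diversity statistics.

#' Compare diversity tables between dataset variants or seasons
#'
#' Paired deltas of the shared diversity statistics per population, with
#' paired t-tests across populations and one-way ANOVA treating the two
#' tables as groups, the standard single-factor comparison for rarefied
#' diversity.
#'
#' @param table_a,table_b diversity tables from [diversity_table()] with
#'   matching populations (e.g. diploid vs polyploid, or summer vs
#'   winter).
#' @param statistics columns to compare.
#' @return list with `deltas` (per population, b minus a), `tests` (one
#'   row per statistic: mean delta, paired t p-value, ANOVA p-value).
#' @export
compare_diversity <- function(table_a, table_b,
                              statistics = c("a_n_dip", "a_rn", "a_rp",
                                             "h_o", "h_e")) {
  common <- intersect(table_a$population, table_b$population)
  if (length(common) == 0) stop("no shared populations to compare")
  a <- table_a[match(common, table_a$population), ]
  b <- table_b[match(common, table_b$population), ]
  statistics <- intersect(statistics, intersect(names(a), names(b)))
  deltas <- data.frame(population = common, stringsAsFactors = FALSE)
  tests <- list()
  for (s in statistics) {
    d <- b[[s]] - a[[s]]
    deltas[[s]] <- d
    tt <- if (length(common) > 1 && stats::sd(d, na.rm = TRUE) > 0)
      stats::t.test(b[[s]], a[[s]], paired = TRUE)$p.value else
      if (all(d == 0, na.rm = TRUE)) 1 else NA_real_
    vals <- c(a[[s]], b[[s]])
    grp <- factor(rep(c("a", "b"), each = length(common)))
    av <- if (stats::sd(vals, na.rm = TRUE) > 0)
      summary(stats::aov(vals ~ grp))[[1]][["Pr(>F)"]][1] else 1
    tests[[s]] <- data.frame(statistic = s, mean_delta = mean(d, na.rm = TRUE),
                             t_paired_p = tt, anova_p = av,
                             stringsAsFactors = FALSE)
  }
  list(deltas = deltas, tests = do.call(rbind, tests))
}
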