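#' Fat-fraction group assignment
#'
#' Muscles of patients are grouped by their (median) fat fraction: weakly
#' fatty replaced (FF < 10%), moderately (10% <= FF < 30%), strongly
#' (30% <= FF < 60%), and excluded (FF >= 60%, where the MESE fit becomes
#' unstable). Boundary values fall into the upper group, matching the
#' closed lower bounds of the grouping convention. Controls are labelled
#' `"CTL"` regardless of FF.
#'
#' @param ff Fat fraction(s) in `[0, 1]`.
#' @param cohort `"patient"` or `"control"` (recycled).
#' @return Factor with levels `CTL`, `FF<10%`, `10-30%`, `30-60%`,
#'   `excluded`.
#' @examples
#' assign_ff_group(c(0.05, 0.30, 0.65), "patient")
#' @export
assign_ff_group <- function(ff, cohort = "patient") {
  cohort <- rep(cohort, length.out = length(ff))
  lev <- c("CTL", "FF<10%", "10-30%", "30-60%", "excluded")
  lab <- ifelse(cohort == "control", "CTL",
         ifelse(is.na(ff), NA_character_,
         ifelse(ff < 0.10, "FF<10%",
         ifelse(ff < 0.30, "10-30%",
         ifelse(ff < 0.60, "30-60%", "excluded")))))
  factor(lab, levels = lev)
}

# exact two-sided rank-sum p by enumeration over all assignments of the
# pooled midranks to group A; handles ties through the midranks
rank_sum_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  s_obs <- sum(r[seq_len(na)])
  mu <- na * (length(pooled) + 1) / 2
  combos <- combn(length(pooled), na)
  sums <- colSums(matrix(r[combos], nrow = na))
  mean(abs(sums - mu) >= abs(s_obs - mu) - 1e-9)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided rank-sum test as used for patient-vs-control comparisons.
#' For combined n <= 12 the p-value is computed by exact enumeration over
#' all assignments of the pooled midranks (valid under ties); larger
#' samples use the normal approximation with tie correction.
#'
#' @param values_a,values_b Numeric samples (each non-empty).
#' @return Tibble with `statistic` (rank sum of the first sample), `p_value`,
#'   `method`, `n_a`, `n_b`, `significant` (at the 0.05 level).
#' @examples
#' compare_two(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_two <- function(values_a, values_b) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 1 || length(b) < 1) abort("both groups must be non-empty")
  r <- rank(c(a, b))
  s <- sum(r[seq_along(a)])
  if (length(a) + length(b) <= 12) {
    p <- rank_sum_exact(a, b)
    method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    p <- wt$p.value
    method <- "normal approximation"
  }
  tibble::tibble(statistic = s, p_value = p, method = method,
                 n_a = length(a), n_b = length(b),
                 significant = is.finite(p) && p < 0.05)
}

#' Kruskal-Wallis comparison across FF groups
#'
#' Kruskal-Wallis H (with tie correction, chi-squared p) across groups,
#' optionally followed by per-group rank-sum comparisons against the
#' control group.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor/vector, same length.
#' @param follow_up Run per-group [compare_two()] against `control_level`.
#' @param control_level Reference group label for follow-ups.
#' @return Tibble with `statistic` (H), `df`, `p_value`; follow-up rows in
#'   the `follow_up` attribute when requested.
#' @export
compare_groups <- function(values, groups, follow_up = FALSE,
                           control_level = "CTL") {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) abort("need >= 2 non-empty groups")
  if (length(unique(values)) == 1) {
    out <- tibble::tibble(statistic = 0, df = nlevels(groups) - 1L,
                          p_value = 1)
  } else {
    kw <- stats::kruskal.test(values, groups)
    out <- tibble::tibble(statistic = unname(kw$statistic),
                          df = unname(kw$parameter),
                          p_value = kw$p.value)
  }
  if (follow_up && control_level %in% levels(groups)) {
    ctl <- values[groups == control_level]
    others <- setdiff(levels(groups), control_level)
    fu <- purrr::map_dfr(others, function(g) {
      dplyr::mutate(compare_two(values[groups == g], ctl), group = g,
                    .before = 1)
    })
    attr(out, "follow_up") <- fu
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties, as used to relate the
#' quantitative measures (FF, water T2, aTSC, aTPC) to one another.
#' Constant input yields an `NA` estimate with a degenerate flag rather
#' than an error.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return Tibble with `rho`, `p_value`, `n`, `degenerate`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need >= 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          n = length(x), degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), degenerate = FALSE)
}

#' Median and interquartile range summary
#'
#' The cohort summary convention: median and IQR (Q3 - Q1) with the
#' linear-interpolation quantile definition (R type 7) by default; the
#' quantile type is configurable.
#'
#' @param values Numeric vector, n >= 1.
#' @param type Quantile type passed to [stats::quantile()].
#' @return Tibble with `n`, `median`, `q1`, `q3`, `iqr`.
#' @examples
#' summarize_miqr(1:5)
#' @export
summarize_miqr <- function(values, type = 7) {
  values <- values[is.finite(values)]
  if (length(values) < 1) abort("need at least one finite value")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  tibble::tibble(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
                 iqr = q[3] - q[1])
}

#' Group-wise cohort summary of muscle records
#'
#' Medians (IQR) of the fat-corrected concentrations by FF group, plus
#' per-group rank-sum comparisons against controls: the tabular mirror of a
#' grouped box-plot of aTSC_fc / aTPC_fc versus fatty-replacement severity.
#'
#' @param records Muscle-record tibble (see [muscle_records()]); rows with
#'   `excluded = TRUE` are dropped.
#' @param value Column to summarize, e.g. `"atsc_fc_mM"`.
#' @return Tibble of per-group summaries with comparison p-values vs CTL.
#' @export
cohort_group_summary <- function(records, value = "atsc_fc_mM") {
  d <- dplyr::filter(records, !.data$excluded, is.finite(.data[[value]]))
  ctl <- d[[value]][d$ff_group == "CTL"]
  d |>
    dplyr::group_by(.data$ff_group) |>
    dplyr::group_modify(function(g, key) {
      s <- summarize_miqr(g[[value]])
      if (key$ff_group != "CTL" && length(ctl) > 0 && nrow(g) > 0) {
        cmp <- compare_two(g[[value]], ctl)
        s$p_vs_ctl <- cmp$p_value
        s$significant <- cmp$significant
      } else {
        s$p_vs_ctl <- NA_real_
        s$significant <- NA
      }
      s
    }) |>
    dplyr::ungroup()
}

#' Box plot of fat-corrected concentrations by FF group
#'
#' @param records Muscle-record tibble.
#' @param value Column to plot.
#' @return A ggplot.
#' @export
plot_cohort_groups <- function(records, value = "atsc_fc_mM") {
  d <- dplyr::filter(records, !.data$excluded, is.finite(.data[[value]]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ff_group, y = .data[[value]])) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = "fat-fraction group", y = value)
}
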