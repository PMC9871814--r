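#' Compare treatments across sections by two-way ANOVA with Tukey HSD
#'
#' Fixed-effects two-way ANOVA of a per-replicate response (typically the
#' mean section intensity over a stated time window) on treatment, section
#' and their interaction, followed by Tukey honestly-significant-difference
#' pairwise comparisons. Requires at least two replicates in every
#' treatment x section cell.
#'
#' @param data A data frame with one row per replicate.
#' @param response,treatment,section Column names (strings).
#' @param alpha Significance level for the `significant` flag.
#' @return A `condition_anova`: the fitted `aov`, a tidy ANOVA table, a tidy
#'   Tukey table and per-cell replicate counts. `tidy()` returns the Tukey
#'   contrasts; `glance()` the ANOVA table.
#' @export
compare_conditions <- function(data, response = "intensity_adu",
                               treatment = "treatment", section = "section",
                               alpha = 0.05) {
  stopifnot(all(c(response, treatment, section) %in% names(data)))
  df <- tibble(
    y = data[[response]],
    treatment = factor(data[[treatment]]),
    section = factor(data[[section]])
  )
  cells <- df |>
    dplyr::count(.data$treatment, .data$section, name = "n_replicates")
  n_cells <- nlevels(df$treatment) * nlevels(df$section)
  if (nrow(cells) < n_cells || any(cells$n_replicates < 2)) {
    abort("Every treatment x section cell needs >= 2 replicates.")
  }
  fit <- aov(y ~ treatment * section, data = df)
  s <- summary(fit)[[1]]
  anova_table <- tibble(
    term = trimws(rownames(s)),
    df = s$Df, sumsq = s$`Sum Sq`, meansq = s$`Mean Sq`,
    statistic = s$`F value`, p.value = s$`Pr(>F)`
  )
  tk <- TukeyHSD(fit)
  tukey <- purrr::imap(tk, function(m, term) {
    tibble(term = term, contrast = rownames(m),
           estimate = m[, "diff"], conf.low = m[, "lwr"],
           conf.high = m[, "upr"], adj.p.value = m[, "p adj"],
           significant = m[, "p adj"] <= alpha)
  }) |> list_rbind()
  structure(list(fit = fit, anova = anova_table, tukey = tukey,
                 cells = cells, alpha = alpha),
            class = "condition_anova")
}

#' @export
print.condition_anova <- function(x, ...) {
  cat("<condition_anova> two-way ANOVA with Tukey HSD\n")
  print(x$anova)
  cat(sprintf("%d of %d Tukey contrasts significant at alpha = %g\n",
              sum(x$tukey$significant), nrow(x$tukey), x$alpha))
  invisible(x)
}

#' @export
tidy.condition_anova <- function(x, ...) x$tukey

#' @export
glance.condition_anova <- function(x, ...) x$anova

#' Per-replicate mean section intensities for condition comparison
#'
#' Reduces section traces of several replicates/treatments to one response
#' value per replicate x section: the mean intensity over a time window.
#'
#' @param traces A tibble binding [extract_traces()] outputs with added
#'   `treatment` and `replicate` columns.
#' @param window_s Length-2 time window (s) averaged over.
#' @return A tibble: `treatment`, `replicate`, `section`, `intensity_adu`.
#' @export
section_means <- function(traces, window_s = c(0, Inf)) {
  stopifnot(all(c("time_s", "section", "intensity_adu",
                  "treatment", "replicate") %in% names(traces)))
  traces |>
    filter(.data$time_s >= window_s[1], .data$time_s <= window_s[2]) |>
    group_by(.data$treatment, .data$replicate, .data$section) |>
    summarise(intensity_adu = mean(.data$intensity_adu), .groups = "drop")
}
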