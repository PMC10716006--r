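#' Factorial group comparison: two-way ANOVA with Tukey contrasts
#'
#' Implements the study's statistics stage for a 2x2 design (shRNA
#' treatment x infusion): per outcome, a two-way ANOVA with type-II sums
#' of squares (factors, interaction), followed by Tukey HSD on the four
#' cell means. Of the six pairwise cell contrasts, only the four the
#' design interprets are reported: the shRNA effect within each infusion
#' (the "*" family) and the infusion effect within each shRNA (the "#"
#' family), each flagged at `alpha`.
#'
#' @param animal_table Per-animal tibble with columns `shrna`,
#'   `infusion` (each 2 levels, >= 2 animals per cell) and the outcome
#'   columns.
#' @param outcomes Character vector of outcome column names.
#' @param alpha Significance level, default 0.05.
#' @return Named list per outcome, each with `anova` (type-II table as a
#'   tibble), `contrasts` (tibble: contrast family, cells compared,
#'   difference, Tukey-adjusted p, significance flag) and `cells`
#'   (mean +/- SEM per cell).
#' @export
compare_groups <- function(animal_table, outcomes, alpha = 0.05) {
  df <- as.data.frame(animal_table)
  for (fac in c("shrna", "infusion")) {
    if (!fac %in% names(df)) {
      stop("design error: missing factor column '", fac, "'",
           call. = FALSE)
    }
    df[[fac]] <- factor(df[[fac]])
    if (nlevels(df[[fac]]) != 2) {
      stop("design error: factor '", fac, "' must have exactly 2 levels",
           call. = FALSE)
    }
  }
  cell_n <- table(df$shrna, df$infusion)
  if (any(cell_n < 2)) {
    stop("design error: every cell needs >= 2 animals", call. = FALSE)
  }
  df$cell <- interaction(df$shrna, df$infusion, sep = "|")

  lapply(stats::setNames(outcomes, outcomes), function(oc) {
    d <- df[!is.na(df[[oc]]), ]
    fit <- stats::aov(stats::reformulate("shrna * infusion", oc), data = d)
    a2 <- car::Anova(fit, type = 2)
    anova_tbl <- tibble::tibble(term = rownames(a2),
                                sum_sq = a2$`Sum Sq`, df = a2$Df,
                                F = a2$`F value`, p = a2$`Pr(>F)`)
    tk <- stats::TukeyHSD(stats::aov(stats::reformulate("cell", oc),
                                     data = d))$cell
    contrasts <- extract_design_contrasts(tk, levels(d$shrna),
                                          levels(d$infusion), alpha)
    cells <- d |>
      dplyr::group_by(.data$shrna, .data$infusion) |>
      dplyr::summarise(n = dplyr::n(),
                       mean = mean(.data[[oc]]),
                       sem = stats::sd(.data[[oc]]) / sqrt(dplyr::n()),
                       .groups = "drop")
    list(outcome = oc, anova = anova_tbl, contrasts = contrasts,
         cells = cells)
  })
}

# pick the 4 interpretable contrasts out of the 6 Tukey pairs
extract_design_contrasts <- function(tk, shrna_levels, infusion_levels,
                                     alpha) {
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  rows <- list()
  for (i in seq_along(pairs)) {
    a <- strsplit(pairs[[i]][1], "|", fixed = TRUE)[[1]]
    b <- strsplit(pairs[[i]][2], "|", fixed = TRUE)[[1]]
    family <- if (a[2] == b[2] && a[1] != b[1]) {
      "shrna_within_infusion"      # the "*" family
    } else if (a[1] == b[1] && a[2] != b[2]) {
      "infusion_within_shrna"      # the "#" family
    } else {
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      family = family,
      within = if (family == "shrna_within_infusion") a[2] else a[1],
      cell_a = pairs[[i]][1], cell_b = pairs[[i]][2],
      diff = tk[i, "diff"], p_adj = tk[i, "p adj"],
      significant = tk[i, "p adj"] < alpha)
  }
  dplyr::bind_rows(rows)
}
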