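# Milk-composition analysis: exclusion filters, group summaries, casein
# number, one-way ANOVA with Tukey HSD and a compact letter display.

#' Apply the sample-exclusion filters
#'
#' Drops records with somatic cell count above `scc_max` (default 400,000
#' cells/mL), records with a missing genotype class, and — when `exclude_C`
#' — C-allele carriers. Idempotent; the exclusions, each with its reason,
#' are attached as attribute `"exclusions"` (also available via
#' [exclusion_log()]).
#'
#' @param records Tibble with `animal_id`, `scc` and `genotype_class`.
#' @param scc_max SCC cutoff in cells/mL (> 0).
#' @param exclude_C Drop `C_carrier` records?
#' @return Tibble of retained records.
#' @export
filter_samples <- function(records, scc_max = 400000, exclude_C = TRUE) {
  stopifnot(scc_max > 0)
  records <- tibble::as_tibble(records)
  reason <- dplyr::case_when(
    !is.na(records$scc) & records$scc > scc_max ~ "scc",
    is.na(records$genotype_class) | records$genotype_class == "" ~ "missing genotype",
    exclude_C & records$genotype_class == "C_carrier" ~ "C allele",
    TRUE ~ NA_character_
  )
  excl <- tibble::tibble(animal_id = records$animal_id[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  out <- records[is.na(reason), ]
  attr(out, "exclusions") <- excl
  out
}

#' Exclusion log of a filtered record set
#'
#' @param records Output of [filter_samples()].
#' @return Tibble: `animal_id`, `reason`.
#' @export
exclusion_log <- function(records) {
  attr(records, "exclusions") %||%
    tibble::tibble(animal_id = character(), reason = character())
}

#' Casein number
#'
#' Casein as a fraction of true protein — the cheese-yield-relevant quantity.
#'
#' @param casein_gl,true_protein_gl Concentrations in g/L (vectorised);
#'   true protein must be positive.
#' @return Dimensionless fraction at full precision (round to 2 decimals for
#'   display).
#' @examples
#' round(casein_number(27.4, 32.3), 2)  # 0.85
#' @export
casein_number <- function(casein_gl, true_protein_gl) {
  if (any(true_protein_gl <= 0)) stop("true protein must be positive", call. = FALSE)
  casein_gl / true_protein_gl
}

#' Summarise milk composition by genotype group
#'
#' Per group and component: n, arithmetic mean and SEM (sample SD over
#' sqrt(n); `NA` for singleton groups). The group casein number is computed
#' from the group-mean casein and group-mean true protein (a per-cow-ratio
#' mode is available via `per_cow_casein_number`). Invariant to record
#' order.
#'
#' @param records Composition tibble with the component columns and a
#'   grouping column.
#' @param group_field Name of the grouping column.
#' @param components Component columns to summarise.
#' @param per_cow_casein_number Average per-cow casein/true-protein ratios
#'   instead of taking the ratio of group means.
#' @return Tibble: one row per group x component (`n`, `mean`, `sem`), with
#'   the casein number appearing as component `"casein_number"`.
#' @export
summarize_groups <- function(records, group_field = "genotype_class",
                             components = c("fat", "crude_protein",
                                            "true_protein", "lactose",
                                            "casein", "blg_units"),
                             per_cow_casein_number = FALSE) {
  components <- intersect(components, names(records))
  long <- records |>
    dplyr::rename(group = dplyr::all_of(group_field)) |>
    tidyr::pivot_longer(dplyr::all_of(components),
                        names_to = "component", values_to = "value") |>
    dplyr::group_by(.data$group, .data$component) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$value),
      sem = ifelse(dplyr::n() >= 2, stats::sd(.data$value) / sqrt(dplyr::n()),
                   NA_real_),
      .groups = "drop"
    )
  if (all(c("casein", "true_protein") %in% components)) {
    cn <- records |>
      dplyr::rename(group = dplyr::all_of(group_field)) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = if (per_cow_casein_number) {
          mean(casein_number(.data$casein, .data$true_protein))
        } else {
          casein_number(mean(.data$casein), mean(.data$true_protein))
        },
        sem = ifelse(dplyr::n() >= 2,
                     stats::sd(casein_number(.data$casein, .data$true_protein)) /
                       sqrt(dplyr::n()), NA_real_),
        .groups = "drop"
      ) |>
      dplyr::mutate(component = "casein_number", .after = "group")
    long <- dplyr::bind_rows(long, cn)
  }
  dplyr::arrange(long, .data$component, .data$group)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Standard insert-and-absorb algorithm: groups sharing a letter are not
#' significantly different at `alpha`; any significant pair appears in no
#' common letter group.
#'
#' @param pmat Symmetric matrix of pairwise p-values with group dimnames.
#' @param alpha Significance level.
#' @return Named character vector of letter codes, one per group.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  groups <- rownames(pmat)
  k <- length(groups)
  # start with one set containing all groups; split on each significant pair
  sets <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
      for (s in seq_along(sets)) {
        if (sets[[s]][i] && sets[[s]][j]) {
          a <- sets[[s]]; a[j] <- FALSE
          b <- sets[[s]]; b[i] <- FALSE
          sets[[s]] <- a
          sets[[length(sets) + 1]] <- b
        }
      }
      # absorb: drop sets contained in another set
      keep <- rep(TRUE, length(sets))
      for (s in seq_along(sets)) {
        for (t in seq_along(sets)) {
          if (s != t && keep[t] && all(sets[[s]] <= sets[[t]]) &&
              any(sets[[s]] < sets[[t]])) {
            keep[s] <- FALSE
            break
          }
        }
      }
      sets <- sets[keep]
      sets <- unique(sets)
    }
  }
  # order sets by the first group they contain, then assign letters
  first <- vapply(sets, function(s) which(s)[1], numeric(1))
  sets <- sets[order(first)]
  letters_out <- stats::setNames(rep("", k), groups)
  for (s in seq_along(sets)) {
    letters_out[sets[[s]]] <- paste0(letters_out[sets[[s]]], letters[s])
  }
  letters_out
}

#' One-way ANOVA with Tukey letter codes
#'
#' One-way ANOVA of a milk component across genotype groups, pairwise
#' comparisons by Tukey's HSD, and a compact letter display: groups sharing
#' a letter are not significantly different at `alpha`. The degenerate case
#' of zero variance everywhere with equal means returns `p = 1` and a single
#' shared letter.
#'
#' @param records Composition tibble.
#' @param component Column to analyse.
#' @param group_field Grouping column.
#' @param alpha Significance level for the letter display.
#' @return Object of class `blg_anova` with `statistic` (F), `p_value`,
#'   `df`, `letters` (tibble `group`, `mean`, `letters`) and `tukey`
#'   (tibble of pairwise comparisons). Has [tidy()] and [glance()] methods.
#' @export
anova_letters <- function(records, component, group_field = "genotype_class",
                          alpha = 0.05) {
  g <- factor(records[[group_field]])
  v <- records[[component]]
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop("need >= 2 groups with >= 2 records each", call. = FALSE)
  }
  means <- tapply(v, g, mean)
  if (stats::var(v) == 0) {
    lev <- levels(g)
    letters_tbl <- tibble::tibble(group = lev, mean = as.numeric(means),
                                  letters = "a")
    return(structure(list(statistic = NA_real_, p_value = 1,
                          df = c(nlevels(g) - 1, length(v) - nlevels(g)),
                          letters = letters_tbl,
                          tukey = tibble::tibble(), alpha = alpha,
                          component = component),
                     class = "blg_anova"))
  }
  df_in <- data.frame(value = v, group = g)
  fit <- stats::aov(value ~ group, data = df_in)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  lev <- levels(g)
  pmat <- matrix(NA_real_, nlevels(g), nlevels(g), dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_along(pairs)) {
    a <- pairs[[r]][1]; b <- pairs[[r]][2]
    pmat[a, b] <- pmat[b, a] <- tk[r, "p adj"]
  }
  lt <- compact_letters(pmat, alpha)
  structure(list(
    statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1],
    df = an$Df,
    letters = tibble::tibble(group = lev, mean = as.numeric(means[lev]),
                             letters = unname(lt[lev])),
    tukey = tibble::as_tibble(tk, rownames = "comparison"),
    alpha = alpha, component = component
  ), class = "blg_anova")
}

#' @export
print.blg_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s: F = %.3f, p = %.3g\n",
              x$component, x$statistic, x$p_value))
  print(x$letters)
  invisible(x)
}

#' Tidy ANOVA letter codes
#'
#' @param x A `blg_anova`.
#' @param ... Unused.
#' @return Tibble: `group`, `mean`, `letters`.
#' @export
tidy.blg_anova <- function(x, ...) x$letters

#' One-row ANOVA summary
#'
#' @param x A `blg_anova`.
#' @param ... Unused.
#' @return Tibble: `statistic`, `p_value`, `df_between`, `df_within`,
#'   `alpha`.
#' @export
glance.blg_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 df_between = x$df[1], df_within = x$df[2], alpha = x$alpha)
}

#' Full composition report by genotype group
#'
#' Combines [summarize_groups()] with per-component ANOVA letters: one row
#' per component x group with mean, SEM and letter code.
#'
#' @param records Filtered composition tibble.
#' @param group_field Grouping column.
#' @param alpha Significance level.
#' @return Tibble: `component`, `group`, `n`, `mean`, `sem`, `letters`,
#'   `anova_p`.
#' @export
composition_report <- function(records, group_field = "genotype_class",
                               alpha = 0.05) {
  summ <- summarize_groups(records, group_field)
  per_cow_cn <- dplyr::mutate(records, casein_number = casein_number(
    .data$casein, .data$true_protein))
  comps <- setdiff(unique(summ$component), NULL)
  letters_tbl <- purrr::map_dfr(comps, function(cmp) {
    src <- if (cmp == "casein_number") per_cow_cn else records
    a <- anova_letters(src, cmp, group_field, alpha)
    dplyr::mutate(a$letters, component = cmp, anova_p = a$p_value,
                  .before = 1)
  })
  dplyr::left_join(summ, dplyr::select(letters_tbl, "component", "group",
                                       "letters", "anova_p"),
                   by = c("component", "group"))
}
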