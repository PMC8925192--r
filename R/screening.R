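# Genotype classification from the A-vs-B concentration plane, low-B outlier
# cohort selection, sire enrichment, and the two-component segregation mixture.

#' Classify screening genotypes from isoform concentrations
#'
#' Calls the protein genotype from the two channel intensities: `AA` when
#' only the A channel exceeds the presence floor, `BB` when only the B
#' channel does, `AB` when both do, `unassigned` when neither does. Within
#' `AB`, cows whose B:A ratio falls below `lowb_ratio_cut` are flagged
#' `AB_lowB`; within `BB`, cows whose B signal falls below the
#' `bb_low_quantile` quantile of the BB cluster are flagged `BB_lowB`.
#'
#' @param quant Tibble with columns `A_units` and `B_units` (one row per cow;
#'   any id columns are preserved).
#' @param floor Presence floor in arb units.
#' @param lowb_ratio_cut B:A ratio below which an AB cow is a low-B outlier.
#' @param bb_low_quantile Quantile of the BB cluster's B signal below which a
#'   BB cow is flagged (set 0 to disable).
#' @return Input tibble with added `ratio_BA` (NA when `A_units = 0`) and
#'   `class_label`.
#' @export
classify_genotype <- function(quant, floor = 10, lowb_ratio_cut = 0.45,
                              bb_low_quantile = 0.05) {
  stopifnot(all(c("A_units", "B_units") %in% names(quant)),
            all(quant$A_units >= 0), all(quant$B_units >= 0))
  quant <- tibble::as_tibble(quant)
  quant$ratio_BA <- ifelse(quant$A_units > 0, quant$B_units / quant$A_units, NA_real_)
  base <- dplyr::case_when(
    quant$A_units >= floor & quant$B_units >= floor ~ "AB",
    quant$A_units >= floor ~ "AA",
    quant$B_units >= floor ~ "BB",
    TRUE ~ "unassigned"
  )
  lab <- base
  lab[base == "AB" & quant$ratio_BA < lowb_ratio_cut] <- "AB_lowB"
  if (bb_low_quantile > 0 && any(base == "BB")) {
    cut_bb <- stats::quantile(quant$B_units[base == "BB"], bb_low_quantile,
                              names = FALSE)
    lab[base == "BB" & quant$B_units < cut_bb] <- "BB_lowB"
  }
  quant$class_label <- lab
  quant
}

#' Select the low-B outlier cohorts
#'
#' Takes the `k` most extreme cows per class: within the AB class (including
#' `AB_lowB`) the lowest B:A ratios; within the BB class (including
#' `BB_lowB`) the lowest B signals. Ties are broken lexicographically by
#' `animal_id`, so the cohort is fully deterministic.
#'
#' @param calls Output of [classify_genotype()] with an `animal_id` column.
#' @param k Cohort size per class (the screen used 180).
#' @return Tibble: `animal_id`, `cohort` (`"AB"` or `"BB"`), `rank`, `value`
#'   (the ranking statistic).
#' @export
select_outlier_cohort <- function(calls, k = 180) {
  pick <- function(df, value, cohort) {
    df <- df[order(value, df$animal_id), ]
    kk <- min(k, nrow(df))
    if (k > nrow(df) && nrow(df) > 0) {
      warning(sprintf("requested k = %d > %s class size %d; truncated",
                      k, cohort, nrow(df)), call. = FALSE)
    }
    if (kk == 0L) {
      return(tibble::tibble(animal_id = character(), cohort = character(),
                            rank = integer(), value = numeric()))
    }
    tibble::tibble(animal_id = df$animal_id[seq_len(kk)], cohort = cohort,
                   rank = seq_len(kk), value = sort(value)[seq_len(kk)])
  }
  ab <- dplyr::filter(calls, .data$class_label %in% c("AB", "AB_lowB"))
  bb <- dplyr::filter(calls, .data$class_label %in% c("BB", "BB_lowB"))
  dplyr::bind_rows(pick(ab, ab$ratio_BA, "AB"), pick(bb, bb$B_units, "BB"))
}

#' Sire enrichment within an outlier cohort
#'
#' Counts each sire's daughters inside the cohort and attaches the upper-tail
#' hypergeometric probability of observing at least that many, given his
#' total daughters, the cohort size and the population size. Cohort animals
#' without a recorded sire are counted under `"unknown"`. The primary output
#' is the ranked count table; the p-value formalises it.
#'
#' @param cohort Character vector of cohort animal ids (or a tibble with an
#'   `animal_id` column).
#' @param cows Population tibble with `animal_id` and `sire_id`.
#' @return Tibble ranked by cohort daughters then p: `sire_id`,
#'   `daughters_in_cohort`, `daughters_total`, `cohort_size`,
#'   `population_size`, `p_hyper`.
#' @export
sire_enrichment <- function(cohort, cows) {
  if (is.data.frame(cohort)) cohort <- cohort$animal_id
  stopifnot(all(cohort %in% cows$animal_id))
  pop <- dplyr::mutate(cows, sire_id = dplyr::coalesce(.data$sire_id, "unknown"),
                       in_cohort = .data$animal_id %in% cohort)
  n_pop <- nrow(pop)
  n_coh <- length(cohort)
  pop |>
    dplyr::group_by(.data$sire_id) |>
    dplyr::summarise(daughters_in_cohort = sum(.data$in_cohort),
                     daughters_total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      cohort_size = n_coh, population_size = n_pop,
      p_hyper = stats::phyper(.data$daughters_in_cohort - 1,
                              .data$daughters_total,
                              n_pop - .data$daughters_total,
                              n_coh, lower.tail = FALSE)
    ) |>
    dplyr::arrange(dplyr::desc(.data$daughters_in_cohort), .data$p_hyper,
                   .data$sire_id)
}

#' Fit a two-component Gaussian segregation mixture by EM
#'
#' Univariate two-component normal mixture, the model behind the bimodal
#' B:A (or B-concentration) distribution in the heterozygous daughters of a
#' carrier sire. Initialisation splits the sample at its median (unimodal-
#' safe and deterministic); EM iterates until the log-likelihood improves by
#' less than `tol`. Component variances are floored to avoid degenerate
#' spikes. Components are reported in decreasing mean order; hard
#' assignments are by maximum responsibility.
#'
#' @param ratios Numeric vector of observations (>= 4, finite).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param seed Integer seed (used only to break exact assignment ties).
#' @return Object of class `blg_mixture`: weights, means, sds, loglik,
#'   responsibilities, assignments, n_iter, converged, and the data.
#' @seealso [tidy.blg_mixture()], [glance.blg_mixture()],
#'   [autoplot.blg_mixture()], [bimodality_check()]
#' @export
fit_segregation_mixture <- function(ratios, max_iter = 500, tol = 1e-8,
                                    seed = 1L) {
  x <- as.numeric(ratios)
  if (any(!is.finite(x))) stop("observations must be finite", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  var_floor <- max(1e-12, 1e-6 * stats::var(x))
  below <- x <= stats::median(x)
  if (all(below) || !any(below)) below <- seq_len(n) <= n / 2
  mu <- c(mean(x[!below]), mean(x[below]))
  sg <- sqrt(pmax(var_floor, c(stats::var(x[!below]), stats::var(x[below]))))
  sg[is.na(sg)] <- sqrt(var_floor)
  w <- c(mean(!below), mean(below))
  loglik <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r1 <- d1 / tot
    ll_new <- sum(log(tot))
    if (ll_new < loglik - 1e-6) {
      stop("internal error: EM log-likelihood decreased", call. = FALSE)
    }
    ll_trace <- c(ll_trace, ll_new)
    if (is.finite(loglik) && ll_new - loglik < tol) {
      loglik <- ll_new
      converged <- TRUE
      break
    }
    loglik <- ll_new
    n1 <- sum(r1); n2 <- n - n1
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    sg <- sqrt(pmax(var_floor,
                    c(sum(r1 * (x - mu[1])^2) / n1,
                      sum((1 - r1) * (x - mu[2])^2) / n2)))
  }
  resp <- cbind(r1, 1 - r1)
  ord <- order(mu, decreasing = TRUE)
  if (mu[1] == mu[2]) ord <- 1:2  # deterministic under ties
  mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]; resp <- resp[, ord, drop = FALSE]
  set.seed(seed)
  assign <- max.col(resp, ties.method = "first")
  structure(list(
    weights = w, means = mu, sds = sg, loglik = loglik,
    responsibilities = unname(resp), assignments = assign,
    n_iter = length(ll_trace), converged = converged, data = x,
    ll_trace = ll_trace
  ), class = "blg_mixture")
}

#' @export
print.blg_mixture <- function(x, ...) {
  cat("Two-component Gaussian segregation mixture\n")
  cat(sprintf("  n = %d, loglik = %.3f, iterations = %d%s\n",
              length(x$data), x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  for (k in 1:2) {
    cat(sprintf("  component %d: weight %.3f, mean %.3f, sd %.3f\n",
                k, x$weights[k], x$means[k], x$sds[k]))
  }
  invisible(x)
}

#' Tidy a segregation mixture fit
#'
#' @param x A `blg_mixture`.
#' @param ... Unused.
#' @return Tibble with one row per component: `component`, `weight`, `mean`,
#'   `sd`, `n_assigned`.
#' @export
tidy.blg_mixture <- function(x, ...) {
  tibble::tibble(
    component = 1:2, weight = x$weights, mean = x$means, sd = x$sds,
    n_assigned = as.integer(tabulate(x$assignments, 2))
  )
}

#' One-row summary of a segregation mixture fit
#'
#' @param x A `blg_mixture`.
#' @param ... Unused.
#' @return Tibble: `n`, `loglik`, `n_iter`, `converged`, `mean_separation`
#'   (difference of component means over pooled sd).
#' @export
glance.blg_mixture <- function(x, ...) {
  tibble::tibble(
    n = length(x$data), loglik = x$loglik, n_iter = x$n_iter,
    converged = x$converged,
    mean_separation = (x$means[1] - x$means[2]) / sqrt(mean(x$sds^2))
  )
}

#' Likelihood-ratio check for segregation (bimodality)
#'
#' Compares the two-component mixture to the single-Gaussian maximum
#' likelihood fit on the same data: statistic `2 * (loglik2 - loglik1)`,
#' with verdict `"segregating"` when it exceeds the decision threshold.
#' (The statistic's null distribution is non-regular, so the threshold is a
#' calibrated decision rule, not a chi-square quantile.)
#'
#' @param fit A `blg_mixture` from [fit_segregation_mixture()].
#' @param single_fit_loglik Optional log-likelihood of the one-component fit;
#'   computed from the fit's data when omitted.
#' @param threshold Decision threshold on the statistic.
#' @return Tibble: `statistic`, `loglik_two`, `loglik_one`, `threshold`,
#'   `segregating`.
#' @export
bimodality_check <- function(fit, single_fit_loglik = NULL, threshold = 10) {
  stopifnot(inherits(fit, "blg_mixture"))
  if (is.null(single_fit_loglik)) {
    x <- fit$data
    sd1 <- sqrt(mean((x - mean(x))^2))
    sd1 <- max(sd1, 1e-12)
    single_fit_loglik <- sum(stats::dnorm(x, mean(x), sd1, log = TRUE))
  }
  if (fit$loglik < single_fit_loglik - 1e-6) {
    stop("internal error: mixture log-likelihood below single-Gaussian fit",
         call. = FALSE)
  }
  stat <- max(0, 2 * (fit$loglik - single_fit_loglik))
  tibble::tibble(
    statistic = stat, loglik_two = fit$loglik, loglik_one = single_fit_loglik,
    threshold = threshold, segregating = stat > threshold
  )
}
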