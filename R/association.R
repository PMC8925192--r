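# Phenotype adjustment, GRM construction, LOCO partitioning, the per-variant
# association scan and the Bonferroni threshold.

#' Adjust phenotypes for design effects
#'
#' Fits a linear mixed model with fixed effects for birth year and breed and
#' independent random intercepts for herd and plate (REML via lme4), and
#' returns the centred residuals as the adjusted phenotype. Random factors
#' with fewer than 3 observed levels are demoted to fixed effects; if no
#' random terms remain an ordinary linear model is used. A rank-deficient
#' fixed-effect design is an error naming the collinear columns.
#'
#' @param records Tibble with a `value` column plus `birth_year`, `breed`,
#'   `herd_id`, `plate_id`.
#' @param value Name of the phenotype column (default `"value"`).
#' @return Input tibble with an added `adjusted` column (residuals, centred
#'   at zero). The fitted variance components are attached as attribute
#'   `"varcomp"` (tibble `term`, `variance`).
#' @export
adjust_phenotype <- function(records, value = "value") {
  records <- tibble::as_tibble(records)
  need <- c(value, "birth_year", "breed", "herd_id", "plate_id")
  missing <- setdiff(need, names(records))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  y <- records[[value]]
  fixed <- c("birth_year", "breed")
  random <- c("herd_id", "plate_id")
  demote <- random[vapply(random, function(v) length(unique(records[[v]])) < 3,
                          logical(1))]
  random <- setdiff(random, demote)
  fixed <- c(fixed, demote)
  # keep only fixed factors with >= 2 levels (constants carry no information)
  fixed <- fixed[vapply(fixed, function(v) length(unique(records[[v]])) >= 2,
                        logical(1))]
  fixed_terms <- if (length(fixed)) paste(sprintf("factor(%s)", fixed), collapse = " + ") else "1"
  mm <- stats::model.matrix(stats::as.formula(paste("~", fixed_terms)), data = records)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[setdiff(seq_len(ncol(mm)), qr_mm$pivot[seq_len(qr_mm$rank)])]
    stop("singular fixed-effect design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(random)) {
    fml <- stats::as.formula(paste(
      value, "~", fixed_terms, "+",
      paste(sprintf("(1 | %s)", random), collapse = " + ")
    ))
    fit <- lme4::lmer(fml, data = records, REML = TRUE)
    res <- stats::residuals(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- tibble::tibble(term = vc$grp, variance = vc$vcov)
  } else {
    fml <- stats::as.formula(paste(value, "~", fixed_terms))
    fit <- stats::lm(fml, data = records)
    res <- stats::residuals(fit)
    varcomp <- tibble::tibble(term = "Residual", variance = stats::sigma(fit)^2)
  }
  records$adjusted <- as.numeric(res - mean(res))
  attr(records, "varcomp") <- varcomp
  records
}

#' Genomic relationship matrix (VanRaden)
#'
#' Centred, frequency-scaled cross-product of dosages:
#' \eqn{G = Z Z' / (2 \sum_j p_j (1 - p_j))} with \eqn{Z = X - 2p}.
#' Missing dosages are mean-imputed per variant and monomorphic variants are
#' dropped; the result is symmetric with diagonal near 1 in expectation
#' under Hardy-Weinberg equilibrium.
#'
#' @param dosage Animals x variants numeric matrix of 0/1/2 dosages (NA
#'   allowed).
#' @return Symmetric animals x animals matrix.
#' @export
build_grm <- function(dosage) {
  stopifnot(is.matrix(dosage), ncol(dosage) >= 2)
  dosage <- impute_dosage(dosage)
  p <- colMeans(dosage) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all variants are monomorphic", call. = FALSE)
  Z <- sweep(dosage[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  (G + t(G)) / 2
}

impute_dosage <- function(dosage) {
  if (!anyNA(dosage)) return(dosage)
  means <- colMeans(dosage, na.rm = TRUE)
  idx <- which(is.na(dosage), arr.ind = TRUE)
  dosage[idx] <- means[idx[, 2]]
  dosage
}

#' Leave-one-chromosome-out GRM
#'
#' Builds the GRM from all variants not on the target chromosome, so the
#' polygenic control never absorbs signal from the chromosome being scanned.
#'
#' @param dosage Animals x variants dosage matrix.
#' @param variants Tibble with `variant_id` and `chrom` aligned with the
#'   matrix columns.
#' @param target_chrom Chromosome label to exclude.
#' @return Symmetric animals x animals matrix.
#' @export
loco_grm <- function(dosage, variants, target_chrom) {
  stopifnot(ncol(dosage) == nrow(variants))
  keep <- variants$chrom != target_chrom
  if (!any(keep)) stop("all variants are on the target chromosome", call. = FALSE)
  build_grm(dosage[, keep, drop = FALSE])
}

# one-time REML variance-component estimate for y = mu + g + e,
# g ~ N(0, sg2 * GRM); returns the eigen-rotation used for per-variant GLS
polygenic_rotation <- function(y, grm) {
  eg <- eigen(grm, symmetric = TRUE)
  U <- eg$vectors
  lam <- pmax(eg$values, 0)
  yt <- drop(crossprod(U, y))
  ones <- drop(crossprod(U, rep(1, length(y))))
  n <- length(y)
  neg_reml <- function(log_ratio) {
    # ratio = sg2 / se2
    d <- exp(log_ratio) * lam + 1
    # profile out mu and se2 (REML)
    w <- 1 / d
    mu <- sum(w * ones * yt) / sum(w * ones^2)
    r <- yt - mu * ones
    se2 <- sum(r^2 / d) / (n - 1)
    0.5 * (sum(log(d)) + (n - 1) * log(se2) + log(sum(ones^2 / d)))
  }
  opt <- stats::optimize(neg_reml, c(-10, 10))
  ratio <- exp(opt$minimum)
  d <- ratio * lam + 1
  list(U = U, d = d, yt = yt, ones = ones, ratio = ratio)
}

#' Single-variant association scan
#'
#' Per variant, the allele-substitution effect on the adjusted phenotype
#' with its Wald standard error and p-value. Without a GRM this is the
#' ordinary least-squares regression of phenotype on dosage. With a GRM,
#' a polygenic random effect is fitted once by REML through an
#' eigendecomposition of the GRM, and each variant is then tested by
#' generalised least squares in the rotated coordinates. Missing dosages
#' are mean-imputed; monomorphic variants are reported with `p = NA`.
#'
#' @param y Adjusted phenotype vector (one value per animal, aligned with
#'   the rows of `dosage`).
#' @param dosage Animals x variants dosage matrix.
#' @param grm Optional GRM from [build_grm()] / [loco_grm()].
#' @param variants Optional tibble (`variant_id`, `chrom`, `pos`) aligned
#'   with the matrix columns; generated labels are used when omitted.
#' @param threshold Nominal p-value threshold for the `significant` flag
#'   (e.g. from [bonferroni_threshold()]); default 0.05 over the number of
#'   variants scanned.
#' @return Tibble of class `blg_scan`: `variant_id`, `chrom`, `pos`, `beta`,
#'   `se`, `p`, `significant`.
#' @export
assoc_scan <- function(y, dosage, grm = NULL, variants = NULL,
                       threshold = NULL) {
  stopifnot(is.matrix(dosage), length(y) == nrow(dosage))
  if (!is.null(grm) && !all(dim(grm) == nrow(dosage))) {
    stop("GRM dimensions do not match the genotype matrix", call. = FALSE)
  }
  if (is.null(variants)) {
    variants <- tibble::tibble(
      variant_id = colnames(dosage) %||% sprintf("v%05d", seq_len(ncol(dosage))),
      chrom = NA_character_, pos = NA_integer_
    )
  }
  stopifnot(nrow(variants) == ncol(dosage))
  if (is.null(threshold)) threshold <- 0.05 / ncol(dosage)
  dosage <- impute_dosage(dosage)
  n <- length(y)
  if (stats::var(y) == 0) {
    out <- tibble::tibble(
      variant_id = variants$variant_id, chrom = variants$chrom,
      pos = variants$pos, beta = 0, se = 0, p = 1, significant = FALSE
    )
    class(out) <- c("blg_scan", class(out))
    attr(out, "threshold") <- threshold
    return(out)
  }
  if (is.null(grm)) {
    yc <- y - mean(y)
    Xc <- sweep(dosage, 2, colMeans(dosage))
    sxx <- colSums(Xc^2)
    sxy <- drop(crossprod(Xc, yc))
    beta <- ifelse(sxx > 0, sxy / sxx, 0)
    rss <- sum(yc^2) - beta^2 * sxx
    df <- n - 2
    se <- ifelse(sxx > 0, sqrt(pmax(rss, 0) / df / sxx), NA_real_)
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df)
    p[sxx == 0] <- NA_real_
    beta[sxx == 0] <- 0
  } else {
    rot <- polygenic_rotation(y, grm)
    w <- 1 / rot$d
    Xt <- crossprod(rot$U, dosage)  # rotated dosages, variants in columns
    ones <- rot$ones
    yt <- rot$yt
    s11 <- sum(w * ones^2)
    s1y <- sum(w * ones * yt)
    s1x <- drop(crossprod(Xt * w, ones))
    sxx <- colSums(Xt^2 * w)
    sxy <- drop(crossprod(Xt * w, yt))
    # GLS with intercept: project out the (rotated) intercept
    sxx_c <- sxx - s1x^2 / s11
    sxy_c <- sxy - s1x * s1y / s11
    syy_c <- sum(w * yt^2) - s1y^2 / s11
    beta <- ifelse(sxx_c > 1e-12, sxy_c / sxx_c, 0)
    df <- n - 2
    rss <- syy_c - beta^2 * sxx_c
    se <- ifelse(sxx_c > 1e-12, sqrt(pmax(rss, 0) / df / sxx_c), NA_real_)
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df)
    mono <- apply(dosage, 2, function(g) stats::var(g) == 0)
    p[mono] <- NA_real_
    beta[mono] <- 0
  }
  out <- tibble::tibble(
    variant_id = variants$variant_id, chrom = variants$chrom,
    pos = variants$pos, beta = beta, se = se, p = p,
    significant = !is.na(p) & p <= threshold
  )
  class(out) <- c("blg_scan", class(out))
  attr(out, "threshold") <- threshold
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni significance threshold
#'
#' Nominal per-test p-value threshold controlling the family-wise error at
#' `alpha` over all variants and traits tested jointly:
#' `alpha / (n_variants * n_traits)`.
#'
#' @param alpha Genome-wide error rate.
#' @param n_variants Number of variants tested.
#' @param n_traits Number of traits treated as independent tests.
#' @return One-row tibble: `threshold` (full precision) and
#'   `threshold_signif` (3 significant figures).
#' @examples
#' bonferroni_threshold(0.01, 16122289, 3)  # 2.07e-10
#' @export
bonferroni_threshold <- function(alpha, n_variants, n_traits = 1) {
  if (alpha <= 0 || n_variants <= 0 || n_traits <= 0) {
    stop("alpha, n_variants and n_traits must all be positive", call. = FALSE)
  }
  th <- alpha / (n_variants * n_traits)
  tibble::tibble(threshold = th, threshold_signif = signif(th, 3))
}

#' Heterozygous-AB subset for isoform-specific scans
#'
#' Returns the animals called heterozygous AB (including the low-B flagged
#' calls) minus an optional explicit exclusion list — the subset on which
#' the A- and B-isoform concentration scans are run.
#'
#' @param calls Output of [classify_genotype()] with `animal_id`.
#' @param exclude Optional character vector of animal ids to drop.
#' @return Tibble with the retained calls.
#' @export
heterozygote_subset <- function(calls, exclude = character()) {
  dplyr::filter(calls, .data$class_label %in% c("AB", "AB_lowB"),
                !.data$animal_id %in% exclude)
}
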