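# Allele-specific expression: genotype-class assignment from the three
# diagnostic SNPs, library-size normalisation, class-level expression ratios
# and within-animal allelic ratios with bootstrap uncertainty.

DIAG_SNPS <- c(g_64 = "rs110066229", g_118 = "rs109625649", g_26 = "rs209645844")

geno_dose <- function(g, snp) {
  d <- c("ref/ref" = 0L, "ref/alt" = 1L, "alt/ref" = 1L, "alt/alt" = 2L)[g]
  if (any(is.na(d))) {
    stop("missing or unrecognised genotype at ", snp,
         " (expected ref/ref, ref/alt or alt/alt)", call. = FALSE)
  }
  unname(d)
}

#' Assign BLG genotype classes from diagnostic-SNP genotypes
#'
#' The two missense SNPs rs110066229 (p.Glu64Asp) and rs109625649
#' (p.Val118Ala) jointly define the A vs B protein lineage (alt = B lineage;
#' they are in complete linkage so their alt doses must agree), and
#' rs209645844 (chr11:103,256,256 G>A, p.Leu26Leu) splits B-lineage alleles
#' into B (ref) and B' (alt). Triplets violating lineage phase — unequal
#' missense doses, or more B' alleles than B-lineage alleles — are labelled
#' `inconsistent`. Animals flagged as C-allele carriers (from the separate
#' C-defining marker) are routed to `C_carrier` and excluded from ratio
#' estimation downstream.
#'
#' @param genotypes Tibble with columns `g_64`, `g_118`, `g_26` (strings
#'   `"ref/ref"`, `"ref/alt"`, `"alt/alt"`) and optionally `c_carrier`
#'   (logical) and `animal_id`.
#' @return Input tibble with an added `genotype_class` column, one of
#'   `AA, AB, ABprime, BB, BBprime, BprimeBprime, C_carrier, inconsistent`.
#' @export
assign_blg_class <- function(genotypes) {
  genotypes <- tibble::as_tibble(genotypes)
  stopifnot(all(c("g_64", "g_118", "g_26") %in% names(genotypes)))
  d64 <- geno_dose(genotypes$g_64, "g_64 (rs110066229)")
  d118 <- geno_dose(genotypes$g_118, "g_118 (rs109625649)")
  d26 <- geno_dose(genotypes$g_26, "g_26 (rs209645844)")
  b_lineage <- d64
  n_bprime <- d26
  cls <- dplyr::case_when(
    d64 != d118 ~ "inconsistent",
    n_bprime > b_lineage ~ "inconsistent",
    b_lineage == 0 ~ "AA",
    b_lineage == 1 & n_bprime == 0 ~ "AB",
    b_lineage == 1 ~ "ABprime",
    n_bprime == 0 ~ "BB",
    n_bprime == 1 ~ "BBprime",
    TRUE ~ "BprimeBprime"
  )
  if ("c_carrier" %in% names(genotypes)) {
    cls[genotypes$c_carrier %in% TRUE] <- "C_carrier"
  }
  genotypes$genotype_class <- cls
  genotypes
}

#' Library-size normalised expression
#'
#' Adjusts a per-animal gene-level read total for that animal's total read
#' count relative to the average read count over all animals:
#' `gene_count * mean_library_size / library_size`. Invariant to rescaling
#' all library sizes and counts by a common constant.
#'
#' @param gene_count Per-animal gene read totals.
#' @param library_size Per-animal total mapped reads (> 0).
#' @param mean_library_size Reference library size; defaults to
#'   `mean(library_size)`.
#' @return Numeric vector of normalised expression values.
#' @export
normalize_expression <- function(gene_count, library_size,
                                 mean_library_size = mean(library_size)) {
  if (any(library_size <= 0)) stop("library sizes must be positive", call. = FALSE)
  gene_count * mean_library_size / library_size
}

#' Ratio of class-mean expression with bootstrap SD
#'
#' Ratio of the mean normalised expression in the numerator class to that in
#' the denominator class. Bootstrap resamples animals within each class
#' independently; the SD of the bootstrap ratios is reported.
#'
#' @param expr Tibble with columns `genotype_class` and `expression` (one
#'   row per animal).
#' @param num_class,den_class Class labels to compare.
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @return One-row tibble: `num_class`, `den_class`, `ratio`, `sd_boot`,
#'   `n_num`, `n_den`.
#' @export
class_ratio <- function(expr, num_class, den_class, n_boot = 1000, seed = 1L) {
  stopifnot(n_boot >= 100)
  xn <- expr$expression[expr$genotype_class == num_class]
  xd <- expr$expression[expr$genotype_class == den_class]
  if (length(xn) == 0 || length(xd) == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  if (mean(xd) == 0) stop("denominator class mean is zero", call. = FALSE)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(xn, replace = TRUE)) / mean(sample(xd, replace = TRUE))
  }, numeric(1))
  tibble::tibble(
    num_class = num_class, den_class = den_class,
    ratio = mean(xn) / mean(xd), sd_boot = stats::sd(boots),
    n_num = length(xn), n_den = length(xd)
  )
}

#' Relative expression of one allele vs the other
#'
#' Plain count ratio `count_allele1 / count_allele2`; the read-level estimate
#' of allele 1's expression relative to allele 2 at a heterozygous site.
#' Returns `NA` (with a warning) when both counts are zero.
#'
#' @param count_allele1,count_allele2 Non-negative read counts (vectorised).
#' @return Numeric vector of ratios.
#' @export
allele_fraction <- function(count_allele1, count_allele2) {
  out <- ifelse(count_allele2 > 0, count_allele1 / count_allele2, NA_real_)
  if (any(count_allele1 == 0 & count_allele2 == 0)) {
    warning("allele fraction undefined where both counts are zero", call. = FALSE)
  }
  out
}

# pooled alt/ref ratio for one class at one SNP, with animal-level bootstrap
pooled_allelic_ratio <- function(counts, ids, snp, n_boot, min_depth, pooled) {
  sub <- counts[counts$animal_id %in% ids & counts$snp_id == snp, ]
  sub <- sub[sub$count_ref + sub$count_alt >= min_depth, ]
  if (nrow(sub) == 0) {
    stop("no animals with sufficient depth at ", snp, call. = FALSE)
  }
  est <- function(d) {
    if (pooled) sum(d$count_alt) / sum(d$count_ref)
    else mean(d$count_alt / d$count_ref)
  }
  boots <- vapply(seq_len(n_boot), function(i) {
    est(sub[sample.int(nrow(sub), replace = TRUE), ])
  }, numeric(1))
  list(ratio = est(sub), boots = boots, n = nrow(sub))
}

#' Allelic expression ratio in one genotype class
#'
#' Pooled alternate/reference read-count ratio at a diagnostic SNP across
#' the animals of one class — e.g. the B-vs-A expression ratio from AB
#' heterozygotes at rs109625649. The default aggregates reads before taking
#' the ratio (read-weighted); `pooled = FALSE` averages per-animal ratios.
#' Uncertainty is an animal-level bootstrap SD.
#'
#' @param counts Allele-count tibble (`animal_id`, `snp_id`, `count_ref`,
#'   `count_alt`).
#' @param classes Tibble with `animal_id` and `genotype_class`.
#' @param class Genotype class whose heterozygous animals are used.
#' @param snp SNP id (default rs109625649, the A-vs-B site).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param min_depth Minimum site depth for an animal to contribute.
#' @param pooled Read-weighted pooled ratio (default) or mean of per-animal
#'   ratios.
#' @return One-row tibble: `class`, `snp_id`, `ratio` (alt / ref), `sd_boot`,
#'   `n_animals`.
#' @export
allelic_ratio <- function(counts, classes, class, snp = "rs109625649",
                          n_boot = 1000, seed = 1L, min_depth = 20,
                          pooled = TRUE) {
  ids <- classes$animal_id[classes$genotype_class == class]
  if (length(ids) == 0) stop("no animals in class ", class, call. = FALSE)
  set.seed(seed)
  r <- pooled_allelic_ratio(counts, ids, snp, n_boot, min_depth, pooled)
  tibble::tibble(class = class, snp_id = snp, ratio = r$ratio,
                 sd_boot = stats::sd(r$boots), n_animals = r$n)
}

#' Expression of the B' allele relative to B
#'
#' Two estimators of the same biological quantity:
#' \describe{
#'   \item{`within_BBprime`}{Within BB' heterozygotes, the ratio of B'-allele
#'     (alt) to B-allele (ref) reads at chr11:103,256,256 (rs209645844),
#'     read-weighted across animals with animal-level bootstrap SD.}
#'   \item{`ABprime_vs_AB`}{The B-lineage/A allele-count ratio at
#'     chr11:103,259,232 (rs109625649) in AB' animals divided by the same
#'     ratio in AB animals; since the A allele is the common reference in
#'     both classes, the quotient estimates B'/B. Bootstraps both classes
#'     independently.}
#' }
#'
#' @param counts Allele-count tibble (`animal_id`, `snp_id`, `count_ref`,
#'   `count_alt`).
#' @param classes Tibble with `animal_id` and `genotype_class` (from
#'   [assign_blg_class()]).
#' @param mode `"within_BBprime"` or `"ABprime_vs_AB"`.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param min_depth Minimum site depth per contributing animal.
#' @param pooled Read-weighted pooling (default) or per-animal means.
#' @return One-row tibble: `mode`, `ratio`, `sd_boot`, `n_animals`.
#' @export
bprime_relative_expression <- function(counts, classes,
                                       mode = c("within_BBprime", "ABprime_vs_AB"),
                                       n_boot = 1000, seed = 1L, min_depth = 20,
                                       pooled = TRUE) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "within_BBprime") {
    ids <- classes$animal_id[classes$genotype_class == "BBprime"]
    if (length(ids) == 0) stop("no BBprime animals", call. = FALSE)
    r <- pooled_allelic_ratio(counts, ids, "rs209645844", n_boot, min_depth, pooled)
    tibble::tibble(mode = mode, ratio = r$ratio, sd_boot = stats::sd(r$boots),
                   n_animals = r$n)
  } else {
    ids_num <- classes$animal_id[classes$genotype_class == "ABprime"]
    ids_den <- classes$animal_id[classes$genotype_class == "AB"]
    if (length(ids_num) == 0 || length(ids_den) == 0) {
      stop("need both ABprime and AB animals", call. = FALSE)
    }
    rn <- pooled_allelic_ratio(counts, ids_num, "rs109625649", n_boot,
                               min_depth, pooled)
    rd <- pooled_allelic_ratio(counts, ids_den, "rs109625649", n_boot,
                               min_depth, pooled)
    tibble::tibble(mode = mode, ratio = rn$ratio / rd$ratio,
                   sd_boot = stats::sd(rn$boots / rd$boots),
                   n_animals = rn$n + rd$n)
  }
}
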