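# Seeded generators for every input the pipeline consumes: pedigreed cow
# populations with BLG haplotypes, per-cow isoform concentrations, flow-
# injection spectra, RNA-seq allele counts, genotype dosage matrices and
# milk-composition records.

HAPLOTYPES <- c("A", "B", "Bprime", "C")

#' Allele-specific expression model for the BLG locus
#'
#' Expected expression per allele copy: `base_A` for A, `base_A * rho_B`
#' for B, `base_A * rho_B * rho_Bprime` for B'. The C allele is expressed
#' at the B level (it shares the B protein channel in the screen).
#' Defaults encode the B allele expressing 64.2% of A and B' expressing
#' 41.9% of B. `cv_noise` is the coefficient of variation of the mean-one
#' multiplicative lognormal noise applied to simulated concentrations.
#'
#' @param base_A Expression units per A allele copy (positive).
#' @param rho_B B-allele expression as a fraction of A, in (0, 1].
#' @param rho_Bprime B'-allele expression as a fraction of B, in (0, 1].
#' @param cv_noise Coefficient of variation of multiplicative noise (>= 0).
#' @return A list of class `expression_model`.
#' @export
expression_model <- function(base_A = 90, rho_B = 0.642, rho_Bprime = 0.419,
                             cv_noise = 0.15) {
  stopifnot(base_A > 0, rho_B > 0, rho_B <= 1, rho_Bprime > 0, rho_Bprime <= 1,
            cv_noise >= 0)
  structure(list(base_A = base_A, rho_B = rho_B, rho_Bprime = rho_Bprime,
                 cv_noise = cv_noise),
            class = "expression_model")
}

# expression units contributed by one haplotype copy
haplotype_expression <- function(hap, model) {
  unname(c(A = model$base_A,
           B = model$base_A * model$rho_B,
           Bprime = model$base_A * model$rho_B * model$rho_Bprime,
           C = model$base_A * model$rho_B)[hap])
}

#' Simulation configuration
#'
#' Bundles population structure, allele frequencies, the expression model,
#' design-effect scales and per-isoform response factors. Response factors
#' convert summed allele expression to arb units; the defaults are tuned so
#' that a homozygous AA cow averages 180 arb units and a homozygous BB cow
#' 80 arb units, the screening assay's reference levels.
#'
#' @param n_animals Number of cows to simulate.
#' @param allele_freqs Named frequencies for haplotypes A, B, Bprime, C;
#'   must sum to 1. Defaults put B' at 1.5% (the 1-2% range reported for
#'   NZ Friesian) and C at 0 (C-carriers are excluded downstream; raise the
#'   frequency to exercise exclusion logic).
#' @param n_sires Number of sires in the sire pool.
#' @param carrier_sire_fraction Fraction of sires forced to carry \{B, B'\}.
#' @param n_herds,n_plates Numbers of herd and 96-well plate levels.
#' @param expression An [expression_model()].
#' @param herd_sd,plate_sd SDs (arb units) of additive random herd and plate
#'   intercepts.
#' @param birth_year_effects,breed_effects Named numeric vectors of additive
#'   fixed effects (arb units); names define the factor levels sampled.
#' @param response_factors Named arb-units-per-expression-unit factors for the
#'   A and B channels; `NULL` tunes them to the 180/80 reference levels.
#' @param seed Integer seed; every generator taking this config is
#'   reproducible under it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 2000,
                       allele_freqs = c(A = 0.55, B = 0.435, Bprime = 0.015, C = 0),
                       n_sires = 100,
                       carrier_sire_fraction = 0.05,
                       n_herds = 40,
                       n_plates = 112,
                       expression = expression_model(),
                       herd_sd = 5, plate_sd = 2,
                       birth_year_effects = c(`2015` = 0, `2016` = 0, `2017` = 0),
                       breed_effects = c(Friesian = 0, Jersey = 0, FJX = 0),
                       response_factors = NULL,
                       seed = 1L) {
  freqs <- allele_freqs[HAPLOTYPES]
  freqs[is.na(freqs)] <- 0
  names(freqs) <- HAPLOTYPES
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("allele frequencies must sum to 1", call. = FALSE)
  }
  if (is.null(response_factors)) {
    response_factors <- c(
      A = 180 / (2 * expression$base_A),
      B = 80 / (2 * expression$base_A * expression$rho_B)
    )
  }
  if (any(response_factors < 0)) stop("response factors must be non-negative", call. = FALSE)
  structure(list(
    n_animals = n_animals, allele_freqs = freqs, n_sires = n_sires,
    carrier_sire_fraction = carrier_sire_fraction, n_herds = n_herds,
    n_plates = n_plates, expression = expression, herd_sd = herd_sd,
    plate_sd = plate_sd, birth_year_effects = birth_year_effects,
    breed_effects = breed_effects, response_factors = response_factors,
    seed = as.integer(seed)
  ), class = "sim_config")
}

draw_haplotype <- function(n, freqs) {
  sample(HAPLOTYPES, n, replace = TRUE, prob = freqs)
}

#' Simulate a pedigreed cow population
#'
#' Sires draw haplotype pairs from the population frequencies, except for a
#' configured fraction forced to carry \{B, B'\} (Sire-99-style carriers).
#' Each cow draws one haplotype from her sire's pair (fair Mendelian coin)
#' and one from the population frequencies; herds and plates are assigned
#' uniformly; SCC is lognormal.
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per cow: `animal_id`, `sire_id`, `breed`,
#'   `birth_year`, `herd_id`, `plate_id`, `hap1` (sire-transmitted), `hap2`
#'   (dam-transmitted), `scc`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_animals
  n_car <- round(config$n_sires * config$carrier_sire_fraction)
  sires <- tibble::tibble(
    sire_id = sprintf("S%03d", seq_len(config$n_sires)),
    s_hap1 = c(rep("B", n_car), draw_haplotype(config$n_sires - n_car, config$allele_freqs)),
    s_hap2 = c(rep("Bprime", n_car), draw_haplotype(config$n_sires - n_car, config$allele_freqs))
  )
  cows <- tibble::tibble(
    animal_id = sprintf("C%05d", seq_len(n)),
    sire_id = sample(sires$sire_id, n, replace = TRUE),
    breed = sample(names(config$breed_effects), n, replace = TRUE),
    birth_year = as.integer(sample(names(config$birth_year_effects), n, replace = TRUE)),
    herd_id = sprintf("H%02d", sample.int(config$n_herds, n, replace = TRUE)),
    plate_id = sprintf("P%03d", sample.int(config$n_plates, n, replace = TRUE)),
    scc = round(stats::rlnorm(n, meanlog = log(68000), sdlog = 0.9))
  )
  cows <- dplyr::left_join(cows, sires, by = "sire_id")
  from_sire <- stats::runif(n) < 0.5
  cows$hap1 <- ifelse(from_sire, cows$s_hap1, cows$s_hap2)
  cows$hap2 <- draw_haplotype(n, config$allele_freqs)
  dplyr::select(cows, -"s_hap1", -"s_hap2")
}

#' Simulate per-cow isoform concentrations
#'
#' Sums per-allele expression into the A channel (A alleles) and the B
#' channel (B, B' and C alleles — the screen cannot discriminate B from C),
#' multiplies by the per-channel response factor, applies mean-one
#' multiplicative lognormal noise and adds the herd/plate/birth-year/breed
#' design effects. In the noiseless, zero-effect limit the output equals the
#' deterministic allele-sum model exactly.
#'
#' @param cows Tibble from [simulate_population()] (needs `hap1`, `hap2`,
#'   `herd_id`, `plate_id`, `birth_year`, `breed`).
#' @param config A [sim_config()].
#' @return Input tibble with added `A_units`, `B_units` (arb) and `A_gl`,
#'   `B_gl` (g/L via the default [blg_panel()] calibration).
#' @export
simulate_concentrations <- function(cows, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  em <- config$expression
  n <- nrow(cows)
  expr_a <- (cows$hap1 == "A") * em$base_A + (cows$hap2 == "A") * em$base_A
  bchan <- function(h) haplotype_expression(h, em) * (h != "A")
  expr_b <- bchan(cows$hap1) + bchan(cows$hap2)
  mean_a <- config$response_factors[["A"]] * expr_a
  mean_b <- config$response_factors[["B"]] * expr_b
  herd_eff <- stats::setNames(stats::rnorm(config$n_herds, 0, config$herd_sd),
                              sprintf("H%02d", seq_len(config$n_herds)))
  plate_eff <- stats::setNames(stats::rnorm(config$n_plates, 0, config$plate_sd),
                               sprintf("P%03d", seq_len(config$n_plates)))
  design <- unname(herd_eff[cows$herd_id]) + unname(plate_eff[cows$plate_id]) +
    unname(config$birth_year_effects[as.character(cows$birth_year)]) +
    unname(config$breed_effects[cows$breed])
  noise <- function() lognormal_mean_one(n, em$cv_noise)
  cows$A_units <- pmax(0, mean_a * noise() + design * (mean_a > 0))
  cows$B_units <- pmax(0, mean_b * noise() + design * (mean_b > 0))
  cows$A_gl <- calibrate_units(cows$A_units, "A")
  cows$B_gl <- calibrate_units(cows$B_units, "B")
  cows
}

# mean-one multiplicative lognormal draws with coefficient of variation cv
lognormal_mean_one <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# lognormal draws matching a target mean and SD
lognormal_moments <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a flow-injection ESI spectrum
#'
#' Places Gaussian-shaped peaks at each isoform's diagnostic charge-state
#' m/z positions, with the total envelope area proportional to the isoform's
#' concentration (equal area per charge state), plus optional additive
#' baseline noise. The m/z support is the screening range 1400-1900.
#'
#' The default grid step (0.05 m/z) divides the 1-decimal diagnostic m/z
#' positions evenly, so every peak is sampled symmetrically and window
#' extraction recovers relative abundances to numerical precision.
#'
#' @param concentrations Named numeric, e.g. `c(A = 120, B = 60)` (arb units).
#' @param panel A [blg_panel()] providing peak positions.
#' @param noise_sd SD of additive Gaussian baseline noise (intensity units).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param peak_sd Gaussian peak SD in m/z.
#' @param mz_step Grid spacing in m/z.
#' @param mz_range Acquisition range.
#' @return Spectrum tibble (`mz`, `intensity`).
#' @export
simulate_spectrum <- function(concentrations, panel = blg_panel(),
                              noise_sd = 0, seed = 1L, peak_sd = 0.5,
                              mz_step = 0.05, mz_range = c(1400, 1900)) {
  panel <- tibble::as_tibble(panel)
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  mz <- seq(mz_range[1], mz_range[2], by = mz_step)
  intensity <- numeric(length(mz))
  for (iso in unique(panel$isoform)) {
    conc <- concentrations[[iso]]
    if (is.null(conc) || conc == 0) next
    centers <- panel$mz[panel$isoform == iso]
    area_per_peak <- conc / length(centers)
    for (ctr in centers) {
      intensity <- intensity + area_per_peak * stats::dnorm(mz, ctr, peak_sd)
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    intensity <- pmax(0, intensity + stats::rnorm(length(mz), 0, noise_sd))
  }
  tibble::tibble(mz = mz, intensity = intensity)
}

#' Simulate RNA-seq allele counts at the three diagnostic BLG SNPs
#'
#' Per animal, a lognormal library-size factor scales both the total library
#' and the per-site depth; at each SNP the alternate-allele count is binomial
#' with the allelic fraction implied by the expression model. Diagnostic
#' sites and allele conventions: rs110066229 and rs109625649 carry the
#' A-lineage allele as `ref` and the B-lineage allele as `alt`;
#' rs209645844 (chr11:103,256,256 G>A) carries G (= B, also A and C
#' haplotypes) as `ref` and A (= B') as `alt`.
#'
#' @param cows Tibble with `animal_id`, `hap1`, `hap2`.
#' @param expression An [expression_model()].
#' @param depth_mean Mean per-site read depth (> 0).
#' @param lib_mean Mean total library size.
#' @param lib_cv CV of the lognormal library-size factor.
#' @param gene_scale Gene-level reads per expression unit (for the
#'   normalisation workflow's `gene_count`).
#' @param seed Integer seed.
#' @return Long tibble: `animal_id`, `snp_id`, `count_ref`, `count_alt`,
#'   `library_size`, `gene_count`.
#' @export
simulate_allele_counts <- function(cows, expression = expression_model(),
                                   depth_mean = 1000, lib_mean = 1e6,
                                   lib_cv = 0.3, gene_scale = 10, seed = 1L) {
  stopifnot(depth_mean > 0)
  set.seed(seed)
  n <- nrow(cows)
  lib_factor <- lognormal_mean_one(n, lib_cv)
  expr1 <- haplotype_expression(cows$hap1, expression)
  expr2 <- haplotype_expression(cows$hap2, expression)
  total <- expr1 + expr2
  base <- tibble::tibble(
    animal_id = cows$animal_id,
    library_size = round(lib_mean * lib_factor),
    gene_count = round(total * lib_factor * gene_scale),
    lib_factor = lib_factor, expr1 = expr1, expr2 = expr2,
    hap1 = cows$hap1, hap2 = cows$hap2
  )
  snp_alt <- list(
    rs110066229 = c("B", "Bprime", "C"),
    rs109625649 = c("B", "Bprime", "C"),
    rs209645844 = "Bprime"
  )
  purrr::map_dfr(names(snp_alt), function(snp) {
    alt_haps <- snp_alt[[snp]]
    frac_alt <- (base$expr1 * (base$hap1 %in% alt_haps) +
                   base$expr2 * (base$hap2 %in% alt_haps)) / total
    depth <- stats::rpois(n, depth_mean * base$lib_factor)
    alt <- stats::rbinom(n, depth, frac_alt)
    tibble::tibble(
      animal_id = base$animal_id, snp_id = snp,
      count_ref = depth - alt, count_alt = alt,
      library_size = base$library_size, gene_count = base$gene_count
    )
  }) |> dplyr::arrange(.data$animal_id, .data$snp_id)
}

#' Diagnostic-SNP genotypes implied by a cow's haplotype pair
#'
#' Translates haplotype pairs into genotype strings at the three diagnostic
#' SNPs (allele conventions as in [simulate_allele_counts()]), plus a
#' `c_carrier` flag from the separate C-defining marker.
#'
#' @param cows Tibble with `animal_id`, `hap1`, `hap2`.
#' @return Tibble: `animal_id`, `g_64`, `g_118`, `g_26`, `c_carrier`.
#' @export
diagnostic_genotypes <- function(cows) {
  geno <- function(n_alt) c("ref/ref", "ref/alt", "alt/alt")[n_alt + 1L]
  b_lineage <- (cows$hap1 %in% c("B", "Bprime", "C")) +
    (cows$hap2 %in% c("B", "Bprime", "C"))
  n_bp <- (cows$hap1 == "Bprime") + (cows$hap2 == "Bprime")
  tibble::tibble(
    animal_id = cows$animal_id,
    g_64 = geno(b_lineage), g_118 = geno(b_lineage), g_26 = geno(n_bp),
    c_carrier = cows$hap1 == "C" | cows$hap2 == "C"
  )
}

#' Simulate a genotype dosage matrix for the association scan
#'
#' Independent variants in Hardy-Weinberg proportions, with uniform minor
#' allele frequencies and variants spread evenly over chromosome labels.
#'
#' @param n_animals,n_variants Dimensions.
#' @param n_chrom Number of chromosome labels.
#' @param maf_range Range of allele frequencies to draw from.
#' @param seed Integer seed.
#' @return List: `dosage` (animals x variants 0/1/2 matrix, dimnames set)
#'   and `variants` (tibble `variant_id`, `chrom`, `pos`).
#' @export
simulate_genotype_matrix <- function(n_animals, n_variants, n_chrom = 5,
                                     maf_range = c(0.05, 0.5), seed = 1L) {
  set.seed(seed)
  p <- stats::runif(n_variants, maf_range[1], maf_range[2])
  dosage <- vapply(p, function(pp) stats::rbinom(n_animals, 2, pp),
                   numeric(n_animals))
  dimnames(dosage) <- list(sprintf("C%05d", seq_len(n_animals)),
                           sprintf("v%05d", seq_len(n_variants)))
  variants <- tibble::tibble(
    variant_id = colnames(dosage),
    chrom = sprintf("chr%d", rep_len(seq_len(n_chrom), n_variants)),
    pos = seq_len(n_variants) * 1000L
  )
  list(dosage = dosage, variants = variants)
}

#' Mendelian offspring dosages from two parent rows
#'
#' Each offspring variant receives one gamete per parent, drawn as
#' Bernoulli(parent dosage / 2) — standard gene dropping.
#'
#' @param sire,dam Numeric dosage vectors (0/1/2) of equal length.
#' @return Integer dosage vector.
#' @export
mendelian_offspring <- function(sire, dam) {
  stopifnot(length(sire) == length(dam))
  stats::rbinom(length(sire), 1, sire / 2) + stats::rbinom(length(dam), 1, dam / 2)
}

#' Table-style milk-composition group parameters
#'
#' Default per-genotype-group means and SEMs (with group sizes 28/64/29 for
#' B'B'/BB/AA) used by [simulate_composition()]: fat, crude protein, true
#' protein, lactose and casein in g/L, the casein number (casein as a
#' fraction of true protein) and the BLG signal in arb units.
#'
#' @return Tibble: `genotype_class`, `n`, `component`, `mean`, `sem`.
#' @export
composition_group_means <- function() {
  tibble::tribble(
    ~genotype_class, ~n, ~component, ~mean, ~sem,
    "BprimeBprime", 28, "fat", 41.0, 4.0,
    "BprimeBprime", 28, "crude_protein", 34.9, 0.7,
    "BprimeBprime", 28, "true_protein", 32.3, 0.7,
    "BprimeBprime", 28, "lactose", 47.7, 0.4,
    "BprimeBprime", 28, "casein", 27.4, 0.6,
    "BprimeBprime", 28, "casein_number", 27.4 / 32.3, 0.004,
    "BprimeBprime", 28, "blg_units", 24, 1.0,
    "BB", 64, "fat", 44.6, 3.1,
    "BB", 64, "crude_protein", 34.9, 0.4,
    "BB", 64, "true_protein", 32.3, 0.4,
    "BB", 64, "lactose", 47.1, 0.4,
    "BB", 64, "casein", 27.0, 0.3,
    "BB", 64, "casein_number", 27.0 / 32.3, 0.003,
    "BB", 64, "blg_units", 46, 1.0,
    "AA", 29, "fat", 43.6, 4.2,
    "AA", 29, "crude_protein", 35.2, 0.6,
    "AA", 29, "true_protein", 32.8, 0.6,
    "AA", 29, "lactose", 47.2, 0.6,
    "AA", 29, "casein", 27.2, 0.5,
    "AA", 29, "casein_number", 27.2 / 32.8, 0.004,
    "AA", 29, "blg_units", 83, 4.0
  )
}

#' Simulate milk-composition records by genotype group
#'
#' Draws per-cow components around genotype-class means. Crude, true and
#' casein protein are built to respect casein <= true protein <= crude
#' protein: true protein is drawn first, the per-cow casein number is drawn
#' around the group ratio (so casein = number x true protein stays tightly
#' coupled to protein, as in real milk), and whey protein (crude minus true)
#' is drawn non-negative. Per-cow SDs are SEM * sqrt(n) from the group table.
#'
#' @param animals Tibble with `animal_id` and `genotype_class` (and
#'   optionally `scc`, preserved if present).
#' @param group_means Parameter tibble as from [composition_group_means()].
#' @param noise Scale factor on all SDs (0 gives noiseless group means).
#' @param seed Integer seed.
#' @return Tibble: one record per animal with `fat`, `crude_protein`,
#'   `true_protein`, `lactose`, `casein`, `blg_units`, `scc`.
#' @export
simulate_composition <- function(animals, group_means = composition_group_means(),
                                 noise = 1, seed = 1L) {
  set.seed(seed)
  wide <- group_means |>
    tidyr::pivot_wider(id_cols = c("genotype_class", "n"),
                       names_from = "component", values_from = c("mean", "sem"))
  if (any(wide$mean_casein > wide$mean_true_protein + 1e-9) ||
      any(wide$mean_true_protein > wide$mean_crude_protein + 1e-9)) {
    stop("group means must satisfy casein <= true protein <= crude protein",
         call. = FALSE)
  }
  missing_cls <- setdiff(unique(animals$genotype_class), wide$genotype_class)
  if (length(missing_cls)) {
    stop("no group means for genotype class: ", paste(missing_cls, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::left_join(animals, wide, by = "genotype_class")
  m <- nrow(out)
  sdv <- function(sem, n) noise * sem * sqrt(n)
  draw <- function(mean, sem, n) pmax(0, stats::rnorm(m, mean, sdv(sem, n)))
  out$true_protein <- draw(out$mean_true_protein, out$sem_true_protein, out$n)
  cn <- pmin(0.999, pmax(0.01, stats::rnorm(m, out$mean_casein / out$mean_true_protein,
                                            sdv(out$sem_casein_number, out$n))))
  out$casein <- cn * out$true_protein
  whey <- pmax(0, stats::rnorm(m, out$mean_crude_protein - out$mean_true_protein,
                               sdv(out$sem_crude_protein, out$n)))
  out$crude_protein <- out$true_protein + whey
  out$fat <- draw(out$mean_fat, out$sem_fat, out$n)
  out$lactose <- draw(out$mean_lactose, out$sem_lactose, out$n)
  out$blg_units <- draw(out$mean_blg_units, out$sem_blg_units, out$n)
  if (!"scc" %in% names(animals)) {
    out$scc <- round(stats::rlnorm(m, meanlog = log(68000), sdlog = 0.9))
  }
  dplyr::select(out, dplyr::any_of(c("animal_id", "genotype_class", "fat",
                                     "crude_protein", "true_protein", "lactose",
                                     "casein", "blg_units", "scc")))
}

#' The carrier-sire half-sib segregation preset
#'
#' Emulates the design used to demonstrate segregation of a low-expression
#' B sub-allele: daughters of one \{B, B'\} carrier sire, dams drawn from an
#' A/B population, screened by mass spectrometry. Heterozygous AB daughters
#' split into a high-B group (B transmitted; mean 54.0, SD 8.7 arb units)
#' and a low-B group (B' transmitted; mean 25.9, SD 6.1 arb units); single-
#' allele A signal averages 90 arb units. Per-allele contributions are
#' Gaussian (truncated at zero, which is 4+ SDs away), matching the
#' two-Gaussian segregation model the EM fit assumes; the protein-level
#' B':B ratio (25.9/54 = 0.48) is deliberately distinct from the
#' mRNA-level 0.419.
#'
#' @param n_daughters Number of daughters sampled (default 576).
#' @param dam_freq_A Frequency of the A haplotype in the dam pool.
#' @param group_stats Named list with `B = c(mean, sd)`, `Bprime = c(mean, sd)`
#'   for the per-allele B-channel contribution, and `A = c(mean, sd)` per A
#'   allele.
#' @param seed Integer seed.
#' @return Tibble of daughters: `animal_id`, `sire_id`, `hap1` (from sire),
#'   `hap2` (from dam), `A_units`, `B_units`, `ratio_BA` (NA when
#'   `A_units = 0`).
#' @export
simulate_sire99 <- function(n_daughters = 576, dam_freq_A = 0.41,
                            group_stats = list(A = c(90, 14.5),
                                               B = c(54.0, 8.7),
                                               Bprime = c(25.9, 6.1)),
                            seed = 1L) {
  set.seed(seed)
  n <- n_daughters
  hap1 <- sample(c("B", "Bprime"), n, replace = TRUE)
  hap2 <- sample(c("A", "B"), n, replace = TRUE,
                 prob = c(dam_freq_A, 1 - dam_freq_A))
  per_allele <- function(h) {
    out <- numeric(n)
    for (lab in names(group_stats)) {
      idx <- h == lab
      st <- group_stats[[lab]]
      out[idx] <- pmax(0, stats::rnorm(sum(idx), st[1], st[2]))
    }
    out
  }
  a1 <- per_allele(hap1); a2 <- per_allele(hap2)
  a_chan <- a1 * (hap1 == "A") + a2 * (hap2 == "A")
  b_chan <- a1 * (hap1 != "A") + a2 * (hap2 != "A")
  tibble::tibble(
    animal_id = sprintf("D%04d", seq_len(n)), sire_id = "Sire99",
    hap1 = hap1, hap2 = hap2,
    A_units = a_chan, B_units = b_chan,
    ratio_BA = ifelse(a_chan > 0, b_chan / a_chan, NA_real_)
  )
}

#' Write the generated tables to disk
#'
#' Writes `cows.csv`, `allele_counts.csv`, `composition.csv` and per-sample
#' spectra (two-column CSVs plus a `spectra_manifest.csv`) under `dir`.
#' Only the tables supplied are written.
#'
#' @param dir Output directory (created if needed).
#' @param cows,allele_counts,composition Optional tibbles.
#' @param spectra Optional named list of spectrum tibbles.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, cows = NULL, allele_counts = NULL,
                             composition = NULL, spectra = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cows)) utils::write.csv(cows, file.path(dir, "cows.csv"), row.names = FALSE)
  if (!is.null(allele_counts)) {
    utils::write.csv(allele_counts, file.path(dir, "allele_counts.csv"), row.names = FALSE)
  }
  if (!is.null(composition)) {
    utils::write.csv(composition, file.path(dir, "composition.csv"), row.names = FALSE)
  }
  if (!is.null(spectra)) {
    files <- sprintf("spectrum_%s.csv", names(spectra))
    purrr::walk2(spectra, files, ~ write_spectrum_csv(.x, file.path(dir, .y)))
    utils::write.csv(
      data.frame(sample_id = names(spectra), file = files),
      file.path(dir, "spectra_manifest.csv"), row.names = FALSE
    )
  }
  invisible(dir)
}
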