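# The seeded generators: population structure, concentrations, spectra,
# allele counts and composition records.

test_that("Mendelian transmission from carrier sires behaves binomially", {
  cfg <- noiseless_config(n_animals = 1000, n_sires = 1,
                          carrier_sire_fraction = 1, seed = 7)
  cows <- simulate_population(cfg)
  # one {B, Bprime} sire: transmitted-Bprime fraction inside the
  # binomial(1000, 0.5) 99% interval
  frac <- mean(cows$hap1 == "Bprime")
  expect_gte(frac, 0.46)
  expect_lte(frac, 0.54)
  expect_true(all(cows$hap1 %in% c("B", "Bprime")))
})

test_that("non-carrier sires never transmit Bprime and degenerate freqs work", {
  cfg <- noiseless_config(n_animals = 500, n_sires = 1, carrier_sire_fraction = 0,
                          allele_freqs = c(A = 0, B = 1, Bprime = 0, C = 0),
                          seed = 3)
  cows <- simulate_population(cfg)
  expect_true(all(cows$hap1 == "B"))
  cfg_a <- noiseless_config(n_animals = 200, allele_freqs = c(A = 1),
                            carrier_sire_fraction = 0, seed = 3)
  cows_a <- simulate_population(cfg_a)
  expect_true(all(cows_a$hap1 == "A" & cows_a$hap2 == "A"))
  expect_error(sim_config(allele_freqs = c(A = 0.6, B = 0.6)), "sum to 1")
})

test_that("dam-side haplotype frequencies converge to the configured values", {
  cfg <- noiseless_config(n_animals = 20000, seed = 2)
  cows <- simulate_population(cfg)
  for (h in c("A", "B", "Bprime")) {
    p <- cfg$allele_freqs[[h]]
    tol <- 3 * sqrt(p * (1 - p) / 20000) + 1e-12
    expect_lt(abs(mean(cows$hap2 == h) - p), max(tol, 0.005))
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_animals = 300, seed = 11)
  expect_identical(simulate_population(cfg), simulate_population(cfg))
  cows <- simulate_population(cfg)
  expect_identical(simulate_concentrations(cows, cfg),
                   simulate_concentrations(cows, cfg))
  expect_identical(simulate_allele_counts(cows, seed = 11),
                   simulate_allele_counts(cows, seed = 11))
})

test_that("noiseless concentrations follow the allele-sum model exactly", {
  cfg <- noiseless_config(n_animals = 3)
  cows <- make_cows(c("A", "B", "B"), c("A", "B", "Bprime"))
  cows$herd_id <- "H01"; cows$plate_id <- "P001"
  cows$birth_year <- 2015L; cows$breed <- "Friesian"
  conc <- simulate_concentrations(cows, cfg)
  expect_equal(conc$A_units, c(180, 0, 0))
  # BB tuned to the 80-arb reference; B' contributes rho_Bprime of a B allele
  expect_equal(conc$B_units[2], 80)
  expect_equal(conc$B_units[3], 80 * (1 + 0.419) / 2, tolerance = 1e-12)
  expect_equal(conc$B_units[3], 56.76, tolerance = 1e-3)
  # calibration columns track the arb units
  expect_equal(conc$A_gl[1], 4.8)
  expect_equal(conc$B_gl[2], 3.4)
})

test_that("the C haplotype is absorbed into the B channel", {
  cfg <- noiseless_config(n_animals = 1)
  cows <- make_cows("B", "C")
  cows$herd_id <- "H01"; cows$plate_id <- "P001"
  cows$birth_year <- 2015L; cows$breed <- "Friesian"
  conc <- simulate_concentrations(cows, cfg)
  expect_equal(conc$B_units, 80)  # C expressed at the B level, same channel
  expect_equal(conc$A_units, 0)
  expect_error(sim_config(response_factors = c(A = -1, B = 1)), "non-negative")
})

test_that("simulated spectra have the stated support and round-trip", {
  flat <- simulate_spectrum(c(A = 0, B = 0), noise_sd = 0)
  expect_true(all(flat$intensity == 0))
  expect_gte(min(flat$mz), 1400)
  expect_lte(max(flat$mz), 1900)
  sp <- simulate_spectrum(c(A = 90, B = 45))
  q <- quantify_isoforms(sp)
  expect_equal(q$units[q$isoform == "A"] / q$units[q$isoform == "B"], 2,
               tolerance = 1e-6)
  expect_error(quantify_isoforms(sp, panel = tibble::tibble()), "empty")
})

test_that("allele counts carry the expression-implied allelic fractions", {
  # {B, Bprime} cows: expected B'-read fraction at the G>A site is
  # 0.419 / 1.419 ~ 0.295
  cows <- make_cows(rep("B", 10000), rep("Bprime", 10000),
                    ids = sprintf("Q%05d", 1:10000))
  counts <- simulate_allele_counts(cows, depth_mean = 1000, seed = 5)
  g26 <- dplyr::filter(counts, snp_id == "rs209645844")
  frac <- sum(g26$count_alt) / sum(g26$count_alt + g26$count_ref)
  expect_lt(abs(frac - 0.419 / 1.419), 0.005)
  # homozygous A cows have no B-lineage reads
  aa <- make_cows(rep("A", 50), rep("A", 50), ids = sprintf("Z%03d", 1:50))
  counts_aa <- simulate_allele_counts(aa, depth_mean = 500, seed = 5)
  expect_true(all(counts_aa$count_alt == 0))
  expect_error(simulate_allele_counts(aa, depth_mean = 0), "depth_mean > 0")
})

test_that("diagnostic genotypes reflect the haplotype pair", {
  cows <- make_cows(c("A", "A", "B", "B", "Bprime", "C"),
                    c("A", "B", "B", "Bprime", "Bprime", "A"))
  g <- diagnostic_genotypes(cows)
  expect_equal(g$g_64, c("ref/ref", "ref/alt", "alt/alt", "alt/alt",
                         "alt/alt", "ref/alt"))
  expect_equal(g$g_26, c("ref/ref", "ref/ref", "ref/ref", "ref/alt",
                         "alt/alt", "ref/ref"))
  expect_equal(g$c_carrier, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("composition generator hits group means and keeps protein ordering", {
  animals <- tibble::tibble(animal_id = sprintf("X%03d", 1:3),
                            genotype_class = c("BprimeBprime", "BB", "AA"))
  noiseless <- simulate_composition(animals, noise = 0)
  bpbp <- noiseless[noiseless$genotype_class == "BprimeBprime", ]
  expect_equal(bpbp$casein, 27.4)
  expect_equal(bpbp$true_protein, 32.3)
  expect_equal(bpbp$crude_protein, 34.9)
  # ordering invariant on noisy draws
  many <- simulate_composition(
    tibble::tibble(animal_id = sprintf("Y%04d", 1:3000),
                   genotype_class = sample(c("BprimeBprime", "BB", "AA"),
                                           3000, TRUE)),
    seed = 2
  )
  expect_true(all(many$casein <= many$true_protein + 1e-9))
  expect_true(all(many$true_protein <= many$crude_protein + 1e-9))
  expect_true(all(many[c("fat", "lactose", "casein", "blg_units")] >= 0))
  # group-mean recovery at n = 1000 within 2 SEM of the simulated group
  an1k <- tibble::tibble(animal_id = sprintf("W%04d", 1:1000),
                         genotype_class = "BB")
  c1k <- simulate_composition(an1k, seed = 1)
  tab <- composition_group_means()
  for (cmp in c("true_protein", "lactose", "casein")) {
    target <- tab$mean[tab$genotype_class == "BB" & tab$component == cmp]
    expect_lt(abs(mean(c1k[[cmp]]) - target),
              2 * stats::sd(c1k[[cmp]]) / sqrt(1000))
  }
  # invalid configuration: casein above true protein
  bad <- dplyr::mutate(tab, mean = ifelse(component == "casein", 40, mean))
  expect_error(simulate_composition(animals, group_means = bad), "casein")
})

test_that("the carrier-sire preset reproduces the half-sib design", {
  d <- simulate_sire99(seed = 1)
  expect_equal(nrow(d), 576)
  het <- d[d$hap2 == "A", ]
  # roughly half the daughters are AB heterozygous (dam A frequency 0.41)
  expect_gt(nrow(het), 180)
  expect_lt(nrow(het), 290)
  # the two transmitted-allele groups sit near the generating means
  m_b <- mean(het$B_units[het$hap1 == "B"])
  m_bp <- mean(het$B_units[het$hap1 == "Bprime"])
  expect_lt(abs(m_b - 54), 3)
  expect_lt(abs(m_bp - 25.9), 3)
  expect_true(all(d$ratio_BA[d$hap2 == "A"] > 0))
})

test_that("simulation tables are written to disk as plain CSV", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_animals = 20, seed = 1)
  cows <- simulate_concentrations(simulate_population(cfg), cfg)
  counts <- simulate_allele_counts(cows, seed = 1)
  write_simulation(dir, cows = cows, allele_counts = counts,
                   spectra = list(s1 = simulate_spectrum(c(A = 10, B = 5))))
  expect_true(file.exists(file.path(dir, "cows.csv")))
  expect_true(file.exists(file.path(dir, "allele_counts.csv")))
  expect_true(file.exists(file.path(dir, "spectra_manifest.csv")))
  back <- utils::read.csv(file.path(dir, "cows.csv"))
  expect_equal(nrow(back), 20)
})
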