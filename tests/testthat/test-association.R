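# Phenotype adjustment, GRM construction, LOCO, the scan and the
# Bonferroni threshold.

make_design <- function(n, herd_sd = 5, plate_sd = 2, noise_sd = 3,
                        n_herd = 40, n_plate = 100, seed = 2) {
  set.seed(seed)
  herd <- sample(n_herd, n, replace = TRUE)
  plate <- sample(n_plate, n, replace = TRUE)
  he <- rnorm(n_herd, 0, herd_sd)
  pe <- rnorm(n_plate, 0, plate_sd)
  tibble::tibble(
    animal_id = sprintf("A%05d", seq_len(n)),
    value = 100 + he[herd] + pe[plate] + rnorm(n, 0, noise_sd),
    birth_year = sample(2015:2017, n, TRUE),
    breed = sample(c("F", "J"), n, TRUE),
    herd_id = sprintf("H%02d", herd), plate_id = sprintf("P%03d", plate)
  )
}

test_that("adjustment recovers variance components and centres residuals", {
  rec <- make_design(2000)
  adj <- adjust_phenotype(rec)
  expect_equal(mean(adj$adjusted), 0, tolerance = 1e-10)
  vc <- attr(adj, "varcomp")
  expect_lt(abs(vc$variance[vc$term == "herd_id"] / 25 - 1), 0.25)
  expect_lt(abs(vc$variance[vc$term == "plate_id"] / 4 - 1), 0.25)
  expect_lt(abs(vc$variance[vc$term == "Residual"] / 9 - 1), 0.25)
})

test_that("adjustment handles null and perfectly-explained designs", {
  rec <- make_design(400, herd_sd = 0, plate_sd = 0, noise_sd = 4, seed = 4)
  adj <- adjust_phenotype(rec)
  expect_gt(cor(adj$adjusted, rec$value - mean(rec$value)), 0.99)
  # data equal to pure plate effects -> residuals all ~ 0
  pe <- rnorm(100, 0, 5)
  rec2 <- dplyr::mutate(rec,
                        value = 10 + pe[as.integer(substring(plate_id, 2))])
  # zero residual variance sits on the optimizer's boundary; the roundoff
  # warning is expected and harmless here
  adj2 <- suppressWarnings(suppressMessages(adjust_phenotype(rec2)))
  expect_lt(max(abs(adj2$adjusted)), 1e-6)
})

test_that("a collinear fixed design errors naming the offending columns", {
  rec <- make_design(200, seed = 5)
  rec$breed <- as.character(rec$birth_year)  # perfectly aliased
  expect_error(adjust_phenotype(rec), "collinear")
  expect_error(adjust_phenotype(dplyr::select(rec, -"herd_id")), "missing columns")
})

test_that("random factors with too few levels are demoted to fixed", {
  rec <- make_design(200, seed = 6)
  rec$plate_id <- "P001"  # single plate: cannot be a random intercept
  adj <- adjust_phenotype(rec)
  expect_false("plate_id" %in% attr(adj, "varcomp")$term)
  expect_equal(mean(adj$adjusted), 0, tolerance = 1e-10)
})

test_that("the GRM is symmetric, PSD, and near-identity for unrelated animals", {
  gm <- simulate_genotype_matrix(100, 5000, seed = 3)
  G <- build_grm(gm$dosage)
  expect_equal(G, t(G))
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  off <- G[upper.tri(G)]
  expect_lt(mean(abs(off)), 0.05)
  expect_equal(mean(diag(G)), 1, tolerance = 0.1)
  # duplicated genotype rows are maximally related
  dup <- rbind(gm$dosage[1:10, ], gm$dosage[1, , drop = FALSE])
  Gd <- build_grm(dup)
  expect_equal(Gd[1, 11], Gd[1, 1], tolerance = 1e-12)
  expect_error(build_grm(matrix(2, nrow = 4, ncol = 3)), "monomorphic")
})

test_that("parent-offspring relatedness is close to one half", {
  gm <- simulate_genotype_matrix(60, 5000, seed = 1)
  sires <- gm$dosage[1:30, ]
  dams <- gm$dosage[31:60, ]
  set.seed(101)
  off <- t(vapply(1:30, function(i) mendelian_offspring(sires[i, ], dams[i, ]),
                  numeric(5000)))
  G <- build_grm(rbind(sires, off))
  rel <- diag(G[1:30, 31:60])
  expect_lt(abs(mean(rel) - 0.5), 0.05)
})

test_that("LOCO partitioning excludes exactly the target chromosome", {
  gm <- simulate_genotype_matrix(80, 400, n_chrom = 2, seed = 7)
  g_chr2 <- gm$dosage[, gm$variants$chrom == "chr2"]
  expect_equal(loco_grm(gm$dosage, gm$variants, "chr1"), build_grm(g_chr2))
  # excluding an absent label reproduces the full GRM
  expect_equal(loco_grm(gm$dosage, gm$variants, "chrX"), build_grm(gm$dosage))
  expect_error(loco_grm(g_chr2, gm$variants[gm$variants$chrom == "chr2", ],
                        "chr2"), "target chromosome")
  # LOCO and full GRM genuinely differ when half the variants are dropped
  expect_gt(max(abs(loco_grm(gm$dosage, gm$variants, "chr1") -
                      build_grm(gm$dosage))), 0.01)
})

test_that("null scans are well calibrated and causal variants surface", {
  gm <- simulate_genotype_matrix(500, 1000, seed = 11)
  set.seed(11)
  y <- rnorm(500)
  scan <- assoc_scan(y, gm$dosage, variants = gm$variants)
  ks <- suppressWarnings(stats::ks.test(scan$p, "punif"))
  expect_lt(unname(ks$statistic), 0.06)
  # type-I error at nominal 0.05 within binomial tolerance
  expect_lt(abs(mean(scan$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  # a variant explaining ~half the variance dominates the scan
  y2 <- y + gm$dosage[, 17] * 2
  scan2 <- assoc_scan(y2, gm$dosage, variants = gm$variants)
  expect_equal(scan2$variant_id[which.min(scan2$p)], "v00017")
  # constant phenotype: zero effects, p = 1
  scan0 <- assoc_scan(rep(4, 500), gm$dosage, variants = gm$variants)
  expect_true(all(scan0$beta == 0) && all(scan0$p == 1))
  expect_error(assoc_scan(y, gm$dosage, grm = diag(10)), "dimensions")
})

test_that("an identity GRM reproduces the plain linear-model scan", {
  gm <- simulate_genotype_matrix(300, 200, seed = 12)
  set.seed(12)
  y <- rnorm(300)
  s_lm <- assoc_scan(y, gm$dosage, variants = gm$variants)
  s_id <- assoc_scan(y, gm$dosage, grm = diag(300), variants = gm$variants)
  expect_lt(max(abs(log10(s_lm$p) - log10(s_id$p))), 1e-6)
  expect_equal(s_lm$beta, s_id$beta, tolerance = 1e-9)
})

test_that("the mixed-model scan controls polygenic confounding", {
  # related animals + polygenic background: the GRM-aware scan stays
  # calibrated where the plain scan inflates
  gm <- simulate_genotype_matrix(120, 1500, seed = 13)
  founders <- gm$dosage[1:40, ]
  set.seed(13)
  kids <- t(vapply(1:80, function(i) {
    pair <- sample(40, 2)
    mendelian_offspring(founders[pair[1], ], founders[pair[2], ])
  }, numeric(1500)))
  dosage <- rbind(founders, kids)
  u <- drop(scale(dosage, scale = FALSE) %*% rnorm(1500, 0, 0.08))
  y <- u + rnorm(120)
  G <- build_grm(dosage)
  s_mm <- assoc_scan(y, dosage, grm = G, variants = gm$variants)
  s_lm <- assoc_scan(y, dosage, variants = gm$variants)
  infl <- function(p) median(stats::qchisq(1 - p, 1), na.rm = TRUE) /
    stats::qchisq(0.5, 1)
  expect_lt(infl(s_mm$p), infl(s_lm$p))
  expect_lt(infl(s_mm$p), 1.3)
})

test_that("effect sizes are recovered within their standard errors", {
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    g <- matrix(rbinom(2000, 2, 0.3), ncol = 1)
    y <- 0.3 * g[, 1] + rnorm(2000)
    sc <- assoc_scan(y, g)
    abs(sc$beta - 0.3) <= 2 * sc$se
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the Bonferroni threshold matches the genome-wide worked example", {
  th <- bonferroni_threshold(0.01, 16122289, 3)
  expect_equal(th$threshold_signif, 2.07e-10)
  expect_equal(th$threshold, 0.01 / (16122289 * 3))
  expect_equal(bonferroni_threshold(0.05, 1, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.01, 10, 1)$threshold, 1e-3)
  expect_error(bonferroni_threshold(0.01, 0, 3), "positive")
})

test_that("the heterozygote subset feeds an isoform-specific scan", {
  quant <- tibble::tibble(
    animal_id = sprintf("h%04d", 1:2500),
    A_units = c(rep(90, 2000), rep(180, 500)),
    B_units = c(rep(45, 2000), rep(2, 500))
  )
  calls <- classify_genotype(quant)
  het <- heterozygote_subset(calls)
  expect_equal(nrow(het), 2000)
  expect_equal(nrow(heterozygote_subset(calls, exclude = het$animal_id[1:9])),
               1991)
  aa_only <- classify_genotype(tibble::tibble(
    animal_id = "x", A_units = 150, B_units = 0))
  expect_equal(nrow(heterozygote_subset(aa_only)), 0)
  # end-to-end: a rare causal variant sized like the segregating groups
  # attains the scan's minimum p in the AB subset
  n <- 2000
  gm <- simulate_genotype_matrix(n, 300, seed = 21)
  set.seed(21)
  carrier <- rbinom(n, 1, 0.02)
  dosage <- cbind(gm$dosage, causal = carrier)
  variants <- dplyr::bind_rows(gm$variants,
                               tibble::tibble(variant_id = "causal",
                                              chrom = "chr11", pos = 1L))
  b_units <- ifelse(carrier == 1, rnorm(n, 25.9, 6.1), rnorm(n, 54, 8.7))
  scan <- assoc_scan(b_units, dosage, variants = variants)
  expect_equal(scan$variant_id[which.min(scan$p)], "causal")
  expect_true(scan$significant[scan$variant_id == "causal"])
  expect_s3_class(plot_manhattan(scan), "ggplot")
})
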