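test_that("configuration validates its knobs", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(n_families = 0, seed = 1))
  expect_error(sim_config(spacing_range = c(1, 30), seed = 1))
  expect_error(sim_config(qtl = list(trait = "DMA", chrom = 1, pos_cM = 10,
                                     var_frac = 0.3), seed = 1))
  expect_error(sim_config(h2 = c(iAs = 0.9, MMA = 0.5),
                          qtl = list(trait = "iAs", chrom = 1, pos_cM = 10,
                                     var_frac = 0.3), seed = 1))
  expect_s3_class(sim_config(seed = 1), "sim_config")
})

test_that("extended pedigree template produces the documented relationships", {
  cfg <- sim_config(n_families = 1, seed = 67)
  ped <- generate_pedigrees(cfg)
  expect_identical(nrow(ped), 18L)
  expect_identical(sum(ped$founder), 6L)   # grandparents + 4 married-in
  cn <- classify_relationships(ped)
  expect_identical(unname(cn[["parent-offspring"]]), 24L)
  expect_identical(unname(cn[["siblings"]]), 14L)
  expect_identical(unname(cn[["half siblings"]]), 2L)
  expect_identical(unname(cn[["avuncular"]]), 28L)
  expect_identical(unname(cn[["first cousins"]]), 15L)

  cfg2 <- sim_config(n_families = 3, family_type = "nuclear", sibship = 4,
                     seed = 67)
  ped2 <- generate_pedigrees(cfg2)
  expect_identical(nrow(ped2), 18L)
  expect_identical(length(unique(ped2$fid)), 3L)
})

test_that("genetic map respects the configured spacing", {
  cfg <- sim_config(n_chrom = 3, markers_per_chrom = 10,
                    spacing_range = c(5, 15), seed = 71)
  map <- generate_map(cfg)
  expect_identical(nrow(map), 30L)
  for (ch in 1:3) {
    pos <- map$pos_cM[map$chrom == ch]
    expect_equal(pos[1], 0)
    gaps <- diff(pos)
    expect_true(all(gaps >= 5 & gaps <= 15))
  }
  expect_equal(haldane_theta(0), 0)
  expect_equal(haldane_theta(1e9), 0.5)
})

test_that("gene-dropped genotypes are Mendelian and track descent", {
  cfg <- sim_config(n_families = 5, seed = 73)
  ped <- generate_pedigrees(cfg)
  map <- generate_map(cfg)
  geno <- gene_drop_genotypes(ped, map, cfg)
  expect_true(all(geno$alleles >= 1 & geno$alleles <= cfg$n_alleles))
  chk <- mendelian_check(ped, geno)
  expect_identical(nrow(chk$inconsistencies), 0L)
  expect_equal(chk$blanking_rate, 0)
  # each allele equals the founder allele of its descent slot
  fo_of_slot <- function(s) (s + 1L) %/% 2L
  side_of_slot <- function(s) 2L - (s %% 2L)
  for (m in c(1, nrow(map))) {
    for (a in 1:2) {
      s <- unname(geno$descent[, m, a])
      want <- geno$alleles[cbind(fo_of_slot(s), m, side_of_slot(s))]
      expect_identical(unname(geno$alleles[, m, a]), want)
    }
  }
})

test_that("injected genotype errors create detectable Mendelian conflicts", {
  cfg <- sim_config(n_families = 20, genotype_error_rate = 0.05, seed = 79)
  ped <- generate_pedigrees(cfg)
  map <- generate_map(cfg)
  geno <- gene_drop_genotypes(ped, map, cfg)
  chk <- mendelian_check(ped, geno)
  expect_gt(nrow(chk$inconsistencies), 0)
  expect_gt(chk$blanking_rate, 0)
  # blanked copy passes a re-check
  expect_identical(nrow(mendelian_check(ped, chk$geno)$inconsistencies), 0L)
})

test_that("simulated trait decomposes into the configured variances", {
  cfg <- sim_config(n_families = 60, family_type = "nuclear", sibship = 4,
                    seed = 83)
  ped <- generate_pedigrees(cfg)
  phi <- kinship_matrix(ped)
  st <- simulate_trait(ped, h2 = 0.5, total_var = 2, phi = phi, seed = 18)
  expect_equal(st$truth$sigma2, c(g = 1, q = 0, e = 1))
  expect_identical(st$trait, st$truth$g + st$truth$q + st$truth$e +
                     st$truth$fixed)
  expect_lt(abs(var(st$trait) - 2), 0.5)
  expect_error(simulate_trait(ped, h2 = 0.8, qtl_var_frac = 0.3, phi = phi),
               "h2")
  expect_error(simulate_trait(ped, h2 = 0.5, qtl_var_frac = 0.2, phi = phi),
               "qtl_slots")
})

test_that("composition induces the study's correlation signs and closure", {
  ds <- default_dataset()
  pct <- compute_percentages(ds$phen$iAs, ds$phen$MMA, ds$phen$DMA)
  s <- spearman_matrix(pct)
  expect_gt(s["pct_iAs", "pct_MMA"], 0)
  expect_lt(s["pct_iAs", "pct_DMA"], 0)
  expect_lt(s["pct_MMA", "pct_DMA"], 0)
  # medians land near the configured composition
  expect_lt(abs(median(pct$pct_DMA) - 78.4), 3)
  expect_lt(abs(median(pct$pct_iAs) - 7.7), 1.5)
  expect_lt(abs(median(pct$pct_MMA) - 13.6), 2)
  expect_true(all(ds$phen[c("iAs", "MMA", "DMA", "creatinine")] > 0))
})

test_that("datasets are reproducible from config and seed", {
  cfg <- sim_config(n_families = 3, seed = 89)
  d1 <- sim_dataset(cfg)
  d2 <- sim_dataset(cfg)
  expect_identical(d1$phen, d2$phen)
  expect_identical(d1$geno$alleles, d2$geno$alleles)
  d3 <- sim_dataset(sim_config(n_families = 3, seed = 90))
  expect_false(identical(d1$phen$iAs, d3$phen$iAs))
})

test_that("planted QTL loci are gene-dropped jointly with the map", {
  cfg <- sim_config(n_families = 10, family_type = "nuclear", sibship = 3,
                    n_chrom = 1, markers_per_chrom = 6,
                    qtl = list(trait = "MMA", chrom = 1, pos_cM = 20,
                               var_frac = 0.3), seed = 97)
  ds <- sim_dataset(cfg)
  expect_false("QTL" %in% ds$map$marker)
  expect_identical(dim(ds$qtl_slots), c(nrow(ds$ped), 2L))
  # realised QTL sharing is a valid IBD matrix consistent with kinship
  pihat <- ibd_from_descent(ds$qtl_slots)
  expect_true(all(diag(pihat) == 1))
  expect_true(all(pihat >= 0 & pihat <= 2))
  phi <- kinship_matrix(ds$ped)
  expect_true(all(pihat[phi == 0 & row(phi) != col(phi)] == 0))
})

test_that("datasets round-trip through the file formats", {
  ds <- sim_dataset(sim_config(n_families = 2, n_chrom = 1,
                               markers_per_chrom = 4, seed = 101))
  dir <- tempfile("ds")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$ped$id, ds$ped$id)
  expect_identical(back$ped$father, ds$ped$father)
  expect_equal(back$map, ds$map, ignore_attr = TRUE)
  expect_identical(unname(back$geno$alleles), unname(ds$geno$alleles))
  expect_equal(back$phen$iAs, ds$phen$iAs, tolerance = 1e-9)
  expect_equal(back$phen$age, ds$phen$age, tolerance = 1e-9)
  expect_equal(back$manifest$seed, 101)
  expect_equal(back$manifest$true_h2$iAs, 0.53)
})
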