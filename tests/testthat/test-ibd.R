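# independent dense-matrix oracle for the sib-pair inheritance HMM:
# 4 meioses (bits: s1 pat, s1 mat, s2 pat, s2 mat), founders fa/mo typed,
# explicit founder-phase enumeration and brute-force transition matrices
sib_pair_oracle <- function(g_fa, g_mo, g_s1, g_s2, freqs, pos, query) {
  nv <- 16
  bits <- function(v) c(bitwAnd(v, 1L) > 0, bitwAnd(v, 2L) > 0,
                        bitwAnd(v, 4L) > 0, bitwAnd(v, 8L) > 0)
  emission <- function(m) {
    em <- numeric(nv)
    for (v in 0:(nv - 1)) {
      b <- bits(v)
      tot <- 0
      for (pf in 1:2) for (pm in 1:2) {
        fa <- if (pf == 1) g_fa[, m] else rev(g_fa[, m])
        mo <- if (pm == 1) g_mo[, m] else rev(g_mo[, m])
        a1 <- c(fa[1 + b[1]], mo[1 + b[2]])
        a2 <- c(fa[1 + b[3]], mo[1 + b[4]])
        ok <- setequal_counts(a1, g_s1[, m]) && setequal_counts(a2, g_s2[, m])
        if (ok) tot <- tot + prod(freqs[g_fa[, m], m]) *
                             prod(freqs[g_mo[, m], m])
      }
      em[v + 1] <- tot
    }
    em   # overall scale cancels in the posterior normalisation
  }
  trans <- function(theta) {
    Tm <- matrix(0, nv, nv)
    for (v in 0:(nv - 1)) for (w in 0:(nv - 1)) {
      d <- sum(bits(bitwXor(v, w)))
      Tm[v + 1, w + 1] <- theta^d * (1 - theta)^(4 - d)
    }
    Tm
  }
  e1 <- emission(1); e2 <- emission(2)
  t1 <- trans(arsqtl:::haldane_theta(query - pos[1]))
  t2 <- trans(arsqtl:::haldane_theta(pos[2] - query))
  post <- drop(e1 %*% t1) * drop(t2 %*% e2)
  post <- post / sum(post)
  share <- vapply(0:(nv - 1), function(v) {
    b <- bits(v)
    (b[1] == b[3]) + (b[2] == b[4])
  }, numeric(1))
  sum(post * share) / 2
}

setequal_counts <- function(a, b) {
  identical(sort(unname(as.integer(a))), sort(unname(as.integer(b))))
}

test_that("multipoint sib-pair IBD matches a dense-matrix oracle", {
  df <- nuclear_df(2)
  ped <- pedigree(df)
  map <- data.frame(marker = c("m1", "m2"), chrom = 1, pos_cM = c(0, 25),
                    stringsAsFactors = FALSE)
  n <- nrow(ped)
  alle <- array(NA_integer_, c(n, 2, 2),
                dimnames = list(ped$id, map$marker, c("pat", "mat")))
  alle["fa", , ] <- rbind(c(1L, 2L), c(1L, 3L))
  alle["mo", , ] <- rbind(c(3L, 4L), c(2L, 2L))
  alle["c1", , ] <- rbind(c(1L, 3L), c(1L, 2L))
  alle["c2", , ] <- rbind(c(2L, 4L), c(3L, 2L))
  geno <- structure(list(ids = ped$id, map = map, alleles = alle,
                         descent = NULL, n_alleles = 4L),
                    class = "arsqtl_geno")
  freqs <- arsqtl:::allele_freqs(ped, geno)
  i <- match("c1", ped$id); j <- match("c2", ped$id)
  for (q in c(0, 6.25, 12.5, 25)) {
    got <- multipoint_ibd(ped, geno, 1, q)[[1]]$pihat[i, j]
    want <- sib_pair_oracle(t(alle["fa", , ]), t(alle["mo", , ]),
                            t(alle["c1", , ]), t(alle["c2", , ]),
                            freqs, map$pos_cM, q)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("inheritance-vector transitions have the Markov properties", {
  set.seed(19)
  p <- runif(8); p <- p / sum(p)
  expect_equal(arsqtl:::iv_transition(p, 0, 3), p)
  expect_equal(sum(arsqtl:::iv_transition(p, 0.3, 3)), 1)
  expect_equal(arsqtl:::iv_transition(p, 0.5, 3), rep(1 / 8, 8))
  # matches the dense transition matrix for 2 bits
  p4 <- runif(4); p4 <- p4 / sum(p4)
  th <- 0.2
  Tm <- matrix(0, 4, 4)
  for (v in 0:3) for (w in 0:3) {
    d <- sum(c(bitwAnd(bitwXor(v, w), 1L) > 0, bitwAnd(bitwXor(v, w), 2L) > 0))
    Tm[v + 1, w + 1] <- th^d * (1 - th)^(2 - d)
  }
  expect_equal(arsqtl:::iv_transition(p4, th, 2), drop(p4 %*% Tm),
               tolerance = 1e-12)
})

test_that("allele frequencies count typed founders with a half pseudo-count", {
  ped <- pedigree(nuclear_df(1))
  map <- data.frame(marker = "m1", chrom = 1, pos_cM = 0)
  alle <- array(NA_integer_, c(3, 1, 2),
                dimnames = list(ped$id, "m1", c("pat", "mat")))
  alle["fa", 1, ] <- c(1L, 1L)
  alle["mo", 1, ] <- c(1L, 2L)
  alle["c1", 1, ] <- c(1L, 2L)
  geno <- structure(list(ids = ped$id, map = map, alleles = alle,
                         descent = NULL, n_alleles = 3L),
                    class = "arsqtl_geno")
  fr <- arsqtl:::allele_freqs(ped, geno)
  expect_equal(fr[, 1], c(3.5, 1.5, 0.5) / 5.5)
})

test_that("a fully informative marker pins IBD to the realised descent", {
  cfg <- sim_config(n_families = 3, family_type = "nuclear", sibship = 3,
                    n_chrom = 1, markers_per_chrom = 5, seed = 103)
  ped <- generate_pedigrees(cfg)
  map <- generate_map(cfg)
  geno <- gene_drop_genotypes(ped, map, cfg)
  # overwrite the middle marker with its own descent labels: every founder
  # allele becomes unique, so the marker is fully informative
  mid <- 3L
  geno$alleles[, mid, ] <- geno$descent[, mid, ]
  geno$n_alleles <- 2L * nrow(ped)
  pos <- map$pos_cM[mid]
  got <- multipoint_ibd(ped, geno, 1, pos)[[1]]$pihat
  exact <- ibd_from_descent(geno$descent[, mid, ])
  expect_equal(got, exact, tolerance = 1e-9)
  # multipoint equals single-point at the informative marker
  geno1 <- geno
  geno1$map <- map[mid, , drop = FALSE]
  geno1$alleles <- geno$alleles[, mid, , drop = FALSE]
  single <- multipoint_ibd(ped, geno1, 1, pos)[[1]]$pihat
  expect_equal(got, single, tolerance = 1e-9)
})

test_that("IBD reverts to kinship without marker information", {
  cfg <- sim_config(n_families = 2, family_type = "nuclear", sibship = 3,
                    n_chrom = 1, markers_per_chrom = 4, seed = 107)
  ped <- generate_pedigrees(cfg)
  map <- generate_map(cfg)
  geno <- gene_drop_genotypes(ped, map, cfg)
  geno$alleles[] <- NA_integer_
  phi <- kinship_matrix(ped)
  for (q in c(0, 17)) {
    pihat <- multipoint_ibd(ped, geno, 1, q)[[1]]$pihat
    expect_equal(pihat, 2 * phi, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("IBD entries are continuous in position and fix parent-offspring", {
  ds <- small_linkage_fixture()
  pos <- ds$map$pos_cM
  q <- mean(pos[2:3])
  ib <- multipoint_ibd(ds$ped, ds$geno, 1, c(q, q + 0.01))
  expect_lt(max(abs(ib[[1]]$pihat - ib[[2]]$pihat)), 0.01)
  # parent-offspring sharing is exactly 1/2 everywhere
  i <- which(!ds$ped$founder)[1]
  fa <- match(ds$ped$father[i], ds$ped$id)
  for (ibx in ib) expect_equal(unname(ibx$pihat[i, fa]), 0.5,
                               tolerance = 1e-9)
})

test_that("multipoint IBD averaged over marker replicates converges to 2*Phi", {
  cfg <- sim_config(n_families = 1, family_type = "nuclear", sibship = 3,
                    n_chrom = 1, markers_per_chrom = 4, seed = 109)
  ped <- generate_pedigrees(cfg)
  map <- generate_map(cfg)
  phi <- kinship_matrix(ped)
  i <- 3L; j <- 4L  # a sibling pair
  R <- 60
  vals <- numeric(R)
  for (r in seq_len(R)) {
    geno <- gene_drop_genotypes(ped, map, cfg, seed = 5000 + r)
    vals[r] <- multipoint_ibd(ped, geno, 1, 10)[[1]]$pihat[i, j]
  }
  se <- sd(vals) / sqrt(R)
  expect_lt(abs(mean(vals) - 2 * phi[i, j]), 3 * se)
})

test_that("meiosis counts beyond the bit limit raise a capability error", {
  cfg <- sim_config(n_families = 1, seed = 113)   # extended: 24 meioses
  ped <- generate_pedigrees(cfg)
  map <- generate_map(cfg)
  geno <- gene_drop_genotypes(ped, map, cfg)
  expect_error(inheritance_hmm(ped, geno, 1, bit_limit = 16), "bit limit")
  expect_error(multipoint_ibd(ped, geno, 2, 0), "bit limit")
})

test_that("Mendelian conflicts are blanked with their typed parents", {
  ped <- pedigree(trio_df())
  map <- data.frame(marker = "m1", chrom = 1, pos_cM = 0)
  alle <- array(c(1L, 3L, 4L, 2L, 3L, 4L), c(3, 1, 2),
                dimnames = list(ped$id, "m1", c("pat", "mat")))
  geno <- structure(list(ids = ped$id, map = map, alleles = alle,
                         descent = NULL, n_alleles = 4L),
                    class = "arsqtl_geno")
  chk <- mendelian_check(ped, geno)
  expect_identical(nrow(chk$inconsistencies), 1L)
  expect_identical(chk$inconsistencies$child, "kid")
  expect_true(all(is.na(chk$geno$alleles)))
  expect_equal(chk$blanking_rate, 1)
})
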