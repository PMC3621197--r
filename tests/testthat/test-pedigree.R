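test_that("pedigree construction validates structure and orders parents first", {
  ped <- pedigree(trio_df())
  expect_s3_class(ped, "arsqtl_pedigree")
  expect_identical(nrow(ped), 3L)
  expect_identical(sum(!ped$founder), 1L)
  # parents precede offspring
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  for (i in which(!ped$founder)) {
    expect_lt(idx[[ped$father[i]]], i)
    expect_lt(idx[[ped$mother[i]]], i)
  }

  d <- trio_df(); d$id[2] <- "fa"
  expect_error(pedigree(d), "duplicate")
  d <- trio_df(); d$mother[3] <- NA
  expect_error(pedigree(d), "one known parent")
  d <- trio_df(); d$father[3] <- "ghost"
  expect_error(pedigree(d), "unknown father")
  d <- trio_df(); d$sex[1] <- "F"
  expect_error(pedigree(d), "father is not male")
  d <- trio_df(); d$sex[2] <- "M"
  expect_error(pedigree(d), "mother is not female")
  d <- trio_df(); d$sex[3] <- "M"; d$father[3] <- "kid"
  expect_error(pedigree(d), "cycle")
  expect_error(pedigree(trio_df()[, 1:3]), "missing columns")
})

test_that("kinship matrix reproduces textbook coefficients", {
  phi <- kinship_matrix(pedigree(nuclear_df(3)))
  expect_equal(unname(phi["fa", "fa"]), 0.5)
  expect_equal(unname(phi["fa", "mo"]), 0)       # unrelated founders
  expect_equal(unname(phi["fa", "c1"]), 0.25)    # parent-offspring
  expect_equal(unname(phi["c1", "c2"]), 0.25)    # full siblings
  expect_true(isSymmetric(phi))
  expect_true(all(phi >= 0 & phi <= 1))

  phi3 <- kinship_matrix(pedigree(three_gen_df()))
  expect_equal(unname(phi3["k1", "k2"]), 0.0625)     # first cousins
  expect_equal(unname(phi3["c1", "k2"]), 0.125)      # avuncular
  expect_equal(unname(phi3["gp1", "k1"]), 0.125)     # grandparent
  expect_equal(unname(phi3["s1", "k2"]), 0)          # married-in vs nephew

  phih <- kinship_matrix(pedigree(half_sib_df()))
  expect_equal(unname(phih["h1", "h2"]), 0.125)      # half siblings

  # father-daughter mating: inbred child has f = 0.25, diagonal 0.625
  inb <- data.frame(fid = "I", id = c("fa", "mo", "dau", "x"),
                    father = c(NA, NA, "fa", "fa"),
                    mother = c(NA, NA, "mo", "dau"),
                    sex = c("M", "F", "F", "M"), stringsAsFactors = FALSE)
  phii <- kinship_matrix(pedigree(inb))
  expect_equal(unname(phii["x", "x"]), 0.5 * (1 + 0.25))
})

test_that("kinship recursion agrees with gene-dropping Monte Carlo", {
  ped <- pedigree(three_gen_df())
  phi <- kinship_matrix(ped)
  set.seed(42)
  R <- 20000
  # realised sharing/2 for the first-cousin and avuncular pairs
  i <- match("k1", ped$id); j <- match("k2", ped$id)
  a <- match("c1", ped$id); b <- match("k2", ped$id)
  x_fc <- x_av <- numeric(R)
  for (r in seq_len(R)) {
    sl <- drop_unlinked_locus(ped)
    x_fc[r] <- ((sl[i, 1] == sl[j, 1]) + (sl[i, 1] == sl[j, 2]) +
                (sl[i, 2] == sl[j, 1]) + (sl[i, 2] == sl[j, 2])) / 4
    x_av[r] <- ((sl[a, 1] == sl[b, 1]) + (sl[a, 1] == sl[b, 2]) +
                (sl[a, 2] == sl[b, 1]) + (sl[a, 2] == sl[b, 2])) / 4
  }
  # 4 SE: with two pairs checked under a fixed seed, a 3 SE band is tight
  # enough to trip on an ordinary Monte Carlo fluctuation
  expect_lt(abs(mean(x_fc) - phi["k1", "k2"]), 4 * sd(x_fc) / sqrt(R))
  expect_lt(abs(mean(x_av) - phi["c1", "k2"]), 4 * sd(x_av) / sqrt(R))
})

test_that("2*Phi is positive semidefinite on generated pedigrees", {
  for (ft in c("extended3", "nuclear")) {
    cfg <- sim_config(n_families = 4, family_type = ft, seed = 5)
    phi <- kinship_matrix(generate_pedigrees(cfg))
    ev <- eigen(2 * phi, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("relationship census assigns each related pair to one class", {
  cn <- classify_relationships(pedigree(nuclear_df(3)))
  expect_identical(unname(cn[["parent-offspring"]]), 6L)
  expect_identical(unname(cn[["siblings"]]), 3L)
  expect_identical(sum(cn), 9L)

  c3 <- classify_relationships(pedigree(three_gen_df()))
  expect_identical(unname(c3[["parent-offspring"]]), 8L)
  expect_identical(unname(c3[["siblings"]]), 1L)
  expect_identical(unname(c3[["avuncular"]]), 2L)
  expect_identical(unname(c3[["first cousins"]]), 1L)
  expect_identical(unname(c3[["other"]]), 4L)   # grandparent pairs

  ch <- classify_relationships(pedigree(half_sib_df()))
  expect_identical(unname(ch[["half siblings"]]), 1L)

  cd <- classify_relationships(pedigree(double_cousin_df()))
  expect_identical(unname(cd[["double first cousins"]]), 1L)

  c4 <- classify_relationships(pedigree(four_gen_df()))
  expect_identical(unname(c4[["grand avuncular"]]), 1L)        # c1 vs gk2
  expect_identical(unname(c4[["first cousins once removed"]]), 1L)

  # class counts account for every related non-identical pair
  ped <- generate_pedigrees(sim_config(n_families = 2, seed = 9))
  phi <- kinship_matrix(ped)
  related <- sum(phi[upper.tri(phi)] > 0)
  expect_identical(sum(classify_relationships(ped)), related)
})

test_that("relationship census is invariant to input row order", {
  df <- generate_pedigrees(sim_config(n_families = 1, seed = 13))
  base <- classify_relationships(df)
  set.seed(1)
  shuffled <- pedigree(as.data.frame(df)[sample(nrow(df)), ])
  expect_identical(classify_relationships(shuffled), base)
})

test_that("household matrix is a 0/1 block indicator", {
  d <- nuclear_df(2)
  d$household <- c("h1", "h1", "h1", "h2")
  h <- household_matrix(pedigree(d))
  expect_true(isSymmetric(h))
  expect_identical(unname(diag(h)), rep(1, 4))
  expect_equal(sum(h), 9 + 1)   # 3x3 block plus singleton
  d$household <- NULL
  expect_error(household_matrix(pedigree(d)), "household tokens missing")
})

test_that("pedigree files round-trip with LINKAGE-style coding", {
  ped <- generate_pedigrees(sim_config(n_families = 2, seed = 17))
  f <- tempfile(fileext = ".tsv")
  write_pedigree(ped, f)
  back <- read_pedigree(f)
  expect_identical(back$id, ped$id)
  expect_identical(back$father, ped$father)
  expect_identical(back$mother, ped$mother)
  expect_identical(back$sex, ped$sex)
  expect_identical(back$household, ped$household)
  # header detection: strip the header manually, still parses
  lines <- readLines(f)
  f2 <- tempfile(fileext = ".tsv")
  writeLines(lines[-1], f2)
  expect_identical(read_pedigree(f2)$id, ped$id)
  expect_identical(n_meioses(ped), 2L * sum(!ped$founder))
})
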