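#' Simulation configuration
#'
#' Bundles and validates all knobs of the synthetic-data generator. Defaults
#' give a desk-scale family study: 40 extended three-generation pedigrees
#' (roughly 700 individuals), two chromosomes of a dozen STR markers each
#' with mean 10 cM spacing (drawn within 2.4-24.1 cM), 4 equifrequent
#' alleles per marker (expected heterozygosity 0.75), latent logit-scale
#' arsenic composition calibrated so overall medians land near
#' %iAs 7.7 / %MMA 13.6 / %DMA 78.4, covariates explaining about 20% of
#' latent variance, and residual heritabilities 0.53 (%iAs latent) and
#' 0.50 (%MMA latent).
#'
#' @param n_families number of independent families
#' @param family_type "extended3" (three generations with married-in
#'   spouses, grandchildren and one half-sibship) or "nuclear"
#' @param sibship number of children per nuclear family (nuclear type)
#' @param n_chrom,markers_per_chrom genetic map size
#' @param spacing_range cM spacing range for adjacent markers (uniform draw;
#'   default mean 10 cM)
#' @param n_alleles alleles per STR, equifrequent (heterozygosity 1 - 1/k)
#' @param h2 named vector: true residual heritability of the two latent
#'   logits (`iAs`, `MMA`)
#' @param covariate_r2 fraction of latent variance explained by covariates
#' @param latent_mu,latent_var medians and variances of the two latent
#'   logits (iAs-vs-DMA and MMA-vs-DMA log-ratios)
#' @param env_cor correlation of the two latent environmental deviations
#' @param qtl optional list(trait = "iAs"|"MMA", chrom, pos_cM, var_frac):
#'   plants an additive QTL carrying `var_frac` of the latent residual
#'   variance (taken out of the polygenic share)
#' @param genotype_error_rate per-genotype probability of a random allele
#'   replacement (Mendelian-error injector; 0 disables)
#' @param seed integer seed (mandatory)
#' @return validated `sim_config` list
#' @export
sim_config <- function(n_families = 40,
                       family_type = c("extended3", "nuclear"),
                       sibship = 4,
                       n_chrom = 2,
                       markers_per_chrom = 12,
                       spacing_range = c(2.4, 17.6),
                       n_alleles = 4,
                       h2 = c(iAs = 0.53, MMA = 0.50),
                       covariate_r2 = 0.20,
                       latent_mu = c(iAs = log(7.7 / 78.4),
                                     MMA = log(13.6 / 78.4)),
                       latent_var = c(iAs = 0.55^2, MMA = 0.40^2),
                       env_cor = 0.5,
                       qtl = NULL,
                       genotype_error_rate = 0,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  family_type <- match.arg(family_type)
  stopifnot(n_families >= 1, sibship >= 1, n_chrom >= 1,
            markers_per_chrom >= 2, n_alleles >= 2,
            length(spacing_range) == 2, all(spacing_range >= 2.4),
            all(spacing_range <= 24.1),
            all(h2 >= 0), all(h2 <= 1),
            covariate_r2 >= 0, covariate_r2 < 1,
            env_cor >= -1, env_cor <= 1,
            genotype_error_rate >= 0, genotype_error_rate < 1)
  if (!is.null(qtl)) {
    stopifnot(qtl$trait %in% c("iAs", "MMA"),
              qtl$var_frac > 0,
              qtl$var_frac + h2[[qtl$trait]] <= 1,
              qtl$chrom >= 1, qtl$pos_cM >= 0)
  }
  structure(list(n_families = n_families, family_type = family_type,
                 sibship = sibship, n_chrom = n_chrom,
                 markers_per_chrom = markers_per_chrom,
                 spacing_range = spacing_range, n_alleles = n_alleles,
                 h2 = h2, covariate_r2 = covariate_r2,
                 latent_mu = latent_mu, latent_var = latent_var,
                 env_cor = env_cor, qtl = qtl,
                 genotype_error_rate = genotype_error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate outbred study pedigrees
#'
#' The extended template per family: a founder couple with five adult
#' children; three children marry (married-in spouses are founders) and have
#' grandchildren, and the eldest child has offspring by two spouses, creating
#' a half-sibship. This yields parent-offspring, sibling, half-sibling,
#' avuncular and first-cousin pairs within each family. The nuclear template
#' is a couple with `sibship` children (used for linkage fixtures, where the
#' inheritance-vector computation favours few meioses). Households follow
#' nuclear units; regions are assigned per family with probabilities matching
#' the study's regional sample shares.
#'
#' @param config a `sim_config`
#' @param seed integer seed (default: the config seed)
#' @return an `arsqtl_pedigree` covering all families
#' @export
generate_pedigrees <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (f in seq_len(config$n_families)) {
    fid <- sprintf("F%03d", f)
    region <- sample(c("AZ", "OK", "DK"), 1, prob = c(0.43, 0.39, 0.18))
    id <- function(k) sprintf("%s_I%02d", fid, k)
    add <- function(k, fa, mo, sex, hh) {
      rows[[length(rows) + 1]] <<- data.frame(
        fid = fid, id = id(k),
        father = if (is.na(fa)) NA_character_ else id(fa),
        mother = if (is.na(mo)) NA_character_ else id(mo),
        sex = sex, household = paste0(fid, "_H", hh), region = region,
        stringsAsFactors = FALSE)
    }
    if (config$family_type == "nuclear") {
      add(1, NA, NA, "M", 1)
      add(2, NA, NA, "F", 1)
      for (k in seq_len(config$sibship))
        add(2 + k, 1, 2, sample(c("M", "F"), 1), 1)
    } else {
      # generation 1
      add(1, NA, NA, "M", 1)
      add(2, NA, NA, "F", 1)
      # generation 2: five siblings, ids 3..7
      sibsex <- sample(c("M", "F"), 5, replace = TRUE)
      for (k in 1:5) add(2 + k, 1, 2, sibsex[k], if (k <= 3) k + 1 else 1)
      # spouses: sib 3(id) with two spouses, sibs 4 and 5 with one each
      sp_sex <- function(s) if (s == "M") "F" else "M"
      add(8, NA, NA, sp_sex(sibsex[1]), 2)   # spouse A of sib id 3
      add(9, NA, NA, sp_sex(sibsex[1]), 5)   # spouse B of sib id 3
      add(10, NA, NA, sp_sex(sibsex[2]), 3)  # spouse of sib id 4
      add(11, NA, NA, sp_sex(sibsex[3]), 4)  # spouse of sib id 5
      par2 <- function(a, b) {
        sa <- if (a <= 7) sibsex[a - 2] else NA
        if (sa == "M") c(a, b) else c(b, a)
      }
      # generation 3
      p <- par2(3, 8);  add(12, p[1], p[2], sample(c("M", "F"), 1), 2)
      p <- par2(3, 8);  add(13, p[1], p[2], sample(c("M", "F"), 1), 2)
      p <- par2(3, 9);  add(14, p[1], p[2], sample(c("M", "F"), 1), 5)
      p <- par2(4, 10); add(15, p[1], p[2], sample(c("M", "F"), 1), 3)
      p <- par2(4, 10); add(16, p[1], p[2], sample(c("M", "F"), 1), 3)
      p <- par2(4, 10); add(17, p[1], p[2], sample(c("M", "F"), 1), 3)
      p <- par2(5, 11); add(18, p[1], p[2], sample(c("M", "F"), 1), 4)
    }
  }
  pedigree(do.call(rbind, rows))
}

#' Generate an STR genetic map
#'
#' Marker spacings are drawn uniformly within `spacing_range` (default mean
#' 10 cM), positions start at 0 on each chromosome.
#'
#' @param config a `sim_config`
#' @param seed integer seed (default: config seed + 1)
#' @return data frame with columns `marker`, `chrom`, `pos_cM`
#' @export
generate_map <- function(config, seed = config$seed + 1L) {
  if (!is.null(seed)) set.seed(seed)
  maps <- lapply(seq_len(config$n_chrom), function(ch) {
    gaps <- stats::runif(config$markers_per_chrom - 1,
                         config$spacing_range[1], config$spacing_range[2])
    pos <- c(0, cumsum(gaps))
    data.frame(marker = sprintf("C%dM%02d", ch,
                                seq_len(config$markers_per_chrom)),
               chrom = ch, pos_cM = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

# Haldane map function: recombination fraction for d centimorgans
haldane_theta <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' Gene-drop STR genotypes on a pedigree
#'
#' Founder alleles are drawn independently per marker from the allele
#' frequency model (default `n_alleles` equifrequent alleles). Transmissions
#' follow Haldane recombination along each chromosome: each meiosis is a
#' two-state Markov chain over the parental grandparental origin with
#' switch probability theta(d) between adjacent markers. Founder descent
#' labels are recorded so realised identity-by-descent is known exactly.
#'
#' @param ped an `arsqtl_pedigree`
#' @param map marker map from [generate_map()]
#' @param config a `sim_config`
#' @param seed integer seed (default: config seed + 2)
#' @return an `arsqtl_geno` object: list with `ids`, `map`, `alleles`
#'   (n x markers x 2 integer array), and `descent` (same shape, founder
#'   slot labels)
#' @export
gene_drop_genotypes <- function(ped, map, config, seed = config$seed + 2L) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  M <- nrow(map)
  idx <- stats::setNames(seq_len(n), ped$id)
  alle <- array(NA_integer_, c(n, M, 2),
                dimnames = list(ped$id, map$marker, c("pat", "mat")))
  desc <- array(NA_integer_, c(n, M, 2),
                dimnames = dimnames(alle))
  k <- config$n_alleles
  # founders: slots 2i-1 (pat) and 2i (mat)
  for (i in which(ped$founder)) {
    alle[i, , 1] <- sample.int(k, M, replace = TRUE)
    alle[i, , 2] <- sample.int(k, M, replace = TRUE)
    desc[i, , 1] <- 2L * i - 1L
    desc[i, , 2] <- 2L * i
  }
  # per-chromosome meiosis chains
  chroms <- split(seq_len(M), map$chrom)
  drop_meiosis <- function(parent_row) {
    # returns marker-length vector of 1 (grandpaternal) / 2 (grandmaternal)
    sel <- integer(M)
    for (cix in chroms) {
      th <- haldane_theta(diff(map$pos_cM[cix]))
      s <- integer(length(cix))
      s[1] <- sample(1:2, 1)
      if (length(cix) > 1) {
        flips <- stats::runif(length(cix) - 1) < th
        for (t in seq_along(flips))
          s[t + 1] <- if (flips[t]) 3L - s[t] else s[t]
      }
      sel[cix] <- s
    }
    sel
  }
  for (i in which(!ped$founder)) {
    fa <- idx[[ped$father[i]]]
    mo <- idx[[ped$mother[i]]]
    sp <- drop_meiosis(fa)
    sm <- drop_meiosis(mo)
    mi <- seq_len(M)
    alle[i, , 1] <- alle[fa, , 1] * (sp == 1) + alle[fa, , 2] * (sp == 2)
    alle[i, , 2] <- alle[mo, , 1] * (sm == 1) + alle[mo, , 2] * (sm == 2)
    desc[i, , 1] <- desc[fa, , 1] * (sp == 1) + desc[fa, , 2] * (sp == 2)
    desc[i, , 2] <- desc[mo, , 1] * (sm == 1) + desc[mo, , 2] * (sm == 2)
  }
  if (config$genotype_error_rate > 0) {
    hit <- which(stats::runif(n * M) < config$genotype_error_rate)
    for (h in hit) {
      i <- ((h - 1) %% n) + 1
      m <- ((h - 1) %/% n) + 1
      a <- sample(1:2, 1)
      alle[i, m, a] <- sample.int(k, 1)
    }
  }
  structure(list(ids = ped$id, map = map, alleles = alle, descent = desc,
                 n_alleles = k),
            class = "arsqtl_geno")
}

#' Drop one fully informative unlinked marker
#'
#' Every founder carries two unique alleles, and the marker is unlinked to
#' everything (independent uniform meiosis choices). Used for the empirical
#' LOD correction: the realised descent, and hence the exact IBD matrix, is
#' observable from the genotypes.
#'
#' @param ped an `arsqtl_pedigree`
#' @return integer n x 2 matrix of founder slot labels
#' @export
drop_unlinked_locus <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  slots <- matrix(NA_integer_, n, 2, dimnames = list(ped$id, c("pat", "mat")))
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      slots[i, ] <- c(2L * i - 1L, 2L * i)
    } else {
      fa <- idx[[ped$father[i]]]
      mo <- idx[[ped$mother[i]]]
      slots[i, 1] <- slots[fa, sample(1:2, 1)]
      slots[i, 2] <- slots[mo, sample(1:2, 1)]
    }
  }
  slots
}

#' Exact IBD-sharing matrix from realised founder-slot descent
#'
#' Entry (i, j) is half the number of slot matches between the allele pairs,
#' i.e. the realised proportion of alleles shared identical by descent.
#'
#' @param slots n x 2 matrix of founder slot labels
#' @return symmetric matrix with entries in [0, 1]
#' @export
ibd_from_descent <- function(slots) {
  n <- nrow(slots)
  s11 <- outer(slots[, 1], slots[, 1], "==")
  s12 <- outer(slots[, 1], slots[, 2], "==")
  s21 <- outer(slots[, 2], slots[, 1], "==")
  s22 <- outer(slots[, 2], slots[, 2], "==")
  pihat <- (s11 + s12 + s21 + s22) / 2
  # diagonal works out to 1 + f (1 for outbred individuals)
  dimnames(pihat) <- list(rownames(slots), rownames(slots))
  pihat
}

#' Simulate an additive polygenic + QTL + noise trait
#'
#' trait = X gamma + g + q + e with g ~ MVN(0, 2 Phi sigma2_g) generated per
#' family via a Cholesky root of 2 Phi, q an additive locus effect built from
#' iid N(0, sigma2_q / 2) founder-slot values at the supplied descent, and e
#' iid normal.
#'
#' @param ped an `arsqtl_pedigree`
#' @param h2 polygenic fraction of the residual (non-covariate) variance
#' @param total_var residual variance scale (default 1)
#' @param fixed optional vector of covariate contributions (added as-is)
#' @param qtl_slots optional n x 2 descent matrix at the QTL locus
#' @param qtl_var_frac fraction of residual variance from the QTL
#' @param phi optional precomputed kinship matrix
#' @param seed optional seed
#' @return list with `trait` and `truth` (g, q, e, fixed, parameters)
#' @export
simulate_trait <- function(ped, h2, total_var = 1, fixed = NULL,
                           qtl_slots = NULL, qtl_var_frac = 0,
                           phi = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(h2 >= 0, h2 <= 1, qtl_var_frac >= 0, h2 + qtl_var_frac <= 1)
  n <- nrow(ped)
  if (is.null(phi)) phi <- kinship_matrix(ped)
  s2g <- h2 * total_var
  s2q <- qtl_var_frac * total_var
  s2e <- (1 - h2 - qtl_var_frac) * total_var
  g <- numeric(n)
  if (s2g > 0) {
    for (fam in split(seq_len(n), ped$fid)) {
      A <- 2 * phi[fam, fam, drop = FALSE]
      R <- chol(A + diag(1e-10, length(fam)))
      g[fam] <- drop(crossprod(R, stats::rnorm(length(fam)))) * sqrt(s2g)
    }
  }
  q <- numeric(n)
  if (s2q > 0) {
    if (is.null(qtl_slots)) stop("qtl_var_frac > 0 requires qtl_slots")
    vals <- stats::rnorm(2 * n, sd = sqrt(s2q / 2))
    q <- vals[qtl_slots[, 1]] + vals[qtl_slots[, 2]]
  }
  e <- stats::rnorm(n, sd = sqrt(s2e))
  fx <- if (is.null(fixed)) numeric(n) else fixed
  list(trait = fx + g + q + e,
       truth = list(g = g, q = q, e = e, fixed = fx,
                    sigma2 = c(g = s2g, q = s2q, e = s2e),
                    h2 = h2, qtl_var_frac = qtl_var_frac))
}

#' Simulate covariates roughly matching the study's marginals
#'
#' Ages follow pedigree generation (founder couples oldest); sex comes from
#' the pedigree; BMI, smoking, alcohol, education follow the study's
#' approximate marginal distributions; total arsenic (ug/g creatinine),
#' creatinine, arsenobetaine and selenium are lognormal around the study
#' medians. No joint structure beyond generation/age is attempted.
#'
#' @param ped an `arsqtl_pedigree`
#' @param seed optional seed
#' @return data frame of covariates, rows aligned with `ped`
#' @export
simulate_covariates <- function(ped, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  # generation level: max parent level + 1; married-in founders inherit
  # their co-parent's level
  lev <- ifelse(ped$founder, 0L, NA_integer_)
  for (i in which(!ped$founder))
    lev[i] <- max(lev[idx[[ped$father[i]]]], lev[idx[[ped$mother[i]]]],
                  na.rm = TRUE) + 1L
  for (i in which(ped$founder)) {
    kids <- which(ped$father == ped$id[i] | ped$mother == ped$id[i])
    if (length(kids) > 0) lev[i] <- max(lev[kids]) - 1L
  }
  age <- pmax(18, pmin(95, stats::rnorm(n, 72 - 18 * lev, 5)))
  data.frame(
    id = ped$id,
    age = age,
    sex = ped$sex,
    education = sample(c("lt12", "ge12"), n, replace = TRUE,
                       prob = c(0.466, 0.534)),
    bmi = pmax(17, stats::rnorm(n, 31.4, 6)),
    smoking = sample(c("never", "former", "current"), n, replace = TRUE,
                     prob = c(0.343, 0.353, 0.304)),
    alcohol = sample(c("never", "former", "current"), n, replace = TRUE,
                     prob = c(0.164, 0.417, 0.419)),
    region = ped$region,
    total_arsenic = stats::rlnorm(n, log(12.9), 0.72),
    creatinine = stats::rlnorm(n, log(1.0), 0.35),
    arsenobetaine = stats::rlnorm(n, log(0.7), 0.8),
    selenium = stats::rlnorm(n, log(47.7), 0.45),
    stringsAsFactors = FALSE)
}

# covariate contributions to the two latent logits (unscaled patterns);
# signs follow the study's subgroup patterns (men and current smokers higher
# %iAs/%MMA, obesity lower %MMA, Dakotas higher %MMA)
latent_covariate_pattern <- function(cov) {
  male <- as.numeric(cov$sex == "M")
  agec <- cov$age - mean(cov$age)
  cur <- as.numeric(cov$smoking == "current")
  bmi30 <- as.numeric(cov$bmi >= 30)
  dk <- as.numeric(cov$region == "DK")
  lta <- log(cov$total_arsenic) - mean(log(cov$total_arsenic))
  list(iAs = 0.30 * male - 0.010 * agec + 0.10 * cur + 0.10 * lta,
       MMA = 0.30 * male - 0.25 * bmi30 + 0.15 * cur + 0.15 * dk -
             0.05 * lta)
}

#' Simulate compositional urine arsenic phenotypes
#'
#' Two latent log-ratio traits (iAs vs DMA and MMA vs DMA) each follow
#' mu + covariates + polygenic + optional QTL + environment, and map to a
#' three-part composition through the multinomial-logistic transform, which
#' guarantees the percentages sum to 100 and induces the negative
#' correlations of %DMA with the other two species. Species concentrations
#' (ug/L) are the composition times simulated total arsenic (ug/g) times
#' creatinine (g/L).
#'
#' @param ped an `arsqtl_pedigree`
#' @param config a `sim_config`
#' @param seed integer seed (default: config seed + 3)
#' @param qtl_slots optional descent matrix at the configured QTL position
#' @param phi optional precomputed kinship matrix
#' @return list with `phen` (data frame: id, concentrations, covariates) and
#'   `truth` (per-latent component records and parameters)
#' @export
simulate_arsenic_composition <- function(ped, config,
                                         seed = config$seed + 3L,
                                         qtl_slots = NULL, phi = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  if (is.null(phi)) phi <- kinship_matrix(ped)
  cov <- simulate_covariates(ped)
  pat <- latent_covariate_pattern(cov)
  mu <- config$latent_mu
  if (any(100 * stats::plogis(mu) <= 0 | 100 * stats::plogis(mu) >= 100))
    stop("configured latent medians imply percentages outside (0, 100)")

  lat <- list()
  truth <- list()
  r2 <- config$covariate_r2
  for (tr in c("iAs", "MMA")) {
    V <- config$latent_var[[tr]]
    p <- pat[[tr]]
    vres <- (1 - r2) * V
    fx <- if (stats::var(p) > 0 && r2 > 0)
      (p - mean(p)) * sqrt(r2 * V / stats::var(p)) else numeric(n)
    qf <- 0
    qs <- NULL
    if (!is.null(config$qtl) && config$qtl$trait == tr) {
      if (is.null(qtl_slots)) stop("config has a QTL; supply qtl_slots")
      qf <- config$qtl$var_frac
      qs <- qtl_slots
    }
    st <- simulate_trait(ped, h2 = config$h2[[tr]], total_var = vres,
                         fixed = fx, qtl_slots = qs, qtl_var_frac = qf,
                         phi = phi)
    lat[[tr]] <- mu[[tr]] + st$trait
    truth[[tr]] <- st$truth
  }
  # correlate the two latents by blending both the polygenic and the
  # environmental deviations of the MMA latent toward the iAs ones; each
  # blend preserves the marginal variance and the 2*Phi family covariance,
  # so per-trait heritability is unchanged
  if (config$env_cor != 0) {
    rho <- config$env_cor
    blend <- function(a, b) {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(b)
      rho * a / stats::sd(a) * stats::sd(b) + sqrt(1 - rho^2) * b
    }
    e2n <- blend(truth$iAs$e, truth$MMA$e)
    g2n <- blend(truth$iAs$g, truth$MMA$g)
    lat$MMA <- lat$MMA - truth$MMA$e + e2n - truth$MMA$g + g2n
    truth$MMA$e <- e2n
    truth$MMA$g <- g2n
  }

  den <- 1 + exp(lat$iAs) + exp(lat$MMA)
  pct_iAs <- 100 * exp(lat$iAs) / den
  pct_MMA <- 100 * exp(lat$MMA) / den
  pct_DMA <- 100 / den

  tot_ugL <- cov$total_arsenic * cov$creatinine
  phen <- data.frame(
    id = ped$id,
    iAs = pct_iAs / 100 * tot_ugL,
    MMA = pct_MMA / 100 * tot_ugL,
    DMA = pct_DMA / 100 * tot_ugL,
    stringsAsFactors = FALSE)
  phen <- cbind(phen, cov[, setdiff(names(cov), "id")])
  list(phen = phen,
       truth = c(truth, list(latents = lat, config = config)))
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates pedigree, map, genotype and phenotype generation from one
#' config and seed; everything is reproducible from the pair. If the config
#' plants a QTL, the QTL locus is gene-dropped jointly with the marker map
#' (Haldane-linked to the flanking markers of its chromosome).
#'
#' @param config a `sim_config`
#' @return list with `ped`, `map`, `geno`, `phen`, `truth`, `qtl_slots`,
#'   `config`
#' @export
sim_dataset <- function(config) {
  ped <- generate_pedigrees(config)
  map <- generate_map(config)
  qtl_slots <- NULL
  if (!is.null(config$qtl)) {
    map_aug <- rbind(map,
                     data.frame(marker = "QTL", chrom = config$qtl$chrom,
                                pos_cM = config$qtl$pos_cM,
                                stringsAsFactors = FALSE))
    map_aug <- map_aug[order(map_aug$chrom, map_aug$pos_cM), ]
    geno_aug <- gene_drop_genotypes(ped, map_aug, config)
    qix <- which(map_aug$marker == "QTL")
    qtl_slots <- geno_aug$descent[, qix, ]
    keep <- which(map_aug$marker != "QTL")
    geno <- structure(list(ids = geno_aug$ids,
                           map = map_aug[keep, ],
                           alleles = geno_aug$alleles[, keep, , drop = FALSE],
                           descent = geno_aug$descent[, keep, , drop = FALSE],
                           n_alleles = geno_aug$n_alleles),
                      class = "arsqtl_geno")
  } else {
    geno <- gene_drop_genotypes(ped, map, config)
  }
  phi <- kinship_matrix(ped)
  sim <- simulate_arsenic_composition(ped, config, qtl_slots = qtl_slots,
                                      phi = phi)
  list(ped = ped, map = geno$map, geno = geno, phen = sim$phen,
       truth = sim$truth, qtl_slots = qtl_slots, config = config)
}
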