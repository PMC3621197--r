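#' Mendelian consistency check and blanking
#'
#' Audits child-parent allele transmission at every marker: a typed child
#' must share at least one allele with each typed parent, and when both
#' parents are typed there must be an assignment of one child allele to each
#' parent. Offending trio genotypes (child plus typed parents at that marker)
#' are blanked. The blanking rate is the fraction of typed genotype entries
#' removed.
#'
#' @param ped an `arsqtl_pedigree`
#' @param geno an `arsqtl_geno`
#' @return list with `geno` (blanked copy), `inconsistencies` (data frame
#'   marker/child/father/mother), and `blanking_rate`
#' @export
mendelian_check <- function(ped, geno) {
  alle <- geno$alleles
  n <- nrow(ped)
  M <- nrow(geno$map)
  idx <- stats::setNames(seq_len(n), ped$id)
  typed0 <- sum(!is.na(alle[, , 1]))
  inc <- list()
  for (i in which(!ped$founder)) {
    fa <- idx[[ped$father[i]]]
    mo <- idx[[ped$mother[i]]]
    for (m in seq_len(M)) {
      c1 <- alle[i, m, 1]; c2 <- alle[i, m, 2]
      if (is.na(c1) || is.na(c2)) next
      f <- alle[fa, m, ]; mm <- alle[mo, m, ]
      ok <- trio_compatible(c(c1, c2), f, mm)
      if (!ok) {
        inc[[length(inc) + 1]] <- data.frame(
          marker = geno$map$marker[m], child = ped$id[i],
          father = ped$id[fa], mother = ped$id[mo],
          stringsAsFactors = FALSE)
        alle[i, m, ] <- NA_integer_
        if (!anyNA(f)) alle[fa, m, ] <- NA_integer_
        if (!anyNA(mm)) alle[mo, m, ] <- NA_integer_
      }
    }
  }
  blanked <- typed0 - sum(!is.na(alle[, , 1]))
  out <- geno
  out$alleles <- alle
  list(geno = out,
       inconsistencies = if (length(inc)) do.call(rbind, inc) else
         data.frame(marker = character(0), child = character(0),
                    father = character(0), mother = character(0)),
       blanking_rate = if (typed0 > 0) blanked / typed0 else 0)
}

trio_compatible <- function(child, f, m) {
  if (!anyNA(f) && !anyNA(m)) {
    for (cf in 1:2) {
      cp <- child[cf]; cm <- child[3 - cf]
      if (cp %in% f && cm %in% m) return(TRUE)
    }
    return(FALSE)
  }
  if (!anyNA(f) && length(intersect(child, f)) == 0) return(FALSE)
  if (!anyNA(m) && length(intersect(child, m)) == 0) return(FALSE)
  TRUE
}

# per-marker allele frequencies counted from typed founders, with a half
# pseudo-count per allele code (uniform prior for monomorphic/missing cases)
allele_freqs <- function(ped, geno) {
  k <- geno$n_alleles
  if (is.null(k)) k <- max(geno$alleles, na.rm = TRUE)
  M <- nrow(geno$map)
  fr <- matrix(0, k, M)
  fo <- which(ped$founder)
  for (m in seq_len(M)) {
    a <- c(geno$alleles[fo, m, 1], geno$alleles[fo, m, 2])
    a <- a[!is.na(a)]
    if (length(a) == 0)
      a <- c(geno$alleles[, m, ], recursive = TRUE)
    a <- a[!is.na(a)]
    cnt <- tabulate(a, nbins = k) + 0.5
    fr[, m] <- cnt / sum(cnt)
  }
  fr
}

# one-step HMM transition over inheritance vectors: each meiosis bit flips
# independently with probability theta (Haldane, no interference)
iv_transition <- function(p, theta, m) {
  if (theta <= 0) return(p)
  v <- 0:(length(p) - 1)
  for (b in seq_len(m)) {
    flip <- bitwXor(v, bitwShiftL(1L, b - 1L)) + 1L
    p <- (1 - theta) * p + theta * p[flip]
  }
  p
}

# founder-slot matrices for all 2^m inheritance vectors of one family.
# Bits 2j-1 / 2j select the paternal / maternal transmitted slot of the
# j-th non-founder (family topological order).
family_slots <- function(fam_ped) {
  n <- nrow(fam_ped)
  nf <- which(!fam_ped$founder)
  m <- 2L * length(nf)
  nvec <- bitwShiftL(1L, m)
  idx <- stats::setNames(seq_len(n), fam_ped$id)
  v <- 0:(nvec - 1)
  S_p <- matrix(0L, nvec, n)
  S_m <- matrix(0L, nvec, n)
  for (i in seq_len(n)) {
    if (fam_ped$founder[i]) {
      S_p[, i] <- 2L * i - 1L
      S_m[, i] <- 2L * i
    }
  }
  for (j in seq_along(nf)) {
    i <- nf[j]
    fa <- idx[[fam_ped$father[i]]]
    mo <- idx[[fam_ped$mother[i]]]
    bp <- bitwAnd(v, bitwShiftL(1L, 2L * j - 2L)) > 0
    bm <- bitwAnd(v, bitwShiftL(1L, 2L * j - 1L)) > 0
    S_p[, i] <- ifelse(bp, S_m[, fa], S_p[, fa])
    S_m[, i] <- ifelse(bm, S_m[, mo], S_p[, mo])
  }
  list(S_p = S_p, S_m = S_m, m = m, nvec = nvec)
}

# emission vector P(marker genotypes | inheritance vector) for one family
# at one marker. Fast path enumerates founder phase configurations when all
# founders are typed; otherwise falls back to per-vector constraint
# propagation over founder-slot allele assignments.
family_emission <- function(slots, fam_ped, g1, g2, freqs) {
  typed <- which(!is.na(g1) & !is.na(g2))
  if (length(typed) == 0) return(rep(1, slots$nvec))
  founders <- which(fam_ped$founder)
  if (all(founders %in% typed)) {
    return(emission_fast(slots, fam_ped, g1, g2, freqs, typed, founders))
  }
  emission_generic(slots, g1, g2, freqs, typed, 2L * nrow(fam_ped))
}

emission_fast <- function(slots, fam_ped, g1, g2, freqs, typed, founders) {
  n_slots <- 2L * nrow(fam_ped)
  het <- founders[g1[founders] != g2[founders]]
  w0 <- prod(freqs[g1[founders]] * freqs[g2[founders]])
  nconf <- bitwShiftL(1L, length(het))
  em <- numeric(slots$nvec)
  tnf <- setdiff(typed, founders)
  for (cfg in 0:(nconf - 1)) {
    a <- integer(n_slots)
    for (f in founders) {
      a[2L * f - 1L] <- g1[f]
      a[2L * f] <- g2[f]
    }
    if (length(het) > 0) {
      swap <- bitwAnd(cfg, bitwShiftL(1L, seq_along(het) - 1L)) > 0
      for (t in which(swap)) {
        f <- het[t]
        a[2L * f - 1L] <- g2[f]
        a[2L * f] <- g1[f]
      }
    }
    cons <- rep(TRUE, slots$nvec)
    for (i in tnf) {
      pa <- a[slots$S_p[, i]]
      ma <- a[slots$S_m[, i]]
      cons <- cons & ((pa == g1[i] & ma == g2[i]) |
                      (pa == g2[i] & ma == g1[i]))
    }
    em <- em + cons
  }
  # summing consistent configs = marginalising the latent founder phases,
  # each phase carrying the same freq product w0
  em * w0
}

emission_generic <- function(slots, g1, g2, freqs, typed, n_slots) {
  em <- numeric(slots$nvec)
  for (vv in seq_len(slots$nvec)) {
    asg <- list(rep(NA_integer_, n_slots))
    dead <- FALSE
    for (i in typed) {
      s1 <- slots$S_p[vv, i]
      s2 <- slots$S_m[vv, i]
      a <- g1[i]; b <- g2[i]
      ords <- if (a == b) list(c(a, b)) else list(c(a, b), c(b, a))
      nxt <- list()
      for (A in asg) {
        for (o in ords) {
          x <- A
          if (s1 == s2) {
            if (o[1] != o[2]) next
            if (!is.na(x[s1]) && x[s1] != o[1]) next
            x[s1] <- o[1]
          } else {
            if (!is.na(x[s1]) && x[s1] != o[1]) next
            x[s1] <- o[1]
            if (!is.na(x[s2]) && x[s2] != o[2]) next
            x[s2] <- o[2]
          }
          nxt[[length(nxt) + 1]] <- x
        }
      }
      if (length(nxt) == 0) { dead <- TRUE; break }
      keys <- vapply(nxt, paste, character(1), collapse = ",")
      asg <- nxt[!duplicated(keys)]
    }
    if (!dead)
      em[vv] <- sum(vapply(asg, function(x)
        prod(freqs[x[!is.na(x)]]), numeric(1)))
  }
  em
}

#' Inheritance-vector hidden Markov model along one chromosome
#'
#' Exact Lander-Green-style multipoint computation: the hidden state is the
#' inheritance vector (one bit per meiosis), transitions between adjacent
#' markers flip each bit independently with the Haldane recombination
#' fraction theta = (1 - exp(-2 d / 100)) / 2 for d cM, and emissions sum
#' genotype probabilities over founder allele assignments (unphased
#' genotypes, founder allele frequencies counted from typed founders).
#' Families are processed independently; a family whose meiosis count
#' exceeds `bit_limit` raises a capability error suggesting pedigree
#' splitting.
#'
#' @param ped an `arsqtl_pedigree`
#' @param geno an `arsqtl_geno` aligned with `ped`
#' @param chrom chromosome to process
#' @param bit_limit maximum meioses per family (default 16)
#' @return an `ibd_hmm` object with per-family forward/backward arrays,
#'   usable by [iv_posterior()] and [multipoint_ibd()]
#' @export
inheritance_hmm <- function(ped, geno, chrom, bit_limit = 16) {
  mk <- which(geno$map$chrom == chrom)
  if (length(mk) == 0) stop("no markers on chromosome ", chrom)
  pos <- geno$map$pos_cM[mk]
  freqs <- allele_freqs(ped, geno)
  fams <- split(seq_len(nrow(ped)), ped$fid)
  out <- list()
  for (fid in names(fams)) {
    rows <- fams[[fid]]
    fam_ped <- ped[rows, , drop = FALSE]
    class(fam_ped) <- class(ped)
    mcount <- 2L * sum(!fam_ped$founder)
    if (mcount > bit_limit)
      stop("family ", fid, " has ", mcount, " meioses, exceeding the ",
           bit_limit, "-bit limit; split the pedigree or raise bit_limit")
    slots <- family_slots(fam_ped)
    nm <- length(mk)
    emis <- matrix(0, slots$nvec, nm)
    for (t in seq_len(nm)) {
      m <- mk[t]
      emis[, t] <- family_emission(slots, fam_ped,
                                   geno$alleles[rows, m, 1],
                                   geno$alleles[rows, m, 2],
                                   freqs[, m])
    }
    # scaled forward-backward
    fwd <- matrix(0, slots$nvec, nm)
    bwd <- matrix(0, slots$nvec, nm)
    f <- emis[, 1] / slots$nvec
    if (sum(f) <= 0) f <- rep(1 / slots$nvec, slots$nvec)
    fwd[, 1] <- f / sum(f)
    for (t in seq_len(nm - 1)) {
      th <- haldane_theta(pos[t + 1] - pos[t])
      f <- iv_transition(fwd[, t], th, slots$m) * emis[, t + 1]
      s <- sum(f)
      fwd[, t + 1] <- if (s > 0) f / s else rep(1 / slots$nvec, slots$nvec)
    }
    bwd[, nm] <- 1
    for (t in rev(seq_len(nm - 1))) {
      th <- haldane_theta(pos[t + 1] - pos[t])
      b <- iv_transition(bwd[, t + 1] * emis[, t + 1], th, slots$m)
      s <- sum(b)
      bwd[, t] <- if (s > 0) b / s else rep(1 / slots$nvec, slots$nvec)
    }
    out[[fid]] <- list(ids = fam_ped$id, rows = rows, slots = slots,
                       emis = emis, fwd = fwd, bwd = bwd)
  }
  structure(list(families = out, chrom = chrom, marker_pos = pos,
                 markers = geno$map$marker[mk], n = nrow(ped),
                 ids = ped$id),
            class = "ibd_hmm")
}

#' Posterior over inheritance vectors at an arbitrary position
#'
#' At a marker, the posterior is the scaled product of forward and backward
#' quantities; between markers (or beyond the terminal markers) the flanking
#' quantities are propagated through the Haldane transition. At infinite
#' distance from all markers the posterior reverts to the uniform prior.
#'
#' @param hmm an `ibd_hmm`
#' @param fid family id within the hmm
#' @param pos_cM query position
#' @return posterior probability vector over the family's inheritance vectors
#' @export
iv_posterior <- function(hmm, fid, pos_cM) {
  fam <- hmm$families[[fid]]
  if (is.null(fam)) stop("unknown family: ", fid)
  pos <- hmm$marker_pos
  m <- fam$slots$m
  nm <- length(pos)
  at <- which(abs(pos - pos_cM) < 1e-9)
  if (length(at) == 1) {
    p <- fam$fwd[, at] * fam$bwd[, at]
  } else if (pos_cM < pos[1]) {
    p <- iv_transition(fam$bwd[, 1] * fam$emis[, 1],
                       haldane_theta(pos[1] - pos_cM), m)
  } else if (pos_cM > pos[nm]) {
    p <- iv_transition(fam$fwd[, nm], haldane_theta(pos_cM - pos[nm]), m)
  } else {
    t <- max(which(pos < pos_cM))
    pl <- iv_transition(fam$fwd[, t], haldane_theta(pos_cM - pos[t]), m)
    pr <- iv_transition(fam$bwd[, t + 1] * fam$emis[, t + 1],
                        haldane_theta(pos[t + 1] - pos_cM), m)
    p <- pl * pr
  }
  s <- sum(p)
  if (s <= 0) rep(1 / fam$slots$nvec, fam$slots$nvec) else p / s
}

# nvec x n(n+1)/2 matrix of pairwise allele-sharing counts per vector
family_share_matrix <- function(slots) {
  n <- ncol(slots$S_p)
  pairs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  SH <- matrix(0, slots$nvec, nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    SH[, r] <- (slots$S_p[, i] == slots$S_p[, j]) +
               (slots$S_p[, i] == slots$S_m[, j]) +
               (slots$S_m[, i] == slots$S_p[, j]) +
               (slots$S_m[, i] == slots$S_m[, j])
  }
  list(pairs = pairs, SH = SH)
}

#' Multipoint IBD matrices at requested positions
#'
#' pihat(i, j) is the posterior expectation of the proportion of alleles the
#' pair shares identical by descent at the position; diagonal entries are 1
#' for outbred individuals and cross-family entries 0. With no marker
#' information the entries equal the kinship expectation 2 Phi.
#'
#' @param ped an `arsqtl_pedigree`
#' @param geno an `arsqtl_geno`
#' @param chrom chromosome
#' @param positions numeric vector of cM positions
#' @param bit_limit maximum meioses per family
#' @param hmm optional precomputed [inheritance_hmm()] result
#' @return list of `list(chrom, pos_cM, pihat)` per position
#' @export
multipoint_ibd <- function(ped, geno, chrom, positions, bit_limit = 16,
                           hmm = NULL) {
  if (is.null(hmm)) hmm <- inheritance_hmm(ped, geno, chrom, bit_limit)
  n <- hmm$n
  shares <- lapply(hmm$families, function(fam) family_share_matrix(fam$slots))
  lapply(positions, function(px) {
    pihat <- matrix(0, n, n, dimnames = list(hmm$ids, hmm$ids))
    for (fid in names(hmm$families)) {
      fam <- hmm$families[[fid]]
      post <- iv_posterior(hmm, fid, px)
      sh <- shares[[fid]]
      vals <- drop(crossprod(sh$SH, post)) / 2
      rows <- fam$rows
      for (r in seq_len(nrow(sh$pairs))) {
        i <- rows[sh$pairs[r, 1]]; j <- rows[sh$pairs[r, 2]]
        pihat[i, j] <- pihat[j, i] <- vals[r]
      }
    }
    diag(pihat)[diag(pihat) == 0] <- 1
    list(chrom = chrom, pos_cM = px, pihat = pihat)
  })
}
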