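#' End-to-end heritability analysis
#'
#' From raw species concentrations to per-trait heritability: detection-limit
#' filtering, percentage computation, logit transform, first-stage covariate
#' adjustment under the polygenic model, inverse normal transformation, and
#' second-stage polygenic ML fit with the boundary-mixture likelihood ratio
#' test, overall and optionally per region. The audit log tracks n at every
#' exclusion step.
#'
#' @param ped an `arsqtl_pedigree`
#' @param phen phenotype/covariate data frame (`id`, `iAs`, `MMA`, `DMA`,
#'   `creatinine`, covariates; see [build_design_matrix()])
#' @param traits subset of c("pct_iAs", "pct_MMA", "pct_DMA")
#' @param variant covariate model variant
#' @param household include a household variance component
#' @param by_region also fit per region
#' @param limits species detection limits for [filter_detectable()]
#' @return `herit_report` list: `table` (trait, stratum, n, h2, se, lrt,
#'   p_value, pct_variance_explained, kurtosis), `audit`, `fits`
#' @export
run_heritability <- function(ped, phen, traits = c("pct_iAs", "pct_MMA",
                                                   "pct_DMA"),
                             variant = "base", household = FALSE,
                             by_region = FALSE,
                             limits = c(iAs = 0.1, MMA = 0.1, DMA = 0.1)) {
  if (length(traits) == 0) stop("empty trait list")
  stopifnot(all(traits %in% c("pct_iAs", "pct_MMA", "pct_DMA")))

  audit <- list(n_input = nrow(phen))
  phen <- phen[phen$id %in% ped$id, , drop = FALSE]
  audit$n_in_pedigree <- nrow(phen)
  flt <- filter_detectable(phen, limits)
  phen <- flt$retained
  audit$detection_exclusions <- as.list(flt$excluded)
  cc <- stats::complete.cases(phen[, c("age", "sex", "education", "bmi",
                                       "smoking", "alcohol", "region",
                                       "total_arsenic", "creatinine")])
  audit$n_missing_covariates <- sum(!cc)
  phen <- phen[cc, , drop = FALSE]
  audit$n_analyzed <- nrow(phen)

  ped_idx <- match(phen$id, ped$id)
  phi_full <- kinship_matrix(ped)
  phi <- phi_full[ped_idx, ped_idx]
  hh <- if (household) household_matrix(ped)[ped_idx, ped_idx] else NULL
  pcts <- compute_percentages(phen$iAs, phen$MMA, phen$DMA)

  rows <- list()
  fits <- list()
  for (tr in traits) {
    tt <- transform_trait(pcts[[tr]], phen, phi, variant)
    y <- stats::setNames(tt$final_trait, phen$id)
    strata <- stats::setNames(phen$region, phen$id)
    if (by_region) {
      res <- stratified_heritability(y, phi, strata, household = hh)
    } else {
      res <- list(overall = c(list(estimable = TRUE, n = length(y)),
                              polygenic_fit(y, phi, household = hh)))
    }
    for (st in names(res)) {
      r <- res[[st]]
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, stratum = st, n = r$n,
        h2 = if (r$estimable) r$h2 else NA_real_,
        se = if (r$estimable) r$h2_se else NA_real_,
        lrt = if (r$estimable) r$lrt else NA_real_,
        p_value = if (r$estimable) r$p_value else NA_real_,
        pct_variance_explained = tt$pct_variance_explained,
        kurtosis = tt$kurtosis,
        stringsAsFactors = FALSE)
    }
    fits[[tr]] <- res
  }
  structure(list(table = do.call(rbind, rows), audit = audit, fits = fits),
            class = "herit_report")
}

#' End-to-end linkage analysis
#'
#' Transforms the requested traits exactly as in [run_heritability()], runs
#' the genome-wide variance-component QTL scan, calls peaks against the
#' suggestive/significant thresholds, and optionally estimates the empirical
#' LOD correction constant per trait and reports adjusted peak LODs.
#' Pedigree members excluded at the detection limit or with missing
#' covariates still contribute marker information: IBD is computed on the
#' full pedigree while the variance-component fits use the phenotyped subset.
#'
#' @inheritParams run_heritability
#' @param geno an `arsqtl_geno`
#' @param grid_step scan grid step in cM
#' @param suggestive,significant LOD thresholds (defaults 1.9 and 3.3)
#' @param adjust_R replicates for the LOD correction (0 disables adjustment)
#' @param seed seed for the correction simulation (required if adjust_R > 0)
#' @param bit_limit maximum meioses per family
#' @return `linkage_report` list: `curves`, `peaks` (with adjusted LODs when
#'   requested), `constants`, `scan_errors`, `audit`
#' @export
run_linkage <- function(ped, phen, geno, traits = c("pct_iAs", "pct_MMA",
                                                    "pct_DMA"),
                        variant = "base", grid_step = 2, suggestive = 1.9,
                        significant = 3.3, adjust_R = 0, seed = NULL,
                        bit_limit = 16,
                        limits = c(iAs = 0.1, MMA = 0.1, DMA = 0.1)) {
  if (length(traits) == 0) stop("empty trait list")
  if (adjust_R > 0 && is.null(seed))
    stop("seed required when adjustment replicates are requested")

  audit <- list(n_input = nrow(phen))
  phen <- phen[phen$id %in% ped$id, , drop = FALSE]
  flt <- filter_detectable(phen, limits)
  phen <- flt$retained
  audit$detection_exclusions <- as.list(flt$excluded)
  cc <- stats::complete.cases(phen[, c("age", "sex", "education", "bmi",
                                       "smoking", "alcohol", "region",
                                       "total_arsenic", "creatinine")])
  audit$n_missing_covariates <- sum(!cc)
  phen <- phen[cc, , drop = FALSE]
  audit$n_analyzed <- nrow(phen)
  audit$n_unphenotyped <- nrow(ped) - nrow(phen)
  if (nrow(phen) < 3) stop("fewer than 3 phenotyped individuals")

  ped_idx <- match(phen$id, ped$id)
  phi <- kinship_matrix(ped)
  phi_obs <- phi[ped_idx, ped_idx, drop = FALSE]
  pcts <- compute_percentages(phen$iAs, phen$MMA, phen$DMA)

  curves <- list()
  peaks <- list()
  constants <- list()
  errors <- list()
  for (tr in traits) {
    tt <- transform_trait(pcts[[tr]], phen, phi_obs, variant)
    y <- stats::setNames(rep(NA_real_, nrow(ped)), ped$id)
    y[ped_idx] <- tt$final_trait
    sc <- qtl_scan(y, ped, geno, grid_step = grid_step,
                   bit_limit = bit_limit, phi = phi)
    errors[[tr]] <- sc$errors
    pk <- call_peaks(sc, suggestive, significant)
    if (nrow(pk) > 0) pk <- cbind(trait = tr, pk)
    if (!is.null(sc$curves)) {
      curves[[tr]] <- cbind(trait = tr, sc$curves)
    }
    if (adjust_R > 0) {
      adj <- estimate_correction_constant(y, ped, R = adjust_R,
                                          seed = seed, phi = phi)
      constants[[tr]] <- adj
      if (nrow(pk) > 0)
        pk$adjusted_lod <- apply_adjustment(pk$lod, adj)
    }
    peaks[[tr]] <- pk
  }
  structure(list(curves = do.call(rbind, curves),
                 peaks = do.call(rbind, peaks),
                 constants = constants, scan_errors = errors, audit = audit),
            class = "linkage_report")
}

#' Write a heritability or linkage report as structured JSON
#' @param report a `herit_report` or `linkage_report`
#' @param path output path
#' @export
write_report_json <- function(report, path) {
  if (inherits(report, "herit_report")) {
    obj <- list(kind = "heritability", table = report$table,
                audit = report$audit)
  } else if (inherits(report, "linkage_report")) {
    obj <- list(kind = "linkage", peaks = report$peaks,
                constants = lapply(report$constants, function(cst)
                  list(constant = cst$constant, R = cst$R, seed = cst$seed,
                       n_positive = cst$n_positive,
                       near_unity = cst$near_unity)),
                audit = report$audit)
  } else stop("unknown report type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
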