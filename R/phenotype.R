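#' Filter records below species detection limits
#'
#' Retains only records where all three urinary arsenic species are strictly
#' above their detection limits, and tallies exclusions per species. A record
#' below more than one limit is tallied under each species it fails.
#'
#' @param records data frame with columns `iAs`, `MMA`, `DMA` (ug/L)
#' @param limits named numeric vector with elements `iAs`, `MMA`, `DMA`
#'   (ug/L); defaults to the 0.1 ug/L speciation detection limit
#' @return list with `retained` (data frame) and `excluded` (named counts
#'   per species plus `total`, the number of records dropped)
#' @export
filter_detectable <- function(records,
                              limits = c(iAs = 0.1, MMA = 0.1, DMA = 0.1)) {
  stopifnot(all(limits >= 0))
  below <- cbind(iAs = records$iAs <= limits[["iAs"]],
                 MMA = records$MMA <= limits[["MMA"]],
                 DMA = records$DMA <= limits[["DMA"]])
  drop <- rowSums(below) > 0
  list(retained = records[!drop, , drop = FALSE],
       excluded = c(colSums(below), total = sum(drop)))
}

#' Arsenic species percentages
#'
#' Divides each species concentration by the sum of the three species and
#' multiplies by 100, yielding %iAs, %MMA and %DMA (summing to 100).
#'
#' @param iAs,MMA,DMA numeric vectors of concentrations (ug/L), all > 0
#' @return data frame with columns `pct_iAs`, `pct_MMA`, `pct_DMA`
#' @export
compute_percentages <- function(iAs, MMA, DMA) {
  if (any(iAs <= 0 | MMA <= 0 | DMA <= 0))
    stop("species concentrations must be strictly positive")
  tot <- iAs + MMA + DMA
  data.frame(pct_iAs = 100 * iAs / tot,
             pct_MMA = 100 * MMA / tot,
             pct_DMA = 100 * DMA / tot)
}

#' Creatinine standardisation
#'
#' Expresses a urine concentration per gram of creatinine to account for
#' urine dilution: ug/L divided by g/L gives ug/g.
#'
#' @param conc concentration in ug/L
#' @param creatinine urine creatinine in g/L, must be > 0
#' @return concentration in ug/g creatinine
#' @export
creatinine_standardize <- function(conc, creatinine) {
  if (any(creatinine <= 0)) stop("creatinine must be strictly positive")
  conc / creatinine
}

#' Median (IQR) descriptive table of species percentages by subgroup
#'
#' @param data data frame containing `pct_iAs`, `pct_MMA`, `pct_DMA` and any
#'   stratifier columns
#' @param groups character vector of stratifier column names; the overall row
#'   is always included
#' @return data frame, one row per (stratifier, level) cell with n, median,
#'   p25 and p75 of each percentage; empty cells get n = 0 and NA statistics
#' @export
descriptive_table <- function(data, groups = character(0)) {
  cell <- function(label, level, rows) {
    d <- data[rows, , drop = FALSE]
    out <- data.frame(group = label, level = level, n = nrow(d))
    for (v in c("pct_iAs", "pct_MMA", "pct_DMA")) {
      if (nrow(d) == 0) {
        q <- c(NA_real_, NA_real_, NA_real_)
      } else {
        q <- stats::quantile(d[[v]], c(0.5, 0.25, 0.75), na.rm = TRUE,
                             names = FALSE)
      }
      out[[paste0(v, "_median")]] <- q[1]
      out[[paste0(v, "_p25")]] <- q[2]
      out[[paste0(v, "_p75")]] <- q[3]
    }
    out
  }
  rows <- list(cell("overall", "all", seq_len(nrow(data))))
  for (g in groups) {
    for (lev in sort(unique(as.character(data[[g]])))) {
      rows[[length(rows) + 1]] <-
        cell(g, lev, which(as.character(data[[g]]) == lev))
    }
  }
  do.call(rbind, rows)
}

#' Spearman rank correlation matrix of the three species percentages
#'
#' @param pcts data frame with columns `pct_iAs`, `pct_MMA`, `pct_DMA`
#' @return 3 x 3 symmetric correlation matrix; constant columns give NA
#'   entries with a warning
#' @export
spearman_matrix <- function(pcts) {
  m <- as.matrix(pcts[, c("pct_iAs", "pct_MMA", "pct_DMA")])
  if (nrow(m) < 3) stop("need at least 3 observations")
  const <- apply(m, 2, function(x) stats::sd(x) == 0)
  if (any(const))
    warning("constant column(s), correlations undefined: ",
            paste(colnames(m)[const], collapse = ", "))
  suppressWarnings(stats::cor(m, method = "spearman"))
}

#' Logit of a percentage
#'
#' Converts a percentage in (0, 100) to log-odds: ln((p/100) / (1 - p/100)).
#'
#' @param p percentage strictly between 0 and 100
#' @return logit-scale value
#' @export
logit_percent <- function(p) {
  if (any(p <= 0 | p >= 100)) stop("percentages must lie strictly in (0, 100)")
  q <- p / 100
  log(q / (1 - q))
}

#' Inverse of [logit_percent()]
#' @param x logit-scale value
#' @return percentage in (0, 100)
#' @export
inv_logit_percent <- function(x) 100 * stats::plogis(x)

#' Rank-based inverse normal transformation
#'
#' Maps values to standard normal quantiles via Blom scores:
#' qnorm((rank - 3/8) / (n + 1/4)), with average ranks for ties. Used to
#' control residual kurtosis before variance-component fitting.
#'
#' @param x numeric vector, n >= 2, not all equal
#' @return transformed vector, same order as input
#' @export
inverse_normal <- function(x) {
  if (length(x) < 2) stop("need at least two values")
  if (stats::sd(x) == 0) stop("all values identical; ranks undefined")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}
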