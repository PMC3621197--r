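#' Write a genetic map file
#'
#' Tab-delimited MAP-style columns: CHROM MARKER CM, with a header.
#' @param map data frame with `marker`, `chrom`, `pos_cM`
#' @param path output path
#' @export
write_map <- function(map, path) {
  utils::write.table(
    data.frame(CHROM = map$chrom, MARKER = map$marker, CM = map$pos_cM),
    path, quote = FALSE, row.names = FALSE, sep = "\t")
}

#' Read a genetic map file written by [write_map()]
#' @param path file path
#' @return data frame with `marker`, `chrom`, `pos_cM`, ordered by
#'   chromosome then position
#' @export
read_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  out <- data.frame(marker = as.character(d$MARKER), chrom = d$CHROM,
                    pos_cM = d$CM, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos_cM), ]
  if (any(unlist(tapply(out$pos_cM, out$chrom, function(p) diff(p) <= 0))))
    stop("marker positions must be strictly increasing within chromosome")
  rownames(out) <- NULL
  out
}

#' Write STR genotypes
#'
#' One row per individual: IID then two allele columns per marker
#' (`<marker>.1`, `<marker>.2`); missing alleles written as 0.
#' @param geno an `arsqtl_geno`
#' @param path output path
#' @export
write_genotypes <- function(geno, path) {
  M <- nrow(geno$map)
  cols <- lapply(seq_len(M), function(m) {
    a <- geno$alleles[, m, ]
    a[is.na(a)] <- 0L
    a
  })
  flat <- do.call(cbind, cols)
  colnames(flat) <- as.vector(rbind(paste0(geno$map$marker, ".1"),
                                    paste0(geno$map$marker, ".2")))
  # interleave: cols gave [a1 a2] per marker already adjacent
  out <- data.frame(IID = geno$ids, flat, check.names = FALSE)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
}

#' Read STR genotypes written by [write_genotypes()]
#' @param path file path
#' @param map genetic map data frame (defines marker order)
#' @param n_alleles optional allele count per marker (for frequency priors)
#' @return an `arsqtl_geno` (without descent labels)
#' @export
read_genotypes <- function(path, map, n_alleles = NULL) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  ids <- as.character(d$IID)
  M <- nrow(map)
  alle <- array(NA_integer_, c(length(ids), M, 2),
                dimnames = list(ids, map$marker, c("pat", "mat")))
  for (m in seq_len(M)) {
    for (a in 1:2) {
      v <- as.integer(d[[paste0(map$marker[m], ".", a)]])
      v[v == 0L] <- NA_integer_
      alle[, m, a] <- v
    }
  }
  if (is.null(n_alleles)) n_alleles <- max(alle, na.rm = TRUE)
  structure(list(ids = ids, map = map, alleles = alle, descent = NULL,
                 n_alleles = n_alleles),
            class = "arsqtl_geno")
}

#' Write the phenotype/covariate table as CSV
#' @param phen data frame with an `id` column
#' @param path output path
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.csv(phen, path, row.names = FALSE, quote = FALSE)
}

#' Read a phenotype/covariate CSV
#' @param path file path
#' @return data frame
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an IBD matrix in sparse triplet form
#'
#' Columns id1, id2, pihat; only nonzero upper-triangle entries (including
#' the diagonal) are stored.
#' @param ibd list with `pihat` (and optionally `chrom`, `pos_cM`) as
#'   returned by [multipoint_ibd()]
#' @param path output path
#' @export
write_ibd_triplets <- function(ibd, path) {
  p <- ibd$pihat
  ij <- which(upper.tri(p, diag = TRUE) & p != 0, arr.ind = TRUE)
  out <- data.frame(id1 = rownames(p)[ij[, 1]], id2 = colnames(p)[ij[, 2]],
                    pihat = p[ij])
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
}

#' Read an IBD triplet file into a full symmetric matrix
#' @param path file path
#' @param ids individual ids fixing the matrix order
#' @return symmetric matrix
#' @export
read_ibd_triplets <- function(path, ids) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  p <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(d)))
    p[d$id1[r], d$id2[r]] <- p[d$id2[r], d$id1[r]] <- d$pihat[r]
  p
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits pedigree.tsv, map.tsv, genotypes.tsv, phenotypes.csv and a
#' manifest.json recording the seed and true simulation parameters.
#' @param dataset output of [sim_dataset()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pedigree(dataset$ped, file.path(dir, "pedigree.tsv"))
  write_map(dataset$map, file.path(dir, "map.tsv"))
  write_genotypes(dataset$geno, file.path(dir, "genotypes.tsv"))
  write_phenotypes(dataset$phen, file.path(dir, "phenotypes.csv"))
  cfg <- dataset$config
  manifest <- list(
    seed = cfg$seed,
    n_families = cfg$n_families,
    family_type = cfg$family_type,
    n_individuals = nrow(dataset$ped),
    true_h2 = as.list(cfg$h2),
    covariate_r2 = cfg$covariate_r2,
    qtl = cfg$qtl,
    true_sigma2 = lapply(dataset$truth[c("iAs", "MMA")],
                         function(t) as.list(t$sigma2)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir dataset directory
#' @return list with `ped`, `map`, `geno`, `phen`, `manifest`
#' @export
read_dataset <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.tsv"))
  map <- read_map(file.path(dir, "map.tsv"))
  geno <- read_genotypes(file.path(dir, "genotypes.tsv"), map)
  phen <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  list(ped = ped, map = map, geno = geno, phen = phen, manifest = manifest)
}
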