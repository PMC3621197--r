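#' Construct a validated pedigree
#'
#' A pedigree is a set of individuals with parental links forming a directed
#' acyclic graph. Founders have both parents missing; an individual with
#' exactly one known parent is rejected as a data error so that the kinship
#' recursion stays well defined.
#'
#' @param df data frame with columns `fid`, `id`, `father`, `mother`, `sex`
#'   and optionally `household` and `region`. Missing parents are coded
#'   `NA` or `"0"`. `sex` is `"M"`/`"F"` or 1/2 (1 = male, 2 = female).
#' @return An object of class `arsqtl_pedigree`: the input data frame with
#'   normalised columns, a logical `founder` column, and rows ordered so
#'   that every parent precedes its offspring (founders first).
#' @export
pedigree <- function(df) {
  req <- c("fid", "id", "father", "mother", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("pedigree table is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$fid <- as.character(df$fid)
  df$id <- as.character(df$id)
  df$father <- norm_parent(df$father)
  df$mother <- norm_parent(df$mother)
  df$sex <- norm_sex(df$sex)
  if (!"household" %in% names(df)) df$household <- NA_character_
  else df$household <- norm_parent(df$household)
  if (!"region" %in% names(df)) df$region <- NA_character_
  else df$region <- as.character(df$region)

  if (anyDuplicated(df$id))
    stop("duplicate individual ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))

  one_parent <- xor(is.na(df$father), is.na(df$mother))
  if (any(one_parent))
    stop("individuals with exactly one known parent (data error): ",
         paste(df$id[one_parent], collapse = ", "))

  for (col in c("father", "mother")) {
    known <- !is.na(df[[col]])
    bad <- known & !(df[[col]] %in% df$id)
    if (any(bad))
      stop("unknown ", col, " id referenced by: ",
           paste(df$id[bad], collapse = ", "))
  }

  idx <- stats::setNames(seq_len(nrow(df)), df$id)
  fsex <- df$sex[idx[df$father]]
  msex <- df$sex[idx[df$mother]]
  if (any(fsex == "F", na.rm = TRUE))
    stop("father is not male for: ",
         paste(df$id[which(fsex == "F")], collapse = ", "))
  if (any(msex == "M", na.rm = TRUE))
    stop("mother is not female for: ",
         paste(df$id[which(msex == "M")], collapse = ", "))

  ord <- ped_topo_order(df)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$founder <- is.na(df$father)
  class(df) <- c("arsqtl_pedigree", "data.frame")
  df
}

norm_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("0", "", "NA")] <- NA_character_
  x
}

norm_sex <- function(x) {
  x <- as.character(x)
  out <- ifelse(x %in% c("1", "M", "m", "male"), "M",
         ifelse(x %in% c("2", "F", "f", "female"), "F", NA_character_))
  if (anyNA(out)) stop("invalid sex codes: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

# Kahn topological sort; reports a cycle by naming the individuals on it.
ped_topo_order <- function(df) {
  n <- nrow(df)
  idx <- stats::setNames(seq_len(n), df$id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(df$father[i], df$mother[i])) {
      if (!is.na(p)) {
        j <- idx[[p]]
        indeg[i] <- indeg[i] + 1L
        children[[j]] <- c(children[[j]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    for (k in children[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    loop <- df$id[setdiff(seq_len(n), ord)]
    stop("pedigree contains a cycle involving: ",
         paste(loop, collapse = ", "))
  }
  ord
}

#' Read a pedigree file
#'
#' Whitespace/tab-delimited, LINKAGE/PLINK style: columns FID IID FATHER
#' MOTHER SEX, optionally followed by HOUSEHOLD and REGION. Missing parents
#' are coded "0"; sex is 1 = male, 2 = female. A header line is detected by
#' a non-numeric SEX field and skipped.
#'
#' @param path file path
#' @return an `arsqtl_pedigree`
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (nrow(raw) > 0 && !raw[1, 5] %in% c("1", "2", "M", "F"))
    raw <- raw[-1, , drop = FALSE]
  nm <- c("fid", "id", "father", "mother", "sex", "household", "region")
  names(raw) <- nm[seq_len(ncol(raw))]
  pedigree(raw)
}

#' Write a pedigree file
#' @param ped an `arsqtl_pedigree`
#' @param path output path
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    FID = ped$fid, IID = ped$id,
    FATHER = ifelse(is.na(ped$father), "0", ped$father),
    MOTHER = ifelse(is.na(ped$mother), "0", ped$mother),
    SEX = ifelse(ped$sex == "M", "1", "2"),
    HOUSEHOLD = ifelse(is.na(ped$household), "0", ped$household),
    REGION = ifelse(is.na(ped$region), "NA", ped$region),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, sep = "\t")
}

#' Kinship coefficient matrix
#'
#' Computes the kinship coefficients Phi(i, j) by the standard recursion over
#' a parent-first ordering: for a non-founder i with parents f, m and any j
#' that is not a descendant of i, Phi(i, j) = (Phi(f, j) + Phi(m, j)) / 2,
#' and Phi(i, i) = (1 + Phi(f, m)) / 2. The additive (numerator) relationship
#' matrix is 2 * Phi.
#'
#' @param ped an `arsqtl_pedigree`
#' @return symmetric matrix of kinship coefficients with ids as dimnames
#' @export
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      phi[i, i] <- 0.5
    } else {
      f <- idx[[ped$father[i]]]
      m <- idx[[ped$mother[i]]]
      if (i > 1) {
        j <- seq_len(i - 1)
        phi[i, j] <- (phi[f, j] + phi[m, j]) / 2
        phi[j, i] <- phi[i, j]
      }
      phi[i, i] <- (1 + phi[f, m]) / 2
    }
  }
  phi
}

# ancestor -> generation distance map for one individual (min distance)
ancestor_depths <- function(ped, idx, i) {
  depths <- integer(0)
  frontier <- stats::setNames(0L, ped$id[i])
  repeat {
    nxt <- integer(0)
    for (k in seq_along(frontier)) {
      ii <- idx[[names(frontier)[k]]]
      for (p in c(ped$father[ii], ped$mother[ii])) {
        if (!is.na(p)) nxt[p] <- frontier[k] + 1L
      }
    }
    if (length(nxt) == 0) break
    for (nm in names(nxt)) {
      if (is.null(depths[nm]) || is.na(depths[nm]) || depths[nm] > nxt[nm])
        depths[nm] <- nxt[nm]
    }
    frontier <- nxt
  }
  depths
}

rel_class_names <- c(
  "parent-offspring", "siblings", "half siblings", "avuncular",
  "half avuncular", "grand avuncular", "first cousins",
  "double first cousins", "first cousins once removed",
  "half first cousins", "half first cousins once removed",
  "half second cousins", "other")

#' Census of pairwise relationship classes
#'
#' Every unordered pair with kinship > 0 is assigned to exactly one named
#' class (parent-offspring, siblings, half siblings, avuncular, half
#' avuncular, grand avuncular, first cousins, double first cousins, first
#' cousins once removed, half first cousins, half first cousins once removed,
#' half second cousins) or to "other". Classification follows the closest
#' sibling link between the two lineages: a pair of lineage members sharing
#' both parents (full link) or one parent (half link), at generation depths
#' (a, b) from the pair. Depths (0,0) give siblings, (0,1) avuncular, (0,2)
#' grand avuncular, (1,1) first cousins, (1,2) first cousins once removed,
#' (2,2) second cousins, each with a half variant when only one parent is
#' shared. Two disjoint full links at (1,1) make double first cousins.
#'
#' @param ped an `arsqtl_pedigree`
#' @return named integer vector of class counts (includes "other")
#' @export
classify_relationships <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  phi <- kinship_matrix(ped)
  depths <- lapply(seq_len(n), function(i) ancestor_depths(ped, idx, i))
  counts <- stats::setNames(integer(length(rel_class_names)),
                            rel_class_names)
  if (n < 2) return(counts)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (phi[i, j] <= 0) next
      cls <- classify_pair(ped, idx, depths, i, j)
      counts[cls] <- counts[cls] + 1L
    }
  }
  counts
}

classify_pair <- function(ped, idx, depths, i, j) {
  di <- depths[[i]]; dj <- depths[[j]]
  # direct ancestry
  if (ped$id[j] %in% names(di))
    return(if (di[[ped$id[j]]] == 1L) "parent-offspring" else "other")
  if (ped$id[i] %in% names(dj))
    return(if (dj[[ped$id[i]]] == 1L) "parent-offspring" else "other")

  lin_i <- c(stats::setNames(0L, ped$id[i]), di)
  lin_j <- c(stats::setNames(0L, ped$id[j]), dj)
  links <- list()
  for (u in names(lin_i)) {
    iu <- idx[[u]]
    pu <- c(ped$father[iu], ped$mother[iu])
    if (all(is.na(pu))) next
    for (v in names(lin_j)) {
      if (u == v) next
      iv <- idx[[v]]
      pv <- c(ped$father[iv], ped$mother[iv])
      shared <- length(intersect(pu[!is.na(pu)], pv[!is.na(pv)]))
      if (shared == 0) next
      links[[length(links) + 1]] <- list(
        t = lin_i[[u]] + lin_j[[v]],
        ab = sort(c(lin_i[[u]], lin_j[[v]])),
        full = shared == 2L, u = u, v = v,
        du = lin_i[[u]], dv = lin_j[[v]])
    }
  }
  if (length(links) == 0) return("other")
  tmin <- min(vapply(links, function(l) l$t, numeric(1)))
  best <- Filter(function(l) l$t == tmin, links)
  fulls <- Filter(function(l) l$full, best)
  use <- if (length(fulls) > 0) fulls[[1]] else best[[1]]
  ab <- use$ab; full <- use$full
  key <- paste(ab[1], ab[2], sep = ",")
  if (full && key == "1,1" && length(fulls) >= 2) {
    us <- unique(vapply(fulls, function(l) l$u, character(1)))
    vs <- unique(vapply(fulls, function(l) l$v, character(1)))
    if (length(us) >= 2 && length(vs) >= 2) return("double first cousins")
  }
  full_map <- c("0,0" = "siblings", "0,1" = "avuncular",
                "0,2" = "grand avuncular", "1,1" = "first cousins",
                "1,2" = "first cousins once removed")
  half_map <- c("0,0" = "half siblings", "0,1" = "half avuncular",
                "1,1" = "half first cousins",
                "1,2" = "half first cousins once removed",
                "2,2" = "half second cousins")
  m <- if (full) full_map else half_map
  if (key %in% names(m)) unname(m[key]) else "other"
}

#' Household sharing indicator matrix
#'
#' Symmetric 0/1 matrix with 1 where two individuals share a household
#' token (diagonal 1). Used as the "shared environment" variance component.
#'
#' @param ped an `arsqtl_pedigree`
#' @return n x n indicator matrix with ids as dimnames
#' @export
household_matrix <- function(ped) {
  if (anyNA(ped$household))
    stop("household tokens missing for some individuals; ",
         "disable the household component or supply households")
  h <- outer(ped$household, ped$household, "==") * 1
  diag(h) <- 1
  dimnames(h) <- list(ped$id, ped$id)
  h
}

#' Number of non-founder meioses in a pedigree
#' @param ped an `arsqtl_pedigree`
#' @return integer, 2 x number of non-founders
#' @export
n_meioses <- function(ped) 2L * sum(!ped$founder)
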