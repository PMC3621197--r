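# Fixture builders shared across the test files. Everything is generated in
# code; the heavier shared objects are computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# father, mother, one daughter
trio_df <- function() {
  data.frame(fid = "T", id = c("fa", "mo", "kid"),
             father = c(NA, NA, "fa"), mother = c(NA, NA, "mo"),
             sex = c("M", "F", "F"), stringsAsFactors = FALSE)
}

# couple with `nsib` children
nuclear_df <- function(nsib = 3) {
  data.frame(fid = "N", id = c("fa", "mo", paste0("c", seq_len(nsib))),
             father = c(NA, NA, rep("fa", nsib)),
             mother = c(NA, NA, rep("mo", nsib)),
             sex = c("M", "F", rep(c("M", "F"), length.out = nsib)),
             stringsAsFactors = FALSE)
}

# grandparents; two sibling children c1, c2 with married-in spouses s1, s2;
# one grandchild each (k1, k2 are first cousins)
three_gen_df <- function() {
  data.frame(
    fid = "G",
    id = c("gp1", "gp2", "c1", "c2", "s1", "s2", "k1", "k2"),
    father = c(NA, NA, "gp1", "gp1", NA, NA, "c1", "c2"),
    mother = c(NA, NA, "gp2", "gp2", NA, NA, "s1", "s2"),
    sex = c("M", "F", "M", "M", "F", "F", "F", "M"),
    stringsAsFactors = FALSE)
}

# one father, two mothers, one child by each (half siblings)
half_sib_df <- function() {
  data.frame(fid = "H", id = c("fa", "mo1", "mo2", "h1", "h2"),
             father = c(NA, NA, NA, "fa", "fa"),
             mother = c(NA, NA, NA, "mo1", "mo2"),
             sex = c("M", "F", "F", "M", "F"),
             stringsAsFactors = FALSE)
}

# two brothers married to two sisters, one child per couple
double_cousin_df <- function() {
  data.frame(
    fid = "D",
    id = c("fa", "mo", "fb", "mb", "b1", "b2", "s1", "s2", "k1", "k2"),
    father = c(NA, NA, NA, NA, "fa", "fa", "fb", "fb", "b1", "b2"),
    mother = c(NA, NA, NA, NA, "mo", "mo", "mb", "mb", "s1", "s2"),
    sex = c("M", "F", "M", "F", "M", "M", "F", "F", "M", "F"),
    stringsAsFactors = FALSE)
}

# four generations down one line: gp couple -> c1, c2 -> c2's child k2 ->
# k2's child gk2. c1 vs gk2 is grand avuncular; k1 (child of c1) vs gk2 is
# first cousins once removed.
four_gen_df <- function() {
  data.frame(
    fid = "Q",
    id = c("gp1", "gp2", "c1", "c2", "s1", "s2", "k1", "k2", "s3", "gk2"),
    father = c(NA, NA, "gp1", "gp1", NA, NA, "c1", "c2", NA, "k2"),
    mother = c(NA, NA, "gp2", "gp2", NA, NA, "s1", "s2", NA, "s3"),
    sex = c("M", "F", "M", "M", "F", "F", "M", "M", "F", "F"),
    stringsAsFactors = FALSE)
}

# default-configuration synthetic dataset (the study conditions)
default_dataset <- function() {
  cached("default_dataset", sim_dataset(sim_config(seed = 301)))
}

# small linkage fixture: nuclear families, one chromosome, typed everywhere
small_linkage_fixture <- function() {
  cached("small_linkage_fixture", {
    cfg <- sim_config(n_families = 15, family_type = "nuclear", sibship = 3,
                      n_chrom = 1, markers_per_chrom = 6, seed = 401)
    ds <- sim_dataset(cfg)
    ds$phi <- kinship_matrix(ds$ped)
    ds
  })
}
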