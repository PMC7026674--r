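# Synthetic cohort generator: paired bacterial and fungal OTU tables plus
# host metadata with the statistical structure the downstream analysis
# assumes (three community states, antibiotic-exposure gradient across them,
# and a configurable CRP - Enterococcus coupling).

DIAGNOSIS_LEAVES <- c("NHC", "CD", "UC", "Infection", "Tumor", "Other")

#' Default generator building blocks
#'
#' Base relative-abundance profiles for the healthy-like community state and
#' the per-cluster log-fold-change matrices behind [cohort_config()]'s
#' defaults. Exposed so users can perturb single entries (e.g. zero out all
#' effects for a null cohort).
#'
#' @return `default_base_profile_*`: named non-negative vector summing to 1.
#'   `default_effects_*`: 3 x taxa matrix (rows `C1`, `C2`, `C3`).
#' @name generator-defaults
NULL

#' @rdname generator-defaults
#' @export
default_base_profile_bact <- function() {
  named <- c(
    Faecalibacterium = 0.16, Roseburia = 0.07, Blautia = 0.09,
    `Escherichia/Shigella` = 0.03, Enterobacteriaceae_other = 0.01,
    Enterococcus = 0.005, Streptococcus = 0.02,
    Bacteroides = 0.14, Prevotella = 0.05, Alistipes = 0.04,
    Parabacteroides = 0.03, Akkermansia = 0.02, Bifidobacterium = 0.03,
    Ruminococcus = 0.06, Coprococcus = 0.04, Dorea = 0.03,
    Lachnospira = 0.03, Dialister = 0.02, Veillonella = 0.01,
    Sutterella = 0.01
  )
  filler <- rep((1 - sum(named)) / 40, 40)
  names(filler) <- sprintf("Clostridiales_sp%02d", 1:40)
  c(named, filler)
}

#' @rdname generator-defaults
#' @param taxa Taxon names (columns of the effect matrix).
#' @export
default_base_profile_fungi <- function() {
  named <- c(
    S_cerevisiae = 0.45, C_albicans = 0.15, C_glabrata = 0.05,
    Penicillium_sp = 0.08, Aspergillus_sp = 0.05,
    Debaryomyces_hansenii = 0.07, Malassezia_restricta = 0.05
  )
  filler <- rep((1 - sum(named)) / 8, 8)
  names(filler) <- sprintf("Fungi_sp%02d", 1:8)
  c(named, filler)
}

default_taxonomy_bact <- function(taxa) {
  order_of <- function(g) {
    if (g %in% c("Escherichia/Shigella", "Enterobacteriaceae_other")) return("Enterobacteriales")
    if (g %in% c("Enterococcus", "Streptococcus")) return("Lactobacillales")
    if (g %in% c("Bacteroides", "Prevotella", "Alistipes", "Parabacteroides")) return("Bacteroidales")
    if (g == "Akkermansia") return("Verrucomicrobiales")
    if (g == "Bifidobacterium") return("Bifidobacteriales")
    if (g %in% c("Dialister", "Veillonella")) return("Veillonellales")
    if (g == "Sutterella") return("Burkholderiales")
    "Clostridiales"
  }
  tibble::tibble(
    otu_id = taxa,
    kingdom = "Bacteria",
    phylum = NA_character_,
    class = NA_character_,
    order = vapply(taxa, order_of, character(1)),
    family = NA_character_,
    genus = taxa
  )
}

default_taxonomy_fungi <- function(taxa) {
  tibble::tibble(
    otu_id = taxa,
    kingdom = "Fungi",
    phylum = NA_character_,
    class = NA_character_,
    order = ifelse(grepl("cerevisiae|albicans|glabrata|hansenii", taxa),
                   "Saccharomycetales", "Fungi_unclassified"),
    family = NA_character_,
    genus = taxa
  )
}

#' @rdname generator-defaults
#' @param taxa Taxon names (columns of the effect matrix).
#' @export
default_effects_bact <- function(taxa) {
  eff <- matrix(0, nrow = 3, ncol = length(taxa),
                dimnames = list(c("C1", "C2", "C3"), taxa))
  eff["C2", c("Escherichia/Shigella", "Enterobacteriaceae_other")] <- c(4.2, 3.9)
  eff["C2", c("Enterococcus", "Faecalibacterium", "Roseburia", "Blautia")] <-
    c(0.9, -1.6, -1.6, -1.0)
  eff["C3", c("Enterococcus", "Streptococcus", "Escherichia/Shigella")] <- c(6.0, 3.0, 1.0)
  eff["C3", c("Faecalibacterium", "Roseburia", "Blautia")] <- c(-2.9, -2.9, -2.1)
  eff
}

#' @rdname generator-defaults
#' @param taxa Taxon names (columns of the effect matrix).
#' @export
default_effects_fungi <- function(taxa) {
  eff <- matrix(0, nrow = 3, ncol = length(taxa),
                dimnames = list(c("C1", "C2", "C3"), taxa))
  eff["C2", c("C_albicans", "S_cerevisiae")] <- c(1.6, -1.0)
  eff["C3", c("C_albicans", "C_glabrata", "S_cerevisiae")] <- c(2.3, 1.3, -2.0)
  eff
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the observational cohort the pipeline was designed for:
#' 121 hospitalized gastroenterological patients split across five
#' diagnosis-based groups plus 162 non-hospitalized healthy controls, three
#' latent community states (a healthy-like state C1, an
#' Enterobacteriaceae-enriched state C2, and an Enterococcus-enriched state
#' C3) with an antibiotic-exposure gradient across them, and C-reactive
#' protein coupled to Enterococcus relative abundance.
#'
#' @param n_per_group Named integer vector, subjects per diagnosis leaf
#'   (`NHC`, `CD`, `UC`, `Infection`, `Tumor`, `Other`).
#' @param cluster_probs List with elements `antibiotic` and `no_antibiotic`,
#'   each a probability vector over `C1`, `C2`, `C3` used for hospitalized
#'   subjects. NHC subjects are always assigned `C1`.
#' @param antibiotic_prob Named vector, probability of antibiotic exposure
#'   per diagnosis leaf.
#' @param age_mean_sd Named list, per-leaf `c(mean, sd)` of age in years.
#' @param female_prob Named vector, per-leaf probability of female gender.
#' @param base_profile_bact,base_profile_fungi Named non-negative vectors
#'   summing to 1: mean relative abundances in the C1 state.
#' @param effect_bact,effect_fungi 3 x taxa matrices (rows `C1`,`C2`,`C3`) of
#'   log-fold-changes applied to the base profile before renormalisation.
#' @param overdispersion Dirichlet concentration (> 0); smaller values mean
#'   more inter-individual variability. Default 50.
#' @param depth_range_bact,depth_range_fungi Integer `c(min, max)` for the
#'   uniform sequencing-depth draw.
#' @param crp_model `c(intercept, slope, sd)`: CRP in mg/L as a linear
#'   function of Enterococcus relative abundance plus Gaussian noise,
#'   truncated at 0.
#' @param leuko_model,neutro_model `c(baseline, c3_shift, sd)` in 1e9
#'   cells/L; the shift applies to subjects in community state C3.
#' @param seed Integer seed controlling all randomness.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(NHC = 162, CD = 15, UC = 25,
                                          Infection = 23, Tumor = 22, Other = 36),
                          cluster_probs = list(
                            antibiotic = c(C1 = 0.35, C2 = 0.45, C3 = 0.20),
                            no_antibiotic = c(C1 = 0.75, C2 = 0.23, C3 = 0.02)
                          ),
                          antibiotic_prob = c(NHC = 9 / 162, CD = 8 / 15, UC = 8 / 25,
                                              Infection = 16 / 23, Tumor = 6 / 22,
                                              Other = 12 / 36),
                          age_mean_sd = list(NHC = c(45.1, 15.5), CD = c(41.1, 15.0),
                                             UC = c(46.2, 14.6), Infection = c(64.6, 10.9),
                                             Tumor = c(69.2, 10.9), Other = c(58.0, 14.1)),
                          female_prob = c(NHC = 0.642, CD = 0.600, UC = 0.480,
                                          Infection = 0.478, Tumor = 0.409, Other = 0.528),
                          base_profile_bact = default_base_profile_bact(),
                          base_profile_fungi = default_base_profile_fungi(),
                          effect_bact = default_effects_bact(names(base_profile_bact)),
                          effect_fungi = default_effects_fungi(names(base_profile_fungi)),
                          overdispersion = 50,
                          depth_range_bact = c(3000L, 10000L),
                          depth_range_fungi = c(900L, 4000L),
                          crp_model = c(intercept = 15, slope = 34, sd = 12.5),
                          leuko_model = c(baseline = 7, c3_shift = 5, sd = 2),
                          neutro_model = c(baseline = 4.5, c3_shift = 4, sd = 1.5),
                          seed = 1L) {
  unknown <- setdiff(names(n_per_group), DIAGNOSIS_LEAVES)
  if (length(unknown) > 0 && any(n_per_group[unknown] > 0)) {
    abort(sprintf("unknown diagnosis leaf with nonzero count: %s",
                  paste(unknown, collapse = ", ")))
  }
  n_per_group <- n_per_group[intersect(DIAGNOSIS_LEAVES, names(n_per_group))]
  assert_prob_vector(cluster_probs$antibiotic, "cluster_probs$antibiotic")
  assert_prob_vector(cluster_probs$no_antibiotic, "cluster_probs$no_antibiotic")
  assert_prob_vector(base_profile_bact, "base_profile_bact")
  assert_prob_vector(base_profile_fungi, "base_profile_fungi")
  if (overdispersion <= 0) abort("`overdispersion` must be > 0.")
  if (any(depth_range_bact < 1) || any(depth_range_fungi < 1)) {
    abort("depth ranges must be positive integers.")
  }
  stopifnot(identical(colnames(effect_bact), names(base_profile_bact)),
            identical(colnames(effect_fungi), names(base_profile_fungi)))
  structure(list(
    n_per_group = n_per_group, cluster_probs = cluster_probs,
    antibiotic_prob = antibiotic_prob, age_mean_sd = age_mean_sd,
    female_prob = female_prob,
    base_profile_bact = base_profile_bact, base_profile_fungi = base_profile_fungi,
    effect_bact = effect_bact, effect_fungi = effect_fungi,
    overdispersion = overdispersion,
    depth_range_bact = as.integer(depth_range_bact),
    depth_range_fungi = as.integer(depth_range_fungi),
    crp_model = crp_model, leuko_model = leuko_model,
    neutro_model = neutro_model, seed = as.integer(seed)
  ), class = "cohort_config")
}

# Dirichlet-multinomial draw: composition = renormalised base * exp(effect),
# Dirichlet concentration = overdispersion * composition, then multinomial.
rdirmult_counts <- function(base, effect, overdispersion, depth) {
  comp <- base * exp(effect)
  comp <- comp / sum(comp)
  alpha <- overdispersion * comp
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g[which.max(alpha)] <- 1
  p <- g / sum(g)
  as.vector(stats::rmultinom(1, size = depth, prob = p))
}

#' Draw inflammation markers for one subject
#'
#' CRP (mg/L) is linear in Enterococcus relative abundance with Gaussian
#' noise; leukocytes and neutrophils (1e9 cells/L) are baseline plus a shift
#' for subjects in community state C3. All three are truncated at 0. Uses the
#' current RNG state.
#'
#' @param enterococcus_rel Enterococcus relative abundance in `[0, 1]`.
#' @param true_cluster `"C1"`, `"C2"` or `"C3"`.
#' @param config A [cohort_config()].
#' @return Named numeric vector `crp`, `leukocytes`, `neutrophils`.
#' @export
sample_inflammation <- function(enterococcus_rel, true_cluster, config) {
  stopifnot(enterococcus_rel >= 0, enterococcus_rel <= 1)
  cm <- config$crp_model; lm_ <- config$leuko_model; nm <- config$neutro_model
  shift <- if (identical(true_cluster, "C3")) 1 else 0
  c(
    crp = max(0, cm[["intercept"]] + cm[["slope"]] * enterococcus_rel +
                rnorm(1, 0, cm[["sd"]])),
    leukocytes = max(0, lm_[["baseline"]] + shift * lm_[["c3_shift"]] +
                       rnorm(1, 0, lm_[["sd"]])),
    neutrophils = max(0, nm[["baseline"]] + shift * nm[["c3_shift"]] +
                        rnorm(1, 0, nm[["sd"]]))
  )
}

#' Generate a synthetic cohort
#'
#' Draws one subject at a time from a per-subject random substream (derived
#' from `config$seed` and the subject index), so the same seed reproduces the
#' cohort bit-exactly and adding subjects never perturbs earlier draws.
#'
#' @param config A [cohort_config()].
#' @return List with elements `bact` (otu_table), `fungi` (otu_table) and
#'   `metadata` (tibble, one row per subject; inflammation markers are `NA`
#'   for non-hospitalized controls).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  leaves <- rep(names(config$n_per_group), times = config$n_per_group)
  n <- length(leaves)
  taxa_b <- names(config$base_profile_bact)
  taxa_f <- names(config$base_profile_fungi)
  counts_b <- matrix(0, n, length(taxa_b), dimnames = list(NULL, taxa_b))
  counts_f <- matrix(0, n, length(taxa_f), dimnames = list(NULL, taxa_f))
  meta <- vector("list", n)

  for (i in seq_len(n)) {
    leaf <- leaves[i]
    res <- with_seed(split_seed(config$seed, i), {
      ams <- config$age_mean_sd[[leaf]]
      age <- max(18, rnorm(1, ams[1], ams[2]))
      gender <- if (runif(1) < config$female_prob[[leaf]]) "F" else "M"
      antibiotic <- runif(1) < config$antibiotic_prob[[leaf]]
      cluster <- if (leaf == "NHC") "C1" else {
        p <- if (antibiotic) config$cluster_probs$antibiotic else config$cluster_probs$no_antibiotic
        sample(c("C1", "C2", "C3"), 1, prob = p)
      }
      depth_b <- sample(config$depth_range_bact[1]:config$depth_range_bact[2], 1)
      depth_f <- sample(config$depth_range_fungi[1]:config$depth_range_fungi[2], 1)
      cb <- rdirmult_counts(config$base_profile_bact, config$effect_bact[cluster, ],
                            config$overdispersion, depth_b)
      cf <- rdirmult_counts(config$base_profile_fungi, config$effect_fungi[cluster, ],
                            config$overdispersion, depth_f)
      ent_rel <- cb[match("Enterococcus", taxa_b)] / depth_b
      infl <- if (leaf == "NHC") {
        c(crp = NA_real_, leukocytes = NA_real_, neutrophils = NA_real_)
      } else {
        sample_inflammation(ent_rel, cluster, config)
      }
      list(age = age, gender = gender, antibiotic = antibiotic,
           cluster = cluster, cb = cb, cf = cf, infl = infl)
    })
    counts_b[i, ] <- res$cb
    counts_f[i, ] <- res$cf
    meta[[i]] <- tibble::tibble(
      subject_id = sprintf("S%03d", i), diagnosis_leaf = leaf,
      hospitalized = leaf != "NHC", age = res$age, gender = res$gender,
      antibiotic = res$antibiotic, true_cluster = res$cluster,
      crp = res$infl[["crp"]], leukocytes = res$infl[["leukocytes"]],
      neutrophils = res$infl[["neutrophils"]]
    )
  }
  metadata <- dplyr::bind_rows(meta)
  rownames(counts_b) <- rownames(counts_f) <- metadata$subject_id
  list(
    bact = otu_table(counts_b, default_taxonomy_bact(taxa_b)),
    fungi = otu_table(counts_f, default_taxonomy_fungi(taxa_f)),
    metadata = metadata
  )
}
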