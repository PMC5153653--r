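#' Configuration for the synthetic enrichment generator
#'
#' Builds a validated configuration for [simulate_enrichment()]. The defaults
#' emulate the microarray cohort the inference model was designed for: 26
#' animals in four age-by-cloning groups, probe clusters of 20 probes, and
#' logistic effects of age and cloning on the per-probe enrichment
#' probability. A region planted as an age (or cloning) DMR shifts the
#' log-odds of enrichment by `age_effect` (`clone_effect`) in adult (clone)
#' samples; all other regions carry no effect.
#'
#' @param n_regions Number of probe clusters (regions) to plant.
#' @param probes_per_region Integer range `c(min, max)`; each region draws its
#'   probe count uniformly from this range. `c(20, 20)` gives fixed-size
#'   clusters.
#' @param group_sizes Named integer vector of samples per group. Names must be
#'   `perinatal_AI`, `perinatal_clone`, `adult_AI`, `adult_clone`.
#' @param baseline_logit Log-odds of enrichment in the reference group
#'   (perinatal AI).
#' @param age_effect,clone_effect Log-odds shifts applied in adult and clone
#'   samples respectively, for regions planted as DMRs of that class.
#' @param frac_age_dmr,frac_clone_dmr Proportions of regions planted as
#'   age-related and cloning-related DMRs.
#' @param overlap `"independent"` draws the two DMR sets independently (a
#'   region may be both, as observed DMR classes can overlap);
#'   `"disjoint"` forbids overlap and requires the fractions to sum to <= 1.
#' @param probe_spacing,probe_length,gap_factor Layout of the synthetic
#'   chromosome: probe starts every `probe_spacing` bp within a region,
#'   probes `probe_length` bp long, and consecutive regions separated by
#'   `gap_factor * 500` bp so that default anchor-extension settings recover
#'   the planted clusters exactly.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 500,
                       probes_per_region = c(20L, 20L),
                       group_sizes = c(perinatal_AI = 4L, perinatal_clone = 7L,
                                       adult_AI = 8L, adult_clone = 7L),
                       baseline_logit = -1,
                       age_effect = 2,
                       clone_effect = -2,
                       frac_age_dmr = 0.1,
                       frac_clone_dmr = 0.1,
                       overlap = c("independent", "disjoint"),
                       probe_spacing = 100L,
                       probe_length = 50L,
                       gap_factor = 10,
                       seed = 1L) {
  overlap <- match.arg(overlap)
  assert_count(n_regions, "n_regions", lower = 1L)
  if (length(probes_per_region) != 2L || probes_per_region[1] < 1 ||
      probes_per_region[1] > probes_per_region[2])
    stopf("`probes_per_region` must be c(min, max) with 1 <= min <= max")
  needed <- c("perinatal_AI", "perinatal_clone", "adult_AI", "adult_clone")
  if (!setequal(names(group_sizes), needed) || any(group_sizes < 1))
    stopf("`group_sizes` must name the four groups %s with counts >= 1",
          paste(needed, collapse = ", "))
  assert_number(baseline_logit, "baseline_logit")
  assert_number(age_effect, "age_effect")
  assert_number(clone_effect, "clone_effect")
  assert_number(frac_age_dmr, "frac_age_dmr", 0, 1)
  assert_number(frac_clone_dmr, "frac_clone_dmr", 0, 1)
  if (overlap == "disjoint" && frac_age_dmr + frac_clone_dmr > 1)
    stopf("disjoint DMR classes require frac_age_dmr + frac_clone_dmr <= 1")
  assert_count(seed, "seed")
  structure(list(n_regions = as.integer(n_regions),
                 probes_per_region = as.integer(probes_per_region),
                 group_sizes = group_sizes[needed],
                 baseline_logit = baseline_logit,
                 age_effect = age_effect,
                 clone_effect = clone_effect,
                 frac_age_dmr = frac_age_dmr,
                 frac_clone_dmr = frac_clone_dmr,
                 overlap = overlap,
                 probe_spacing = as.integer(probe_spacing),
                 probe_length = as.integer(probe_length),
                 gap_factor = gap_factor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# sample metadata for the configured cohort; perinatal clones are split into
# foetuses and calves as in the study cohort (both count as perinatal)
build_sample_meta <- function(group_sizes) {
  groups <- rep(names(group_sizes), group_sizes)
  n <- length(groups)
  age_class <- ifelse(grepl("^adult", groups), "adult", "perinatal")
  clone_status <- ifelse(grepl("clone$", groups), "clone", "AI")
  stage <- character(n)
  stage[age_class == "adult"] <- "adult"
  for (g in c("perinatal_AI", "perinatal_clone")) {
    idx <- which(groups == g)
    if (!length(idx)) next
    # most perinatal animals are foetuses; the last two clones are calves
    st <- rep("foetus", length(idx))
    if (g == "perinatal_clone" && length(idx) > 2) st[seq_along(idx) > length(idx) - 2] <- "calf"
    stage[idx] <- st
  }
  age_days <- ifelse(stage == "foetus", 265,
                     ifelse(stage == "calf", 283, 5 * 365))
  data.frame(animal_id = sprintf("A%02d", seq_len(n)),
             stage = stage,
             age_class = age_class,
             clone_status = clone_status,
             group = groups,
             genotype = NA_character_,
             age_days = age_days,
             stringsAsFactors = FALSE)
}

#' Simulate a binary enrichment matrix with planted DMRs
#'
#' Draws probe-by-sample Bernoulli enrichment calls under the logistic model
#' `logit P(call = 1) = baseline + age_effect * adult + clone_effect * clone`,
#' with the two effects zeroed for regions not planted as DMRs of the
#' corresponding class. Probes are laid out on one synthetic chromosome with
#' regular within-region spacing and wide inter-region gaps, so that
#' [anchor_extend()] at default settings recovers the planted regions
#' exactly.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `calls` (probes x samples 0/1 matrix),
#'   `probes` (probe table: `probe_id`, `chrom`, `start`, `end`,
#'   `cpg_class`), `regions` (planted region table: `region_id`, `chrom`,
#'   `start`, `end`, `n_probes`, `probe_ids` list column), `meta` (sample
#'   metadata) and `truth` (per region: `region_id`, `is_age_dmr`,
#'   `is_clone_dmr`, `true_age_effect`, `true_clone_effect`).
#' @export
simulate_enrichment <- function(config) {
  if (!inherits(config, "sim_config")) stopf("`config` must come from sim_config()")
  set.seed(config$seed)
  meta <- build_sample_meta(config$group_sizes)
  n_samp <- nrow(meta)
  adult <- as.numeric(meta$age_class == "adult")
  clone <- as.numeric(meta$clone_status == "clone")

  n_reg <- config$n_regions
  sizes <- if (config$probes_per_region[1] == config$probes_per_region[2])
    rep(config$probes_per_region[1], n_reg)
  else
    sample(seq(config$probes_per_region[1], config$probes_per_region[2]),
           n_reg, replace = TRUE)

  n_age <- round(config$frac_age_dmr * n_reg)
  n_clone <- round(config$frac_clone_dmr * n_reg)
  is_age <- logical(n_reg)
  is_age[sample.int(n_reg, n_age)] <- TRUE
  is_clone <- logical(n_reg)
  if (config$overlap == "independent") {
    is_clone[sample.int(n_reg, n_clone)] <- TRUE
  } else {
    pool <- which(!is_age)
    is_clone[pool[sample.int(length(pool), n_clone)]] <- TRUE
  }

  region_id <- sprintf("region_%04d", seq_len(n_reg))
  truth <- data.frame(region_id = region_id,
                      is_age_dmr = is_age,
                      is_clone_dmr = is_clone,
                      true_age_effect = ifelse(is_age, config$age_effect, 0),
                      true_clone_effect = ifelse(is_clone, config$clone_effect, 0),
                      stringsAsFactors = FALSE)

  # genomic layout: probes every `probe_spacing` bp within a region, regions
  # separated by gap_factor x 500 bp on a single synthetic chromosome
  gap <- as.integer(config$gap_factor * 500)
  spacing <- config$probe_spacing
  plen <- config$probe_length
  reg_rows <- vector("list", n_reg)
  probe_rows <- vector("list", n_reg)
  cursor <- 0L
  for (r in seq_len(n_reg)) {
    starts <- cursor + spacing * (seq_len(sizes[r]) - 1L)
    ends <- starts + plen
    ids <- sprintf("%s_p%03d", region_id[r], seq_len(sizes[r]))
    probe_rows[[r]] <- data.frame(probe_id = ids, chrom = "chrSim1",
                                  start = starts, end = ends,
                                  stringsAsFactors = FALSE)
    reg_rows[[r]] <- data.frame(region_id = region_id[r], chrom = "chrSim1",
                                start = starts[1], end = ends[sizes[r]],
                                n_probes = sizes[r], stringsAsFactors = FALSE)
    cursor <- ends[sizes[r]] + gap
  }
  probes <- do.call(rbind, probe_rows)
  probes$cpg_class <- sample(c("high", "intermediate", "low"),
                             nrow(probes), replace = TRUE)
  regions <- do.call(rbind, reg_rows)
  regions$probe_ids <- lapply(probe_rows, function(p) p$probe_id)

  # per-region x per-sample enrichment probability, expanded to probes
  eta <- outer(truth$true_age_effect, adult) +
    outer(truth$true_clone_effect, clone) + config$baseline_logit
  p_reg <- 1 / (1 + exp(-eta))
  p_probe <- p_reg[rep(seq_len(n_reg), sizes), , drop = FALSE]
  calls <- matrix(rbinom(length(p_probe), 1L, p_probe), nrow = nrow(p_probe))
  dimnames(calls) <- list(probes$probe_id, meta$animal_id)

  list(calls = calls, probes = probes, regions = regions,
       meta = meta, truth = truth, config = config)
}

#' Simulate phenotype tables coupled to methylation summaries
#'
#' Generates per-animal quantitative phenotype tables (histomorphometry and
#' fatty-acid percentages) with group-mean structure, optional linear
#' coupling to per-individual methylation summaries (`Pi_age` or
#' `Pi_cloning`), and Gaussian noise. Fatty-acid percentage variables are
#' renormalized to sum to 100 within each lipid fraction.
#'
#' @param meta Sample metadata with `animal_id` and `group` columns.
#' @param pi_summary Per-individual methylation summary with columns
#'   `animal_id`, `Pi_age`, `Pi_cloning` (the `summary` element of
#'   [compute_pi()]), or `NULL` when no variable is coupled.
#' @param morpho_spec,fa_spec Named lists of variable specifications. Each
#'   specification is a list with `group_means` (named numeric vector over
#'   the groups in `meta`), and optionally `coupling` (slope on the coupled
#'   methylation summary; default 0), `couple_to` (`"Pi_age"` or
#'   `"Pi_cloning"`), `noise_sd` (default 0) and, for fatty-acid variables,
#'   `fraction` (`"PL"` or `"NL"`; default `"PL"`).
#' @param seed Integer seed.
#' @return List with data frames `morpho` and `fa`; rows are animals
#'   (rownames = `animal_id`), columns the specified variables.
#' @export
simulate_phenotypes <- function(meta, pi_summary = NULL, morpho_spec = list(),
                                fa_spec = list(), seed = 1L) {
  set.seed(seed)
  groups <- unique(meta$group)
  gen_var <- function(spec, name) {
    gm <- spec$group_means
    if (is.null(gm) || !all(meta$group %in% names(gm)))
      stopf("variable '%s': `group_means` must cover every group label", name)
    v <- unname(gm[meta$group])
    coupling <- spec$coupling %||% 0
    if (coupling != 0) {
      ct <- spec$couple_to %||% "Pi_age"
      if (is.null(pi_summary) || !ct %in% names(pi_summary))
        stopf("variable '%s' couples to %s but no such summary was supplied",
              name, ct)
      pi_v <- pi_summary[[ct]][match(meta$animal_id, pi_summary$animal_id)]
      v <- v + coupling * pi_v
    }
    sd <- spec$noise_sd %||% 0
    if (sd > 0) v <- v + rnorm(nrow(meta), 0, sd)
    v
  }
  morpho <- as.data.frame(lapply(seq_along(morpho_spec), function(i)
    gen_var(morpho_spec[[i]], names(morpho_spec)[i])),
    col.names = names(morpho_spec), check.names = FALSE)
  fa <- as.data.frame(lapply(seq_along(fa_spec), function(i)
    gen_var(fa_spec[[i]], names(fa_spec)[i])),
    col.names = names(fa_spec), check.names = FALSE)
  if (ncol(fa)) {
    fraction <- vapply(fa_spec, function(s) s$fraction %||% "PL", "")
    for (fr in unique(fraction)) {
      cols <- which(fraction == fr)
      tot <- rowSums(fa[, cols, drop = FALSE])
      if (any(tot <= 0)) stopf("fatty-acid percentages in fraction %s sum to <= 0", fr)
      fa[, cols] <- 100 * fa[, cols, drop = FALSE] / tot
    }
  }
  if (ncol(morpho)) rownames(morpho) <- meta$animal_id
  if (ncol(fa)) rownames(fa) <- meta$animal_id
  list(morpho = morpho, fa = fa)
}

#' Vocabulary of histopathology score codes
#'
#' The ordered category codes used to grade the seven types of liver lesions:
#' alteration of hepatocyte rows (R), fibrosis (F), glycogen storage (G),
#' steatosis (S), anisocytosis (C), aspect of sinusoidal capillaries /
#' aneurysm (A) and inflammation (I). Within each variable the codes are
#' ordered by increasing severity.
#'
#' @return Named list of character vectors of ordered category codes.
#' @export
lesion_vocabulary <- function() {
  list(R = c("R0", "R1", "R2"),
       F = c("F0", "F1", "F2", "F3"),
       G = c("G0", "G1", "G2"),
       S = c("S0", "S1", "S2"),
       C = c("C0", "C1", "C2"),
       A = c("A0", "A1", "A2", "A3"),
       I = c("I0", "I1", "I2"))
}

#' Load the packaged liver lesion-score table
#'
#' Returns the lesion scores of the 36-animal cattle cohort: 30 animals carry
#' complete scores for the seven histopathological variables, the remaining
#' six were not assessed and are marked `NA`. Scores use the codes of
#' [lesion_vocabulary()].
#'
#' @return List with `scores` (data frame, one row per animal, columns
#'   `animal_id` plus the seven score variables) and `meta` (sample
#'   metadata: `animal_id`, `group`, `stage`, `age_class`, `clone_status`,
#'   `genotype`, `sex`, `age`).
#' @export
load_lesion_fixture <- function() {
  path <- system.file("extdata", "lesion_scores.csv", package = "medipdmr",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, colClasses = "character")
  vars <- names(lesion_vocabulary())
  voc <- lesion_vocabulary()
  for (v in vars) {
    bad <- setdiff(stats::na.omit(tab[[v]]), voc[[v]])
    if (length(bad)) stopf("fixture column %s holds unknown codes: %s",
                           v, paste(bad, collapse = ", "))
  }
  list(scores = tab[, c("animal_id", vars)],
       meta = tab[, c("animal_id", "group", "stage", "age_class",
                      "clone_status", "genotype", "sex", "age")])
}
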