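# small in-code fixtures shared across tests

tiny_meta <- function(age_class, clone_status) {
  n <- length(age_class)
  data.frame(animal_id = sprintf("s%02d", seq_len(n)),
             stage = ifelse(age_class == "adult", "adult", "foetus"),
             age_class = age_class,
             clone_status = clone_status,
             group = paste(age_class, clone_status, sep = "_"),
             stringsAsFactors = FALSE)
}

tiny_region <- function(probe_ids, region_id = "r1") {
  out <- data.frame(region_id = region_id, chrom = "chrT",
                    start = 0, end = 100 * length(probe_ids),
                    n_probes = length(probe_ids), stringsAsFactors = FALSE)
  out$probe_ids <- list(probe_ids)
  out
}

# evenly spaced probe table on one chromosome
tiny_probes <- function(starts, len = 60L, chrom = "chrT") {
  data.frame(probe_id = sprintf("p%03d", seq_along(starts)), chrom = chrom,
             start = starts, end = starts + len, stringsAsFactors = FALSE)
}

# grid-search maximizer of the binomial log-likelihood for a logistic model
# with one binary covariate; the independent oracle for the nested-model LRT.
# Aggregates to the two covariate levels, then scans (b0, b1) on a grid.
grid_lrt_oracle <- function(succ, trials, covariate, step = 0.01, bound = 10) {
  s0 <- sum(succ[covariate == 0]); t0 <- sum(trials[covariate == 0])
  s1 <- sum(succ[covariate == 1]); t1 <- sum(trials[covariate == 1])
  g <- seq(-bound, bound, by = step)
  ll0 <- dbinom(s0, t0, plogis(g), log = TRUE)   # choose() terms cancel in LRT
  ll_null <- max(ll0 + dbinom(s1, t1, plogis(g), log = TRUE))
  eta1 <- outer(g, g, `+`)                        # b0 + b1
  ll_full <- max(ll0 + dbinom(s1, t1, plogis(eta1), log = TRUE))
  2 * (ll_full - ll_null)
}
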