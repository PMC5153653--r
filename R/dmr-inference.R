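#' Fit nested binomial enrichment models per region
#'
#' For each region, the per-probe binary enrichment calls of all samples are
#' modelled with a Bernoulli working likelihood on the logit scale:
#' `logit P(call = 1) = b0 + b_age * adult + b_clone * clone` (no
#' interaction; the two covariates are sample-level indicators). Two reduced
#' models drop one term each. Likelihood-ratio statistics compare the full
#' model against each reduced model and are referred to a chi-square
#' distribution with one degree of freedom: dropping the cloning term tests
#' for a cloning effect (`p_clone`), dropping the age term tests for an age
#' effect (`p_age`). Missing calls are excluded from the likelihood. Regions
#' whose non-missing calls are all 0 or all 1 are untestable and get
#' `p_age = p_clone = 1` without a fit.
#'
#' @param regions Region table as returned by [anchor_extend()] (needs
#'   `region_id` and `probe_ids`).
#' @param calls Probes x samples 0/1/`NA` matrix.
#' @param meta Sample metadata with `animal_id`, `age_class`,
#'   `clone_status`.
#' @return Data frame with one row per region: `region_id`, `loglik_full`,
#'   `loglik_age_only`, `loglik_clone_only`, `lrt_age`, `lrt_clone`,
#'   `p_age`, `p_clone` (raw p-values).
#' @export
fit_region_models <- function(regions, calls, meta) {
  adult <- as.numeric(meta$age_class[match(colnames(calls), meta$animal_id)] == "adult")
  clone <- as.numeric(meta$clone_status[match(colnames(calls), meta$animal_id)] == "clone")
  if (anyNA(adult) || anyNA(clone))
    stopf("every sample column must be present in `meta`")
  rows <- lapply(seq_len(nrow(regions)), function(r) {
    ids <- regions$probe_ids[[r]]
    miss <- setdiff(ids, rownames(calls))
    if (length(miss)) stopf("region %s references unknown probes", regions$region_id[r])
    sub <- calls[ids, , drop = FALSE]
    # collapse probes to per-sample binomial counts; the per-probe Bernoulli
    # likelihood only depends on these because covariates are sample-level
    succ <- colSums(sub == 1L, na.rm = TRUE)
    trials <- colSums(!is.na(sub))
    ok <- trials > 0
    succ <- succ[ok]; trials <- trials[ok]
    a <- adult[ok]; cl <- clone[ok]
    if (sum(succ) == 0 || sum(succ) == sum(trials)) {
      message("region ", regions$region_id[r],
              ": constant response, declared untestable (p = 1)")
      return(data.frame(region_id = regions$region_id[r],
                        loglik_full = NA_real_, loglik_age_only = NA_real_,
                        loglik_clone_only = NA_real_,
                        lrt_age = 0, lrt_clone = 0, p_age = 1, p_clone = 1))
    }
    fit_ll <- function(X) {
      fit <- suppressWarnings(stats::glm.fit(X, succ / trials, weights = trials,
                                             family = stats::binomial()))
      sum(stats::dbinom(succ, trials, fit$fitted.values, log = TRUE))
    }
    ll_full <- fit_ll(cbind(1, a, cl))
    ll_age <- fit_ll(cbind(1, a))
    ll_clone <- fit_ll(cbind(1, cl))
    lrt_clone <- max(0, 2 * (ll_full - ll_age))   # does cloning add to age?
    lrt_age <- max(0, 2 * (ll_full - ll_clone))   # does age add to cloning?
    data.frame(region_id = regions$region_id[r],
               loglik_full = ll_full, loglik_age_only = ll_age,
               loglik_clone_only = ll_clone,
               lrt_age = lrt_age, lrt_clone = lrt_clone,
               p_age = stats::pchisq(lrt_age, 1, lower.tail = FALSE),
               p_clone = stats::pchisq(lrt_clone, 1, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

#' Adjust region p-values and classify DMRs
#'
#' Applies a step-up false-discovery-rate correction (Benjamini-Hochberg by
#' default) separately to the age-test and cloning-test p-value families
#' across all tested regions, then flags regions with adjusted p below
#' `alpha` as age-related and/or cloning-related DMRs.
#'
#' @param fits Output of [fit_region_models()].
#' @param alpha Significance level on the adjusted scale.
#' @param method Adjustment method passed to [stats::p.adjust()].
#' @return Data frame per region: raw and adjusted p-values, `is_age_dmr`,
#'   `is_clone_dmr` and a `class` factor in `none`/`age`/`cloning`/`both`.
#' @export
adjust_and_classify <- function(fits, alpha = 0.05, method = "BH") {
  assert_number(alpha, "alpha", 0, 1)
  if (!nrow(fits))
    return(data.frame(region_id = character(), p_age = numeric(),
                      adj_p_age = numeric(), p_clone = numeric(),
                      adj_p_clone = numeric(), is_age_dmr = logical(),
                      is_clone_dmr = logical(),
                      class = factor(character(),
                                     levels = c("none", "age", "cloning", "both"))))
  out <- data.frame(region_id = fits$region_id,
                    p_age = fits$p_age,
                    adj_p_age = stats::p.adjust(fits$p_age, method = method),
                    p_clone = fits$p_clone,
                    adj_p_clone = stats::p.adjust(fits$p_clone, method = method),
                    stringsAsFactors = FALSE)
  out$is_age_dmr <- out$adj_p_age < alpha
  out$is_clone_dmr <- out$adj_p_clone < alpha
  out$class <- factor(ifelse(out$is_age_dmr & out$is_clone_dmr, "both",
                             ifelse(out$is_age_dmr, "age",
                                    ifelse(out$is_clone_dmr, "cloning", "none"))),
                      levels = c("none", "age", "cloning", "both"))
  out
}

#' Per-individual percentage of enriched probes
#'
#' For each region r and individual i computes `P_ri = 100 * E_ri / T_r`,
#' where `E_ri` counts the individual's enriched probes in the region and
#' `T_r` is the number of probes in the region. Missing calls count as not
#' enriched in `E_ri` while `T_r` stays fixed (set
#' `rescale_missing = TRUE` to divide by the non-missing probe count
#' instead). When a DMR classification is supplied, per-individual averages
#' over the age-related and cloning-related DMR sets (`Pi_age`,
#' `Pi_cloning`) are added.
#'
#' @param calls Probes x samples 0/1/`NA` matrix.
#' @param regions Region table with `region_id` and `probe_ids`.
#' @param dmr_table Optional output of [adjust_and_classify()].
#' @param rescale_missing Divide by non-missing probe counts instead of
#'   `T_r`.
#' @return List with `P` (regions x samples percentage matrix) and, when
#'   `dmr_table` is given, `summary` (data frame `animal_id`, `Pi_age`,
#'   `Pi_cloning`).
#' @export
compute_pi <- function(calls, regions, dmr_table = NULL, rescale_missing = FALSE) {
  P <- t(vapply(seq_len(nrow(regions)), function(r) {
    ids <- regions$probe_ids[[r]]
    sub <- calls[ids, , drop = FALSE]
    e <- colSums(sub == 1L, na.rm = TRUE)
    denom <- if (rescale_missing) pmax(colSums(!is.na(sub)), 1L) else length(ids)
    100 * e / denom
  }, numeric(ncol(calls))))
  dimnames(P) <- list(regions$region_id, colnames(calls))
  res <- list(P = P)
  if (!is.null(dmr_table)) {
    cls_mean <- function(flag, label) {
      rows <- dmr_table$region_id[flag]
      if (!length(rows)) {
        warnf("no %s DMRs; the %s summary is absent", label, label)
        return(rep(NA_real_, ncol(P)))
      }
      colMeans(P[rows, , drop = FALSE])
    }
    res$summary <- data.frame(
      animal_id = colnames(P),
      Pi_age = cls_mean(dmr_table$is_age_dmr, "age-related"),
      Pi_cloning = cls_mean(dmr_table$is_clone_dmr, "cloning-related"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res
}
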