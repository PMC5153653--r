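#' Call enriched probes from replicate log-ratios
#'
#' Converts per-probe replicate log2(MeDIP/input) ratios into binary
#' enrichment calls. A probe is called enriched in a sample when the mean of
#' its available replicate values reaches `threshold` (default 1, i.e. a
#' two-fold MeDIP over input signal) and at least `min_replicates` values
#' are available; with enough replicates but a sub-threshold mean the call
#' is 0, and with too few replicates the call is `NA`.
#'
#' @param log_ratios Named list, one element per sample, each a numeric
#'   probes x replicates matrix (rownames = probe ids, shared across
#'   samples).
#' @param threshold Minimum mean log2 ratio for an enriched call.
#' @param min_replicates Minimum number of non-missing replicate values.
#' @return Integer probes x samples matrix of 0/1/`NA` calls.
#' @export
call_enriched_probes <- function(log_ratios, threshold = 1, min_replicates = 1L) {
  if (!is.list(log_ratios) || is.null(names(log_ratios)))
    stopf("`log_ratios` must be a named list of probes x replicates matrices")
  assert_number(threshold, "threshold")
  min_replicates <- assert_count(min_replicates, "min_replicates", lower = 1L)
  ref <- rownames(log_ratios[[1]])
  calls <- vapply(names(log_ratios), function(s) {
    m <- log_ratios[[s]]
    if (!is.numeric(m)) stopf("log-ratios for sample %s are not numeric", s)
    m <- as.matrix(m)
    if (!identical(rownames(m), ref))
      stopf("probe rows of sample %s do not match the first sample", s)
    avail <- rowSums(is.finite(m))
    mu <- rowMeans(m, na.rm = TRUE)
    out <- ifelse(avail < min_replicates, NA_integer_,
                  as.integer(mu >= threshold))
    out
  }, integer(length(ref)))
  rownames(calls) <- ref
  calls
}

#' Collapse sample-level calls to condition-level calls
#'
#' A probe is enriched in a condition (an age-by-cloning group) when strictly
#' more than `majority` of that condition's non-missing sample calls are 1.
#' A probe with no non-missing call in a condition is not enriched there.
#'
#' @param calls Probes x samples 0/1/`NA` matrix (columns named by
#'   `animal_id`).
#' @param meta Sample metadata with `animal_id` and `group`.
#' @param majority Proportion that must be strictly exceeded (default 0.5,
#'   i.e. a strict majority; exact ties are not enriched).
#' @return Probes x conditions 0/1 integer matrix.
#' @export
condition_level_calls <- function(calls, meta, majority = 0.5) {
  assert_number(majority, "majority", 0, 1)
  missing_meta <- setdiff(colnames(calls), meta$animal_id)
  if (length(missing_meta))
    stopf("samples absent from metadata: %s", paste(missing_meta, collapse = ", "))
  grp <- meta$group[match(colnames(calls), meta$animal_id)]
  conds <- unique(grp)
  out <- vapply(conds, function(g) {
    sub <- calls[, grp == g, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    n_enr <- rowSums(sub == 1L, na.rm = TRUE)
    as.integer(n_obs > 0 & n_enr > majority * n_obs)
  }, integer(nrow(calls)))
  rownames(out) <- rownames(calls)
  out
}

#' Delineate regions of interest by anchor extension
#'
#' Clusters qualifying ("anchor") probes into regions: within a chromosome, a
#' maximal run of anchor probes in which each consecutive pair is separated
#' by at most `max_gap` bp (next start minus previous end) forms one region;
#' runs with fewer than `min_probes` anchors are discarded. Region
#' coordinates span the first probe start to the last probe end (0-based,
#' half-open).
#'
#' @param probes Probe table with columns `probe_id`, `chrom`, `start`,
#'   `end`.
#' @param anchor_mask Logical vector aligned to `probes` rows marking
#'   qualifying probes.
#' @param max_gap Maximum inter-probe gap in bp within a region.
#' @param min_probes Minimum number of anchor probes per region.
#' @return Region table: `region_id`, `chrom`, `start`, `end`, `n_probes`
#'   and a `probe_ids` list column, sorted and non-overlapping.
#' @export
anchor_extend <- function(probes, anchor_mask, max_gap = 500L, min_probes = 3L) {
  if (length(anchor_mask) != nrow(probes))
    stopf("`anchor_mask` must align with `probes` rows")
  assert_number(max_gap, "max_gap", lower = 0)
  min_probes <- assert_count(min_probes, "min_probes", lower = 1L)
  if (any(probes$end <= probes$start))
    stopf("probe intervals must satisfy start < end")
  ord <- order(probes$chrom, probes$start)
  if (!identical(ord, seq_len(nrow(probes)))) {
    warnf("probes were not sorted by (chrom, start); sorting internally")
    probes <- probes[ord, , drop = FALSE]
    anchor_mask <- anchor_mask[ord]
  }
  anc <- probes[which(anchor_mask), , drop = FALSE]
  if (!nrow(anc)) return(empty_region_set())
  new_run <- c(TRUE, anc$chrom[-1] != anc$chrom[-nrow(anc)] |
                 anc$start[-1] - anc$end[-nrow(anc)] > max_gap)
  run_id <- cumsum(new_run)
  keep <- tabulate(run_id)[run_id] >= min_probes
  anc <- anc[keep, , drop = FALSE]
  run_id <- run_id[keep]
  if (!nrow(anc)) return(empty_region_set())
  idx <- unname(split(seq_len(nrow(anc)), run_id))
  out <- data.frame(
    region_id = sprintf("region_%04d", seq_along(idx)),
    chrom = vapply(idx, function(i) anc$chrom[i[1]], ""),
    start = vapply(idx, function(i) anc$start[i[1]], 0),
    end = vapply(idx, function(i) anc$end[i[length(i)]], 0),
    n_probes = lengths(idx),
    stringsAsFactors = FALSE, row.names = NULL)
  out$probe_ids <- lapply(idx, function(i) anc$probe_id[i])
  out
}

empty_region_set <- function() {
  out <- data.frame(region_id = character(), chrom = character(),
                    start = numeric(), end = numeric(),
                    n_probes = integer(), stringsAsFactors = FALSE)
  out$probe_ids <- list()
  out
}
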