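# --- file formats -----------------------------------------------------------
# probes / regions / DMRs: BED-like TSV (chrom, start, end, name, score=".",
# strand = ".", extra columns), coordinates 0-based half-open; matrices as
# TSV with row ids in the first column; every output carries a provenance
# header (# key: value) so reruns are comparable

write_with_header <- function(df, path, provenance) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(provenance))
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_skip_header <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

regions_to_bed <- function(regions, extra = NULL) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, name = regions$region_id,
                    score = ".", strand = ".",
                    n_probes = regions$n_probes, stringsAsFactors = FALSE)
  if (!is.null(extra)) bed <- cbind(bed, extra)
  bed
}

#' Validate pipeline input tables
#'
#' Checks coordinate sanity and sortedness of a probe table, cross-references
#' between an enrichment matrix and sample metadata, lesion-score vocabulary
#' and fatty-acid percentage sums. Issues are classified as `"fatal"` or
#' `"warning"`; fatty-acid fraction sums may drift from 100 by up to 5
#' percentage points (trace fatty acids are commonly excluded) before a
#' warning is raised, and are never fatal.
#'
#' @param probes Optional probe table (`probe_id`, `chrom`, `start`, `end`).
#' @param calls Optional probes x samples matrix.
#' @param meta Optional sample metadata (`animal_id`, `group`).
#' @param lesions Optional categorical lesion-score table.
#' @param fa_percent Optional fatty-acid percentage table for one fraction.
#' @return Data frame of issues (`severity`, `message`); zero rows means
#'   everything passed.
#' @export
validate_inputs <- function(probes = NULL, calls = NULL, meta = NULL,
                            lesions = NULL, fa_percent = NULL) {
  issues <- list()
  note <- function(severity, fmt, ...)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, message = sprintf(fmt, ...), stringsAsFactors = FALSE)
  if (!is.null(probes)) {
    if (any(probes$end <= probes$start))
      note("fatal", "probe intervals with end <= start: %s",
           paste(utils::head(probes$probe_id[probes$end <= probes$start], 3),
                 collapse = ", "))
    if (anyDuplicated(probes$probe_id))
      note("fatal", "duplicated probe ids")
    ord <- order(probes$chrom, probes$start)
    if (!identical(ord, seq_len(nrow(probes))))
      note("warning", "probes not sorted by (chrom, start)")
  }
  if (!is.null(calls) && !is.null(meta)) {
    missing_meta <- setdiff(colnames(calls), meta$animal_id)
    if (length(missing_meta))
      note("fatal", "samples missing from metadata: %s",
           paste(missing_meta, collapse = ", "))
  }
  if (!is.null(calls)) {
    vals <- calls[!is.na(calls)]
    if (!all(vals %in% c(0L, 1L)))
      note("fatal", "enrichment calls must be 0, 1 or missing")
  }
  if (!is.null(lesions)) {
    voc <- lesion_vocabulary()
    for (v in intersect(names(lesions), names(voc))) {
      bad <- setdiff(stats::na.omit(lesions[[v]]), voc[[v]])
      if (length(bad))
        note("fatal", "lesion column %s holds unknown code(s): %s", v,
             paste(bad, collapse = ", "))
    }
  }
  if (!is.null(fa_percent)) {
    tot <- rowSums(as.matrix(fa_percent), na.rm = TRUE)
    off <- abs(tot - 100) > 5
    if (any(off))
      note("warning", "%d animal(s) with fatty-acid percentages off 100 by > 5",
           sum(off))
  }
  do.call(rbind, issues) %||%
    data.frame(severity = character(), message = character())
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Orchestrates the full chain on generated data: simulate a cohort with
#' planted DMRs, delineate regions by anchor extension, fit the nested
#' binomial models, classify DMRs at the chosen FDR level, compute
#' per-individual enrichment percentages, run the lesion-score MCA on the
#' packaged cohort fixture, and write every intermediate as a TSV with a
#' provenance header plus a JSON summary report. Re-running with the same
#' configuration produces byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim A [sim_config()]; its seed drives all randomness.
#' @param max_gap,min_probes Anchor-extension settings.
#' @param alpha,adjust_method DMR classification settings.
#' @param run_mca Include the lesion-score MCA stage.
#' @return Invisibly, the report list (also written to `report.json`):
#'   region/DMR counts, the planted-vs-detected confusion matrices, and MCA
#'   variance fractions when run.
#' @export
run_pipeline <- function(out_dir, sim = sim_config(), max_gap = 500L,
                         min_probes = 3L, alpha = 0.05,
                         adjust_method = "BH", run_mca = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(sim = unclass(sim), max_gap = max_gap, min_probes = min_probes,
              alpha = alpha, adjust_method = adjust_method, run_mca = run_mca)
  prov <- c(tool = "medipdmr", config_hash = config_hash(cfg),
            seed = sim$seed)

  dat <- simulate_enrichment(sim)
  write_with_header(dat$probes, file.path(out_dir, "probes.tsv"),
                    c(prov, stage = "simulate"))
  write_with_header(dat$meta, file.path(out_dir, "sample_meta.tsv"),
                    c(prov, stage = "simulate"))
  write_with_header(cbind(probe_id = rownames(dat$calls), as.data.frame(dat$calls)),
                    file.path(out_dir, "calls.tsv"), c(prov, stage = "simulate"))
  write_with_header(dat$truth, file.path(out_dir, "truth.tsv"),
                    c(prov, stage = "simulate"))

  issues <- validate_inputs(probes = dat$probes, calls = dat$calls, meta = dat$meta)
  if (any(issues$severity == "fatal"))
    stopf("input validation failed: %s",
          paste(issues$message[issues$severity == "fatal"], collapse = "; "))

  regions <- anchor_extend(dat$probes, rep(TRUE, nrow(dat$probes)),
                           max_gap = max_gap, min_probes = min_probes)
  write_with_header(regions_to_bed(regions), file.path(out_dir, "regions.bed"),
                    c(prov, stage = "regions"))

  fits <- fit_region_models(regions, dat$calls, dat$meta)
  dmrs <- adjust_and_classify(fits, alpha = alpha, method = adjust_method)
  bed <- regions_to_bed(regions,
                        extra = dmrs[match(regions$region_id, dmrs$region_id),
                                     c("p_age", "adj_p_age", "p_clone",
                                       "adj_p_clone", "class")])
  write_with_header(bed, file.path(out_dir, "dmrs.bed"), c(prov, stage = "dmrs"))

  pi_res <- suppressWarnings(compute_pi(dat$calls, regions, dmrs))
  write_with_header(cbind(region_id = rownames(pi_res$P), as.data.frame(pi_res$P)),
                    file.path(out_dir, "pi_table.tsv"), c(prov, stage = "pi"))
  if (!is.null(pi_res$summary))
    write_with_header(pi_res$summary, file.path(out_dir, "pi_summary.csv"),
                      c(prov, stage = "pi"))

  # planted-vs-detected confusion matrices: detected regions map to planted
  # ones by identical coordinates (the generator's layout guarantees this
  # when the gap settings match)
  key_planted <- paste(dat$regions$chrom, dat$regions$start, dat$regions$end)
  key_found <- paste(regions$chrom, regions$start, regions$end)
  planted_idx <- match(key_found, key_planted)
  confusion <- function(truth_flag, called_flag) {
    tr <- truth_flag[planted_idx]
    table(planted = factor(tr, c(FALSE, TRUE)),
          detected = factor(called_flag, c(FALSE, TRUE)))
  }
  conf_age <- confusion(dat$truth$is_age_dmr, dmrs$is_age_dmr)
  conf_clone <- confusion(dat$truth$is_clone_dmr, dmrs$is_clone_dmr)

  report <- list(
    config_hash = unname(prov[["config_hash"]]),
    seed = sim$seed,
    n_regions = nrow(regions),
    n_age_dmrs = sum(dmrs$is_age_dmr),
    n_clone_dmrs = sum(dmrs$is_clone_dmr),
    n_overlap_dmrs = sum(dmrs$is_age_dmr & dmrs$is_clone_dmr),
    confusion_age = as.vector(conf_age),
    confusion_clone = as.vector(conf_clone),
    confusion_levels = c("TN", "FN", "FP", "TP"))

  if (run_mca) {
    fixture <- load_lesion_fixture()
    scores <- fixture$scores[stats::complete.cases(fixture$scores), ]
    merged <- merge_rare_categories(scores[, setdiff(names(scores), "animal_id")])
    ord <- mca(merged)
    report$mca_pct_variance <- round(ord$eig$pct_variance, 4)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
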