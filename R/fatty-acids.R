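# canonical long-chain fatty acids detected in both adults and perinatal
# animals; names use Cx:y followed by the omega family (w = omega)
CORE_FAS <- c("C14:0", "C16:0", "C16:1w7", "C18:0", "C18:1w9", "C18:2w6",
              "C18:3w3", "C20:3w6", "C20:4w6", "C20:5w3", "C22:4w6",
              "C22:5w3", "C22:6w3")

# variables removed from the rank-PCA because each is highly correlated to a
# retained partner (prefix PL/NL = phospholipid / neutral-lipid fraction)
PCA_REMOVALS <- c("PL_C18:1w9", "NL_C20:3w6", "PL_C22:4w6", "NL_C20:5w3")

parse_fa_name <- function(names) {
  nm <- normalize_fa_names(names)
  m <- regmatches(nm, regexec("^C([0-9]+):([0-9]+)(w([0-9]+))?$", nm))
  bad <- names[vapply(m, length, 0L) == 0L]
  if (length(bad))
    stopf("unrecognized fatty-acid name(s): %s", paste(bad, collapse = ", "))
  data.frame(name = names,
             carbons = vapply(m, function(g) as.integer(g[2]), 0L),
             double_bonds = vapply(m, function(g) as.integer(g[3]), 0L),
             omega = vapply(m, function(g)
               if (g[5] == "") NA_integer_ else as.integer(g[5]), 0L),
             stringsAsFactors = FALSE)
}

#' Derived fatty-acid features for one lipid fraction
#'
#' From a per-animal table of fatty-acid percentages (of total fatty acids in
#' one lipid fraction, phospholipids or neutral lipids) derives the family
#' totals and diagnostic ratios used downstream. Family membership is
#' resolved from the fatty-acid name: the `:x` part gives saturation
#' (saturated x = 0, monounsaturated x = 1, polyunsaturated x >= 2) and the
#' omega suffix the omega-3/omega-6 family. Derived features: total
#' saturated (SFA), monounsaturated (MUFA), polyunsaturated (PUFA), omega-3
#' and omega-6 percentages, and the ratios omega-3/omega-6, PUFA/SFA,
#' SFA/UFA, MUFA/SFA, C18:2w6/C20:4w6 and C22:6w3/C20:4w6. A ratio whose
#' denominator is not strictly positive (or whose terms are absent) is
#' `NA`.
#'
#' @param percent Data frame or matrix of fatty-acid percentages, rows =
#'   animals, columns named like `C22:6w3` (the Greek omega is accepted).
#' @return Data frame with the input percentages (names normalized) followed
#'   by the derived features `SFA`, `MUFA`, `PUFA`, `w3`, `w6`, `w3_w6`,
#'   `PUFA_SFA`, `SFA_UFA`, `MUFA_SFA`, `C18:2w6_C20:4w6`,
#'   `C22:6w3_C20:4w6`.
#' @export
fa_features <- function(percent) {
  x <- as.data.frame(percent, check.names = FALSE)
  names(x) <- normalize_fa_names(names(x))
  info <- parse_fa_name(names(x))
  if (any(x < 0, na.rm = TRUE)) stopf("fatty-acid percentages must be >= 0")
  rs <- function(cols) if (length(cols)) rowSums(x[, cols, drop = FALSE]) else
    rep(0, nrow(x))
  sfa <- rs(info$name[info$double_bonds == 0])
  mufa <- rs(info$name[info$double_bonds == 1])
  pufa <- rs(info$name[info$double_bonds >= 2])
  w3 <- rs(info$name[!is.na(info$omega) & info$omega == 3])
  w6 <- rs(info$name[!is.na(info$omega) & info$omega == 6])
  safe_ratio <- function(num, den) ifelse(is.na(den) | den <= 0, NA_real_, num / den)
  single <- function(nm) if (nm %in% names(x)) x[[nm]] else rep(NA_real_, nrow(x))
  out <- cbind(x,
               SFA = sfa, MUFA = mufa, PUFA = pufa, w3 = w3, w6 = w6,
               w3_w6 = safe_ratio(w3, w6),
               PUFA_SFA = safe_ratio(pufa, sfa),
               SFA_UFA = safe_ratio(sfa, mufa + pufa),
               MUFA_SFA = safe_ratio(mufa, sfa),
               `C18:2w6_C20:4w6` = safe_ratio(single("C18:2w6"), single("C20:4w6")),
               `C22:6w3_C20:4w6` = safe_ratio(single("C22:6w3"), single("C20:4w6")))
  names(out) <- c(names(x), "SFA", "MUFA", "PUFA", "w3", "w6", "w3_w6",
                  "PUFA_SFA", "SFA_UFA", "MUFA_SFA",
                  "C18:2w6_C20:4w6", "C22:6w3_C20:4w6")
  out
}

#' Build the rank-PCA fatty-acid variable set
#'
#' Combines the 13 core fatty-acid percentage variables of the phospholipid
#' (`PL_`) and neutral-lipid (`NL_`) fractions and removes the four
#' variables that are highly correlated to a retained partner, leaving the
#' 22 active variables analysed by [rank_pca()].
#'
#' @param pl,nl Per-animal percentage tables for the two fractions, columns
#'   covering the 13 core fatty acids.
#' @param drop Variables to remove (defaults to the four standard removals).
#' @return Data frame of 22 prefixed variables.
#' @export
fa_pca_variables <- function(pl, nl, drop = PCA_REMOVALS) {
  pick_core <- function(tab, prefix) {
    tab <- as.data.frame(tab, check.names = FALSE)
    names(tab) <- normalize_fa_names(names(tab))
    miss <- setdiff(CORE_FAS, names(tab))
    if (length(miss)) stopf("%s fraction lacks fatty acid(s): %s", prefix,
                            paste(miss, collapse = ", "))
    out <- tab[, CORE_FAS, drop = FALSE]
    names(out) <- paste(prefix, names(out), sep = "_")
    out
  }
  both <- cbind(pick_core(pl, "PL"), pick_core(nl, "NL"))
  both[, setdiff(names(both), normalize_fa_names(drop)), drop = FALSE]
}

#' Build the MFA fatty-acid variable set
#'
#' For each lipid fraction, the 13 core fatty-acid percentages plus the five
#' family totals and six ratios of [fa_features()] (24 variables), prefixed
#' `PL_`/`NL_` and combined into the 48-variable set used as the "FA" set
#' of the multiple factor analysis.
#'
#' @inheritParams fa_pca_variables
#' @return Data frame of 48 prefixed variables.
#' @export
fa_mfa_variables <- function(pl, nl) {
  build <- function(tab, prefix) {
    tab <- as.data.frame(tab, check.names = FALSE)
    names(tab) <- normalize_fa_names(names(tab))
    miss <- setdiff(CORE_FAS, names(tab))
    if (length(miss)) stopf("%s fraction lacks fatty acid(s): %s", prefix,
                            paste(miss, collapse = ", "))
    feats <- fa_features(tab[, CORE_FAS, drop = FALSE])
    names(feats) <- paste(prefix, names(feats), sep = "_")
    feats
  }
  cbind(build(pl, "PL"), build(nl, "NL"))
}
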