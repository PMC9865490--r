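# Relative crosstalk (RC) scoring.
#
# Under the law of mass action the abundance of a ligand-receptor complex is
# proportional to the product of ligand and receptor concentrations divided
# by the dissociation constant. Taking compartment mRNA means as
# concentration proxies and assuming constant binding kinetics, the
# dissociation constant cancels from the ratio of one directional complex to
# the sum of all four, leaving e.g. for tumor ligand -> stroma receptor:
#
#   RC_TS = (L_T * R_S) / (L_T*R_S + L_T*R_T + L_S*R_S + L_S*R_T)
#
# The denominator is exactly the sum of the four numerators, so the four
# directional scores sum to 1, and the score factorizes as
# [L_T/(L_T+L_S)] * [R_S/(R_T+R_S)].

#' Read a ligand-receptor pair table
#'
#' @param path TSV with two or three columns (ligand, receptor, optional
#'   source tag), with a header row.
#' @return data frame with columns `ligand`, `receptor`, `source`,
#'   `self_pair`; deduplicated on (ligand, receptor), symbols uppercased.
#'   Self-pairs (ligand == receptor) are kept and flagged.
#' @export
read_pairs <- function(path) {
  df <- read_tsv_strict(path)
  if (nrow(df) == 0L) stop("empty pair table: ", path, call. = FALSE)
  if (ncol(df) < 2L) stop("pair table needs >= 2 columns", call. = FALSE)
  lig <- norm_symbol(as.character(df[[1L]]))
  rec <- norm_symbol(as.character(df[[2L]]))
  bad <- which(!nzchar(lig) | !nzchar(rec) | is.na(lig) | is.na(rec))
  if (length(bad)) {
    stop("missing ligand/receptor field at data line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  src <- if (ncol(df) >= 3L) as.character(df[[3L]]) else NA_character_
  out <- data.frame(ligand = lig, receptor = rec, source = src,
                    stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("ligand", "receptor")])
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicate pair(s)")
    out <- out[!dup, , drop = FALSE]
  }
  out$self_pair <- out$ligand == out$receptor
  if (any(out$self_pair)) {
    message(sum(out$self_pair), " self-pair(s) (ligand == receptor) kept ",
            "and flagged")
  }
  message("loaded ", nrow(out), " ligand-receptor pairs from ", path)
  rownames(out) <- NULL
  out
}

#' Four-directional relative crosstalk scores
#'
#' Vectorized over pairs. Directions are named ligand-compartment first:
#' `tt` = tumor ligand to tumor receptor, `ts` = tumor ligand to stroma
#' receptor, `st` = stroma ligand to tumor receptor, `ss` = stroma ligand to
#' stroma receptor.
#'
#' @param ligand_tumor,ligand_stroma nonnegative compartment means of the
#'   ligand gene.
#' @param receptor_tumor,receptor_stroma nonnegative compartment means of
#'   the receptor gene.
#' @return data frame with columns `rc_tt`, `rc_ts`, `rc_st`, `rc_ss`,
#'   `ligand_tumor_frac`, `receptor_tumor_frac`, `defined`. Scores are `NA`
#'   and `defined` is `FALSE` when the ligand or receptor total vanishes
#'   (the denominator is zero; 0/0 expresses no preference).
#' @export
rc_scores <- function(ligand_tumor, ligand_stroma,
                      receptor_tumor, receptor_stroma) {
  lt <- as.numeric(ligand_tumor); ls <- as.numeric(ligand_stroma)
  rt <- as.numeric(receptor_tumor); rs <- as.numeric(receptor_stroma)
  if (any(c(lt, ls, rt, rs) < 0, na.rm = TRUE)) {
    stop("compartment means must be nonnegative", call. = FALSE)
  }
  l_tot <- lt + ls
  r_tot <- rt + rs
  defined <- is.finite(l_tot) & is.finite(r_tot) & l_tot > 0 & r_tot > 0
  denom <- l_tot * r_tot   # = lt*rt + lt*rs + ls*rt + ls*rs
  denom[!defined] <- NA_real_
  data.frame(rc_tt = lt * rt / denom,
             rc_ts = lt * rs / denom,
             rc_st = ls * rt / denom,
             rc_ss = ls * rs / denom,
             ligand_tumor_frac = ifelse(defined, lt / l_tot, NA_real_),
             receptor_tumor_frac = ifelse(defined, rt / r_tot, NA_real_),
             defined = defined)
}

#' Score all ligand-receptor pairs in both cohorts
#'
#' @param pairs data frame from [read_pairs()] (columns `ligand`,
#'   `receptor`, optionally `source`).
#' @param prof_primary,prof_metastatic `compartment_profiles` for the two
#'   cohorts, over the same gene universe.
#' @return data frame with one row per pair per cohort and columns
#'   `ligand`, `receptor`, `cohort`, the four `rc_*` scores, the
#'   compartment fractions and `defined`; a `skips` attribute tabulates
#'   pairs dropped because a gene was absent or flagged unidentifiable.
#' @export
score_crosstalk <- function(pairs, prof_primary, prof_metastatic) {
  profs <- list(primary = prof_primary, metastatic = prof_metastatic)
  res <- list()
  skips <- list()
  for (cohort in names(profs)) {
    prof <- profs[[cohort]]
    idx_l <- match(pairs$ligand, prof$gene)
    idx_r <- match(pairs$receptor, prof$gene)
    absent <- is.na(idx_l) | is.na(idx_r)
    flagged <- !absent &
      (prof$flag[idx_l] != "ok" | prof$flag[idx_r] != "ok" |
         !is.finite(prof$tumor_mean[idx_l]) |
         !is.finite(prof$tumor_mean[idx_r]))
    keep <- !absent & !flagged
    if (any(!keep)) {
      skips[[cohort]] <- data.frame(
        ligand = pairs$ligand[!keep], receptor = pairs$receptor[!keep],
        cohort = cohort,
        reason = ifelse(absent[!keep], "absent", "unidentifiable"),
        stringsAsFactors = FALSE)
    }
    if (!any(keep)) next
    sc <- rc_scores(prof$tumor_mean[idx_l[keep]],
                    prof$stroma_mean[idx_l[keep]],
                    prof$tumor_mean[idx_r[keep]],
                    prof$stroma_mean[idx_r[keep]])
    res[[cohort]] <- cbind(
      data.frame(ligand = pairs$ligand[keep],
                 receptor = pairs$receptor[keep],
                 cohort = cohort, stringsAsFactors = FALSE),
      sc)
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  attr(out, "skips") <- if (length(skips)) {
    do.call(rbind, c(skips, list(make.row.names = FALSE)))
  } else {
    data.frame(ligand = character(), receptor = character(),
               cohort = character(), reason = character())
  }
  out
}

# direction -> rc column name; direction labels use ligand compartment first
direction_column <- c(TT = "rc_tt", TS = "rc_ts", ST = "rc_st", SS = "rc_ss")

#' Rank the top ligand-receptor pairs for one signaling direction
#'
#' @param results data frame from [score_crosstalk()].
#' @param direction one of `"TT"`, `"TS"`, `"ST"`, `"SS"` (ligand
#'   compartment first, so `"TS"` is tumor ligand to stroma receptor).
#' @param k number of pairs to return (default 15).
#' @param key how to pool the two cohorts' scores for ranking:
#'   `"max_over_cohorts"` (default), `"mean_over_cohorts"`,
#'   `"primary_only"` or `"metastatic_only"`.
#' @return data frame of at most `k` rows, sorted descending by the ranking
#'   key (ties broken by ligand then receptor symbol, ascending), with the
#'   direction's contribution percentage (RC x 100) per cohort and a
#'   per-cohort `decisive` flag (RC > 0.5: the direction outweighs the
#'   other three combined).
#' @export
rank_direction <- function(results, direction = c("TT", "TS", "ST", "SS"),
                           k = 15L,
                           key = c("max_over_cohorts", "mean_over_cohorts",
                                   "primary_only", "metastatic_only")) {
  direction <- match.arg(direction)
  key <- match.arg(key)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  col <- direction_column[[direction]]
  def <- results[results$defined, , drop = FALSE]
  prim <- def[def$cohort == "primary", c("ligand", "receptor", col)]
  met <- def[def$cohort == "metastatic", c("ligand", "receptor", col)]
  names(prim)[3L] <- "rc_primary"
  names(met)[3L] <- "rc_metastatic"
  merged <- merge(prim, met, by = c("ligand", "receptor"), all = TRUE)
  keyval <- switch(key,
    max_over_cohorts = pmax(merged$rc_primary, merged$rc_metastatic,
                            na.rm = TRUE),
    mean_over_cohorts = rowMeans(merged[, c("rc_primary", "rc_metastatic")],
                                 na.rm = TRUE),
    primary_only = merged$rc_primary,
    metastatic_only = merged$rc_metastatic)
  merged$rank_key <- keyval
  merged <- merged[is.finite(merged$rank_key), , drop = FALSE]
  ord <- order(-merged$rank_key, merged$ligand, merged$receptor)
  merged <- merged[ord, , drop = FALSE]
  if (nrow(merged) < k) {
    warning("only ", nrow(merged), " defined pair(s) available for ",
            "direction ", direction, " (k = ", k, ")", call. = FALSE)
  }
  top <- utils::head(merged, k)
  out <- data.frame(
    direction = direction,
    ligand = top$ligand, receptor = top$receptor,
    rank_key = top$rank_key,
    primary_pct = 100 * top$rc_primary,
    metastatic_pct = 100 * top$rc_metastatic,
    decisive_primary = !is.na(top$rc_primary) & top$rc_primary > 0.5,
    decisive_metastatic = !is.na(top$rc_metastatic) & top$rc_metastatic > 0.5,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
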