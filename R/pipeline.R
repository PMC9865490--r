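# End-to-end pipeline driver.
#
# Stages: load expression -> (optional TPM normalization) -> purity
# (estimated from signatures or user-supplied) -> cohort split ->
# per-cohort deconvolution with bootstrap CIs -> crosstalk scoring ->
# per-direction rankings -> report files. Every figure is derived from a
# TSV twin so no number exists only in graphical output.

#' Run the full deconvolution-and-crosstalk pipeline
#'
#' @param config a YAML file path or a list with entries:
#'   \describe{
#'     \item{expression}{path to the expression TSV (required).}
#'     \item{expression_unit}{`"counts"`, `"tpm"` or `"log2tpm"`
#'       (default `"tpm"`).}
#'     \item{gene_lengths}{gene-length TSV, required when
#'       `expression_unit = "counts"`.}
#'     \item{metadata}{sample-to-cohort TSV (required).}
#'     \item{pairs}{ligand-receptor pair TSV (required).}
#'     \item{purity_file}{optional user purity TSV; skips estimation.}
#'     \item{signatures}{GMT with `stromal` and `immune` sets; required
#'       when no purity file is given.}
#'     \item{conversion}{purity conversion name (default `"cosine"`).}
#'     \item{bootstrap}{list with `B` (default 1000) and `seed`
#'       (default 17).}
#'     \item{ranking}{list with `k` (default 15) and `key`
#'       (default `"max_over_cohorts"`).}
#'     \item{outdir}{output directory (required).}
#'   }
#' @return the output directory path, invisibly. Outputs: `purity.tsv`,
#'   `compartments_primary.tsv` / `compartments_metastatic.tsv` (+ JSON
#'   sidecars), `crosstalk.tsv`, `ranking_<dir>.tsv` and
#'   `ranking_<dir>.png` for each direction, `run_config.yaml`,
#'   `run_metadata.json` and `pipeline.log`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (req in c("expression", "metadata", "pairs", "outdir")) {
    if (is.null(cfg[[req]])) stop("config missing '", req, "'", call. = FALSE)
  }
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "pipeline.log")
  t0 <- Sys.time()
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, code) {
    log_line("stage ", name, " started")
    res <- tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_line("stage ", name, " done")
    res
  }

  unit <- cfg$expression_unit %||% "tpm"
  expr <- stage("load_expression", {
    m <- read_expression(cfg$expression, unit_state = unit)
    if (unit_state(m) == "counts") {
      if (is.null(cfg$gene_lengths)) {
        stop("gene_lengths required for counts input")
      }
      m <- tpm_normalize(m, read_gene_lengths(cfg$gene_lengths))
    }
    m
  })

  purity <- stage("purity", {
    if (!is.null(cfg$purity_file)) {
      log_line("using user-supplied purities; estimation skipped")
      read_purity(cfg$purity_file)
    } else {
      if (is.null(cfg$signatures)) {
        stop("signatures GMT required when no purity_file is given")
      }
      sets <- read_gmt(cfg$signatures)
      if (!all(c("stromal", "immune") %in% names(sets))) {
        stop("signatures GMT must contain sets 'stromal' and 'immune'")
      }
      estimate_purity(expr, sets$stromal, sets$immune,
                      conversion = cfg$conversion %||% "cosine")
    }
  })
  write_tsv(data.frame(sample_id = names(purity),
                       purity = as.numeric(purity),
                       source = attr(purity, "source")),
            file.path(outdir, "purity.tsv"))

  cohorts <- stage("split_cohorts", {
    meta <- read_tsv_strict(cfg$metadata)
    names(meta)[1:2] <- c("sample_id", "cohort")
    split_cohorts(expr, meta)
  })

  B <- cfg$bootstrap$B %||% 1000L
  seed <- cfg$bootstrap$seed %||% 17L
  profs <- stage("deconvolution", {
    lapply(stats::setNames(nm = names(cohorts)), function(lab) {
      prof <- bootstrap_ci(cohorts[[lab]], purity, cohort = lab,
                           B = as.integer(B), seed = as.integer(seed))
      write_profiles(prof, file.path(outdir,
                                     paste0("compartments_", lab, ".tsv")))
      prof
    })
  })

  pairs <- stage("load_pairs", read_pairs(cfg$pairs))
  results <- stage("crosstalk", {
    res <- score_crosstalk(pairs, profs$primary, profs$metastatic)
    write_tsv(res, file.path(outdir, "crosstalk.tsv"))
    skips <- attr(res, "skips")
    if (nrow(skips)) {
      write_tsv(skips, file.path(outdir, "crosstalk_skips.tsv"))
      log_line(nrow(skips), " pair x cohort combination(s) skipped")
    }
    res
  })

  k <- cfg$ranking$k %||% 15L
  key <- cfg$ranking$key %||% "max_over_cohorts"
  rankings <- stage("ranking", {
    lapply(stats::setNames(nm = c("TT", "TS", "ST", "SS")), function(d) {
      rank_direction(results, d, k = as.integer(k), key = key)
    })
  })
  stage("report", write_report(results, rankings, outdir))

  yaml::write_yaml(cfg, file.path(outdir, "run_config.yaml"))
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("stromatalk")),
         r_version = as.character(getRversion()),
         seed = seed, bootstrap_B = B,
         n_genes = nrow(expr),
         cohort_sizes = lapply(cohorts, ncol),
         n_pairs = nrow(pairs),
         elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    file.path(outdir, "run_metadata.json"), auto_unbox = TRUE)
  log_line("pipeline complete")
  invisible(outdir)
}

#' Write per-direction ranking tables and stacked-bar figures
#'
#' For each direction, writes `ranking_<dir>.tsv` and a horizontal
#' stacked-bar figure `ranking_<dir>.png` with one row per top-k pair and
#' cohort, segments showing the four directions' contribution percentages.
#' Figures are drawn strictly from the rows of the TSV twin.
#'
#' @param results data frame from [score_crosstalk()].
#' @param rankings named list of [rank_direction()] outputs (names `TT`,
#'   `TS`, `ST`, `SS`).
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(results, rankings, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(rankings)) {
    rk <- rankings[[d]]
    write_tsv(rk, file.path(outdir, paste0("ranking_", d, ".tsv")))
    if (!nrow(rk)) next
    long <- do.call(rbind, lapply(seq_len(nrow(rk)), function(i) {
      pair_lab <- paste0(rk$ligand[i], "-", rk$receptor[i])
      sub <- results[results$ligand == rk$ligand[i] &
                       results$receptor == rk$receptor[i] &
                       results$defined, , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      data.frame(pair = pair_lab, rank = i, cohort = sub$cohort,
                 direction = rep(c("TT", "TS", "ST", "SS"),
                                 each = nrow(sub)),
                 pct = 100 * c(sub$rc_tt, sub$rc_ts, sub$rc_st, sub$rc_ss),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(long) || !nrow(long)) next
    long$pair <- factor(long$pair, levels = rev(unique(long$pair[order(long$rank)])))
    fig <- ggplot2::ggplot(long, ggplot2::aes(
      x = .data$pct, y = .data$pair, fill = .data$direction)) +
      ggplot2::geom_col(position = "stack") +
      ggplot2::facet_wrap(~cohort) +
      ggplot2::labs(x = "directionality contribution (%)", y = NULL,
                    title = paste0("Top pairs, direction ", d)) +
      ggplot2::theme_minimal(base_size = 9)
    ggplot2::ggsave(file.path(outdir, paste0("ranking_", d, ".png")),
                    fig, width = 7, height = 5, dpi = 120)
  }
  invisible(outdir)
}
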