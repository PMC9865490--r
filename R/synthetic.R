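# Synthetic cohorts with known compartment truth.
#
# The generator emulates exactly the data-generating assumptions of the
# two-compartment model: fixed per-gene tumor and stroma means, per-sample
# purities, linear mixing by purity, and (its one addition) multiplicative
# mean-one log-normal noise on the bulk observation so values stay
# nonnegative while mimicking RNA-seq dispersion.

#' Draw per-sample tumor purities
#'
#' Beta(alpha, beta) draws clipped into \[0.05, 0.95\]. The default (5, 2)
#' gives a high-purity cohort (mean 5/7), the typical situation for
#' melanoma.
#'
#' @param n_samples number of samples (>= 2).
#' @param alpha,beta positive Beta shape parameters.
#' @param seed integer seed.
#' @return a [purity_set()] with samples named `S001`, `S002`, ...
#' @export
gen_purities <- function(n_samples, alpha = 5, beta = 2, seed = 17L) {
  if (n_samples < 2L) stop("need at least 2 samples", call. = FALSE)
  if (alpha <= 0 || beta <= 0) stop("alpha, beta must be > 0", call. = FALSE)
  p <- with_seed(seed, stats::rbeta(n_samples, alpha, beta))
  p <- clamp(p, 0.05, 0.95)
  purity_set(stats::setNames(p, sprintf("S%03d", seq_len(n_samples))),
             source = "user_supplied")
}

#' Generate compartment truth, ligand-receptor pairs and signature sets
#'
#' Background genes draw log-normal (meanlog 3, sdlog 1) tumor and stroma
#' means on the TPM scale. The two compartments of a background gene share
#' a per-gene base abundance with correlation `bg_compartment_cor` on the
#' log scale (each marginal stays exactly lognormal(3, 1)): background
#' genes are non-directional apart from moderate compartment differences,
#' so strong directional skew is the property of planted pairs alone.
#' For each planted pair in a
#' direction, the ligand and receptor totals are drawn log-normal
#' (meanlog 4, sdlog 0.3) and split `skew : (1 - skew)` toward the
#' direction's compartments — e.g. a TS-dominant pair gets a tumor-skewed
#' ligand and a stroma-skewed receptor, so at the default skew 0.9 its true
#' RC_TS is 0.81. Stromal/immune signature genes are stroma-skewed and
#' disjoint from all pair genes so purity estimation and crosstalk tests do
#' not couple.
#'
#' @param n_genes total gene count (background + planted + signature).
#' @param planted named integer vector of planted dominant pairs per
#'   direction, e.g. `c(TT = 10, TS = 10, ST = 10, SS = 10)`.
#' @param n_pairs total pair count; pairs beyond the planted ones link
#'   background genes.
#' @param skew compartment share of a planted gene's total (default 0.9).
#' @param sig_sizes named vector: genes per signature set
#'   (default `c(stromal = 50, immune = 50)`).
#' @param bg_compartment_cor log-scale correlation between a background
#'   gene's tumor and stroma means (default 0.75, i.e. typical compartment
#'   differences around two-fold).
#' @param seed integer seed.
#' @return list with `tumor_mean`, `stroma_mean` (named vectors),
#'   `pairs` (data frame with `ligand`, `receptor`, `planted` direction or
#'   `"background"`), `pair_truth` (true RC quadruples from the true
#'   compartments), and `signatures` (named list of gene sets).
#' @export
gen_compartments <- function(n_genes = 2000L,
                             planted = c(TT = 10L, TS = 10L, ST = 10L,
                                         SS = 10L),
                             n_pairs = 100L, skew = 0.9,
                             sig_sizes = c(stromal = 50L, immune = 50L),
                             bg_compartment_cor = 0.75, seed = 17L) {
  if (any(planted < 0L)) stop("planted counts must be nonnegative",
                              call. = FALSE)
  planted <- planted[c("TT", "TS", "ST", "SS")]
  planted[is.na(planted)] <- 0L
  names(planted) <- c("TT", "TS", "ST", "SS")
  n_planted_genes <- 2L * sum(planted)
  n_sig <- sum(sig_sizes)
  n_bg <- n_genes - n_planted_genes - n_sig
  n_bg_pairs <- n_pairs - sum(planted)
  if (n_bg < 2L * max(0L, n_bg_pairs)) {
    stop("planted pairs and signatures exceed available genes", call. = FALSE)
  }
  if (n_bg_pairs < 0L) stop("planted pairs exceed n_pairs", call. = FALSE)

  with_seed(seed, {
    bg_genes <- sprintf("BG%04d", seq_len(n_bg))
    # shared + compartment-specific log-normal components; each marginal is
    # lognormal(3, 1), within-gene log-scale correlation bg_compartment_cor
    sd_shared <- sqrt(bg_compartment_cor)
    sd_ind <- sqrt(1 - bg_compartment_cor)
    z_base <- stats::rnorm(n_bg)
    tumor <- stats::setNames(
      exp(3 + sd_shared * z_base + sd_ind * stats::rnorm(n_bg)), bg_genes)
    stroma <- stats::setNames(
      exp(3 + sd_shared * z_base + sd_ind * stats::rnorm(n_bg)), bg_genes)

    pairs <- data.frame(ligand = character(), receptor = character(),
                        planted = character(), stringsAsFactors = FALSE)
    # ligand compartment first: TS = tumor ligand, stroma receptor
    dir_skew <- list(TT = c(TRUE, TRUE), TS = c(TRUE, FALSE),
                     ST = c(FALSE, TRUE), SS = c(FALSE, FALSE))
    for (d in names(planted)) {
      nd <- planted[[d]]
      if (nd == 0L) next
      lig <- sprintf("L%s%02d", d, seq_len(nd))
      rec <- sprintf("R%s%02d", d, seq_len(nd))
      l_tot <- stats::rlnorm(nd, 4, 0.3)
      r_tot <- stats::rlnorm(nd, 4, 0.3)
      lig_tumor_skewed <- dir_skew[[d]][1L]
      rec_tumor_skewed <- dir_skew[[d]][2L]
      tumor[lig] <- l_tot * (if (lig_tumor_skewed) skew else 1 - skew)
      stroma[lig] <- l_tot * (if (lig_tumor_skewed) 1 - skew else skew)
      tumor[rec] <- r_tot * (if (rec_tumor_skewed) skew else 1 - skew)
      stroma[rec] <- r_tot * (if (rec_tumor_skewed) 1 - skew else skew)
      pairs <- rbind(pairs, data.frame(ligand = lig, receptor = rec,
                                       planted = d,
                                       stringsAsFactors = FALSE))
    }
    if (n_bg_pairs > 0L) {
      pick <- sample(bg_genes, 2L * n_bg_pairs)
      pairs <- rbind(pairs, data.frame(
        ligand = pick[seq_len(n_bg_pairs)],
        receptor = pick[n_bg_pairs + seq_len(n_bg_pairs)],
        planted = "background", stringsAsFactors = FALSE))
    }

    signatures <- list()
    offset <- 0L
    for (s in names(sig_sizes)) {
      g <- sprintf("SIG%s%03d", toupper(substr(s, 1L, 3L)),
                   seq_len(sig_sizes[[s]]))
      # stroma-skewed: high stromal content lifts these genes' ranks
      tumor[g] <- stats::rlnorm(sig_sizes[[s]], 1, 0.3)
      stroma[g] <- stats::rlnorm(sig_sizes[[s]], 4.5, 0.3)
      signatures[[s]] <- g
      offset <- offset + sig_sizes[[s]]
    }
    truth_sc <- rc_scores(tumor[pairs$ligand], stroma[pairs$ligand],
                          tumor[pairs$receptor], stroma[pairs$receptor])
    list(tumor_mean = tumor, stroma_mean = stroma, pairs = pairs,
         pair_truth = cbind(pairs, truth_sc), signatures = signatures)
  })
}

#' Mix compartment truth into a noisy bulk expression matrix
#'
#' Each bulk value is the purity-weighted mixture
#' `p_i * tumor_mean + (1 - p_i) * stroma_mean` times a mean-one log-normal
#' factor `exp(eps)`, `eps ~ Normal(-sigma^2/2, sigma^2)` with `sigma`
#' chosen so the factor's coefficient of variation equals `noise_cv`.
#' `noise_cv = 0` reproduces the exact mixture.
#'
#' @param tumor_mean,stroma_mean named nonnegative vectors over genes.
#' @param purities a [purity_set()] (or named vector in (0, 1)).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return a `bulk_matrix` (TPM scale, `unit_state = "tpm"`).
#' @export
gen_bulk <- function(tumor_mean, stroma_mean, purities, noise_cv = 0.2,
                     seed = 17L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  stopifnot(identical(names(tumor_mean), names(stroma_mean)))
  p <- as.numeric(purities)
  mix <- outer(tumor_mean, p) + outer(stroma_mean, 1 - p)
  if (noise_cv > 0) {
    sigma2 <- log(1 + noise_cv^2)
    eps <- with_seed(seed, matrix(
      stats::rnorm(length(mix), -sigma2 / 2, sqrt(sigma2)),
      nrow = nrow(mix)))
    mix <- mix * exp(eps)
  }
  dimnames(mix) <- list(names(tumor_mean), names(purities))
  bulk_matrix(mix, "tpm")
}

#' Simulate one cohort with known truth
#'
#' Convenience wrapper around [gen_compartments()], [gen_purities()] and
#' [gen_bulk()], deriving the three stage seeds deterministically from one
#' master seed. Defaults match the benchmark study conditions: 470 samples,
#' 2000 genes, 100 pairs of which 10 planted per direction, purity
#' Beta(5, 2), noise CV 0.2.
#'
#' @param n_genes,n_samples,purity_alpha,purity_beta,noise_cv,n_pairs
#'   generator parameters.
#' @param planted,skew,sig_sizes passed to [gen_compartments()].
#' @param seed master seed; identical parameters and seed reproduce the
#'   dataset bit-identically.
#' @return list with `expr` (`bulk_matrix`), `purities`, `truth` (the
#'   [gen_compartments()] list), and `params`.
#' @export
simulate_cohort <- function(n_genes = 2000L, n_samples = 470L,
                            purity_alpha = 5, purity_beta = 2,
                            noise_cv = 0.2, n_pairs = 100L,
                            planted = c(TT = 10L, TS = 10L, ST = 10L,
                                        SS = 10L),
                            skew = 0.9,
                            sig_sizes = c(stromal = 50L, immune = 50L),
                            seed = 17L) {
  seeds <- derive_seeds(seed, 3L)
  truth <- gen_compartments(n_genes, planted, n_pairs, skew, sig_sizes,
                            seed = seeds[1L])
  purities <- gen_purities(n_samples, purity_alpha, purity_beta,
                           seed = seeds[2L])
  expr <- gen_bulk(truth$tumor_mean, truth$stroma_mean, purities,
                   noise_cv, seed = seeds[3L])
  list(expr = expr, purities = purities, truth = truth,
       params = list(n_genes = n_genes, n_samples = n_samples,
                     purity_alpha = purity_alpha, purity_beta = purity_beta,
                     noise_cv = noise_cv, n_pairs = n_pairs,
                     planted = as.list(planted), skew = skew, seed = seed))
}

#' Simulate a two-cohort study sharing one compartment truth
#'
#' Primary and metastatic cohorts share the gene universe, pair list and
#' compartment truth but draw independent purities and noise, emulating two
#' lesion types profiled on a common transcriptome.
#'
#' @param n_primary,n_metastatic cohort sizes.
#' @inheritParams simulate_cohort
#' @return list with `expr` (combined `bulk_matrix`), `metadata`
#'   (sample_id/cohort data frame), `purities`, `truth` and `params`.
#' @export
simulate_study <- function(n_primary = 100L, n_metastatic = 100L,
                           n_genes = 2000L, purity_alpha = 5,
                           purity_beta = 2, noise_cv = 0.2, n_pairs = 100L,
                           planted = c(TT = 10L, TS = 10L, ST = 10L,
                                       SS = 10L),
                           skew = 0.9,
                           sig_sizes = c(stromal = 50L, immune = 50L),
                           seed = 17L) {
  seeds <- derive_seeds(seed, 5L)
  truth <- gen_compartments(n_genes, planted, n_pairs, skew, sig_sizes,
                            seed = seeds[1L])
  p_prim <- gen_purities(n_primary, purity_alpha, purity_beta,
                         seed = seeds[2L])
  p_met <- gen_purities(n_metastatic, purity_alpha, purity_beta,
                        seed = seeds[3L])
  names(p_prim) <- sprintf("P%03d", seq_len(n_primary))
  names(p_met) <- sprintf("M%03d", seq_len(n_metastatic))
  e_prim <- gen_bulk(truth$tumor_mean, truth$stroma_mean, p_prim,
                     noise_cv, seed = seeds[4L])
  e_met <- gen_bulk(truth$tumor_mean, truth$stroma_mean, p_met,
                    noise_cv, seed = seeds[5L])
  expr <- bulk_matrix(cbind(unclass(e_prim), unclass(e_met)), "tpm")
  metadata <- data.frame(
    sample_id = c(names(p_prim), names(p_met)),
    cohort = rep(c("primary", "metastatic"), c(n_primary, n_metastatic)),
    stringsAsFactors = FALSE)
  purities <- purity_set(c(stats::setNames(as.numeric(p_prim), names(p_prim)),
                           stats::setNames(as.numeric(p_met), names(p_met))),
                         source = "user_supplied")
  list(expr = expr, metadata = metadata, purities = purities, truth = truth,
       params = list(n_primary = n_primary, n_metastatic = n_metastatic,
                     n_genes = n_genes, purity_alpha = purity_alpha,
                     purity_beta = purity_beta, noise_cv = noise_cv,
                     n_pairs = n_pairs, planted = as.list(planted),
                     skew = skew, seed = seed))
}

# Derive k child seeds from one master seed, staying within 32-bit range.
derive_seeds <- function(seed, k) {
  (as.integer(seed) + 1000003L * seq_len(k)) %% 2147483629L
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Writes `expression.tsv`, `metadata.tsv`, `purity.tsv`, `pairs.tsv`,
#' `signatures.gmt` and `truth.json` under `dir`.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(study$expr, file.path(dir, "expression.tsv"))
  write_tsv(study$metadata, file.path(dir, "metadata.tsv"))
  write_tsv(data.frame(sample_id = names(study$purities),
                       purity = as.numeric(study$purities)),
            file.path(dir, "purity.tsv"))
  write_tsv(study$truth$pairs[, c("ligand", "receptor", "planted")],
            file.path(dir, "pairs.tsv"))
  gmt <- vapply(names(study$truth$signatures), function(s) {
    paste(c(s, "synthetic signature",
            study$truth$signatures[[s]]), collapse = "\t")
  }, character(1L))
  writeLines(gmt, file.path(dir, "signatures.gmt"))
  jsonlite::write_json(
    list(tumor_mean = as.list(study$truth$tumor_mean),
         stroma_mean = as.list(study$truth$stroma_mean),
         purities = as.list(stats::setNames(as.numeric(study$purities),
                                            names(study$purities))),
         params = study$params),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
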