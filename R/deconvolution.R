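# Two-compartment mixture deconvolution.
#
# Model: e_bulk_i = p_i * tumor_mean + (1 - p_i) * stroma_mean, with both
# compartment means constant across the samples of a cohort and constrained
# nonnegative. With two coefficients the nonnegative least-squares problem
# has a closed form: the unconstrained normal-equation solution if it is
# feasible, otherwise the better of the two single-coefficient fits on the
# boundary (the objective is convex, so the optimum lies on an active
# constraint whenever the interior solution is infeasible).

# Vectorized NNLS over genes: Y is genes x samples, p the purity vector.
# Returns a list with tumor/stroma estimates and sufficient statistics.
fit_genes_matrix <- function(Y, p) {
  q <- 1 - p
  s11 <- sum(p * p)
  s12 <- sum(p * q)
  s22 <- sum(q * q)
  det <- s11 * s22 - s12 * s12
  if (det <= .Machine$double.eps * s11 * s22) {
    stop("purities carry no contrast (all identical): compartments are ",
         "unidentifiable", call. = FALSE)
  }
  b1 <- as.numeric(Y %*% p)
  b2 <- as.numeric(Y %*% q)
  t_hat <- (s22 * b1 - s12 * b2) / det
  s_hat <- (s11 * b2 - s12 * b1) / det
  infeasible <- which(t_hat < 0 | s_hat < 0)
  if (length(infeasible)) {
    # boundary candidates: one compartment clamped to zero, the other from
    # its 1-D least-squares projection (itself clamped at zero)
    t0 <- pmax(b1[infeasible] / s11, 0)   # stroma = 0
    s0 <- pmax(b2[infeasible] / s22, 0)   # tumor = 0
    # SSE difference up to the common ||y||^2 term
    sse_t0 <- -2 * t0 * b1[infeasible] + t0^2 * s11
    sse_s0 <- -2 * s0 * b2[infeasible] + s0^2 * s22
    use_t0 <- sse_t0 <= sse_s0
    t_hat[infeasible] <- ifelse(use_t0, t0, 0)
    s_hat[infeasible] <- ifelse(use_t0, 0, s0)
  }
  list(tumor = t_hat, stroma = s_hat)
}

#' Fit tumor and stroma compartment means for a single gene
#'
#' Solves min over nonnegative (tumor_mean, stroma_mean) of
#' sum_i (e_bulk_i - p_i * tumor_mean - (1 - p_i) * stroma_mean)^2.
#'
#' @param e_bulk nonnegative numeric vector of bulk expression over samples.
#' @param p numeric vector of tumor purities in \[0, 1\], same length.
#' @return named numeric vector `c(tumor = ..., stroma = ...)`.
#' @export
fit_gene <- function(e_bulk, p) {
  if (length(e_bulk) != length(p)) {
    stop("e_bulk and p must have the same length", call. = FALSE)
  }
  if (length(p) < 2L) {
    stop("need at least 2 samples", call. = FALSE)
  }
  fit <- fit_genes_matrix(matrix(e_bulk, nrow = 1L), p)
  c(tumor = fit$tumor, stroma = fit$stroma)
}

#' Fit compartment means for every gene of a cohort
#'
#' Applies the per-gene nonnegative mixture fit across all genes of a
#' cohort's expression matrix on the linear TPM scale (the mixture is
#' additive in expression, so no log transform is applied here).
#'
#' @param m a `bulk_matrix` with `unit_state = "tpm"`.
#' @param purity a [purity_set()] covering every sample of `m`.
#' @param cohort cohort label recorded in the result (`"primary"`,
#'   `"metastatic"`, or any tag for synthetic cohorts).
#' @return a `compartment_profiles` data frame with columns `gene`,
#'   `tumor_mean`, `stroma_mean`, CI placeholders (`NA` until
#'   [bootstrap_ci()] fills them) and `flag`; attributes `cohort` and
#'   `n_samples`.
#' @export
fit_compartments <- function(m, purity, cohort = "cohort") {
  if (unit_state(m) != "tpm") {
    stop("deconvolution expects linear TPM input, got ", unit_state(m),
         call. = FALSE)
  }
  if (ncol(m) == 0L) stop("no samples in cohort '", cohort, "'", call. = FALSE)
  missing <- setdiff(colnames(m), names(purity))
  if (length(missing)) {
    stop("samples without purity: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- as.numeric(purity[colnames(m)])
  fit <- fit_genes_matrix(unclass(m), p)
  out <- data.frame(gene = rownames(m),
                    tumor_mean = fit$tumor, tumor_lo = NA_real_,
                    tumor_hi = NA_real_,
                    stroma_mean = fit$stroma, stroma_lo = NA_real_,
                    stroma_hi = NA_real_,
                    flag = "ok", stringsAsFactors = FALSE)
  structure(out, cohort = cohort, n_samples = ncol(m),
            class = c("compartment_profiles", "data.frame"))
}

#' Percentile-bootstrap confidence intervals for compartment means
#'
#' Resamples samples (columns) with replacement `B` times, refits every
#' gene on each replicate, and reports the 2.5th and 97.5th percentiles of
#' the replicate estimates as the 95% interval. Replicates whose resampled
#' purities are all identical (unidentifiable design) are skipped and
#' counted; more than 10% skipped is an error.
#'
#' @param m,purity,cohort as in [fit_compartments()].
#' @param B number of bootstrap resamples (default 1000, minimum 100).
#' @param seed integer seed; results are reproducible given `(seed, B)`.
#' @param level confidence level (default 0.95).
#' @return a `compartment_profiles` data frame with CI columns filled and a
#'   `bootstrap` attribute recording `B`, `seed`, and skipped-replicate
#'   count.
#' @export
bootstrap_ci <- function(m, purity, cohort = "cohort", B = 1000L,
                         seed = 17L, level = 0.95) {
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  prof <- fit_compartments(m, purity, cohort)
  p <- as.numeric(purity[colnames(m)])
  Y <- unclass(m)
  n <- ncol(Y)
  G <- nrow(Y)
  boot_t <- matrix(NA_real_, G, B)
  boot_s <- matrix(NA_real_, G, B)
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      pb <- p[idx]
      if (max(pb) - min(pb) < .Machine$double.eps) {
        skipped <- skipped + 1L
        next
      }
      fit <- fit_genes_matrix(Y[, idx, drop = FALSE], pb)
      boot_t[, b] <- fit$tumor
      boot_s[, b] <- fit$stroma
    }
  })
  if (skipped > 0.1 * B) {
    stop(skipped, " of ", B, " bootstrap replicates had unidentifiable ",
         "purity designs (>10%)", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  probs <- c(alpha, 1 - alpha)
  qt <- t(apply(boot_t, 1L, stats::quantile, probs = probs, na.rm = TRUE))
  qs <- t(apply(boot_s, 1L, stats::quantile, probs = probs, na.rm = TRUE))
  prof$tumor_lo <- qt[, 1L]
  prof$tumor_hi <- qt[, 2L]
  prof$stroma_lo <- qs[, 1L]
  prof$stroma_hi <- qs[, 2L]
  attr(prof, "bootstrap") <- list(method = "percentile", B = B, seed = seed,
                                  level = level, skipped = skipped)
  prof
}

#' @export
print.compartment_profiles <- function(x, ...) {
  cat(sprintf("compartment_profiles: %d genes, cohort '%s', n = %d\n",
              nrow(x), attr(x, "cohort"), attr(x, "n_samples")))
  NextMethod()
}

#' Write compartment profiles to TSV with a JSON run-metadata sidecar
#'
#' @param prof a `compartment_profiles` data frame.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @return the TSV path, invisibly.
#' @export
write_profiles <- function(prof, path) {
  write_tsv(as.data.frame(prof), path)
  meta <- list(cohort = attr(prof, "cohort"),
               n_samples = attr(prof, "n_samples"),
               n_genes = nrow(prof),
               bootstrap = attr(prof, "bootstrap"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
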