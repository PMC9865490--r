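#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene symbols.
#' Symbols are uppercased and deduplicated.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(l, 1L, 60L), call. = FALSE)
    }
    unique(norm_symbol(parts[-c(1L, 2L)]))
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  sets
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based per-sample enrichment in the single-sample GSEA style used by
#' purity estimation from stromal/immune signatures. Per sample, genes are
#' ranked ascending by expression (average ranks for ties); walking the
#' list from the highest-expressed gene down, the score is the sum of the
#' difference between the weighted cumulative distribution of in-set genes
#' (weights = rank^`weight_exponent`) and the uniform cumulative
#' distribution of out-of-set genes.
#'
#' Because the statistic depends on expression only through ranks, it is
#' invariant to any strictly monotone transform of a sample's values.
#'
#' @param m a `bulk_matrix` with `unit_state = "log2tpm"`.
#' @param signature character vector of gene symbols (the gene set).
#' @param weight_exponent exponent on the rank weight; default 0.25.
#' @return named numeric vector, one enrichment score per sample.
#' @export
ssgsea_score <- function(m, signature, weight_exponent = 0.25) {
  if (unit_state(m) != "log2tpm") {
    stop("ssgsea_score expects log2-transformed TPM input", call. = FALSE)
  }
  if (nrow(m) < 2L) {
    stop("ranking degenerate: need at least 2 genes", call. = FALSE)
  }
  sig <- unique(norm_symbol(signature))
  in_set <- rownames(m) %in% sig
  if (!any(in_set)) {
    stop("no signature genes present in the expression matrix",
         call. = FALSE)
  }
  n_out <- sum(!in_set)
  vals <- unclass(m)
  scores <- vapply(seq_len(ncol(vals)), function(j) {
    r <- rank(vals[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    w <- ifelse(in_set, r^weight_exponent, 0)[ord]
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!in_set[ord]) / n_out
    sum(p_in - p_out)
  }, numeric(1L))
  stats::setNames(scores, colnames(vals))
}

#' Combine stromal and immune scores into an overall score
#'
#' The combined score (stromal + immune, elementwise over a shared sample
#' set) is the quantity converted downstream to a tumor-purity estimate.
#'
#' @param stromal,immune named numeric vectors over identical sample sets.
#' @return named numeric vector of combined scores.
#' @export
estimate_score <- function(stromal, immune) {
  if (is.null(names(stromal)) || is.null(names(immune)) ||
      !setequal(names(stromal), names(immune)) ||
      length(stromal) != length(immune)) {
    stop("stromal and immune scores must cover identical sample sets",
         call. = FALSE)
  }
  stromal + immune[names(stromal)]
}

# Registry of score -> purity conversions. The cosine conversion with its
# two published constants is the default; the constants are calibration
# parameters carried in configuration, external to this package's model.
purity_conversions <- list(
  cosine = function(s, constants = c(a = 0.6049872018, b = 0.0001467884)) {
    arg <- constants[["a"]] + constants[["b"]] * s
    # cos() is decreasing only on [0, pi]; clamping the argument keeps the
    # conversion monotonically non-increasing in the score everywhere.
    cos(clamp(arg, 0, pi))
  },
  complement = function(s, constants = NULL) 1 - s
)

#' Convert combined stromal/immune scores to tumor purity estimates
#'
#' The default `"cosine"` conversion is the published calibration
#' purity = cos(a + b * score); `"complement"` (purity = 1 - score) is a
#' simple stub for testing. Raw conversions falling outside (0, 1) are
#' clamped into \[0.01, 0.99\] with a warning: the clamp keeps both columns
#' of the downstream deconvolution design informative.
#'
#' @param scores named numeric vector of combined scores.
#' @param conversion name of a registered conversion, or a function of the
#'   score vector.
#' @param constants optional named constants passed to the conversion.
#' @return a [purity_set()] with `source = "estimated"`.
#' @export
scores_to_purity <- function(scores, conversion = "cosine", constants = NULL) {
  fn <- if (is.function(conversion)) {
    conversion
  } else {
    if (!conversion %in% names(purity_conversions)) {
      stop("unknown purity conversion: ", conversion, call. = FALSE)
    }
    purity_conversions[[conversion]]
  }
  raw <- if (is.null(constants)) fn(scores) else fn(scores, constants)
  out_of_range <- raw < 0.01 | raw > 0.99
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " purity value(s) clamped into [0.01, 0.99]", call. = FALSE)
  }
  purity_set(stats::setNames(clamp(raw, 0.01, 0.99), names(scores)),
             source = "estimated")
}

#' Construct a per-sample tumor purity set
#'
#' @param p named numeric vector of purities in \[0, 1\]; `1 - p` is the
#'   stromal fraction used by deconvolution.
#' @param source `"estimated"` or `"user_supplied"`.
#' @return a `purity_set` (named numeric vector with a `source` attribute).
#' @export
purity_set <- function(p, source = c("estimated", "user_supplied")) {
  source <- match.arg(source)
  if (is.null(names(p)) || anyDuplicated(names(p))) {
    stop("purities must be named by unique sample ids", call. = FALSE)
  }
  bad <- names(p)[!is.finite(p) | p < 0 | p > 1]
  if (length(bad)) {
    stop("purity outside [0, 1] for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(as.numeric(stats::setNames(p, names(p))), names = names(p),
            source = source, class = "purity_set")
}

#' @export
print.purity_set <- function(x, ...) {
  cat(sprintf("purity_set: %d samples (%s), range [%.3f, %.3f]\n",
              length(x), attr(x, "source"), min(x), max(x)))
  invisible(x)
}

#' Read user-supplied purities from a two-column TSV
#'
#' @param path TSV with columns (sample_id, purity).
#' @return a [purity_set()] with `source = "user_supplied"`.
#' @export
read_purity <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L) stop("purity file needs two columns", call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicated sample row(s) in purity file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  purity_set(stats::setNames(as.numeric(df[[2L]]), ids),
             source = "user_supplied")
}

#' Estimate tumor purity from a TPM expression matrix
#'
#' Convenience wrapper: log2-transforms the matrix, scores the stromal and
#' immune signatures per sample, combines them, and converts the combined
#' score to purity. Purity estimation is pluggable: any `purity_set`
#' (e.g. from [read_purity()]) can be fed to the deconvolution instead.
#'
#' @param m a `bulk_matrix` with `unit_state = "tpm"` (or `"log2tpm"`).
#' @param stromal_genes,immune_genes character vectors of signature genes.
#' @param conversion,constants passed to [scores_to_purity()].
#' @param weight_exponent passed to [ssgsea_score()].
#' @return a [purity_set()].
#' @export
estimate_purity <- function(m, stromal_genes, immune_genes,
                            conversion = "cosine", constants = NULL,
                            weight_exponent = 0.25) {
  if (unit_state(m) == "tpm") m <- log2_transform(m)
  stromal <- ssgsea_score(m, stromal_genes, weight_exponent)
  immune <- ssgsea_score(m, immune_genes, weight_exponent)
  scores_to_purity(estimate_score(stromal, immune),
                   conversion = conversion, constants = constants)
}
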