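#' Construct a bulk expression matrix
#'
#' A `bulk_matrix` is a nonnegative numeric gene-by-sample matrix carrying a
#' `unit_state` attribute that records where it sits in the normalization
#' chain: raw `counts`, linear `tpm`, or `log2tpm` (log2(TPM + 1), used only
#' as input to purity estimation).
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers).
#' @param unit_state one of `"counts"`, `"tpm"`, `"log2tpm"`.
#' @return a `bulk_matrix` object.
#' @export
bulk_matrix <- function(values, unit_state = c("counts", "tpm", "log2tpm")) {
  unit_state <- match.arg(unit_state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames", call. = FALSE)
  }
  rownames(values) <- norm_symbol(rownames(values))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("expression values must be nonnegative and non-missing",
         call. = FALSE)
  }
  structure(values, unit_state = unit_state,
            class = c("bulk_matrix", class(values)))
}

#' @export
print.bulk_matrix <- function(x, ...) {
  cat(sprintf("bulk_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), unit_state(x)))
  invisible(x)
}

#' Unit state of a bulk expression matrix
#' @param m a `bulk_matrix`.
#' @return `"counts"`, `"tpm"` or `"log2tpm"`.
#' @export
unit_state <- function(m) attr(m, "unit_state") %||% "counts"

# Subset while preserving class/attributes (drop never collapses dims).
#' @export
`[.bulk_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  structure(out, unit_state = attr(x, "unit_state"), class = class(x))
}

#' Read a gene-by-sample expression matrix from a TSV file
#'
#' The first column holds gene identifiers and the header row sample
#' identifiers. Gene symbols are uppercased and stripped; duplicate gene
#' rows (as occur in Firehose RSEM exports) are collapsed by keeping the row
#' with the highest total signal, with a message per collapsed symbol.
#'
#' @param path path to a tab-separated file.
#' @param unit_state unit state of the stored values (default `"counts"`).
#' @return a [bulk_matrix()].
#' @export
read_expression <- function(path, unit_state = c("counts", "tpm", "log2tpm")) {
  unit_state <- match.arg(unit_state)
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L) {
    stop("malformed expression file (need gene column + >=1 sample): ", path,
         call. = FALSE)
  }
  if (anyDuplicated(names(df)[-1L])) {
    stop("duplicate sample identifiers in header of ", path, call. = FALSE)
  }
  genes <- norm_symbol(as.character(df[[1L]]))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    stop("non-numeric expression values in ", path, call. = FALSE)
  }
  if (anyNA(vals) || any(vals < 0)) {
    stop("negative or missing expression values in ", path, call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    keep <- rep(TRUE, length(genes))
    totals <- rowSums(vals)
    for (g in unique(genes[duplicated(genes)])) {
      idx <- which(genes == g)
      best <- idx[which.max(totals[idx])]
      drop_idx <- setdiff(idx, best)
      keep[drop_idx] <- FALSE
      message("collapsing duplicate gene ", g, ": kept row with total ",
              format(totals[best]), ", dropped ", length(drop_idx), " row(s)")
    }
    genes <- genes[keep]
    vals <- vals[keep, , drop = FALSE]
  }
  rownames(vals) <- genes
  bulk_matrix(vals, unit_state)
}

#' Write an expression matrix to TSV
#' @param m a `bulk_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), as.data.frame(unclass(m)[, , drop = FALSE]),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Normalize counts to transcripts per million
#'
#' Standard TPM: each gene's count is divided by its length in kilobases,
#' then every sample column is scaled so the rates sum to one million.
#' Applying it to an already-TPM matrix performs the column rescale only
#' (a no-op up to floating tolerance), so the operation is idempotent in
#' effect.
#'
#' @param m a `bulk_matrix` with `unit_state` `"counts"` or `"tpm"`.
#' @param gene_lengths_kb named numeric vector of gene lengths in kilobases;
#'   required when `unit_state` is `"counts"`.
#' @return a `bulk_matrix` with `unit_state = "tpm"`, columns summing to 1e6.
#' @export
tpm_normalize <- function(m, gene_lengths_kb = NULL) {
  us <- unit_state(m)
  vals <- unclass(m)
  if (us == "counts") {
    if (is.null(gene_lengths_kb)) {
      stop("gene_lengths_kb required to TPM-normalize counts", call. = FALSE)
    }
    missing <- setdiff(rownames(vals), names(gene_lengths_kb))
    if (length(missing)) {
      stop("missing gene lengths for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    len <- gene_lengths_kb[rownames(vals)]
    if (any(!is.finite(len)) || any(len <= 0)) {
      stop("gene lengths must be positive and finite", call. = FALSE)
    }
    vals <- vals / len
  } else if (us != "tpm") {
    stop("tpm_normalize expects counts or tpm input, got ", us, call. = FALSE)
  }
  colsum <- colSums(vals)
  zero <- colnames(vals)[colsum == 0]
  if (length(zero)) {
    stop("all-zero sample column(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  vals <- sweep(vals, 2L, colsum, "/") * 1e6
  bulk_matrix(vals, "tpm")
}

#' Log2-transform a TPM matrix
#'
#' Replaces values with log2(x + 1) (pseudocount 1). Used only to prepare
#' input for rank-based purity estimation; deconvolution operates on the
#' linear TPM scale where the compartment mixture is additive.
#'
#' @param m a `bulk_matrix` with `unit_state = "tpm"`.
#' @return a `bulk_matrix` with `unit_state = "log2tpm"`.
#' @export
log2_transform <- function(m) {
  if (unit_state(m) != "tpm") {
    stop("log2_transform expects unit_state 'tpm', got ", unit_state(m),
         call. = FALSE)
  }
  bulk_matrix(log2(unclass(m) + 1), "log2tpm")
}

#' Split an expression matrix into primary and metastatic cohorts
#'
#' @param m a `bulk_matrix`.
#' @param metadata either a data frame with columns `sample_id` and `cohort`,
#'   or a named character vector mapping sample id to `"primary"` /
#'   `"metastatic"`.
#' @return named list with elements `primary` and `metastatic`, column-
#'   disjoint submatrices partitioning the samples of `m`. An empty cohort
#'   is returned as a zero-column matrix with a warning.
#' @export
split_cohorts <- function(m, metadata) {
  if (is.data.frame(metadata)) {
    if (!all(c("sample_id", "cohort") %in% names(metadata))) {
      stop("metadata needs columns sample_id and cohort", call. = FALSE)
    }
    labels <- stats::setNames(as.character(metadata$cohort),
                              as.character(metadata$sample_id))
  } else {
    labels <- metadata
  }
  bad <- setdiff(unique(labels), c("primary", "metastatic"))
  if (length(bad)) {
    stop("unknown cohort label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(colnames(m), names(labels))
  if (length(missing)) {
    stop("samples missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(c(primary = "primary", metastatic = "metastatic"), function(lab) {
    keep <- colnames(m)[labels[colnames(m)] == lab]
    m[, keep, drop = FALSE]
  })
  for (lab in names(out)) {
    if (ncol(out[[lab]]) == 0L) {
      warning("cohort '", lab, "' is empty", call. = FALSE)
    }
  }
  out
}

#' Derive cohort labels from TCGA sample barcodes
#'
#' TCGA barcodes carry a two-digit sample-type code in their fourth field
#' (e.g. `TCGA-XX-YYYY-01A`); by TCGA convention 01 is a primary solid tumor
#' and 06 a metastasis. The code-to-label map is an argument, not a
#' constant, because the convention is a property of the data source.
#'
#' @param sample_ids character vector of TCGA-style barcodes.
#' @param codes named character vector mapping cohort label to two-digit code.
#' @return named character vector of cohort labels; barcodes with a code not
#'   in `codes` map to `NA`.
#' @export
tcga_cohort_labels <- function(sample_ids,
                               codes = c(primary = "01", metastatic = "06")) {
  field4 <- vapply(strsplit(sample_ids, "-", fixed = TRUE), function(p) {
    if (length(p) >= 4L) substr(p[[4L]], 1L, 2L) else NA_character_
  }, character(1L))
  rev_map <- stats::setNames(names(codes), codes)
  stats::setNames(unname(rev_map[field4]), sample_ids)
}

#' Read a gene-length table
#' @param path TSV with columns (gene symbol, length in kilobases).
#' @return named numeric vector of lengths in kilobases.
#' @export
read_gene_lengths <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L) stop("gene-length file needs two columns", call. = FALSE)
  stats::setNames(as.numeric(df[[2L]]), norm_symbol(as.character(df[[1L]])))
}
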