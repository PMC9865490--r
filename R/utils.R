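# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so package functions never perturb it.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Read a TSV tolerating quoted fields and CRLF line endings.
read_tsv_strict <- function(path, header = TRUE, ...) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, header = header, sep = "\t", quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Gene symbols are matched on uppercased, whitespace-stripped text so that
# pair tables and signature sets from different sources agree.
norm_symbol <- function(x) toupper(trimws(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
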