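make_log2_matrix <- function(vals) {
  bulk_matrix(vals, "log2tpm")
}

test_that("enrichment score matches a brute-force running-sum oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 6L
    vals <- matrix(rexp(n * 3), n, 3,
                   dimnames = list(sprintf("G%d", 1:n), c("A", "B", "C")))
    m <- make_log2_matrix(vals)
    sig <- c("G2", "G5")
    in_set <- rownames(m) %in% sig
    for (expo in c(0, 0.25)) {
      got <- ssgsea_score(m, sig, weight_exponent = expo)
      want <- vapply(1:3, function(j) brute_enrichment(vals[, j], in_set, expo),
                     numeric(1))
      expect_equal(unname(got), want, tolerance = 1e-12)
    }
  }
})

test_that("signature genes at the top rank score higher than at the bottom", {
  genes <- sprintf("G%02d", 1:20)
  top <- matrix(20:1, 20, 1, dimnames = list(genes, "S"))
  bottom <- matrix(1:20, 20, 1, dimnames = list(genes, "S"))
  sig <- genes[1:4]
  s_top <- ssgsea_score(make_log2_matrix(top), sig)
  s_bottom <- ssgsea_score(make_log2_matrix(bottom), sig)
  expect_gt(s_top, s_bottom)
})

test_that("scores are rank-based: monotone transforms and sample order", {
  set.seed(7)
  vals <- matrix(rexp(40), 10, 4,
                 dimnames = list(sprintf("G%d", 1:10), sprintf("S%d", 1:4)))
  sig <- c("G1", "G7", "G9")
  base <- ssgsea_score(make_log2_matrix(vals), sig)
  # strictly monotone transform of each sample leaves scores unchanged
  warped <- ssgsea_score(make_log2_matrix(sqrt(vals) + 0.3), sig)
  expect_equal(base, warped)
  # permuting sample order permutes but does not change per-sample scores
  perm <- c(3, 1, 4, 2)
  shuffled <- ssgsea_score(make_log2_matrix(vals[, perm]), sig)
  expect_equal(shuffled, base[perm])
})

test_that("enrichment scoring rejects degenerate inputs", {
  vals <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  expect_error(ssgsea_score(make_log2_matrix(vals), "ZZZ"), "no signature")
  one <- matrix(1:2, 1, 2, dimnames = list("A", c("S1", "S2")))
  expect_error(ssgsea_score(make_log2_matrix(one), "A"), "2 genes")
  tpm <- bulk_matrix(vals, "tpm")
  expect_error(ssgsea_score(tpm, "A"), "log2")
})

test_that("combined score is the elementwise stromal + immune sum", {
  expect_equal(unname(estimate_score(c(S1 = 2), c(S1 = 3))), 5)
  s <- c(A = 0, B = 0); i <- c(B = 1.5, A = 2.5)
  expect_equal(estimate_score(s, i), c(A = 2.5, B = 1.5))
  expect_error(estimate_score(c(S1 = 1), c(S2 = 1)), "identical sample sets")
})

test_that("score-to-purity conversion is monotone, clamped and pluggable", {
  # stub conversion: purity = 1 - score
  p <- scores_to_purity(c(S1 = 0.3), conversion = "complement")
  expect_equal(unname(as.numeric(p)), 0.7)
  expect_equal(attr(p, "source"), "estimated")

  # default cosine conversion: non-increasing in score
  scores <- c(A = -2000, B = 0, C = 1500, D = 4000)
  pc <- as.numeric(scores_to_purity(scores))
  expect_true(all(diff(pc) <= 1e-12))

  # raw conversion below zero clamps to 0.01 with a warning;
  # oracle: evaluate the formula directly at that score
  s_big <- (pi / 2 - 0.6049872018) / 0.0001467884 + 1000
  raw <- cos(0.6049872018 + 0.0001467884 * s_big)
  expect_lt(raw, 0)
  expect_warning(pl <- scores_to_purity(c(S = s_big)), "clamped")
  expect_equal(unname(as.numeric(pl)), 0.01)

  expect_error(scores_to_purity(c(S = 1), conversion = "nope"),
               "unknown purity conversion")
})

test_that("user purity files validate ranges and duplicates", {
  ok <- write_expr_fixture(data.frame(sample_id = c("S1", "S2"),
                                      purity = c(0.8, 0.35)))
  p <- read_purity(ok)
  expect_length(p, 2L)
  expect_equal(attr(p, "source"), "user_supplied")

  bad <- write_expr_fixture(data.frame(sample_id = "S1", purity = 1.2))
  expect_error(read_purity(bad), "S1")
  dup <- write_expr_fixture(data.frame(sample_id = c("S1", "S1"),
                                       purity = c(0.5, 0.6)))
  expect_error(read_purity(dup), "duplicated")
})

test_that("GMT files parse into deduplicated uppercase sets", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("stromal\tdesc\tcol1a1\tCOL1A1\tDCN",
               "immune\tdesc\tPTPRC\tCD3E"), path)
  sets <- read_gmt(path)
  expect_equal(sets$stromal, c("COL1A1", "DCN"))
  expect_equal(sets$immune, c("PTPRC", "CD3E"))
})

test_that("spiking stromal signature genes decreases estimated purity", {
  set.seed(11)
  genes <- sprintf("G%03d", 1:200)
  stromal <- genes[1:20]; immune <- genes[21:40]
  base_vals <- matrix(rlnorm(200 * 2, 3, 1), 200, 2,
                      dimnames = list(genes, c("LOW", "HIGH")))
  # HIGH sample gets its stromal+immune signature genes spiked upward
  base_vals[c(stromal, immune), "HIGH"] <-
    base_vals[c(stromal, immune), "HIGH"] * 50
  p <- estimate_purity(bulk_matrix(base_vals, "tpm"), stromal, immune)
  expect_lt(p[["HIGH"]], p[["LOW"]])
})

test_that("estimated purity tracks generator truth (Spearman > 0.8)", {
  sim <- simulate_cohort(n_genes = 1000, n_samples = 80, noise_cv = 0.2,
                         n_pairs = 40,
                         planted = c(TT = 5, TS = 5, ST = 5, SS = 5),
                         seed = 101)
  est <- estimate_purity(sim$expr, sim$truth$signatures$stromal,
                         sim$truth$signatures$immune)
  rho <- cor(as.numeric(est[names(sim$purities)]),
             as.numeric(sim$purities), method = "spearman")
  expect_gt(rho, 0.8)
})
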