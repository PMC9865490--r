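make_profiles <- function(genes, tumor, stroma, cohort = "primary",
                          flag = "ok") {
  structure(data.frame(gene = genes, tumor_mean = tumor,
                       tumor_lo = NA_real_, tumor_hi = NA_real_,
                       stroma_mean = stroma, stroma_lo = NA_real_,
                       stroma_hi = NA_real_, flag = flag,
                       stringsAsFactors = FALSE),
            cohort = cohort, n_samples = 10L,
            class = c("compartment_profiles", "data.frame"))
}

test_that("pair tables load with dedup, case-folding and validation", {
  path <- write_expr_fixture(data.frame(
    ligand = c("tgfb1", "WNT1", "TGFB1"),
    receptor = c("tgfbr2", "FZD9", "TGFBR2")))
  pairs <- suppressMessages(read_pairs(path))
  expect_equal(nrow(pairs), 2L)
  expect_equal(pairs$ligand[1], "TGFB1")
  expect_equal(pairs$receptor[1], "TGFBR2")
  expect_false(any(pairs$self_pair))

  empty <- write_expr_fixture(data.frame(ligand = character(),
                                         receptor = character()))
  expect_error(suppressMessages(read_pairs(empty)), "empty")
  holed <- tempfile(fileext = ".tsv")
  writeLines(c("ligand\treceptor", "A\tB", "C\t"), holed)
  expect_error(suppressMessages(read_pairs(holed)), "line")
})

test_that("RC quadruple matches the four-term mass-action formula", {
  sc <- rc_scores(6, 2, 1, 3)
  # oracle: denominator 6*3 + 6*1 + 2*3 + 2*1 = 32, evaluated longhand
  expect_equal(sc$rc_ts, 18 / 32)
  expect_equal(sc$rc_tt, 6 / 32)
  expect_equal(sc$rc_ss, 6 / 32)
  expect_equal(sc$rc_st, 2 / 32)
  expect_equal(sc$rc_tt + sc$rc_ts + sc$rc_st + sc$rc_ss, 1,
               tolerance = 1e-12)
  # cross-check against the factorization (6/8)*(3/4)
  expect_equal(sc$rc_ts, (6 / 8) * (3 / 4), tolerance = 1e-12)
  expect_equal(sc$ligand_tumor_frac, 6 / 8)
  expect_equal(sc$receptor_tumor_frac, 1 / 4)
})

test_that("RC extremes and symmetric inputs behave as expected", {
  # tumor-exclusive ligand, stroma-exclusive receptor: pure TS signal
  sc <- rc_scores(5, 0, 0, 2)
  expect_equal(sc$rc_ts, 1)
  expect_equal(sc$rc_tt + sc$rc_st + sc$rc_ss, 0)
  # full symmetry: all scores 0.25
  sc2 <- rc_scores(3, 3, 7, 7)
  expect_equal(as.numeric(sc2[1, c("rc_tt", "rc_ts", "rc_st", "rc_ss")]),
               rep(0.25, 4))
  # vanishing ligand total: undefined, not zero
  sc3 <- rc_scores(0, 0, 1, 1)
  expect_false(sc3$defined)
  expect_true(is.na(sc3$rc_tt))
  expect_error(rc_scores(-1, 1, 1, 1), "nonnegative")
})

test_that("RC identities hold on random inputs", {
  set.seed(77)
  n <- 500L
  lt <- rexp(n); ls <- rexp(n); rt <- rexp(n); rs <- rexp(n)
  sc <- rc_scores(lt, ls, rt, rs)
  quad_sum <- sc$rc_tt + sc$rc_ts + sc$rc_st + sc$rc_ss
  expect_lt(max(abs(quad_sum - 1)), 1e-12)
  # factorization identity
  fact_ts <- (lt / (lt + ls)) * (rs / (rt + rs))
  expect_lt(max(abs(sc$rc_ts - fact_ts)), 1e-12)
  # dissociation-constant independence: per-gene rescaling cancels
  a <- rexp(n) + 0.1; b <- rexp(n) + 0.1
  sc_scaled <- rc_scores(a * lt, a * ls, b * rt, b * rs)
  expect_equal(sc_scaled$rc_ts, sc$rc_ts, tolerance = 1e-12)
  expect_equal(sc_scaled$rc_ss, sc$rc_ss, tolerance = 1e-12)
  # swapping tumor and stroma compartments swaps tt<->ss and ts<->st
  sw <- rc_scores(ls, lt, rs, rt)
  expect_equal(sw$rc_tt, sc$rc_ss, tolerance = 1e-12)
  expect_equal(sw$rc_ts, sc$rc_st, tolerance = 1e-12)
})

test_that("scoring all pairs yields one row per pair per cohort with skips", {
  genes <- c("L1", "R1", "L2", "R2", "L3", "R3", "L4", "R4", "L5", "R5")
  prof_p <- make_profiles(genes, tumor = 1:10, stroma = 10:1)
  prof_m <- make_profiles(genes, tumor = 2 * (1:10), stroma = rep(3, 10),
                          cohort = "metastatic")
  pairs <- data.frame(ligand = paste0("L", 1:5),
                      receptor = paste0("R", 1:5))
  res <- score_crosstalk(pairs, prof_p, prof_m)
  expect_equal(nrow(res), 10L)
  expect_equal(nrow(attr(res, "skips")), 0L)

  # absent receptor and unidentifiable ligand are skipped with reasons
  pairs2 <- rbind(pairs, data.frame(ligand = "L1", receptor = "MISSING"))
  prof_p2 <- prof_p
  prof_p2$flag[prof_p2$gene == "L2"] <- "unidentifiable"
  res2 <- score_crosstalk(pairs2, prof_p2, prof_m)
  skips <- attr(res2, "skips")
  expect_true(any(skips$reason == "absent"))
  expect_true(any(skips$reason == "unidentifiable" &
                    skips$ligand == "L2"))
  expect_false(any(res2$ligand == "L2" & res2$cohort == "primary"))
})

test_that("direction rankings sort, break ties and warn when short", {
  pairs <- data.frame(ligand = c("B", "A", "C"),
                      receptor = c("R1", "R2", "R3"))
  mk <- function(cohort, ts_scores) {
    data.frame(ligand = pairs$ligand, receptor = pairs$receptor,
               cohort = cohort, rc_tt = (1 - ts_scores) / 3,
               rc_ts = ts_scores, rc_st = (1 - ts_scores) / 3,
               rc_ss = (1 - ts_scores) / 3,
               ligand_tumor_frac = 0.5, receptor_tumor_frac = 0.5,
               defined = TRUE, stringsAsFactors = FALSE)
  }
  res <- rbind(mk("primary", c(0.9, 0.5, 0.1)),
               mk("metastatic", c(0.9, 0.5, 0.1)))
  top2 <- rank_direction(res, "TS", k = 2)
  expect_equal(top2$ligand, c("B", "A"))
  expect_equal(top2$primary_pct, c(90, 50))
  expect_true(top2$decisive_primary[1])
  expect_false(top2$decisive_primary[2])

  # identical keys: alphabetical by ligand
  res_tie <- rbind(mk("primary", c(0.4, 0.4, 0.4)),
                   mk("metastatic", c(0.4, 0.4, 0.4)))
  t3 <- rank_direction(res_tie, "TS", k = 3)
  expect_equal(t3$ligand, c("A", "B", "C"))

  expect_warning(rank_direction(res, "TS", k = 15), "3 defined")
})

test_that("ranking keys pool cohorts as configured", {
  mk1 <- function(cohort, sc) data.frame(
    ligand = "L", receptor = "R", cohort = cohort,
    rc_tt = 1 - sc, rc_ts = sc, rc_st = 0, rc_ss = 0,
    ligand_tumor_frac = 0.5, receptor_tumor_frac = 0.5, defined = TRUE)
  res <- rbind(mk1("primary", 0.2), mk1("metastatic", 0.8))
  expect_equal(rank_direction(res, "TS", k = 1)$rank_key, 0.8)
  expect_equal(rank_direction(res, "TS", k = 1,
                              key = "mean_over_cohorts")$rank_key, 0.5)
  expect_equal(rank_direction(res, "TS", k = 1,
                              key = "primary_only")$rank_key, 0.2)
})

test_that("planted directional signals dominate their recovered direction", {
  study <- simulate_study(n_primary = 60, n_metastatic = 60,
                          n_genes = 600, n_pairs = 40,
                          planted = c(TT = 5, TS = 5, ST = 5, SS = 5),
                          sig_sizes = c(stromal = 10, immune = 10),
                          noise_cv = 0.2, seed = 21)
  cohorts <- split_cohorts(study$expr, study$metadata)
  prof_p <- fit_compartments(cohorts$primary, study$purities, "primary")
  prof_m <- fit_compartments(cohorts$metastatic, study$purities,
                             "metastatic")
  res <- score_crosstalk(study$truth$pairs, prof_p, prof_m)
  # a planted TS pair's maximal recovered direction is TS
  ts_pairs <- study$truth$pairs[study$truth$pairs$planted == "TS", ]
  sub <- res[res$ligand %in% ts_pairs$ligand & res$cohort == "primary", ]
  maxdir <- apply(sub[, c("rc_tt", "rc_ts", "rc_st", "rc_ss")], 1,
                  which.max)
  expect_true(all(maxdir == 2))
})
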