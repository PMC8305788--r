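ranked_universe <- function(n) {
  tibble::tibble(gene = sprintf("g%04d", 1:n), rank = 1:n)
}

test_that("ks enrichment separates top-loaded from uniformly spread targets", {
  ranked <- ranked_universe(1000)
  top <- ks_enrichment(ranked, ranked$gene[1:10])
  expect_lt(top$p, 0.001)
  expect_equal(top$n_targets_in_universe, 10)

  spread <- ks_enrichment(ranked, ranked$gene[seq(100, 1000, by = 100)])
  expect_gt(spread$p, 0.5)

  expect_error(ks_enrichment(ranked, c("absent1", "absent2")), "untestable")
  expect_error(ks_enrichment(ranked, ranked$gene), "untestable")
})

test_that("ks statistic equals the brute-force ECDF gap oracle", {
  ranked <- ranked_universe(500)
  tg <- ranked$gene[c(1, 2, 3, 50, 400)]
  got <- ks_enrichment(ranked, tg)
  hit <- ranked$gene %in% tg
  expect_equal(got$ks_statistic,
               oracle_ks_dplus(ranked$rank[hit], ranked$rank[!hit]),
               tolerance = 1e-12)

  withr::with_seed(31, {
    for (i in 1:30) {
      n <- sample(20:200, 1)
      ranked <- ranked_universe(n)
      m <- sample(seq_len(n - 1), 1)
      tg <- sample(ranked$gene, m)
      hit <- ranked$gene %in% tg
      got <- ks_enrichment(ranked, tg)
      expect_equal(got$ks_statistic,
                   oracle_ks_dplus(ranked$rank[hit], ranked$rank[!hit]),
                   tolerance = 1e-12)
      # cross-check against the standard one-sided two-sample KS statistic
      ref <- suppressWarnings(stats::ks.test(ranked$rank[hit],
                                             ranked$rank[!hit],
                                             alternative = "greater"))
      expect_equal(got$ks_statistic, unname(ref$statistic), tolerance = 1e-12)
    }
  })
})

test_that("ks p is permutation-invariant for non-targets and monotone in target rank", {
  ranked <- ranked_universe(100)
  tg <- ranked$gene[c(5, 30, 70)]
  base <- ks_enrichment(ranked, tg)
  # shuffling non-targets among themselves preserves target rank positions
  withr::with_seed(41, {
    others <- setdiff(ranked$gene, tg)
    shuffled <- ranked
    shuffled$gene[!(ranked$gene %in% tg)] <- sample(others)
    expect_equal(ks_enrichment(shuffled, tg)$p, base$p)
  })
  # moving one target strictly up never increases the one-sided p
  up <- ranked
  up$gene[c(2, 30)] <- up$gene[c(30, 2)] # target at 30 moves to rank 2
  expect_lte(ks_enrichment(up, tg)$p, base$p)
})

test_that("recommend_drugs orders by p with id tie-break and keeps untestable drugs", {
  ranked <- ranked_universe(50)
  catalog <- tibble::tibble(
    drug_id = c(rep("top", 3), rep("zz_dup", 3), rep("aa_dup", 3),
                rep("lost", 2)),
    gene = c(ranked$gene[1:3], ranked$gene[c(10, 20, 30)],
             ranked$gene[c(10, 20, 30)], "absent1", "absent2")
  )
  rec <- recommend_drugs(ranked, catalog, alpha = 0.05)
  expect_equal(rec$drug_id[1], "top")
  expect_true(rec$suitable[1])
  # identical target sets: identical p, ordered by drug id
  dup <- rec[rec$drug_id %in% c("aa_dup", "zz_dup"), ]
  expect_equal(dup$p[1], dup$p[2])
  expect_equal(dup$drug_id, c("aa_dup", "zz_dup"))
  # untestable listed last, not dropped
  expect_equal(rec$drug_id[4], "lost")
  expect_false(rec$testable[4])

  expect_warning(empty <- recommend_drugs(ranked, catalog[0, ]), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("best treatment effect is the minimum p over administered drugs", {
  rec <- tibble::tibble(
    drug_id = c("a", "b", "c"), ks_statistic = 0.5,
    p = c(0.3, 0.01, 0.2), n_targets_in_universe = 3L,
    suitable = FALSE, testable = TRUE
  )
  expect_equal(best_treatment_effect(rec, c("a", "b")), 0.01)
  expect_equal(best_treatment_effect(rec, "c"), 0.2)
  rec$testable[3] <- FALSE
  expect_message(out <- best_treatment_effect(rec, "c"), "excluded")
  expect_true(is.na(out))
})

test_that("median split assigns strictly-below-median effects to properly treated", {
  eff <- tibble::tibble(sample_id = sprintf("p%d", 1:4),
                        effect_p = c(0.01, 0.2, 0.5, 0.9))
  sp <- split_treated_groups(eff)
  expect_equal(as.character(sp$group), c("properly", "properly",
                                         "improperly", "improperly"))
  # odd n: only the value below the median is properly treated
  odd <- split_treated_groups(tibble::tibble(
    sample_id = c("a", "b", "c"), effect_p = c(0.1, 0.2, 0.3)
  ))
  expect_equal(as.character(odd$group), c("properly", "improperly",
                                          "improperly"))
  # degenerate all-equal effects
  expect_warning(
    allsame <- split_treated_groups(tibble::tibble(
      sample_id = c("a", "b"), effect_p = c(0.5, 0.5)
    )),
    "degenerate"
  )
  expect_true(all(allsame$group == "improperly"))
})

test_that("survival comparison recovers a known hazard ratio and flags null cases", {
  ss <- simulate_survival_split(n_per_arm = 500, hazard_ratio = 2, seed = 11)
  sc <- survival_compare(ss$clinical, ss$groups)
  expect_gt(sc$hazard_ratio, 1.7)
  expect_lt(sc$hazard_ratio, 2.3)
  expect_lt(sc$logrank_p, 0.001)
  expect_true(sc$hr_ci95[1] <= sc$hazard_ratio &&
              sc$hazard_ratio <= sc$hr_ci95[2])

  # two identical groups: HR ~ 1, log-rank p ~ 1
  days <- rep(c(100, 200, 300, 400, 500, 600, 700, 800), 2)
  clin <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:16), survival_days = days,
    vital_status = "dead", er = NA_character_, pr = NA_character_,
    her2 = NA_character_
  )
  groups <- tibble::tibble(
    sample_id = clin$sample_id,
    group = factor(rep(c("properly", "improperly"), each = 8),
                   levels = c("properly", "improperly"))
  )
  eq <- survival_compare(clin, groups)
  expect_equal(eq$hazard_ratio, 1, tolerance = 0.1)
  expect_gt(eq$logrank_p, 0.9)

  # a group with zero events is an error
  clin2 <- clin
  clin2$vital_status[1:8] <- "alive"
  expect_error(survival_compare(clin2, groups), "zero events")
})

test_that("log-rank statistic reduces to the 2x2 hypergeometric form with one event time", {
  # all events at one time: chisq = (O - E)^2 / V with hypergeometric E, V
  clin <- tibble::tibble(
    sample_id = sprintf("s%d", 1:10),
    survival_days = c(rep(100, 4), rep(500, 6)),
    vital_status = c(rep("dead", 4), rep("alive", 6)),
    er = NA_character_, pr = NA_character_, her2 = NA_character_
  )
  groups <- tibble::tibble(
    sample_id = clin$sample_id,
    group = factor(c("properly", "properly", "improperly", "improperly",
                     rep(c("properly", "improperly"), 3)),
                   levels = c("properly", "improperly"))
  )
  # add one late event per arm so both arms have events at distinct times
  clin$vital_status[5:6] <- "dead"
  sc <- survival_compare(clin, groups)
  # independent computation via the counting formula
  ref <- survival::survdiff(
    survival::Surv(clin$survival_days,
                   as.integer(clin$vital_status == "dead")) ~ groups$group
  )
  expect_equal(sc$logrank_chisq, unname(ref$chisq))
})

test_that("enrichment benchmark separates constructed signal from random lists", {
  withr::with_seed(51, {
    universe <- sprintf("g%03d", 1:150)
    reference <- universe[1:12]
    # real lists: reference genes forced to the top
    real <- purrr::map(1:15, function(i) {
      tibble::tibble(gene = c(sample(reference),
                              sample(setdiff(universe, reference))),
                     rank = 1:150)
    })
    bench <- enrichment_benchmark(real, reference, seed = 8)
    expect_equal(bench$frac_significant_real, 1)
    expect_lt(bench$frac_significant_random, 0.5)
    expect_lt(bench$mwu_p, 0.01)
    expect_error(enrichment_benchmark(real, c("none1", "none2")),
                 "does not intersect")
  })
})

test_that("binomial subtype screen matches the exact upper tail", {
  suit <- tibble::tibble(
    sample_id = sprintf("p%02d", 1:20),
    suitable = c(rep(TRUE, 9), FALSE, rep(c(TRUE, FALSE), 5))
  )
  subtypes <- tibble::tibble(
    sample_id = suit$sample_id,
    subtype = rep(c("TNBC", "LuminalA"), each = 10)
  )
  # force baseline p0 = 0.5: 9/10 TNBC + 1/10 LuminalA would give 10/20
  suit$suitable <- c(rep(TRUE, 9), FALSE, TRUE, rep(FALSE, 9))
  sb <- subtype_binomial(suit, subtypes, "drugX")
  expect_equal(sb$p0[1], 0.5)
  tn <- sb[sb$subtype == "TNBC", ]
  expect_equal(tn$k, 9)
  # oracle: C(10,9)/2^10 + C(10,10)/2^10 = 11/1024
  expect_equal(tn$p, 11 / 1024, tolerance = 1e-12)

  # k = 0 -> p = 1; closed form and monotonicity in k
  expect_equal(pbinom(-1, 10, 0.5, lower.tail = FALSE), 1)
  ps <- pbinom((0:20) - 1, 20, 0.3, lower.tail = FALSE)
  expect_true(all(diff(ps) <= 0))
  # regularized incomplete beta identity
  expect_equal(pbinom(8, 10, 0.5, lower.tail = FALSE),
               pbeta(0.5, 9, 2), tolerance = 1e-12)
})

test_that("consistency of the packaged prediction records is 11 of 14", {
  rec <- load_combination_records()
  expect_equal(nrow(rec), 14)
  cr <- consistency_report(rec)
  expect_equal(cr$n_consistent, 11)
  expect_equal(cr$accuracy, 11 / 14)
  # spot checks: overlapping efficacious record is consistent,
  # disjoint efficacious record is not
  cons <- setNames(cr$records$consistent, cr$records$combination_id)
  expect_true(cons[["DC006857"]])
  expect_false(cons[["DC000229"]])
})

test_that("consistency rule handles list-columns and single records", {
  rec <- tibble::tibble(
    combination_id = c("x", "y"),
    predicted_subtypes = list(c("TNBC"), c("LuminalA")),
    trial_subtypes = list(c("TNBC", "HER2+"), c("HER2+")),
    effectiveness = c("efficacious", "efficacious")
  )
  cr <- consistency_report(rec)
  expect_equal(cr$records$consistent, c(TRUE, FALSE))
})
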