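#' Kolmogorov-Smirnov target enrichment of a ranked gene list
#'
#' One-sided two-sample KS comparison of the rank positions of a drug's
#' targets against the non-targets, with the alternative that target ranks
#' are stochastically smaller (targets concentrated among the patient's
#' top-ranked genes). The statistic is the maximal signed ECDF gap
#' \eqn{D^+ = \sup_x [F_{targets}(x) - F_{others}(x)]} over rank positions,
#' and the p-value is the one-sided asymptotic tail
#' \eqn{\exp(-2 (D^+)^2 mn/(m+n))}.
#'
#' @param ranked A ranked gene tibble (`gene`, `rank`) such as an
#'   `np_generank`.
#' @param targets Character vector of target gene ids.
#' @return A one-row tibble: `ks_statistic`, `p`, `n_targets_in_universe`.
#' @export
ks_enrichment <- function(ranked, targets) {
  stopifnot(all(c("gene", "rank") %in% names(ranked)))
  hit <- ranked$gene %in% targets
  m <- sum(hit)
  n <- sum(!hit)
  if (m == 0) abort("untestable drug: no target in the ranked universe")
  if (n == 0) abort("untestable drug: every ranked gene is a target")
  d_plus <- ks_dplus(ranked$rank[hit], ranked$rank[!hit])
  p <- exp(-2 * d_plus^2 * m * n / (m + n))
  tibble::tibble(
    ks_statistic = d_plus,
    p = min(max(p, 0), 1),
    n_targets_in_universe = m
  )
}

# one-sided two-sample KS statistic D+ = sup ECDF(x) - ECDF(y)
ks_dplus <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  Fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(c(Fx - Fy, 0))
}

#' Score and order a drug catalog for one patient
#'
#' Computes [ks_enrichment()] for every drug in the catalog against the
#' patient's ranked gene list and orders drugs by p-value ascending (ties
#' broken by drug id). Drugs whose targets all fall outside the ranked
#' universe are listed with `testable = FALSE` rather than dropped.
#'
#' @param ranked Ranked gene tibble for one patient.
#' @param catalog Drug catalog: a long tibble with columns `drug_id` and
#'   `gene` (one row per drug-target link; a combination id simply carries
#'   the union of its member drugs' targets).
#' @param alpha Suitability threshold on the KS p-value (default 0.05): a
#'   drug is flagged `suitable` when its targets are enriched among the
#'   patient's key genes at this level.
#' @return A tibble `drug_id`, `ks_statistic`, `p`, `n_targets_in_universe`,
#'   `suitable`, `testable`, ordered by p.
#' @export
recommend_drugs <- function(ranked, catalog, alpha = 0.05) {
  stopifnot(all(c("drug_id", "gene") %in% names(catalog)))
  if (nrow(catalog) == 0) {
    warn("empty drug catalog")
    return(tibble::tibble(
      drug_id = character(0), ks_statistic = numeric(0), p = numeric(0),
      n_targets_in_universe = integer(0), suitable = logical(0),
      testable = logical(0)
    ))
  }
  res <- catalog |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(targets = list(unique(.data$gene)), .groups = "drop") |>
    dplyr::mutate(fit = purrr::map(.data$targets, function(tg) {
      in_univ <- sum(ranked$gene %in% tg)
      if (in_univ == 0 || in_univ == nrow(ranked)) {
        tibble::tibble(ks_statistic = NA_real_, p = NA_real_,
                       n_targets_in_universe = in_univ)
      } else {
        ks_enrichment(ranked, tg)
      }
    })) |>
    tidyr::unnest("fit") |>
    dplyr::select(-"targets") |>
    dplyr::mutate(
      testable = !is.na(.data$p),
      suitable = !is.na(.data$p) & .data$p < alpha
    )
  dplyr::arrange(res, !.data$testable, .data$p, .data$drug_id)
}

#' Best administered-drug effect for a patient
#'
#' When a patient received several drugs, the patient's treatment effect is
#' the best (minimum) KS enrichment p-value over the administered drugs.
#'
#' @param recommendations A recommendation tibble from [recommend_drugs()].
#' @param administered Character vector of administered drug ids.
#' @return The minimum p over administered testable drugs, or NA (with a
#'   message) when none is testable.
#' @export
best_treatment_effect <- function(recommendations, administered) {
  hit <- recommendations$drug_id %in% administered & recommendations$testable
  if (!any(hit)) {
    inform("no testable administered drug: patient excluded from evaluation")
    return(NA_real_)
  }
  min(recommendations$p[hit])
}

#' Split patients into properly / improperly treated groups
#'
#' Patients with treatment-effect p-values strictly below the cohort median
#' form the properly treated group; the remainder are improperly treated.
#' With heavy ties at the median the split can be degenerate, which is
#' flagged with a warning.
#'
#' @param effects A tibble with columns `sample_id` and `effect_p`.
#' @return The tibble with an added `group` factor
#'   (properly / improperly).
#' @export
split_treated_groups <- function(effects) {
  stopifnot(all(c("sample_id", "effect_p") %in% names(effects)))
  eff <- dplyr::filter(effects, !is.na(.data$effect_p))
  if (nrow(eff) < 2) abort("need >= 2 patients with a defined treatment effect")
  med <- median(eff$effect_p)
  out <- dplyr::mutate(eff, group = factor(
    ifelse(.data$effect_p < med, "properly", "improperly"),
    levels = c("properly", "improperly")
  ))
  if (all(out$group == "improperly")) {
    warn("degenerate split: no effect strictly below the median")
  }
  out
}

#' Compare survival between two patient groups
#'
#' Two-group log-rank test plus a hazard ratio (with 95% CI) from a
#' univariate Cox proportional-hazards fit on the group indicator.
#' Right-censoring is taken from `vital_status` (alive = censored). The
#' hazard ratio is reported for the second factor level relative to the
#' first, so with the properly/improperly split the value is the hazard of
#' the improperly treated group relative to the properly treated group.
#'
#' @param clinical Clinical tibble with `sample_id`, `survival_days`,
#'   `vital_status`.
#' @param groups A tibble with `sample_id` and a two-level `group` factor.
#' @return An object of class `np_survcmp`: list with `hazard_ratio`,
#'   `hr_ci95` (length-2), `logrank_p`, `logrank_chisq`, `n` (per group),
#'   `events` (per group).
#' @export
survival_compare <- function(clinical, groups) {
  clinical <- validate_clinical(clinical)
  df <- dplyr::inner_join(
    dplyr::select(clinical, "sample_id", "survival_days", "vital_status"),
    dplyr::select(groups, "sample_id", "group"),
    by = "sample_id"
  )
  df <- dplyr::filter(df, !is.na(.data$survival_days), !is.na(.data$vital_status))
  df$group <- droplevels(factor(df$group))
  if (nlevels(df$group) != 2) abort("exactly two groups required")
  df$event <- as.integer(df$vital_status == "dead")
  ev <- tapply(df$event, df$group, sum)
  if (any(ev == 0)) {
    abort(sprintf("group '%s' has zero events; the log-rank test is undefined",
                  names(ev)[ev == 0][1]))
  }
  sdf <- survival::survdiff(survival::Surv(survival_days, event) ~ group, data = df)
  logrank_p <- pchisq_upper(sdf$chisq, df = 1)
  cox <- survival::coxph(survival::Surv(survival_days, event) ~ group, data = df)
  hr <- unname(exp(coef(cox)))
  ci <- unname(exp(stats::confint(cox)))
  structure(
    list(hazard_ratio = hr, hr_ci95 = c(ci[1], ci[2]),
         logrank_p = logrank_p, logrank_chisq = unname(sdf$chisq),
         n = table(df$group), events = ev,
         reference = levels(df$group)[1]),
    class = "np_survcmp"
  )
}

pchisq_upper <- function(q, df) stats::pchisq(q, df = df, lower.tail = FALSE)

#' @export
print.np_survcmp <- function(x, ...) {
  cat(sprintf(
    "<np_survcmp> HR %.3f (95%% CI %.3f-%.3f) vs '%s'; log-rank p = %.3g\n",
    x$hazard_ratio, x$hr_ci95[1], x$hr_ci95[2], x$reference, x$logrank_p
  ))
  invisible(x)
}

#' @describeIn survival_compare Hazard-ratio row as a tibble.
#' @param x An `np_survcmp`.
#' @param ... Unused.
#' @export
tidy.np_survcmp <- function(x, ...) {
  tibble::tibble(
    hazard_ratio = x$hazard_ratio,
    hr_low = x$hr_ci95[1], hr_high = x$hr_ci95[2],
    logrank_p = x$logrank_p
  )
}

#' @describeIn survival_compare One-row summary with group sizes.
#' @export
glance.np_survcmp <- function(x, ...) {
  tibble::tibble(
    n_properly = unname(x$n[1]), n_improperly = unname(x$n[2]),
    events_properly = unname(x$events[1]), events_improperly = unname(x$events[2]),
    logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p
  )
}

#' Benchmark real ranked lists against random gene lists
#'
#' Computes the KS enrichment of a reference gene set (for example known
#' cancer genes) in each patient's ranked list, repeats the computation on
#' randomly permuted gene lists, and compares the two p-value samples with a
#' Mann-Whitney U test.
#'
#' @param ranked_lists A list of ranked gene tibbles (one per patient).
#' @param reference Character vector of reference gene ids.
#' @param n_random Number of random lists (defaults to the number of real
#'   lists).
#' @param seed Seed for the permutations.
#' @param alpha Significance level for the per-list enrichment call.
#' @return A list: `frac_significant_real`, `frac_significant_random`,
#'   `mwu_p`, plus the underlying p-value vectors.
#' @export
enrichment_benchmark <- function(ranked_lists, reference, n_random = NULL,
                                 seed = 1, alpha = 0.05) {
  stopifnot(length(ranked_lists) > 0)
  if (is.null(n_random)) n_random <- length(ranked_lists)
  universe <- ranked_lists[[1]]$gene
  if (length(intersect(universe, reference)) == 0) {
    abort("reference set does not intersect the ranked universe")
  }
  p_real <- purrr::map_dbl(ranked_lists, function(rl) ks_enrichment(rl, reference)$p)
  p_rand <- withr::with_seed(seed, purrr::map_dbl(seq_len(n_random), function(i) {
    shuffled <- tibble::tibble(gene = sample(universe),
                               rank = seq_along(universe))
    ks_enrichment(shuffled, reference)$p
  }))
  mwu <- wilcox.test(p_real, p_rand, alternative = "less", exact = FALSE)
  list(
    frac_significant_real = mean(p_real < alpha),
    frac_significant_random = mean(p_rand < alpha),
    mwu_p = mwu$p.value,
    p_real = p_real,
    p_random = p_rand
  )
}

#' Subtype-stratified binomial screen for one drug
#'
#' Tests, per subtype, whether the drug's effective rate is higher than the
#' cohort-wide baseline rate with a one-sided upper-tail exact binomial test
#' \eqn{P(X \ge k \mid n, p_0)}.
#'
#' @param suitability A tibble with `sample_id` and logical `suitable` for
#'   one drug across all patients.
#' @param subtypes A tibble with `sample_id` and `subtype`.
#' @param drug_id Identifier echoed in the output.
#' @return A tibble with one row per subtype: `drug_id`, `subtype`, `k`,
#'   `n`, `p0`, `p`.
#' @export
subtype_binomial <- function(suitability, subtypes, drug_id = NA_character_) {
  stopifnot(all(c("sample_id", "suitable") %in% names(suitability)))
  df <- dplyr::inner_join(suitability, subtypes, by = "sample_id")
  df <- dplyr::filter(df, !is.na(.data$suitable), !is.na(.data$subtype))
  if (nrow(df) == 0) abort("no patients with both a suitability call and a subtype")
  p0 <- mean(df$suitable)
  if (p0 == 0 && any(df$suitable)) inform("baseline rate 0 with successes; p = 0 exactly")
  out <- df |>
    dplyr::group_by(subtype = .data$subtype) |>
    dplyr::summarise(k = sum(.data$suitable), n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      drug_id = drug_id,
      p0 = p0,
      p = pbinom(.data$k - 1, .data$n, p0, lower.tail = FALSE)
    )
  dplyr::select(out, "drug_id", "subtype", "k", "n", "p0", "p")
}

#' Consistency between predicted and clinical subtype activity
#'
#' A prediction record is consistent when the predicted subtype set overlaps
#' the clinical-trial subtype set and the combination was efficacious, or
#' when the sets are disjoint and the combination was non-efficacious.
#'
#' @param records A tibble with columns `combination_id`,
#'   `predicted_subtypes`, `trial_subtypes` (slash-separated subtype strings
#'   or list-columns of character vectors) and `effectiveness`
#'   (`efficacious` / `non-efficacious`).
#' @return A list with `n_consistent`, `n_total`, `accuracy`, and `records`
#'   (the input with a logical `consistent` column).
#' @export
consistency_report <- function(records) {
  stopifnot(nrow(records) > 0)
  as_set <- function(x) {
    if (is.list(x)) purrr::map(x, as.character)
    else strsplit(as.character(x), "/", fixed = TRUE)
  }
  pred <- as_set(records$predicted_subtypes)
  clin <- as_set(records$trial_subtypes)
  overlap <- purrr::map2_lgl(pred, clin, function(a, b) length(intersect(a, b)) > 0)
  eff <- records$effectiveness == "efficacious"
  consistent <- (overlap & eff) | (!overlap & !eff)
  list(
    n_consistent = sum(consistent),
    n_total = length(consistent),
    accuracy = mean(consistent),
    records = dplyr::mutate(tibble::as_tibble(records), consistent = consistent)
  )
}

#' Packaged breast-cancer combination prediction records
#'
#' Loads the 14 packaged records pairing predicted subtype activity of
#' breast-cancer drug combinations with their clinical-trial subtype
#' activity and effectiveness, as used by [consistency_report()].
#'
#' @return A tibble with one row per drug combination.
#' @export
load_combination_records <- function() {
  path <- system.file("extdata", "bc_combination_records.tsv",
                      package = "netpharm", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ccccc", progress = FALSE)
}

#' Packaged single-drug IC50 values for three breast-cancer cell lines
#'
#' Measured 50% growth-inhibition concentrations (uM) for seven drugs in
#' MCF-7, MDA-MB-231 and SK-BR-3 cells; the IC50 ratios set the fixed dose
#' ratios used in combination experiments.
#'
#' @return A tibble with columns `drug`, `cell_line`, `ic50_uM`.
#' @export
load_ic50_table <- function() {
  path <- system.file("extdata", "bc_ic50.tsv", package = "netpharm",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "ccd", progress = FALSE)
}
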