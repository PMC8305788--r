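#' Cancer-type parameter presets
#'
#' Named parameter sets for the three studied cancers: breast (`bc`,
#' damping d = 0.85, horizon 1825 days), ovarian (`ov`, d = 0.30, 1200
#' days), glioblastoma (`gbm`, d = 0.30, 400 days).
#'
#' @param name One of "bc", "ov", "gbm".
#' @return A list with `d` and `horizon_days`.
#' @export
np_preset <- function(name = c("bc", "ov", "gbm")) {
  name <- match.arg(name)
  switch(name,
    bc = list(d = 0.85, horizon_days = 1825L),
    ov = list(d = 0.30, horizon_days = 1200L),
    gbm = list(d = 0.30, horizon_days = 400L)
  )
}

#' Read a drug-target table
#'
#' Two-column TSV (`drug_id`, `gene`), one row per drug-target link.
#'
#' @param path Path to the TSV.
#' @return A long catalog tibble.
#' @export
load_drug_targets <- function(path) {
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

#' Expand drug combinations into a catalog of unioned target sets
#'
#' A combination's target set is the union of its member drugs' target
#' sets.
#'
#' @param combinations A tibble with columns `combo_id`, `drug1`, `drug2`.
#' @param catalog A long catalog tibble (`drug_id`, `gene`).
#' @return A long catalog tibble keyed by `combo_id` as `drug_id`.
#' @export
combos_to_catalog <- function(combinations, catalog) {
  stopifnot(all(c("combo_id", "drug1", "drug2") %in% names(combinations)))
  rows <- purrr::pmap(combinations, function(combo_id, drug1, drug2, ...) {
    genes <- unique(catalog$gene[catalog$drug_id %in% c(drug1, drug2)])
    if (length(genes) == 0) return(NULL)
    tibble::tibble(drug_id = combo_id, gene = genes)
  })
  dplyr::bind_rows(rows)
}

stage_abort <- function(stage, msg) abort(sprintf("[%s] %s", stage, msg))

check_paths <- function(stage, ...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stage_abort(stage, sprintf("missing input file(s): %s",
                               paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

write_run_log <- function(out_dir, stage, params) {
  lines <- c(
    sprintf("stage: %s", stage),
    sprintf("config_hash: %s", rlang::hash(params)),
    vapply(names(params), function(k) {
      sprintf("%s: %s", k, paste(format(params[[k]]), collapse = ","))
    }, character(1))
  )
  writeLines(lines, file.path(out_dir, sprintf("%s.log", stage)))
}

#' Build-network pipeline stage
#'
#' Reads the tumour expression and clinical tables, binarizes expression and
#' prognosis, fits the empirical CMI null, builds the dependency network,
#' and writes the edge list, a null-model sidecar, and a run log into
#' `out_dir`.
#'
#' @param expression_path,clinical_path Input TSV paths.
#' @param out_dir Output directory (created if needed).
#' @param horizon_days Survival horizon.
#' @param p_threshold Edge significance threshold.
#' @param n_values Null sample size.
#' @param seed Seed for the null draw.
#' @param ties Median tie policy for expression binarization.
#' @return The `np_depnet`, invisibly.
#' @export
run_build_network <- function(expression_path, clinical_path, out_dir,
                              horizon_days = 1825, p_threshold = 1e-5,
                              n_values = 10000, seed = 1, ties = "strict") {
  check_paths("build-network", expression_path, clinical_path)
  expr <- load_expression(expression_path)
  clinical <- load_clinical(clinical_path)
  cohort <- binarize_cohort(expr, clinical, horizon_days, ties = ties)
  null <- cmi_null(cohort, n_values = n_values, seed = seed)
  network <- build_network(cohort, null, p_threshold = p_threshold)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_network(network, file.path(out_dir, "edges.tsv"))
  jsonlite::write_json(
    list(mean = null$mean, sd = null$sd, n = null$n, seed = null$seed),
    file.path(out_dir, "null.json"), auto_unbox = TRUE, digits = NA
  )
  write_run_log(out_dir, "build-network", list(
    expression = expression_path, clinical = clinical_path,
    horizon_days = horizon_days, p_threshold = p_threshold,
    n_values = n_values, seed = seed, ties = ties
  ))
  invisible(network)
}

#' Per-patient ranking and drug recommendation stage
#'
#' For each requested patient: fold-change prior against the control
#' profile, directed GeneRank over the dependency network, and KS target
#' enrichment for every catalog entry; one recommendation TSV is written
#' per patient. Patients whose prior is identically zero fall back to the
#' topology-only uniform prior with a warning; patients absent from the
#' expression table are reported in `skipped_patients.txt` rather than
#' failing the stage.
#'
#' @param expression_path,control_path Input expression TSVs.
#' @param network_path Edge-list TSV from [run_build_network()].
#' @param targets_path Drug-target TSV.
#' @param out_dir Output directory.
#' @param patients Patient ids (default: all expression samples).
#' @param d,eps,max_iter GeneRank settings.
#' @param pseudocount Fold-change pseudocount.
#' @param alpha Suitability threshold.
#' @return A named list of recommendation tibbles, invisibly.
#' @export
run_recommend <- function(expression_path, control_path, network_path,
                          targets_path, out_dir, patients = NULL, d = 0.85,
                          eps = 1e-5, max_iter = 1000, pseudocount = 1,
                          alpha = 0.05) {
  check_paths("recommend", expression_path, control_path, network_path,
              targets_path)
  expr <- load_expression(expression_path)
  control <- control_profile(load_expression(control_path))
  network <- read_network(network_path)
  catalog <- load_drug_targets(targets_path)
  all_samples <- names(expr)[-1]
  if (is.null(patients)) patients <- all_samples
  skipped <- setdiff(patients, all_samples)
  patients <- intersect(patients, all_samples)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- purrr::map(patients, function(pid) {
    f <- fold_change_scores(expr, control, pid, pseudocount = pseudocount)
    f <- f[f$gene %in% network$genes, ]
    ranked <- if (all(f$f == 0)) {
      warn(sprintf("uninformative prior for '%s': falling back to topology", pid))
      generank(network, scores = NULL, d = d, eps = eps, max_iter = max_iter)
    } else {
      generank(network, f, d = d, eps = eps, max_iter = max_iter)
    }
    rec <- recommend_drugs(ranked, catalog, alpha = alpha)
    readr::write_tsv(rec, file.path(out_dir, sprintf("recommend_%s.tsv", pid)),
                     progress = FALSE)
    rec
  })
  names(results) <- patients
  writeLines(skipped, file.path(out_dir, "skipped_patients.txt"))
  write_run_log(out_dir, "recommend", list(
    expression = expression_path, control = control_path,
    network = network_path, targets = targets_path, d = d, eps = eps,
    max_iter = max_iter, pseudocount = pseudocount, alpha = alpha
  ))
  invisible(results)
}

#' Subtype-stratified binomial screening stage
#'
#' Aggregates per-patient suitability calls into a per-drug, per-subtype
#' binomial screen (effective rate in the subtype versus the cohort-wide
#' baseline). Subtypes with zero patients yield NA cells.
#'
#' @param recommendations A named list of recommendation tibbles as returned
#'   by [run_recommend()] (names are patient ids), or a directory containing
#'   `recommend_<id>.tsv` files.
#' @param clinical_path Clinical TSV with receptor status.
#' @param out_dir Output directory for `subtype_screen.tsv` (optional).
#' @return A tibble with one row per drug x subtype: `drug_id`, `subtype`,
#'   `k`, `n`, `p0`, `p`.
#' @export
run_subtype_screen <- function(recommendations, clinical_path,
                               out_dir = NULL) {
  check_paths("subtype-screen", clinical_path)
  if (is.character(recommendations)) {
    files <- list.files(recommendations, pattern = "^recommend_.*\\.tsv$",
                        full.names = TRUE)
    if (length(files) == 0) stage_abort("subtype-screen", "no recommendation files found")
    ids <- sub("^recommend_(.*)\\.tsv$", "\\1", basename(files))
    recommendations <- setNames(
      purrr::map(files, readr::read_tsv, col_types = "cddill",
                 progress = FALSE),
      ids
    )
  }
  clinical <- add_subtypes(load_clinical(clinical_path))
  subtypes <- dplyr::select(clinical, "sample_id", "subtype")
  suit <- purrr::imap(recommendations, function(rec, pid) {
    tibble::tibble(sample_id = pid, drug_id = rec$drug_id,
                   suitable = rec$suitable)
  }) |> dplyr::bind_rows()
  screen <- suit |>
    dplyr::group_split(.data$drug_id) |>
    purrr::map(function(df) {
      res <- subtype_binomial(
        dplyr::select(df, "sample_id", "suitable"),
        subtypes, drug_id = df$drug_id[1]
      )
      grid <- tibble::tibble(drug_id = df$drug_id[1],
                             subtype = sim_subtype_levels)
      dplyr::left_join(
        grid,
        dplyr::mutate(res, subtype = as.character(.data$subtype)),
        by = c("drug_id", "subtype")
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$drug_id, .data$subtype)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(screen, file.path(out_dir, "subtype_screen.tsv"),
                     progress = FALSE)
    write_run_log(out_dir, "subtype-screen", list(clinical = clinical_path))
  }
  screen
}
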