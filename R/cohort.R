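#' Read a gene-by-sample expression table
#'
#' Expression tables are tab-delimited: the first column holds gene
#' identifiers, the header row holds sample identifiers, and the body is
#' numeric (FPKM-like, nonnegative). The same dialect is used for tumour and
#' control matrices.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a `gene` character column followed by one numeric
#'   column per sample.
#' @export
load_expression <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2) abort("expression table needs a gene column plus >= 1 sample column")
  names(df)[1] <- "gene"
  for (cn in names(df)[-1]) {
    parsed <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(parsed) & !is.na(df[[cn]]) | is.na(df[[cn]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric expression value '%s' at gene '%s', sample column '%s'",
        as.character(df[[cn]][bad[1]]), df$gene[bad[1]], cn
      ))
    }
    df[[cn]] <- parsed
  }
  validate_expression(df)
}

#' Validate an expression tibble
#'
#' Checks the invariants expected of an expression table: unique gene and
#' sample identifiers, finite nonnegative values.
#'
#' @param expr A tibble as returned by [load_expression()].
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_expression <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2)
  if (names(expr)[1] != "gene") abort("first column must be named 'gene'")
  dup <- expr$gene[duplicated(expr$gene)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  sn <- names(expr)[-1]
  if (anyDuplicated(sn)) abort("duplicate sample id(s) in header")
  vals <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("expression body must be numeric")
  if (any(!is.finite(vals))) abort("expression values must be finite")
  if (any(vals < 0)) abort("expression values must be >= 0")
  tibble::as_tibble(expr)
}

#' Write an expression tibble to TSV
#'
#' Round-trips bit-exactly through [load_expression()] (full double
#' precision is preserved).
#'
#' @param expr Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  expr <- validate_expression(expr)
  out <- expr
  for (cn in names(out)[-1]) out[[cn]] <- sprintf("%.17g", out[[cn]])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# genes x samples numeric matrix from an expression tibble
expr_matrix <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene
  m
}

#' Binarize expression at the per-gene median
#'
#' Each gene is split at its median across all samples: values strictly
#' greater than the median become 1, values at or below the median become 0.
#' The at-median tie policy (`"strict"`, the default) assigns 0; `"weak"`
#' assigns 1 to values greater than or equal to the median.
#'
#' @param expr Expression tibble (>= 2 samples).
#' @param ties `"strict"` (at-median values map to 0) or `"weak"`.
#' @return A tibble of the same shape with 0/1 entries.
#' @export
binarize_expression <- function(expr, ties = c("strict", "weak")) {
  ties <- match.arg(ties)
  expr <- validate_expression(expr)
  if (ncol(expr) < 3) abort("median split undefined for a single-sample matrix")
  m <- expr_matrix(expr)
  med <- apply(m, 1, median)
  b <- if (ties == "strict") (m > med) else (m >= med)
  out <- tibble::as_tibble(as.data.frame(b * 1L))
  names(out) <- colnames(m)
  dplyr::bind_cols(tibble::tibble(gene = expr$gene), out)
}

#' Read a clinical table
#'
#' Tab-delimited with columns `sample_id`, `survival_days`, `vital_status`
#' (`dead`/`alive`), `er`, `pr`, `her2` (`+`, `-`, or empty for missing), and
#' `drugs` (semicolon-separated drug ids, empty allowed).
#'
#' @param path Path to a TSV file.
#' @return A tibble; `drugs` is a list-column of character vectors.
#' @export
load_clinical <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    survival_days = readr::col_double(),
    vital_status = readr::col_character(),
    er = readr::col_character(),
    pr = readr::col_character(),
    her2 = readr::col_character(),
    drugs = readr::col_character()
  ), progress = FALSE)
  validate_clinical(dplyr::mutate(
    df,
    drugs = purrr::map(.data$drugs, function(x) {
      if (is.na(x) || x == "") character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
    })
  ))
}

#' Validate a clinical tibble
#' @param clinical Clinical tibble (see [load_clinical()] for columns).
#' @return The validated tibble.
#' @export
validate_clinical <- function(clinical) {
  need <- c("sample_id", "survival_days", "vital_status", "er", "pr", "her2")
  miss <- setdiff(need, names(clinical))
  if (length(miss) > 0) abort(sprintf("clinical table missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(clinical$sample_id)) abort("duplicate sample_id in clinical table")
  ok_days <- is.na(clinical$survival_days) | clinical$survival_days >= 0
  if (!all(ok_days)) abort("survival_days must be >= 0")
  ok_status <- clinical$vital_status %in% c("dead", "alive") | is.na(clinical$vital_status)
  if (!all(ok_status)) abort("vital_status must be 'dead' or 'alive'")
  if (!"drugs" %in% names(clinical)) clinical$drugs <- replicate(nrow(clinical), character(0), simplify = FALSE)
  tibble::as_tibble(clinical)
}

#' Write a clinical tibble to TSV
#' @param clinical Clinical tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  clinical <- validate_clinical(clinical)
  out <- dplyr::mutate(clinical, drugs = purrr::map_chr(.data$drugs, paste, collapse = ";"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Binarize prognosis against a survival horizon
#'
#' A patient who died within the horizon is high-risk (1); a patient who
#' survived past the horizon (regardless of vital status) is low-risk (0);
#' a patient censored alive before the horizon, or with missing survival, is
#' excluded (NA). Horizons of 1825 days (breast), 1200 days (ovarian) and
#' 400 days (glioblastoma) match the cancer presets (see [np_preset()]).
#'
#' @param clinical Clinical tibble.
#' @param horizon_days Positive integer horizon.
#' @return A tibble with columns `sample_id` and `risk` (integer 0/1, NA when
#'   excluded).
#' @export
binarize_prognosis <- function(clinical, horizon_days) {
  stopifnot(horizon_days > 0)
  clinical <- validate_clinical(clinical)
  risk <- dplyr::case_when(
    is.na(clinical$survival_days) | is.na(clinical$vital_status) ~ NA_integer_,
    clinical$survival_days > horizon_days ~ 0L,
    clinical$vital_status == "dead" ~ 1L,
    TRUE ~ NA_integer_ # alive, follow-up <= horizon: censored before horizon
  )
  tibble::tibble(sample_id = clinical$sample_id, risk = risk)
}

#' Mean control expression profile
#'
#' The per-gene arithmetic mean over healthy control samples, used as the
#' denominator of per-patient fold-changes.
#'
#' @param normals Control expression tibble (>= 1 sample).
#' @return A tibble with columns `gene` and `mean_value`.
#' @export
control_profile <- function(normals) {
  normals <- validate_expression(normals)
  if (ncol(normals) < 2) abort("control matrix has no samples")
  m <- expr_matrix(normals)
  tibble::tibble(gene = rownames(m), mean_value = unname(rowMeans(m)))
}

#' Assign breast-cancer molecular subtype from receptor status
#'
#' Receptor-status rule: luminal A (ER+, PR±, HER2−), luminal B
#' (ER+, PR±, HER2+), HER2+ (ER−, PR−, HER2+), TNBC (ER−, PR−, HER2−).
#' PR is ignored for the luminal classes but must be negative for HER2+ and
#' TNBC; any other pattern (including missing markers or ER− PR+) is
#' `Unclassified`.
#'
#' @param er,pr,her2 Character vectors with entries `"+"`, `"-"`, or
#'   NA/anything else for missing.
#' @return A factor with levels LuminalA, LuminalB, HER2pos, TNBC,
#'   Unclassified.
#' @export
assign_subtype <- function(er, pr, her2) {
  n <- max(length(er), length(pr), length(her2))
  er <- rep_len(as.character(er), n)
  pr <- rep_len(as.character(pr), n)
  her2 <- rep_len(as.character(her2), n)
  out <- dplyr::case_when(
    er == "+" & her2 == "-" ~ "LuminalA",
    er == "+" & her2 == "+" ~ "LuminalB",
    er == "-" & pr == "-" & her2 == "+" ~ "HER2pos",
    er == "-" & pr == "-" & her2 == "-" ~ "TNBC",
    TRUE ~ "Unclassified"
  )
  factor(out, levels = c("LuminalA", "LuminalB", "HER2pos", "TNBC", "Unclassified"))
}

#' Add a subtype column to a clinical tibble
#' @param clinical Clinical tibble with `er`, `pr`, `her2` columns.
#' @return The tibble with an added `subtype` factor column.
#' @export
add_subtypes <- function(clinical) {
  clinical <- validate_clinical(clinical)
  dplyr::mutate(clinical, subtype = assign_subtype(.data$er, .data$pr, .data$her2))
}

#' Assemble a binarized cohort for network inference
#'
#' Binarizes expression at the per-gene median and prognosis at the survival
#' horizon, then retains the samples with a defined risk label (samples
#' censored before the horizon are excluded from network construction but are
#' still available downstream for survival evaluation).
#'
#' @param expr Tumour expression tibble.
#' @param clinical Clinical tibble covering the expression samples.
#' @param horizon_days Survival horizon in days.
#' @param ties Tie policy passed to [binarize_expression()].
#' @return An object of class `np_cohort`: a list with `X` (0/1 genes x
#'   samples matrix), `risk` (named 0/1 integer vector), `genes`, `samples`,
#'   and `horizon_days`.
#' @export
binarize_cohort <- function(expr, clinical, horizon_days, ties = "strict") {
  expr <- validate_expression(expr)
  risk <- binarize_prognosis(clinical, horizon_days)
  keep <- risk$sample_id[!is.na(risk$risk)]
  keep <- intersect(names(expr)[-1], keep)
  if (length(keep) < 2) abort("fewer than 2 samples with defined risk labels")
  b <- binarize_expression(expr[, c("gene", keep)], ties = ties)
  X <- expr_matrix(b)
  r <- setNames(risk$risk[match(keep, risk$sample_id)], keep)
  structure(
    list(X = X, risk = r, genes = rownames(X), samples = keep,
         horizon_days = horizon_days),
    class = "np_cohort"
  )
}

#' @export
print.np_cohort <- function(x, ...) {
  cat(sprintf(
    "<np_cohort> %d genes x %d samples, horizon %d days (%d high-risk / %d low-risk)\n",
    nrow(x$X), ncol(x$X), x$horizon_days, sum(x$risk == 1), sum(x$risk == 0)
  ))
  invisible(x)
}
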