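#' Configuration for the synthetic cohort generator
#'
#' Desk-scale defaults: 60 genes, 200 tumour samples, 30 controls, 6 planted
#' ordered dependency edges (3 gene pairs, both orientations) at strength
#' 0.9, 12 drugs of which 4 are effective (one per breast-cancer subtype),
#' 5 targets per drug, and the 1825-day survival horizon.
#'
#' @param n_genes Number of genes.
#' @param n_tumour_samples,n_control_samples Sample counts.
#' @param n_planted_edges Number of planted ordered dependency edges. Planted
#'   dependencies are symmetric by construction (see
#'   [simulate_cohort()]), so this must be even; each planted gene pair
#'   contributes both orientations.
#' @param dependency_strength Strength in (0, 1]; the risk label agrees with
#'   gene A's state (given gene B high) with probability
#'   (1 + strength) / 2.
#' @param n_drugs,targets_per_drug,n_effective_drugs Drug catalog shape.
#' @param horizon_days Survival horizon used to encode the risk label.
#' @param driver_fold Fold-shift of subtype driver genes versus control.
#' @param drivers_per_subtype Driver module size per subtype.
#' @param noise_sdlog Log-normal noise sd (log scale) for background
#'   expression.
#' @param driver_hazard Per-active-driver multiplicative increment of the
#'   baseline hazard.
#' @param early_censor_frac Fraction of tumour samples censored alive before
#'   the horizon (excluded from network construction).
#' @param seed Integer seed; all generator output is a pure function of the
#'   configuration including the seed.
#' @return A list of class `np_simcfg`.
#' @export
sim_cohort_config <- function(n_genes = 60, n_tumour_samples = 200,
                              n_control_samples = 30, n_planted_edges = 6,
                              dependency_strength = 0.9, n_drugs = 12,
                              targets_per_drug = 5, n_effective_drugs = 4,
                              horizon_days = 1825, driver_fold = 4,
                              drivers_per_subtype = 5, noise_sdlog = 0.4,
                              driver_hazard = 0.5, early_censor_frac = 0,
                              seed = 1) {
  cfg <- list(
    n_genes = n_genes, n_tumour_samples = n_tumour_samples,
    n_control_samples = n_control_samples, n_planted_edges = n_planted_edges,
    dependency_strength = dependency_strength, n_drugs = n_drugs,
    targets_per_drug = targets_per_drug, n_effective_drugs = n_effective_drugs,
    horizon_days = horizon_days, driver_fold = driver_fold,
    drivers_per_subtype = drivers_per_subtype, noise_sdlog = noise_sdlog,
    driver_hazard = driver_hazard, early_censor_frac = early_censor_frac,
    seed = seed
  )
  if (n_planted_edges %% 2 != 0) {
    abort("n_planted_edges must be even: planted dependencies are symmetric, so ordered edges come in orientation pairs")
  }
  if (n_planted_edges > n_genes * (n_genes - 1)) abort("too many planted edges")
  if (n_effective_drugs > n_drugs) abort("n_effective_drugs exceeds n_drugs")
  if (dependency_strength <= 0 || dependency_strength > 1) {
    abort("dependency_strength must lie in (0, 1]")
  }
  n_special <- n_planted_edges + 4 * drivers_per_subtype
  if (n_special + 10 > n_genes) {
    abort(sprintf("infeasible config: %d planted + driver genes need n_genes >= %d",
                  n_special, n_special + 10))
  }
  if (targets_per_drug > n_genes) abort("targets_per_drug exceeds n_genes")
  structure(cfg, class = "np_simcfg")
}

sim_subtype_levels <- c("LuminalA", "LuminalB", "HER2pos", "TNBC")
# cohort composition mirrors the 373/99/37/116 subtype counts of the
# reference breast-cancer cohort
sim_subtype_probs <- c(373, 99, 37, 116) / 625

#' Simulate a cohort with planted prognosis-dependent gene dependencies
#'
#' Generates a tumour expression matrix, a healthy-control matrix, and a
#' clinical table with known ground truth:
#' \itemize{
#'   \item Background genes are i.i.d. log-normal.
#'   \item Each planted gene pair (A, B) carries an XOR-type dependency on
#'     the prognostic risk label P: when B is high, A agrees with P with
#'     probability (1 + strength)/2; when B is low, A disagrees with P with
#'     the same probability. P is therefore marginally independent of both
#'     genes but strongly dependent on A given B (and, symmetrically, on B
#'     given A), which is exactly the conditional signal the dependency
#'     network detects; both orientations of the pair are planted edges.
#'   \item Each patient carries the driver module of their molecular
#'     subtype, up-/down-shifted `driver_fold`-fold versus control.
#'   \item Survival days are exponential with hazard increasing in the
#'     number of active driver genes, then truncated to the horizon side
#'     dictated by the risk label so that the prognosis binarization
#'     recovers P exactly.
#' }
#'
#' @param cfg An `np_simcfg` from [sim_cohort_config()].
#' @return A list of class `np_simcohort` with elements `tumour`, `control`
#'   (expression tibbles), `clinical` (clinical tibble with subtype
#'   markers and administered drugs), and `truth` (class `np_truth`: planted
#'   edge list, driver modules per subtype, effective drug assignments, the
#'   per-sample risk label, and the configuration).
#' @export
simulate_cohort <- function(cfg = sim_cohort_config()) {
  stopifnot(inherits(cfg, "np_simcfg"))
  G <- cfg$n_genes; n <- cfg$n_tumour_samples; nc <- cfg$n_control_samples
  genes <- sprintf("G%03d", seq_len(G))
  tumour_ids <- sprintf("T%03d", seq_len(n))
  control_ids <- sprintf("N%03d", seq_len(nc))
  n_pairs <- cfg$n_planted_edges / 2
  pair_genes <- matrix(seq_len(2 * n_pairs), ncol = 2, byrow = TRUE) # A, B columns
  driver_idx <- matrix(
    2 * n_pairs + seq_len(4 * cfg$drivers_per_subtype),
    ncol = 4
  ) # one column per subtype
  q <- (1 + cfg$dependency_strength) / 2

  out <- withr::with_seed(cfg$seed, {
    subtype <- sample(sim_subtype_levels, n, replace = TRUE,
                      prob = sim_subtype_probs)
    risk <- rbinom(n, 1, 0.5)

    meanlog <- runif(G, log(10), log(200))
    tum <- matrix(rlnorm(G * n, meanlog, cfg$noise_sdlog), nrow = G)
    ctl <- matrix(rlnorm(G * nc, meanlog, cfg$noise_sdlog), nrow = G)

    # planted XOR dependencies: continuous values follow a well-separated
    # two-component log-normal so the median split recovers the latent state
    sep <- 1.2
    for (k in seq_len(n_pairs)) {
      ai <- pair_genes[k, 1]; bi <- pair_genes[k, 2]
      b_state <- sample(rep(c(0L, 1L), length.out = n))
      agree <- rbinom(n, 1, q)
      a_state <- ifelse(b_state == 1,
                        ifelse(agree == 1, risk, 1 - risk),
                        ifelse(agree == 1, 1 - risk, risk))
      tum[ai, ] <- rlnorm(n, meanlog[ai] + (2 * a_state - 1) * sep, 0.25)
      tum[bi, ] <- rlnorm(n, meanlog[bi] + (2 * b_state - 1) * sep, 0.25)
    }

    # subtype driver modules, alternating up/down shifts
    for (s in seq_along(sim_subtype_levels)) {
      members <- which(subtype == sim_subtype_levels[s])
      for (g_pos in seq_len(cfg$drivers_per_subtype)) {
        gi <- driver_idx[g_pos, s]
        dir <- if (g_pos %% 2 == 1) 1 else -1
        tum[gi, members] <- rlnorm(length(members),
                                   meanlog[gi] + dir * log(cfg$driver_fold),
                                   cfg$noise_sdlog)
      }
    }

    # survival: exponential hazard scaled by active driver count, truncated
    # to the horizon side encoding the risk label
    k_active <- rep(cfg$drivers_per_subtype, n)
    h <- cfg$horizon_days
    lambda <- log(2) / h * (1 + cfg$driver_hazard * k_active)
    u <- runif(n)
    days <- ifelse(
      risk == 1,
      -log(1 - u * (1 - exp(-lambda * h))) / lambda,           # death in (0, h]
      h + rexp(n, lambda)                                       # survival past h
    )
    days <- pmax(1, ceiling(days))
    days[risk == 1] <- pmin(days[risk == 1], h)
    vital <- ifelse(risk == 1, "dead", ifelse(runif(n) < 0.5, "dead", "alive"))

    censored <- rep(FALSE, n)
    if (cfg$early_censor_frac > 0) {
      censored <- runif(n) < cfg$early_censor_frac
      days[censored] <- ceiling(runif(sum(censored), 1, h - 1))
      vital[censored] <- "alive"
    }

    er <- ifelse(subtype %in% c("LuminalA", "LuminalB"), "+", "-")
    pr <- ifelse(subtype %in% c("LuminalA", "LuminalB"),
                 sample(c("+", "-"), n, replace = TRUE), "-")
    her2 <- ifelse(subtype %in% c("LuminalB", "HER2pos"), "+", "-")

    drug_ids <- sprintf("D%02d", seq_len(cfg$n_drugs))
    effective <- tibble::tibble(
      drug_id = drug_ids[seq_len(cfg$n_effective_drugs)],
      subtype = sim_subtype_levels[((seq_len(cfg$n_effective_drugs) - 1) %% 4) + 1]
    )
    administered <- purrr::map(seq_len(n), function(i) {
      own <- effective$drug_id[effective$subtype == subtype[i]]
      extra <- sample(drug_ids, 1)
      if (length(own) > 0 && runif(1) < 0.5) unique(c(own[1], extra)) else extra
    })

    list(tum = tum, ctl = ctl, subtype = subtype, risk = risk, days = days,
         vital = vital, censored = censored, er = er, pr = pr, her2 = her2,
         administered = administered, effective = effective)
  })

  tumour <- dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(setNames(as.data.frame(out$tum), tumour_ids))
  )
  control <- dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(setNames(as.data.frame(out$ctl), control_ids))
  )
  clinical <- tibble::tibble(
    sample_id = tumour_ids,
    survival_days = out$days,
    vital_status = out$vital,
    er = out$er, pr = out$pr, her2 = out$her2,
    drugs = out$administered
  )
  planted <- dplyr::bind_rows(purrr::map(seq_len(n_pairs), function(k) {
    a <- genes[pair_genes[k, 1]]; b <- genes[pair_genes[k, 2]]
    tibble::tibble(source = c(a, b), target = c(b, a))
  }))
  drivers <- setNames(
    purrr::map(seq_len(4), function(s) genes[driver_idx[, s]]),
    sim_subtype_levels
  )
  truth <- structure(
    list(
      planted_edges = planted,
      driver_genes = drivers,
      effective_drugs = out$effective,
      risk = setNames(out$risk, tumour_ids),
      subtype = setNames(out$subtype, tumour_ids),
      background_genes = setdiff(genes, genes[seq_len(2 * n_pairs + 4 * cfg$drivers_per_subtype)]),
      config = cfg
    ),
    class = "np_truth"
  )
  structure(
    list(tumour = tumour, control = control, clinical = clinical,
         truth = truth),
    class = "np_simcohort"
  )
}

#' @export
print.np_simcohort <- function(x, ...) {
  cat(sprintf(
    "<np_simcohort> %d genes x %d tumour / %d control samples, %d planted edges\n",
    nrow(x$tumour), ncol(x$tumour) - 1, ncol(x$control) - 1,
    nrow(x$truth$planted_edges)
  ))
  invisible(x)
}

#' Simulate a drug catalog against a cohort's ground truth
#'
#' Effective drugs draw their targets from the planted driver module of
#' their assigned subtype; ineffective drugs draw targets from background
#' genes only.
#'
#' @param cfg The `np_simcfg` used for the cohort.
#' @param truth The `np_truth` of the simulated cohort.
#' @param noise_targets Number of background genes mixed into each
#'   effective drug's target set (default 0).
#' @return A long tibble with columns `drug_id` and `gene`.
#' @export
simulate_drug_catalog <- function(cfg, truth, noise_targets = 0) {
  stopifnot(inherits(cfg, "np_simcfg"), inherits(truth, "np_truth"))
  if (cfg$targets_per_drug > cfg$n_genes) abort("targets_per_drug exceeds n_genes")
  drug_ids <- sprintf("D%02d", seq_len(cfg$n_drugs))
  withr::with_seed(cfg$seed + 1L, {
    rows <- purrr::map(seq_len(cfg$n_drugs), function(i) {
      id <- drug_ids[i]
      eff_row <- truth$effective_drugs[truth$effective_drugs$drug_id == id, ]
      if (nrow(eff_row) == 1) {
        module <- truth$driver_genes[[eff_row$subtype]]
        n_mod <- min(cfg$targets_per_drug - noise_targets, length(module))
        tg <- c(sample(module, n_mod),
                sample(truth$background_genes,
                       cfg$targets_per_drug - n_mod))
      } else {
        tg <- sample(truth$background_genes, cfg$targets_per_drug)
      }
      tibble::tibble(drug_id = id, gene = unique(tg))
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate a two-arm survival cohort with a known hazard ratio
#'
#' Draws exponential survival times for a reference ("properly" treated) arm
#' and a comparison ("improperly" treated) arm whose hazard is
#' `hazard_ratio` times larger, with optional uniform right-censoring; used
#' to check hazard-ratio recovery of [survival_compare()] against known
#' truth.
#'
#' @param n_per_arm Patients per arm.
#' @param hazard_ratio True hazard ratio (improperly / properly).
#' @param base_hazard Baseline hazard per day of the properly treated arm.
#' @param censor_frac Fraction of patients censored alive.
#' @param seed Seed.
#' @return A list with `clinical` (clinical tibble) and `groups` (tibble
#'   `sample_id`, `group`).
#' @export
simulate_survival_split <- function(n_per_arm = 500, hazard_ratio = 2,
                                    base_hazard = log(2) / 1000,
                                    censor_frac = 0, seed = 1) {
  stopifnot(n_per_arm >= 2, hazard_ratio > 0, base_hazard > 0)
  n <- 2 * n_per_arm
  withr::with_seed(seed, {
    group <- factor(rep(c("properly", "improperly"), each = n_per_arm),
                    levels = c("properly", "improperly"))
    rate <- ifelse(group == "properly", base_hazard,
                   base_hazard * hazard_ratio)
    days <- pmax(1, ceiling(rexp(n, rate)))
    vital <- rep("dead", n)
    if (censor_frac > 0) {
      cens <- runif(n) < censor_frac
      days[cens] <- pmax(1, ceiling(days[cens] * runif(sum(cens))))
      vital[cens] <- "alive"
    }
    ids <- sprintf("S%04d", seq_len(n))
    list(
      clinical = tibble::tibble(
        sample_id = ids, survival_days = days, vital_status = vital,
        er = NA_character_, pr = NA_character_, her2 = NA_character_,
        drugs = replicate(n, character(0), simplify = FALSE)
      ),
      groups = tibble::tibble(sample_id = ids, group = group)
    )
  })
}

#' Write a simulated cohort to disk
#'
#' Emits `expression.tsv`, `control.tsv`, `clinical.tsv` in the standard
#' dialects plus a `ground_truth.json` sidecar, so the ground truth never
#' needs re-deriving.
#'
#' @param sim An `np_simcohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "np_simcohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$tumour, file.path(dir, "expression.tsv"))
  write_expression(sim$control, file.path(dir, "control.tsv"))
  write_clinical(sim$clinical, file.path(dir, "clinical.tsv"))
  tr <- sim$truth
  jsonlite::write_json(
    list(
      planted_edges = tr$planted_edges,
      driver_genes = tr$driver_genes,
      effective_drugs = tr$effective_drugs,
      risk = as.list(tr$risk),
      subtype = as.list(tr$subtype),
      background_genes = tr$background_genes,
      config = unclass(tr$config)
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
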