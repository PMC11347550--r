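#' Specification of a train/validation/test split
#'
#' Splitting is done at the unit level (recruiting center by default,
#' mirroring center-level assignment, or individual patients). The
#' validation and test unit counts are floors of their fractions; the
#' remainder goes to training.
#'
#' @param unit `"center"` or `"patient"`.
#' @param fractions positive `(train, validation, test)` fractions summing
#'   to 1; the default corresponds to a held-out test assignment followed by
#'   an 8:2 train/validation division of the development units.
#' @param seed integer seed for the unit shuffle.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(unit = c("center", "patient"),
                       fractions = c(0.64, 0.16, 0.20), seed = 1L) {
  unit <- match.arg(unit)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("invalid split: fractions must be positive and sum to 1")
  structure(list(unit = unit, fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a cohort into train/validation/test patient-id sets
#'
#' @param records cohort data frame with `patient_id` and (for center-level
#'   splits) `center`.
#' @param spec a [split_spec()].
#' @return list of disjoint, exhaustive character vectors `train`,
#'   `validation`, `test`.
#' @export
split_cohort <- function(records, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  units <- if (spec$unit == "center") records$center else records$patient_id
  if (is.null(units)) stop("records lack the split unit column")
  uq <- unique(units)
  if (length(uq) < 3) stop("too few units to split (need >= 3)")
  perm <- with_seed(spec$seed, sample(uq))
  n <- length(perm)
  n_val <- floor(spec$fractions[2] * n)
  n_test <- floor(spec$fractions[3] * n)
  n_train <- n - n_val - n_test
  assign_of <- rep(c("train", "validation", "test"), c(n_train, n_val, n_test))
  lab <- assign_of[match(units, perm)]
  pid <- as.character(records$patient_id)
  list(train = pid[lab == "train"],
       validation = pid[lab == "validation"],
       test = pid[lab == "test"])
}

eval_variant_split <- function(scores, times, events, cutoff, horizons) {
  out <- list(n = length(scores))
  out$c_index <- tryCatch(harrell_c(scores, times, events),
                          error = function(e) NULL)
  out$auc <- vapply(horizons, function(h)
    tryCatch(time_dependent_auc(scores, times, events, h),
             error = function(e) NA_real_), 0)
  names(out$auc) <- paste0("t", horizons)
  out$stratification <- tryCatch(
    logrank_and_hr(times, events, stratify(scores, cutoff)),
    error = function(e) NULL)
  out$cutoff <- cutoff
  out
}

#' Run the full prognostic pipeline on a synthetic cohort
#'
#' Generates phantoms, assembles slice packs, splits by center, trains the
#' static and dynamic imaging networks on the training split, fits the
#' clinical Cox model and the bivariate fusions on the training split,
#' freezes the training-median cutoffs, and evaluates all five model
#' variants (cln, rad_s, rad_d, radcln_s, radcln_d) on every split:
#' C-index, time-dependent AUC at the requested horizons, and the
#' cutoff-stratified log-rank/hazard-ratio.
#'
#' @param phantom_cfg a [phantom_config()].
#' @param net_cfg a [net_config()] used for the dynamic network; the static
#'   network reuses it with `variant = "rad_s"`.
#' @param split a [split_spec()].
#' @param horizons evaluation horizons in days (default 365 and 730).
#' @param verbose print progress.
#' @return list of class `pipeline_result` with `metrics` (per variant, per
#'   split), `scores` (long data frame), `cutoffs`, `splits`, `selection`
#'   (per-patient slice-selection report), `fits` and `cohort`.
#' @export
run_pipeline <- function(phantom_cfg, net_cfg,
                         split = split_spec(), horizons = c(365, 730),
                         verbose = FALSE) {
  cohort <- generate_cohort(phantom_cfg)
  records <- cohort$records
  packs <- lapply(cohort$volumes, assemble_pack)
  names(packs) <- vapply(packs, `[[`, "", "patient_id")
  splits <- split_cohort(records, split)
  tr <- splits$train
  if (length(tr) < 2) stop("pipeline: training split too small")
  rows <- function(ids) match(ids, records$patient_id)

  if (verbose) message("training rad_d ...")
  cfg_d <- net_cfg; cfg_d$variant <- "rad_d"
  fit_d <- train_survnet(packs[tr], records[rows(tr), ], cfg_d)
  if (verbose) message("training rad_s ...")
  cfg_s <- net_cfg; cfg_s$variant <- "rad_s"
  fit_s <- train_survnet(packs[tr], records[rows(tr), ], cfg_s)

  cln_fit <- fit_cox(as.matrix(records[rows(tr), names(hcc_clinical_coefficients())]),
                     records$os_days[rows(tr)], records$event[rows(tr)])

  all_ids <- as.character(records$patient_id)
  sc <- list(
    cln = clinical_scores(records, cln_fit)$score,
    rad_s = predict_survnet(fit_s, packs[all_ids])$score,
    rad_d = predict_survnet(fit_d, packs[all_ids])$score)
  it <- rows(tr)
  fus_d <- fit_fusion(sc$rad_d[it], sc$cln[it],
                      records$os_days[it], records$event[it])
  fus_s <- fit_fusion(sc$rad_s[it], sc$cln[it],
                      records$os_days[it], records$event[it])
  sc$radcln_d <- fuse(sc$rad_d, sc$cln, fus_d)
  sc$radcln_s <- fuse(sc$rad_s, sc$cln, fus_s)

  cutoffs <- vapply(sc, function(s) median(s[it]), 0)

  metrics <- list()
  for (v in names(sc)) {
    metrics[[v]] <- list()
    for (sp in names(splits)) {
      ids <- splits[[sp]]
      if (length(ids) == 0) next
      ir <- rows(ids)
      metrics[[v]][[sp]] <- eval_variant_split(
        sc[[v]][ir], records$os_days[ir], records$event[ir],
        cutoffs[[v]], horizons)
    }
  }

  scores_df <- do.call(rbind, lapply(names(sc), function(v)
    data.frame(patient_id = all_ids, score = sc[[v]], variant = v)))
  selection <- lapply(packs, function(p)
    list(patient_id = p$patient_id, selected_indices = p$selected_indices,
         selection_basis = p$selection_basis, locf_applied = p$locf_applied))

  structure(list(metrics = metrics, scores = scores_df, cutoffs = cutoffs,
                 splits = splits, selection = unname(selection),
                 fits = list(rad_d = fit_d, rad_s = fit_s, cln = cln_fit,
                             fusion_d = fus_d, fusion_s = fus_s),
                 horizons = horizons, cohort = cohort),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (v in names(x$metrics)) {
    for (sp in names(x$metrics[[v]])) {
      m <- x$metrics[[v]][[sp]]
      ci <- if (is.null(m$c_index)) NA_real_ else m$c_index$c_index
      cat(sprintf("  %-9s %-10s n=%3d C=%.3f AUC(%s)=%s\n", v, sp, m$n, ci,
                  paste(x$horizons, collapse = ","),
                  paste(sprintf("%.3f", m$auc), collapse = ",")))
    }
  }
  invisible(x)
}
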