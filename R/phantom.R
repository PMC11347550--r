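#' Configuration for the synthetic CT phantom cohort
#'
#' Defines the generative model behind [generate_cohort()]: venous-phase-like
#' abdomen and chest volumes at 5-mm slice thickness, ellipsoidal liver/lung
#' organ masks, 0-3 spherical tumors per organ that grow (or shrink) by a
#' per-patient multiplicative factor between baseline and follow-up, seven
#' clinical covariates, and right-censored survival times whose log-hazard is
#' a known linear function of log tumor burden, log volume growth, and the
#' clinical covariates.
#'
#' @param n_patients number of patients (>= 1).
#' @param volume_shape integer (z, y, x) voxel grid, each >= 8.
#' @param slice_thickness_mm axial (z) voxel spacing in mm.
#' @param pixel_spacing_mm in-plane (y, x) voxel spacing in mm.
#' @param organ_hu named list `organ -> c(mean HU, sd HU)`.
#' @param tumor_hu named numeric, mean HU of tumor tissue per organ (noise sd
#'   is inherited from the organ).
#' @param background_hu `c(mean, sd)` HU outside the organ.
#' @param tumor_count_range named list `organ -> c(min, max)` tumors, or a
#'   single `c(min, max)` applied to both organs.
#' @param tumor_radius_range_mm `c(min, max)` baseline tumor radius in mm.
#' @param growth_factor_range `c(min, max)` multiplicative radius change from
#'   baseline to follow-up, drawn uniformly per patient.
#' @param beta_volume log-hazard coefficient on
#'   `log1p(baseline tumor volume mm^3) - log1p(1e4)` (10 mL reference keeps
#'   the linear predictor near zero for typical burden).
#' @param beta_growth log-hazard coefficient on `log(V_followup / V_baseline)`
#'   (equal to three times the log growth factor for spherical tumors).
#' @param beta_clinical named 7-vector of clinical log-hazard coefficients;
#'   defaults to the published clinical Cox coefficients
#'   (see [hcc_clinical_coefficients()]).
#' @param clinical_prevalence named list of marginal covariate distributions:
#'   `differentiation` is a 4-vector of multinomial probabilities over codes
#'   0-3 (high, moderate, low, undifferentiated); the six binary covariates
#'   are Bernoulli probabilities. Defaults follow the trial cohort marginals.
#' @param baseline_hazard_rate constant baseline hazard (1/days); events are
#'   exponential with rate `baseline_hazard_rate * exp(linear predictor)`.
#' @param censoring_horizon_days censoring times are uniform on
#'   `(0, censoring_horizon_days)`, independent of the event time.
#' @param p_missing_chest_followup probability that the follow-up chest scan
#'   is absent (handled downstream by LOCF).
#' @param n_centers number of synthetic recruiting centers (used for
#'   center-level data splits).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return an object of class `phantom_config`.
#' @seealso [generate_cohort()], [size_based_progression()]
#' @export
phantom_config <- function(n_patients,
                           volume_shape = c(32L, 64L, 64L),
                           slice_thickness_mm = 5,
                           pixel_spacing_mm = c(1.5, 1.5),
                           organ_hu = list(liver = c(100, 12), lung = c(-700, 60)),
                           tumor_hu = c(liver = 60, lung = 20),
                           background_hu = c(0, 15),
                           tumor_count_range = list(liver = c(1L, 3L), lung = c(0L, 2L)),
                           tumor_radius_range_mm = c(4, 12),
                           growth_factor_range = c(0.8, 1.6),
                           beta_volume = 0.5,
                           beta_growth = 1.0,
                           beta_clinical = hcc_clinical_coefficients(),
                           clinical_prevalence = list(
                             differentiation = c(0.14, 0.74, 0.11, 0.01),
                             nash_nafld = 0.17, surgery = 0.53, pvtt = 0.17,
                             ebrt = 0.05, tae_tace = 0.58, rfa_mwa = 0.28),
                           baseline_hazard_rate = 1 / 475,
                           censoring_horizon_days = 1095,
                           p_missing_chest_followup = 0.15,
                           n_centers = 10L,
                           seed = 1L) {
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 1)
    stop("invalid config: n_patients must be >= 1")
  if (length(volume_shape) != 3L || any(volume_shape < 8))
    stop("invalid config: volume_shape must be (z, y, x) with all >= 8")
  if (slice_thickness_mm <= 0 || any(pixel_spacing_mm <= 0))
    stop("invalid config: voxel spacings must be positive")
  if (!is.list(tumor_count_range))
    tumor_count_range <- list(liver = tumor_count_range, lung = tumor_count_range)
  for (org in ORGANS) {
    rng <- tumor_count_range[[org]]
    if (length(rng) != 2L || any(rng < 0) || rng[1] > rng[2])
      stop("invalid config: tumor_count_range must be 0 <= min <= max")
  }
  if (any(tumor_radius_range_mm <= 0) ||
      tumor_radius_range_mm[1] > tumor_radius_range_mm[2])
    stop("invalid config: tumor_radius_range_mm must be positive with min <= max")
  if (growth_factor_range[1] <= 0 || growth_factor_range[1] > growth_factor_range[2])
    stop("invalid config: growth_factor_range must be positive with min <= max")
  if (p_missing_chest_followup < 0 || p_missing_chest_followup > 1)
    stop("invalid config: p_missing_chest_followup must be in [0, 1]")
  if (length(beta_clinical) != 7L)
    stop("invalid config: beta_clinical must have 7 entries")
  if (baseline_hazard_rate <= 0 || censoring_horizon_days <= 0)
    stop("invalid config: hazard rate and censoring horizon must be positive")
  structure(list(
    n_patients = as.integer(n_patients),
    volume_shape = as.integer(volume_shape),
    slice_thickness_mm = slice_thickness_mm,
    pixel_spacing_mm = pixel_spacing_mm,
    organ_hu = organ_hu, tumor_hu = tumor_hu, background_hu = background_hu,
    tumor_count_range = tumor_count_range,
    tumor_radius_range_mm = tumor_radius_range_mm,
    growth_factor_range = growth_factor_range,
    beta_volume = beta_volume, beta_growth = beta_growth,
    beta_clinical = beta_clinical,
    clinical_prevalence = clinical_prevalence,
    baseline_hazard_rate = baseline_hazard_rate,
    censoring_horizon_days = censoring_horizon_days,
    p_missing_chest_followup = p_missing_chest_followup,
    n_centers = as.integer(n_centers),
    seed = as.integer(seed)),
    class = "phantom_config")
}

# reference tumor burden (mm^3) at which the volume term of the linear
# predictor is zero: 10 mL, a mid-range multifocal burden
.VOLUME_REF_MM3 <- 1e4

# binary ellipsoid mask on a (z, y, x) voxel grid; semi_axes in voxels
ellipsoid_mask <- function(shape, center, semi_axes) {
  z <- (seq_len(shape[1]) - center[1]) / semi_axes[1]
  y <- (seq_len(shape[2]) - center[2]) / semi_axes[2]
  x <- (seq_len(shape[3]) - center[3]) / semi_axes[3]
  d2 <- outer(outer(z^2, y^2, "+"), x^2, "+")
  array(d2 <= 1, shape)
}

# rejection-sample tumor centers so the whole (grown) tumor stays inside the
# organ; after 100 failed placements the radius is shrunk by 20% and the
# budget reset, guaranteeing termination for any nonempty organ
place_tumors <- function(organ_mask, n_tumors, radii_mm, growth, spacing) {
  shape <- dim(organ_mask)
  inside <- which(organ_mask)
  centers <- matrix(0, 0, 3)
  radii <- numeric(0)
  for (k in seq_len(n_tumors)) {
    r <- radii_mm[k]
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      idx <- inside[sample.int(length(inside), 1L)]
      ctr <- arrayInd(idx, shape)[1, ]
      r_eff <- r * max(1, growth)
      tm <- ellipsoid_mask(shape, ctr, pmax(r_eff / spacing, 0.51))
      if (!any(tm & !organ_mask)) {
        centers <- rbind(centers, ctr)
        radii <- c(radii, r)
        break
      }
      if (attempts >= 100L) {
        r <- r * 0.8
        attempts <- 0L
        if (r < 0.5) { # pathological organ; skip this tumor
          r <- NA_real_
          break
        }
      }
    }
    if (is.na(r)) next
  }
  list(centers = centers, radii_mm = radii)
}

tumor_mask_from <- function(shape, centers, radii_mm, spacing) {
  tm <- array(FALSE, shape)
  for (k in seq_len(length(radii_mm))) {
    tm <- tm | ellipsoid_mask(shape, centers[k, ], pmax(radii_mm[k] / spacing, 0.51))
  }
  tm
}

draw_hu_volume <- function(organ_mask, tumor_mask, organ_hu, tumor_mu, bg) {
  shape <- dim(organ_mask)
  vol <- array(rnorm(prod(shape), bg[1], bg[2]), shape)
  n_org <- sum(organ_mask)
  if (n_org > 0)
    vol[organ_mask] <- rnorm(n_org, organ_hu[1], organ_hu[2])
  n_tum <- sum(tumor_mask)
  if (n_tum > 0)
    vol[tumor_mask] <- rnorm(n_tum, tumor_mu, organ_hu[2])
  vol
}

#' Generate a synthetic two-timepoint CT cohort with a known hazard
#'
#' Draws, per patient: ellipsoidal liver and lung organ masks in separate
#' abdomen/chest volumes, spherical tumors grown by a per-patient factor at
#' follow-up, HU volumes with Gaussian voxel noise, seven clinical covariates,
#' and right-censored overall survival. Event times are exponential with rate
#' `baseline_hazard_rate * exp(lp)` where the true linear predictor is
#' `lp = beta_volume * (log1p(V_base) - log1p(1e4)) + beta_growth *
#' log(V_fu / V_base) + beta_clinical' x`; censoring is an independent
#' uniform time on `(0, censoring_horizon_days)`. The truth table returns
#' `lp` so recovery of the hazard ordering can be tested.
#'
#' @param config a [phantom_config()].
#' @return a list of class `phantom_cohort` with elements
#'   * `volumes`: list of `patient_volume_set` objects (HU volumes plus organ
#'     and tumor masks for liver/lung at baseline/follow-up; the follow-up
#'     chest entries are absent when `followup_chest_present` is `FALSE`),
#'   * `records`: data frame of clinical covariates, `os_days`, `event`,
#'     `center` and `followup_chest_present`,
#'   * `truth`: data frame with the true linear predictor `lp`, per-patient
#'     hazard `rate`, analytic tumor volumes and growth factor.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  set.seed(config$seed)
  shape <- config$volume_shape
  spacing <- c(config$slice_thickness_mm, config$pixel_spacing_mm)
  n <- config$n_patients
  prev <- config$clinical_prevalence

  volumes <- vector("list", n)
  rec <- vector("list", n)
  truth <- vector("list", n)
  for (p in seq_len(n)) {
    pid <- sprintf("P%04d", p)
    growth <- runif(1, config$growth_factor_range[1], config$growth_factor_range[2])
    vols <- list(); omasks <- list(); tmasks <- list()
    v_base <- 0; v_fu <- 0
    for (org in ORGANS) {
      axes <- c(0.38, 0.30, 0.38) * shape * runif(3, 0.9, 1.1)
      ctr <- shape / 2 + runif(3, -1, 1)
      om <- ellipsoid_mask(shape, ctr, axes)
      n_rng <- config$tumor_count_range[[org]]
      n_tum <- if (n_rng[1] == n_rng[2]) n_rng[1] else
        sample(seq(n_rng[1], n_rng[2]), 1L)
      radii <- if (n_tum > 0)
        runif(n_tum, config$tumor_radius_range_mm[1], config$tumor_radius_range_mm[2])
        else numeric(0)
      pl <- place_tumors(om, n_tum, radii, growth, spacing)
      v_base <- v_base + sum(4 / 3 * pi * pl$radii_mm^3)
      v_fu <- v_fu + sum(4 / 3 * pi * (pl$radii_mm * growth)^3)
      for (tp in TIMEPOINTS) {
        r_tp <- if (tp == "baseline") pl$radii_mm else pl$radii_mm * growth
        tm <- tumor_mask_from(shape, pl$centers, r_tp, spacing) & om
        key <- vkey(org, tp)
        omasks[[key]] <- om
        tmasks[[key]] <- tm
        vols[[key]] <- draw_hu_volume(om, tm, config$organ_hu[[org]],
                                      config$tumor_hu[[org]], config$background_hu)
      }
    }
    chest_fu <- runif(1) >= config$p_missing_chest_followup
    if (!chest_fu) {
      key <- vkey("lung", "followup")
      vols[[key]] <- NULL; omasks[[key]] <- NULL; tmasks[[key]] <- NULL
    }

    x <- c(
      differentiation = sample(0:3, 1L, prob = prev$differentiation),
      nash_nafld = rbinom(1, 1, prev$nash_nafld),
      surgery = rbinom(1, 1, prev$surgery),
      pvtt = rbinom(1, 1, prev$pvtt),
      ebrt = rbinom(1, 1, prev$ebrt),
      tae_tace = rbinom(1, 1, prev$tae_tace),
      rfa_mwa = rbinom(1, 1, prev$rfa_mwa))

    lp <- config$beta_volume * (log1p(v_base) - log1p(.VOLUME_REF_MM3)) +
      config$beta_growth * (if (v_base > 0) log(v_fu / v_base) else 0) +
      sum(config$beta_clinical * x)
    rate <- config$baseline_hazard_rate * exp(lp)
    t_event <- rexp(1, rate)
    t_cens <- runif(1, 0, config$censoring_horizon_days)
    os <- min(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    volumes[[p]] <- structure(list(
      patient_id = pid, volumes = vols, organ_masks = omasks,
      tumor_masks = tmasks, followup_chest_present = chest_fu,
      spacing_mm = spacing), class = "patient_volume_set")
    rec[[p]] <- data.frame(patient_id = pid, t(x), os_days = os, event = event,
                           center = sample.int(config$n_centers, 1L),
                           followup_chest_present = chest_fu)
    truth[[p]] <- data.frame(patient_id = pid, lp = lp, rate = rate,
                             baseline_volume_mm3 = v_base,
                             followup_volume_mm3 = v_fu,
                             growth_factor = growth)
  }
  structure(list(volumes = volumes,
                 records = do.call(rbind, rec),
                 truth = do.call(rbind, truth),
                 config = config),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d patients, %d centers, %d events (%.0f%% censored)\n",
              nrow(x$records), length(unique(x$records$center)),
              sum(x$records$event), 100 * mean(1 - x$records$event)))
  invisible(x)
}

# longest in-plane (axial) diameter of a tumor mask, in mm; the maximum over
# slices of the largest pairwise distance between tumor voxel centers
longest_inplane_diameter <- function(mask, spacing) {
  d <- dim(mask)
  best <- 0
  for (z in seq_len(d[1])) {
    sl <- mask[z, , ]
    idx <- which(sl != 0, arr.ind = TRUE)
    if (nrow(idx) < 2) next
    pts <- cbind(idx[, 1] * spacing[2], idx[, 2] * spacing[3])
    if (nrow(pts) > 3) {
      hull <- grDevices::chull(pts)
      pts <- pts[hull, , drop = FALSE]
    }
    best <- max(best, max(dist(pts)))
  }
  best
}

#' Size-based progression call from two-timepoint tumor masks
#'
#' A simplified RECIST-like comparator: sums, over organs with both timepoints
#' available, the longest in-plane tumor diameter, and calls progression when
#' the follow-up sum has grown by at least 20% over a measurable baseline.
#' Patients with no measurable baseline disease are never called progressive.
#'
#' @param vols a `patient_volume_set`.
#' @return integer 0/1 progression label.
#' @export
size_based_progression <- function(vols) {
  stopifnot(inherits(vols, "patient_volume_set"))
  base_sum <- 0; fu_sum <- 0; any_organ <- FALSE
  for (org in ORGANS) {
    kb <- vkey(org, "baseline"); kf <- vkey(org, "followup")
    if (is.null(vols$tumor_masks[[kb]]) || is.null(vols$tumor_masks[[kf]])) next
    any_organ <- TRUE
    base_sum <- base_sum + longest_inplane_diameter(vols$tumor_masks[[kb]], vols$spacing_mm)
    fu_sum <- fu_sum + longest_inplane_diameter(vols$tumor_masks[[kf]], vols$spacing_mm)
  }
  if (!any_organ)
    stop("size_based_progression: no organ with tumor masks at both timepoints")
  if (base_sum <= 0) return(0L)
  as.integer(fu_sum >= 1.2 * base_sum - 1e-9)
}

#' Write a phantom cohort to disk
#'
#' Volumes and masks go to one NIfTI file per patient/organ/timepoint/kind;
#' clinical records and the ground-truth linear predictor go to CSV; the
#' configuration spacing and seed go to a small JSON sidecar.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- cohort$config$pixel_spacing_mm
  pixdim <- c(cohort$config$slice_thickness_mm, pd[1], pd[2])
  for (vs in cohort$volumes) {
    for (key in names(vs$volumes)) {
      base <- file.path(dir, paste0(vs$patient_id, "_", key))
      RNifti::writeNifti(RNifti::asNifti(vs$volumes[[key]], pixdim = pixdim),
                         paste0(base, "_ct.nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(vs$organ_masks[[key]] * 1L, pixdim = pixdim),
                         paste0(base, "_organmask.nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(vs$tumor_masks[[key]] * 1L, pixdim = pixdim),
                         paste0(base, "_tumormask.nii.gz"))
    }
  }
  write.csv(cohort$records, file.path(dir, "cohort.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(spacing_mm = pixdim, seed = cohort$config$seed,
                            n_patients = cohort$config$n_patients),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a phantom cohort written by [write_cohort()]
#'
#' @param dir directory produced by [write_cohort()].
#' @return a `phantom_cohort`-like list with `volumes`, `records` and (when
#'   present) `truth`; the generating configuration is not reconstructed.
#' @export
read_cohort <- function(dir) {
  records <- read.csv(file.path(dir, "cohort.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) read.csv(truth_path) else NULL
  volumes <- lapply(seq_len(nrow(records)), function(i) {
    pid <- records$patient_id[i]
    vols <- list(); omasks <- list(); tmasks <- list()
    for (org in ORGANS) for (tp in TIMEPOINTS) {
      key <- vkey(org, tp)
      f <- file.path(dir, paste0(pid, "_", key, "_ct.nii.gz"))
      if (!file.exists(f)) next
      vols[[key]] <- array(as.numeric(RNifti::readNifti(f)),
                           dim = dim(RNifti::readNifti(f)))
      om <- RNifti::readNifti(file.path(dir, paste0(pid, "_", key, "_organmask.nii.gz")))
      tm <- RNifti::readNifti(file.path(dir, paste0(pid, "_", key, "_tumormask.nii.gz")))
      omasks[[key]] <- array(as.numeric(om) > 0.5, dim = dim(om))
      tmasks[[key]] <- array(as.numeric(tm) > 0.5, dim = dim(tm))
    }
    structure(list(patient_id = pid, volumes = vols, organ_masks = omasks,
                   tumor_masks = tmasks,
                   followup_chest_present = isTRUE(records$followup_chest_present[i]),
                   spacing_mm = meta$spacing_mm),
              class = "patient_volume_set")
  })
  structure(list(volumes = volumes, records = records, truth = truth,
                 config = NULL), class = "phantom_cohort")
}
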