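# shared fixtures; heavier objects are built lazily and memoized so the
# cost is paid once per test run
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_phantom_config <- function(n = 6, seed = 101, ...) {
  phantom_config(n_patients = n, volume_shape = c(12L, 32L, 32L),
                 tumor_radius_range_mm = c(3, 8), seed = seed, ...)
}

small_cohort <- function() {
  # elevated missing-chest probability so both the LOCF and the ordinary
  # path occur in a 6-patient fixture
  memo("small_cohort", function()
    generate_cohort(small_phantom_config(p_missing_chest_followup = 0.5)))
}

small_packs <- function() {
  memo("small_packs", function() lapply(small_cohort()$volumes, assemble_pack))
}

vol_only_cohort <- function() {
  memo("vol_only_cohort", function()
    generate_cohort(phantom_config(n_patients = 500, volume_shape = c(8, 8, 8),
                                   tumor_radius_range_mm = c(1, 4),
                                   tumor_count_range = list(liver = c(1, 3), lung = c(0, 2)),
                                   beta_volume = 1, beta_growth = 0,
                                   beta_clinical = rep(0, 7), seed = 9)))
}

null_cohort <- function() {
  memo("null_cohort", function()
    generate_cohort(phantom_config(n_patients = 500, volume_shape = c(8, 8, 8),
                                   tumor_radius_range_mm = c(1, 4),
                                   beta_volume = 0, beta_growth = 0,
                                   beta_clinical = rep(0, 7), seed = 10)))
}

tiny_net_config <- function(variant = "rad_d", ...) {
  net_config(variant = variant, input_size = 16L,
             conv_channels = c(4L, 6L, 8L, 8L), embed_dim = 12L,
             recurrent_hidden = 6L, head_dims = c(8L, 1L), seed = 5L, ...)
}

# direct small tensors at backbone resolution, bypassing pack assembly
fake_tensor <- function(cfg, seed = 1) {
  set.seed(seed)
  tens <- list()
  for (key in ctprog:::svn_keys(cfg$variant)) {
    tens[[key]] <- lapply(1:3, function(i)
      matrix(rnorm(cfg$input_size^2), cfg$input_size, cfg$input_size))
  }
  tens
}

# exhaustive oracle for the slice-selection rules: ranks tumor slices by
# area then unchosen organ slices by area, ties to the smaller index
oracle_select <- function(a_t, a_o, k = 3) {
  depth <- length(a_t)
  k_eff <- min(k, depth)
  cand_t <- which(a_t > 0)
  cand_t <- cand_t[order(-a_t[cand_t], cand_t)]
  sel <- head(cand_t, k_eff)
  basis <- rep("tumor_area", length(sel))
  cand_o <- setdiff(which(a_o > 0), sel)
  cand_o <- cand_o[order(-a_o[cand_o], cand_o)]
  add <- head(cand_o, k_eff - length(sel))
  sel <- c(sel, add)
  basis <- c(basis, rep("organ_area", length(add)))
  while (length(sel) < k_eff) {
    sel <- c(sel, sel[length(sel)])
    basis <- c(basis, "padded")
  }
  list(indices = as.integer(sel), basis = basis)
}

# brute-force longest in-plane diameter: all voxel pairs, no convex hull
oracle_diameter <- function(mask, spacing) {
  best <- 0
  for (z in seq_len(dim(mask)[1])) {
    idx <- which(mask[z, , ] != 0, arr.ind = TRUE)
    if (nrow(idx) < 2) next
    pts <- cbind(idx[, 1] * spacing[2], idx[, 2] * spacing[3])
    for (i in seq_len(nrow(pts) - 1)) for (j in (i + 1):nrow(pts)) {
      best <- max(best, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    }
  }
  best
}

# random mask pair on a small grid for property tests
random_mask_pair <- function(depth = 6, side = 8) {
  org <- array(runif(depth * side * side) < 0.5, c(depth, side, side))
  while (!any(org)) org <- array(runif(depth * side * side) < 0.5, c(depth, side, side))
  tum <- org & array(runif(depth * side * side) < 0.2, c(depth, side, side))
  list(tumor = tum, organ = org)
}

# small continuous-time survival dataset without ties
sim_surv <- function(n, beta = 0.7, cens_rate = 0.01) {
  x <- rnorm(n)
  tt <- rexp(n, exp(beta * x) / 100)
  ce <- rexp(n, cens_rate)
  list(x = x, times = pmin(tt, ce), events = as.integer(tt <= ce))
}
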