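#' CT display window specification
#'
#' @param width window width (WW) in HU, must be positive.
#' @param level window level (WL) in HU.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(width, level) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("invalid window: width must be a positive scalar")
  structure(list(width = width, level = level), class = "window_spec")
}

#' @rdname window_spec
#' @details `abdomen_window()` (WW 400, WL 0) and `chest_window()`
#'   (WW 1200, WL -600) are the venous-phase abdomen and chest settings used
#'   throughout the pipeline.
#' @export
abdomen_window <- function() window_spec(400, 0)

#' @rdname window_spec
#' @export
chest_window <- function() window_spec(1200, -600)

#' Resample a volume to 5-mm axial spacing by linear interpolation along z
#'
#' Only the z axis is resampled; in-plane sampling is untouched. The output
#' grid starts at the first input slice and covers the input z extent to
#' within one output slice.
#'
#' @param volume 3D array ordered (z, y, x).
#' @param spacing_mm numeric (z, y, x) voxel spacing of `volume`, all > 0.
#' @param target_mm desired axial spacing (default 5).
#' @return 3D array at `target_mm` axial spacing.
#' @export
resample_axial <- function(volume, spacing_mm, target_mm = 5) {
  if (any(spacing_mm <= 0)) stop("invalid input: spacing_mm must be positive")
  d <- dim(volume)
  if (length(d) != 3L) stop("invalid input: volume must be 3D (z, y, x)")
  sz <- spacing_mm[1]
  if (abs(sz - target_mm) < 1e-9) return(volume)
  extent <- (d[1] - 1) * sz
  n_out <- floor(extent / target_mm + 1e-9) + 1L
  pos <- (seq_len(n_out) - 1) * target_mm / sz + 1
  i0 <- pmin(floor(pos), d[1])
  w <- pos - i0
  i1 <- pmin(i0 + 1L, d[1])
  out <- array(0, c(n_out, d[2], d[3]))
  for (k in seq_len(n_out)) {
    out[k, , ] <- (1 - w[k]) * volume[i0[k], , ] + w[k] * volume[i1[k], , ]
  }
  out
}

#' Map HU values into [0, 1] with a window width/level transform
#'
#' `out = clip((HU - (level - width/2)) / width, 0, 1)`; monotone
#' non-decreasing in HU, with the window endpoints mapping to 0 and 1.
#'
#' @param x HU array of any shape.
#' @param spec a [window_spec()].
#' @return array of the same shape with values in `[0, 1]`.
#' @export
apply_window <- function(x, spec) {
  if (!inherits(spec, "window_spec")) stop("invalid input: spec must be a window_spec")
  lo <- spec$level - spec$width / 2
  pmin(pmax((x - lo) / spec$width, 0), 1)
}

#' Select representative axial slices from tumor and organ masks
#'
#' Slices containing tumor are ranked by axial tumor area (descending) and
#' fill the selection first (basis tag `"tumor_area"`); remaining positions
#' are filled by not-yet-chosen slices ranked by organ area (descending,
#' basis tag `"organ_area"`). Ties are broken by the smaller axial index.
#' If fewer than `k` slices contain any organ or tumor, the last selected
#' index is repeated with basis tag `"padded"`.
#'
#' @param tumor_mask,organ_mask binary 3D arrays (z, y, x) of equal shape;
#'   the organ mask must be nonempty.
#' @param k number of slices to select (default 3); at most the volume depth.
#' @return list with integer `indices` (length `min(k, depth)`) and
#'   character `basis` tags.
#' @export
select_slices <- function(tumor_mask, organ_mask, k = 3L) {
  d <- dim(organ_mask)
  if (!identical(dim(tumor_mask), d))
    stop("invalid input: masks must share one shape")
  a_t <- rowSums(matrix(tumor_mask, nrow = d[1]))
  a_o <- rowSums(matrix(organ_mask, nrow = d[1]))
  if (all(a_o == 0)) stop("no-organ: organ mask is empty")
  k_eff <- min(k, d[1])
  tum <- which(a_t > 0)
  tum <- tum[order(-a_t[tum], tum)]
  sel <- head(tum, k_eff)
  basis <- rep("tumor_area", length(sel))
  if (length(sel) < k_eff) {
    rest <- setdiff(which(a_o > 0), sel)
    rest <- rest[order(-a_o[rest], rest)]
    add <- head(rest, k_eff - length(sel))
    sel <- c(sel, add)
    basis <- c(basis, rep("organ_area", length(add)))
  }
  while (length(sel) < k_eff) { # degenerate: fewer mask-bearing slices than k
    sel <- c(sel, sel[length(sel)])
    basis <- c(basis, "padded")
  }
  list(indices = as.integer(sel), basis = basis)
}

# bilinear resize of a 2D matrix to size x size
resize_bilinear <- function(m, size) {
  if (all(dim(m) == size)) return(m)
  as.matrix(EBImage::resize(m, w = size, h = size))
}

# per-image standardization to mean 0, variance 1; constant images map to 0
standardize_image <- function(m) {
  s <- sd(m)
  if (!is.finite(s) || s < 1e-12) return(m * 0)
  (m - mean(m)) / s
}

#' Assemble the model-ready 12-image pack for one patient
#'
#' Per organ and timepoint: resample the volume and masks to 5-mm axial
#' spacing, apply the organ's HU window, select three representative axial
#' slices from the masks, resize each slice to `target_size` x `target_size`
#' (bilinear), and standardize each image to mean 0 / variance 1. When the
#' follow-up chest scan is absent the processed lung baseline images are
#' carried forward (LOCF) and `locf_applied` is set.
#'
#' @param vols a `patient_volume_set` with baseline volumes for both organs.
#' @param windows named list `organ -> window_spec`; defaults to the abdomen
#'   window for liver and the chest window for lung.
#' @param target_size output image side (default 224).
#' @return an object of class `slice_pack` with `images` (per organ/timepoint
#'   lists of three standardized matrices), `selected_indices`,
#'   `selection_basis` and `locf_applied`.
#' @export
assemble_pack <- function(vols,
                          windows = list(liver = abdomen_window(),
                                         lung = chest_window()),
                          target_size = 224L) {
  stopifnot(inherits(vols, "patient_volume_set"))
  spacing <- vols$spacing_mm
  images <- list(); sel_idx <- list(); sel_basis <- list()
  locf <- FALSE
  for (org in ORGANS) {
    if (is.null(vols$volumes[[vkey(org, "baseline")]]))
      stop(sprintf("missing baseline %s volume: inclusion criterion violated", org))
    for (tp in TIMEPOINTS) {
      key <- vkey(org, tp)
      if (org == "lung" && tp == "followup" && !isTRUE(vols$followup_chest_present)) {
        kb <- vkey("lung", "baseline")
        images[[key]] <- images[[kb]]
        sel_idx[[key]] <- sel_idx[[kb]]
        sel_basis[[key]] <- sel_basis[[kb]]
        locf <- TRUE
        next
      }
      vol <- vols$volumes[[key]]
      if (is.null(vol)) stop(sprintf("missing %s volume", key))
      om <- vols$organ_masks[[key]]
      tm <- vols$tumor_masks[[key]]
      if (abs(spacing[1] - 5) > 1e-9) {
        vol <- resample_axial(vol, spacing)
        om <- resample_axial(om * 1, spacing) > 0.5
        tm <- resample_axial(tm * 1, spacing) > 0.5
      }
      wv <- apply_window(vol, windows[[org]])
      sel <- select_slices(tm, om, 3L)
      images[[key]] <- lapply(sel$indices, function(z)
        standardize_image(resize_bilinear(wv[z, , ], target_size)))
      sel_idx[[key]] <- sel$indices
      sel_basis[[key]] <- sel$basis
    }
  }
  structure(list(patient_id = vols$patient_id, images = images,
                 selected_indices = sel_idx, selection_basis = sel_basis,
                 locf_applied = locf),
            class = "slice_pack")
}

#' @export
print.slice_pack <- function(x, ...) {
  cat(sprintf("slice_pack %s: %d images%s\n", x$patient_id,
              sum(vapply(x$images, length, 1L)),
              if (x$locf_applied) " (lung follow-up carried forward)" else ""))
  invisible(x)
}

flip_horizontal <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

#' Random horizontal flip augmentation of a slice pack
#'
#' Each image is independently mirrored left-right with probability `p`.
#' Intended for training only; evaluation uses the unaugmented pack.
#'
#' @param pack a `slice_pack`.
#' @param p flip probability in `[0, 1]` (default 0.5).
#' @param seed optional seed making the augmentation deterministic without
#'   disturbing the caller's RNG stream.
#' @return the augmented `slice_pack`.
#' @export
augment_flip <- function(pack, p = 0.5, seed = NULL) {
  stopifnot(inherits(pack, "slice_pack"))
  if (p < 0 || p > 1) stop("invalid input: p must be in [0, 1]")
  do_flip <- function() {
    for (key in names(pack$images)) {
      pack$images[[key]] <<- lapply(pack$images[[key]], function(m)
        if (runif(1) < p) flip_horizontal(m) else m)
    }
  }
  if (is.null(seed)) do_flip() else with_seed(seed, do_flip())
  pack
}
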