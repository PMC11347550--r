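#' Grad-CAM heatmaps for the risk score
#'
#' For every slice in the pack: the gradient of the scalar risk score with
#' respect to the backbone's last convolutional activations is global-average
#' pooled into channel weights, the weighted channel sum is rectified
#' (negative evidence clipped to zero), bilinearly upsampled to the input
#' resolution, and min-max normalized to `[0, 1]`. A map with zero gradient
#' everywhere comes back all-zero with a warning. Because of the final
#' normalization, rescaling the network head by any positive constant leaves
#' the maps unchanged.
#'
#' @param pack a `slice_pack`.
#' @param fit a `survnet_fit` (or a list with `params` and `config`).
#' @param target_size output heatmap side (default: the pack's image side).
#' @return list of `heatmap` objects: `values` (matrix in `[0, 1]`),
#'   `organ`, `timepoint`, `slice` (1-3 within the selection),
#'   `slice_index` (axial index in the volume), and the pack's `score`.
#' @export
grad_cam <- function(pack, fit, target_size = NULL) {
  stopifnot(inherits(pack, "slice_pack"))
  config <- fit$config; params <- fit$params
  if (is.null(target_size)) target_size <- nrow(pack$images[[1]][[1]])
  tens <- svn_pack_tensor(pack, config)
  fw <- svn_forward_tensor(tens, params, config, keep_cache = TRUE)
  bk <- svn_backward_tensor(fw, params, config, dscore = 1, keep_dact = TRUE)
  maps <- list()
  for (key in names(fw$slice_caches)) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    for (s in 1:3) {
      A <- fw$slice_caches[[key]][[s]]$caches[[length(config$conv_channels)]]$act
      dA <- bk$dacts[[key]][[s]]
      alpha <- colMeans(matrix(dA, prod(dim(dA)[1:2]), dim(dA)[3]))
      m <- matrix(0, dim(A)[1], dim(A)[2])
      for (ch in seq_along(alpha)) m <- m + alpha[ch] * A[, , ch]
      m <- pmax(m, 0)
      up <- resize_bilinear(m, target_size)
      rng <- range(up)
      if (rng[2] - rng[1] < 1e-12) {
        warning(sprintf("grad_cam: constant map for %s slice %d", key, s))
        up <- up * 0
      } else {
        up <- (up - rng[1]) / (rng[2] - rng[1])
      }
      maps[[length(maps) + 1L]] <- structure(
        list(values = up, organ = parts[1], timepoint = parts[2], slice = s,
             slice_index = pack$selected_indices[[key]][s], score = fw$score),
        class = "heatmap")
    }
  }
  maps
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("heatmap %s/%s slice %d (z=%d), %dx%d\n", x$organ, x$timepoint,
              x$slice, x$slice_index, nrow(x$values), ncol(x$values)))
  invisible(x)
}
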