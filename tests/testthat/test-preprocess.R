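test_that("windowing maps endpoints, midpoint and known HU values correctly", {
  ab <- abdomen_window()
  expect_equal(apply_window(-200, ab), 0)
  expect_equal(apply_window(200, ab), 1)
  expect_equal(apply_window(100, ab), 0.75) # (100 - (-200)) / 400
  ch <- chest_window()
  expect_equal(apply_window(-600, ch), 0.5) # level maps to midpoint
  x <- seq(-1500, 1500, by = 10)
  w <- apply_window(x, ch)
  expect_true(all(diff(w) >= 0))            # monotone in HU
  expect_true(all(w >= 0 & w <= 1))
  # re-windowing a [0,1] image with (width 1, level 0.5) is the identity
  expect_equal(apply_window(w, window_spec(1, 0.5)), w)
  expect_error(window_spec(0, 0), "width")
})

test_that("axial resampling: identity at 5 mm, exact on linear ramps, constant-preserving", {
  vol <- array(rnorm(6 * 4 * 4), c(6, 4, 4))
  expect_identical(resample_axial(vol, c(5, 1, 1)), vol)
  # 2.5-mm input linear in z: values at the 5-mm grid follow the same line
  ramp <- array(rep(seq(0, 10, length.out = 9), 16), c(9, 4, 4))
  out <- resample_axial(ramp, c(2.5, 1, 1))
  z_mm <- (seq_len(dim(out)[1]) - 1) * 5
  expect_equal(out[, 1, 1], z_mm * 10 / 20)
  expect_lte(abs((dim(out)[1] - 1) * 5 - (9 - 1) * 2.5), 5) # extent within a slice
  cvol <- array(3.3, c(7, 4, 4))
  expect_true(all(resample_axial(cvol, c(3.1, 1, 1)) == 3.3))
  expect_error(resample_axial(vol, c(0, 1, 1)), "spacing")
})

test_that("slice selection follows the tumor-then-organ ranking with index tie-breaks", {
  mk <- function(areas, side = 7) {
    m <- array(FALSE, c(length(areas), side, side))
    for (z in seq_along(areas)) if (areas[z] > 0) {
      sl <- matrix(FALSE, side, side)
      sl[seq_len(areas[z])] <- TRUE
      m[z, , ] <- sl
    }
    m
  }
  full <- function(n, side = 7) array(TRUE, c(n, side, side))
  s1 <- select_slices(mk(c(0, 5, 9, 2)), full(4))
  expect_identical(s1$indices, c(3L, 2L, 4L))
  expect_identical(s1$basis, rep("tumor_area", 3))
  s2 <- select_slices(mk(c(0, 0, 0, 0)), mk(c(10, 40, 40, 5), side = 7))
  expect_identical(s2$indices, c(2L, 3L, 1L)) # tie at 40 broken by smaller z
  expect_identical(s2$basis, rep("organ_area", 3))
  s3 <- select_slices(mk(c(0, 7, 0, 0)), mk(c(9, 1, 8, 3)))
  expect_identical(s3$indices, c(2L, 1L, 3L)) # tumor slice not reused
  expect_identical(s3$basis, c("tumor_area", "organ_area", "organ_area"))
  expect_error(select_slices(mk(c(0, 0)), mk(c(0, 0))), "no-organ")
  # degenerate: single organ-bearing slice is padded
  s4 <- select_slices(mk(c(0, 0, 0)), mk(c(0, 4, 0)))
  expect_identical(s4$indices, c(2L, 2L, 2L))
  expect_identical(s4$basis, c("organ_area", "padded", "padded"))
})

test_that("slice selection equals the brute-force oracle on random mask pairs", {
  set.seed(404)
  for (r in 1:200) {
    mp <- random_mask_pair()
    if (!any(mp$organ)) next
    a_t <- rowSums(matrix(mp$tumor, nrow = dim(mp$tumor)[1]))
    a_o <- rowSums(matrix(mp$organ, nrow = dim(mp$organ)[1]))
    got <- select_slices(mp$tumor, mp$organ)
    exp_ <- oracle_select(a_t, a_o)
    expect_identical(got$indices, exp_$indices)
    expect_identical(got$basis, exp_$basis)
  }
})

test_that("assembled packs hold 12 standardized 224x224 images with valid provenance", {
  packs <- small_packs()
  co <- small_cohort()
  for (i in seq_along(packs)) {
    p <- packs[[i]]
    expect_equal(sum(vapply(p$images, length, 1L)), 12L)
    depth <- dim(co$volumes[[i]]$volumes[["liver_baseline"]])[1]
    for (key in names(p$images)) {
      for (img in p$images[[key]]) {
        expect_identical(dim(img), c(224L, 224L))
        if (sd(img) > 0) {
          expect_lt(abs(mean(img)), 1e-5)
          expect_lt(abs(var(as.vector(img)) - 1), 1e-5)
        }
      }
      idx <- p$selected_indices[[key]]
      expect_true(all(idx >= 1 & idx <= depth))
      not_pad <- p$selection_basis[[key]] != "padded"
      expect_false(anyDuplicated(idx[not_pad]) > 0)
    }
  }
})

test_that("missing follow-up chest triggers LOCF with bitwise-equal lung images", {
  co <- small_cohort()
  missing <- which(!vapply(co$volumes, `[[`, TRUE, "followup_chest_present"))
  skip_if(length(missing) == 0, "fixture cohort has no missing chest follow-up")
  p <- small_packs()[[missing[1]]]
  expect_true(p$locf_applied)
  expect_identical(p$images[["lung_followup"]], p$images[["lung_baseline"]])
  present <- which(vapply(co$volumes, `[[`, TRUE, "followup_chest_present"))[1]
  expect_false(small_packs()[[present]]$locf_applied)
})

test_that("LOCF equals physically-identical follow-up and missing baseline errors", {
  co <- generate_cohort(small_phantom_config(n = 2, seed = 55,
                                             p_missing_chest_followup = 0))
  vs <- co$volumes[[1]]
  # clone with follow-up chest equal to baseline but physically present
  vs_same <- vs
  for (fld in c("volumes", "organ_masks", "tumor_masks"))
    vs_same[[fld]][["lung_followup"]] <- vs_same[[fld]][["lung_baseline"]]
  vs_absent <- vs
  vs_absent$followup_chest_present <- FALSE
  p_same <- assemble_pack(vs_same)
  p_absent <- assemble_pack(vs_absent)
  expect_equal(p_same$images[["lung_followup"]], p_absent$images[["lung_followup"]])
  vs_bad <- vs
  vs_bad$volumes[["liver_baseline"]] <- NULL
  expect_error(assemble_pack(vs_bad), "baseline")
})

test_that("flip augmentation: p=0 identity, p=1 mirror, p=0.5 binomial fraction", {
  p <- small_packs()[[1]]
  expect_identical(augment_flip(p, 0, seed = 1)$images, p$images)
  flipped <- augment_flip(p, 1, seed = 1)
  for (key in names(p$images)) for (s in 1:3)
    expect_identical(flipped$images[[key]][[s]],
                     p$images[[key]][[s]][, 224:1])
  # fraction over many draws
  n_flip <- 0; n_tot <- 0
  for (r in 1:84) { # 84 packs x 12 images = 1008 draws
    f <- augment_flip(p, 0.5, seed = 1000 + r)
    for (key in names(p$images)) for (s in 1:3) {
      n_tot <- n_tot + 1
      if (!identical(f$images[[key]][[s]], p$images[[key]][[s]]))
        n_flip <- n_flip + 1
    }
  }
  expect_lt(abs(n_flip / n_tot - 0.5), 0.05)
})
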