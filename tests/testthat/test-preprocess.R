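test_that("z-score normalization matches the whole-image moment definition", {
  img <- matrix(c(90, 100, 110), 1, 3)   # mean 100, sample SD exactly 10
  expect_equal(as.vector(zscore_normalize(img)), c(-1, 0, 1))

  set.seed(7)
  x <- matrix(rnorm(64 * 64, 50, 9), 64, 64)
  z <- zscore_normalize(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(as.vector(z)) - 1), 1e-9)

  expect_error(zscore_normalize(matrix(5, 4, 4)), "degenerate")
})

test_that("reference normalization drives the reference ROI to mean 100, SD 10", {
  set.seed(21)
  img <- matrix(rnorm(40 * 40, 300, 55), 40, 40)
  mask <- matrix(FALSE, 40, 40); mask[5:15, 8:20] <- TRUE
  out <- reference_normalize(img, mask)
  expect_lt(abs(mean(out[mask]) - 100), 1e-9)
  expect_lt(abs(sd(out[mask]) - 10), 1e-9)

  ## already at target: identity map
  expect_equal(reference_normalize(out, mask), out, tolerance = 1e-12)
  ## idempotence (affine composition)
  expect_equal(reference_normalize(out, mask),
               reference_normalize(reference_normalize(img, mask), mask),
               tolerance = 1e-12)

  expect_error(reference_normalize(img, matrix(FALSE, 40, 40)), "empty")
  flat <- img; flat[mask] <- 1
  expect_error(reference_normalize(flat, mask), "degenerate")
})

test_that("normalizations are affine: rank-one correlation and invariant moments", {
  case <- generate_subject_phantom(clean_params(), "PKD1", 1, 3)
  roi <- case$kidney_mask & !case$cyst_mask
  z <- zscore_normalize(case$image)
  r <- reference_normalize(case$image, case$psoas_mask)
  expect_equal(cor(case$image[roi], z[roi]), 1, tolerance = 1e-12)
  expect_equal(cor(case$image[roi], r[roi]), 1, tolerance = 1e-12)
  skew <- function(x) mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
  kurt <- function(x) mean((x - mean(x))^4) / mean((x - mean(x))^2)^2
  expect_lt(abs(skew(case$image[roi]) - skew(z[roi])), 1e-9)
  expect_lt(abs(skew(case$image[roi]) - skew(r[roi])), 1e-9)
  expect_lt(abs(kurt(case$image[roi]) - kurt(z[roi])), 1e-9)
  expect_lt(abs(kurt(case$image[roi]) - kurt(r[roi])), 1e-9)
})

test_that("matrix resizing uses center-aligned nearest neighbor", {
  img <- matrix(rnorm(256 * 256), 256, 256)
  expect_identical(unname(resize_to_matrix(img, 256)), img)

  cb <- matrix(c(1, 2, 1, 2,
                 2, 1, 2, 1,
                 1, 2, 1, 2,
                 2, 1, 2, 1), 4, 4, byrow = TRUE)
  out <- resize_to_matrix(cb, 2)
  ## output centers land on source boundaries; ties resolve to lower index
  expect_equal(unname(out), cb[c(1, 3), c(1, 3)])

  set.seed(3)
  m <- matrix(runif(512 * 512) > 0.5, 512, 512)
  rm_ <- resize_to_matrix(m, 256, is_mask = TRUE)
  expect_true(all(rm_ %in% c(TRUE, FALSE)))
  expect_identical(dim(rm_), c(256L, 256L))

  ## spacing rescales to preserve the physical extent
  img <- structure(img, spacing = 1.2)
  half <- resize_to_matrix(img, 128)
  expect_equal(attr(half, "spacing"), 2.4)
})

test_that("resampling to a target spacing follows extent arithmetic", {
  img <- structure(matrix(rnorm(200 * 200), 200, 200), spacing = 1.0)
  down <- resample_to_spacing(img, 2.0)
  expect_identical(dim(down), c(100L, 100L))
  expect_equal(attr(down, "spacing"), 2.0)

  same <- resample_to_spacing(img, 1.0)
  expect_equal(unname(same), unname(img), ignore_attr = TRUE)

  expect_error(resample_to_spacing(matrix(1, 4, 4), 2.0), "spacing")

  ## mask area is preserved up to one pixel-row of boundary error
  case <- generate_subject_phantom(small_params(), "PKD2", 1, 9)
  mask <- structure(case$kidney_mask, spacing = pixel_spacing(case$image))
  res <- resample_to_spacing(mask, 2.0, is_mask = TRUE)
  area_before <- sum(mask) * pixel_spacing(case$image)^2
  area_after <- sum(res) * 4.0
  boundary <- res & !(res[c(1, seq_len(nrow(res) - 1)), ] &
                      res[c(seq_len(nrow(res) - 1) + 1, nrow(res)), ] &
                      res[, c(1, seq_len(ncol(res) - 1))] &
                      res[, c(seq_len(ncol(res) - 1) + 1, ncol(res))])
  expect_lt(abs(area_after - area_before), sum(boundary) * 4.0)
})

test_that("noncystic mask is the kidney/cyst set difference", {
  k <- matrix(FALSE, 10, 10); k[3:8, 3:8] <- TRUE
  cst <- matrix(FALSE, 10, 10); cst[4:5, 4:5] <- TRUE
  expect_identical(noncystic_mask(k, matrix(FALSE, 10, 10)), k)
  expect_error(noncystic_mask(k, k), "empty")
  set.seed(11)
  r1 <- matrix(runif(100) > 0.5, 10, 10)
  r2 <- matrix(runif(100) > 0.5, 10, 10)
  if (any(r1 & !r2)) {
    expect_equal(sum(noncystic_mask(r1, r2)), sum(r1) - sum(r1 & r2))
  }
  expect_error(noncystic_mask(k, matrix(FALSE, 9, 9)), "congruent")
})

test_that("apply_preprocessing composes normalize, resize, resample in order", {
  case <- generate_subject_phantom(small_params(), "PKD1", 2, 13)
  pre <- apply_preprocessing(case, "zscore", "down_2.0mm", target_matrix = 128L)
  manual <- resample_to_spacing(
    resize_to_matrix(zscore_normalize(case$image), 128L), 2.0)
  expect_equal(pre$image, manual)
  expect_equal(pixel_spacing(pre$image), 2.0)
  expect_identical(dim(pre$image), dim(pre$kidney_mask))
  expect_identical(dim(pre$image), dim(pre$psoas_mask))
  ## reference arm uses native-resolution psoas statistics
  pre_ref <- apply_preprocessing(case, "reference", "up_1.0mm",
                                 target_matrix = 128L)
  manual_ref <- resample_to_spacing(
    resize_to_matrix(reference_normalize(case$image, case$psoas_mask), 128L),
    1.0)
  expect_equal(pre_ref$image, manual_ref)
})

test_that("the settings grid enumerates the studied design", {
  grid <- preprocess_settings()
  expect_equal(nrow(grid), 3 * 2 * 6)
  expect_setequal(unique(grid$n_gray_levels), c(8L, 16L, 32L, 64L, 128L, 256L))
  expect_error(preprocess_settings(normalizations = "histogram"))
})
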