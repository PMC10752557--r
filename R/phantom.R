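#' Parameters for synthetic kidney phantoms
#'
#' Builds the parameter set controlling the synthetic T2-like kidney phantom
#' generator. A phantom is a single coronal 2D slice containing one kidney
#' with hyperintense cysts, a hypointense psoas reference muscle, and a
#' parenchymal texture whose spatial correlation length depends on the
#' genotype-like class label. A per-site affine intensity transform emulates
#' the arbitrary signal scales of multi-site qualitative MRI.
#'
#' @param image_matrix Image side length in pixels. A scalar, or a length-2
#'   range from which a per-case size (multiple of 32) is sampled.
#' @param pixel_spacing Pixel size in mm (isotropic). A scalar, or a length-2
#'   range sampled per case, emulating heterogeneous acquisitions.
#' @param kidney_axes Full axis lengths (mm) of the elliptical kidney,
#'   c(width, length).
#' @param psoas_axes Full axis lengths (mm) of the elliptical psoas muscle.
#' @param n_cysts Number of cysts placed inside the kidney.
#' @param cyst_radius_range Cyst radius range in mm, c(min, max).
#' @param cyst_contrast Cyst intensity as a multiple of `parenchyma_mean`;
#'   must exceed 1 (cysts are hyperintense on T2-weighted images).
#' @param parenchyma_mean,parenchyma_sd Mean and texture amplitude of the
#'   noncystic parenchyma signal (arbitrary units).
#' @param psoas_mean,psoas_sd Mean and texture amplitude of the psoas signal;
#'   `psoas_mean` must be below `parenchyma_mean` (muscle is hypointense).
#' @param background_mean Background signal level.
#' @param texture_corr_length_by_class Named numeric vector (names are the
#'   class labels, default `PKD1`/`PKD2`) giving the Gaussian correlation
#'   length (mm) of the parenchymal texture for each class. This is the
#'   class-separating knob: equal values give a null cohort.
#' @param site_scale_range,site_offset_range Ranges of the per-site
#'   multiplicative and additive intensity perturbation.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise added
#'   after the site transform (arbitrary units).
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(image_matrix = 256L,
                           pixel_spacing = c(0.9, 1.5),
                           kidney_axes = c(55, 110),
                           psoas_axes = c(26, 55),
                           n_cysts = 12L,
                           cyst_radius_range = c(2.5, 8),
                           cyst_contrast = 2.5,
                           parenchyma_mean = 400,
                           parenchyma_sd = 60,
                           psoas_mean = 150,
                           psoas_sd = 12,
                           background_mean = 30,
                           texture_corr_length_by_class = c(PKD1 = 1.5, PKD2 = 3.0),
                           site_scale_range = c(0.6, 1.6),
                           site_offset_range = c(-30, 80),
                           noise_sd = 10) {
  p <- list(image_matrix = image_matrix, pixel_spacing = pixel_spacing,
            kidney_axes = kidney_axes, psoas_axes = psoas_axes,
            n_cysts = as.integer(n_cysts),
            cyst_radius_range = cyst_radius_range,
            cyst_contrast = cyst_contrast,
            parenchyma_mean = parenchyma_mean, parenchyma_sd = parenchyma_sd,
            psoas_mean = psoas_mean, psoas_sd = psoas_sd,
            background_mean = background_mean,
            texture_corr_length_by_class = texture_corr_length_by_class,
            site_scale_range = site_scale_range,
            site_offset_range = site_offset_range,
            noise_sd = noise_sd)
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  lens <- c(p$pixel_spacing, p$kidney_axes, p$psoas_axes,
            p$cyst_radius_range, p$texture_corr_length_by_class)
  if (any(lens <= 0)) stop("all lengths must be > 0", call. = FALSE)
  if (p$cyst_contrast <= 1) {
    stop("cyst_contrast must be > 1: cysts are hyperintense relative to parenchyma",
         call. = FALSE)
  }
  if (p$psoas_mean >= p$parenchyma_mean) {
    stop("psoas_mean must be < parenchyma_mean: muscle is hypointense",
         call. = FALSE)
  }
  if (p$n_cysts < 0) stop("n_cysts must be >= 0", call. = FALSE)
  if (is.null(names(p$texture_corr_length_by_class)) ||
      length(p$texture_corr_length_by_class) < 2L) {
    stop("texture_corr_length_by_class must be a named vector with one entry per class",
         call. = FALSE)
  }
  invisible(TRUE)
}

sample_scalar_or_range <- function(x) {
  if (length(x) == 1L) return(x)
  stats::runif(1L, min(x), max(x))
}

## Per-site affine intensity transform: a pure function of the site id and
## the perturbation ranges, so every case from one site shares it.
site_affine <- function(site_id, scale_range, offset_range) {
  with_seed(derive_seed(880301, paste0("site_", site_id)), {
    list(scale = stats::runif(1L, min(scale_range), max(scale_range)),
         offset = stats::runif(1L, min(offset_range), max(offset_range)))
  })
}

## Stationary Gaussian random field on an n x n grid: white noise convolved
## with an isotropic Gaussian kernel (sd = corr_len mm), rescaled by the
## kernel l2 norm so the field has unit variance for any correlation length.
gaussian_random_field <- function(n, corr_len_mm, spacing_mm) {
  sigma_px <- corr_len_mm / spacing_mm
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sqrt(sum(k^2))             # unit-variance output per axis
  w <- matrix(stats::rnorm(n * n), n, n)
  ## separable convolution as banded matrix products (replicate-pad edges)
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in seq_along(k)) {
    j <- pmin(pmax(idx + o - half - 1L, 1L), n)
    K[cbind(idx, j)] <- K[cbind(idx, j)] + k[o]
  }
  K %*% w %*% t(K)
}

ellipse_mask <- function(n, spacing, center_mm, semi_axes_mm) {
  cx <- (seq_len(n) - 0.5) * spacing
  dx <- outer((cx - center_mm[1])^2 / semi_axes_mm[1]^2,
              (cx - center_mm[2])^2 / semi_axes_mm[2]^2, `+`)
  dx <= 1
}

#' Generate one synthetic kidney phantom
#'
#' Deterministically renders a single-subject phantom: kidney and psoas
#' ellipses, class-dependent correlated parenchymal texture, hyperintense
#' cyst disks placed by rejection sampling inside the eroded kidney, then a
#' site-specific affine intensity transform plus Gaussian noise.
#'
#' @param params A [phantom_params()] object.
#' @param class_label One of the names of
#'   `params$texture_corr_length_by_class` (default classes `"PKD1"`,
#'   `"PKD2"`).
#' @param site_id Integer site identifier; fixes the site intensity scale.
#' @param seed Integer seed; the case is a pure function of
#'   `(params, class_label, site_id, seed)`.
#' @return A `phantom_case`: list with `image` (matrix, `"spacing"` attribute
#'   in mm), logical `kidney_mask`, `cyst_mask`, `psoas_mask`, plus
#'   `class_label`, `site_id`, `seed`.
#' @export
generate_subject_phantom <- function(params, class_label, site_id, seed) {
  validate_phantom_params(params)
  if (!class_label %in% names(params$texture_corr_length_by_class)) {
    stop(sprintf("unknown class_label '%s'", class_label), call. = FALSE)
  }
  with_seed(seed, {
    spacing <- sample_scalar_or_range(params$pixel_spacing)
    n <- if (length(params$image_matrix) == 1L) as.integer(params$image_matrix)
         else 32L * round(stats::runif(1L, min(params$image_matrix),
                                       max(params$image_matrix)) / 32)
    fov <- n * spacing
    kid_c <- c(0.38, 0.50) * fov
    kid_a <- params$kidney_axes / 2
    pso_c <- c(0.80, 0.55) * fov
    pso_a <- params$psoas_axes / 2
    kidney <- ellipse_mask(n, spacing, kid_c, kid_a)
    psoas <- ellipse_mask(n, spacing, pso_c, pso_a)
    if (any(kidney & psoas)) stop("kidney and psoas ellipses overlap; enlarge the field of view",
                                  call. = FALSE)

    corr_len <- params$texture_corr_length_by_class[[class_label]]
    texture <- gaussian_random_field(n, corr_len, spacing)
    img <- matrix(params$background_mean, n, n)
    img[kidney] <- params$parenchyma_mean + params$parenchyma_sd * texture[kidney]
    pso_tex <- matrix(stats::rnorm(n * n), n, n)
    img[psoas] <- params$psoas_mean + params$psoas_sd * pso_tex[psoas]

    ## cysts: rejection-sample centers so the whole disk stays inside the
    ## kidney ellipse (analytic erosion by the cyst radius)
    cysts <- matrix(FALSE, n, n)
    cx <- (seq_len(n) - 0.5) * spacing
    for (ci in seq_len(params$n_cysts)) {
      r <- stats::runif(1L, params$cyst_radius_range[1], params$cyst_radius_range[2])
      placed <- FALSE
      for (try in seq_len(1000L)) {
        u <- stats::runif(2L, -1, 1)
        cen <- kid_c + u * (kid_a - r)
        if (all(kid_a - r > 0) &&
            sum(((cen - kid_c) / (kid_a - r))^2) <= 1) {
          disk <- outer((cx - cen[1])^2, (cx - cen[2])^2, `+`) <= r^2
          cysts <- cysts | disk
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf(
          "could not place cyst %d (radius %.1f mm) inside the kidney after 1000 retries; cyst_radius_range is too large for kidney_axes",
          ci, r), call. = FALSE)
      }
    }
    cysts <- cysts & kidney
    img[cysts] <- params$cyst_contrast * params$parenchyma_mean

    noncystic <- kidney & !cysts
    if (!any(noncystic)) stop("kidney mask minus cysts is empty", call. = FALSE)
    ## tissue-contrast invariant, checked before the site transform
    if (!(params$n_cysts == 0 || mean(img[cysts]) > mean(img[noncystic])) ||
        !(mean(img[noncystic]) > mean(img[psoas]))) {
      stop("tissue contrast invariant violated: need cysts > parenchyma > psoas",
           call. = FALSE)
    }

    aff <- site_affine(site_id, params$site_scale_range, params$site_offset_range)
    img <- aff$scale * img + aff$offset + stats::rnorm(n * n, sd = params$noise_sd)
    img <- set_spacing(img, spacing)

    structure(list(image = img, kidney_mask = kidney, cyst_mask = cysts,
                   psoas_mask = psoas, class_label = class_label,
                   site_id = as.integer(site_id), seed = as.integer(seed)),
              class = "phantom_case")
  })
}

#' Generate a balanced multi-site phantom cohort
#'
#' Classes are balanced and sites are assigned round-robin identically within
#' each class, so the site distribution is matched across classes. Per-case
#' seeds are derived deterministically from the master seed.
#'
#' @param params A [phantom_params()] object.
#' @param n_per_class Cases per class (>= 1).
#' @param n_sites Number of sites (>= 1).
#' @param seed Master seed.
#' @param classes Class labels; default the names of
#'   `params$texture_corr_length_by_class`.
#' @return List of `phantom_case` objects, with a `manifest` attribute
#'   (data frame: case_id, class, site, seed).
#' @export
generate_cohort <- function(params, n_per_class, n_sites, seed,
                            classes = names(params$texture_corr_length_by_class)) {
  stopifnot(n_per_class >= 1, n_sites >= 1, length(classes) == 2L)
  layout <- do.call(rbind, lapply(seq_len(n_per_class), function(i) {
    data.frame(class = classes, idx = i,
               site = (i - 1L) %% n_sites + 1L,
               stringsAsFactors = FALSE)
  }))
  layout$case_id <- sprintf("case_%s_%03d", layout$class, layout$idx)
  layout$seed <- vapply(layout$case_id, function(id) derive_seed(seed, id), integer(1))
  cohort <- lapply(seq_len(nrow(layout)), function(i) {
    generate_subject_phantom(params, layout$class[i], layout$site[i], layout$seed[i])
  })
  names(cohort) <- layout$case_id
  attr(cohort, "manifest") <- layout[, c("case_id", "class", "site", "seed")]
  cohort
}

#' Cohort manifest
#' @param cohort A list returned by [generate_cohort()].
#' @return Data frame with case_id, class, site, seed.
#' @export
cohort_manifest <- function(cohort) attr(cohort, "manifest")

#' Write a phantom case to disk
#'
#' Image and masks are stored as 2D NIfTI files (pixel spacing in the
#' header); a JSON sidecar carries the class label, site, seed, and spacing.
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @param case_id Basename stem for the files.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_phantom_case <- function(case, dir, case_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- pixel_spacing(case$image)
  paths <- c(image = file.path(dir, paste0(case_id, "_image.nii.gz")),
             kidney = file.path(dir, paste0(case_id, "_kidney.nii.gz")),
             cyst = file.path(dir, paste0(case_id, "_cyst.nii.gz")),
             psoas = file.path(dir, paste0(case_id, "_psoas.nii.gz")),
             sidecar = file.path(dir, paste0(case_id, ".json")))
  wr <- function(m, path) {
    im <- RNifti::asNifti(array(as.numeric(m), dim = dim(m)))
    im <- RNifti::`pixdim<-`(im, c(sp, sp))
    RNifti::writeNifti(im, path)
  }
  wr(case$image, paths["image"])
  wr(case$kidney_mask, paths["kidney"])
  wr(case$cyst_mask, paths["cyst"])
  wr(case$psoas_mask, paths["psoas"])
  jsonlite::write_json(list(case_id = case_id, class = case$class_label,
                            site = case$site_id, seed = case$seed,
                            pixel_spacing_mm = sp),
                       paths["sidecar"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a phantom case written by [write_phantom_case()]
#' @param dir Directory holding the files.
#' @param case_id Basename stem used at write time.
#' @return A `phantom_case`.
#' @export
read_phantom_case <- function(dir, case_id) {
  side <- jsonlite::read_json(file.path(dir, paste0(case_id, ".json")))
  rd <- function(stem) {
    im <- RNifti::readNifti(file.path(dir, paste0(case_id, "_", stem, ".nii.gz")))
    m <- matrix(as.numeric(im), nrow = dim(im)[1])
    set_spacing(m, RNifti::pixdim(im)[1])
  }
  img <- rd("image")
  structure(list(image = img,
                 kidney_mask = unname(rd("kidney") > 0.5),
                 cyst_mask = unname(rd("cyst") > 0.5),
                 psoas_mask = unname(rd("psoas") > 0.5),
                 class_label = side$class, site_id = as.integer(side$site),
                 seed = as.integer(side$seed)),
            class = "phantom_case")
}

#' Write a whole cohort plus its CSV manifest
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the manifest data frame (with file paths).
#' @export
write_cohort <- function(cohort, dir) {
  man <- cohort_manifest(cohort)
  for (i in seq_len(nrow(man))) {
    write_phantom_case(cohort[[man$case_id[i]]], dir, man$case_id[i])
  }
  man$image_path <- file.path(dir, paste0(man$case_id, "_image.nii.gz"))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
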