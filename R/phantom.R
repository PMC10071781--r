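#' @title Synthetic brain phantoms with known ground truth
#' @description Procedural 3D brain phantoms emulating amyloid PET / T1 MR
#'   pairs: a fixed template brain (ellipsoidal head, paired ventricles,
#'   white matter, cortical gray-matter shell, an inferior cerebellar
#'   gray-matter blob and two subcortical nuclei), individual-space images
#'   generated by known smooth deformations, ventricular enlargement and a
#'   random affine, amyloid-positive / negative uptake patterns, optional
#'   focal lesions and additive Gaussian noise. Because the deformation that
#'   produced each phantom is stored, registration output can be scored
#'   against exact ground truth.
#' @name phantom
NULL

# Tissue label codes used throughout.
TISSUE_BG <- 0L; TISSUE_CSF <- 1L; TISSUE_WM <- 2L
TISSUE_CORTEX <- 3L; TISSUE_CEREBELLUM <- 4L; TISSUE_SUBCORT <- 5L

# PET intensity per tissue; cortical / subcortical gray matter depends on
# amyloid status. Ratios chosen so positive phantoms sit clearly above and
# negative phantoms clearly below a 1.5 global-SUVR positivity threshold.
.pet_intensity <- function(status) {
  gm <- if (status == "positive") 1.3 else 0.6
  c(bg = 0, csf = 0.1, wm = 1.0, cortex = gm, cerebellum = 0.6, subcort = gm)
}

.mr_intensity <- c(bg = 0, csf = 0.2, wm = 0.85, gm = 0.55)

#' Phantom generation parameters
#'
#' @param grid_shape integer length-3 grid (default 48^3); at least 32 per
#'   axis.
#' @param seed integer; every random element of the phantom derives from it.
#' @param amyloid_status `"positive"` or `"negative"` uptake pattern.
#' @param deform_amplitude maximum ground-truth displacement magnitude in
#'   voxels (>= 0).
#' @param ventricle_scale ventricular enlargement factor (>= 1; 1 = none).
#' @param lesion optional `list(center = c(x, y, z), radius = r)` in 0-based
#'   individual-space voxel coordinates; carves a CSF-intensity sphere.
#' @param noise_sd Gaussian noise SD as a fraction of the cortical PET
#'   intensity (>= 0).
#' @param affine_max_rotation,affine_max_translation,affine_max_logscale
#'   half-ranges of the random true affine (degrees, voxels, log-scale).
#'   All zero gives an identity true affine.
#' @return A `pn_phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48), seed = 1,
                         amyloid_status = c("negative", "positive"),
                         deform_amplitude = 2, ventricle_scale = 1,
                         lesion = NULL, noise_sd = 0.05,
                         affine_max_rotation = 4,
                         affine_max_translation = 1.5,
                         affine_max_logscale = 0.03) {
  amyloid_status <- match.arg(amyloid_status)
  if (deform_amplitude < 0) stop("deform_amplitude must be >= 0")
  if (ventricle_scale < 1) stop("ventricle_scale must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(lesion))
    stopifnot(is.list(lesion), length(lesion$center) == 3, lesion$radius > 0)
  structure(list(grid_shape = as.integer(grid_shape), seed = as.integer(seed),
                 amyloid_status = amyloid_status,
                 deform_amplitude = deform_amplitude,
                 ventricle_scale = ventricle_scale, lesion = lesion,
                 noise_sd = noise_sd,
                 affine_max_rotation = affine_max_rotation,
                 affine_max_translation = affine_max_translation,
                 affine_max_logscale = affine_max_logscale),
            class = "pn_phantom_spec")
}

# Normalized ellipsoid "distance": 1 on the surface, < 1 inside.
.ellipsoid <- function(g, dm, center, radii) {
  tx <- (g$x + 0.5) / dm[1]; ty <- (g$y + 0.5) / dm[2]; tz <- (g$z + 0.5) / dm[3]
  sqrt(((tx - center[1]) / radii[1])^2 + ((ty - center[2]) / radii[2])^2 +
         ((tz - center[3]) / radii[3])^2)
}

#' Build the template brain
#'
#' Deterministic procedural template standing in for a T1 MNI-space
#' template: ellipsoidal cerebrum with a cortical gray-matter shell and
#' white-matter interior, paired CSF ventricles, two subcortical gray
#' nuclei and an inferior cerebellar gray-matter blob. The T1-like template
#' image has CSF < GM < WM intensities modulated by a smooth seeded bias
#' field; the gray-matter probability map is 1 on gray-matter labels and
#' smoothed at tissue borders.
#'
#' @param grid_shape integer length-3, each >= 32
#' @param seed integer controlling the texture field
#' @param texture_sigma,texture_amp smoothness (voxels) and relative
#'   amplitude of the multiplicative MR texture; the texture plays the
#'   role of anatomical detail and gives windowed similarity losses their
#'   gradient inside otherwise homogeneous tissue
#' @param gm_border_sigma width (voxels) of the gray-matter probability
#'   ramp at tissue borders; a ramp wider than one voxel keeps soft-Dice
#'   overlap sensitive to alignment rather than to interpolation blur
#' @return list with `template_mr`, `tissue_labels`, `gm_probability`
#'   (`pn_volume` objects) and `brain_mask` (logical array).
#' @export
make_template <- function(grid_shape = c(48, 48, 48), seed = 42,
                          texture_sigma = 1.5, texture_amp = 0.5,
                          gm_border_sigma = 1.5) {
  dm <- as.integer(grid_shape)
  if (length(dm) != 3L || any(dm < 32L))
    stop("template grid must be at least 32 voxels per axis, got ",
         paste(dm, collapse = "x"))
  g <- .grid_coords(dm)
  lab <- integer(prod(dm))

  cer <- .ellipsoid(g, dm, c(0.50, 0.50, 0.58), c(0.36, 0.40, 0.33))
  lab[cer <= 1] <- TISSUE_CORTEX
  lab[cer <= 0.80] <- TISSUE_WM

  vent_l <- .ellipsoid(g, dm, c(0.42, 0.52, 0.60), c(0.055, 0.13, 0.095))
  vent_r <- .ellipsoid(g, dm, c(0.58, 0.52, 0.60), c(0.055, 0.13, 0.095))
  lab[(vent_l <= 1 | vent_r <= 1) & lab == TISSUE_WM] <- TISSUE_CSF

  nuc_l <- .ellipsoid(g, dm, c(0.33, 0.48, 0.56), c(0.06, 0.075, 0.06))
  nuc_r <- .ellipsoid(g, dm, c(0.67, 0.48, 0.56), c(0.06, 0.075, 0.06))
  lab[(nuc_l <= 1 | nuc_r <= 1) & lab == TISSUE_WM] <- TISSUE_SUBCORT

  cbl <- .ellipsoid(g, dm, c(0.50, 0.38, 0.20), c(0.21, 0.16, 0.13))
  lab[cbl <= 1 & lab == TISSUE_BG] <- TISSUE_CEREBELLUM

  labels <- array(lab, dm)

  mr <- array(0, dm)
  mr[labels == TISSUE_CSF] <- .mr_intensity["csf"]
  mr[labels == TISSUE_WM] <- .mr_intensity["wm"]
  mr[labels %in% c(TISSUE_CORTEX, TISSUE_CEREBELLUM, TISSUE_SUBCORT)] <-
    .mr_intensity["gm"]
  set.seed(derive_seed(seed, 1))
  bias <- smooth_gaussian(array(rnorm(prod(dm)), dm), texture_sigma)
  bias <- 1 + texture_amp * bias / stats::sd(bias) * 0.5
  mr <- mr * pmax(bias, 0.5)

  gm <- array(0, dm)
  gm[labels %in% c(TISSUE_CORTEX, TISSUE_CEREBELLUM, TISSUE_SUBCORT)] <- 1
  gm <- pmin(pmax(smooth_gaussian(gm, gm_border_sigma), 0), 1)

  # PET shares the anatomical intensity modulation with the MR (uptake
  # follows tissue density), at twice the relative amplitude; without a
  # modulation that is visible in the PET itself, within-tissue
  # deformation would be unobservable from the network input
  pet_texture <- pmax(1 + 2 * (bias - 1), 0.3)

  list(template_mr = as_volume(mr, id = "template_mr"),
       tissue_labels = as_volume(labels, id = "tissue_labels"),
       gm_probability = as_volume(gm, id = "template_gm"),
       brain_mask = labels > 0,
       pet_texture = pet_texture)
}

#' Sample a smooth random displacement field
#'
#' Gaussian-smoothed white-noise vector field rescaled so its maximum
#' magnitude equals `amplitude`, redrawn (bounded retries with a
#' seed-derived stream) until all Jacobian determinants are positive, i.e.
#' the field does not fold.
#'
#' @param grid_shape integer length-3
#' @param amplitude maximum displacement magnitude in voxels (>= 0)
#' @param seed integer
#' @param sigma Gaussian smoothing in voxels (>= 4 for credible anatomy)
#' @param max_retry maximum redraw attempts
#' @return A `pn_field`.
#' @export
sample_deformation <- function(grid_shape, amplitude, seed, sigma = 4,
                               max_retry = 20L) {
  dm <- as.integer(grid_shape)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(zero_field(dm))
  for (attempt in seq_len(max_retry)) {
    set.seed(derive_seed(seed, 100 + attempt))
    u <- array(rnorm(prod(dm) * 3), c(dm, 3))
    for (comp in 1:3) u[, , , comp] <- smooth_gaussian(u[, , , comp], sigma)
    mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
    u <- u * (amplitude / max(mag))
    f <- as_field(u)
    if (min(jacobian_determinant(f)$data) > 0) return(f)
  }
  stop("sample_deformation: no fold-free field after ", max_retry,
       " attempts (amplitude ", amplitude, ", sigma ", sigma, ")")
}

# Radial pull field enlarging the ventricles by `scale`: voxels within the
# ventricle read the template closer to the ventricle centroid, with a
# smoothstep falloff outside.
.ventricle_field <- function(tissue_labels, scale) {
  dm <- vol_dim(tissue_labels)
  if (scale == 1) return(zero_field(dm))
  idx <- which(tissue_labels$data == TISSUE_CSF)
  if (length(idx) == 0) stop("template has no ventricle voxels")
  g <- .grid_coords(dm)
  cx <- mean(g$x[idx]); cy <- mean(g$y[idx]); cz <- mean(g$z[idx])
  r0 <- sqrt(max((g$x[idx] - cx)^2 + (g$y[idx] - cy)^2 + (g$z[idx] - cz)^2))
  r1 <- 2.2 * r0
  d <- sqrt((g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2)
  t <- pmin(pmax((d - r0) / (r1 - r0), 0), 1)
  falloff <- 1 - t^2 * (3 - 2 * t)          # 1 inside r0, 0 beyond r1
  fac <- (1 / scale - 1) * falloff
  u <- array(0, c(dm, 3))
  u[, , , 1] <- array(fac * (g$x - cx), dm)
  u[, , , 2] <- array(fac * (g$y - cy), dm)
  u[, , , 3] <- array(fac * (g$z - cz), dm)
  as_field(u)
}

# Random small pull affine from the spec ranges (rotation about each axis,
# translation, per-axis log-scale), centered on the grid center.
.random_affine <- function(spec) {
  set.seed(derive_seed(spec$seed, 300))
  ang <- runif(3, -spec$affine_max_rotation, spec$affine_max_rotation) * pi / 180
  tr <- runif(3, -spec$affine_max_translation, spec$affine_max_translation)
  sc <- exp(runif(3, -spec$affine_max_logscale, spec$affine_max_logscale))
  rot <- function(a, axis) {
    R <- diag(3); c1 <- cos(a); s1 <- sin(a)
    ix <- setdiff(1:3, axis)
    R[ix[1], ix[1]] <- c1; R[ix[2], ix[2]] <- c1
    R[ix[1], ix[2]] <- -s1; R[ix[2], ix[1]] <- s1
    R
  }
  M <- rot(ang[1], 1) %*% rot(ang[2], 2) %*% rot(ang[3], 3) %*% diag(sc)
  ctr <- (spec$grid_shape - 1) / 2
  affine_transform(M, ctr - M %*% ctr + tr)
}

#' Generate an individual-space phantom pair
#'
#' Builds the ground-truth deformation (ventricular enlargement field
#' composed with a smooth random field), warps the template tissues through
#' it and a random affine into individual space, paints PET uptake by
#' amyloid status (negative: WM 1.0, cortical GM 0.6, cerebellar GM 0.6,
#' CSF 0.1; positive: cortical and subcortical GM raised to 1.3 while the
#' cerebellar reference stays 0.6), optionally carves a CSF-intensity
#' spherical lesion, and adds Gaussian noise clipped at 0.
#'
#' `true_field` is the pull field on the template grid that carries
#' template-space content into the deformed anatomy; together with
#' `true_affine` (individual voxel to deformed-template voxel) it defines
#' the exact template-to-individual mapping.
#'
#' @param spec a `pn_phantom_spec`
#' @param template output of [make_template()] on the same grid
#' @return A `pn_phantom` list: `pet`, `mr`, `gm_segment`,
#'   `labels_individual` (individual space), `true_field`, `true_affine`,
#'   `tissue_labels` (template space), `spec`.
#' @export
make_phantom_pair <- function(spec, template) {
  stopifnot(inherits(spec, "pn_phantom_spec"))
  dm <- spec$grid_shape
  if (!identical(dm, vol_dim(template$tissue_labels)))
    stop("template grid does not match spec grid_shape")

  f_def <- sample_deformation(dm, spec$deform_amplitude, spec$seed)
  f_vent <- .ventricle_field(template$tissue_labels, spec$ventricle_scale)
  # deformed template D = warp(warp(T, f_vent), f_def)
  true_field <- compose_displacements(f_vent, f_def)
  true_affine <- .random_affine(spec)

  ind <- function(vol, mode) {
    apply_affine(warp_volume(vol, true_field, mode), true_affine,
                 out_shape = dm, mode = mode)
  }

  pet_t <- phantom_pet_template(template, spec$amyloid_status)
  if (!is.null(template$pet_texture))
    pet_t$data <- pet_t$data * template$pet_texture
  pet <- ind(pet_t, "linear")
  mr <- ind(template$template_mr, "linear")
  gm <- ind(template$gm_probability, "linear")
  gm$data <- pmin(pmax(gm$data, 0), 1)
  labels_ind <- ind(template$tissue_labels, "nearest")

  if (!is.null(spec$lesion)) {
    ctr <- spec$lesion$center
    ci <- round(ctr) + 1
    if (any(ci < 1) || any(ci > dm) ||
        labels_ind$data[ci[1], ci[2], ci[3]] == TISSUE_BG)
      stop("lesion center is outside the brain mask")
    g <- .grid_coords(dm)
    inside <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <=
      spec$lesion$radius^2
    pet$data[inside] <- .pet_intensity(spec$amyloid_status)["csf"]
    mr$data[inside] <- .mr_intensity["csf"]
  }

  if (spec$noise_sd > 0) {
    gm_pet <- if (spec$amyloid_status == "positive") 1.3 else 0.6
    set.seed(derive_seed(spec$seed, 500))
    pet$data <- pmax(pet$data +
                       array(rnorm(prod(dm), sd = spec$noise_sd * gm_pet), dm), 0)
    mr$data <- pmax(mr$data +
                      array(rnorm(prod(dm),
                                  sd = spec$noise_sd * .mr_intensity["gm"]), dm), 0)
  }
  pet$id <- sprintf("phantom%03d_pet", spec$seed)
  mr$id <- sprintf("phantom%03d_mr", spec$seed)
  gm$id <- sprintf("phantom%03d_gm", spec$seed)

  structure(list(pet = pet, mr = mr, gm_segment = gm,
                 labels_individual = labels_ind, true_field = true_field,
                 true_affine = true_affine,
                 tissue_labels = template$tissue_labels, spec = spec),
            class = "pn_phantom")
}

#' Noise-free template-space PET construction for a given amyloid status
#'
#' The piecewise-constant PET uptake map painted directly on the template
#' tissue labels, before any deformation or noise. For a positive phantom
#' the analytic global-cortex SUVR of this construction is
#' 1.3 / 0.6 = 2.1667.
#'
#' @param template output of [make_template()]
#' @param amyloid_status `"positive"` or `"negative"`
#' @return A `pn_volume`.
#' @export
phantom_pet_template <- function(template,
                                 amyloid_status = c("negative", "positive")) {
  amyloid_status <- match.arg(amyloid_status)
  pv <- .pet_intensity(amyloid_status)
  lab <- template$tissue_labels$data
  pet <- array(0, dim(lab))
  pet[lab == TISSUE_CSF] <- pv["csf"]
  pet[lab == TISSUE_WM] <- pv["wm"]
  pet[lab == TISSUE_CORTEX] <- pv["cortex"]
  pet[lab == TISSUE_CEREBELLUM] <- pv["cerebellum"]
  pet[lab == TISSUE_SUBCORT] <- pv["subcort"]
  as_volume(pet, id = paste0("pet_template_", amyloid_status))
}

#' Write a phantom to NIfTI files with a JSON sidecar
#'
#' @param phantom a `pn_phantom`
#' @param dir output directory (created if missing)
#' @param prefix file-name prefix
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(s) file.path(dir, paste0(prefix, "_", s))
  write_volume(phantom$pet, p("pet.nii.gz"))
  write_volume(phantom$mr, p("mr.nii.gz"))
  write_volume(phantom$gm_segment, p("gm.nii.gz"))
  write_volume(phantom$labels_individual, p("labels.nii.gz"))
  write_field(phantom$true_field, p("true_field.nii.gz"))
  sp <- phantom$spec
  sidecar <- c(sp[setdiff(names(sp), "lesion")],
               list(lesion = if (is.null(sp$lesion)) NULL else sp$lesion,
                    true_affine_matrix = phantom$true_affine$matrix,
                    true_affine_translation = phantom$true_affine$translation))
  jsonlite::write_json(sidecar, p("spec.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
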