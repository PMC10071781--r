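#' @title End-to-end phantom study driver
#' @description Generates training and test phantom cohorts, trains the
#'   cascade, normalizes the test PETs through the MRI-less pipeline (the
#'   network arm), quantifies composite SUVRs, computes reference SUVRs by
#'   mapping each test PET back to template space through its stored
#'   ground-truth transform (the ground-truth arm, standing in for
#'   individual-space parcellation), and runs the full agreement battery
#'   between the two arms. Everything derives from one master seed.
#' @name study
NULL

#' Phantom study configuration
#'
#' @param n_train,n_test cohort sizes (>= 1)
#' @param seed master seed; all phantom seeds, initialization and training
#'   randomness derive from it
#' @param grid_shape template grid
#' @param deform_amplitude ground-truth deformation amplitude (voxels)
#' @param noise_sd phantom noise level (fraction of cortical intensity)
#' @param ventricle_scales enlargement factors cycled over the cohort
#' @param cascade a `pn_cascade_config`
#' @param train a `pn_train_config`
#' @param out_dir optional output directory; when set, all volumes, SUVR
#'   tables and the agreement table are written there
#' @return A `pn_study_config`.
#' @export
study_config <- function(n_train = 10L, n_test = 10L, seed = 1L,
                         grid_shape = c(48, 48, 48), deform_amplitude = 3,
                         noise_sd = 0.05,
                         ventricle_scales = c(1, 1.2, 1.4),
                         cascade = cascade_config(),
                         train = train_config(), out_dir = NULL) {
  if (n_train < 1 || n_test < 1) stop("cohort sizes must be >= 1")
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 seed = as.integer(seed), grid_shape = as.integer(grid_shape),
                 deform_amplitude = deform_amplitude, noise_sd = noise_sd,
                 ventricle_scales = ventricle_scales, cascade = cascade,
                 train = train, out_dir = out_dir),
            class = "pn_study_config")
}

# One cohort phantom; alternating amyloid status, cycled ventricle scales.
.study_phantom <- function(config, template, index, cohort) {
  offset <- if (cohort == "train") 0L else 500L
  sd <- derive_seed(config$seed, offset + index)
  spec <- phantom_spec(
    grid_shape = config$grid_shape, seed = sd,
    amyloid_status = if (index %% 2L == 0L) "positive" else "negative",
    deform_amplitude = config$deform_amplitude,
    ventricle_scale =
      config$ventricle_scales[(index - 1L) %% length(config$ventricle_scales) + 1L],
    noise_sd = config$noise_sd)
  make_phantom_pair(spec, template)
}

# Ground-truth arm: map the individual-space PET back to template space
# through the numerically inverted true field followed by the inverse
# true affine, composed into a single resampling. Never used by the
# network arm.
.ground_truth_normalize <- function(phantom) {
  resample_chain(phantom$pet, invert_displacement(phantom$true_field),
                 affine_invert(phantom$true_affine))
}

#' Run the full phantom study
#'
#' @param config a `pn_study_config`
#' @return list with `agreement` (per-region table), `metrics` (per-test-
#'   subject geometry metrics), `suvr_reference` / `suvr_network` (report
#'   tables), `model`, `history`, `template`, `atlas`, `config`.
#' @export
run_phantom_study <- function(config = study_config()) {
  stopifnot(inherits(config, "pn_study_config"))
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e)
      stop("study stage '", name, "' failed",
           if (!is.null(id)) paste0(" (subject ", id, ")"), ": ",
           conditionMessage(e), call. = FALSE))
  }
  template <- stage("template", NULL, make_template(config$grid_shape,
                                                    seed = 42))
  aa <- stage("atlas", NULL, build_phantom_atlas(template$tissue_labels))

  train_ph <- lapply(seq_len(config$n_train), function(i)
    stage("train-phantom", i, .study_phantom(config, template, i, "train")))
  samples <- lapply(seq_along(train_ph), function(i)
    stage("affine-train", i, prepare_training_sample(train_ph[[i]], template)))

  model <- build_model(config$cascade, config$grid_shape,
                       seed = derive_seed(config$seed, 900))
  tc <- config$train
  tc$seed <- derive_seed(config$seed, 901)
  model <- stage("training", NULL, train_model(model, samples, template, tc))

  tgm <- template$gm_probability$data
  brain <- template$brain_mask
  dm <- config$grid_shape
  reports_x <- list(); reports_y <- list()
  metrics <- NULL
  test_ph <- list()
  for (i in seq_len(config$n_test)) {
    id <- sprintf("sub%03d", i)
    ph <- stage("test-phantom", id, .study_phantom(config, template, i, "test"))
    test_ph[[i]] <- ph
    sn <- stage("normalize", id, spatially_normalize(model, ph$pet, template))
    reports_y[[i]] <- stage("quantify-network", id,
                            compute_suvr(sn$pet, aa$atlas, aa$voi_map,
                                         subject_id = id))
    gt_pet <- stage("ground-truth", id, .ground_truth_normalize(ph))
    reports_x[[i]] <- stage("quantify-reference", id,
                            compute_suvr(gt_pet, aa$atlas, aa$voi_map,
                                         subject_id = id))
    # geometry metrics of the network arm against the stored truth; the
    # true template-to-individual mapping is the inverse affine applied
    # after the inverted construction field
    gm_aff <- apply_affine(ph$gm_segment, sn$affine, dm)
    gm_dnn <- warp_volume(gm_aff, sn$field)
    jd <- jacobian_determinant(sn$field)$data
    interior <- jd[2:(dm[1] - 1), 2:(dm[2] - 1), 2:(dm[3] - 1)]
    true_norm_field <- invert_displacement(ph$true_field)
    true_norm_affine <- affine_invert(ph$true_affine)
    metrics <- rbind(metrics, data.frame(
      subject_id = id,
      dice_affine = 1 - dice_loss(pmin(pmax(gm_aff$data, 0), 1), tgm),
      dice_network = 1 - dice_loss(pmin(pmax(gm_dnn$data, 0), 1), tgm),
      epe_zero = endpoint_error(zero_field(dm), sn$affine,
                                true_norm_field, true_norm_affine, brain),
      epe_network = endpoint_error(sn$field, sn$affine,
                                   true_norm_field, true_norm_affine, brain),
      fold_fraction = mean(interior <= 0),
      status_true = ph$spec$amyloid_status,
      status_network = reports_y[[i]]$status))
    if (!is.null(config$out_dir)) {
      dir.create(file.path(config$out_dir, "volumes"), recursive = TRUE,
                 showWarnings = FALSE)
      write_volume(sn$pet, file.path(config$out_dir, "volumes",
                                     paste0(id, "_pet_sn.nii.gz")))
      write_field(sn$field, file.path(config$out_dir, "volumes",
                                      paste0(id, "_field.nii.gz")))
    }
  }
  agreement <- stage("agreement", NULL,
                     compare_methods(reports_x, reports_y))

  out <- list(agreement = agreement, metrics = metrics,
              suvr_reference = suvr_table(reports_x),
              suvr_network = suvr_table(reports_y),
              model = model, history = model$history,
              template = template, atlas = aa, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(agreement, file.path(config$out_dir, "agreement.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(out$suvr_reference,
                     file.path(config$out_dir, "suvr_reference.csv"),
                     row.names = FALSE)
    utils::write.csv(out$suvr_network,
                     file.path(config$out_dir, "suvr_network.csv"),
                     row.names = FALSE)
    utils::write.csv(model$history,
                     file.path(config$out_dir, "training_log.csv"),
                     row.names = FALSE)
    write_volume(template$template_mr,
                 file.path(config$out_dir, "template_mr.nii.gz"))
    write_atlas(aa$atlas, file.path(config$out_dir, "atlas.nii.gz"),
                file.path(config$out_dir, "atlas.json"))
    write_composite_map(aa$voi_map,
                        file.path(config$out_dir, "composite_map.json"))
  }
  out
}
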