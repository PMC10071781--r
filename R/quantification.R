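#' @title Atlas-based SUVR quantification
#' @description Regional uptake extraction in template space, grouping of
#'   atlas labels into the six composite volumes of interest (global
#'   cerebral cortex, frontal, posterior cingulate-precuneus, lateral
#'   parietal, lateral temporal, medial temporal), SUVR computation against
#'   a cerebellar gray-matter reference, and amyloid-positivity
#'   classification by a global-cortex SUVR threshold.
#' @name quantification
NULL

#' Canonical composite VOI names
#' @export
COMPOSITE_NAMES <- c("global_cerebral_cortex", "frontal",
                     "posterior_cingulate_precuneus", "lateral_parietal",
                     "lateral_temporal", "medial_temporal")

#' Create a VOI atlas
#'
#' @param labels a `pn_volume` of integer labels in template space
#' @param names named character vector mapping label (as name) to region
#'   name; every nonzero label present in the volume must be named
#' @return A `pn_voi_atlas`.
#' @export
voi_atlas <- function(labels, names) {
  stopifnot(inherits(labels, "pn_volume"))
  if (any(labels$data != round(labels$data)))
    stop("atlas labels must be integers")
  present <- setdiff(sort(unique(as.vector(labels$data))), 0)
  missing <- setdiff(as.character(present), base::names(names))
  if (length(missing) > 0)
    stop("unnamed atlas labels: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, names = names), class = "pn_voi_atlas")
}

#' Create a composite VOI map
#'
#' @param composites named list: composite name -> integer vector of atlas
#'   labels; must contain exactly the six canonical composite names
#' @param reference integer vector of reference-region (cerebellar gray
#'   matter) labels, disjoint from every composite
#' @return A `pn_composite_map`.
#' @export
composite_voi_map <- function(composites, reference) {
  if (!setequal(names(composites), COMPOSITE_NAMES))
    stop("composites must be named exactly: ",
         paste(COMPOSITE_NAMES, collapse = ", "))
  for (nm in names(composites))
    if (length(intersect(composites[[nm]], reference)) > 0)
      stop("reference labels overlap composite '", nm, "'")
  structure(list(composites = composites, reference = as.integer(reference)),
            class = "pn_composite_map")
}

#' Mean uptake over a label set
#'
#' @param pet_template a `pn_volume` in template space
#' @param atlas a `pn_voi_atlas` on the same grid
#' @param labels nonempty integer vector of atlas labels
#' @return list with `mean` and `voxel_count`.
#' @export
extract_regional_means <- function(pet_template, atlas, labels) {
  stopifnot(inherits(pet_template, "pn_volume"),
            inherits(atlas, "pn_voi_atlas"))
  if (!identical(vol_dim(pet_template), vol_dim(atlas$labels)))
    stop("PET and atlas grids differ")
  if (length(labels) == 0) stop("empty label set")
  mask <- atlas$labels$data %in% labels
  if (!any(mask))
    stop("no voxels carry labels {", paste(labels, collapse = ", "), "}")
  list(mean = mean(pet_template$data[mask]), voxel_count = sum(mask))
}

#' Classify amyloid status from a global-cortex SUVR
#'
#' Positive iff the global SUVR strictly exceeds the threshold; a value
#' exactly at the threshold is classified negative.
#'
#' @param global_suvr positive scalar
#' @param threshold decision threshold (default 1.5)
#' @return `"positive"` or `"negative"`.
#' @export
classify_amyloid_status <- function(global_suvr, threshold = 1.5) {
  if (!is.finite(global_suvr) || global_suvr <= 0)
    stop("global SUVR must be positive, got ", global_suvr)
  if (global_suvr > threshold) "positive" else "negative"
}

#' Compute a composite-VOI SUVR report
#'
#' Each composite mean is divided by the cerebellar gray-matter reference
#' mean; amyloid status is set from the global cerebral cortex SUVR.
#'
#' @param pet_template spatially normalized PET (`pn_volume`)
#' @param atlas a `pn_voi_atlas`
#' @param voi_map a `pn_composite_map`
#' @param subject_id identifier carried into the report
#' @param threshold positivity threshold on the global-cortex SUVR
#' @return A `pn_suvr_report`: `suvr` (named vector), `reference_mean`,
#'   `status`, `subject_id`.
#' @export
compute_suvr <- function(pet_template, atlas, voi_map, subject_id = "subject",
                         threshold = 1.5) {
  stopifnot(inherits(voi_map, "pn_composite_map"))
  ref <- extract_regional_means(pet_template, atlas, voi_map$reference)
  if (ref$mean <= 0)
    stop("non-positive reference mean (", ref$mean, "): SUVR undefined")
  suvr <- vapply(voi_map$composites, function(lab)
    extract_regional_means(pet_template, atlas, lab)$mean / ref$mean,
    numeric(1))
  structure(list(suvr = suvr, reference_mean = ref$mean,
                 status = classify_amyloid_status(
                   suvr[["global_cerebral_cortex"]], threshold),
                 subject_id = subject_id),
            class = "pn_suvr_report")
}

#' @export
print.pn_suvr_report <- function(x, ...) {
  cat(sprintf("<pn_suvr_report> %s (%s)\n", x$subject_id, x$status))
  print(round(x$suvr, 4))
  invisible(x)
}

# Atlas label codes of the phantom atlas.
.PHANTOM_ATLAS <- c(frontal = 1L, posterior_cingulate_precuneus = 2L,
                    lateral_parietal = 3L, lateral_temporal = 4L,
                    occipital = 5L, medial_temporal = 6L,
                    cerebellar_gray = 7L)

#' Build the geometric phantom atlas
#'
#' Stands in for a FreeSurfer-parcellated template atlas: the cortical
#' gray-matter shell is split into five exhaustive geometric sectors
#' (frontal, posterior cingulate-precuneus, lateral parietal, lateral
#' temporal, occipital), the subcortical nuclei map to the medial temporal
#' composite, and the cerebellar gray matter forms the reference region.
#' Global cerebral cortex is the union of the five cortical sectors.
#'
#' @param tissue_labels template tissue labels from [make_template()]
#' @return list with `atlas` (`pn_voi_atlas`) and `voi_map`
#'   (`pn_composite_map`).
#' @export
build_phantom_atlas <- function(tissue_labels) {
  stopifnot(inherits(tissue_labels, "pn_volume"))
  lab <- tissue_labels$data
  dm <- dim(lab)
  for (cls in c(TISSUE_CORTEX, TISSUE_CEREBELLUM, TISSUE_SUBCORT))
    if (!any(lab == cls)) stop("missing tissue class ", cls, " in template")
  g <- .grid_coords(dm)
  tx <- (g$x + 0.5) / dm[1] - 0.5
  ty <- (g$y + 0.5) / dm[2] - 0.5
  tz <- (g$z + 0.5) / dm[3] - 0.58
  out <- integer(prod(dm))
  ctx <- as.vector(lab == TISSUE_CORTEX)
  frontal <- ctx & ty > 0.08
  post <- ctx & !frontal
  sup <- post & tz > 0.05
  pcc <- sup & abs(tx) < 0.12
  lpar <- sup & !(abs(tx) < 0.12)
  inf <- post & !sup
  ltem <- inf & abs(tx) >= 0.12
  occ <- inf & !(abs(tx) >= 0.12)
  out[frontal] <- .PHANTOM_ATLAS[["frontal"]]
  out[pcc] <- .PHANTOM_ATLAS[["posterior_cingulate_precuneus"]]
  out[lpar] <- .PHANTOM_ATLAS[["lateral_parietal"]]
  out[ltem] <- .PHANTOM_ATLAS[["lateral_temporal"]]
  out[occ] <- .PHANTOM_ATLAS[["occipital"]]
  out[as.vector(lab == TISSUE_SUBCORT)] <- .PHANTOM_ATLAS[["medial_temporal"]]
  out[as.vector(lab == TISSUE_CEREBELLUM)] <- .PHANTOM_ATLAS[["cerebellar_gray"]]
  atlas <- voi_atlas(as_volume(array(out, dm), spacing = tissue_labels$spacing,
                               affine = tissue_labels$affine, id = "phantom_atlas"),
                     stats::setNames(names(.PHANTOM_ATLAS),
                                     as.character(.PHANTOM_ATLAS)))
  voi_map <- composite_voi_map(
    composites = list(
      global_cerebral_cortex = unname(.PHANTOM_ATLAS[1:5]),
      frontal = .PHANTOM_ATLAS[["frontal"]],
      posterior_cingulate_precuneus =
        .PHANTOM_ATLAS[["posterior_cingulate_precuneus"]],
      lateral_parietal = .PHANTOM_ATLAS[["lateral_parietal"]],
      lateral_temporal = .PHANTOM_ATLAS[["lateral_temporal"]],
      medial_temporal = .PHANTOM_ATLAS[["medial_temporal"]]),
    reference = .PHANTOM_ATLAS[["cerebellar_gray"]])
  list(atlas = atlas, voi_map = voi_map)
}

# ---- serialization --------------------------------------------------------

#' Convert SUVR reports to a long-format table
#' @param reports a `pn_suvr_report` or list of them
#' @return data.frame with columns subject_id, region, suvr,
#'   reference_mean, status.
#' @export
suvr_table <- function(reports) {
  if (inherits(reports, "pn_suvr_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r)
    data.frame(subject_id = r$subject_id, region = names(r$suvr),
               suvr = unname(r$suvr), reference_mean = r$reference_mean,
               status = r$status, row.names = NULL)))
}

#' Write SUVR reports to CSV
#' @param reports a `pn_suvr_report` or list of them
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_suvr_csv <- function(reports, path) {
  utils::write.csv(suvr_table(reports), path, row.names = FALSE)
  invisible(path)
}

#' Read SUVR reports from CSV
#' @param path CSV written by [write_suvr_csv()]
#' @return list of `pn_suvr_report` objects.
#' @export
read_suvr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$subject_id), function(d) {
    structure(list(suvr = stats::setNames(d$suvr, d$region),
                   reference_mean = d$reference_mean[1],
                   status = d$status[1], subject_id = d$subject_id[1]),
              class = "pn_suvr_report")
  })
}

#' Write an atlas as NIfTI labels plus a JSON name map
#' @param atlas a `pn_voi_atlas`
#' @param nifti_path,json_path output paths
#' @return `nifti_path`, invisibly.
#' @export
write_atlas <- function(atlas, nifti_path, json_path) {
  write_volume(atlas$labels, nifti_path)
  jsonlite::write_json(as.list(atlas$names), json_path, auto_unbox = TRUE)
  invisible(nifti_path)
}

#' Read an atlas from NIfTI labels plus a JSON name map
#' @param nifti_path,json_path paths written by [write_atlas()]
#' @return A `pn_voi_atlas`.
#' @export
read_atlas <- function(nifti_path, json_path) {
  labels <- read_volume(nifti_path)
  labels$data <- round(labels$data)
  nm <- unlist(jsonlite::read_json(json_path))
  voi_atlas(labels, nm)
}

#' Write a composite VOI map as JSON
#' @param voi_map a `pn_composite_map`
#' @param path output JSON path
#' @return `path`, invisibly.
#' @export
write_composite_map <- function(voi_map, path) {
  jsonlite::write_json(list(composites = voi_map$composites,
                            reference = voi_map$reference),
                       path)
  invisible(path)
}

#' Read a composite VOI map from JSON
#' @param path JSON written by [write_composite_map()]
#' @return A `pn_composite_map`.
#' @export
read_composite_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  composite_voi_map(lapply(j$composites, as.integer), j$reference)
}
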