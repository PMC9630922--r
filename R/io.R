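# NIfTI and manifest I/O for study bundles. Volumes are written as NIfTI-1
# (.nii.gz) with the voxel size encoded in the header; masks as unsigned
# 8-bit {0,1}, images and z-maps as 32-bit float.

write_nifti_vol <- function(x, file, voxel_size_mm, datatype = "float") {
  if (is.logical(x)) {
    storage.mode(x) <- "integer"
    datatype <- "uint8"
  }
  im <- RNifti::asNifti(x)
  RNifti::pixdim(im) <- voxel_size_mm
  RNifti::writeNifti(im, file, datatype = datatype)
  invisible(file)
}

read_mask_vol <- function(file) {
  as.array(RNifti::readNifti(file)) > 0
}

#' Write a study bundle to disk
#'
#' Writes, per dataset: the phantom image, the reference cord mask and the
#' gray- and white-matter atlas masks, one mask and one registered image per
#' rater, and the left/right activation z-maps for the reference and every
#' rater; plus a JSON manifest listing every file with its role, the
#' registration displacements, the per-slice contrast profile and all seeds.
#' Fully reproducible from the configuration's master seed.
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if needed).
#' @return The bundle, invisibly, with its `dir` element set.
#' @export
write_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create output directory '%s'", dir))
  cfg <- bundle$config
  vs <- cfg$voxel_size_mm
  rn <- names(cfg$rater_models)
  manifest <- list(
    package = "cordmaskvar",
    n_datasets = cfg$n_datasets,
    raters = rn,
    grid_shape = cfg$grid_shape,
    voxel_size_mm = vs,
    master_seed = cfg$master_seed,
    act_extent = cfg$act_extent,
    datasets = list())
  for (d in seq_along(bundle$datasets)) {
    ds <- bundle$datasets[[d]]
    dd <- file.path(dir, sprintf("ds%02d", d))
    dir.create(dd, showWarnings = FALSE)
    rel <- function(f) file.path(sprintf("ds%02d", d), f)
    files <- list()
    add <- function(files, f, role, rater = NULL, side = NULL) {
      rec <- list(path = rel(f), role = role)
      if (!is.null(rater)) rec$rater <- rater
      if (!is.null(side)) rec$side <- side
      c(files, list(rec))
    }
    write_nifti_vol(ds$phantom$image, file.path(dd, "image.nii.gz"), vs)
    files <- add(files, "image.nii.gz", "image")
    write_nifti_vol(ds$phantom$cord_mask, file.path(dd, "mask_REF.nii.gz"), vs)
    files <- add(files, "mask_REF.nii.gz", "reference", rater = "REF")
    write_nifti_vol(ds$phantom$gm_mask, file.path(dd, "atlas_gm.nii.gz"), vs)
    files <- add(files, "atlas_gm.nii.gz", "atlas_gm")
    write_nifti_vol(ds$phantom$wm_mask, file.path(dd, "atlas_wm.nii.gz"), vs)
    files <- add(files, "atlas_wm.nii.gz", "atlas_wm")
    for (r in rn) {
      f <- sprintf("mask_%s.nii.gz", r)
      write_nifti_vol(ds$rater_masks[[r]], file.path(dd, f), vs)
      files <- add(files, f, "rater", rater = r)
    }
    for (r in c("REF", rn)) {
      f <- sprintf("registered_%s.nii.gz", r)
      write_nifti_vol(registered_image(bundle, d, r), file.path(dd, f), vs)
      files <- add(files, f, "registered", rater = r)
      for (side in c("left", "right")) {
        zf <- sprintf("zmap_%s_%s.nii.gz", r, side)
        write_nifti_vol(get_activation_map(bundle, d, r, side)$z,
                        file.path(dd, zf), vs)
        files <- add(files, zf, "zmap", rater = r, side = side)
      }
    }
    manifest$datasets[[d]] <- list(
      id = d,
      files = files,
      displacement = lapply(ds$displacement, function(m) unname(as.matrix(m))),
      csf_ratio = ds$profile$csf_ratio,
      difficulty = ds$profile$difficulty,
      volume_dsc = as.list(ds$volume_dsc))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle$dir <- dir
  invisible(bundle)
}

#' Read a study bundle back from disk
#'
#' Reconstructs a `study_bundle` from a directory written by [write_study()].
#' Missing files raise an error naming the file.
#'
#' @param dir study directory containing `manifest.json`.
#' @return A `study_bundle`.
#' @export
read_study <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("manifest not found: %s", mf))
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  rn <- unlist(manifest$raters)
  vs <- unlist(manifest$voxel_size_mm)
  gs <- as.integer(unlist(manifest$grid_shape))
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("missing study file: %s", p))
    p
  }
  datasets <- vector("list", length(manifest$datasets))
  for (d in seq_along(manifest$datasets)) {
    md <- manifest$datasets[[d]]
    paths <- list()
    for (rec in md$files) {
      key <- paste(c(rec$role, rec$rater, rec$side), collapse = ".")
      paths[[key]] <- rec$path
    }
    img <- as.array(RNifti::readNifti(need(paths[["image"]])))
    cord <- read_mask_vol(need(paths[["reference.REF"]]))
    gm <- read_mask_vol(need(paths[["atlas_gm"]]))
    wm <- read_mask_vol(need(paths[["atlas_wm"]]))
    phantom <- structure(list(image = img, cord_mask = cord, gm_mask = gm,
                              wm_mask = wm,
                              spec = list(grid_shape = gs, voxel_size_mm = vs)),
                         class = "phantom_volume")
    rater_masks <- lapply(rn, function(r) {
      read_mask_vol(need(paths[[paste("rater", r, sep = ".")]]))
    })
    names(rater_masks) <- rn
    displacement <- lapply(md$displacement, function(m) {
      do.call(rbind, lapply(m, unlist))
    })
    act_read <- function(r) {
      lapply(stats::setNames(c("left", "right"), c("left", "right")),
             function(side) {
               z <- as.array(RNifti::readNifti(
                 need(paths[[paste("zmap", r, side, sep = ".")]])))
               list(z = z[cord], side = side)
             })
    }
    act_raters <- lapply(stats::setNames(rn, rn), act_read)
    datasets[[d]] <- list(
      phantom = phantom,
      profile = list(csf_ratio = unlist(md$csf_ratio),
                     difficulty = unlist(md$difficulty)),
      rater_masks = rater_masks,
      displacement = displacement,
      volume_dsc = unlist(md$volume_dsc),
      act = list(REF = act_read("REF"), raters = act_raters))
  }
  # minimal config carrying what downstream stages need
  models <- stats::setNames(rep(list(rater_model()), length(rn)), rn)
  config <- structure(list(n_datasets = length(datasets),
                           rater_models = models,
                           grid_shape = gs, voxel_size_mm = vs,
                           act_extent = as.integer(unlist(manifest$act_extent)),
                           master_seed = manifest$master_seed),
                      class = "study_config")
  structure(list(config = config, datasets = datasets, dir = dir),
            class = "study_bundle")
}

#' Group-level spatial correlations from a published contouring study
#'
#' Returns the bundled table of group-level activation-map spatial
#' correlations (Fisher's z) between each of eight raters and a reference
#' rater, by stimulated side and condition (ipsilateral or contralateral
#' activation), from a cervical spinal cord fMRI study of manual contouring
#' variability. Useful as a worked example for
#' [summarize_fisher_table()].
#'
#' @return Data frame with columns `rater, side, condition, fisher_z`
#'   (32 rows).
#' @export
example_group_correlations <- function() {
  f <- system.file("extdata", "group_level_fisher_z.csv",
                   package = "cordmaskvar", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
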