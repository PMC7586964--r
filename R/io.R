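# File formats and case layout: NIfTI volumes, PNG histology slices and
# labels, JSON for correspondence, ground truth, transforms and reports.

#' Write a phantom case to disk
#'
#' MRI and prostate mask as NIfTI (.nii.gz) with physical spacing in the
#' header, histology slices as RGB PNG, masks and labels as 8-bit PNG,
#' correspondence table plus pixel-size metadata and artifact ground truth as
#' JSON.
#'
#' @param phantom A \code{"phantom_case"}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_phantom_case <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- phantom$stack
  sp3 <- phantom$mri$spacing
  wr_nii <- function(arr, name) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp3
    RNifti::writeNifti(img, file.path(dir, name))
  }
  wr_nii(phantom$mri$img, "mri.nii.gz")
  wr_nii(phantom$mri$mask, "mri_mask.nii.gz")
  D <- length(st$slices)
  for (i in seq_len(D)) {
    png::writePNG(aperm(st$slices[[i]], c(1, 2, 3)) / 255,
                  file.path(dir, sprintf("hist_%02d.png", i)))
    png::writePNG(st$masks[[i]], file.path(dir, sprintf("hist_mask_%02d.png", i)))
    if (!is.null(st$cancer))
      png::writePNG(st$cancer[[i]], file.path(dir, sprintf("hist_cancer_%02d.png", i)))
    if (!is.null(st$urethra))
      png::writePNG(st$urethra[[i]], file.path(dir, sprintf("hist_urethra_%02d.png", i)))
  }
  meta <- list(pixel_size_mm = st$pixel_size,
               correspondence = st$correspondence,
               gross_rotation_deg = st$gross_rotation,
               flip_lr = st$flip_lr,
               n_slices = D)
  jsonlite::write_json(meta, file.path(dir, "correspondence.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(phantom$truth, file.path(dir, "ground_truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Read a case directory
#'
#' Fails fast: every file referenced by the correspondence table must exist,
#' the MRI mask must share the MRI grid, and pixel-size metadata must be
#' present (physical units are never guessed).
#'
#' @param dir Case directory written by \code{\link{write_phantom_case}} (or
#'   following the same layout).
#' @return List \code{(mri, stack)}.
#' @export
read_case <- function(dir) {
  need <- file.path(dir, c("mri.nii.gz", "mri_mask.nii.gz",
                           "correspondence.json"))
  for (f in need) if (!file.exists(f)) stop("read_case: missing file: ", f)
  meta <- jsonlite::read_json(file.path(dir, "correspondence.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$pixel_size_mm))
    stop("read_case: pixel_size_mm missing from correspondence.json; physical units are required")
  mimg <- RNifti::readNifti(file.path(dir, "mri.nii.gz"))
  mmask <- RNifti::readNifti(file.path(dir, "mri_mask.nii.gz"))
  if (!all(dim(mimg) == dim(mmask)))
    stop("read_case: MRI mask grid does not match MRI grid")
  sp3 <- RNifti::pixdim(mimg)
  mri <- mri_volume(array(as.numeric(mimg), dim(mimg)),
                    array(as.numeric(mmask), dim(mmask)), sp3)
  D <- meta$n_slices
  rd_png <- function(pattern, i, required = TRUE) {
    f <- file.path(dir, sprintf(pattern, i))
    if (!file.exists(f)) {
      if (required) stop("read_case: missing slice file: ", f)
      return(NULL)
    }
    png::readPNG(f)
  }
  slices <- vector("list", D); masks <- vector("list", D)
  cancer <- list(); urethra <- list()
  for (i in seq_len(D)) {
    im <- rd_png("hist_%02d.png", i)
    if (length(dim(im)) == 2) im <- array(rep(im, 3), c(dim(im), 3))
    slices[[i]] <- im[, , 1:3] * 255
    masks[[i]] <- (rd_png("hist_mask_%02d.png", i) > 0.5) * 1
    cm <- rd_png("hist_cancer_%02d.png", i, required = FALSE)
    if (!is.null(cm)) cancer[[i]] <- (cm > 0.5) * 1
    um <- rd_png("hist_urethra_%02d.png", i, required = FALSE)
    if (!is.null(um)) urethra[[i]] <- (um > 0.5) * 1
  }
  stack <- hist_stack(slices = slices, masks = masks,
                      cancer = if (length(cancer) == D) cancer else NULL,
                      urethra = if (length(urethra) == D) urethra else NULL,
                      pixel_size = meta$pixel_size_mm,
                      correspondence = meta$correspondence,
                      gross_rotation = meta$gross_rotation_deg,
                      flip_lr = meta$flip_lr)
  list(mri = mri, stack = stack)
}

tf_to_list <- function(tf) {
  if (inherits(tf, "rigid2d"))
    list(type = "rigid", angle_deg = tf$angle_deg, t_mm = tf$t,
         center_mm = tf$center)
  else if (inherits(tf, "affine2d"))
    list(type = "affine", A = as.numeric(tf$A), t_mm = tf$t,
         center_mm = tf$center)
  else
    list(type = "bspline", mesh = tf$mesh, domain_mm = tf$domain,
         cpx_mm = as.numeric(tf$cpx), cpy_mm = as.numeric(tf$cpy))
}

tf_from_list <- function(l) {
  switch(l$type,
         rigid = rigid2d(l$angle_deg, l$t_mm[1], l$t_mm[2],
                         l$center_mm[1], l$center_mm[2]),
         affine = affine2d(matrix(l$A, 2, 2), l$t_mm, l$center_mm),
         bspline = {
           nr <- l$mesh[2] + 3
           bspline2d(l$mesh, l$domain_mm,
                     cpx = matrix(l$cpx_mm, nr),
                     cpy = matrix(l$cpy_mm, nr))
         },
         stop("unknown transform type: ", l$type))
}

#' Serialize per-slice transform chains to JSON
#' @param chains A \code{"case_chains"}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_chains <- function(chains, path) {
  out <- lapply(chains, function(ch)
    list(slice = ch$slice, mri_slice = ch$mri_slice,
         direction = ch$direction,
         rigid = tf_to_list(ch$rigid), affine = tf_to_list(ch$affine),
         field = tf_to_list(ch$field)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read transform chains written by \code{\link{write_chains}}
#' @param path JSON path.
#' @return A \code{"case_chains"} list.
#' @export
read_chains <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(lapply(raw, function(l)
    slice_chain(tf_from_list(l$rigid), tf_from_list(l$affine),
                tf_from_list(l$field), slice = l$slice,
                mri_slice = l$mri_slice)),
    class = "case_chains")
}

#' Run the full pipeline on a case directory
#'
#' Reads the case, registers it, writes the transform chains, warped
#' histology and mapped labels (NIfTI on the MRI grid), and, when reference
#' labels are available (phantom cases), an evaluation report JSON.
#'
#' @param dir Case directory (layout of \code{\link{write_phantom_case}}).
#' @param out Output directory.
#' @param config A \code{\link{registration_config}}.
#' @return The \code{"case_chains"}, invisibly; writes
#'   \code{transforms.json}, \code{mapped_prostate.nii.gz},
#'   \code{mapped_cancer.nii.gz}, \code{mapped_hist.nii.gz} under \code{out}.
#' @export
run_pipeline <- function(dir, out, config = registration_config()) {
  case <- read_case(dir)
  chains <- register_case(case$mri, case$stack, config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_chains(chains, file.path(out, "transforms.json"))
  st <- case$stack
  sp <- st$pixel_size
  dims <- dim(case$mri$img)
  map_vol <- function(lbls, interp) {
    v <- array(0, dims)
    for (i in seq_along(chains)) {
      k <- st$correspondence[i]
      v[, , k] <- if (interp == "nearest")
        warp_label(lbls[[i]], chains[[i]], out_dim = dims[1:2], spacing = sp)
      else warp_image(lbls[[i]], chains[[i]], out_dim = dims[1:2], spacing = sp)
    }
    v
  }
  wr <- function(v, name) {
    img <- RNifti::asNifti(v)
    RNifti::pixdim(img) <- case$mri$spacing
    RNifti::writeNifti(img, file.path(out, name))
  }
  wr(map_vol(st$masks, "nearest"), "mapped_prostate.nii.gz")
  if (!is.null(st$cancer)) wr(map_vol(st$cancer, "nearest"), "mapped_cancer.nii.gz")
  if (!is.null(st$urethra)) wr(map_vol(st$urethra, "nearest"), "mapped_urethra.nii.gz")
  grays <- lapply(st$slices, rgb_to_gray)
  wr(map_vol(grays, "linear"), "mapped_hist.nii.gz")
  invisible(chains)
}
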