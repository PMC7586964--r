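# Digital prostate phantom: paired synthetic T2w MRI and RGB histology with
# a shared analytic anatomy, region-mean intensity fills, Gaussian noise, and
# injected histologic-processing artifacts (per-slice rotation, shrinkage,
# translation, optional left-right flip, out-of-plane slice offset) with
# known ground-truth transforms.

#' Phantom specification
#'
#' Parameters of the synthetic anatomy, intensity model and injected
#' artifacts. Defaults emulate a 0.4 x 0.4 x 4.0 mm T2w acquisition on a
#' 256 x 256 grid with 6 slices through the gland.
#'
#' @param in_plane_size Square in-plane grid size in pixels.
#' @param n_slices Number of axial slices (>= 2).
#' @param in_plane_mm In-plane pixel size, mm.
#' @param slice_mm Slice thickness, mm.
#' @param region_mri_means Named MRI intensities for
#'   \code{background, prostate, peripheral_zone, cancer, urethra}.
#' @param region_rgb_means Named list of RGB triples (0-255) for the same
#'   regions (H&E-like fills).
#' @param noise_sd Gaussian noise sd applied to both modalities
#'   (default 5\% of the prostate/background MRI contrast).
#' @param max_rotation_deg Per-slice mounting rotation r: each slice gets an
#'   angle drawn uniformly from [-r, r] degrees.
#' @param shrink_factor Fractional isotropic shrinkage s in [0, 1) applied to
#'   every slice; slices shrink to scale (1 - s).
#' @param translation_frac Maximum random translation as a fraction of image
#'   width, drawn independently in x and y; applied only when s > 0 (rotation-
#'   only experiments carry no translation).
#' @param slice_offset_mm Out-of-plane correspondence offset: histology slices
#'   are synthesized this many mm away (along the slice axis) from their
#'   paired MRI slices. 0 = perfect correspondence; 2 mimics a one-half-slice
#'   mismatch.
#' @param flip_lr Simulate a left-right mounting flip on every slice.
#' @param seed RNG seed for all random draws.
#' @return Object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(in_plane_size = 256L,
                         n_slices = 6L,
                         in_plane_mm = 0.4,
                         slice_mm = 4.0,
                         region_mri_means = c(background = 30, prostate = 120,
                                              peripheral_zone = 170,
                                              cancer = 85, urethra = 210),
                         region_rgb_means = list(
                           background = c(245, 245, 245),
                           prostate = c(205, 125, 165),
                           peripheral_zone = c(175, 95, 150),
                           cancer = c(120, 55, 115),
                           urethra = c(240, 210, 225)),
                         noise_sd = 0.05 * 90,
                         max_rotation_deg = 0,
                         shrink_factor = 0,
                         translation_frac = 0.05,
                         slice_offset_mm = 0,
                         flip_lr = FALSE,
                         seed = 1L) {
  regions <- c("background", "prostate", "peripheral_zone", "cancer", "urethra")
  stopifnot(in_plane_size >= 32, n_slices >= 2,
            in_plane_mm > 0, slice_mm > 0,
            max_rotation_deg >= 0,
            shrink_factor >= 0, shrink_factor < 1,
            translation_frac >= 0, translation_frac < 0.5,
            noise_sd >= 0,
            all(regions %in% names(region_mri_means)),
            all(regions %in% names(region_rgb_means)))
  if (anyDuplicated(region_mri_means[regions]))
    stop("phantom_spec: region MRI means must be distinct")
  fov <- (in_plane_size - 1) * in_plane_mm
  ctr <- fov / 2
  half_z <- (n_slices - 1) * slice_mm / 2
  geom <- list(
    # all mm; gland with gentle apex/base taper and a realistically
    # asymmetric axial outline (lateral lobes, fuller posterior, slight
    # left-right imbalance -- prostate sections are not ellipses, and the
    # asymmetry is what makes mounting rotations recoverable from the mask),
    # posterior crescent peripheral zone, curved urethra tube, lateral
    # cancer focus
    center = c(ctr, ctr),
    prostate_r0 = 0.205 * fov,
    # polar radius modulation r(phi) = r0 * f(z) * shape(phi)
    shape_coef = c(c2 = 0.14,   # lateral (cos 2phi) elongation
                   s1 = 0.20,   # fuller posterior (sin phi)
                   c1 = 0.14,   # left-right imbalance (cos phi)
                   s3 = 0.10),  # lobular detail (sin 3phi)
    prostate_az = 2.0 * half_z,
    pz_inner_scale = 0.72,
    urethra_radius = max(0.058 * 0.205 * fov, 2.4 * in_plane_mm),
    urethra_slope = 0.12,                 # mm lateral drift per mm of z
    urethra_post_mm = 3.0,
    cancer_center_off = c(-7, 5),
    cancer_ax = 6.5, cancer_ay = 5,
    cancer_az = 1.6 * max(half_z, 4),
    half_z = half_z)
  structure(list(in_plane_size = as.integer(in_plane_size),
                 n_slices = as.integer(n_slices),
                 in_plane_mm = in_plane_mm, slice_mm = slice_mm,
                 region_mri_means = region_mri_means,
                 region_rgb_means = region_rgb_means,
                 noise_sd = noise_sd,
                 max_rotation_deg = max_rotation_deg,
                 shrink_factor = shrink_factor,
                 translation_frac = translation_frac,
                 slice_offset_mm = slice_offset_mm,
                 flip_lr = isTRUE(flip_lr),
                 seed = as.integer(seed),
                 geom = geom),
            class = "phantom_spec")
}

# z position (mm, gland-centred) of MRI slice i. The gland centre sits 0.3
# slice thicknesses off the stack midplane so apex/base taper is visible for
# any slice count (real glands are never sampled symmetrically).
slice_z <- function(spec, i)
  (i - (spec$n_slices + 1) / 2 - 0.3) * spec$slice_mm

# Rasterize the analytic anatomy at out-of-plane position z. Returns an
# integer label matrix: 0 background, 1 prostate, 2 peripheral zone,
# 3 cancer, 4 urethra (precedence urethra > cancer > peripheral_zone >
# prostate).
rasterize_labels <- function(spec, z) {
  g <- spec$geom
  n <- spec$in_plane_size
  co <- (seq_len(n) - 1) * spec$in_plane_mm
  X <- matrix(co, n, n, byrow = TRUE)
  Y <- matrix(co, n, n)
  fz2 <- 1 - (z / g$prostate_az)^2
  lab <- matrix(0L, n, n)
  if (fz2 <= 0) return(lab)
  f <- sqrt(fz2)
  dx <- X - g$center[1]; dy <- Y - g$center[2]
  rho <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  cf <- g$shape_coef
  rb <- g$prostate_r0 * f *
    (1 + cf["c2"] * cos(2 * phi) + cf["s1"] * sin(phi) +
       cf["c1"] * cos(phi) + cf["s3"] * sin(3 * phi))
  prost <- rho <= rb
  lab[prost] <- 1L
  # peripheral zone: posterior (larger y) band between the gland boundary
  # and the same outline scaled inward
  lab[prost & rho > g$pz_inner_scale * rb & dy > 0] <- 2L
  # cancer focus
  cz2 <- 1 - (z / g$cancer_az)^2
  if (cz2 > 0) {
    fc <- sqrt(cz2)
    cc <- g$center + g$cancer_center_off
    canc <- ((X - cc[1]) / (g$cancer_ax * fc))^2 +
      ((Y - cc[2]) / (g$cancer_ay * fc))^2 <= 1
    lab[prost & canc] <- 3L
  }
  # urethra tube
  ux <- g$center[1] + g$urethra_slope * z
  uy <- g$center[2] - g$urethra_post_mm
  ur <- (X - ux)^2 + (Y - uy)^2 <= g$urethra_radius^2
  lab[prost & ur] <- 4L
  lab
}

#' Generate the labeled 3D phantom anatomy
#'
#' Rasterizes the analytic anatomy (ellipsoidal prostate, posterior-crescent
#' peripheral zone, thin curved urethra, lateral cancer focus) on the MRI
#' slice grid. Labels are mutually exclusive per voxel with precedence
#' urethra > cancer > peripheral zone > prostate.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return List with \code{labels} (H x W x D integer array), per-region mask
#'   lists \code{prostate, peripheral_zone, cancer, urethra} (the prostate
#'   masks include all interior structures), and \code{spec}.
#' @export
make_anatomy <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  D <- spec$n_slices
  n <- spec$in_plane_size
  labels <- array(0L, c(n, n, D))
  for (i in seq_len(D)) {
    lab <- rasterize_labels(spec, slice_z(spec, i))
    if (!any(lab > 0))
      stop(sprintf("make_anatomy: prostate empty at slice %d", i))
    labels[, , i] <- lab
  }
  masks <- function(which_lab, incl = NULL) {
    lapply(seq_len(D), function(i) {
      m <- labels[, , i]
      if (is.null(incl)) (m == which_lab) * 1 else (m %in% incl) * 1
    })
  }
  list(labels = labels,
       prostate = lapply(seq_len(D), function(i) (labels[, , i] > 0) * 1),
       peripheral_zone = masks(2L),
       cancer = masks(3L),
       urethra = masks(4L),
       spec = spec)
}

#' Synthesize the phantom T2w MRI volume
#'
#' Fills each region with its configured mean intensity and adds i.i.d.
#' Gaussian noise. Deterministic given \code{spec$seed}.
#'
#' @param anatomy Output of \code{\link{make_anatomy}}.
#' @param spec The same \code{\link{phantom_spec}}.
#' @return An \code{\link{mri_volume}}.
#' @export
synthesize_mri <- function(anatomy, spec) {
  means <- spec$region_mri_means[c("background", "prostate", "peripheral_zone",
                                   "cancer", "urethra")]
  vol <- array(means[anatomy$labels + 1L], dim(anatomy$labels))
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, spec$noise_sd), dim(vol))
  }
  mri_volume(img = vol, mask = (anatomy$labels > 0) * 1,
             spacing = c(spec$in_plane_mm, spec$in_plane_mm, spec$slice_mm))
}

#' Synthesize the artifact-free phantom histology stack
#'
#' One RGB slice per anatomy slice, filled with the per-region mean colors
#' plus Gaussian noise, generated on the MRI slice grid (same size and pixel
#' spacing, so the zero-artifact registration is exactly the identity). With
#' \code{spec$slice_offset_mm != 0} the histology anatomy is sampled that far
#' along the slice axis from the paired MRI slice, emulating imperfect slice
#' correspondence. Noiseless copies are retained for artifact injection.
#'
#' @param anatomy Output of \code{\link{make_anatomy}}.
#' @param spec The same \code{\link{phantom_spec}}.
#' @return A \code{\link{hist_stack}}.
#' @export
synthesize_histology <- function(anatomy, spec) {
  D <- spec$n_slices
  n <- spec$in_plane_size
  rgbm <- spec$region_rgb_means
  order_regions <- c("background", "prostate", "peripheral_zone", "cancer",
                     "urethra")
  set.seed(spec$seed + 1L)
  slices <- vector("list", D); clean <- vector("list", D)
  masks <- vector("list", D); cancer <- vector("list", D)
  urethra <- vector("list", D)
  for (i in seq_len(D)) {
    lab <- rasterize_labels(spec, slice_z(spec, i) + spec$slice_offset_mm)
    if (!any(lab > 0))
      stop(sprintf("synthesize_histology: prostate empty at slice %d", i))
    img <- array(0, c(n, n, 3))
    for (ch in 1:3) {
      mv <- vapply(order_regions, function(r) rgbm[[r]][ch], numeric(1))
      img[, , ch] <- matrix(mv[lab + 1L], n, n)
    }
    clean[[i]] <- img
    noisy <- img
    if (spec$noise_sd > 0)
      noisy <- noisy + array(stats::rnorm(length(img), 0, spec$noise_sd),
                             dim(img))
    slices[[i]] <- clip255(noisy)
    masks[[i]] <- (lab > 0) * 1
    cancer[[i]] <- (lab == 3L) * 1
    urethra[[i]] <- (lab == 4L) * 1
  }
  hist_stack(slices = slices, masks = masks, cancer = cancer,
             urethra = urethra, pixel_size = spec$in_plane_mm,
             correspondence = seq_len(D), clean = clean)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Inject histologic-processing artifacts into a histology stack
#'
#' Each slice is independently rotated by an angle drawn uniformly from
#' [-r, r] about the slice centre, shrunk to scale (1 - s) about the centre,
#' and (only when s > 0, matching the study design in which rotation-only
#' experiments carry no translation) translated by up to
#' \code{translation_frac} of the image width independently in x and y; an
#' optional left-right flip is applied first. Images are resampled once
#' (bilinear; nearest-neighbour for masks and labels) and noise is re-drawn
#' after resampling. Ground-truth per-slice similarity parameters are
#' returned.
#'
#' @param stack Artifact-free \code{\link{hist_stack}} from
#'   \code{\link{synthesize_histology}} (with noiseless copies).
#' @param spec The \code{\link{phantom_spec}}.
#' @return List \code{(stack, truth)}: the corrupted stack and a data frame
#'   with one row per slice (\code{slice, angle_deg, scale, tx_mm, ty_mm,
#'   flip}).
#' @export
apply_artifacts <- function(stack, spec) {
  D <- length(stack$slices)
  n <- nrow(stack$masks[[1]])
  sp <- stack$pixel_size
  ctr <- c((n - 1) * sp / 2, (n - 1) * sp / 2)
  set.seed(spec$seed + 2L)
  r <- spec$max_rotation_deg
  s <- spec$shrink_factor
  ang <- if (r > 0) stats::runif(D, -r, r) else numeric(D)
  width_mm <- (n - 1) * sp
  tr <- if (s > 0) {
    matrix(stats::runif(2 * D, -spec$translation_frac, spec$translation_frac) *
             width_mm, D, 2)
  } else matrix(0, D, 2)
  out <- stack
  truth <- data.frame(slice = seq_len(D), angle_deg = ang, scale = 1 - s,
                      tx_mm = tr[, 1], ty_mm = tr[, 2], flip = spec$flip_lr)
  for (i in seq_len(D)) {
    A <- rotmat(ang[i]) * (1 - s)
    if (spec$flip_lr) A <- A %*% diag(c(-1, 1))
    fwd <- affine2d(A = A, t = tr[i, ], center = ctr)   # original -> corrupted
    inv <- tf_invert(fwd)                               # resampling map
    src <- if (!is.null(stack$clean)) stack$clean[[i]] else stack$slices[[i]]
    img <- resample_image(src, inv, spacing = sp, interp = "linear",
                          default = spec$region_rgb_means$background[1])
    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    out$slices[[i]] <- clip255(img)
    out$masks[[i]] <- resample_image(stack$masks[[i]], inv, spacing = sp,
                                     interp = "nearest")
    if (sum(out$masks[[i]]) == 0)
      stop(sprintf("apply_artifacts: prostate pushed outside the frame at slice %d", i))
    out$cancer[[i]] <- resample_image(stack$cancer[[i]], inv, spacing = sp,
                                      interp = "nearest")
    out$urethra[[i]] <- resample_image(stack$urethra[[i]], inv, spacing = sp,
                                       interp = "nearest")
    truth$angle_deg[i] <- ang[i]
  }
  out$clean <- NULL
  list(stack = out, truth = truth)
}

#' Generate a complete phantom case
#'
#' Convenience wrapper: anatomy, MRI volume, artifact-free histology,
#' corrupted histology and ground truth in one object.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return List of class \code{"phantom_case"} with \code{anatomy, mri,
#'   stack} (corrupted), \code{clean_stack}, \code{truth}, \code{spec}.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  anatomy <- make_anatomy(spec)
  mri <- synthesize_mri(anatomy, spec)
  clean <- synthesize_histology(anatomy, spec)
  art <- apply_artifacts(clean, spec)
  structure(list(anatomy = anatomy, mri = mri, stack = art$stack,
                 clean_stack = clean, truth = art$truth, spec = spec),
            class = "phantom_case")
}
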