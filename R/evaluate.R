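# End-to-end evaluation of a registered case against reference masks/labels
# on the MRI grid, and the phantom recovery experiment driver.

label_com <- function(mask, spacing) {
  if (sum(mask > 0) == 0) return(c(NA_real_, NA_real_))
  mask_centroid(mask, spacing)
}

#' Evaluate a registered phantom case against its ground truth
#'
#' Warps the (corrupted) histology prostate mask and labels onto the MRI grid
#' through the composite chains and computes the slice-averaged Dice,
#' boundary Hausdorff (mm), urethra centre-of-mass deviation (mm) and mean
#' landmark deviation (mm, cancer and urethra centres of mass per slice), as
#' well as per-slice rotation/scale recovery errors against the injected
#' artifact transforms. Stage-wise Dice (input / after affine / after
#' deformable) is reported for monotonicity checks.
#'
#' @param phantom A \code{"phantom_case"} from \code{\link{generate_phantom}}.
#' @param chains A \code{"case_chains"} from \code{\link{register_case}}.
#' @return List of class \code{"metrics_report"}.
#' @export
evaluate_phantom_case <- function(phantom, chains) {
  st <- phantom$stack
  an <- phantom$anatomy
  sp <- st$pixel_size
  D <- length(st$slices)
  out_dim <- dim(an$labels)[1:2]

  chain_stage <- function(ch, stage) {
    if (stage == "final") return(ch)
    zero <- bspline2d(ch$field$mesh, ch$field$domain)
    if (stage == "affine") return(slice_chain(ch$rigid, ch$affine, zero,
                                              ch$slice, ch$mri_slice))
    # input: identity mapping
    slice_chain(rigid2d(), affine2d(), zero, ch$slice, ch$mri_slice)
  }
  stage_dice <- function(stage) {
    warped <- lapply(seq_len(D), function(i)
      warp_label(st$masks[[i]], chain_stage(chains[[i]], stage),
                 out_dim = out_dim, spacing = sp))
    list(warped = warped,
         dice = dice_stack(warped, an$prostate[st$correspondence]))
  }
  input <- stage_dice("input")
  affine <- stage_dice("affine")
  final <- stage_dice("final")

  haus <- tryCatch(
    hausdorff_stack(final$warped, an$prostate[st$correspondence], sp),
    error = function(e) NA_real_)

  warped_ur <- lapply(seq_len(D), function(i)
    warp_label(st$urethra[[i]], chains[[i]], out_dim = out_dim, spacing = sp))
  ur <- tryCatch(
    urethra_deviation(warped_ur, an$urethra[st$correspondence], sp),
    error = function(e) NA_real_)

  # landmarks: cancer + urethra centres of mass per slice
  lm_rows <- list()
  for (i in seq_len(D)) {
    k <- st$correspondence[i]
    for (lab in c("cancer", "urethra")) {
      hc <- label_com(st[[lab]][[i]], sp)
      mc <- label_com(an[[lab]][[k]], sp)
      if (anyNA(hc) || anyNA(mc)) next
      lm_rows[[length(lm_rows) + 1]] <-
        data.frame(name = sprintf("%s_s%02d", lab, i), slice = i,
                   x_mm = hc[1], y_mm = hc[2],
                   ref_x = mc[1], ref_y = mc[2])
    }
  }
  lm_mm <- NA_real_
  if (length(lm_rows) > 0) {
    lm <- do.call(rbind, lm_rows)
    mapped <- warp_landmarks(lm[, c("name", "slice", "x_mm", "y_mm")], chains)
    ref <- data.frame(name = lm$name, x_mm = lm$ref_x, y_mm = lm$ref_y)
    lm_mm <- tryCatch(landmark_distance(mapped, ref[match(mapped$name, ref$name), ]),
                      error = function(e) NA_real_)
  }

  # per-slice rotation/scale recovery: linear part of the composite
  # histology -> MRI map vs the inverse of the injected similarity
  ang_err <- numeric(D); scale_rec <- numeric(D)
  for (i in seq_len(D)) {
    ch <- chains[[i]]
    M <- tf_matrix(ch$affine) %*% tf_matrix(tf_invert(ch$rigid))
    rec <- tf_rotation_deg(affine_from_matrix(M))
    gt <- -phantom$truth$angle_deg[i]      # corrupted -> original rotation
    ang_err[i] <- abs(normalize_angle(rec - gt))
    scale_rec[i] <- sqrt(abs(det(M[1:2, 1:2])))
  }

  structure(list(dice = final$dice,
                 dice_affine = affine$dice,
                 dice_input = input$dice,
                 hausdorff_mm = haus,
                 urethra_mm = ur,
                 landmark_mm = lm_mm,
                 angle_err_deg = ang_err,
                 scale_recovered = scale_rec,
                 scale_true = phantom$truth$scale,
                 n_slices = D),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("registration metrics over %d slices:\n",
                     "  Dice (input/affine/final): %.3f / %.3f / %.3f\n",
                     "  Hausdorff: %.2f mm  urethra: %.2f mm  landmarks: %.2f mm\n",
                     "  max |angle error|: %.2f deg\n"),
              x$n_slices, x$dice_input, x$dice_affine, x$dice,
              x$hausdorff_mm, x$urethra_mm, x$landmark_mm,
              max(x$angle_err_deg)))
  invisible(x)
}

#' Run a phantom recovery experiment sweep
#'
#' For each condition x repetition (distinct seeds), generates a phantom,
#' runs the full registration pipeline and evaluates all metrics against the
#' phantom ground truth. A failed registration is recorded as a failed row,
#' not a crash of the sweep.
#'
#' @param conditions List of \code{\link{phantom_spec}} objects (their
#'   \code{seed} is re-derived per repetition).
#' @param n_reps Repetitions per condition.
#' @param config A \code{\link{registration_config}}.
#' @param base_seed Base seed; the seed of condition c, rep k is
#'   \code{base_seed + 1009 * c + k}.
#' @return Tidy data frame: one row per condition x rep with columns
#'   \code{condition, rep, r_deg, shrink, offset_mm, dice, dice_affine,
#'   dice_input, hausdorff_mm, urethra_mm, landmark_mm, angle_err_deg,
#'   scale_err, ok, error}.
#' @export
run_phantom_experiment <- function(conditions, n_reps = 10,
                                   config = registration_config(),
                                   base_seed = 20210L) {
  rows <- list()
  for (ci in seq_along(conditions)) {
    for (k in seq_len(n_reps)) {
      spec <- conditions[[ci]]
      spec$seed <- as.integer(base_seed + 1009L * ci + k)
      row <- data.frame(condition = ci, rep = k,
                        r_deg = spec$max_rotation_deg,
                        shrink = spec$shrink_factor,
                        offset_mm = spec$slice_offset_mm,
                        dice = NA_real_, dice_affine = NA_real_,
                        dice_input = NA_real_, hausdorff_mm = NA_real_,
                        urethra_mm = NA_real_, landmark_mm = NA_real_,
                        angle_err_deg = NA_real_, scale_err = NA_real_,
                        ok = FALSE, error = "")
      res <- tryCatch({
        ph <- generate_phantom(spec)
        chains <- register_case(ph$mri, ph$stack, config)
        evaluate_phantom_case(ph, chains)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        row$dice <- res$dice
        row$dice_affine <- res$dice_affine
        row$dice_input <- res$dice_input
        row$hausdorff_mm <- res$hausdorff_mm
        row$urethra_mm <- res$urethra_mm
        row$landmark_mm <- res$landmark_mm
        row$angle_err_deg <- mean(res$angle_err_deg)
        row$scale_err <- mean(abs(res$scale_recovered - 1 / res$scale_true))
        row$ok <- TRUE
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Summarize a phantom experiment by condition
#'
#' Means and variances of every metric per condition (the per-condition
#' summary the sweep figures report).
#'
#' @param results Output of \code{\link{run_phantom_experiment}}.
#' @return Data frame with one row per condition.
#' @export
summarize_experiment <- function(results) {
  sp <- split(results, results$condition)
  do.call(rbind, lapply(sp, function(d) {
    ok <- d[d$ok, ]
    data.frame(condition = d$condition[1], r_deg = d$r_deg[1],
               shrink = d$shrink[1], offset_mm = d$offset_mm[1],
               n = nrow(d), n_ok = nrow(ok),
               dice_mean = mean(ok$dice), dice_var = stats::var(ok$dice),
               hausdorff_mean = mean(ok$hausdorff_mm),
               hausdorff_var = stats::var(ok$hausdorff_mm),
               urethra_mean = mean(ok$urethra_mm),
               landmark_mean = mean(ok$landmark_mm),
               angle_err_mean = mean(ok$angle_err_deg))
  }))
}
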