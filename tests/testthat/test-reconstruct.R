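# Histology stack reconstruction: anchor slice, pairwise rigid recovery,
# outward chaining.

test_that("the anchor slice index follows the floor rule", {
  expect_equal(middle_index(6), 3)
  expect_equal(middle_index(7), 3)
  expect_equal(middle_index(1), 0)
  expect_error(middle_index(0), "D >= 1")
})

test_that("pairwise rigid registration recovers identity, rotation and translation", {
  sp <- 0.5
  n <- 96
  co <- (seq_len(n) - 1) * sp
  X <- matrix(co, n, n, byrow = TRUE); Y <- matrix(co, n, n)
  ctr <- (n - 1) * sp / 2
  # asymmetric blob (two fused disks) so rotation is well determined
  blob <- ((X - ctr)^2 + (Y - ctr)^2 <= 14^2) |
    ((X - ctr - 10)^2 + (Y - ctr + 6)^2 <= 8^2)
  blob <- blob * 1
  # identity
  tf0 <- register_rigid_pair(blob, blob, sp)
  expect_lt(abs(tf0$angle_deg), 0.5)
  expect_lt(max(abs(tf0$t)), 0.5 * sp)
  # +10 degree content rotation: the resampling map must carry +10
  fwd <- rigid2d(10, 0, 0, ctr, ctr)
  rot <- resample_image(blob, tf_invert(fwd), spacing = sp, interp = "nearest")
  tfr <- register_rigid_pair(rot, blob, sp)
  expect_equal(tf_rotation_deg(tfr), 10, tolerance = 1)
  expect_gte(attr(tfr, "dice_after"), 0.98)
  # two same-size disks offset by 10 px: translation recovered within 1 px
  d1 <- (((X - ctr)^2 + (Y - ctr)^2) <= 12^2) * 1
  d2 <- (((X - ctr - 10 * sp)^2 + (Y - ctr)^2) <= 12^2) * 1
  tft <- register_rigid_pair(d2, d1, sp)
  expect_equal(tft$t[1] / sp, 10, tolerance = 1)
  expect_equal(tft$t[2] / sp, 0, tolerance = 1)
  expect_gte(attr(tft, "dice_after"), 0.98)
  expect_error(register_rigid_pair(matrix(0, 8, 8), d1, sp), "moving")
  expect_error(register_rigid_pair(d1, matrix(0, 8, 8), sp), "fixed")
})

test_that("reconstruction anchors the middle slice and chains consistently", {
  spec <- small_spec(max_rotation_deg = 15, seed = 55L)
  ph <- generate_phantom(spec)
  tfs <- reconstruct_stack(ph$stack)
  D <- length(tfs)
  mid <- middle_index(D) + 1
  expect_equal(tfs[[mid]]$angle_deg, 0)
  expect_equal(tfs[[mid]]$t, c(0, 0))
  # chain consistency: total(j) == pairwise(j) o total(neighbour), exactly
  pw <- attr(tfs, "pairwise")
  for (j in seq_len(D)) {
    if (j == mid) next
    nb <- if (j < mid) j + 1 else j - 1
    expect_equal(tf_matrix(tfs[[j]]),
                 tf_matrix(tf_compose(pw[[j]], tfs[[nb]])), tolerance = 1e-9)
  }
  # adjacent-pair mask Dice does not fall below the unaligned value
  sp <- ph$stack$pixel_size
  aligned <- lapply(seq_len(D), function(j)
    resample_image(ph$stack$masks[[j]], tfs[[j]], spacing = sp,
                   interp = "nearest"))
  pair_dice <- function(masks) mean(vapply(seq_len(D - 1), function(j)
    dice_stack(masks[j], masks[j + 1]), 0))
  expect_gte(pair_dice(aligned), pair_dice(ph$stack$masks))
})

test_that("an aligned stack reconstructs to near-identity transforms", {
  spec <- small_spec(seed = 56L)   # no artifacts
  ph <- generate_phantom(spec)
  tfs <- reconstruct_stack(ph$stack)
  for (tf in tfs) {
    expect_lt(abs(tf$angle_deg), 1)
    expect_lt(max(abs(tf$t)), 1)    # mm
  }
  # single-slice stack: one identity transform
  st1 <- hist_stack(slices = ph$stack$slices[1], masks = ph$stack$masks[1],
                    pixel_size = ph$stack$pixel_size, correspondence = 1L)
  tf1 <- reconstruct_stack(st1)
  expect_length(tf1, 1)
  expect_equal(tf_matrix(tf1[[1]]), diag(3), tolerance = 1e-12)
})

test_that("per-slice rotations are recovered relative to the anchor frame", {
  cs <- registered_small_case()
  ph <- cs$phantom
  tfs <- lapply(cs$chains, function(ch) ch$rigid)
  mid <- middle_index(length(tfs)) + 1
  # the anchor keeps its injected rotation; every other slice's rigid must
  # account for its rotation relative to the anchor's frame
  for (j in seq_along(tfs)) {
    if (j == mid) next
    rel_gt <- ph$truth$angle_deg[j] - ph$truth$angle_deg[mid]
    expect_equal(tf_rotation_deg(tfs[[j]]), rel_gt, tolerance = 2)
  }
})
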