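# Digital phantom: anatomy partition, intensity model, determinism, and the
# injected-artifact contracts.

rotmat_deg2 <- function(a) {
  th <- a * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

test_that("anatomy labels partition the grid with the stated precedence", {
  spec <- tiny_spec()
  an <- make_anatomy(spec)
  D <- spec$n_slices
  for (i in seq_len(D)) {
    lab <- an$labels[, , i]
    # masks are pairwise disjoint and tile the grid with background
    s <- (lab == 1) + (lab == 2) + (lab == 3) + (lab == 4) + (lab == 0)
    expect_true(all(s == 1))
    expect_gt(sum(an$prostate[[i]]), 0)
    # interior structures lie inside the prostate
    expect_true(all(an$prostate[[i]][an$cancer[[i]] > 0] == 1))
    expect_true(all(an$prostate[[i]][an$urethra[[i]] > 0] == 1))
    expect_equal(sum(an$cancer[[i]] * an$urethra[[i]]), 0)
  }
  # at the study scale the urethra is a small blob (< 2% of the gland)
  an_big <- make_anatomy(small_spec())
  for (i in seq_len(4))
    expect_lt(sum(an_big$urethra[[i]]), 0.02 * sum(an_big$prostate[[i]]))
  # apex/base taper: end slices smaller than the middle
  areas <- vapply(an$prostate, sum, 0)
  expect_lt(areas[1], max(areas))
  an2 <- make_anatomy(phantom_spec(n_slices = 2))
  expect_false(sum(an2$prostate[[1]]) == sum(an2$prostate[[2]]) &&
                 isTRUE(all.equal(an2$prostate[[1]], an2$prostate[[2]])))
})

test_that("MRI synthesis fills regions with configured means plus noise", {
  spec0 <- tiny_spec(noise_sd = 0)
  an <- make_anatomy(spec0)
  mri <- synthesize_mri(an, spec0)
  lab <- an$labels
  means <- spec0$region_mri_means
  for (r in seq_along(means)) {
    sel <- lab == (r - 1)
    if (any(sel)) expect_true(all(mri$img[sel] == means[r]))
  }
  # CLT check: with sd 10 the per-region sample mean stays within
  # 3 * 10 / sqrt(N) of the configured mean
  spec1 <- tiny_spec(noise_sd = 10, seed = 9L)
  mri1 <- synthesize_mri(an, spec1)
  for (r in c(1, 2)) {
    sel <- lab == (r - 1)
    n <- sum(sel)
    expect_lt(abs(mean(mri1$img[sel]) - means[r]), 3 * 10 / sqrt(n))
  }
  # determinism: same seed, bit-identical volumes
  expect_identical(synthesize_mri(an, spec1)$img, mri1$img)
})

test_that("histology synthesis shares the anatomy and honors the slice offset", {
  spec0 <- tiny_spec(noise_sd = 0)
  an <- make_anatomy(spec0)
  st <- synthesize_histology(an, spec0)
  # zero noise: each slice has exactly as many distinct colors as regions
  lab1 <- an$labels[, , 1]
  n_regions <- length(unique(as.vector(lab1)))
  col_key <- st$slices[[1]][, , 1] + 1000 * st$slices[[1]][, , 2] +
    1e6 * st$slices[[1]][, , 3]
  expect_equal(length(unique(as.vector(col_key))), n_regions)
  # perfect correspondence: histology mask equals the MRI-frame mask
  expect_equal(st$masks[[2]], an$prostate[[2]])
  # 2 mm out-of-plane offset: masks differ from the paired MRI slice
  spec2 <- tiny_spec(noise_sd = 0, slice_offset_mm = 2)
  st2 <- synthesize_histology(make_anatomy(spec2), spec2)
  expect_gt(sum(abs(st2$masks[[2]] - an$prostate[[2]])), 0)
})

test_that("artifact injection draws within declared ranges and is invertible", {
  spec <- small_spec(noise_sd = 0, max_rotation_deg = 20, seed = 21L)
  ph_clean <- synthesize_histology(make_anatomy(spec), spec)
  art <- apply_artifacts(ph_clean, spec)
  expect_true(all(abs(art$truth$angle_deg) <= 20))
  expect_true(all(art$truth$scale == 1))          # no shrink requested
  expect_true(all(art$truth$tx_mm == 0))          # rotation-only: no translation
  # identity case: no artifacts leave the stack pixel-identical
  spec_id <- small_spec(noise_sd = 0)
  clean_id <- synthesize_histology(make_anatomy(spec_id), spec_id)
  art_id <- apply_artifacts(clean_id, spec_id)
  expect_identical(art_id$stack$masks, clean_id$masks)
  expect_equal(art_id$stack$slices[[1]], clean_id$slices[[1]], tolerance = 1e-12)
  expect_true(all(art_id$truth$angle_deg == 0))
  # shrinkage scales areas by (1 - s)^2 and triggers translations
  spec_s <- small_spec(noise_sd = 0, shrink_factor = 0.2, seed = 22L)
  clean_s <- synthesize_histology(make_anatomy(spec_s), spec_s)
  art_s <- apply_artifacts(clean_s, spec_s)
  for (i in seq_along(clean_s$masks)) {
    ratio <- sum(art_s$stack$masks[[i]]) / sum(clean_s$masks[[i]])
    expect_equal(ratio, 0.8^2, tolerance = 0.02)
  }
  expect_true(any(art_s$truth$tx_mm != 0) || any(art_s$truth$ty_mm != 0))
  expect_true(all(abs(art_s$truth$tx_mm) <=
                    0.05 * (spec_s$in_plane_size - 1) * spec_s$in_plane_mm))
  # invertibility: applying the inverse ground-truth transform recovers the
  # original mask (Dice >= 0.98, interpolation-limited)
  spec_rs <- small_spec(noise_sd = 0, max_rotation_deg = 15,
                        shrink_factor = 0.1, seed = 23L)
  clean_rs <- synthesize_histology(make_anatomy(spec_rs), spec_rs)
  art_rs <- apply_artifacts(clean_rs, spec_rs)
  n <- spec_rs$in_plane_size
  ctr <- rep((n - 1) * spec_rs$in_plane_mm / 2, 2)
  for (i in seq_along(clean_rs$masks)) {
    gt <- art_rs$truth[i, ]
    A <- rotmat_deg2(gt$angle_deg) * gt$scale
    fwd <- affine2d(A, c(gt$tx_mm, gt$ty_mm), ctr)
    rec <- resample_image(art_rs$stack$masks[[i]], fwd,
                          spacing = spec_rs$in_plane_mm, interp = "nearest")
    d <- dice_stack(list(rec), list(clean_rs$masks[[i]]))
    expect_gte(d, 0.98)
  }
})

test_that("phantom generation is deterministic and angle draws are uniform", {
  spec <- tiny_spec(max_rotation_deg = 10, seed = 31L)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$mri$img, p2$mri$img)
  expect_identical(p1$stack$slices, p2$stack$slices)
  expect_identical(p1$truth, p2$truth)
  # pooled angle draws across many seeds are uniform on [-r, r]
  spec_a <- phantom_spec(in_plane_size = 64L, n_slices = 8L,
                         max_rotation_deg = 12, noise_sd = 0)
  an <- make_anatomy(spec_a)
  clean <- synthesize_histology(an, spec_a)
  angles <- unlist(lapply(1:130, function(k) {
    s <- spec_a; s$seed <- 1000L + k
    apply_artifacts(clean, s)$truth$angle_deg
  }))
  expect_gte(length(angles), 1000)
  ks <- suppressWarnings(stats::ks.test(angles, "punif", -12, 12))
  expect_gt(ks$p.value, 0.01)
})
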