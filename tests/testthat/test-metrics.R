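# Evaluation metrics against brute-force oracles and the stated edge rules.

# brute-force oracles: straight re-implementations by pixel/pair enumeration
brute_dice <- function(a, b) {
  na <- sum(a > 0); nb <- sum(b > 0)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  inter <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    if (a[i, j] > 0 && b[i, j] > 0) inter <- inter + 1
  2 * inter / (na + nb)
}

brute_boundary <- function(m) {
  pts <- NULL
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (m[i, j] > 0) {
      nb <- c(if (i > 1) m[i - 1, j] else 0, if (i < H) m[i + 1, j] else 0,
              if (j > 1) m[i, j - 1] else 0, if (j < W) m[i, j + 1] else 0)
      if (any(nb == 0) || i == 1 || i == H || j == 1 || j == W)
        pts <- rbind(pts, c(i, j))
    }
  }
  pts
}

brute_hausdorff <- function(a, b, px) {
  pa <- brute_boundary(a); pb <- brute_boundary(b)
  dab <- max(apply(pa, 1, function(p)
    min(sqrt((pb[, 1] - p[1])^2 + (pb[, 2] - p[2])^2))))
  dba <- max(apply(pb, 1, function(p)
    min(sqrt((pa[, 1] - p[1])^2 + (pa[, 2] - p[2])^2))))
  max(dab, dba) * px
}

test_that("stack Dice matches hand-computed and brute-force values", {
  sq <- function(r, c) { m <- matrix(0, 8, 8); m[r, c] <- 1; m }
  a1 <- sq(3:4, 3:4)
  b1 <- sq(3:4, 4:5)           # shares a 2x1 strip: 2*2/(4+4) = 0.5
  expect_equal(dice_stack(list(a1, a1), list(a1, b1)), 0.75)
  expect_equal(dice_stack(list(a1), list(a1)), 1)
  expect_equal(dice_stack(list(sq(1:2, 1:2)), list(sq(5:6, 5:6))), 0)
  set.seed(11)
  for (k in 1:5) {
    a <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
    b <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
    expect_equal(dice_stack(list(a), list(b)), brute_dice(a, b))
    expect_equal(dice_stack(list(a), list(b)), dice_stack(list(b), list(a)))
  }
  expect_error(dice_stack(list(a1, a1), list(a1)), "slice counts")
})

test_that("stack Hausdorff matches brute-force boundary-pair enumeration", {
  disk <- function(r0) {
    co <- seq_len(32)
    m <- outer(co, co, function(i, j) ((i - 16)^2 + (j - 16)^2 <= r0^2) * 1)
    m
  }
  # concentric axis-aligned squares, half-widths 10 and 12 px, 0.4 mm pixels:
  # farthest boundary points are corner-to-corner, 2*sqrt(2) px
  sqm <- function(h) { m <- matrix(0, 32, 32); m[(16 - h):(16 + h), (16 - h):(16 + h)] <- 1; m }
  expect_equal(hausdorff_stack(list(sqm(10)), list(sqm(12)), 0.4),
               2 * sqrt(2) * 0.4, tolerance = 1e-9)
  expect_equal(hausdorff_stack(list(disk(8)), list(disk(8)), 0.5), 0)
  set.seed(12)
  for (k in 1:4) {
    a <- disk(sample(6:12, 1)); b <- disk(sample(6:12, 1))
    expect_equal(hausdorff_stack(list(a), list(b), 0.4),
                 brute_hausdorff(a, b, 0.4), tolerance = 1e-9)
    expect_equal(hausdorff_stack(list(a), list(b), 0.4),
                 hausdorff_stack(list(b), list(a), 0.4))
  }
  # mean over slices equals hand-computed mean on a 3-slice toy
  hs <- hausdorff_stack(list(sqm(10), sqm(10), sqm(8)),
                        list(sqm(12), sqm(10), sqm(12)), 0.4)
  expect_equal(hs, mean(c(2 * sqrt(2) * 0.4, 0, 4 * sqrt(2) * 0.4)),
               tolerance = 1e-9)
  expect_error(hausdorff_stack(list(sqm(4)), list(matrix(0, 32, 32)), 0.4),
               "empty")
})

test_that("landmark distance averages Euclidean distances matched by name", {
  lm <- function(...) {
    v <- list(...)
    data.frame(name = vapply(v, `[[`, "", 1),
               x_mm = vapply(v, function(z) as.numeric(z[2]), 0),
               y_mm = vapply(v, function(z) as.numeric(z[3]), 0))
  }
  a <- lm(c("p1", 0, 0), c("p2", 5, 5))
  expect_equal(landmark_distance(a, a), 0)
  # 3-4-5 triangle at 0.4 mm/px: offset (3, 4) px = 5 px = 2 mm
  b <- lm(c("p1", 3 * 0.4, 4 * 0.4), c("p2", 5, 5))
  expect_equal(landmark_distance(a, b), 1.0)   # mean of 2 mm and 0 mm
  d3 <- lm(c("a", 1, 0), c("b", 2, 0), c("c", 3, 0))
  z3 <- lm(c("a", 0, 0), c("b", 0, 0), c("c", 0, 0))
  expect_equal(landmark_distance(d3, z3), 2)
  expect_error(landmark_distance(a, lm(c("p1", 0, 0), c("q", 1, 1))),
               "unmatched")
})

test_that("urethra deviation averages only slices visible in both modalities", {
  blob <- function(r, c) { m <- matrix(0, 20, 20); m[r, c] <- 1; m }
  e <- matrix(0, 20, 20)
  h <- list(blob(5, 5), blob(10, 4), e, blob(4, 4))
  m <- list(blob(5, 10), blob(10, 19), e, e)   # only slices 1-2 qualify
  # slice 1: 5 px * 0.2 mm = 1 mm; slice 2: 15 px * 0.2 mm = 3 mm
  expect_equal(urethra_deviation(h, m, 0.2), 2.0)
  expect_equal(urethra_deviation(h, h, 0.2), 0)
  expect_error(urethra_deviation(list(e), list(blob(1, 1)), 0.2), "no slice")
})

test_that("mm-valued metrics scale with pixel size, Dice does not", {
  set.seed(13)
  a <- matrix(0, 24, 24); a[6:18, 8:16] <- 1
  b <- matrix(0, 24, 24); b[8:20, 6:14] <- 1
  expect_equal(hausdorff_stack(list(a), list(b), 0.8),
               2 * hausdorff_stack(list(a), list(b), 0.4))
  expect_equal(urethra_deviation(list(a), list(b), 0.8),
               2 * urethra_deviation(list(a), list(b), 0.4))
  expect_equal(dice_stack(list(a), list(b)), dice_stack(list(a), list(b)))
})
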