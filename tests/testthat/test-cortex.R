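test_that("6-connectivity erosion matches a brute-force neighbourhood scan", {
  # 3x3x3 solid cube inside a 7^3 volume erodes to its single center voxel
  cube <- array(FALSE, c(7, 7, 7))
  cube[3:5, 3:5, 3:5] <- TRUE
  er <- erode_mask_6conn(cube)
  expect_identical(sum(er), 1L)
  expect_true(er[4, 4, 4])
  # brute-force oracle on a random mask
  set.seed(12)
  m <- array(runif(10^3) < 0.5, c(10, 10, 10))
  er <- erode_mask_6conn(m)
  oracle <- array(FALSE, c(10, 10, 10))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    if (!m[i, j, k]) next
    keep <- TRUE
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      p <- c(i, j, k) + d
      if (any(p < 1 | p > 10) || !m[p[1], p[2], p[3]]) { keep <- FALSE; break }
    }
    oracle[i, j, k] <- keep
  }
  expect_identical(er, oracle)
})

test_that("erosion is anti-extensive and strips k layers from cuboids", {
  expect_identical(sum(erode_mask_6conn(array(FALSE, c(5, 5, 5)))), 0L)
  set.seed(3)
  m <- array(runif(12^3) < 0.6, c(12, 12, 12))
  expect_true(all(!(erode_mask_6conn(m) & !m)))   # eroded is a subset
  cuboid <- array(FALSE, c(14, 12, 10))
  cuboid[2:13, 2:11, 2:9] <- TRUE
  for (k in 1:3) {
    ek <- erode_mask_6conn(cuboid, iterations = k)
    expect_identical(sum(ek), as.integer((12 - 2 * k) * (10 - 2 * k) *
                                           (8 - 2 * k)))
  }
})

test_that("depth field matches the quadratic-time distance oracle on 20^3", {
  lab <- slab_labels(n = 20, formalin_to = 5, cortex_to = 13)
  d <- depth_field(lab)
  lc <- label_codes()
  dp <- brute_force_distance(lab$data == lc[["formalin"]], lab$voxel_size)
  dw <- brute_force_distance(lab$data == lc[["wm"]], lab$voxel_size)
  ctx <- lab$data == lc[["cortex"]]
  expect_equal(d[ctx], (dp / (dp + dw))[ctx], tolerance = 1e-12)
  expect_true(all(d[ctx] >= 0 & d[ctx] <= 1))
  expect_true(all(is.na(d[!ctx])))
})

test_that("flat slab depth is symmetric and ordered from the pial surface", {
  lab <- slab_labels(n = 20, formalin_to = 6, cortex_to = 14)  # 8-voxel ribbon
  d <- depth_field(lab)
  # mid-thickness voxels sit at 0.5 up to voxel quantization
  mid <- d[10, 10, 10:11]
  expect_true(all(abs(mid - 0.5) <= 0.5 / 4))
  # the voxel face-adjacent to formalin is in the superficial half
  expect_lt(d[10, 10, 7], 0.5)
  expect_gt(d[10, 10, 14], 0.5)
})

test_that("depth is invariant to relabeling cortex voxels as lesion", {
  sp <- small_spec()
  lab <- build_geometry(sp)
  d0 <- depth_field(lab)
  imp <- implant_lesions(lab, assign_tissue_parameters(lab, sp, depth = d0),
                         sp, depth = d0)
  d1 <- depth_field(imp$labels)
  expect_equal(d1[!is.na(d1)], d0[!is.na(d0)], tolerance = 1e-12)
  expect_identical(is.na(d1), is.na(d0))
})

test_that("depth computation demands both boundaries", {
  lc <- label_codes()
  lab <- array(lc[["cortex"]], c(8, 8, 8))
  lab[, , 1:2] <- lc[["formalin"]]
  expect_error(depth_field(label_volume(lab, 0.35)), "white matter boundary")
  lab[, , 1:2] <- lc[["wm"]]
  expect_error(depth_field(label_volume(lab, 0.35)), "pial")
})

test_that("depth-band sampling is exact on uniform maps and bands are disjoint", {
  # 9-voxel ribbon puts quantized depths at k/10, populating all three bands
  lab <- slab_labels(n = 20, formalin_to = 5, cortex_to = 14)
  d <- depth_field(lab)
  u <- array(42, dim = dim(lab$data))
  bands <- lapply(c(0.25, 0.5, 0.75), function(fr)
    sample_at_depth(u, d, fr, band = 0.05))
  for (b in bands) expect_equal(b$mean, 42)
  # pairwise disjoint membership
  key <- function(b) paste(b$table$x, b$table$y, b$table$z)
  expect_length(intersect(key(bands[[1]]), key(bands[[2]])), 0)
  expect_length(intersect(key(bands[[2]]), key(bands[[3]])), 0)
  # an empty band is an explicit empty result, not an error
  d2 <- d; d2[!is.na(d2)] <- 0.9
  empty <- sample_at_depth(u, d2, 0.25, band = 0.05)
  expect_identical(empty$n, 0L)
  expect_true(is.na(empty$mean))
})

test_that("laminar T1 is longer superficially; subpial lesions amplify it there", {
  sp <- small_spec()
  lab <- build_geometry(sp)
  d <- depth_field(lab)
  maps <- assign_tissue_parameters(lab, sp, depth = d)
  imp <- implant_lesions(lab, maps, sp, depth = d)
  ribbon <- !is.na(d)
  s25 <- sample_at_depth(imp$maps$t1, d, 0.25, mask = ribbon)
  s75 <- sample_at_depth(imp$maps$t1, d, 0.75, mask = ribbon)
  expect_gt(s25$mean, s75$mean)   # superficial layers less myelinated
  # within the lesion footprint, superficial T1 elevation beats deep elevation
  lesion <- imp$lesion_masks[[1]]
  ctx <- imp$labels$data == label_codes()[["cortex"]]
  elev <- function(fr) {
    les <- sample_at_depth(imp$maps$t1, d, fr, mask = lesion)
    ref <- sample_at_depth(imp$maps$t1, d, fr, mask = ctx)
    if (les$n == 0) 0 else les$mean - ref$mean
  }
  expect_gt(elev(0.25), elev(0.75))
})
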