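test_that("two-point rate-linear calibration hits both tissue rows exactly", {
  tab <- tissue_table_default()
  cp <- myelin_coupling(tab)
  # analytic solution of the two-point calibration, solved independently
  k1_expected <- (1 / 209 - 1 / 236) / (7.96 - 1.96)
  expect_equal(cp$k1, k1_expected, tolerance = 1e-12)
  at <- coupling_apply(c(7.96, 1.96), cp)
  expect_equal(at$t1, c(209, 236), tolerance = 1e-9)
  expect_equal(at$t2, c(64, 91), tolerance = 1e-9)
  expect_equal(at$m0, c(3797, 3835), tolerance = 1e-9)
  expect_equal(at$delta, c(0.0747, 0.0709), tolerance = 1e-9)
})

test_that("calibration refuses a non-monotone tissue table", {
  tab <- tissue_table_default()
  tab["cl", "t1_mean"] <- 150   # lesion T1 below NAC breaks monotonicity
  expect_error(myelin_coupling(tab), "non-monotone")
})

test_that("generated cortical T1 decreases strictly as myelin increases", {
  sp <- small_spec()
  lab <- build_geometry(sp)
  maps <- assign_tissue_parameters(lab, sp)
  ctx <- lab$data == label_codes()[["cortex"]]
  m <- maps$myelin[ctx]
  t1 <- maps$t1[ctx]
  o <- order(m)
  dm <- diff(m[o]) > 1e-12
  expect_true(all(diff(t1[o])[dm] < 0))
})

test_that("direct-draw tissues match their configured rows (Monte Carlo)", {
  sp <- small_spec()
  lab <- build_geometry(sp)
  maps <- assign_tissue_parameters(lab, sp)
  tab <- sp$tissue_table
  wm <- lab$data == label_codes()[["wm"]]
  n <- sum(wm)
  expect_gt(n, 500)
  for (p in c("t1", "t2", "m0", "delta")) {
    mu <- tab["nawm", paste0(p, "_mean")]
    se <- tab["nawm", paste0(p, "_sd")] / sqrt(n)
    expect_lt(abs(mean(maps[[p]][wm]) - mu), 2 * se + 1e-12)
  }
  # cortex: parameters must equal the couplings applied to realized myelin
  ctx <- lab$data == label_codes()[["cortex"]]
  cp <- coupling_apply(maps$myelin[ctx], myelin_coupling(tab))
  expect_equal(maps$t1[ctx], cp$t1, tolerance = 1e-12)
  expect_equal(maps$m0[ctx], cp$m0, tolerance = 1e-12)
  # and the realized cortex myelin mean sits near the NAC row (clamping at 0
  # shifts it up by well under one SD)
  expect_lt(abs(mean(maps$myelin[ctx]) - tab["nac", "myelin_mean"]), 1)
})

test_that("parameter maps respect their physical invariants", {
  sp <- small_spec()
  lab <- build_geometry(sp)
  imp <- implant_lesions(lab, assign_tissue_parameters(lab, sp), sp)
  maps <- imp$maps
  def <- !is.na(maps$t1)
  expect_true(all(maps$t1[def] > 0))
  expect_true(all(maps$t2[def] < maps$t1[def]))
  expect_true(all(maps$delta[def] >= 0 & maps$delta[def] <= 1))
  expect_true(all(maps$myelin[def] >= 0 & maps$myelin[def] <= 100))
})

test_that("subpial lesions obey both geometric predicates exactly", {
  sp <- small_spec()
  lab <- build_geometry(sp)
  dep <- depth_field(lab)
  maps <- assign_tissue_parameters(lab, sp, depth = dep)
  imp <- implant_lesions(lab, maps, sp, depth = dep)
  lc <- label_codes()
  ls <- sp$lesion_specs[[1]]
  sel <- imp$lesion_masks[[1]]
  expect_gt(sum(sel), 0)
  # no relabeled voxel deeper than the configured depth fraction
  expect_true(all(dep[sel] < ls$depth_fraction))
  # brute-force predicate scan: recover the seed as the implant does, then
  # count voxels satisfying (cortex, within radius, shallow) independently
  ctx <- lab$data == lc[["cortex"]]
  pial <- cortexqmr:::.adjacent_to(ctx, lab$data == lc[["formalin"]])
  pidx <- which(pial, arr.ind = TRUE)
  vs <- lab$voxel_size
  ctr <- ls$center * vs
  d2seed <- rowSums(sweep(sweep(pidx - 1, 2, vs, `*`), 2, ctr, `-`)^2)
  seed_mm <- (pidx[which.min(d2seed), ] - 1) * vs
  cidx <- which(ctx, arr.ind = TRUE)
  cd2 <- rowSums(sweep(sweep(cidx - 1, 2, vs, `*`), 2, seed_mm, `-`)^2)
  shallow <- dep[ctx] < ls$depth_fraction & !is.na(dep[ctx])
  n_oracle <- sum(cd2 <= ls$tangential_radius^2 & shallow)
  expect_identical(sum(sel), n_oracle)
})

test_that("implanted cortical-lesion myelin matches the lesion row", {
  sp <- small_spec()
  lab <- build_geometry(sp)
  imp <- implant_lesions(lab, assign_tissue_parameters(lab, sp), sp)
  cl <- imp$labels$data == label_codes()[["cortical_lesion"]]
  expect_gt(sum(cl), 500)
  expect_lt(abs(mean(imp$maps$myelin[cl]) - 1.96), 0.5)
})

test_that("lesion centers in the wrong tissue fail loudly", {
  sp <- small_spec()
  sp$lesion_specs <- list(lesion_spec("subpial_typeIII", center = c(2, 2, 2),
                                      tangential_radius = 2))
  lab <- build_geometry(sp)
  maps <- assign_tissue_parameters(lab, sp)
  expect_error(implant_lesions(lab, maps, sp), "not in cortex")
  sp$lesion_specs <- list(lesion_spec("wm_focal", center = c(2, 2, 2),
                                      tangential_radius = 2))
  expect_error(implant_lesions(lab, maps, sp), "not in white matter")
})
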