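# shared fixtures built in code

# uniform single-tissue parameter maps on an n^3 grid
uniform_maps <- function(t1, t2, m0, delta, myelin = 0, n = 4,
                         voxel_size = 0.35) {
  parameter_maps(array(t1, c(n, n, n)), array(t2, c(n, n, n)),
                 array(m0, c(n, n, n)), array(delta, c(n, n, n)),
                 array(myelin, c(n, n, n)), voxel_size)
}

# closed-form SPGR signal, written independently of the simulator
spgr_scalar <- function(t1, m0, tr, flip_deg, db1 = 1) {
  a <- db1 * flip_deg * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

# closed-form on-resonance bSSFP signal
bssfp_scalar <- function(t1, t2, m0, tr, flip_deg, db1 = 1) {
  a <- db1 * flip_deg * pi / 180
  e1 <- exp(-tr / t1)
  e2 <- exp(-tr / t2)
  m0 * sin(a) * (1 - e1) / (1 - e1 * e2 - (e1 - e2) * cos(a))
}

# a 20^3 flat-slab label volume: formalin | cortex | wm stacked along z
slab_labels <- function(n = 20, formalin_to = 5, cortex_to = 13,
                        voxel_size = 0.35) {
  lc <- label_codes()
  lab <- array(lc[["wm"]], c(n, n, n))
  lab[, , 1:formalin_to] <- lc[["formalin"]]
  lab[, , (formalin_to + 1):cortex_to] <- lc[["cortex"]]
  label_volume(lab, voxel_size)
}

# quadratic-time brute-force distance (mm) to the nearest TRUE voxel
brute_force_distance <- function(mask, voxel_size) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  src <- which(mask, arr.ind = TRUE)
  src_mm <- sweep(src, 2, voxel_size, `*`)
  out <- array(Inf, dim = dim(mask))
  all_idx <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
  for (r in seq_len(nrow(all_idx))) {
    p <- all_idx[r, ] * voxel_size
    out[all_idx[r, 1], all_idx[r, 2], all_idx[r, 3]] <-
      sqrt(min(rowSums(sweep(src_mm, 2, p, `-`)^2)))
  }
  out
}

small_spec <- function(..., grid_shape = c(48, 48, 48), seed = 42L) {
  phantom_spec(grid_shape = grid_shape, seed = seed, ...)
}
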