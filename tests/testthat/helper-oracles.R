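# Brute-force oracles, intentionally independent of the package internals.

# O(n * m) exact Euclidean distance transform by direct enumeration.
brute_edt <- function(mask, sp) {
  dm <- dim(mask)
  out <- array(Inf, dm)
  src <- which(mask, arr.ind = TRUE)
  if (nrow(src) == 0L) return(out)
  src_mm <- sweep(src - 1, 2, sp, `*`)
  all_idx <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                                   z = seq_len(dm[3])))
  all_mm <- sweep(all_idx - 1, 2, sp, `*`)
  for (i in seq_len(nrow(all_idx))) {
    d2 <- (src_mm[, 1] - all_mm[i, 1])^2 + (src_mm[, 2] - all_mm[i, 2])^2 +
      (src_mm[, 3] - all_mm[i, 3])^2
    out[all_idx[i, 1], all_idx[i, 2], all_idx[i, 3]] <- sqrt(min(d2))
  }
  out
}

ball_offsets <- function(radius_mm, sp) {
  r_vox <- floor(radius_mm / sp)
  offs <- as.matrix(expand.grid(x = -r_vox[1]:r_vox[1],
                                y = -r_vox[2]:r_vox[2],
                                z = -r_vox[3]:r_vox[3]))
  keep <- sqrt((offs[, 1] * sp[1])^2 + (offs[, 2] * sp[2])^2 +
                 (offs[, 3] * sp[3])^2) <= radius_mm
  offs[keep, , drop = FALSE]
}

# Shift-and-combine morphology; offsets leaving the grid are ignored (the
# image boundary is not treated as background), matching the EDT-based
# definitions in the package.
brute_dilate <- function(mask, radius_mm, sp) {
  dm <- dim(mask)
  offs <- ball_offsets(radius_mm, sp)
  out <- array(FALSE, dm)
  src <- which(mask, arr.ind = TRUE)
  if (nrow(src) == 0L) return(out)
  for (k in seq_len(nrow(offs))) {
    pts <- sweep(src, 2, offs[k, ], `+`)
    ok <- pts[, 1] >= 1 & pts[, 1] <= dm[1] &
      pts[, 2] >= 1 & pts[, 2] <= dm[2] &
      pts[, 3] >= 1 & pts[, 3] <= dm[3]
    out[pts[ok, , drop = FALSE]] <- TRUE
  }
  out
}

brute_erode <- function(mask, radius_mm, sp) {
  dm <- dim(mask)
  offs <- ball_offsets(radius_mm, sp)
  out <- array(FALSE, dm)
  for (i in which(mask)) {
    co <- arrayInd(i, dm)
    pts <- sweep(offs, 2, as.integer(co), `+`)
    ok <- pts[, 1] >= 1 & pts[, 1] <= dm[1] &
      pts[, 2] >= 1 & pts[, 2] <= dm[2] &
      pts[, 3] >= 1 & pts[, 3] <= dm[3]
    out[i] <- all(mask[pts[ok, , drop = FALSE]])
  }
  out
}

# Iterative-dilation penumbra rings: dilate by k steps, subtract the previous
# dilation, intersect with NAWM.
dilation_rings <- function(wmh, nawm, step_mm, max_mm, sp) {
  k_max <- as.integer(max_mm / step_mm)
  out <- array(0L, dim(wmh))
  prev <- wmh
  for (k in seq_len(k_max)) {
    cur <- brute_dilate(wmh, k * step_mm, sp)
    ring <- cur & !prev & nawm
    out[ring] <- k
    prev <- cur
  }
  out
}

random_mask <- function(dm, p = 0.2) array(runif(prod(dm)) < p, dm)

# a small cohort configuration for fast end-to-end tests
tiny_config <- function(seed = 1, ...) {
  simulation_config(grid_shape = c(26, 30, 26), n_case = 10, n_control = 6,
                    seed = seed, ...)
}
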