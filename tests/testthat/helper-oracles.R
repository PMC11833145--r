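# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Isochromat Bloch-rotation summation of a CPMG/MESE train: N magnetization
# vectors with uniformly spaced gradient dephasing per half echo spacing,
# explicit 3x3 rotations, relaxation as exponential decay. With N larger
# than twice the highest configuration order this sums the phase graph
# exactly, so it serves as a machine-precision oracle for the EPG recursion.
iso_mese <- function(t2_ms, t1_ms, proto, b1, n_iso = 2048) {
  theta <- 2 * pi * (seq_len(n_iso) - 1) / n_iso
  rot_y <- function(M, ang) {
    c_ <- cos(ang); s_ <- sin(ang)
    cbind(c_ * M[, 1] + s_ * M[, 3], M[, 2], -s_ * M[, 1] + c_ * M[, 3])
  }
  rot_x <- function(M, ang) {
    c_ <- cos(ang); s_ <- sin(ang)
    cbind(M[, 1], c_ * M[, 2] - s_ * M[, 3], s_ * M[, 2] + c_ * M[, 3])
  }
  e2 <- exp(-proto$esp_ms / 2 / t2_ms)
  e1 <- exp(-proto$esp_ms / 2 / t1_ms)
  step <- function(M) {     # relax then dephase over half an echo spacing
    M <- cbind(M[, 1] * e2, M[, 2] * e2, M[, 3] * e1)
    c_ <- cos(theta); s_ <- sin(theta)
    cbind(c_ * M[, 1] - s_ * M[, 2], s_ * M[, 1] + c_ * M[, 2], M[, 3])
  }
  M <- cbind(rep(0, n_iso), 0, 1)
  M <- rot_y(M, b1 * proto$exc_flip_deg * pi / 180)
  ech <- numeric(proto$etl)
  for (n in seq_len(proto$etl)) {
    M <- step(M)
    M <- rot_x(M, b1 * proto$ref_flip_deg * pi / 180)
    M <- step(M)
    ech[n] <- sqrt(mean(M[, 1])^2 + mean(M[, 2])^2)
  }
  ech
}

# brute-force circular convolution of a 3D array with a centred spatial
# kernel given as an array of offsets/weights (named list x, y, z, w)
brute_circ_conv <- function(vol, offsets) {
  n <- dim(vol)
  out <- array(0, n)
  for (i in seq_along(offsets$w)) {
    sh <- c(offsets$x[i], offsets$y[i], offsets$z[i])
    idx <- lapply(1:3, function(a) ((seq_len(n[a]) - 1 - sh[a]) %% n[a]) + 1)
    out <- out + offsets$w[i] * vol[idx[[1]], idx[[2]], idx[[3]]]
  }
  out
}

# exact two-sided rank-sum p over all assignments (independent of the
# package implementation: recomputed from scratch with plain loops)
enum_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  mu <- na * (length(pooled) + 1) / 2
  s_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  cnt <- 0L
  for (j in seq_len(ncol(combos))) {
    if (abs(sum(r[combos[, j]]) - mu) >= abs(s_obs - mu) - 1e-9) cnt <- cnt + 1L
  }
  cnt / ncol(combos)
}

# a tiny two-region phantom on a small grid, used by several quant tests
tiny_two_region_spec <- function(n = c(16, 16, 8), vox = c(2, 2, 4)) {
  regions <- dplyr::bind_rows(
    region_spec("A", 1L, na_mM = 30, k_mM = 120, ff = 0,
                geometry = cylinder(c(-6, 0, 0), 5, 24)),
    region_spec("B", 2L, na_mM = 10, k_mM = 240, ff = 0,
                geometry = cylinder(c(7, 0, 0), 5, 24)))
  phantom_spec(n, vox, regions)
}
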