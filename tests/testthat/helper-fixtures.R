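# Shared fixtures: small geometries keep the FFT work light while preserving
# the 76.8 mm field of view of the default acquisition.

small_geometry <- function(n = 48L, vox = 76.8 / n, echoes = default_echo_times()) {
  acquisition_geometry(grid_shape = rep(n, 3L), voxel_size = rep(vox, 3L),
                       echo_times = echoes)
}

# echo_series from explicit magnitude/phase arrays
as_echo_series <- function(magnitude, phase, geometry) {
  structure(list(magnitude = magnitude, phase = phase, geometry = geometry),
            class = "echo_series")
}

# noiseless series with spatially constant frequency (Hz), m0 and r2star
uniform_series <- function(geometry, freq_hz = 0, m0 = 100, r2star = 0) {
  te_s <- geometry$echo_times / 1000
  dims <- geometry$grid_shape
  ne <- length(te_s)
  mag <- array(0, dim = c(dims, ne))
  ph <- array(0, dim = c(dims, ne))
  for (e in seq_len(ne)) {
    idx <- (e - 1) * prod(dims) + seq_len(prod(dims))
    mag[idx] <- m0 * exp(-r2star * te_s[e])
    ph[idx] <- dgmiron:::wrap_phase(array(2 * pi * freq_hz * te_s[e], dim = dims))
  }
  as_echo_series(mag, ph, geometry)
}

# field_map wrapper for a raw frequency volume
as_field_map <- function(freq, mask, residual = array(0, dim = dim(freq))) {
  structure(list(frequency = freq, mask = mask, residual = residual),
            class = "field_map")
}

# susceptibility_map wrapper around a known chi volume (used to test ROI
# statistics independently of the reconstruction)
as_chi_map <- function(chi, mask) {
  structure(list(chi = chi, mask = mask, reference = "none"),
            class = "susceptibility_map")
}

# brute-force Mann-Whitney oracle: enumerate every assignment of the combined
# ranks to group a (no ties assumed)
mw_enumeration_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(na + nb, na)
  us <- apply(sets, 2, function(ii) sum(seq_len(na + nb)[ii]) - na * (na + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(u = u_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

# closed-form OLS oracle via explicit matrix algebra
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  cov <- s2 * solve(t(X) %*% X)
  t_slope <- beta[2] / sqrt(cov[2, 2])
  list(intercept = beta[1], slope = beta[2],
       intercept_se = sqrt(cov[1, 1]), slope_se = sqrt(cov[2, 2]),
       p_value = 2 * stats::pt(-abs(t_slope), n - 2))
}
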