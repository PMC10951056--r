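# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
enumerate_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_obs <- sum(rank(pooled)[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  r <- rank(pooled)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  pl <- mean(us <= u_obs)
  pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

# All self-consistent IsoData partitions by exhaustive search over splits.
isodata_fixed_points <- function(x) {
  u <- sort(unique(as.numeric(x)))
  out <- list()
  for (i in seq_len(length(u) - 1)) {
    lo <- x[x <= u[i]]; hi <- x[x > u[i]]
    t_mid <- (mean(lo) + mean(hi)) / 2
    if (t_mid >= u[i] && t_mid < u[i + 1])
      out[[length(out) + 1L]] <- list(split = u[i], t = t_mid)
  }
  out
}

# GSI oracle: mean of the expanded per-glomerulus score list.
gsi_by_expansion <- function(n0, n1, n2, n3, n4)
  mean(rep(0:4, times = c(n0, n1, n2, n3, n4)))

# Analytic mean apparent caliper diameter of a sphere of radius r sampled
# by a slab of thickness t with uniform center offset:
# (r t + pi r^2 / 2) / (r + t / 2).
analytic_mean_apparent <- function(r, t) (r * t + pi * r^2 / 2) / (r + t / 2)

# Small synthetic biopsy built by hand.
make_biopsy <- function(pid = "P1", areas = c(10000, 20000),
                        scores = rep(0L, length(areas)),
                        diam = rep(list(c(7.1, 7.5)), length(areas)),
                        snp = rep(1300, length(areas)),
                        optics = optical_config()) {
  gl <- lapply(seq_along(areas), function(i)
    glomerulus_measurement(sprintf("g%d", i), areas[i], scores[i],
                           diam[[i]], snp[i]))
  biopsy_measurement(pid, gl, optics)
}

# Directly assembled geometry (bypasses the dart-throwing generator).
make_geometry <- function(centers, radii, tuft_radius,
                          truth = synthetic_truth("T", nrow(centers),
                                                  2 * max(radii, 1),
                                                  tuft_radius, 0.13)) {
  structure(list(tuft_radius = tuft_radius, centers = centers,
                 radii = radii, truth = truth),
            class = "glomerulus_geometry")
}
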