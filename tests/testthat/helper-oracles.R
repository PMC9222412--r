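# Independent oracles, deliberately coded differently from the package
# implementations they check.

# Dihedral via normal-plane acos with explicit sign, not atan2 of cross
# products. Returns degrees in (-180, 180].
oracle_dihedral <- function(a, b, c, d) {
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  unitize <- function(v) v / sqrt(sum(v^2))
  n1 <- unitize(cross(b - a, c - b))
  n2 <- unitize(cross(c - b, d - c))
  ang <- acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
  if (sum(cross(n1, n2) * (c - b)) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

# Brute-force entropy by explicit double loop over histogram cells.
oracle_entropy <- function(counts, R0 = 8.314) {
  n <- sum(counts)
  s <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      if (counts[i, j] > 0) {
        p <- counts[i, j] / n
        s <- s - R0 * p * log(p)
      }
    }
  }
  s
}

# Exact bin probabilities of a von Mises density (degrees) on the
# (-180, 180] grid, by fine trapezoidal quadrature of the analytic density.
# Exponentially scaled Bessel keeps large kappa stable.
vm_bin_probs <- function(mu_deg, kappa, bins) {
  sub <- 200L
  edges <- seq(-pi, pi, length.out = bins * sub + 1L)
  mu <- mu_deg * pi / 180
  dens <- exp(kappa * (cos(edges - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  h <- diff(edges)[1]
  cell <- (dens[-length(dens)] + dens[-1]) / 2 * h
  p <- colSums(matrix(cell, sub, bins))
  p / sum(p)
}

# True binned entropy (J K^-1 mol^-1) of a mixture of axis-independent von
# Mises clusters plus uniform background, on a bins x bins grid.
mixture_binned_entropy <- function(clusters, background, bins, R0 = 8.314) {
  P <- matrix(background / bins^2, bins, bins)
  for (cl in clusters) {
    P <- P + cl$weight * outer(vm_bin_probs(cl$mean_phi, cl$kappa, bins),
                               vm_bin_probs(cl$mean_psi, cl$kappa, bins))
  }
  P <- P / sum(P)
  -R0 * sum(P[P > 0] * log(P[P > 0]))
}

random_quadruple <- function() {
  repeat {
    pts <- matrix(stats::rnorm(12), 4, 3)
    b2 <- pts[3, ] - pts[2, ]
    if (sqrt(sum(b2^2)) > 0.1) return(pts)
  }
}

random_rigid_transform <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_r <- qr(m)
  R <- qr.Q(qr_r)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 10))
}

make_series <- function(phi_vals, psi_vals, nf, nl, type = "one_four") {
  torsion_series(matrix(phi_vals, nf, nl), matrix(psi_vals, nf, nl), type)
}
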