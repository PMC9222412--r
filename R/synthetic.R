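# Synthetic angle time series with known mixture structure, and embedding
# of prescribed torsions into idealized 3D coordinates.

#' Angular cluster specification
#'
#' One component of a bivariate angular mixture: an independent von Mises
#' distribution on each axis, centered at (\code{mean_phi},
#' \code{mean_psi}) with common concentration \code{kappa}. Larger
#' \code{kappa} means a tighter cluster; \code{kappa = Inf} is the
#' zero-dispersion (point-mass) limit and \code{kappa = 0} is circular
#' uniform.
#'
#' @param mean_phi,mean_psi cluster center in degrees, in (-180, 180].
#' @param kappa von Mises concentration (dimensionless, >= 0, may be Inf).
#' @param weight mixing probability in [0, 1].
#' @return object of class \code{"cluster_spec"}.
#' @export
cluster_spec <- function(mean_phi, mean_psi, kappa, weight) {
  if (mean_phi <= -180 || mean_phi > 180 || mean_psi <= -180 || mean_psi > 180)
    stop("cluster means must lie in (-180, 180]", call. = FALSE)
  if (is.na(kappa) || kappa < 0)
    stop("'kappa' must be >= 0 (Inf allowed)", call. = FALSE)
  if (weight < 0 || weight > 1)
    stop("'weight' must be in [0, 1]", call. = FALSE)
  structure(list(mean_phi = mean_phi, mean_psi = mean_psi,
                 kappa = kappa, weight = weight),
            class = "cluster_spec")
}

#' Synthetic angle-series specification
#'
#' Defines the generative model for one synthetic torsion-angle series: a
#' mixture of angular clusters plus a uniform background on
#' (-180, 180]^2, sampled independently for \code{n_frames} frames and
#' \code{n_linkages} linkages. Cluster weights plus the background weight
#' must sum to 1 (tolerance 1e-9).
#'
#' An optional sticky-switching parameter \code{ar1} in [0, 1) introduces
#' temporal correlation: per linkage, the mixture component is kept from
#' the previous frame with probability \code{ar1} and redrawn from the
#' mixture weights otherwise. This leaves the marginal (Phi, Psi)
#' distribution unchanged (the entropy of the pooled histogram is
#' order-invariant) and only slows convergence; it is off (0) by default.
#'
#' @param clusters list of \code{\link{cluster_spec}} objects.
#' @param uniform_background_weight probability mass of the uniform
#'   background component.
#' @param n_linkages,n_frames series dimensions.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @param ar1 component stickiness in [0, 1); 0 = i.i.d. frames.
#' @return object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(clusters, uniform_background_weight = 0,
                           n_linkages, n_frames, seed = NULL, ar1 = 0) {
  stopifnot(is.list(clusters),
            all(vapply(clusters, inherits, logical(1), "cluster_spec")))
  if (n_frames < 1 || n_linkages < 0)
    stop("'n_frames' must be >= 1 and 'n_linkages' >= 0", call. = FALSE)
  if (ar1 < 0 || ar1 >= 1)
    stop("'ar1' must be in [0, 1)", call. = FALSE)
  w <- vapply(clusters, `[[`, numeric(1), "weight")
  total <- sum(w) + uniform_background_weight
  if (abs(total - 1) > 1e-9)
    stop(sprintf("spec error: cluster weights + background weight must sum to 1 (got %.12f)",
                 total), call. = FALSE)
  structure(list(clusters = clusters,
                 uniform_background_weight = uniform_background_weight,
                 n_linkages = as.integer(n_linkages),
                 n_frames = as.integer(n_frames),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 ar1 = ar1),
            class = "synthetic_spec")
}

#' von Mises random deviates
#'
#' Samples from the von Mises distribution on the circle, parameterized in
#' degrees, by the Best-Fisher (1979) wrapped-Cauchy rejection envelope.
#' \code{kappa = 0} gives the circular uniform distribution and
#' \code{kappa = Inf} the point mass at \code{mu_deg}.
#'
#' @param n number of deviates.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration (>= 0, may be Inf).
#' @return numeric vector of angles in degrees, in (-180, 180].
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  if (n == 0) return(numeric(0))
  if (is.infinite(kappa)) return(rep(mu_deg, n))
  if (kappa == 0) return(stats::runif(n, -180, 180))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.3))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
    out <- c(out, theta)
  }
  deg <- (mu + out[seq_len(n)]) * 180 / pi
  wrap_angle(deg)
}

#' Wrap angles into (-180, 180]
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into the half-open interval
#'   (-180, 180].
#' @export
wrap_angle <- function(deg) {
  w <- deg - 360 * floor((deg + 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

#' Sample a torsion-angle time series from an angular mixture
#'
#' Draws \code{n_frames * n_linkages} (Phi, Psi) pairs from the mixture
#' defined by \code{spec} and arranges them as a
#' \code{\link{torsion_series}}. Within a cluster, Phi and Psi are
#' independent von Mises draws; the background is uniform on
#' (-180, 180]^2. With a fixed \code{spec$seed}, output is bit-identical
#' across calls.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param angle_pair_type series label, \code{"one_four"} (default) or
#'   \code{"one_three"}.
#' @param gag_type,ion,realization_id metadata to attach.
#' @return a \code{"torsion_series"}.
#' @export
sample_angle_series <- function(spec, angle_pair_type = "one_four",
                                gag_type = NA_character_, ion = NA_character_,
                                realization_id = NA_integer_) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nf <- spec$n_frames; nl <- spec$n_linkages
  n <- nf * nl
  w <- c(vapply(spec$clusters, `[[`, numeric(1), "weight"),
         spec$uniform_background_weight)
  n_comp <- length(w)  # background is component n_comp
  if (n == 0) {
    return(torsion_series(matrix(numeric(0), nf, 0), matrix(numeric(0), nf, 0),
                          angle_pair_type, gag_type, ion, realization_id))
  }
  if (spec$ar1 == 0) {
    comp <- sample.int(n_comp, n, replace = TRUE, prob = w)
  } else {
    # sticky Markov switching per linkage; stationary distribution = w
    comp <- matrix(0L, nf, nl)
    comp[1, ] <- sample.int(n_comp, nl, replace = TRUE, prob = w)
    for (t in seq_len(nf)[-1]) {
      keep <- stats::runif(nl) < spec$ar1
      redraw <- sample.int(n_comp, nl, replace = TRUE, prob = w)
      comp[t, ] <- ifelse(keep, comp[t - 1, ], redraw)
    }
    comp <- as.vector(comp)
  }
  phi <- numeric(n); psi <- numeric(n)
  for (k in seq_len(n_comp)) {
    sel <- which(comp == k)
    if (!length(sel)) next
    if (k > length(spec$clusters)) {
      phi[sel] <- stats::runif(length(sel), -180, 180)
      psi[sel] <- stats::runif(length(sel), -180, 180)
    } else {
      cl <- spec$clusters[[k]]
      phi[sel] <- rvonmises(length(sel), cl$mean_phi, cl$kappa)
      psi[sel] <- rvonmises(length(sel), cl$mean_psi, cl$kappa)
    }
  }
  torsion_series(matrix(phi, nf, nl), matrix(psi, nf, nl),
                 angle_pair_type, gag_type, ion, realization_id)
}

# --- embedding prescribed torsions as 3D coordinates --------------------

# NeRF placement: position D given three reference points so that
# |D - C| = r, angle(D, C, B) = theta and dihedral(A, B, C, D) = tau.
# A, B, C are n x 3 matrices; theta, tau in degrees; tau may be length n.
.nerf_place <- function(A, B, C, r, theta_deg, tau_deg) {
  th <- theta_deg * pi / 180
  ta <- tau_deg * pi / 180
  b2 <- C - B
  u2 <- b2 / .rownorm(b2)
  nrm <- .cross3(B - A, u2)
  nrm <- nrm / .rownorm(nrm)
  m <- .cross3(nrm, u2)
  C + r * (-u2 * cos(th) + m * (sin(th) * cos(ta)) + nrm * (sin(th) * sin(ta)))
}

# Build the internal-coordinate placement plan for a topology: one row per
# atom with its three reference atoms and the torsion source (a fixed
# scaffold value, or phi/psi of a specific linkage).
.embedding_plan <- function(topology) {
  units <- topology$units
  n_units <- nrow(units)
  atoms <- c("C1", "C2", "C3", "C4", "C5", "O5", "O1")
  id <- function(u, a) (u - 1L) * length(atoms) + match(a, atoms)
  plan <- list()
  add <- function(u, a, bond, ang, tor, source, fixed = NA_real_,
                  link_index = NA_integer_) {
    plan[[length(plan) + 1L]] <<- list(
      row = id(u, a), unit = u, atom = a,
      bond = bond, ang = ang, tor = tor,
      source = source, fixed = fixed, link_index = link_index)
  }
  # seed unit 1 (an N unit): O5, C1 placed explicitly; O1 by planar rule
  add(1L, "O1", id(1L, "C1"), id(1L, "O5"), NA_integer_, "seed")
  # remaining scaffold of unit 1
  add(1L, "C5", id(1L, "O5"), id(1L, "C1"), id(1L, "O1"), "fixed", 60)
  add(1L, "C4", id(1L, "C5"), id(1L, "O5"), id(1L, "C1"), "fixed", 60)
  add(1L, "C3", id(1L, "C4"), id(1L, "C5"), id(1L, "O5"), "fixed", 60)
  add(1L, "C2", id(1L, "C3"), id(1L, "C4"), id(1L, "C5"), "fixed", 60)

  types <- linkage_types(topology)
  count <- c(one_four = 0L, one_three = 0L)
  for (li in seq_along(topology$linkages)) {
    lk <- topology$linkages[[li]]
    type <- types[li]
    count[type] <- count[type] + 1L
    u <- lk$donor_unit; v <- lk$acceptor_unit
    if (type == "one_four") {
      # phi places C4(G), psi places C5(G)
      add(v, "C4", id(u, "O1"), id(u, "C1"), id(u, "O5"), "phi",
          link_index = count[type])
      add(v, "C5", id(v, "C4"), id(u, "O1"), id(u, "C1"), "psi",
          link_index = count[type])
      add(v, "O5", id(v, "C5"), id(v, "C4"), id(u, "O1"), "fixed", -60)
      add(v, "C1", id(v, "O5"), id(v, "C5"), id(v, "C4"), "fixed", -60)
      add(v, "O1", id(v, "C1"), id(v, "O5"), id(v, "C5"), "fixed", -60)
      add(v, "C3", id(v, "C4"), id(v, "C5"), id(v, "O5"), "fixed", 60)
      add(v, "C2", id(v, "C3"), id(v, "C4"), id(v, "C5"), "fixed", 60)
    } else {
      # phi places C3(N), psi places C4(N)
      add(v, "C3", id(u, "O1"), id(u, "C1"), id(u, "O5"), "phi",
          link_index = count[type])
      add(v, "C4", id(v, "C3"), id(u, "O1"), id(u, "C1"), "psi",
          link_index = count[type])
      add(v, "C5", id(v, "C4"), id(v, "C3"), id(u, "O1"), "fixed", -60)
      add(v, "O5", id(v, "C5"), id(v, "C4"), id(v, "C3"), "fixed", -60)
      add(v, "C1", id(v, "O5"), id(v, "C5"), id(v, "C4"), "fixed", -60)
      add(v, "O1", id(v, "C1"), id(v, "O5"), id(v, "C5"), "fixed", -60)
      add(v, "C2", id(v, "C3"), id(v, "C4"), id(v, "C5"), "fixed", 60)
    }
  }
  list(plan = plan, n_atoms = n_units * length(atoms), atom_names = atoms)
}

#' Embed prescribed torsion angles as 3D coordinates
#'
#' Builds an idealized coordinate trajectory of the chain in which every
#' glycosidic Phi/Psi dihedral equals the prescribed series value. All
#' bond lengths are 1 and all bond angles 109.5 degrees (tetrahedral); the
#' geometry is a scaffold, not a physical sugar: only the dihedrals are
#' meaningful, and extracting torsions from the returned trajectory
#' reproduces the input series to numerical precision. Atoms not
#' constrained by any glycosidic torsion are placed with fixed scaffold
#' torsions.
#'
#' @param topology a \code{"chain_topology"}.
#' @param series a \code{"torsion_series"} (either angle-pair type) or a
#'   list containing one series per type. Column counts must match the
#'   topology's linkage counts; a missing type is scaffolded at a fixed
#'   torsion of 180 degrees.
#' @return object of class \code{"gag_trajectory"}: list with an
#'   \code{atoms} table (\code{eleno}, \code{elety}, \code{unit},
#'   \code{kind}, \code{resid}), a \code{coords} array (atoms x 3 x
#'   frames, Angstrom-like scaffold units) and \code{meta}.
#' @export
embed_torsions_as_coordinates <- function(topology, series) {
  stopifnot(inherits(topology, "chain_topology"))
  if (inherits(series, "torsion_series")) series <- list(series)
  by_type <- list()
  for (s in series) {
    stopifnot(inherits(s, "torsion_series"))
    by_type[[s$angle_pair_type]] <- s
  }
  types <- linkage_types(topology)
  n_expect <- c(one_four = sum(types == "one_four"),
                one_three = sum(types == "one_three"))
  n_frames <- NULL
  for (type in names(by_type)) {
    if (ncol(by_type[[type]]$phi) != n_expect[[type]])
      stop(sprintf("spec error: %s series has %d columns, topology has %d linkages",
                   type, ncol(by_type[[type]]$phi), n_expect[[type]]),
           call. = FALSE)
    nf <- nrow(by_type[[type]]$phi)
    if (!is.null(n_frames) && nf != n_frames)
      stop("spec error: series frame counts differ", call. = FALSE)
    n_frames <- nf
  }
  if (is.null(n_frames))
    stop("at least one torsion_series is required", call. = FALSE)

  emb <- .embedding_plan(topology)
  coords <- array(NA_real_, c(emb$n_atoms, 3L, n_frames))
  atoms_per_unit <- length(emb$atom_names)
  # seed atoms of unit 1: O5 at origin, C1 on x-axis
  o5 <- match("O5", emb$atom_names); c1 <- match("C1", emb$atom_names)
  coords[o5, , ] <- c(0, 0, 0)
  coords[c1, , ] <- c(1, 0, 0)

  theta <- 109.5
  ones <- rep(1, n_frames)
  get_xyz <- function(row) t(coords[row, , , drop = FALSE][1, , ])
  for (p in emb$plan) {
    if (p$source == "seed") {
      # O1 of unit 1 in the xy-plane at the tetrahedral angle from C1
      ang <- theta * pi / 180
      coords[p$row, , ] <- c(1 - cos(ang), sin(ang), 0)
      next
    }
    if (p$source == "fixed") {
      tau <- rep(p$fixed, n_frames)
    } else {
      type <- .plan_type(p, topology)
      s <- by_type[[type]]
      tau <- if (is.null(s)) rep(180, n_frames) else s[[p$source]][, p$link_index]
    }
    D <- .nerf_place(get_xyz(p$tor), get_xyz(p$ang), get_xyz(p$bond),
                     r = 1, theta_deg = theta, tau_deg = tau)
    coords[p$row, , ] <- t(D)
  }

  units <- topology$units
  atoms <- data.frame(
    eleno = seq_len(emb$n_atoms),
    elety = rep(emb$atom_names, nrow(units)),
    unit = rep(units$index, each = atoms_per_unit),
    kind = rep(units$kind, each = atoms_per_unit),
    resid = rep(units$residue, each = atoms_per_unit),
    stringsAsFactors = FALSE)
  meta0 <- (by_type[[1]])$meta
  structure(list(atoms = atoms, coords = coords,
                 meta = list(gag_type = topology$gag_type,
                             ion = meta0$ion,
                             realization_id = meta0$realization_id)),
            class = "gag_trajectory")
}

# which angle-pair type a plan entry's linkage belongs to
.plan_type <- function(p, topology) {
  # link_index counts within type; recover type from the plan row's unit kinds
  # (the acceptor unit's kind determines it: G acceptor => one_four)
  if (topology$units$kind[p$unit] == "G") "one_four" else "one_three"
}

#' @export
print.gag_trajectory <- function(x, ...) {
  cat(sprintf("gag_trajectory: %d atoms x %d frames (%s)\n",
              nrow(x$atoms), dim(x$coords)[3],
              x$meta$gag_type %||% "unknown GAG"))
  invisible(x)
}
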