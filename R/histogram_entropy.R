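# Bivariate (Phi, Psi) histograms, conformational Shannon entropy, modal
# conformations and region occupancy.

#' Gas constant used to scale conformational entropy
#'
#' R0 = 8.314 J K^-1 mol^-1.
#' @export
R0_GAS <- 8.314

.bin_index <- function(x, bins) {
  # half-open (low, high] bins on (-180, 180]; +180 falls in the last bin
  i <- ceiling((x + 180) / (360 / bins))
  pmin.int(pmax.int(i, 1L), bins)
}

#' Bivariate histogram of pooled (Phi, Psi) angle pairs
#'
#' Pools the (Phi, Psi) pairs of all linkages and all frames of a torsion
#' series into one 2D histogram on (-180, 180]^2 with \code{bins_per_axis}
#' equal-width bins per axis. Bins are half-open (low, high], so a sample
#' at exactly +180 degrees lands in the last bin. The total count n equals
#' n_frames x n_linkages, matching the pooling used for Ramachandran-type
#' occupancy maps of a whole chain over a whole trajectory.
#'
#' @param series a \code{"torsion_series"}, or a list/2-column source:
#'   alternatively pass numeric vectors via \code{phi}/\code{psi}.
#' @param bins_per_axis number of bins per axis (>= 2); default 72,
#'   i.e. 5-degree bins.
#' @param phi,psi optional numeric vectors, used when \code{series} is
#'   missing.
#' @return object of class \code{"angle_histogram2d"}: list with
#'   \code{phi_edges}, \code{psi_edges} (length bins+1), integer
#'   \code{counts} (phi bins x psi bins), total \code{n}, probability
#'   matrix \code{p = counts / n}, \code{bins_per_axis} and \code{meta}.
#' @export
angle_histogram2d <- function(series = NULL, bins_per_axis = 72,
                              phi = NULL, psi = NULL) {
  if (bins_per_axis < 2 || bins_per_axis != round(bins_per_axis))
    stop("'bins_per_axis' must be an integer >= 2", call. = FALSE)
  bins <- as.integer(bins_per_axis)
  meta <- list()
  if (!is.null(series)) {
    stopifnot(inherits(series, "torsion_series"))
    phi <- as.vector(series$phi)
    psi <- as.vector(series$psi)
    meta <- c(series$meta, angle_pair_type = series$angle_pair_type)
  }
  if (is.null(phi) || is.null(psi) || length(phi) != length(psi))
    stop("supply a torsion_series or equal-length phi/psi vectors",
         call. = FALSE)
  n <- length(phi)
  if (n == 0) stop("input error: empty angle series", call. = FALSE)
  if (min(phi, psi) <= -180 || max(phi, psi) > 180)
    stop("angles must lie in (-180, 180]", call. = FALSE)
  i <- .bin_index(phi, bins)
  j <- .bin_index(psi, bins)
  counts <- matrix(tabulate(i + (j - 1L) * bins, nbins = bins * bins),
                   bins, bins)
  edges <- seq(-180, 180, length.out = bins + 1L)
  structure(list(phi_edges = edges, psi_edges = edges,
                 counts = counts, n = n, p = counts / n,
                 bins_per_axis = bins, meta = meta),
            class = "angle_histogram2d")
}

#' Bin centers of a histogram axis
#' @param hist an \code{"angle_histogram2d"}.
#' @param axis \code{"phi"} or \code{"psi"}.
#' @return numeric vector of bin centers in degrees.
#' @export
bin_centers <- function(hist, axis = c("phi", "psi")) {
  axis <- match.arg(axis)
  e <- if (axis == "phi") hist$phi_edges else hist$psi_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Conformational entropy of a binned angle distribution
#'
#' Computes the Shannon entropy of the normalized bivariate histogram,
#' scaled by the gas constant:
#' \deqn{S = -R_0 \sum_{i,j} p_{i,j} \ln p_{i,j}}
#' with R0 = 8.314 J K^-1 mol^-1 and the natural logarithm, so S is in
#' J K^-1 mol^-1. Empty bins contribute zero. The default estimator is the
#' plug-in (maximum-likelihood) estimate from the empirical frequencies;
#' \code{miller_madow = TRUE} adds the Miller-Madow bias correction
#' R0 (m - 1) / (2 n), where m is the number of occupied bins.
#'
#' S is 0 for a point mass and at most R0 ln(B) for B total bins; its
#' value depends on the bin width, which is therefore carried in the
#' returned record.
#'
#' @param hist an \code{"angle_histogram2d"}.
#' @param R0 scaling constant, default \code{R0_GAS}.
#' @param miller_madow apply the Miller-Madow correction? Default FALSE.
#' @return object of class \code{"entropy_record"}: list with \code{S}
#'   (J K^-1 mol^-1), \code{R0}, \code{bins_per_axis}, \code{n},
#'   \code{estimator} and \code{meta}.
#' @export
conformational_entropy <- function(hist, R0 = R0_GAS, miller_madow = FALSE) {
  stopifnot(inherits(hist, "angle_histogram2d"))
  if (hist$n == 0) stop("input error: empty histogram", call. = FALSE)
  p <- hist$p[hist$p > 0]
  S <- -R0 * sum(p * log(p))
  if (miller_madow) S <- S + R0 * (length(p) - 1) / (2 * hist$n)
  structure(list(S = S, R0 = R0, bins_per_axis = hist$bins_per_axis,
                 n = hist$n,
                 estimator = if (miller_madow) "miller_madow" else "plug_in",
                 meta = hist$meta),
            class = "entropy_record")
}

#' @export
print.entropy_record <- function(x, ...) {
  cat(sprintf("conformational entropy S = %.3f J K^-1 mol^-1 (%d x %d bins, n = %d, %s)\n",
              x$S, x$bins_per_axis, x$bins_per_axis, x$n, x$estimator))
  invisible(x)
}

#' Most frequent (Phi, Psi) conformation
#'
#' Returns the center of the maximal-count histogram bin — the modal
#' conformation of the pooled angle distribution. Ties are broken by the
#' lexicographically smallest (phi center, psi center) pair. Because the
#' mode is a bin center, it is discretized to the bin width.
#'
#' @param hist an \code{"angle_histogram2d"} with n >= 1.
#' @return named numeric vector \code{c(phi = , psi = )} in degrees.
#' @export
most_frequent_angles <- function(hist) {
  stopifnot(inherits(hist, "angle_histogram2d"))
  if (hist$n < 1) stop("input error: empty histogram", call. = FALSE)
  mx <- max(hist$counts)
  hits <- which(hist$counts == mx, arr.ind = TRUE)
  pc <- bin_centers(hist, "phi")[hits[, 1]]
  sc <- bin_centers(hist, "psi")[hits[, 2]]
  ord <- order(pc, sc)[1]
  c(phi = pc[ord], psi = sc[ord])
}

#' Probability mass of a rectangular (Phi, Psi) region
#'
#' Sums the normalized histogram over all bins whose centers fall inside
#' the given closed rectangle, e.g. to measure the occupancy of a known
#' conformational basin such as Phi in [-100, -30], Psi in [70, 180].
#'
#' @param hist an \code{"angle_histogram2d"}.
#' @param phi_range,psi_range length-2 numeric ranges (degrees) within
#'   (-180, 180], min < max.
#' @return occupancy fraction in [0, 1].
#' @export
region_occupancy <- function(hist, phi_range, psi_range) {
  stopifnot(inherits(hist, "angle_histogram2d"))
  ok_range <- function(r) length(r) == 2 && r[1] < r[2] &&
    r[1] >= -180 && r[2] <= 180
  if (!ok_range(phi_range) || !ok_range(psi_range))
    stop("input error: degenerate or out-of-domain region", call. = FALSE)
  pc <- bin_centers(hist, "phi")
  sc <- bin_centers(hist, "psi")
  ii <- pc >= phi_range[1] & pc <= phi_range[2]
  jj <- sc >= psi_range[1] & sc <= psi_range[2]
  sum(hist$p[ii, jj])
}

#' Export a histogram as plain-text CSV
#'
#' Writes the counts matrix with phi bin centers as row names and psi bin
#' centers as column names, plus a companion \code{*_edges.csv} with the
#' bin edges.
#'
#' @param hist an \code{"angle_histogram2d"}.
#' @param path output CSV path for the counts matrix.
#' @return \code{path}, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "angle_histogram2d"))
  m <- hist$counts
  dimnames(m) <- list(phi_center = bin_centers(hist, "phi"),
                      psi_center = bin_centers(hist, "psi"))
  utils::write.csv(m, path)
  edges_path <- sub("\\.csv$", "_edges.csv", path)
  utils::write.csv(data.frame(phi_edge = hist$phi_edges,
                              psi_edge = hist$psi_edges),
                   edges_path, row.names = FALSE)
  invisible(path)
}

#' Plot a normalized (Phi, Psi) histogram
#'
#' Base-graphics occupancy map of the normalized bivariate histogram, the
#' standard Ramachandran-type view of glycosidic linkage conformations.
#'
#' @param x an \code{"angle_histogram2d"}.
#' @param main plot title.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot.angle_histogram2d <- function(x, main = "(Phi, Psi) occupancy", ...) {
  graphics::image(bin_centers(x, "phi"), bin_centers(x, "psi"), x$p,
                  xlab = expression(Phi ~ "(deg)"),
                  ylab = expression(Psi ~ "(deg)"),
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}
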