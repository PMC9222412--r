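# Dihedral geometry and extraction of per-linkage torsion time series.

.cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

.rownorm <- function(m) sqrt(rowSums(m * m))

# Vectorized dihedral for n x 3 point matrices A, B, C, D; degrees in
# (-180, 180]. atan2 formulation: y = |b2| * b1.(b2 x b3), x = (b1 x b2).(b2 x b3).
.dihedral_mat <- function(A, B, C, D, check = TRUE) {
  b1 <- B - A
  b2 <- C - B
  b3 <- D - C
  c12 <- .cross3(b1, b2)
  c23 <- .cross3(b2, b3)
  if (check) {
    nb2 <- .rownorm(b2)
    tol <- 1e-10
    bad <- nb2 < tol | .rownorm(c12) < tol * pmax(1, .rownorm(b1) * nb2) |
      .rownorm(c23) < tol * pmax(1, nb2 * .rownorm(b3))
    if (any(bad)) {
      stop("geometry error: coincident or collinear points in dihedral ",
           "(first offending row ", which(bad)[1], ")", call. = FALSE)
    }
  }
  y <- .rownorm(b2) * rowSums(b1 * c23)
  x <- rowSums(c12 * c23)
  deg <- atan2(y, x) * 180 / pi
  # branch choice: trans is +180, never -180
  deg[deg <= -180] <- deg[deg <= -180] + 360
  deg
}

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle a-b-c-d in degrees using the IUPAC sign
#' convention: looking from b towards c, the angle is positive when the
#' far bond c-d is rotated clockwise relative to the near bond b-a. The
#' result lies in the half-open interval (-180, 180]; the planar trans
#' arrangement is reported as +180, never -180. The value is invariant
#' under rigid rotation and translation, unchanged by reversing the atom
#' order (d,c,b,a), and negated by mirror reflection.
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (or n x 3 matrices
#'   for n dihedrals at once).
#' @return numeric vector of angles in degrees, in (-180, 180].
#' @examples
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))   #   0 (cis)
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))  # 180 (trans)
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))   # +90
#' @export
dihedral <- function(a, b, c, d) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  A <- as_m(a); B <- as_m(b); C <- as_m(c); D <- as_m(d)
  stopifnot(ncol(A) == 3, nrow(A) == nrow(B), nrow(B) == nrow(C),
            nrow(C) == nrow(D))
  .dihedral_mat(A, B, C, D)
}

#' Construct a torsion-angle time series
#'
#' Bundles the per-frame, per-linkage Phi and Psi dihedral values (degrees)
#' of one glycosidic angle-pair type, together with provenance metadata.
#' Rows index trajectory frames, columns index linkages along the chain.
#'
#' @param phi,psi numeric matrices (frames x linkages), values in
#'   (-180, 180]; identical dimensions.
#' @param angle_pair_type \code{"one_four"} or \code{"one_three"}.
#' @param gag_type,ion,realization_id optional provenance metadata.
#' @return object of class \code{"torsion_series"}.
#' @export
torsion_series <- function(phi, psi,
                           angle_pair_type = c("one_four", "one_three"),
                           gag_type = NA_character_, ion = NA_character_,
                           realization_id = NA_integer_) {
  angle_pair_type <- match.arg(angle_pair_type)
  phi <- as.matrix(phi); psi <- as.matrix(psi)
  if (!identical(dim(phi), dim(psi)))
    stop("'phi' and 'psi' must have identical dimensions", call. = FALSE)
  if (length(phi)) {
    rng <- range(c(phi, psi), na.rm = FALSE)
    if (rng[1] <= -180 || rng[2] > 180)
      stop("angle values must lie in (-180, 180]", call. = FALSE)
  }
  structure(list(phi = phi, psi = psi, angle_pair_type = angle_pair_type,
                 meta = list(gag_type = gag_type, ion = ion,
                             realization_id = as.integer(realization_id))),
            class = "torsion_series")
}

#' @export
print.torsion_series <- function(x, ...) {
  cat(sprintf("torsion_series [%s]: %d frames x %d linkages (%s, ion %s, realization %s)\n",
              x$angle_pair_type, nrow(x$phi), ncol(x$phi),
              x$meta$gag_type, x$meta$ion, x$meta$realization_id))
  invisible(x)
}

# (unit, atom) -> coordinate row lookup for a trajectory atom table
.atom_row_index <- function(atoms) {
  setNames(seq_len(nrow(atoms)), paste(atoms$unit, atoms$elety, sep = "/"))
}

.resolve_atom <- function(index, unit, atom, context = "") {
  row <- index[paste(unit, atom, sep = "/")]
  if (is.na(row)) {
    stop("extraction error: cannot resolve atom ", atom, " of unit ", unit,
         context, call. = FALSE)
  }
  row
}

#' Extract Phi/Psi time series for one linkage type from a trajectory
#'
#' For every glycosidic linkage of the requested type, computes the Phi and
#' Psi dihedral angles (degrees) in every frame from the trajectory
#' coordinates, using the atom quadruples of
#' \code{\link{linkage_quadruples}}. For a chain of M NG repeats this
#' yields a frames x M matrix for the 1->4 angles and a frames x (M-1)
#' matrix for the 1->3 angles.
#'
#' @param trajectory a \code{"gag_trajectory"} (see
#'   \code{\link{read_trajectory}} or
#'   \code{\link{embed_torsions_as_coordinates}}).
#' @param topology the matching \code{"chain_topology"}.
#' @param angle_pair_type \code{"one_four"} or \code{"one_three"}.
#' @return a \code{"torsion_series"} with the trajectory's metadata.
#' @export
extract_torsion_series <- function(trajectory, topology,
                                   angle_pair_type = c("one_four", "one_three")) {
  angle_pair_type <- match.arg(angle_pair_type)
  stopifnot(inherits(trajectory, "gag_trajectory"),
            inherits(topology, "chain_topology"))
  links <- topology$linkages[linkage_types(topology) == angle_pair_type]
  n_frames <- dim(trajectory$coords)[3]
  phi <- matrix(NA_real_, n_frames, length(links))
  psi <- matrix(NA_real_, n_frames, length(links))
  idx <- .atom_row_index(trajectory$atoms)
  for (k in seq_along(links)) {
    q <- linkage_quadruples(links[[k]])
    for (which_angle in c("phi", "psi")) {
      qd <- q[[which_angle]]
      rows <- mapply(.resolve_atom, qd$unit, qd$atom,
                     MoreArgs = list(index = idx,
                                     context = sprintf(" (linkage %d, %s)", k, which_angle)))
      pts <- lapply(rows, function(r) t(trajectory$coords[r, , , drop = FALSE][1, , ]))
      val <- .dihedral_mat(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
      if (which_angle == "phi") phi[, k] <- val else psi[, k] <- val
    }
  }
  m <- trajectory$meta %||% list()
  torsion_series(phi, psi, angle_pair_type,
                 gag_type = m$gag_type %||% topology$gag_type,
                 ion = m$ion %||% NA_character_,
                 realization_id = m$realization_id %||% NA_integer_)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write torsion series to a plain CSV table
#'
#' Long format with columns \code{frame} (1-based), \code{linkage_index},
#' \code{phi}, \code{psi}, \code{angle_pair_type}. Several series (e.g. the
#' 1->4 and 1->3 sets of one realization) may share a file.
#'
#' @param series a \code{"torsion_series"} or list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_angle_csv <- function(series, path) {
  if (inherits(series, "torsion_series")) series <- list(series)
  tabs <- lapply(series, function(s) {
    nf <- nrow(s$phi); nl <- ncol(s$phi)
    data.frame(frame = rep(seq_len(nf), times = nl),
               linkage_index = rep(seq_len(nl), each = nf),
               phi = as.vector(s$phi), psi = as.vector(s$psi),
               angle_pair_type = s$angle_pair_type,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read torsion series from a plain CSV table
#'
#' Inverse of \code{\link{write_angle_csv}}. Metadata fields may be
#' supplied since the CSV dialect does not carry them.
#'
#' @param path CSV file with columns \code{frame}, \code{linkage_index},
#'   \code{phi}, \code{psi}, \code{angle_pair_type}.
#' @param gag_type,ion,realization_id optional metadata to attach.
#' @return named list of \code{"torsion_series"}, one per angle-pair type
#'   present in the file.
#' @export
read_angle_csv <- function(path, gag_type = NA_character_,
                           ion = NA_character_,
                           realization_id = NA_integer_) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "linkage_index", "phi", "psi", "angle_pair_type")
  if (!all(need %in% names(tab)))
    stop("angle CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (type in unique(tab$angle_pair_type)) {
    sub <- tab[tab$angle_pair_type == type, ]
    nf <- max(sub$frame); nl <- max(sub$linkage_index)
    if (nrow(sub) != nf * nl)
      stop("angle CSV is not a complete frame x linkage grid for type ",
           type, call. = FALSE)
    ord <- order(sub$linkage_index, sub$frame)
    out[[type]] <- torsion_series(
      matrix(sub$phi[ord], nf, nl), matrix(sub$psi[ord], nf, nl),
      angle_pair_type = type, gag_type = gag_type, ion = ion,
      realization_id = realization_id)
  }
  out
}
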