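# Canonical ring/linker atom labels (GLYCAM-style) carried by every unit.
# Only O5, C1, O1, C3, C4, C5 enter the torsion definitions; C2 is kept for
# completeness of the pyranose ring inventory.
.canonical_atoms <- c("C1", "C2", "C3", "C4", "C5", "O5", "O1")

#' Build the chain topology of a linear GAG
#'
#' Constructs the alternating N,G,N,G,... unit sequence of a
#' glycosaminoglycan built from NG disaccharide repeats, where G is
#' beta-D-glucuronic acid (GlcA) and N is the hexosamine:
#' N-acetyl-glucosamine (GlcNAc) for hyaluronan (\code{"HA"}) or
#' N-acetyl-galactosamine (GalNAc) for chondroitin-6-sulfate
#' (\code{"CS6"}). With \code{n_repeats = M} the chain has \code{2*M}
#' monosaccharide units, \code{M} 1->4 linkages (N to G) and \code{M - 1}
#' 1->3 linkages (G to N). The chain starts with an N unit and ends with a
#' G unit; terminal modifications are not modeled.
#'
#' For CS6 the sulfation at C-6 of GalNAc is recorded as metadata only: it
#' distinguishes the two GAGs chemically but plays no role in the torsion
#' or entropy arithmetic.
#'
#' @param gag_type \code{"HA"} or \code{"CS6"}.
#' @param n_repeats number of NG disaccharide repeats (positive integer).
#'
#' @return An object of class \code{"chain_topology"}: a list with
#'   \code{gag_type}, \code{n_repeats}, a \code{units} data frame
#'   (\code{index}, \code{kind}, \code{residue}), a list-column style
#'   \code{unit_atoms} (atom inventory per unit) and \code{linkages}, a
#'   list of \code{"glycosidic_linkage"} objects in chain order.
#'
#' @examples
#' top <- build_chain("HA", 24)
#' nrow(top$units)                    # 48 units
#' sum(linkage_types(top) == "one_four")   # 24
#' sum(linkage_types(top) == "one_three")  # 23
#' @export
build_chain <- function(gag_type = c("HA", "CS6"), n_repeats) {
  gag_type <- match.arg(gag_type)
  if (length(n_repeats) != 1L || !is.finite(n_repeats) ||
      n_repeats < 1 || n_repeats != round(n_repeats)) {
    stop("'n_repeats' must be a positive integer", call. = FALSE)
  }
  n_repeats <- as.integer(n_repeats)
  n_units <- 2L * n_repeats

  kind <- rep(c("N", "G"), n_repeats)
  residue <- ifelse(kind == "G", "GlcA",
                    if (gag_type == "HA") "GlcNAc" else "GalNAc")
  units <- data.frame(index = seq_len(n_units), kind = kind,
                      residue = residue, stringsAsFactors = FALSE)
  unit_atoms <- rep(list(.canonical_atoms), n_units)

  linkages <- vector("list", n_units - 1L)
  for (u in seq_len(n_units - 1L)) {
    type <- if (kind[u] == "N") "one_four" else "one_three"
    linkages[[u]] <- new_glycosidic_linkage(
      linkage_type = type, donor_unit = u, acceptor_unit = u + 1L,
      donor_kind = kind[u], acceptor_kind = kind[u + 1L],
      donor_atoms = unit_atoms[[u]], acceptor_atoms = unit_atoms[[u + 1L]])
  }

  structure(list(gag_type = gag_type, n_repeats = n_repeats,
                 units = units, unit_atoms = unit_atoms,
                 linkages = linkages,
                 sulfation = if (gag_type == "CS6") "C6 of GalNAc" else NA_character_),
            class = "chain_topology")
}

new_glycosidic_linkage <- function(linkage_type, donor_unit, acceptor_unit,
                                   donor_kind, acceptor_kind,
                                   donor_atoms, acceptor_atoms) {
  structure(list(linkage_type = linkage_type,
                 donor_unit = as.integer(donor_unit),
                 acceptor_unit = as.integer(acceptor_unit),
                 donor_kind = donor_kind, acceptor_kind = acceptor_kind,
                 donor_atoms = donor_atoms, acceptor_atoms = acceptor_atoms),
            class = "glycosidic_linkage")
}

#' Linkage types of a chain topology
#'
#' @param topology a \code{"chain_topology"}.
#' @return character vector, one of \code{"one_four"} / \code{"one_three"}
#'   per linkage, in chain order.
#' @export
linkage_types <- function(topology) {
  stopifnot(inherits(topology, "chain_topology"))
  vapply(topology$linkages, `[[`, character(1), "linkage_type")
}

#' Phi/Psi atom quadruples of a glycosidic linkage
#'
#' Returns the two ordered atom quadruples defining the glycosidic torsion
#' angles about a linkage. For the 1->4 linkage (hexosamine N donating to
#' GlcA G):
#' \deqn{\Phi_{1-4} = O5(N)-C1(N)-O1(N)-C4(G), \quad
#'       \Psi_{1-4} = C1(N)-O1(N)-C4(G)-C5(G)}
#' and for the 1->3 linkage (G donating to N):
#' \deqn{\Phi_{1-3} = O5(G)-C1(G)-O1(G)-C3(N), \quad
#'       \Psi_{1-3} = C1(G)-O1(G)-C3(N)-C4(N)}
#' The bridging glycosidic oxygen is labeled O1 of the donor unit.
#'
#' @param linkage a \code{"glycosidic_linkage"} (element of
#'   \code{topology$linkages}).
#' @return list with elements \code{phi} and \code{psi}, each a 4-row data
#'   frame with columns \code{atom} and \code{unit}.
#' @export
linkage_quadruples <- function(linkage) {
  stopifnot(inherits(linkage, "glycosidic_linkage"))
  d <- linkage$donor_unit
  a <- linkage$acceptor_unit
  if (linkage$linkage_type == "one_four") {
    need_d <- c("O5", "C1", "O1")
    need_a <- c("C4", "C5")
    phi <- data.frame(atom = c("O5", "C1", "O1", "C4"),
                      unit = c(d, d, d, a), stringsAsFactors = FALSE)
    psi <- data.frame(atom = c("C1", "O1", "C4", "C5"),
                      unit = c(d, d, a, a), stringsAsFactors = FALSE)
  } else if (linkage$linkage_type == "one_three") {
    need_d <- c("O5", "C1", "O1")
    need_a <- c("C3", "C4")
    phi <- data.frame(atom = c("O5", "C1", "O1", "C3"),
                      unit = c(d, d, d, a), stringsAsFactors = FALSE)
    psi <- data.frame(atom = c("C1", "O1", "C3", "C4"),
                      unit = c(d, d, a, a), stringsAsFactors = FALSE)
  } else {
    stop("unsupported linkage_type: ", linkage$linkage_type, call. = FALSE)
  }
  miss_d <- setdiff(need_d, linkage$donor_atoms)
  miss_a <- setdiff(need_a, linkage$acceptor_atoms)
  if (length(miss_d) || length(miss_a)) {
    bad <- c(if (length(miss_d)) paste0(miss_d, " in unit ", d),
             if (length(miss_a)) paste0(miss_a, " in unit ", a))
    stop("topology error: missing atom(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  list(phi = phi, psi = psi)
}

#' @export
print.chain_topology <- function(x, ...) {
  lt <- linkage_types(x)
  cat(sprintf("GAG chain topology: %s, %d NG repeats (%d units)\n",
              x$gag_type, x$n_repeats, nrow(x$units)))
  cat(sprintf("  linkages: %d x 1->4 (N-G), %d x 1->3 (G-N)\n",
              sum(lt == "one_four"), sum(lt == "one_three")))
  if (!is.na(x$sulfation))
    cat(sprintf("  sulfation (metadata): %s\n", x$sulfation))
  invisible(x)
}
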