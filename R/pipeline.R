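# Orchestration: per-realization analysis, synthetic studies grouped by
# ion, cross-realization summaries, and trajectory / results I/O.

.known_ions <- c("Na+", "Ca2+", "Mg2+")

#' Default angular clusters emulating GAG glycosidic conformers
#'
#' Study conditions of the synthetic generator: cluster centers follow the
#' modal (Phi, Psi) conformations and basin locations reported for
#' HSA-bound HA and CS6 chains — e.g. the dominant CS6 1->4 conformer near
#' (-72, -76) with a secondary positive-Phi basin, the CS6 1->3 basins
#' near (-76, 169) and (-86, -76), the HA 1->4 helix basins near
#' (-72, -126) and (-97, -155), and the HA 1->3 basins near (-115, -61),
#' (-54, 151) and (50, 120). Weights favor the dominant basin; a diffuse
#' uniform background (10%) represents transient excursions.
#'
#' @param gag_type \code{"HA"} or \code{"CS6"}.
#' @param angle_pair_type \code{"one_four"} or \code{"one_three"}.
#' @param base_kappa concentration of the dominant basin (default 3).
#' @return list of \code{\link{cluster_spec}}; weights sum to 0.9, leaving
#'   0.1 for the uniform background.
#' @export
gag_default_clusters <- function(gag_type = c("HA", "CS6"),
                                 angle_pair_type = c("one_four", "one_three"),
                                 base_kappa = 3) {
  gag_type <- match.arg(gag_type)
  angle_pair_type <- match.arg(angle_pair_type)
  k <- base_kappa
  cl <- switch(paste(gag_type, angle_pair_type, sep = "."),
    CS6.one_four = list(
      cluster_spec(-72,  -76, 2.0 * k, 0.45),
      cluster_spec(-104, -76, 1.5 * k, 0.20),
      cluster_spec(110, -120, 1.0 * k, 0.25)),
    CS6.one_three = list(
      cluster_spec(-76,  169, 2.0 * k, 0.40),
      cluster_spec(-86,  -76, 1.5 * k, 0.35),
      cluster_spec(-65,  120, 1.0 * k, 0.15)),
    HA.one_four = list(
      cluster_spec(-72, -126, 2.0 * k, 0.40),
      cluster_spec(-97, -155, 1.5 * k, 0.30),
      cluster_spec(60,   120, 1.0 * k, 0.20)),
    HA.one_three = list(
      cluster_spec(-115, -61, 2.0 * k, 0.35),
      cluster_spec(-54,  151, 1.5 * k, 0.35),
      cluster_spec(50,   120, 1.0 * k, 0.20)))
  cl
}

#' Ion-specific concentration multiplier of the synthetic generator
#'
#' Encodes, as a generative study condition, the observed ion ordering of
#' conformational disorder: Na+ systems are the most ordered (tightest
#' clusters, lowest entropy) and Ca2+ systems the most disordered. The
#' multiplier scales every cluster's von Mises concentration kappa.
#'
#' @param ion \code{"Na+"}, \code{"Mg2+"} or \code{"Ca2+"}.
#' @return numeric multiplier (Na+ 1.25, Mg2+ 1.0, Ca2+ 0.8).
#' @export
ion_kappa_multiplier <- function(ion) {
  mult <- c("Na+" = 1.25, "Mg2+" = 1.0, "Ca2+" = 0.8)
  if (!ion %in% names(mult))
    stop("unknown ion: ", ion, " (expected one of ",
         paste(names(mult), collapse = ", "), ")", call. = FALSE)
  unname(mult[ion])
}

.scale_kappa <- function(clusters, mult) {
  lapply(clusters, function(cl)
    cluster_spec(cl$mean_phi, cl$mean_psi, cl$kappa * mult, cl$weight))
}

#' Simulate one synthetic realization of a GAG chain
#'
#' Generates the 1->4 and 1->3 torsion-angle time series of one synthetic
#' MD realization: a chain of \code{n_repeats} NG repeats sampled for
#' \code{n_frames} frames (the default 1000 frames mirrors saving every
#' 100 ps over 100 ns) from the GAG- and linkage-specific default mixture,
#' with cluster concentrations scaled by the ion multiplier.
#'
#' @param gag_type \code{"HA"} or \code{"CS6"}.
#' @param ion \code{"Na+"}, \code{"Ca2+"} or \code{"Mg2+"}.
#' @param realization_id integer label of the realization.
#' @param n_repeats NG repeats (default 24).
#' @param n_frames frames (default 1000).
#' @param seed integer seed for this realization.
#' @param base_kappa dominant-basin concentration before ion scaling.
#' @param background_weight uniform background mass (default 0.1).
#' @return named list with \code{one_four} and \code{one_three}
#'   \code{"torsion_series"}.
#' @export
simulate_realization <- function(gag_type, ion, realization_id, seed,
                                 n_repeats = 24, n_frames = 1000,
                                 base_kappa = 3, background_weight = 0.1) {
  out <- list()
  for (type in c("one_four", "one_three")) {
    nl <- if (type == "one_four") n_repeats else n_repeats - 1L
    clusters <- .scale_kappa(
      gag_default_clusters(gag_type, type, base_kappa),
      ion_kappa_multiplier(ion))
    # rescale cluster weights so they fill 1 - background_weight
    w0 <- sum(vapply(clusters, `[[`, numeric(1), "weight"))
    clusters <- lapply(clusters, function(cl)
      cluster_spec(cl$mean_phi, cl$mean_psi, cl$kappa,
                   cl$weight * (1 - background_weight) / w0))
    spec <- synthetic_spec(clusters,
                           uniform_background_weight = background_weight,
                           n_linkages = nl, n_frames = n_frames,
                           seed = seed + (type == "one_three"))
    out[[type]] <- sample_angle_series(spec, type, gag_type, ion,
                                       realization_id)
  }
  out
}

#' Analyze one realization: histograms, entropy and modes
#'
#' Runs the per-realization analysis stage: extracts (or accepts) the 1->4
#' and 1->3 torsion series, pools each into a bivariate histogram with a
#' common bin setting, and computes the conformational entropy and modal
#' (Phi, Psi) conformation of each angle-pair type.
#'
#' @param input one of: a \code{"gag_trajectory"}, a path to a multi-model
#'   PDB file, a path to an angle CSV (see \code{\link{read_angle_csv}}),
#'   or a named list of \code{"torsion_series"} (as from
#'   \code{\link{simulate_realization}}).
#' @param topology the \code{"chain_topology"} of the chain; required for
#'   coordinate inputs, optional (validation only) for angle inputs.
#' @param config list of options: \code{bins_per_axis} (default 72),
#'   \code{ion}, \code{realization_id}, \code{miller_madow}
#'   (default FALSE), \code{atom_alias_map}.
#' @return object of class \code{"realization_result"}: list with
#'   \code{gag_type}, \code{ion}, \code{realization_id}, and per-type
#'   \code{entropy} (entropy_record), \code{mode} (phi/psi centers),
#'   \code{histogram} and sample sizes \code{n}.
#' @export
run_realization <- function(input, topology = NULL, config = list()) {
  bins <- config$bins_per_axis %||% 72
  mm <- isTRUE(config$miller_madow)

  series <- NULL
  if (inherits(input, "gag_trajectory") ||
      (is.character(input) && grepl("\\.pdb$", input, ignore.case = TRUE))) {
    if (is.null(topology))
      stop("a chain topology is required for coordinate input", call. = FALSE)
    traj <- if (is.character(input)) {
      read_trajectory(input, topology, atom_alias_map = config$atom_alias_map)
    } else input
    series <- list(
      one_four = extract_torsion_series(traj, topology, "one_four"),
      one_three = extract_torsion_series(traj, topology, "one_three"))
  } else if (is.character(input)) {
    series <- read_angle_csv(input,
                             gag_type = topology$gag_type %||% NA_character_,
                             ion = config$ion %||% NA_character_,
                             realization_id = config$realization_id %||% NA_integer_)
  } else if (is.list(input)) {
    series <- input
  }
  if (is.null(series) || !length(series))
    stop("input error: no torsion series could be obtained", call. = FALSE)
  if (!is.null(topology)) {
    types <- linkage_types(topology)
    for (type in names(series)) {
      expect <- sum(types == type)
      got <- ncol(series[[type]]$phi)
      if (got != expect)
        stop(sprintf("validation error: %s series has %d linkages but topology has %d",
                     type, got, expect), call. = FALSE)
    }
  }

  res <- list(gag_type = series[[1]]$meta$gag_type %||% topology$gag_type,
              ion = config$ion %||% series[[1]]$meta$ion,
              realization_id = config$realization_id %||%
                series[[1]]$meta$realization_id,
              bins_per_axis = bins,
              entropy = list(), mode = list(), histogram = list(), n = list())
  for (type in c("one_four", "one_three")) {
    s <- series[[type]]
    if (is.null(s) || ncol(s$phi) == 0) next
    h <- angle_histogram2d(s, bins_per_axis = bins)
    res$histogram[[type]] <- h
    res$entropy[[type]] <- conformational_entropy(h, miller_madow = mm)
    res$mode[[type]] <- most_frequent_angles(h)
    res$n[[type]] <- h$n
  }
  structure(res, class = "realization_result")
}

#' @export
print.realization_result <- function(x, ...) {
  cat(sprintf("realization %s (%s, ion %s):\n",
              x$realization_id, x$gag_type, x$ion))
  for (type in names(x$entropy)) {
    cat(sprintf("  %-9s S = %7.3f J K^-1 mol^-1, mode (%.1f, %.1f), n = %d\n",
                type, x$entropy[[type]]$S, x$mode[[type]]["phi"],
                x$mode[[type]]["psi"], x$n[[type]]))
  }
  invisible(x)
}

#' Run a synthetic multi-realization study
#'
#' Generates and analyzes \code{n_realizations} independent synthetic
#' realizations for every (GAG, ion) combination, mirroring a study design
#' of N independent MD runs per ionic condition, and summarizes entropies
#' per group.
#'
#' @param gags character vector of GAG types (default both HA and CS6).
#' @param ions character vector of ions (default Na+, Ca2+, Mg2+).
#' @param n_realizations realizations per (GAG, ion) group (default 10).
#' @param n_repeats,n_frames chain size and trajectory length per
#'   realization (defaults 24 and 1000).
#' @param bins_per_axis histogram bins per axis (default 72).
#' @param seed master seed; per-realization seeds are derived from it.
#' @param base_kappa,background_weight generator conditions, see
#'   \code{\link{simulate_realization}}.
#' @return list with \code{results} (list of
#'   \code{"realization_result"}) and \code{summary} (the
#'   \code{\link{summarize_entropy}} table).
#' @export
run_study <- function(gags = c("HA", "CS6"), ions = .known_ions,
                      n_realizations = 10, n_repeats = 24, n_frames = 1000,
                      bins_per_axis = 72, seed = 1, base_kappa = 3,
                      background_weight = 0.1) {
  results <- list()
  counter <- 0L
  for (gag in gags) for (ion in ions) for (r in seq_len(n_realizations)) {
    counter <- counter + 1L
    series <- simulate_realization(gag, ion, realization_id = r,
                                   seed = (seed * 10007L + counter * 2L) %% 2147483647L,
                                   n_repeats = n_repeats, n_frames = n_frames,
                                   base_kappa = base_kappa,
                                   background_weight = background_weight)
    results[[counter]] <- run_realization(
      series, config = list(bins_per_axis = bins_per_axis,
                            ion = ion, realization_id = r))
  }
  list(results = results, summary = summarize_entropy(results))
}

#' Summarize entropies across realizations
#'
#' Order statistics of conformational entropy per (GAG, ion, angle-pair
#' type) group: median, minimum and maximum over the group's
#' realizations. With N = 10 realizations the minimum and maximum roughly
#' estimate the 10th and 90th percentiles.
#'
#' @param results list of \code{"realization_result"}.
#' @return data frame with columns \code{gag_type}, \code{ion},
#'   \code{angle_pair_type}, \code{n_realizations}, \code{median_S},
#'   \code{min_S}, \code{max_S}.
#' @export
summarize_entropy <- function(results) {
  if (!length(results)) stop("input error: no results to summarize",
                             call. = FALSE)
  rows <- list()
  for (res in results) {
    for (type in names(res$entropy)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gag_type = res$gag_type, ion = res$ion,
        realization_id = res$realization_id %||% NA_integer_,
        angle_pair_type = type, S = res$entropy[[type]]$S,
        stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  groups <- unique(long[c("gag_type", "ion", "angle_pair_type")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- long$gag_type == groups$gag_type[g] & long$ion == groups$ion[g] &
      long$angle_pair_type == groups$angle_pair_type[g]
    s <- long$S[sel]
    data.frame(groups[g, , drop = FALSE], n_realizations = sum(sel),
               median_S = stats::median(s), min_S = min(s), max_S = max(s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# --- trajectory I/O ------------------------------------------------------

#' Read a multi-model PDB trajectory
#'
#' Reads a coordinate trajectory stored as a multi-model PDB (MODEL /
#' ENDMDL records, one model per saved frame) via
#' \code{bio3d::read.pdb}, and maps atoms onto the chain topology:
#' residue numbers are taken as unit indices and atom names as the
#' canonical labels, optionally translated through an alias map for other
#' PDB naming dialects.
#'
#' @param path PDB file path.
#' @param topology the expected \code{"chain_topology"}; every atom
#'   required by a linkage quadruple must resolve in every frame.
#' @param atom_alias_map optional named character vector mapping file atom
#'   names to canonical names, e.g. \code{c("O5'" = "O5")}.
#' @return a \code{"gag_trajectory"}.
#' @export
read_trajectory <- function(path, topology, atom_alias_map = NULL) {
  if (!file.exists(path)) stop("cannot read trajectory: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("parse error reading PDB '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  atoms <- data.frame(eleno = pdb$atom$eleno,
                      elety = trimws(pdb$atom$elety),
                      unit = pdb$atom$resno,
                      resid = trimws(pdb$atom$resid),
                      stringsAsFactors = FALSE)
  if (!is.null(atom_alias_map)) {
    hit <- atoms$elety %in% names(atom_alias_map)
    atoms$elety[hit] <- unname(atom_alias_map[atoms$elety[hit]])
  }
  if (!is.null(topology)) {
    atoms$kind <- topology$units$kind[atoms$unit]
  }
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- nrow(atoms)
  coords <- array(NA_real_, c(n_atoms, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  traj <- structure(list(atoms = atoms, coords = coords,
                         meta = list(gag_type = topology$gag_type)),
                    class = "gag_trajectory")
  # fail early, naming the atom, if a quadruple cannot be resolved
  idx <- .atom_row_index(atoms)
  for (lk in topology$linkages) {
    q <- linkage_quadruples(lk)
    for (qq in q) mapply(.resolve_atom, qq$unit, qq$atom,
                         MoreArgs = list(index = idx, context = paste0(" in ", path)))
  }
  traj
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, HETATM records with the canonical
#' atom names and the unit index as residue number. Round-trips through
#' \code{\link{read_trajectory}}.
#'
#' @param trajectory a \code{"gag_trajectory"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "gag_trajectory"))
  atoms <- trajectory$atoms
  n_frames <- dim(trajectory$coords)[3]
  resid3 <- substr(ifelse(is.na(atoms$resid), "UNK", atoms$resid), 1, 3)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- trajectory$coords[, , f]
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      atoms$eleno, atoms$elety, toupper(resid3), atoms$unit,
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# --- results I/O and config ---------------------------------------------

#' Write study results to CSV and a JSON manifest
#'
#' Writes \code{entropies.csv} (one row per realization and angle-pair
#' type), \code{summary.csv} (the group summary table) and
#' \code{manifest.json} (config echo, seed, package version). Content is
#' deterministic given identical inputs.
#'
#' @param results list of \code{"realization_result"}.
#' @param summary a summary table from \code{\link{summarize_entropy}}.
#' @param out_dir output directory (created if absent).
#' @param config optional config list echoed into the manifest.
#' @return named character vector of the files written, invisibly.
#' @export
write_results <- function(results, summary, out_dir, config = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create ", out_dir, call. = FALSE)
  }
  rows <- list()
  for (res in results) {
    for (type in names(res$entropy)) {
      rec <- res$entropy[[type]]
      rows[[length(rows) + 1L]] <- data.frame(
        gag_type = res$gag_type, ion = res$ion,
        realization_id = res$realization_id, angle_pair_type = type,
        S = rec$S, n = rec$n, bins_per_axis = rec$bins_per_axis,
        mode_phi = res$mode[[type]]["phi"], mode_psi = res$mode[[type]]["psi"],
        stringsAsFactors = FALSE)
    }
  }
  entropies <- do.call(rbind, rows)
  rownames(entropies) <- NULL
  f1 <- file.path(out_dir, "entropies.csv")
  f2 <- file.path(out_dir, "summary.csv")
  f3 <- file.path(out_dir, "manifest.json")
  utils::write.csv(entropies, f1, row.names = FALSE)
  utils::write.csv(summary, f2, row.names = FALSE)
  manifest <- list(package = "gagentropy",
                   version = as.character(utils::packageVersion("gagentropy")),
                   config = config)
  jsonlite::write_json(manifest, f3, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(entropies = f1, summary = f2, manifest = f3))
}

#' Read a run configuration file
#'
#' YAML or JSON run config with keys such as \code{gag_type},
#' \code{n_repeats}, \code{atom_alias_map}, \code{bins_per_axis},
#' \code{ion}, \code{seed}.
#'
#' @param path a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  }
}
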