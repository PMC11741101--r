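header_synonyms <- list(
  n_tot_s = c("n_tot_s", "n_tot^s", "n_tot.s", "ntot_s", "n_solvent"),
  n_tot = c("n_tot", "ntot", "n_solute"),
  n_ss = c("n_ss", "n_xtal_ss", "n_xtal^ss", "n_xtal.ss", "nss"),
  temperature = c("temperature", "t", "temp", "t_k"),
  polymorph = c("polymorph", "form", "phase")
)

#' Read a seed-observation table
#'
#' Reads a CSV or TSV table of confined seeded simulations - one row per
#' simulation with its box composition and observed steady-state crystal
#' size - and validates it for [fit_thermo_params()]. Common header
#' synonyms (`n_tot^s`, `n_xtal_ss`, `T`, ...) are accepted and normalised
#' to `n_tot_s`, `n_tot`, `n_ss`, `temperature`, `polymorph`.
#'
#' @param path Path to a delimited text file; the delimiter is taken from
#'   the extension (`.tsv`/`.tab` = tab, otherwise comma).
#' @return A validated observation tibble.
#' @seealso [lga_table1()] for the packaged reference table.
#' @export
read_observation_table <- function(path) {
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE)
  if (nrow(raw) == 0) abort(paste0("no observation rows in '", path, "'."))
  nm <- tolower(names(raw))
  for (canon in names(header_synonyms)) {
    hit <- which(nm %in% tolower(header_synonyms[[canon]]))
    if (length(hit) >= 1) names(raw)[hit[1]] <- canon
  }
  required <- c("n_tot_s", "n_tot", "n_ss")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0(
      "'", path, "' is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  for (col in required) {
    v <- raw[[col]]
    bad <- which(!is.finite(v) | v != round(v) | v < 0)
    if (length(bad)) {
      abort(paste0(
        "column `", col, "` must hold non-negative integers; bad value in row(s) ",
        paste(bad, collapse = ", "), " of '", path, "'."
      ))
    }
  }
  bad <- which(raw$n_ss >= raw$n_tot)
  if (length(bad)) {
    abort(paste0(
      "`n_ss` must be smaller than `n_tot`; violated in row(s) ",
      paste(bad, collapse = ", "), " of '", path, "'."
    ))
  }
  validate_observations(raw)
}

#' Write a seed-observation table
#'
#' Writes observations in the same CSV dialect [read_observation_table()]
#' reads, so a read-write round trip is lossless.
#'
#' @param observations Observation data frame.
#' @param path Output path (`.tsv` for tab-delimited).
#' @return `path`, invisibly.
#' @export
write_observation_table <- function(observations, path) {
  obs <- validate_observations(observations)
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(obs, path, delim = delim)
  invisible(path)
}

#' Reference seed-observation table for aqueous L-glutamic acid
#'
#' The packaged table of finite-size seeded MD simulations of alpha- and
#' beta-LGA in water at 298 K: eight beta and six alpha boxes, each with its
#' solvent count, solute count, and the steady-state crystal size the
#' simulation relaxed to. This is the canonical input of the
#' solubility/surface-energy fit.
#'
#' @param polymorph `"alpha"`, `"beta"`, or `NULL` (default) for all rows.
#' @return An observation tibble (see [read_observation_table()]).
#' @examples
#' fit_thermo_params(lga_table1("beta"))
#' @export
lga_table1 <- function(polymorph = NULL) {
  obs <- read_observation_table(
    system.file("extdata", "lga_seed_observations.csv", package = "seedtherm",
                mustWork = TRUE)
  )
  if (!is.null(polymorph)) {
    polymorph <- match.arg(polymorph, c("alpha", "beta"))
    obs <- dplyr::filter(obs, .data$polymorph == !!polymorph)
  }
  obs
}

#' Save or load an orientation fingerprint
#'
#' Fingerprints are stored as small structured JSON text files.
#'
#' @param fingerprint An `orientation_fingerprint`.
#' @param path File path.
#' @return `write_fingerprint()` returns `path` invisibly;
#'   `read_fingerprint()` returns the fingerprint.
#' @export
write_fingerprint <- function(fingerprint, path) {
  stopifnot(inherits(fingerprint, "orientation_fingerprint"))
  jsonlite::write_json(unclass(fingerprint), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fingerprint
#' @export
read_fingerprint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      theta_bins = as.numeric(raw$theta_bins),
      density = as.numeric(raw$density),
      acceptance_mask = as.logical(raw$acceptance_mask),
      r_cut = as.numeric(raw$r_cut),
      accept_frac = as.numeric(raw$accept_frac),
      fold = as.logical(raw$fold),
      n_pairs = as.integer(raw$n_pairs)
    ),
    class = "orientation_fingerprint"
  )
}

#' Read a molecular snapshot from a PDB file
#'
#' Reads a structure (or multi-model trajectory) PDB through bio3d and
#' reduces each residue to a reference point and an internal vector defined
#' by a designated atom pair: the first atom's coordinates are the
#' reference point and the vector points from the first to the second atom.
#' The choice of atom pair is a required input - it fixes the orientation
#' convention the fingerprint is built with.
#'
#' @param path PDB file path.
#' @param atom_pair Character vector of two atom names (PDB `elety`), e.g.
#'   `c("C1", "C2")`.
#' @param box Periodic cell lengths (Angstrom) or `NULL`.
#' @param multi Read all models as a trajectory (list of snapshots).
#' @return A `molecular_snapshot`, or a list of them when `multi = TRUE`.
#' @export
read_snapshot_pdb <- function(path, atom_pair, box = NULL, multi = FALSE) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB snapshots requires the 'bio3d' package.")
  }
  if (length(atom_pair) != 2) abort("`atom_pair` must name exactly two atoms.")
  pdb <- bio3d::read.pdb(path, multi = multi)
  at <- pdb$atom
  sel1 <- which(at$elety == atom_pair[1])
  sel2 <- which(at$elety == atom_pair[2])
  if (length(sel1) == 0 || length(sel2) == 0 || length(sel1) != length(sel2)) {
    abort("`atom_pair` atoms must occur once per residue and in equal numbers.")
  }
  make_snap <- function(xyz) {
    m <- matrix(xyz, ncol = 3, byrow = TRUE)
    molecular_snapshot(m[sel1, , drop = FALSE],
                       m[sel2, , drop = FALSE] - m[sel1, , drop = FALSE],
                       box = box)
  }
  if (multi && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1) {
    purrr::map(seq_len(nrow(pdb$xyz)), function(i) make_snap(pdb$xyz[i, ]))
  } else {
    make_snap(as.numeric(pdb$xyz))
  }
}

#' Write a molecular snapshot as a PDB file
#'
#' Writes each molecule as a two-atom residue: the reference point and a
#' second atom displaced along the internal vector, so
#' [read_snapshot_pdb()] recovers the snapshot.
#'
#' @param snapshot A `molecular_snapshot`.
#' @param path Output PDB path.
#' @param atom_pair Names for the two atoms of each molecule.
#' @param bond_length Distance between the two atoms, Angstrom.
#' @return `path`, invisibly.
#' @export
write_snapshot_pdb <- function(snapshot, path, atom_pair = c("C1", "C2"),
                               bond_length = 1.5) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("writing PDB snapshots requires the 'bio3d' package.")
  }
  stopifnot(inherits(snapshot, "molecular_snapshot"))
  n <- nrow(snapshot$positions)
  a1 <- snapshot$positions
  a2 <- snapshot$positions + bond_length * snapshot$internal_vectors
  # interleave atom1/atom2 per molecule
  coords <- matrix(0, nrow = 2 * n, ncol = 3)
  coords[seq(1, 2 * n, by = 2), ] <- a1
  coords[seq(2, 2 * n, by = 2), ] <- a2
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords)),
    resno = rep(seq_len(n), each = 2),
    resid = rep("MOL", 2 * n),
    elety = rep(atom_pair, n)
  )
  invisible(path)
}
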