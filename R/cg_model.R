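# Two-site-per-residue coarse-grained protein model built from PDB input.
#
# Each residue is reduced to its Calpha site plus a side-chain functional
# center (SC) placed at the centroid of the side-chain heavy atoms (GLY: the
# Calpha itself). Charges sit on SC sites of ionizable residues;
# Kyte-Doolittle hydropathies are carried per residue on the SC site.

# Read a PDB (path or bio3d object), keep model 1 heavy atoms of the named
# chains, and return a per-atom data.frame with a residue ordinal column
# (1..n across the selected chains, chains in the order given). This single
# parse path guarantees that coarse models and atom-level contact detection
# index residues identically.
parse_residues <- function(pdb, chains, nonstd = c("error", "skip")) {
  nonstd <- match.arg(nonstd)
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  missing_chains <- setdiff(chains, unique(atoms$chain))
  if (length(missing_chains) > 0)
    stop("chain(s) not present in structure: ",
         paste(missing_chains, collapse = ", "))
  # heavy atoms only; tolerate blank element symbols by falling back to the
  # first letter of the atom name
  ele <- toupper(trimws(atoms$elesy))
  guess <- substr(gsub("^[0-9]+", "", trimws(atoms$elety)), 1, 1)
  ele[is.na(ele) | ele == ""] <- guess[is.na(ele) | ele == ""]
  atoms <- atoms[!(ele %in% c("H", "D")), , drop = FALSE]
  # primary altloc only
  atoms <- atoms[atoms$alt %in% c("", " ", NA, "A"), , drop = FALSE]

  pieces <- lapply(chains, function(ch) atoms[atoms$chain == ch, , drop = FALSE])
  atoms <- do.call(rbind, pieces)
  insert <- ifelse(is.na(atoms$insert), "", atoms$insert)
  res_key <- paste(atoms$chain, atoms$resno, insert, sep = "|")
  ord <- match(res_key, unique(res_key))
  atoms$res_ordinal <- ord
  atoms$restype <- canonical_restype(atoms$resid)

  bad <- !(atoms$restype %in% AA3)
  if (any(bad)) {
    bad_names <- unique(atoms$resid[bad])
    if (nonstd == "error")
      stop("unmappable non-standard residue(s): ",
           paste(bad_names, collapse = ", "))
    atoms <- atoms[!bad, , drop = FALSE]
    atoms$res_ordinal <- match(res_key[!bad], unique(res_key[!bad]))
  }
  atoms
}

#' Load a protein as a two-site-per-residue coarse model
#'
#' Parses a PDB file (model 1, heavy atoms) and reduces each residue of the
#' selected chains to two sites: the Calpha (`CA`) and the side-chain
#' functional center (`SC`), placed at the centroid of the side-chain heavy
#' atoms. Glycine's SC coincides with its Calpha. Formal charges
#' (ASP/GLU -1, LYS/ARG +1, HIS 0 by default) and Kyte-Doolittle
#' hydropathies are attached to the SC site of each residue.
#'
#' Reference coordinates are stored centered at the center of mass; the
#' protein carries a rigid-body pose (see [cg_pose()]) initialized so that
#' [placed_xyz()] reproduces the input coordinates. The hydrodynamic radius
#' defaults to `0.9 * Rg + 4` Angstrom, a documented Stokes-Einstein size
#' proxy, and can be overridden.
#'
#' @param pdb path to a PDB file, or a `bio3d` pdb object.
#' @param chains character vector of chain identifiers to include.
#' @param charge_overrides optional named numeric vector of per-residue-type
#'   charges, e.g. `c(HIS = 0.5)`.
#' @param hydrodynamic_radius optional override (Angstrom).
#' @param nonstd `"error"` (default) to reject unmappable non-standard
#'   residues, `"skip"` to drop them.
#' @return An object of class `coarse_protein` with fields `xyz` (centered
#'   reference coordinates, 2 sites per residue), `kind`, `res_ordinal`,
#'   `restype`, `charge`, `hp`, `pose`, `n_res`, `chains`, `rg`,
#'   `hydrodynamic_radius`.
#' @export
load_coarse_protein <- function(pdb, chains, charge_overrides = NULL,
                                hydrodynamic_radius = NULL,
                                nonstd = "error") {
  atoms <- parse_residues(pdb, chains, nonstd)
  n_res <- max(atoms$res_ordinal)

  charge_table <- RESIDUE_CHARGE
  if (!is.null(charge_overrides)) {
    stopifnot(all(names(charge_overrides) %in% AA3))
    charge_table[names(charge_overrides)] <- charge_overrides
  }

  ca_xyz <- matrix(NA_real_, n_res, 3)
  sc_xyz <- matrix(NA_real_, n_res, 3)
  restype <- character(n_res)
  no_sc <- character(0)
  for (i in seq_len(n_res)) {
    res <- atoms[atoms$res_ordinal == i, , drop = FALSE]
    restype[i] <- res$restype[1]
    ca <- res[res$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0)
      stop("residue ", i, " (", restype[i], ") has no CA atom")
    ca_xyz[i, ] <- as.numeric(ca[1, c("x", "y", "z")])
    side <- res[!(res$elety %in% BACKBONE_ATOMS), , drop = FALSE]
    if (restype[i] != "GLY" && nrow(side) > 0) {
      sc_xyz[i, ] <- colMeans(side[, c("x", "y", "z"), drop = FALSE])
    } else {
      sc_xyz[i, ] <- ca_xyz[i, ]
      if (restype[i] != "GLY")
        no_sc <- c(no_sc, paste0(restype[i], i))
    }
  }
  if (length(no_sc) > 0)
    warning("no side-chain heavy atoms for residue(s) ",
            paste(no_sc, collapse = ", "), "; SC site set to CA")

  # interleave CA/SC so sites of one residue are adjacent
  xyz <- matrix(NA_real_, 2 * n_res, 3)
  xyz[seq(1, 2 * n_res, 2), ] <- ca_xyz
  xyz[seq(2, 2 * n_res, 2), ] <- sc_xyz
  kind <- rep(c("CA", "SC"), n_res)
  res_ordinal <- rep(seq_len(n_res), each = 2)
  site_restype <- rep(restype, each = 2)
  charge <- ifelse(kind == "SC", charge_table[site_restype], 0)
  hp <- ifelse(kind == "SC", KYTE_DOOLITTLE[site_restype], 0)

  com <- colMeans(xyz)
  centered <- sweep(xyz, 2, com)
  rg <- sqrt(mean(rowSums(centered^2)))
  r_h <- if (is.null(hydrodynamic_radius)) 0.9 * rg + 4 else hydrodynamic_radius

  structure(list(
    xyz = centered,
    kind = kind,
    res_ordinal = res_ordinal,
    restype = site_restype,
    residue_types = restype,
    charge = unname(charge),
    hp = unname(hp),
    pose = cg_pose(diag(3), com),
    n_res = n_res,
    chains = chains,
    rg = rg,
    hydrodynamic_radius = r_h
  ), class = "coarse_protein")
}

#' @export
print.coarse_protein <- function(x, ...) {
  cat("Coarse protein:", x$n_res, "residues (",
      nrow(x$xyz), "sites ), chains",
      paste(x$chains, collapse = ","),
      sprintf("| Rg %.1f A, Rh %.1f A\n", x$rg, x$hydrodynamic_radius))
  invisible(x)
}

# SC-site row indices ordered by residue ordinal.
sc_indices <- function(protein) which(protein$kind == "SC")

# CA-site row indices ordered by residue ordinal.
ca_indices <- function(protein) which(protein$kind == "CA")

#' Extract the native interface contact map
#'
#' Two residues (one per binding partner) form a native contact when any
#' pair of their side-chain heavy atoms lies within `atom_cutoff` (default
#' 5.5 Angstrom) in the native complex. Each contact stores the native
#' SC-SC functional-center distance `r0` used by the Go-like statistical
#' potential and the native-likeness criterion. Glycine contributes its
#' Calpha as the side-chain proxy.
#'
#' @param receptor,ligand `coarse_protein` objects loaded from the same
#'   native structure (their stored poses must reproduce the native
#'   coordinates).
#' @param native_pdb the native complex: path or bio3d pdb object.
#' @param atom_cutoff side-chain heavy-atom distance criterion (Angstrom).
#' @return Object of class `native_contact_map`: a list with `pairs` (a
#'   data.frame `ri`, `li`, `r0`), `atom_cutoff`, `n_native`, and the
#'   interface residue ordinals per side.
#' @export
native_contacts <- function(receptor, ligand, native_pdb, atom_cutoff = 5.5) {
  pdb <- if (is.character(native_pdb))
    bio3d::read.pdb(native_pdb, multi = FALSE, verbose = FALSE) else native_pdb
  side_atoms <- function(chains) {
    a <- parse_residues(pdb, chains)
    gly <- a$restype == "GLY"
    keep <- (!(a$elety %in% BACKBONE_ATOMS)) | (gly & a$elety == "CA")
    a[keep, , drop = FALSE]
  }
  ra <- side_atoms(receptor$chains)
  la <- side_atoms(ligand$chains)
  d2 <- pair_dist_sq(as.matrix(ra[, c("x", "y", "z")]),
                     as.matrix(la[, c("x", "y", "z")]))
  hit <- which(d2 <= atom_cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0)
    stop("no native contacts within ", atom_cutoff,
         " A between the selected chain groups; check the receptor/ligand ",
         "chain assignment")
  pairs <- unique(data.frame(ri = ra$res_ordinal[hit[, 1]],
                             li = la$res_ordinal[hit[, 2]]))
  pairs <- pairs[order(pairs$ri, pairs$li), , drop = FALSE]
  rownames(pairs) <- NULL

  rsc <- placed_xyz(receptor)[sc_indices(receptor), , drop = FALSE]
  lsc <- placed_xyz(ligand)[sc_indices(ligand), , drop = FALSE]
  pairs$r0 <- row_dist(rsc[pairs$ri, , drop = FALSE],
                       lsc[pairs$li, , drop = FALSE])
  structure(list(
    pairs = pairs,
    atom_cutoff = atom_cutoff,
    n_native = nrow(pairs),
    receptor_interface = sort(unique(pairs$ri)),
    ligand_interface = sort(unique(pairs$li))
  ), class = "native_contact_map")
}

#' @export
print.native_contact_map <- function(x, ...) {
  cat("Native contact map:", x$n_native, "residue pairs (atom cutoff",
      x$atom_cutoff, "A)\n")
  invisible(x)
}

#' Dump a coarse model as TSV
#'
#' Writes one row per site (residue ordinal, residue type, site kind, x, y,
#' z at the current pose, charge, hydropathy) for inspection and fixtures.
#'
#' @param protein a `coarse_protein`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coarse_tsv <- function(protein, path) {
  xyz <- placed_xyz(protein)
  df <- data.frame(
    res_ordinal = protein$res_ordinal,
    restype = protein$restype,
    kind = protein$kind,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    q = protein$charge,
    hp = protein$hp)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
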