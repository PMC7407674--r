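# Structural and energetic analysis of trajectory ensembles: RMSD to the
# native complex, energy-RMSD correlation over final configurations, and
# spatial distributions of final ligand centers of mass in the
# receptor-aligned native frame.

# Ligand coordinates shifted to the periodic image nearest the receptor,
# so a partner that wrapped across the boundary is not artificially far.
unwrap_ligand_xyz <- function(l_xyz, pose_r, pose_l, box) {
  if (is.null(box)) return(l_xyz)
  shift <- box * round((pose_l$t - pose_r$t) / box)
  sweep(l_xyz, 2, shift)
}

#' RMSD of a configuration from the native complex
#'
#' Superposes the current receptor Calpha sites onto the native receptor
#' Calpha sites by a least-squares rigid-body (Kabsch) fit, then reports
#' the RMSD of the ligand Calpha sites from their native positions
#' (`atoms = "ligand"`, default: isolates the binding-pose error), or of
#' all Calpha sites (`atoms = "complex"`). Ligand coordinates are
#' unwrapped to the periodic image nearest the receptor first. The native
#' reference is the pose stored in each `coarse_protein` at load time.
#'
#' @param receptor,ligand `coarse_protein` objects.
#' @param poses list with current `pose_r`, `pose_l`.
#' @param box box edge (Angstrom) or NULL.
#' @param atoms `"ligand"` or `"complex"`.
#' @return RMSD in Angstrom.
#' @export
complex_rmsd <- function(receptor, ligand, poses, box = NULL,
                         atoms = c("ligand", "complex")) {
  atoms <- match.arg(atoms)
  rca <- ca_indices(receptor); lca <- ca_indices(ligand)
  cur_r <- placed_xyz(receptor, poses$pose_r)[rca, , drop = FALSE]
  cur_l <- placed_xyz(ligand, poses$pose_l)[lca, , drop = FALSE]
  cur_l <- unwrap_ligand_xyz(cur_l, poses$pose_r, poses$pose_l, box)
  nat_r <- placed_xyz(receptor)[rca, , drop = FALSE]
  nat_l <- placed_xyz(ligand)[lca, , drop = FALSE]

  if (atoms == "ligand") {
    tr <- kabsch_transform(cur_r, nat_r)
    moved_l <- apply_kabsch(tr, cur_l)
    sqrt(mean(rowSums((moved_l - nat_l)^2)))
  } else {
    cur <- rbind(cur_r, cur_l)
    nat <- rbind(nat_r, nat_l)
    tr <- kabsch_transform(cur, nat)
    sqrt(mean(rowSums((apply_kabsch(tr, cur) - nat)^2)))
  }
}

# Final ligand center of mass mapped into the receptor-aligned native
# frame (the frame of Fig.-5-style spatial distributions).
ligand_com_native_frame <- function(receptor, ligand, poses, box = NULL) {
  rca <- ca_indices(receptor)
  cur_r <- placed_xyz(receptor, poses$pose_r)[rca, , drop = FALSE]
  nat_r <- placed_xyz(receptor)[rca, , drop = FALSE]
  com_l <- poses$pose_l$t
  if (!is.null(box))
    com_l <- com_l - box * round((com_l - poses$pose_r$t) / box)
  tr <- kabsch_transform(cur_r, nat_r)
  as.numeric(apply_kabsch(tr, matrix(com_l, 1)))
}

#' Energy-RMSD correlation over final configurations
#'
#' Pearson correlation between the final intermolecular energy and the
#' final RMSD to native across all trajectories of an ensemble (associated
#' and not). A positive value is the signature of a funnel-like
#' association landscape.
#'
#' @param ensemble a `kmc_ensemble` (or its `summary` data.frame).
#' @return list with `pcc` and `scatter` (data.frame `rmsd`, `energy`,
#'   `associated`).
#' @export
energy_rmsd_correlation <- function(ensemble) {
  s <- if (inherits(ensemble, "kmc_ensemble")) ensemble$summary else ensemble
  stopifnot(all(c("final_energy", "final_rmsd") %in% names(s)))
  if (nrow(s) < 3) stop("need at least 3 trajectories")
  if (stats::sd(s$final_energy) == 0 || stats::sd(s$final_rmsd) == 0)
    stop("zero variance in energy or RMSD; correlation undefined")
  list(pcc = stats::cor(s$final_rmsd, s$final_energy),
       scatter = data.frame(rmsd = s$final_rmsd,
                            energy = s$final_energy,
                            associated = s$associated))
}

#' Spatial cloud of final ligand positions
#'
#' Randomly subsamples final configurations (deterministically for a given
#' seed) and returns the ligand centers of mass in the receptor-aligned
#' native frame, flagging the encounter (associated) subset. The native
#' ligand center of mass in this frame is attached as attribute
#' `native_com`.
#'
#' @param ensemble a `kmc_ensemble`.
#' @param ligand the ligand `coarse_protein` (for the native center).
#' @param sample_size number of configurations to keep (default 1000); if
#'   larger than the ensemble, all are used with a warning.
#' @param seed RNG seed for the subsample.
#' @return data.frame `x`, `y`, `z`, `associated`, `dist_native`.
#' @export
ligand_cloud <- function(ensemble, ligand, sample_size = 1000, seed = 1) {
  s <- ensemble$summary
  n <- nrow(s)
  if (sample_size >= n) {
    if (sample_size > n)
      warning("sample_size ", sample_size, " exceeds ensemble size ", n,
              "; using all records")
    keep <- seq_len(n)
  } else {
    set.seed(seed)
    keep <- sort(sample.int(n, sample_size))
  }
  native_com <- ligand$pose$t
  out <- data.frame(x = s$com_x[keep], y = s$com_y[keep],
                    z = s$com_z[keep], associated = s$associated[keep])
  out$dist_native <- sqrt((out$x - native_com[1])^2 +
                          (out$y - native_com[2])^2 +
                          (out$z - native_com[3])^2)
  attr(out, "native_com") <- native_com
  out
}

#' Write a ligand cloud as TSV and pseudo-atom PDB
#'
#' @param cloud output of [ligand_cloud()].
#' @param tsv_path,pdb_path output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_ligand_cloud <- function(cloud, tsv_path = NULL, pdb_path = NULL) {
  written <- character(0)
  if (!is.null(tsv_path)) {
    utils::write.table(cloud, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tsv_path)
  }
  if (!is.null(pdb_path)) {
    n <- nrow(cloud)
    bio3d::write.pdb(file = pdb_path,
                     xyz = as.numeric(t(as.matrix(cloud[, c("x", "y", "z")]))),
                     type = rep("HETATM", n),
                     resno = seq_len(n),
                     resid = ifelse(cloud$associated, "ENC", "CLD"),
                     elety = rep("C", n),
                     chain = rep("X", n))
    written <- c(written, pdb_path)
  }
  invisible(written)
}
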