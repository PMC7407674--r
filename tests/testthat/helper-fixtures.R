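# Shared fixtures and independent oracles for the test suite. The oracle
# implementations below are deliberately naive (scalar double loops,
# explicit if-branches) and must stay independent of the vectorized code
# paths they check.

# Uniform attractive Go table: every residue pair has u_sc = -s kT.
go_table <- function(s) {
  stat_potential_table(matrix(-s, 20, 20, dimnames = list(AA3, AA3)),
                       provenance = sprintf("uniform attractive %g kT", s))
}

# Scalar minimum-image distance.
mi_dist <- function(a, b, box = NULL) {
  d <- a - b
  if (!is.null(box)) d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# Naive per-term energies by explicit double loops over all site pairs.
naive_energies <- function(receptor, ligand, poses, ff, contacts,
                           box = NULL) {
  p <- ff$physics
  xyzA <- placed_xyz(receptor, poses$pose_r)
  xyzB <- placed_xyz(ligand, poses$pose_l)
  elec <- 0; hp <- 0; ev <- 0
  coul <- cgassoc:::COULOMB_KT
  for (i in seq_len(nrow(xyzA))) {
    for (j in seq_len(nrow(xyzB))) {
      r <- mi_dist(xyzA[i, ], xyzB[j, ], box)
      ka <- receptor$kind[i]; kb <- ligand$kind[j]
      s0 <- if (ka == "CA" && kb == "CA") p$sigma0[["CA-CA"]]
            else if (ka == "SC" && kb == "SC") p$sigma0[["SC-SC"]]
            else p$sigma0[["CA-SC"]]
      if (r < s0)
        ev <- ev + p$epsilon_rep * ((s0 / r)^12 - (s0 / r)^6)
      if (ka == "SC" && kb == "SC") {
        if (r <= p$hp_cutoff)
          hp <- hp + p$hp_sign * p$w_alpha * (receptor$hp[i] + ligand$hp[j])
        qi <- receptor$charge[i]; qj <- ligand$charge[j]
        if (qi != 0 && qj != 0 && r <= p$elec_cutoff)
          elec <- elec + coul * qi * qj / (p$D_s * exp(r / p$xi) * r)
      }
    }
  }
  stat <- 0
  if (!is.null(ff$table) && !is.null(contacts)) {
    sa <- which(receptor$kind == "SC"); sb <- which(ligand$kind == "SC")
    for (k in seq_len(nrow(contacts$pairs))) {
      ri <- contacts$pairs$ri[k]; li <- contacts$pairs$li[k]
      r0 <- contacts$pairs$r0[k]
      r <- mi_dist(xyzA[sa[ri], ], xyzB[sb[li], ], box)
      u <- ff$table$u[receptor$restype[sa[ri]], ligand$restype[sb[li]]]
      x6 <- (r0 / r)^6
      contrib <- if (ff$stat_mode == "go") {
        if (u < 0) abs(u) * (x6 * x6 - 2 * x6)
        else if (u > 0) u * x6
        else 0
      } else {
        f <- if (u < 0) 1 else if (u > 0) -1 else 0
        g <- if (u < 0) -1 else 0
        sc <- if (ff$stat_mode == "scaled") abs(u) else 1
        sc * (g * x6 * x6 - f * x6)
      }
      stat <- stat + contrib
    }
  }
  list(elec = elec, hp = hp, ev = ev, physics = elec + hp + ev,
       statistics = stat,
       total = (1 - ff$omega) * (elec + hp + ev) + ff$omega * stat)
}

# Brute-force native-contact extraction: double loop over all side-chain
# heavy atoms of a parsed PDB.
naive_contact_pairs <- function(pdb_path, chains_r, chains_l,
                                cutoff = 5.5) {
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", ]
  side <- function(chs) {
    a <- atoms[atoms$chain %in% chs, ]
    keep <- !(a$elety %in% c("N", "CA", "C", "O", "OXT")) |
      (a$resid == "GLY" & a$elety == "CA")
    a[keep, ]
  }
  ra <- side(chains_r); la <- side(chains_l)
  ra_res <- match(paste(ra$chain, ra$resno), unique(paste(ra$chain, ra$resno)))
  la_res <- match(paste(la$chain, la$resno), unique(paste(la$chain, la$resno)))
  hits <- list()
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                (ra$z[i] - la$z[j])^2)
      if (d <= cutoff)
        hits[[length(hits) + 1]] <- c(ra_res[i], la_res[j])
    }
  }
  if (length(hits) == 0) return(data.frame(ri = integer(0), li = integer(0)))
  df <- unique(as.data.frame(do.call(rbind, hits)))
  names(df) <- c("ri", "li")
  df[order(df$ri, df$li), ]
}

# Brute-force count of restored native contacts for given poses.
naive_restored <- function(receptor, ligand, poses, contacts, tol = 2,
                           box = NULL) {
  xyzA <- placed_xyz(receptor, poses$pose_r)
  xyzB <- placed_xyz(ligand, poses$pose_l)
  sa <- which(receptor$kind == "SC"); sb <- which(ligand$kind == "SC")
  n <- 0
  for (k in seq_len(nrow(contacts$pairs))) {
    r <- mi_dist(xyzA[sa[contacts$pairs$ri[k]], ],
                 xyzB[sb[contacts$pairs$li[k]], ], box)
    if (abs(r - contacts$pairs$r0[k]) < tol) n <- n + 1
  }
  n
}

# A small hand-written two-residue PDB (ALA at the origin, ASP ~10 A
# away) with full side-chain heavy atoms, plus a GLY tail.
write_two_residue_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1      -1.000   1.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       1.200   0.800   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       2.200   0.300   0.500  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      6  N   ASP A   2       9.000   1.000   0.000  1.00  0.00           N",
    "ATOM      7  CA  ASP A   2      10.000   0.000   0.000  1.00  0.00           C",
    "ATOM      8  C   ASP A   2      11.000   1.000   0.500  1.00  0.00           C",
    "ATOM      9  O   ASP A   2      12.000   0.800   1.200  1.00  0.00           O",
    "ATOM     10  CB  ASP A   2      11.000   0.000   0.000  1.00  0.00           C",
    "ATOM     11  CG  ASP A   2      12.000   0.500   0.000  1.00  0.00           C",
    "ATOM     12  OD1 ASP A   2      13.000   1.000   0.000  1.00  0.00           O",
    "ATOM     13  OD2 ASP A   2      12.000  -0.500   1.000  1.00  0.00           O",
    "ATOM     14  N   GLY A   3      15.000   1.000   0.000  1.00  0.00           N",
    "ATOM     15  CA  GLY A   3      16.000   0.000   0.000  1.00  0.00           C",
    "ATOM     16  C   GLY A   3      17.000   1.000   0.000  1.00  0.00           C",
    "ATOM     17  O   GLY A   3      18.000   0.800   0.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}

# Toy dimer with charged and hydrophobic residues on both chains, used
# where electrostatics must be exercised.
charged_dimer <- function(n_residues = 10, n_contacts = 5, seed = 7) {
  make_toy_dimer(
    n_residues = n_residues, n_contacts = n_contacts, seed = seed,
    restypes_receptor = c("ASP", "ILE", "LYS", "SER", "GLU"),
    restypes_ligand = c("ARG", "LEU", "ASP", "THR", "LYS"))
}

# The frozen funnel-study scenario shared by engine tests and the
# acceptance checks: a compact 8-residue / 4-contact dimer with a mildly
# sticky hydrophobic mid-range term and boosted rotational search.
funnel_scenario <- function(strength, n_steps, n_traj, base_seed,
                            terminate = TRUE) {
  td <- make_toy_dimer(n_residues = 8, n_contacts = 4, seed = 3)
  ff <- hybrid_forcefield(
    omega = 0.6,
    physics = physics_params(w_alpha = 0.2, hp_cutoff = 10),
    table = go_table(strength))
  dd <- list(receptor = diffusion_params(8, 0.3),
             ligand = diffusion_params(8, 0.3))
  cfg <- simulation_config(
    box_edge = 35, n_steps = n_steps, dt = 1, n_trajectories = n_traj,
    base_seed = base_seed, record_every = n_steps, record_rmsd = FALSE,
    diffusion = dd, terminate_on_association = terminate)
  list(td = td, ff = ff, cfg = cfg)
}

run_funnel <- function(strength, n_steps, n_traj, base_seed,
                       terminate = TRUE) {
  sc <- funnel_scenario(strength, n_steps, n_traj, base_seed, terminate)
  run_ensemble(sc$td$receptor, sc$td$ligand, sc$ff, sc$td$contacts, sc$cfg)
}
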