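#' @keywords internal
"_PACKAGE"

# The 20 standard residues, three-letter codes, fixed order used for all
# 20x20 tables.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# Kyte-Doolittle hydropathy scale, dimensionless, range [-4.5, 4.5].
KYTE_DOOLITTLE <- c(
  ALA =  1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS =  2.5,
  GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE =  4.5,
  LEU =  3.8, LYS = -3.9, MET =  1.9, PHE =  2.8, PRO = -1.6,
  SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL =  4.2)

# Formal side-chain charges (elementary charge units) placed at the
# side-chain functional center. HIS defaults to neutral; override via
# `charge_overrides` in load_coarse_protein().
RESIDUE_CHARGE <- c(
  ALA = 0, ARG = +1, ASN = 0, ASP = -1, CYS = 0,
  GLN = 0, GLU = -1, GLY = 0, HIS =  0, ILE = 0,
  LEU = 0, LYS = +1, MET = 0, PHE =  0, PRO = 0,
  SER = 0, THR =  0, TRP = 0, TYR =  0, VAL = 0)

# Aliases for common modified/alternative residue names. Unmappable
# non-standard residues are rejected at parse time.
RESIDUE_ALIAS <- c(
  MSE = "MET", SEC = "CYS", CSO = "CYS", SEP = "SER", TPO = "THR",
  PTR = "TYR", HSD = "HIS", HSE = "HIS", HSP = "HIS", HID = "HIS",
  HIE = "HIS", HIP = "HIS", MLY = "LYS", CME = "CYS", PCA = "GLU")

# Backbone heavy-atom names; everything else among heavy atoms belongs to
# the side chain for the purposes of the functional-center and the 5.5 A
# interface criterion.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Coulomb constant e^2/(4 pi eps0) expressed in kT(298.15 K) * Angstrom,
# so that E_elec = COULOMB_KT * q_i q_j / (D_eff * r) is in kT.
ELEMENTARY_CHARGE <- 1.602176634e-19   # C
VACUUM_PERMITTIVITY <- 8.8541878128e-12 # F/m
BOLTZMANN <- 1.380649e-23              # J/K
ROOM_T <- 298.15                       # K
COULOMB_KT <- ELEMENTARY_CHARGE^2 /
  (4 * pi * VACUUM_PERMITTIVITY) /
  (BOLTZMANN * ROOM_T) * 1e10          # kT * Angstrom

canonical_restype <- function(res) {
  res <- toupper(res)
  idx <- match(res, names(RESIDUE_ALIAS))
  res[!is.na(idx)] <- RESIDUE_ALIAS[idx[!is.na(idx)]]
  res
}
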