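# Synthetic fixtures: toy two-chain "mini-protein" dimers with a
# prescribed native contact map, written as valid PDB files, and synthetic
# contact libraries with known pair statistics. Everything is a pure
# function of its spec and seed, so tests and examples need no external
# structures.

#' Build a toy dimer with a prescribed native contact map
#'
#' Two straight virtual-Calpha chains (3.8 A spacing) face each other
#' across the interface. Alternating residues of each chain point their
#' side-chain site (written as a CB pseudo-atom) toward the partner; the
#' first `n_contacts` such residue pairs sit at `contact_distance` SC-SC
#' (default 4 A), all other inter-chain side-chain pairs are well beyond
#' the 5.5 A interface criterion, so the native contact map has exactly
#' `n_contacts` pairs by construction. A small seeded jitter on the
#' out-of-plane coordinate makes distinct seeds give distinct (but
#' deterministic) geometries. The emitted PDB re-parses through
#' [load_coarse_protein()] to the same sites.
#'
#' @param n_residues residues per chain (needs
#'   `ceiling(n_residues / 2) >= n_contacts`).
#' @param n_contacts native contacts to realize (0 allowed: the dimer is
#'   built but no contact map is extracted).
#' @param contact_distance native SC-SC distance (Angstrom), must lie in
#'   (2.2, 5.5) to be clash-free yet within the atom criterion.
#' @param restypes_receptor,restypes_ligand residue types per chain
#'   (recycled); defaults mix hydrophobic interface residues with polar
#'   ones elsewhere.
#' @param seed jitter seed.
#' @param path output PDB path (default: a tempfile).
#' @return list with `receptor`, `ligand` (`coarse_protein`s re-parsed
#'   from the file), `contacts` (`native_contact_map`, or NULL when
#'   `n_contacts = 0`), `pdb_path`, and the realized `spec`.
#' @export
make_toy_dimer <- function(n_residues = 12, n_contacts = 6,
                           contact_distance = 4.0,
                           restypes_receptor = NULL,
                           restypes_ligand = NULL,
                           seed = 1,
                           path = tempfile(fileext = ".pdb")) {
  if (ceiling(n_residues / 2) < n_contacts)
    stop("unrealizable spec: need ceiling(n_residues/2) >= n_contacts")
  if (contact_distance <= 2.2 || contact_distance >= 5.5)
    stop("unrealizable spec: contact_distance must be in (2.2, 5.5) A")
  if (is.null(restypes_receptor))
    restypes_receptor <- rep(c("ILE", "SER", "LEU", "THR", "VAL", "ASN"),
                             length.out = n_residues)
  if (is.null(restypes_ligand))
    restypes_ligand <- rep(c("LEU", "GLN", "PHE", "SER", "MET", "THR"),
                           length.out = n_residues)
  restypes_receptor <- rep(restypes_receptor, length.out = n_residues)
  restypes_ligand <- rep(restypes_ligand, length.out = n_residues)
  stopifnot(all(restypes_receptor %in% AA3), all(restypes_ligand %in% AA3))
  if (any(c(restypes_receptor, restypes_ligand) == "GLY"))
    stop("toy dimers do not support GLY (its SC proxy is the CA)")

  interface <- seq(1, n_residues, by = 2)[seq_len(min(n_contacts,
                                                      ceiling(n_residues / 2)))]
  D <- contact_distance + 3  # CA-plane separation; SC offset is 1.5 A
  set.seed(seed)
  jitter_a <- stats::rnorm(n_residues, sd = 0.05)
  jitter_b <- stats::rnorm(n_residues, sd = 0.05)

  build_chain <- function(y_ca, toward, jit) {
    ca <- cbind(3.8 * (seq_len(n_residues) - 1), y_ca, jit)
    off <- ifelse(seq_len(n_residues) %in% interface, toward, -toward)
    sc <- ca
    sc[, 2] <- sc[, 2] + off * 1.5
    list(ca = ca, sc = sc)
  }
  a <- build_chain(0, +1, jitter_a)
  b <- build_chain(D, -1, jitter_b)

  write_toy_pdb(path,
                list(list(chain = "A", restype = restypes_receptor,
                          ca = a$ca, sc = a$sc),
                     list(chain = "B", restype = restypes_ligand,
                          ca = b$ca, sc = b$sc)))

  receptor <- load_coarse_protein(path, "A")
  ligand <- load_coarse_protein(path, "B")
  contacts <- if (n_contacts > 0)
    native_contacts(receptor, ligand, path) else NULL
  if (!is.null(contacts) && contacts$n_native != n_contacts)
    stop("fixture construction failed: expected ", n_contacts,
         " contacts, got ", contacts$n_native)
  list(receptor = receptor, ligand = ligand, contacts = contacts,
       pdb_path = path,
       spec = list(n_residues = n_residues, n_contacts = n_contacts,
                   contact_distance = contact_distance, seed = seed))
}

# Write chains of CA + CB pseudo-atom residues as a PDB file.
write_toy_pdb <- function(path, chains) {
  xyz <- c(); elety <- c(); resid <- c(); chain <- c(); resno <- c()
  for (ch in chains) {
    n <- length(ch$restype)
    for (i in seq_len(n)) {
      xyz <- c(xyz, ch$ca[i, ], ch$sc[i, ])
      elety <- c(elety, "CA", "CB")
      resid <- c(resid, ch$restype[i], ch$restype[i])
      chain <- c(chain, ch$chain, ch$chain)
      resno <- c(resno, i, i)
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", length(elety)),
                   elety = elety, resid = resid, chain = chain,
                   resno = resno)
  invisible(path)
}

#' Sample a synthetic contact library with known pair statistics
#'
#' Draws residue-pair contacts from the quasi-chemical distribution
#' implied by a contact potential: `p(i, j) proportional to chi_i chi_j
#' exp(-u_sc(i, j))`, with `chi` the table's own self-consistent mole
#' fractions when it carries them (tables from [random_usc_table()] do),
#' else the supplied `chi_bg`, else uniform. A quasi-chemical table is
#' identifiable from pair statistics only up to an additive constant, so
#' the table that [derive_usc()] converges to on this library - the
#' quasi-chemical transform of the sampling distribution - is attached as
#' attribute `effective_usc`. For tables built by [random_usc_table()]
#' the effective table equals `true_usc` exactly; recovery RMSE then
#' measures pure sampling error.
#'
#' @param true_usc a `stat_potential_table`.
#' @param n_contacts total contacts to draw.
#' @param n_interfaces number of interfaces the contacts are split into
#'   (the library is a list of per-interface data.frames).
#' @param chi_bg optional background mole fractions (length 20, order of
#'   `AA3`), used when the table carries no `chi` attribute.
#' @param seed RNG seed.
#' @return list of data.frames with columns `res_i`, `res_j`; attributes
#'   `effective_usc` and `chi` (the asymptotic interface mole fractions).
#' @export
make_contact_library <- function(true_usc, n_contacts = 1e5,
                                 n_interfaces = 100, chi_bg = NULL,
                                 seed = 1) {
  stopifnot(inherits(true_usc, "stat_potential_table"),
            n_contacts >= 1, n_interfaces >= 1)
  chi0 <- attr(true_usc, "chi")
  if (is.null(chi0)) {
    chi0 <- if (is.null(chi_bg)) rep(1 / 20, 20) else chi_bg
  }
  stopifnot(length(chi0) == 20, all(chi0 > 0))
  chi0 <- chi0 / sum(chi0)
  p <- outer(chi0, chi0) * exp(-true_usc$u)
  p <- p / sum(p)
  eff <- qc_transform(p, provenance = "effective table of sampled library")
  chi <- attr(eff, "chi")
  set.seed(seed)
  draw <- sample.int(400L, n_contacts, replace = TRUE, prob = as.numeric(p))
  ri <- AA3[((draw - 1L) %% 20L) + 1L]
  rj <- AA3[((draw - 1L) %/% 20L) + 1L]
  iface <- rep(seq_len(n_interfaces), length.out = n_contacts)
  df <- data.frame(res_i = ri, res_j = rj)
  lib <- split(df, iface)
  names(lib) <- NULL
  attr(lib, "effective_usc") <- eff
  attr(lib, "chi") <- chi
  lib
}

#' Random gauge-consistent contact potential table
#'
#' Builds a synthetic ground-truth table directly from an explicit pair
#' distribution: a random symmetric Boltzmann weight matrix is normalized
#' to a distribution `p`, and the table is its quasi-chemical transform
#' `u = -ln(p / (q_i q_j))` with `q` the marginals of `p`. By
#' construction the table is exactly recoverable by [derive_usc()] (its
#' gauge shift is zero), making it suitable ground truth for
#' parameter-recovery studies. Entry magnitudes are of order `scale`.
#'
#' @param scale width (kT) of the random weights behind the table.
#' @param seed RNG seed.
#' @return A `stat_potential_table` with attribute `chi` (its
#'   self-consistent mole fractions).
#' @export
random_usc_table <- function(scale = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(stats::runif(400, -scale, scale), 20, 20)
  w <- (w + t(w)) / 2
  p <- exp(-w)
  p <- p / sum(p)
  qc_transform(p, provenance = sprintf(
    "random synthetic table, scale %.2f kT, seed %d", scale, seed))
}
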