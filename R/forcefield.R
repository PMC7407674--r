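# Hybrid intermolecular force field: physics-based terms (Kim-Hummer
# screened electrostatics, Kyte-Doolittle hydrophobic term, 12-6 excluded
# volume) mixed with a Go-like statistical contact potential,
#   E_tot = (1 - omega) * E_physics + omega * E_statistics.
# All energies are in kT, lengths in Angstrom; the Metropolis temperature
# is therefore 1.

#' Physics-based potential parameters
#'
#' @param D_s solvent dielectric constant (dimensionless).
#' @param xi Debye screening length (Angstrom). See [debye_length()].
#' @param w_alpha weight of the hydrophobic term (kT per unit
#'   Kyte-Doolittle score). The tuned value is benchmark-dependent; it is a
#'   free parameter here.
#' @param epsilon_rep excluded-volume step depth (kT): the 12-6 prefactor
#'   is `epsilon_rep` for pairs closer than their `sigma0`, else 0.
#' @param sigma0 named vector of contact radii by site-kind pair:
#'   `CA-CA` 3.8, `CA-SC` 2.8, `SC-SC` 2.2 (Angstrom).
#' @param hp_cutoff SC-SC distance (Angstrom) within which a residue pair
#'   contributes to the hydrophobic term.
#' @param hp_sign -1 (default) makes hydrophobic-hydrophobic burial
#'   favorable; +1 gives the sign-verbatim form.
#' @param elec_cutoff electrostatic truncation distance (Angstrom).
#' @return Object of class `physics_params`.
#' @export
physics_params <- function(D_s = 80, xi = 10, w_alpha = 0.1,
                           epsilon_rep = 5,
                           sigma0 = c("CA-CA" = 3.8, "CA-SC" = 2.8,
                                      "SC-SC" = 2.2),
                           hp_cutoff = 7.5, hp_sign = -1,
                           elec_cutoff = 30) {
  stopifnot(D_s > 0, xi > 0, epsilon_rep >= 0, all(sigma0 > 0),
            hp_cutoff > 0, elec_cutoff > 0, hp_sign %in% c(-1, 1))
  stopifnot(all(c("CA-CA", "CA-SC", "SC-SC") %in% names(sigma0)))
  structure(list(D_s = D_s, xi = xi, w_alpha = w_alpha,
                 epsilon_rep = epsilon_rep, sigma0 = sigma0,
                 hp_cutoff = hp_cutoff, hp_sign = hp_sign,
                 elec_cutoff = elec_cutoff),
            class = "physics_params")
}

#' Debye length from ionic strength
#'
#' `xi = 3.04 / sqrt(I)` Angstrom for ionic strength `I` in mol/L (water,
#' room temperature).
#'
#' @param ionic_strength mol/L.
#' @return Debye length in Angstrom.
#' @export
debye_length <- function(ionic_strength) {
  stopifnot(ionic_strength > 0)
  3.04 / sqrt(ionic_strength)
}

#' Hybrid force field
#'
#' @param omega weight of the statistical potential, in `[0, 1]`; 0 is
#'   purely physics-based, 1 purely statistical.
#' @param physics a [physics_params()] object.
#' @param table a `stat_potential_table` (see [derive_usc()],
#'   [read_usc_table()]), or NULL when `omega = 0`.
#' @param stat_mode functional form of the statistical term; see
#'   [statistical_energy()]. `"go"` (default) is a proper Go contact well
#'   with its minimum `-|u_sc|` at the native distance; `"scaled"` and
#'   `"literal"` follow the sign-function form, which has no repulsive
#'   wall for attractive pairs.
#' @return Object of class `hybrid_forcefield`.
#' @export
hybrid_forcefield <- function(omega = 0.6, physics = physics_params(),
                              table = NULL,
                              stat_mode = c("go", "scaled", "literal")) {
  stat_mode <- match.arg(stat_mode)
  stopifnot(omega >= 0, omega <= 1, inherits(physics, "physics_params"))
  if (omega > 0 && is.null(table))
    stop("omega > 0 requires a statistical potential table")
  if (!is.null(table)) stopifnot(inherits(table, "stat_potential_table"))
  structure(list(omega = omega, physics = physics, table = table,
                 stat_mode = stat_mode),
            class = "hybrid_forcefield")
}

#' Sites of a coarse protein at a pose
#'
#' Bundles the coordinates of a protein at a given rigid-body pose with
#' the per-site metadata (kind, charge, hydropathy, residue type) that the
#' energy functions consume. Energy functions also accept a
#' `coarse_protein` directly, in which case its stored pose is used.
#'
#' @param protein a `coarse_protein`.
#' @param pose a [cg_pose()]; defaults to the protein's stored pose.
#' @return list with `xyz`, `kind`, `charge`, `hp`, `restype`,
#'   `res_ordinal`.
#' @export
placed_sites <- function(protein, pose = protein$pose) {
  list(xyz = placed_xyz(protein, pose),
       kind = protein$kind,
       charge = protein$charge,
       hp = protein$hp,
       restype = protein$restype,
       res_ordinal = protein$res_ordinal)
}

#' Screened electrostatic energy (Kim-Hummer form)
#'
#' Sum over inter-protein charged SC site pairs of
#' `q_i q_j / (4 pi eps0 D_eff r)` with the distance-dependent dielectric
#' `D_eff = D_s * exp(r / xi)`, in kT. Pairs beyond `elec_cutoff`
#' contribute zero; distances use the minimum image when `box` is given.
#'
#' @param sites_A,sites_B placed site lists (see internals) or
#'   `coarse_protein` objects at their current poses.
#' @param params a [physics_params()].
#' @param box cubic box edge (Angstrom) or NULL for open boundaries.
#' @return energy in kT.
#' @export
electrostatic_energy <- function(sites_A, sites_B, params, box = NULL) {
  A <- as_placed(sites_A); B <- as_placed(sites_B)
  ia <- which(A$kind == "SC" & A$charge != 0)
  ib <- which(B$kind == "SC" & B$charge != 0)
  if (length(ia) == 0 || length(ib) == 0) return(0)
  d2 <- pair_dist_sq(A$xyz[ia, , drop = FALSE], B$xyz[ib, , drop = FALSE], box)
  if (any(d2 == 0)) stop("overlapping charged sites (r = 0)")
  r <- sqrt(d2)
  qq <- outer(A$charge[ia], B$charge[ib])
  e <- COULOMB_KT * qq / (params$D_s * exp(r / params$xi) * r)
  sum(e[r <= params$elec_cutoff])
}

#' Hydrophobic contact energy
#'
#' `hp_sign * w_alpha * sum(HP_i + HP_j)` over inter-protein SC-SC pairs
#' within `hp_cutoff`; with the default `hp_sign = -1`, burying
#' hydrophobic (positive-score) residues lowers the energy.
#'
#' @inheritParams electrostatic_energy
#' @return energy in kT.
#' @export
hydrophobic_energy <- function(sites_A, sites_B, params, box = NULL) {
  A <- as_placed(sites_A); B <- as_placed(sites_B)
  ia <- which(A$kind == "SC"); ib <- which(B$kind == "SC")
  d2 <- pair_dist_sq(A$xyz[ia, , drop = FALSE], B$xyz[ib, , drop = FALSE], box)
  within <- d2 <= params$hp_cutoff^2
  if (!any(within)) return(0)
  hsum <- outer(A$hp[ia], B$hp[ib], "+")
  params$hp_sign * params$w_alpha * sum(hsum[within])
}

#' Excluded-volume energy
#'
#' 12-6 form `eps_ij * ((sigma0/r)^12 - (sigma0/r)^6)` summed over all
#' inter-protein site pairs, where `eps_ij` is a step function: 0 when
#' `r > sigma0` for that site-kind pair, `epsilon_rep` (default 5 kT)
#' otherwise. `sigma0` is 3.8 A for CA-CA, 2.8 A for CA-SC and 2.2 A for
#' SC-SC.
#'
#' @inheritParams electrostatic_energy
#' @return energy in kT (non-negative).
#' @export
excluded_volume_energy <- function(sites_A, sites_B, params, box = NULL) {
  A <- as_placed(sites_A); B <- as_placed(sites_B)
  d2 <- pair_dist_sq(A$xyz, B$xyz, box)
  s0 <- sigma0_matrix(A$kind, B$kind, params$sigma0)
  inside <- d2 < s0^2
  if (!any(inside)) return(0)
  sr2 <- (s0[inside]^2) / d2[inside]
  sr6 <- sr2^3
  params$epsilon_rep * sum(sr6 * sr6 - sr6)
}

# sigma0 lookup matrix for all site-kind pairs of A (rows) vs B (cols).
sigma0_matrix <- function(kind_A, kind_B, sigma0) {
  key <- outer(kind_A, kind_B, function(a, b)
    ifelse(a == b, paste(a, b, sep = "-"),
           "CA-SC"))
  m <- matrix(sigma0[key], nrow = length(kind_A))
  m
}

#' Go-like statistical potential energy
#'
#' Sum over the native interface residue pairs of a 12-6 term in
#' `x = r0 / r`, where `u = u_sc(i, j)` is the quasi-chemical contact
#' potential of the pair's residue types, `r0` the native SC-SC distance
#' and `r` the current (minimum-image) SC-SC distance. Three functional
#' forms are available; in all of them a pair with `u = 0` contributes
#' nothing and the contribution vanishes as `r -> Inf`:
#'
#' * `"go"` (default): attractive pairs (`u < 0`) get the standard Go
#'   contact well `|u| (x^12 - 2 x^6)`, whose minimum `-|u|` lies exactly
#'   at the native distance and whose `x^12` wall prevents the pair from
#'   collapsing below it; repulsive pairs (`u > 0`) get `|u| x^6`.
#' * `"scaled"`: `|u| (g(u) x^12 - f(u) x^6)` with the sign functions
#'   `f(u) = 1` for `u < 0`, `-1` for `u > 0`; `g(u) = -1` for `u < 0`,
#'   `0` for `u > 0`. For attractive pairs this is attractive at every
#'   distance (no repulsive wall).
#' * `"literal"`: the same sign-function bracket with unit prefactors,
#'   `g(u) x^12 - f(u) x^6` (equals -2 at `r = r0` for attractive pairs).
#'
#' @param sites_A,sites_B receptor and ligand placed sites (receptor first:
#'   contact map rows index A, columns B).
#' @param contacts a `native_contact_map` from [native_contacts()].
#' @param table a `stat_potential_table`.
#' @param stat_mode `"go"`, `"scaled"` or `"literal"`.
#' @param box cubic box edge (Angstrom) or NULL.
#' @return energy in kT.
#' @export
statistical_energy <- function(sites_A, sites_B, contacts, table,
                               stat_mode = c("go", "scaled", "literal"),
                               box = NULL) {
  stat_mode <- match.arg(stat_mode)
  A <- as_placed(sites_A); B <- as_placed(sites_B)
  p <- contacts$pairs
  sa <- which(A$kind == "SC"); sb <- which(B$kind == "SC")
  ra <- A$xyz[sa[p$ri], , drop = FALSE]
  rb <- B$xyz[sb[p$li], , drop = FALSE]
  r <- row_dist(ra, rb, box)
  if (any(r == 0)) stop("zero SC-SC distance in statistical term")
  ti <- A$restype[sa[p$ri]]; tj <- B$restype[sb[p$li]]
  if (any(!(ti %in% rownames(table$u)) | !(tj %in% rownames(table$u))))
    stop("residue type missing from statistical potential table")
  u <- table$u[cbind(ti, tj)]
  co <- stat_coefficients(u, stat_mode)
  x6 <- (p$r0 / r)^6
  sum(co$cg * x6 * x6 - co$cf * x6)
}

# 12-6 bracket coefficients (cg * x^12 - cf * x^6) per pair for each
# statistical-term mode; shared by the reference path and the simulation
# hot loop.
stat_coefficients <- function(u, stat_mode) {
  f <- ifelse(u < 0, 1, ifelse(u > 0, -1, 0))
  g <- ifelse(u < 0, -1, 0)
  switch(stat_mode,
    go = list(cg = ifelse(u < 0, abs(u), 0),
              cf = ifelse(u < 0, 2 * abs(u), ifelse(u > 0, -u, 0))),
    scaled = list(cg = abs(u) * g, cf = abs(u) * f),
    literal = list(cg = g, cf = f),
    stop("unknown stat_mode: ", stat_mode))
}

#' Total hybrid energy and its components
#'
#' `E_tot = (1 - omega) * E_physics + omega * E_statistics`, with
#' `E_physics` the sum of the electrostatic, hydrophobic and
#' excluded-volume terms.
#'
#' @param sites_A,sites_B receptor and ligand placed sites or
#'   `coarse_protein` objects.
#' @param ff a [hybrid_forcefield()].
#' @param contacts a `native_contact_map` (required when `omega > 0`).
#' @param box cubic box edge (Angstrom) or NULL.
#' @return `total_energy()` returns the scalar total (kT);
#'   `energy_components()` returns a named list with `elec`, `hp`, `ev`,
#'   `physics`, `statistics`, `total`.
#' @export
total_energy <- function(sites_A, sites_B, ff, contacts = NULL, box = NULL) {
  energy_components(sites_A, sites_B, ff, contacts, box)$total
}

#' @rdname total_energy
#' @export
energy_components <- function(sites_A, sites_B, ff, contacts = NULL,
                              box = NULL) {
  A <- as_placed(sites_A); B <- as_placed(sites_B)
  el <- electrostatic_energy(A, B, ff$physics, box)
  hp <- hydrophobic_energy(A, B, ff$physics, box)
  ev <- excluded_volume_energy(A, B, ff$physics, box)
  phys <- el + hp + ev
  stat <- 0
  if (!is.null(ff$table) && !is.null(contacts))
    stat <- statistical_energy(A, B, contacts, ff$table, ff$stat_mode, box)
  else if (ff$omega > 0)
    stop("omega > 0 requires a statistical table and a native contact map")
  list(elec = el, hp = hp, ev = ev, physics = phys, statistics = stat,
       total = (1 - ff$omega) * phys + ff$omega * stat)
}

as_placed <- function(x) {
  if (inherits(x, "coarse_protein")) placed_sites(x) else x
}

# Precomputed evaluation context for the simulation hot loop. All
# pair-level constants (sigma0^2 per site pair, charge products,
# hydropathy sums, statistical-pair coefficients and native distances,
# and the linear indices of each interaction's pairs within the full
# inter-protein distance matrix) are computed once per
# (receptor, ligand, ff, contacts, box); the returned closures evaluate
# the energy and the restored-contact count from bare coordinate
# matrices. Must agree with the public energy functions to numerical
# identity (asserted in the test suite).
make_energy_context <- function(receptor, ligand, ff, contacts = NULL,
                                box = NULL) {
  p <- ff$physics
  nA <- nrow(receptor$xyz); nB <- nrow(ligand$xyz)
  S0sq <- sigma0_matrix(receptor$kind, ligand$kind, p$sigma0)^2
  eps <- p$epsilon_rep

  sa <- sc_indices(receptor); sb <- sc_indices(ligand)
  lin_sc <- as.vector(outer(sa, (sb - 1L) * nA, "+"))
  hpsum <- as.vector(outer(receptor$hp[sa], ligand$hp[sb], "+"))
  hp_cut2 <- p$hp_cutoff^2
  hp_w <- p$hp_sign * p$w_alpha

  ia <- which(receptor$kind == "SC" & receptor$charge != 0)
  ib <- which(ligand$kind == "SC" & ligand$charge != 0)
  lin_q <- if (length(ia) && length(ib))
    as.vector(outer(ia, (ib - 1L) * nA, "+")) else integer(0)
  qq <- if (length(lin_q))
    as.vector(outer(receptor$charge[ia], ligand$charge[ib])) else numeric(0)

  has_contacts <- !is.null(contacts) && nrow(contacts$pairs) > 0
  has_stat <- has_contacts && !is.null(ff$table)
  if (ff$omega > 0 && !has_stat)
    stop("omega > 0 requires a statistical table and a native contact map")
  if (has_contacts) {
    pr <- contacts$pairs
    iA <- sa[pr$ri]; iB <- sb[pr$li]
    r0 <- pr$r0
  } else {
    iA <- iB <- integer(0); r0 <- numeric(0)
  }
  if (has_stat) {
    lin_stat <- (iB - 1L) * nA + iA
    u <- ff$table$u[cbind(receptor$restype[iA], ligand$restype[iB])]
    co <- stat_coefficients(u, ff$stat_mode)
    cg <- co$cg; cf <- co$cf
    r0sq <- r0^2
  } else {
    lin_stat <- integer(0); cg <- cf <- r0sq <- numeric(0)
  }
  omega <- ff$omega

  energy <- function(xyzA, xyzB) {
    d2 <- pair_dist_sq(xyzA, xyzB, box)
    ev <- 0
    ins <- which(d2 < S0sq)
    if (length(ins)) {
      sr6 <- (S0sq[ins] / d2[ins])^3
      ev <- eps * sum(sr6 * sr6 - sr6)
    }
    d2sc <- d2[lin_sc]
    w <- d2sc <= hp_cut2
    hp <- if (any(w)) hp_w * sum(hpsum[w]) else 0
    el <- 0
    if (length(lin_q)) {
      r <- sqrt(d2[lin_q])
      keep <- r <= p$elec_cutoff
      if (any(keep))
        el <- COULOMB_KT *
          sum(qq[keep] / (p$D_s * exp(r[keep] / p$xi) * r[keep]))
    }
    phys <- el + hp + ev
    st <- 0
    if (length(lin_stat)) {
      x6 <- (r0sq / d2[lin_stat])^3
      st <- sum(cg * x6 * x6 - cf * x6)
    }
    list(physics = phys, statistics = st,
         total = (1 - omega) * phys + omega * st)
  }

  n_restored <- function(xyzA, xyzB, tolerance) {
    if (length(iA) == 0) return(0L)
    dx <- xyzA[iA, 1] - xyzB[iB, 1]
    dy <- xyzA[iA, 2] - xyzB[iB, 2]
    dz <- xyzA[iA, 3] - xyzB[iB, 3]
    if (!is.null(box)) {
      dx <- dx - box * round(dx / box)
      dy <- dy - box * round(dy / box)
      dz <- dz - box * round(dz / box)
    }
    sum(abs(sqrt(dx * dx + dy * dy + dz * dz) - r0) < tolerance)
  }

  list(energy = energy, n_restored = n_restored,
       n_native = length(iA))
}
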