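# Hybrid force field: screened electrostatics, hydrophobic term, excluded
# volume, Go-like statistical term, and the omega mixing.

# minimal placed-site list with a single SC site
one_sc <- function(pos, charge = 0, hp = 0, restype = "ALA") {
  list(xyz = matrix(pos, 1, 3), kind = "SC", charge = charge, hp = hp,
       restype = restype, res_ordinal = 1L)
}

test_that("screened electrostatics matches the closed form and its limits", {
  p <- physics_params(D_s = 80, xi = 10)
  a <- one_sc(c(0, 0, 0), charge = 1)
  b <- one_sc(c(5, 0, 0), charge = 1)
  # independent scalar evaluation of q^2 e^2/(4 pi eps0) / (D_s e^(r/xi) r)
  coul_kT <- (1.602176634e-19^2 / (4 * pi * 8.8541878128e-12)) /
    (1.380649e-23 * 298.15) * 1e10
  expect_equal(electrostatic_energy(a, b, p),
               coul_kT / (80 * exp(0.5) * 5), tolerance = 1e-12)

  # zero charge contributes nothing
  expect_equal(electrostatic_energy(one_sc(c(0, 0, 0)), b, p), 0)

  # opposite charges: strictly negative, magnitude decreasing with r
  b2 <- one_sc(c(5, 0, 0), charge = -1)
  e5 <- electrostatic_energy(a, b2, p)
  e8 <- electrostatic_energy(a, one_sc(c(8, 0, 0), charge = -1), p)
  expect_lt(e5, 0)
  expect_lt(abs(e8), abs(e5))

  # beyond the cutoff the pair contributes nothing
  far <- one_sc(c(p$elec_cutoff + 1, 0, 0), charge = -1)
  expect_equal(electrostatic_energy(a, far, p), 0)

  # xi -> Inf recovers the unscreened Coulomb limit
  p_inf <- physics_params(D_s = 80, xi = 1e12)
  expect_equal(electrostatic_energy(a, b, p_inf), coul_kT / (80 * 5),
               tolerance = 1e-9)

  # overlapping charges are fatal
  expect_error(electrostatic_energy(a, one_sc(c(0, 0, 0), charge = 1), p),
               "overlapping")
})

test_that("hydrophobic term sums Kyte-Doolittle scores within the cutoff", {
  p <- physics_params(w_alpha = 0.25)
  ile_a <- one_sc(c(0, 0, 0), hp = 4.5, restype = "ILE")
  ile_b <- one_sc(c(4, 0, 0), hp = 4.5, restype = "ILE")
  # ILE-ILE in contact: -w_alpha * (4.5 + 4.5)
  expect_equal(hydrophobic_energy(ile_a, ile_b, p), -0.25 * 9)
  # linear in w_alpha
  p2 <- physics_params(w_alpha = 0.5)
  expect_equal(hydrophobic_energy(ile_a, ile_b, p2),
               2 * hydrophobic_energy(ile_a, ile_b, p))
  # beyond hp_cutoff: zero
  far <- one_sc(c(p$hp_cutoff + 0.1, 0, 0), hp = 4.5)
  expect_equal(hydrophobic_energy(ile_a, far, p), 0)
  # verbatim sign option flips the term
  p3 <- physics_params(w_alpha = 0.25, hp_sign = 1)
  expect_equal(hydrophobic_energy(ile_a, ile_b, p3), 0.25 * 9)
})

test_that("excluded volume is the stepped 12-6 with kind-dependent sigma0", {
  p <- physics_params()
  ca <- function(pos) list(xyz = matrix(pos, 1, 3), kind = "CA", charge = 0,
                           hp = 0, restype = "GLY", res_ordinal = 1L)
  # CA-CA at 4.0 A (> 3.8): zero
  expect_equal(excluded_volume_energy(ca(c(0, 0, 0)), ca(c(4, 0, 0)), p), 0)
  # exactly at sigma0 the bracket vanishes
  expect_equal(excluded_volume_energy(ca(c(0, 0, 0)), ca(c(3.8, 0, 0)), p), 0)
  # CA-CA at 3.8 / 2^(1/6): 5 * (4 - 2) = 10 kT
  r <- 3.8 / 2^(1 / 6)
  expect_equal(excluded_volume_energy(ca(c(0, 0, 0)), ca(c(r, 0, 0)), p), 10,
               tolerance = 1e-12)
  # SC-SC pair switches at 2.2 A
  s1 <- one_sc(c(0, 0, 0)); s2 <- one_sc(c(2.3, 0, 0))
  expect_equal(excluded_volume_energy(s1, s2, p), 0)
  s3 <- one_sc(c(2.0, 0, 0))
  expect_gt(excluded_volume_energy(s1, s3, p), 0)
})

test_that("statistical term honors its three functional forms", {
  td <- make_toy_dimer(n_residues = 6, n_contacts = 3, seed = 4)
  poses_native <- list(pose_r = td$receptor$pose, pose_l = td$ligand$pose)
  A <- cgassoc:::placed_sites(td$receptor)
  B <- cgassoc:::placed_sites(td$ligand)

  # u = 0 everywhere: no contribution in any mode
  zero <- stat_potential_table(matrix(0, 20, 20,
                                      dimnames = list(AA3, AA3)))
  for (m in c("go", "scaled", "literal"))
    expect_equal(statistical_energy(A, B, td$contacts, zero, m), 0)

  # literal mode at the native distance: -2 per attractive pair
  tab <- go_table(3)
  expect_equal(statistical_energy(A, B, td$contacts, tab, "literal"),
               -2 * td$contacts$n_native, tolerance = 1e-6)
  # scaled mode multiplies by |u|
  expect_equal(statistical_energy(A, B, td$contacts, tab, "scaled"),
               -2 * 3 * td$contacts$n_native, tolerance = 1e-6)
  # go mode: the well minimum -|u| sits at the native distance
  expect_equal(statistical_energy(A, B, td$contacts, tab, "go"),
               -3 * td$contacts$n_native, tolerance = 1e-6)

  # far apart every mode vanishes
  pl <- td$ligand$pose; pl$t <- pl$t + c(0, 500, 0)
  Bfar <- cgassoc:::placed_sites(td$ligand, pl)
  for (m in c("go", "scaled", "literal"))
    expect_lt(abs(statistical_energy(A, Bfar, td$contacts, tab, m)), 1e-10)

  # go mode is repulsive below the native distance (unlike scaled)
  pl2 <- td$ligand$pose; pl2$t <- pl2$t - c(0, 2.2, 0)  # SC-SC ~ 1.8 A
  Bnear <- cgassoc:::placed_sites(td$ligand, pl2)
  expect_gt(statistical_energy(A, Bnear, td$contacts, tab, "go"), 0)
  expect_lt(statistical_energy(A, Bnear, td$contacts, tab, "scaled"), 0)
})

test_that("total energy is the omega mixture of its components", {
  td <- charged_dimer()
  tab <- random_usc_table(scale = 0.8, seed = 9)
  set.seed(31)
  pose_r <- cg_pose(random_rotation(), runif(3, 0, 60))
  pose_l <- cg_pose(random_rotation(), runif(3, 0, 60))
  A <- cgassoc:::placed_sites(td$receptor, pose_r)
  B <- cgassoc:::placed_sites(td$ligand, pose_l)

  ff0 <- hybrid_forcefield(omega = 0, physics = physics_params())
  e0 <- energy_components(A, B, ff0, td$contacts, box = 100)
  expect_equal(e0$total, e0$physics)

  ff1 <- hybrid_forcefield(omega = 1, table = tab)
  e1 <- energy_components(A, B, ff1, td$contacts, box = 100)
  expect_equal(e1$total, e1$statistics)

  ff6 <- hybrid_forcefield(omega = 0.6, table = tab)
  e6 <- energy_components(A, B, ff6, td$contacts, box = 100)
  expect_equal(e6$total, 0.4 * e6$physics + 0.6 * e6$statistics,
               tolerance = 1e-12)
})

test_that("every energy term equals the naive double-loop oracle", {
  td <- charged_dimer(n_residues = 20, n_contacts = 8, seed = 13)
  tab <- random_usc_table(scale = 0.8, seed = 5)
  set.seed(99)
  for (mode in c("go", "scaled", "literal")) {
    ff <- hybrid_forcefield(omega = 0.6, table = tab, stat_mode = mode,
                            physics = physics_params(w_alpha = 0.3))
    for (k in 1:3) {
      poses <- list(pose_r = cg_pose(random_rotation(), runif(3, 0, 80)),
                    pose_l = cg_pose(random_rotation(), runif(3, 0, 80)))
      A <- cgassoc:::placed_sites(td$receptor, poses$pose_r)
      B <- cgassoc:::placed_sites(td$ligand, poses$pose_l)
      want <- naive_energies(td$receptor, td$ligand, poses, ff,
                             td$contacts, box = 80)
      expect_equal(electrostatic_energy(A, B, ff$physics, box = 80),
                   want$elec, tolerance = 1e-9)
      expect_equal(hydrophobic_energy(A, B, ff$physics, box = 80),
                   want$hp, tolerance = 1e-9)
      expect_equal(excluded_volume_energy(A, B, ff$physics, box = 80),
                   want$ev, tolerance = 1e-9)
      expect_equal(statistical_energy(A, B, td$contacts, tab, mode,
                                      box = 80),
                   want$statistics, tolerance = 1e-9)
      # and the precomputed hot-loop context agrees exactly
      ctx <- cgassoc:::make_energy_context(td$receptor, td$ligand, ff,
                                           td$contacts, box = 80)
      got <- ctx$energy(A$xyz, B$xyz)
      expect_equal(got$total, want$total, tolerance = 1e-9)
      expect_equal(got$physics, want$physics, tolerance = 1e-9)
      expect_equal(got$statistics, want$statistics, tolerance = 1e-9)
    }
  }
})

test_that("physics terms are symmetric under exchanging the proteins", {
  td <- charged_dimer()
  set.seed(55)
  p <- physics_params(w_alpha = 0.3)
  for (k in 1:3) {
    pa <- cg_pose(random_rotation(), runif(3, 0, 50))
    pb <- cg_pose(random_rotation(), runif(3, 0, 50))
    A <- cgassoc:::placed_sites(td$receptor, pa)
    B <- cgassoc:::placed_sites(td$ligand, pb)
    expect_equal(electrostatic_energy(A, B, p, box = 60),
                 electrostatic_energy(B, A, p, box = 60), tolerance = 1e-12)
    expect_equal(hydrophobic_energy(A, B, p, box = 60),
                 hydrophobic_energy(B, A, p, box = 60), tolerance = 1e-12)
    expect_equal(excluded_volume_energy(A, B, p, box = 60),
                 excluded_volume_energy(B, A, p, box = 60),
                 tolerance = 1e-12)
  }
})

test_that("force-field constructors validate their inputs", {
  expect_error(physics_params(D_s = -1))
  expect_error(physics_params(xi = 0))
  expect_error(hybrid_forcefield(omega = 1.2))
  expect_error(hybrid_forcefield(omega = 0.5, table = NULL), "table")
  expect_equal(debye_length(0.1), 3.04 / sqrt(0.1))
  expect_error(debye_length(0))
})
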