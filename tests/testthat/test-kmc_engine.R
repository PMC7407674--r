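# Kinetic Monte Carlo engine: initialization, diffusion moves, Metropolis
# acceptance, encounter detection, trajectory and ensemble behavior.

test_that("random initial placements are uniform, clash-free and seeded", {
  td <- make_toy_dimer(n_residues = 4, n_contacts = 2, seed = 8)
  cfg <- simulation_config(box_edge = 80, n_steps = 1, n_trajectories = 1)
  set.seed(123)
  n <- 4000
  xs <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    poses <- random_initial_configuration(td$receptor, td$ligand, cfg)
    xs[k, ] <- poses$pose_r$t
  }
  # per-axis Kolmogorov-Smirnov against Uniform(0, box)
  for (ax in 1:3)
    expect_gt(suppressWarnings(
      ks.test(xs[, ax], "punif", 0, 80)$p.value), 0.001)

  # clash-free postcondition against the kind-dependent contact radii
  sig <- physics_params()$sigma0
  set.seed(7)
  for (k in 1:20) {
    poses <- random_initial_configuration(td$receptor, td$ligand, cfg)
    a <- placed_xyz(td$receptor, poses$pose_r)
    b <- placed_xyz(td$ligand, poses$pose_l)
    d2 <- cgassoc:::pair_dist_sq(a, b, 80)
    s0 <- cgassoc:::sigma0_matrix(td$receptor$kind, td$ligand$kind, sig)
    expect_true(all(d2 >= s0^2))
  }

  # determinism: same seed, same placement; different seed differs
  set.seed(55); p1 <- random_initial_configuration(td$receptor, td$ligand, cfg)
  set.seed(55); p2 <- random_initial_configuration(td$receptor, td$ligand, cfg)
  set.seed(56); p3 <- random_initial_configuration(td$receptor, td$ligand, cfg)
  expect_identical(p1, p2)
  expect_false(identical(p1$pose_r$t, p3$pose_r$t))
})

test_that("an over-packed box is rejected after the attempt budget", {
  td <- make_toy_dimer(n_residues = 12, n_contacts = 6, seed = 8)
  cfg <- simulation_config(box_edge = 6, n_steps = 1, n_trajectories = 1,
                           max_init_attempts = 25)
  set.seed(1)
  expect_error(random_initial_configuration(td$receptor, td$ligand, cfg),
               "clash")
})

test_that("diffusion moves have the prescribed variance and keep rigidity", {
  td <- make_toy_dimer(n_residues = 4, n_contacts = 2, seed = 8)
  D <- diffusion_params(D_trans = 10, D_rot = 0.05)
  dd <- list(receptor = D, ligand = D)
  pose0 <- cg_pose(diag(3), c(0, 0, 0))
  big_box <- 1e9  # effectively unwrapped
  # zero diffusion leaves the configuration untouched
  dz <- list(receptor = diffusion_params(0, 0), ligand = diffusion_params(0, 0))
  set.seed(3)
  moved <- diffusion_move(list(pose_r = pose0, pose_l = pose0), dz, 1, big_box)
  expect_equal(moved$pose_r$t, pose0$t)
  expect_equal(moved$pose_r$R, pose0$R)

  # empirical per-axis displacement variance = 2 * D_trans * dt within 3%
  set.seed(11)
  n <- 1e5
  dt <- 0.5
  center <- cg_pose(diag(3), rep(big_box / 2, 3))  # far from the wrap seam
  disp <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    m <- cgassoc:::move_pose(center, D, dt, big_box)
    disp[k, ] <- m$t - center$t
  }
  v <- apply(disp, 2, var)
  expect_true(all(abs(v / (2 * D$D_trans * dt) - 1) < 0.03))
  expect_lt(abs(mean(disp)), 0.05)

  # rigid body: intra-protein distances unchanged by any move
  ref <- as.matrix(dist(td$receptor$xyz))
  set.seed(4)
  poses <- list(pose_r = cg_pose(random_rotation(), c(10, 10, 10)),
                pose_l = cg_pose(random_rotation(), c(30, 30, 30)))
  for (k in 1:10) {
    poses <- diffusion_move(poses, dd, 1, 100)
    cur <- as.matrix(dist(placed_xyz(td$receptor, poses$pose_r)))
    expect_lt(max(abs(cur - ref)), 1e-9)
  }
  # and centers stay inside the periodic box
  expect_true(all(poses$pose_r$t >= 0 & poses$pose_r$t < 100))
})

test_that("Metropolis acceptance has the exact downhill and e^-dE behavior", {
  set.seed(21)
  # downhill or flat: always accepted
  expect_true(all(metropolis_accept(rep(5, 100), rep(5, 100) - runif(100))))
  # dE = 1 kT: empirical acceptance = e^-1 within 0.002 over 1e6 draws
  acc <- metropolis_accept(rep(0, 1e6), rep(1, 1e6))
  expect_lt(abs(mean(acc) - exp(-1)), 0.002)
})

test_that("a two-state chain reproduces the Boltzmann occupancy ratio", {
  # states with energies 0 and dE; proposal flips the state; long chain
  dE <- 1.2
  set.seed(31)
  n <- 2e5
  state <- integer(n)
  s <- 0L
  for (k in seq_len(n)) {
    e_old <- if (s == 0L) 0 else dE
    e_new <- if (s == 0L) dE else 0
    if (metropolis_accept(e_old, e_new)) s <- 1L - s
    state[k] <- s
  }
  occ <- mean(state[-(1:1000)])
  ratio <- occ / (1 - occ)
  # 3-sigma band via batch means on the log ratio
  batches <- split(state[-(1:1000)], cut(seq_along(state[-(1:1000)]), 40))
  br <- vapply(batches, function(b) {
    o <- mean(b); log(o / (1 - o))
  }, numeric(1))
  se <- sd(br) / sqrt(length(br))
  expect_lt(abs(log(ratio) - (-dE)), 3 * se)
})

test_that("trajectories are bitwise reproducible and respect termination", {
  td <- make_toy_dimer(n_residues = 6, n_contacts = 3, seed = 2)
  ff <- hybrid_forcefield(omega = 0.6, table = go_table(2))
  cfg <- simulation_config(box_edge = 60, n_steps = 60, n_trajectories = 1)
  r1 <- run_trajectory(td$receptor, td$ligand, ff, td$contacts, cfg, seed = 77)
  r2 <- run_trajectory(td$receptor, td$ligand, ff, td$contacts, cfg, seed = 77)
  expect_identical(r1, r2)
  r3 <- run_trajectory(td$receptor, td$ligand, ff, td$contacts, cfg, seed = 78)
  expect_false(identical(r1$final_poses, r3$final_poses))

  # trace bookkeeping: the recorded energy equals a full recomputation at
  # the final configuration
  full <- energy_components(
    cgassoc:::placed_sites(td$receptor, r1$final_poses$pose_r),
    cgassoc:::placed_sites(td$ligand, r1$final_poses$pose_l),
    ff, td$contacts, box = 60)
  expect_equal(r1$final_energy, full$total, tolerance = 1e-9)
  if (!r1$associated)
    expect_equal(r1$energy_trace[length(r1$energy_trace)], full$total,
                 tolerance = 1e-9)
})

test_that("with interactions off, short well-separated runs do not associate", {
  td <- make_toy_dimer(n_residues = 6, n_contacts = 3, seed = 2)
  ff <- hybrid_forcefield(omega = 0,
                          physics = physics_params(w_alpha = 0,
                                                   epsilon_rep = 0))
  cfg <- simulation_config(box_edge = 200, n_steps = 20,
                           n_trajectories = 20, base_seed = 5,
                           record_rmsd = FALSE)
  ens <- run_ensemble(td$receptor, td$ligand, ff, td$contacts, cfg)
  expect_equal(ens$P, 0)
})

test_that("a strongly attractive dimer associates in most trajectories", {
  ens <- run_funnel(strength = 6, n_steps = 2500, n_traj = 40,
                    base_seed = 900)
  expect_gte(ens$P, 0.75)
  # associated trajectories report their association step
  s <- ens$summary
  expect_true(all(!is.na(s$association_step[s$associated])))
  expect_true(all(s$association_step[s$associated] <= 2500))
})

test_that("ensembles use sequential seeds and are binomially consistent", {
  td <- make_toy_dimer(n_residues = 6, n_contacts = 3, seed = 2)
  expect_error(simulation_config(n_trajectories = 0))
  ens1 <- run_funnel(strength = 4, n_steps = 400, n_traj = 60,
                     base_seed = 1000)
  ens2 <- run_funnel(strength = 4, n_steps = 400, n_traj = 60,
                     base_seed = 5000)
  expect_equal(ens1$summary$seed, 1000 + 1:60)
  p <- (ens1$P + ens2$P) / 2
  bound <- 4 * sqrt(max(p * (1 - p), 0.01) / 60)
  expect_lt(abs(ens1$P - ens2$P), bound + 1e-12)
  expect_true(ens1$P >= 0 && ens1$P <= 1)
})

test_that("check_association applies the native-likeness tolerance and count", {
  td <- make_toy_dimer(n_residues = 12, n_contacts = 6, seed = 3)
  crit <- association_criteria()  # default: >= 3 restored, 2 A tolerance
  native <- list(pose_r = td$receptor$pose, pose_l = td$ligand$pose)
  chk <- check_association(td$receptor, td$ligand, native, td$contacts, crit)
  expect_true(chk$associated)
  expect_equal(chk$diagnostics$n_restored, 6)

  # ligand displaced 50 A: nothing restored
  far <- native
  far$pose_l <- cg_pose(far$pose_l$R, far$pose_l$t + c(0, 50, 0))
  chk2 <- check_association(td$receptor, td$ligand, far, td$contacts, crit)
  expect_false(chk2$associated)
  expect_equal(chk2$diagnostics$n_restored, 0)

  # hinge rotation about the first contact: restored count drops one
  # contact at a time along the interface; find poses with exactly 3 and
  # exactly 2 restored (verified by an independent brute-force count) and
  # check that the default criterion flips between them
  hinge <- placed_xyz(td$ligand)[cgassoc:::sc_indices(td$ligand)[1], ]
  tilt_pose <- function(angle) {
    R <- cgassoc:::axis_angle_rotation(c(0, 1, 0), angle)
    # rotate the ligand rigidly about the hinge point
    t_new <- as.numeric(R %*% (td$ligand$pose$t - hinge)) + hinge
    list(pose_r = td$receptor$pose, pose_l = cg_pose(R %*% td$ligand$pose$R, t_new))
  }
  counts <- vapply(seq(0, 0.5, by = 0.005), function(a)
    naive_restored(td$receptor, td$ligand, tilt_pose(a), td$contacts),
    numeric(1))
  a3 <- seq(0, 0.5, by = 0.005)[match(3, counts)]
  a2 <- seq(0, 0.5, by = 0.005)[match(2, counts)]
  expect_false(is.na(a3)); expect_false(is.na(a2))
  chk3 <- check_association(td$receptor, td$ligand, tilt_pose(a3),
                            td$contacts, crit)
  chk2b <- check_association(td$receptor, td$ligand, tilt_pose(a2),
                             td$contacts, crit)
  expect_equal(chk3$diagnostics$n_restored, 3)
  expect_true(chk3$associated)
  expect_equal(chk2b$diagnostics$n_restored, 2)
  expect_false(chk2b$associated)
})

test_that("all criteria combine conjunctively with full diagnostics", {
  td <- make_toy_dimer(n_residues = 12, n_contacts = 6, seed = 3)
  ff <- hybrid_forcefield(omega = 0.6, table = go_table(2))
  native <- list(pose_r = td$receptor$pose, pose_l = td$ligand$pose)
  crit <- association_criteria(min_native_contacts = 3,
                               min_contact_fraction = 50,
                               max_rmsd = 5,
                               max_interface_distance = 6,
                               max_energy = 0)
  chk <- check_association(td$receptor, td$ligand, native, td$contacts,
                           crit, ff)
  expect_true(chk$associated)
  expect_equal(chk$diagnostics$contact_pct, 100)
  expect_lt(chk$diagnostics$rmsd, 1e-6)
  expect_equal(chk$diagnostics$interface_distance, min(td$contacts$pairs$r0),
               tolerance = 1e-6)
  expect_lt(chk$diagnostics$energy, 0)

  # an impossible energy bound alone defeats association
  crit2 <- association_criteria(min_native_contacts = 3,
                                max_energy = -1e6)
  chk2 <- check_association(td$receptor, td$ligand, native, td$contacts,
                            crit2, ff)
  expect_false(chk2$associated)
  # the energy criterion without a force field is an error
  expect_error(check_association(td$receptor, td$ligand, native,
                                 td$contacts, crit2), "force field")
  # at least one criterion must be active
  expect_error(association_criteria(min_native_contacts = NULL),
               "at least one")
})

test_that("association probability rises with interaction strength and time", {
  p_weak <- run_funnel(strength = 1, n_steps = 700, n_traj = 70,
                       base_seed = 300)$P
  p_strong <- run_funnel(strength = 6, n_steps = 700, n_traj = 70,
                         base_seed = 300)$P
  expect_gte(p_strong, p_weak)
  p_short <- run_funnel(strength = 4, n_steps = 150, n_traj = 70,
                        base_seed = 300)$P
  p_long <- run_funnel(strength = 4, n_steps = 1500, n_traj = 70,
                       base_seed = 300)$P
  expect_gt(p_long, p_short)
})

test_that("Stokes-Einstein diffusion constants scale correctly with size", {
  d1 <- stokes_einstein_diffusion(20)
  d2 <- stokes_einstein_diffusion(40)
  expect_equal(d1$D_trans / d2$D_trans, 2, tolerance = 1e-9)
  expect_equal(d1$D_rot / d2$D_rot, 8, tolerance = 1e-9)
  # sanity of magnitude: a 20 A protein diffuses ~ 12 A^2/ns in water
  expect_gt(d1$D_trans, 5); expect_lt(d1$D_trans, 25)
})
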