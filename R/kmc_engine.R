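# Rigid-body kinetic Monte Carlo engine: random initialization in a
# periodic cubic box, joint translational/rotational diffusion moves for
# both partners, Metropolis acceptance on the hybrid total energy (kT
# units, T = 1), and encounter detection against combinable association
# criteria. One step is `dt` nanoseconds of diffusion.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration
#'
#' @param box_edge cubic box edge (Angstrom). Default 100 A (10 nm).
#' @param n_steps maximum steps per trajectory (default 1000).
#' @param dt time step (ns, default 1): each trajectory spans up to 1 us.
#' @param n_trajectories ensemble size (default 10000).
#' @param base_seed trajectory `t` uses seed `base_seed + t`.
#' @param record_every record energy/RMSD every this many steps.
#' @param criteria an [association_criteria()] object.
#' @param terminate_on_association stop a trajectory at first encounter
#'   (default TRUE); set FALSE for landscape/criteria-scan studies where
#'   all final configurations are needed.
#' @param record_rmsd record the RMSD trace (default TRUE; requires the
#'   native poses stored in the coarse proteins).
#' @param diffusion optional list with elements `receptor` and `ligand`,
#'   each a [diffusion_params()]; defaults to Stokes-Einstein estimates
#'   from each protein's hydrodynamic radius.
#' @param max_init_attempts resampling budget for a clash-free placement.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(box_edge = 100, n_steps = 1000, dt = 1,
                              n_trajectories = 10000, base_seed = 1,
                              record_every = 1,
                              criteria = association_criteria(),
                              terminate_on_association = TRUE,
                              record_rmsd = TRUE,
                              diffusion = NULL,
                              max_init_attempts = 1000) {
  stopifnot(box_edge > 0, n_steps > 0, dt > 0, n_trajectories > 0,
            record_every > 0, inherits(criteria, "association_criteria"))
  structure(list(box_edge = box_edge, n_steps = n_steps, dt = dt,
                 n_trajectories = n_trajectories, base_seed = base_seed,
                 record_every = record_every, criteria = criteria,
                 terminate_on_association = terminate_on_association,
                 record_rmsd = record_rmsd, diffusion = diffusion,
                 max_init_attempts = max_init_attempts),
            class = "simulation_config")
}

#' Diffusion parameters
#'
#' @param D_trans translational diffusion constant (Angstrom^2/ns).
#' @param D_rot rotational diffusion constant (rad^2/ns).
#' @return Object of class `diffusion_params`.
#' @export
diffusion_params <- function(D_trans, D_rot) {
  stopifnot(D_trans >= 0, D_rot >= 0)
  structure(list(D_trans = D_trans, D_rot = D_rot),
            class = "diffusion_params")
}

#' Stokes-Einstein diffusion constants
#'
#' `D_trans = kT / (6 pi eta R_h)` and `D_rot = kT / (8 pi eta R_h^3)` for
#' a sphere of hydrodynamic radius `R_h` in water (viscosity 0.89 mPa s at
#' 298.15 K), converted to Angstrom^2/ns and rad^2/ns.
#'
#' @param r_hyd hydrodynamic radius (Angstrom).
#' @param temperature K.
#' @param viscosity Pa s.
#' @return A [diffusion_params()] object.
#' @export
stokes_einstein_diffusion <- function(r_hyd, temperature = 298.15,
                                      viscosity = 8.9e-4) {
  stopifnot(r_hyd > 0)
  kT <- BOLTZMANN * temperature            # J
  r_m <- r_hyd * 1e-10
  d_t <- kT / (6 * pi * viscosity * r_m)   # m^2/s
  d_r <- kT / (8 * pi * viscosity * r_m^3) # rad^2/s
  diffusion_params(D_trans = d_t * 1e11,   # -> A^2/ns
                   D_rot = d_r * 1e-9)     # -> rad^2/ns
}

#' Association (encounter-complex) criteria
#'
#' A configuration is an encounter complex when ALL active criteria hold.
#' A native contact counts as restored when its current SC-SC distance is
#' within `contact_tolerance` (default 2 A) of its native distance.
#'
#' @param min_native_contacts minimum restored native contacts (default 3),
#'   or NULL to deactivate.
#' @param min_contact_fraction minimum restored fraction of native
#'   contacts, in percent, or NULL.
#' @param max_rmsd maximum ligand RMSD to native after receptor
#'   superposition (Angstrom), or NULL.
#' @param max_interface_distance maximum of the minimum SC-SC distance
#'   between interface residues (Angstrom), or NULL.
#' @param max_energy maximum total energy (kT), or NULL.
#' @param contact_tolerance native-likeness distance tolerance (Angstrom).
#' @return Object of class `association_criteria`.
#' @export
association_criteria <- function(min_native_contacts = 3,
                                 min_contact_fraction = NULL,
                                 max_rmsd = NULL,
                                 max_interface_distance = NULL,
                                 max_energy = NULL,
                                 contact_tolerance = 2) {
  active <- !vapply(list(min_native_contacts, min_contact_fraction,
                         max_rmsd, max_interface_distance, max_energy),
                    is.null, logical(1))
  if (!any(active)) stop("at least one association criterion must be active")
  stopifnot(contact_tolerance > 0)
  structure(list(min_native_contacts = min_native_contacts,
                 min_contact_fraction = min_contact_fraction,
                 max_rmsd = max_rmsd,
                 max_interface_distance = max_interface_distance,
                 max_energy = max_energy,
                 contact_tolerance = contact_tolerance),
            class = "association_criteria")
}

# Any inter-protein site pair closer than its kind-dependent sigma0?
has_clash <- function(xyz_A, kind_A, xyz_B, kind_B, sigma0, box = NULL) {
  d2 <- pair_dist_sq(xyz_A, xyz_B, box)
  s0 <- sigma0_matrix(kind_A, kind_B, sigma0)
  any(d2 < s0^2)
}

#' Random initial configuration
#'
#' Places both partners uniformly in the box (centers of mass uniform per
#' axis, orientations uniform over rotations via random quaternions) and
#' resamples the whole placement until no inter-protein site pair violates
#' the excluded-volume contact radii.
#'
#' @param receptor,ligand `coarse_protein` objects.
#' @param config a [simulation_config()].
#' @param sigma0 contact radii used for the clash check.
#' @return list with `pose_r` and `pose_l` ([cg_pose()] objects).
#' @export
random_initial_configuration <- function(receptor, ligand, config,
                                         sigma0 = physics_params()$sigma0) {
  box <- config$box_edge
  for (attempt in seq_len(config$max_init_attempts)) {
    pose_r <- cg_pose(random_rotation(), stats::runif(3, 0, box))
    pose_l <- cg_pose(random_rotation(), stats::runif(3, 0, box))
    if (!has_clash(placed_xyz(receptor, pose_r), receptor$kind,
                   placed_xyz(ligand, pose_l), ligand$kind,
                   sigma0, box))
      return(list(pose_r = pose_r, pose_l = pose_l))
  }
  stop("could not place proteins without steric clash after ",
       config$max_init_attempts, " attempts; box too small")
}

# One rigid-body diffusion step for a single pose.
move_pose <- function(pose, D, dt, box) {
  disp <- stats::rnorm(3, sd = sqrt(2 * D$D_trans * dt))
  axis <- random_unit_vector()
  angle <- stats::rnorm(1, sd = sqrt(2 * D$D_rot * dt))
  R <- if (angle == 0) pose$R else axis_angle_rotation(axis, angle) %*% pose$R
  cg_pose(R, wrap_position(pose$t + disp, box))
}

#' Propose a joint diffusion move
#'
#' Each protein is translated by an isotropic Gaussian displacement
#' (per-axis sd `sqrt(2 D_trans dt)`) and rotated about a uniformly random
#' axis through its center of mass by a Gaussian angle (sd
#' `sqrt(2 D_rot dt)`); centers are re-wrapped into the periodic box.
#'
#' @param poses list with `pose_r`, `pose_l`.
#' @param diffusion list with `receptor`, `ligand` ([diffusion_params()]).
#' @param dt time step (ns).
#' @param box box edge (Angstrom).
#' @return list with the proposed `pose_r`, `pose_l`.
#' @export
diffusion_move <- function(poses, diffusion, dt, box) {
  list(pose_r = move_pose(poses$pose_r, diffusion$receptor, dt, box),
       pose_l = move_pose(poses$pose_l, diffusion$ligand, dt, box))
}

#' Metropolis acceptance
#'
#' Accepts with probability `min(1, exp(-(E_new - E_old)))`; energies are
#' in kT so the temperature is 1. Vectorized over paired energies.
#'
#' @param E_old,E_new energies (kT).
#' @return logical vector.
#' @export
metropolis_accept <- function(E_old, E_new) {
  dE <- E_new - E_old
  dE <= 0 | stats::runif(length(dE)) < exp(-dE)
}

#' Check the association criteria for a configuration
#'
#' Evaluates the restored-native-contact count (|r - r0| <
#' `contact_tolerance`), and, where the corresponding criteria are active,
#' the restored percentage, the ligand RMSD to native, the minimum
#' interface SC-SC distance, and the total energy. The configuration is
#' associated when all active criteria pass.
#'
#' @param receptor,ligand `coarse_protein` objects (their stored poses are
#'   the native placement used for RMSD).
#' @param poses list with current `pose_r`, `pose_l`.
#' @param contacts a `native_contact_map`.
#' @param criteria an [association_criteria()].
#' @param ff a [hybrid_forcefield()]; required when `max_energy` is active.
#' @param box box edge (Angstrom) or NULL.
#' @return list `associated` (logical) and `diagnostics` (named list with
#'   `n_restored`, `contact_pct`, and any of `rmsd`, `interface_distance`,
#'   `energy` that were evaluated).
#' @export
check_association <- function(receptor, ligand, poses, contacts, criteria,
                              ff = NULL, box = NULL) {
  d <- contact_distances(receptor, ligand, poses, contacts, box)
  restored <- abs(d - contacts$pairs$r0) < criteria$contact_tolerance
  n_restored <- sum(restored)
  pct <- 100 * n_restored / contacts$n_native
  diag <- list(n_restored = n_restored, contact_pct = pct)
  ok <- TRUE
  if (!is.null(criteria$min_native_contacts))
    ok <- ok && n_restored >= criteria$min_native_contacts
  if (!is.null(criteria$min_contact_fraction))
    ok <- ok && pct >= criteria$min_contact_fraction
  if (!is.null(criteria$max_rmsd)) {
    diag$rmsd <- complex_rmsd(receptor, ligand, poses, box)
    ok <- ok && diag$rmsd <= criteria$max_rmsd
  }
  if (!is.null(criteria$max_interface_distance)) {
    diag$interface_distance <-
      interface_distance(receptor, ligand, poses, contacts, box)
    ok <- ok && diag$interface_distance <= criteria$max_interface_distance
  }
  if (!is.null(criteria$max_energy)) {
    if (is.null(ff)) stop("max_energy criterion requires a force field")
    diag$energy <- total_energy(placed_sites(receptor, poses$pose_r),
                                placed_sites(ligand, poses$pose_l),
                                ff, contacts, box)
    ok <- ok && diag$energy <= criteria$max_energy
  }
  list(associated = ok, diagnostics = diag)
}

# Current SC-SC distances of the native contact pairs (minimum image).
contact_distances <- function(receptor, ligand, poses, contacts, box = NULL) {
  rsc <- placed_xyz(receptor, poses$pose_r)[sc_indices(receptor), ,
                                            drop = FALSE]
  lsc <- placed_xyz(ligand, poses$pose_l)[sc_indices(ligand), ,
                                          drop = FALSE]
  p <- contacts$pairs
  row_dist(rsc[p$ri, , drop = FALSE], lsc[p$li, , drop = FALSE], box)
}

#' Minimum interface SC-SC distance
#'
#' Minimum (minimum-image) distance between any SC site of a receptor
#' interface residue and any SC site of a ligand interface residue, the
#' interface being the residues of the native contact map.
#'
#' @inheritParams check_association
#' @return distance in Angstrom.
#' @export
interface_distance <- function(receptor, ligand, poses, contacts,
                               box = NULL) {
  rsc <- placed_xyz(receptor, poses$pose_r)[sc_indices(receptor), ,
                                            drop = FALSE]
  lsc <- placed_xyz(ligand, poses$pose_l)[sc_indices(ligand), ,
                                          drop = FALSE]
  d2 <- pair_dist_sq(rsc[contacts$receptor_interface, , drop = FALSE],
                     lsc[contacts$ligand_interface, , drop = FALSE], box)
  sqrt(min(d2))
}

#' Run one KMC trajectory
#'
#' Random initialization, then `n_steps` iterations of joint diffusion
#' move, Metropolis acceptance on the hybrid total energy, and (after
#' every accepted move) the association check. Terminates early at the
#' first encounter unless `terminate_on_association` is FALSE. Bitwise
#' reproducible for a fixed seed.
#'
#' @param receptor,ligand `coarse_protein` objects.
#' @param ff a [hybrid_forcefield()].
#' @param contacts a `native_contact_map`.
#' @param config a [simulation_config()].
#' @param seed integer RNG seed for this trajectory.
#' @return Object of class `trajectory_record`: seed, associated flag,
#'   association step (NA if none), recorded energy traces (total,
#'   physics, statistics), RMSD trace (if enabled), recorded step indices,
#'   final poses and final diagnostics (energy, RMSD, restored contacts,
#'   contact percentage, interface distance).
#' @export
run_trajectory <- function(receptor, ligand, ff, contacts, config, seed) {
  set.seed(seed)
  box <- config$box_edge
  crit <- config$criteria
  diffusion <- list(
    receptor = config$diffusion$receptor %||%
      stokes_einstein_diffusion(receptor$hydrodynamic_radius),
    ligand = config$diffusion$ligand %||%
      stokes_einstein_diffusion(ligand$hydrodynamic_radius))
  ctx <- make_energy_context(receptor, ligand, ff, contacts, box)
  # criteria beyond contact count/fraction need per-check geometry work
  slow_criteria <- !is.null(crit$max_rmsd) ||
    !is.null(crit$max_interface_distance) || !is.null(crit$max_energy)

  assoc_now <- function(xyzA, xyzB, poses, total) {
    n <- ctx$n_restored(xyzA, xyzB, crit$contact_tolerance)
    ok <- TRUE
    if (!is.null(crit$min_native_contacts))
      ok <- ok && n >= crit$min_native_contacts
    if (!is.null(crit$min_contact_fraction))
      ok <- ok && 100 * n / ctx$n_native >= crit$min_contact_fraction
    if (ok && slow_criteria) {
      if (!is.null(crit$max_rmsd))
        ok <- ok && complex_rmsd(receptor, ligand, poses, box) <= crit$max_rmsd
      if (ok && !is.null(crit$max_interface_distance))
        ok <- ok && interface_distance(receptor, ligand, poses, contacts,
                                       box) <= crit$max_interface_distance
      if (ok && !is.null(crit$max_energy))
        ok <- ok && total <= crit$max_energy
    }
    ok
  }

  poses <- random_initial_configuration(receptor, ligand, config,
                                        ff$physics$sigma0)
  xyzA <- placed_xyz(receptor, poses$pose_r)
  xyzB <- placed_xyz(ligand, poses$pose_l)
  comp <- ctx$energy(xyzA, xyzB)

  n_rec <- floor(config$n_steps / config$record_every) + 1L
  rec_step <- integer(n_rec)
  e_tot <- numeric(n_rec); e_phys <- numeric(n_rec); e_stat <- numeric(n_rec)
  rmsd_tr <- if (config$record_rmsd) numeric(n_rec) else NULL
  k <- 1L
  record <- function(step) {
    rec_step[k] <<- step
    e_tot[k] <<- comp$total; e_phys[k] <<- comp$physics
    e_stat[k] <<- comp$statistics
    if (config$record_rmsd)
      rmsd_tr[k] <<- complex_rmsd(receptor, ligand, poses, box)
    k <<- k + 1L
  }
  record(0L)

  associated <- FALSE
  assoc_step <- NA_integer_
  if (assoc_now(xyzA, xyzB, poses, comp$total)) {
    associated <- TRUE; assoc_step <- 0L
  }

  step <- 0L
  while (step < config$n_steps &&
         !(associated && config$terminate_on_association)) {
    step <- step + 1L
    prop <- diffusion_move(poses, diffusion, config$dt, box)
    xyzA_new <- placed_xyz(receptor, prop$pose_r)
    xyzB_new <- placed_xyz(ligand, prop$pose_l)
    comp_new <- ctx$energy(xyzA_new, xyzB_new)
    if (metropolis_accept(comp$total, comp_new$total)) {
      poses <- prop
      xyzA <- xyzA_new; xyzB <- xyzB_new
      comp <- comp_new
      if (!associated && assoc_now(xyzA, xyzB, poses, comp$total)) {
        associated <- TRUE; assoc_step <- step
      }
    }
    if (step %% config$record_every == 0L) record(step)
  }

  len <- k - 1L
  final_rmsd <- complex_rmsd(receptor, ligand, poses, box)
  final_chk <- check_association(receptor, ligand, poses, contacts,
                                 config$criteria, ff, box)
  structure(list(
    seed = seed,
    associated = associated,
    association_step = assoc_step,
    steps_run = step,
    rec_step = rec_step[seq_len(len)],
    energy_trace = e_tot[seq_len(len)],
    physics_trace = e_phys[seq_len(len)],
    statistics_trace = e_stat[seq_len(len)],
    rmsd_trace = if (config$record_rmsd) rmsd_tr[seq_len(len)] else NULL,
    final_poses = poses,
    final_energy = comp$total,
    final_physics = comp$physics,
    final_statistics = comp$statistics,
    final_rmsd = final_rmsd,
    final_native_contacts = final_chk$diagnostics$n_restored,
    final_contact_pct = final_chk$diagnostics$contact_pct,
    final_interface_distance =
      interface_distance(receptor, ligand, poses, contacts, box)
  ), class = "trajectory_record")
}

#' Run a trajectory ensemble
#'
#' Runs `n_trajectories` independent trajectories (trajectory `t` seeded
#' with `base_seed + t`) and estimates the association probability as the
#' associated fraction. Trajectories are independent given their seeds, so
#' any execution order yields identical results.
#'
#' @inheritParams run_trajectory
#' @param keep_records keep full per-trajectory records incl. traces
#'   (default FALSE: only the summary table is retained).
#' @return Object of class `kmc_ensemble`: `P` (association probability),
#'   `n`, `summary` (one row per trajectory: seed, associated,
#'   association_step, final energies, final RMSD, final contact count and
#'   percentage, final interface distance, final ligand center of mass in
#'   the receptor-aligned native frame), and `records` if kept.
#' @export
run_ensemble <- function(receptor, ligand, ff, contacts, config,
                         keep_records = FALSE) {
  n <- config$n_trajectories
  stopifnot(n >= 1)
  records <- vector("list", n)
  rows <- vector("list", n)
  for (t in seq_len(n)) {
    rec <- run_trajectory(receptor, ligand, ff, contacts, config,
                          seed = config$base_seed + t)
    com <- ligand_com_native_frame(receptor, ligand, rec$final_poses,
                                   config$box_edge)
    rows[[t]] <- data.frame(
      seed = rec$seed,
      associated = rec$associated,
      association_step = rec$association_step,
      final_energy = rec$final_energy,
      final_physics = rec$final_physics,
      final_statistics = rec$final_statistics,
      final_rmsd = rec$final_rmsd,
      final_native_contacts = rec$final_native_contacts,
      final_contact_pct = rec$final_contact_pct,
      final_interface_distance = rec$final_interface_distance,
      com_x = com[1], com_y = com[2], com_z = com[3])
    if (keep_records) records[[t]] <- rec
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(
    P = mean(summary$associated),
    n = n,
    summary = summary,
    records = if (keep_records) records else NULL,
    config = config
  ), class = "kmc_ensemble")
}

#' @export
print.kmc_ensemble <- function(x, ...) {
  cat(sprintf(
    "KMC ensemble: %d trajectories, association probability P = %.4f\n",
    x$n, x$P))
  invisible(x)
}

#' Write an ensemble summary as TSV
#'
#' @param ensemble a `kmc_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_tsv <- function(ensemble, path) {
  utils::write.table(ensemble$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
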