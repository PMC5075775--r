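params_min <- data.frame(resid = "TST", elety = c("X1", "X2", "X3"),
                         charge = 0, rmin_half = 1, epsilon = 0,
                         vdw_radius = 1.7)

pdb_line <- function(serial, name, xyz, chain = "A") {
  sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, name, "TST", chain, serial, xyz[1], xyz[2], xyz[3])
}

test_that("PDB reading yields one frame per model with merged parameters", {
  one <- c(pdb_line(1, "X1", c(0, 0, 0)), pdb_line(2, "X2", c(3, 0, 0)), "END")
  fr <- read_frames(one, params_min)
  expect_length(fr, 1L)
  expect_identical(nrow(fr[[1]]), 2L)
  expect_identical(fr[[1]]$vdw_radius, c(1.7, 1.7))

  multi <- c("MODEL     1", pdb_line(1, "X1", c(0, 0, 0)), "ENDMDL",
             "MODEL     2", pdb_line(1, "X1", c(1, 0, 0)), "ENDMDL",
             "MODEL     3", pdb_line(1, "X1", c(2, 0, 0)), "ENDMDL", "END")
  frs <- read_frames(multi, params_min)
  expect_length(frs, 3L)
  expect_identical(vapply(frs, function(f) f$x, 0), c(0, 1, 2))
  expect_identical(vapply(frs, attr, 0L, "frame_index"), 1:3)

  expect_error(read_frames(c("REMARK nothing", "END"), params_min), "no ATOM")
  expect_error(read_frames(c(pdb_line(1, "ZZ9", c(0, 0, 0)), "END"), params_min),
               "no parameters .* ZZ9")
})

test_that("SASA matches analytic sphere areas and a dense-grid oracle", {
  # isolated atom: exact sphere area regardless of sampling
  f <- toy_frame(matrix(c(0, 0, 0), 1), charge = 0, vdw = 1.9)
  expect_equal(sasa(f, 1L), 4 * pi * 3.3^2, tolerance = 0.005)

  # two distant atoms: areas add
  f2 <- toy_frame(rbind(c(0, 0, 0), c(100, 0, 0)), charge = 0, vdw = 1.9)
  expect_equal(sasa(f2, 1:2), 2 * 4 * pi * 3.3^2, tolerance = 0.005)

  # overlapping pair: closed-form two-sphere and dense-grid oracles
  f3 <- toy_frame(rbind(c(0, 0, 0), c(2, 0, 0)), charge = 0, vdw = 1.7)
  r <- 1.7 + 1.4
  analytic <- 2 * oracle_sasa_two_spheres(r, r, 2)
  expect_equal(sasa(f3, 1:2), analytic, tolerance = 0.01)
  grid <- oracle_sasa_grid(rbind(c(0, 0, 0), c(2, 0, 0)), c(r, r))
  expect_equal(sasa(f3, 1:2), grid, tolerance = 0.01)

  # burial is monotone: adding surrounding atoms never raises an atom's SASA
  f4 <- toy_frame(rbind(c(0, 0, 0), c(2.5, 0, 0), c(-2.5, 0, 0)),
                  charge = 0, vdw = 1.7)
  a1 <- sasa(f4, 1L)
  a12 <- sasa(f4, 1:2) - sasa(toy_frame(matrix(c(2.5, 0, 0), 1), 0, vdw = 1.7), 1L)
  expect_lte(a12, a1 + 1e-9)
  expect_error(sasa(f4, integer(0)), "empty")
})

test_that("contact area is zero when separated, symmetric, and oracle-exact", {
  far <- toy_frame(rbind(c(0, 0, 0), c(100, 0, 0)), charge = 0,
                   chain = c("A", "B"))
  ca <- contact_area(far, 1L, 2L)
  expect_identical(ca$s_contact, 0)

  near <- toy_frame(rbind(c(0, 0, 0), c(2, 0, 0)), charge = 0,
                    chain = c("A", "B"))
  ab <- contact_area(near, 1L, 2L)
  ba <- contact_area(near, 2L, 1L)
  expect_equal(ab$s_contact, ba$s_contact, tolerance = 1e-12)
  expect_equal(ab$s_contact,
               ab$s_protein + ab$s_nucleic_acid - ab$s_complex)
  expect_gt(ab$s_contact, 0)

  # three-atom contact against the dense-grid oracle
  xyz <- rbind(c(0, 0, 0), c(3.0, 0, 0), c(1.5, 2.2, 0))
  f3 <- toy_frame(xyz, charge = 0, chain = c("A", "A", "B"))
  got <- contact_area(f3, 1:2, 3L)
  r <- rep(1.7 + 1.4, 3)
  oracle <- oracle_sasa_grid(xyz[1:2, , drop = FALSE], r[1:2]) +
    oracle_sasa_grid(xyz[3, , drop = FALSE], r[3]) -
    oracle_sasa_grid(xyz, r)
  expect_equal(got$s_contact, oracle, tolerance = 0.02)
  expect_error(contact_area(f3, 1:2, 2:3), "overlap")
})

test_that("switched nonbonded energy obeys the closed forms and the cutoff", {
  # Coulomb closed form below the switch region
  f <- toy_frame(rbind(c(0, 0, 0), c(3.320636, 0, 0)), charge = c(1, -1),
                 chain = c("A", "B"))
  expect_equal(nonbonded_energy(f, 1L, 2L), -100, tolerance = 1e-6)

  # exactly zero beyond the cutoff
  f13 <- toy_frame(rbind(c(0, 0, 0), c(13, 0, 0)), charge = c(1, -1),
                   chain = c("A", "B"))
  expect_identical(nonbonded_energy(f13, 1L, 2L), 0)

  # LJ minimum: at r = Rmin the pair energy is -epsilon
  flj <- toy_frame(rbind(c(0, 0, 0), c(3.8, 0, 0)), charge = 0,
                   rmin_half = 1.9, epsilon = 0.1, chain = c("A", "B"))
  expect_equal(nonbonded_energy(flj, 1L, 2L), -0.1, tolerance = 1e-10)

  # dense sweep through the switch zone: continuity, monotone decay of the
  # switching factor, and agreement with the unswitched formula below 10 A
  rs <- seq(9.5, 12.5, by = 0.005)
  es <- vapply(rs, function(r) {
    fr <- toy_frame(rbind(c(0, 0, 0), c(r, 0, 0)), charge = c(1, -1),
                    chain = c("A", "B"))
    nonbonded_energy(fr, 1L, 2L)
  }, 0)
  direct <- 332.0636 * -1 / rs
  expect_equal(es[rs <= 10], direct[rs <= 10], tolerance = 1e-12)
  # no jumps anywhere in the sweep: steps bounded by (max slope) x (step)
  expect_true(all(abs(diff(es)) < 40 * 0.005))
  expect_identical(es[rs >= 12], rep(0, sum(rs >= 12)))
  ratio <- es / direct                        # the switching factor itself
  in_zone <- rs > 10 & rs < 12
  expect_true(all(diff(ratio[in_zone]) < 0))
})

test_that("trajectory energy statistics reduce to direct computation", {
  # distances chosen so the Coulomb pair energy is exactly -1, -2, -3
  mk <- function(r) toy_frame(rbind(c(0, 0, 0), c(r, 0, 0)),
                              charge = c(0.1, -0.1), chain = c("A", "B"))
  qq <- 332.0636 * 0.1 * 0.1
  traj <- lapply(qq / c(1, 2, 3), mk)
  st <- binding_energy_stats(traj, 1L, 2L)
  expect_equal(st$mean, -2, tolerance = 1e-12)
  expect_equal(st$sd, 1, tolerance = 1e-12)
  expect_identical(st$n, 3L)

  same <- binding_energy_stats(traj[c(1, 1, 1, 1, 1)], 1L, 2L)
  expect_identical(same$sd, 0)
  expect_identical(same$n, 5L)
  one <- binding_energy_stats(traj[1], 1L, 2L)
  expect_identical(one$sd, 0)
  expect_error(binding_energy_stats(list(), 1L, 2L), "empty")

  st2 <- binding_energy_stats(traj, 1L, 2L, frame_stride = 2L)
  expect_identical(st2$n, 2L)
  expect_equal(st2$energies, c(-1, -3), tolerance = 1e-12)
})

test_that("H-bond detection equals a brute-force pair scan", {
  # ideal N-H...O: donor at origin, H on the axis, acceptor at 2.9 A with a
  # 5-degree bend
  ang <- 5 * pi / 180
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1),
               c(2.9 * sin(ang), 0, 2.9 * cos(ang)))
  f <- toy_frame(xyz, charge = 0)
  tab <- data.frame(donor_serial = 1L, h_serial = 2L, acceptor_serial = 3L)
  expect_identical(nrow(detect_hbonds(f, tab)), 1L)

  xyz_far <- xyz; xyz_far[3, ] <- c(0, 0, 5)
  expect_identical(nrow(detect_hbonds(toy_frame(xyz_far, 0), tab)), 0L)

  # randomized frames: hit set equals an independent all-pairs scan
  set.seed(33)
  for (rep in 1:10) {
    n_d <- 3L; n_a <- 4L
    pos <- matrix(runif((2 * n_d + n_a) * 3, 0, 8), ncol = 3)
    f <- toy_frame(pos, charge = 0)
    donors <- data.frame(donor_serial = seq_len(n_d),
                         h_serial = n_d + seq_len(n_d))
    acceptors <- 2L * n_d + seq_len(n_a)
    hits <- detect_hbonds(f, hbond_pairs(donors, acceptors))
    expected <- character(0)
    for (d in seq_len(n_d)) for (a in acceptors) {
      dist <- sqrt(sum((pos[d, ] - pos[a, ])^2))
      v1 <- pos[d, ] - pos[d + n_d, ]; v2 <- pos[a, ] - pos[d + n_d, ]
      angle <- acos(min(1, max(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (dist <= 3.5 && (180 - angle) <= 30)
        expected <- c(expected, sprintf("%d-%d", d, a))
    }
    expect_setequal(hits$id, expected)
  }
})

test_that("pi-stack geometry classifies parallel and T-shaped contacts", {
  hexa <- function(center, rot = diag(3)) {
    ang <- (0:5) * pi / 3
    t(apply(cbind(1.39 * cos(ang), 1.39 * sin(ang), 0), 1,
            function(p) rot %*% p + center))
  }
  rot_x90 <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))

  par_f <- toy_frame(rbind(hexa(c(0, 0, 0)), hexa(c(0, 0, 3.5))), charge = 0)
  hit <- detect_pi_stacks(par_f, list(a = 1:6, b = 7:12))
  expect_identical(hit$kind, "pi_parallel")

  perp_f <- toy_frame(rbind(hexa(c(0, 0, 0)), hexa(c(0, 0, 5), rot_x90)),
                      charge = 0)
  hit2 <- detect_pi_stacks(perp_f, list(a = 1:6, b = 7:12))
  expect_identical(hit2$kind, "pi_tshaped")

  far_f <- toy_frame(rbind(hexa(c(0, 0, 0)), hexa(c(0, 0, 9))), charge = 0)
  expect_identical(nrow(detect_pi_stacks(far_f, list(a = 1:6, b = 7:12))), 0L)

  expect_error(detect_pi_stacks(par_f, list(a = 1:2, b = 7:12)), "at least 3")
})

test_that("H-bond occupancy counts detection frames", {
  tr <- gen_trajectory(list(n_frames = 12, target_occupancy = 1, seed = 2))
  frames <- read_frames(tr$pdb, tr$params)
  expect_identical(hbond_occupancy(frames, tr$hbond_table, "7-15"), 1)
  tr0 <- gen_trajectory(list(n_frames = 12, target_occupancy = 0, seed = 2))
  frames0 <- read_frames(tr0$pdb, tr0$params)
  expect_identical(hbond_occupancy(frames0, tr0$hbond_table, "7-15"), 0)
  expect_error(hbond_occupancy(frames, tr$hbond_table, "nope"), "unknown bond")
})
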