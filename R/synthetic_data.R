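# Seeded generators producing fixtures with the statistical / geometric
# structure each pipeline stage assumes: the printed oligonucleotide panel,
# toy antibody-oligonucleotide complexes with known interface geometry,
# occupancy-controlled trajectories, 1:1 sensorgram sets and absorbance
# plates with group location/scale structure.

#' The printed oligonucleotide panel
#'
#' SEQ1-SEQ8 and the printed complementary strands, exactly as tabulated.
#' Where two printed readings of the same strand differ they are both kept:
#' \code{SEQ4} carries the explicit position-column LNA set \{4, 10, 14, 19\}
#' (taken as authoritative) while \code{SEQ4_notation} is the literal parse
#' of its "+" notation \{4, 10, 13, 19\}; \code{SEQ1_complement_modelling}
#' and \code{SEQ4_complement_modelling} preserve printed complement variants
#' whose final bases are not Watson-Crick consistent with their partners,
#' whereas \code{SEQ1_complement}/\code{SEQ5_complement} are the consistent
#' duplex-annealing strands.
#'
#' @return named list of \code{annotated_strand}.
#' @export
fixture_sequences <- function() {
  p <- function(txt, name, pol = "5'->3'") parse_lna_notation(txt, pol, name)
  seq4 <- p("TCC TCT CTT TCT CTT TCT CTT", "SEQ4")
  seq4 <- annotated_strand(seq4$bases, c(4L, 10L, 14L, 19L), name = "SEQ4")
  list(
    SEQ1 = p("TCC + TCT CTT TCT + CTT TCT + CTT", "SEQ1"),
    SEQ2 = p("ATT + TAT TTT + TAT ATT TAT + ATT", "SEQ2"),
    SEQ3 = p("TGA ACT + CTA TGT + CTG TAT + CAT", "SEQ3"),
    SEQ4 = seq4,
    SEQ4_notation = p("TCC + TCT CTT + TCT + CTT TCT + CTT", "SEQ4_notation"),
    SEQ5 = p("TCC TCT CTT TCT CTT TCT CTT", "SEQ5"),
    SEQ6 = p("ATT TAT TTT TAT ATT TAT ATT", "SEQ6"),
    SEQ7 = p("TGA ACT CTA TGT CTG TAT CAT", "SEQ7"),
    SEQ8 = p("TTAGGGTTAGGGTTAGGGTTAGGGTTAG", "SEQ8"),
    SEQ1_complement = p("AGG AGA GAA AGA GAA AGA GAA", "SEQ1_complement", "3'->5'"),
    SEQ5_complement = p("AGG AGA GAA AGA GAA AGA GAA", "SEQ5_complement", "3'->5'"),
    SEQ1_complement_modelling = p("AGG + AGA GAA AGA + GAA AGA + GTT",
                                  "SEQ1_complement_modelling", "3'->5'"),
    SEQ2_complement = p("TAA + ATA AAA + ATA TAA ATA + TAA",
                        "SEQ2_complement", "3'->5'"),
    SEQ3_complement = p("ACT TGA + GAT ACA + GAC ATA + GTA",
                        "SEQ3_complement", "3'->5'"),
    SEQ4_complement_modelling = p("AGG + AGA GAA + AGA + GAA AGA + GTT",
                                  "SEQ4_complement_modelling", "3'->5'"),
    SEQ5_complement_modelling = p("AGG AGA GAA AGA GAA AGA GTT",
                                  "SEQ5_complement_modelling", "3'->5'")
  )
}

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz, element) {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resid, chain, resno, xyz[1], xyz[2], xyz[3],
          1.0, 0.0, element)
}

# Parameter side-table for the toy system, keyed by (residue, atom name);
# ring carbons RC1..RC6 share one parameter set.
toy_params_full <- function() {
  ring <- data.frame(resid = "RNG", elety = paste0("RC", 1:6),
                     charge = -0.10, rmin_half = 2.00, epsilon = 0.07,
                     vdw_radius = 1.70)
  rest <- data.frame(resid = c("DON", "DON", "ACC"),
                     elety = c("ND", "HD", "OA"),
                     charge = c(-0.30, 0.30, -0.40),
                     rmin_half = c(1.85, 0.22, 1.70),
                     epsilon = c(0.20, 0.046, 0.12),
                     vdw_radius = c(1.55, 1.20, 1.52))
  rbind(ring, rest)
}

hexagon <- function(radius = 1.39) {
  ang <- (0:5) * pi / 3
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

toy_atoms <- function(separation, jitter, rng) {
  hx <- hexagon()
  atoms <- rbind(
    # chain A: "protein" -- aromatic ring + donor N-H
    data.frame(serial = 1:6, name = paste0("RC", 1:6), resid = "RNG",
               chain = "A", resno = 50L, x = hx[, 1], y = hx[, 2], z = hx[, 3],
               element = "C"),
    data.frame(serial = 7L, name = "ND", resid = "DON", chain = "A",
               resno = 35L, x = 4, y = 0, z = 0, element = "N"),
    data.frame(serial = 8L, name = "HD", resid = "DON", chain = "A",
               resno = 35L, x = 4, y = 0, z = 1.0, element = "H"),
    # chain B: "nucleic acid" -- stacked base ring + acceptor O
    data.frame(serial = 9:14, name = paste0("RC", 1:6), resid = "RNG",
               chain = "B", resno = 10L, x = hx[, 1], y = hx[, 2],
               z = 3.4 + separation, element = "C"),
    data.frame(serial = 15L, name = "OA", resid = "ACC", chain = "B",
               resno = 10L, x = 4, y = 0, z = 2.9 + separation, element = "O")
  )
  if (jitter > 0) {
    d <- matrix(rng(3L * nrow(atoms)), ncol = 3L) * jitter
    atoms$x <- atoms$x + d[, 1]; atoms$y <- atoms$y + d[, 2]
    atoms$z <- atoms$z + d[, 3]
  }
  atoms
}

#' Generate a toy antibody-oligonucleotide complex as PDB text
#'
#' A minimal two-body system with known interface geometry: chain A
#' ("protein") holds an aromatic six-carbon ring and an N-H donor, chain B
#' ("nucleic acid") a parallel base ring stacked 3.4 A above it and a
#' carbonyl-like acceptor placed 2.9 A from the donor on the N-H axis. At
#' contact (separation 0) the system shows a nonzero buried contact area,
#' one ideal hydrogen bond and one parallel pi-stack; increasing
#' \code{separation} pulls chain B away along z.
#'
#' @param config list: \code{separation} (A, default 0), \code{jitter}
#'   (coordinate noise SD in A, default 0), \code{seed} (default 1).
#' @return list with \code{pdb} (text lines), \code{params} (parameter
#'   side-table), \code{rings} (serial sets), \code{hbond_table},
#'   \code{sel_protein}, \code{sel_nucleic} (chain selections).
#' @export
gen_toy_complex <- function(config = list()) {
  separation <- config[["separation"]] %||% 0
  jitter <- config[["jitter"]] %||% 0
  seed <- config[["seed"]] %||% 1L
  set.seed(seed)
  atoms <- toy_atoms(separation, jitter, stats::rnorm)
  pdb <- c("REMARK synthetic toy complex (oligoantigen)",
           mapply(function(i) pdb_atom_line(atoms$serial[i], atoms$name[i],
                                            atoms$resid[i], atoms$chain[i],
                                            atoms$resno[i],
                                            c(atoms$x[i], atoms$y[i], atoms$z[i]),
                                            atoms$element[i]),
                  seq_len(nrow(atoms))),
           "END")
  list(pdb = pdb,
       params = toy_params_full(),
       rings = list(protein_ring = 1:6, nucleic_ring = 9:14),
       hbond_table = data.frame(donor_serial = 7L, h_serial = 8L,
                                acceptor_serial = 15L, id = "7-15"),
       sel_protein = atom_selection(chain = "A", label = "protein"),
       sel_nucleic = atom_selection(chain = "B", label = "nucleic_acid"))
}

#' Generate a multi-model trajectory with controlled H-bond occupancy
#'
#' Frames of the toy complex in which the donor-acceptor contact toggles in
#' and out of hydrogen-bond geometry by seeded Bernoulli draws with success
#' probability \code{target_occupancy}: "in" frames use the ideal 2.9 A
#' contact, "out" frames displace the acceptor well beyond the distance
#' threshold.
#'
#' @param config list: \code{n_frames} (default 200),
#'   \code{target_occupancy} in [0, 1] (default 0.6), \code{seed} (default 1).
#' @return list with \code{pdb} (multi-model text), \code{params},
#'   \code{hbond_table}, \code{rings}, \code{draws} (the Bernoulli vector).
#' @export
gen_trajectory <- function(config = list()) {
  n_frames <- config[["n_frames"]] %||% 200L
  occ <- config[["target_occupancy"]] %||% 0.6
  seed <- config[["seed"]] %||% 1L
  if (occ < 0 || occ > 1) stop("target_occupancy must lie in [0, 1]")
  set.seed(seed)
  draws <- stats::runif(n_frames) < occ
  lines <- character(0)
  for (m in seq_len(n_frames)) {
    atoms <- toy_atoms(separation = 0, jitter = 0, rng = stats::rnorm)
    if (!draws[m]) atoms$z[atoms$serial == 15L] <- 6.5  # break the contact
    lines <- c(lines, sprintf("MODEL     %4d", m),
               vapply(seq_len(nrow(atoms)), function(i)
                 pdb_atom_line(atoms$serial[i], atoms$name[i], atoms$resid[i],
                               atoms$chain[i], atoms$resno[i],
                               c(atoms$x[i], atoms$y[i], atoms$z[i]),
                               atoms$element[i]), ""),
               "ENDMDL")
  }
  list(pdb = c(lines, "END"), params = toy_params_full(),
       hbond_table = data.frame(donor_serial = 7L, h_serial = 8L,
                                acceptor_serial = 15L, id = "7-15"),
       rings = list(protein_ring = 1:6, nucleic_ring = 9:14),
       draws = draws)
}

#' Generate a 1:1 sensorgram concentration series
#'
#' Two-fold dilution series (default: the 2.5 -> 0.16 mg/mL antibody series,
#' converted to molar with a 150 kDa molecular weight) simulated from the
#' closed-form 1:1 model over a 60 s association / 60 s dissociation
#' schedule, with seeded Gaussian noise.
#'
#' @param config list: \code{ka} (default 1e5), \code{kd} (default 1e-3),
#'   \code{rmax} RU (default 400), \code{start_mg_ml} (default 2.5),
#'   \code{factor} (2), \code{n} (5), \code{mw_da} (150000),
#'   \code{schedule}, \code{noise_sd} RU (default 1), \code{seed} (1).
#' @return list of \code{sensorgram}, highest concentration first.
#' @export
gen_sensorgram_set <- function(config = list()) {
  ka <- config[["ka"]] %||% 1e5
  kd <- config[["kd"]] %||% 1e-3
  rmax <- config[["rmax"]] %||% 400
  mg <- serial_dilution(config[["start_mg_ml"]] %||% 2.5, config[["factor"]] %||% 2,
                        config[["n"]] %||% 5L, decimals = 2)
  concs <- mass_to_molar(mg, config[["mw_da"]] %||% 150000)
  schedule <- config[["schedule"]] %||% injection_schedule()
  noise_sd <- config[["noise_sd"]] %||% 1
  seed <- config[["seed"]] %||% 1L
  lapply(seq_along(concs), function(i)
    simulate_sensorgram(ka, kd, rmax, concs[i], schedule, noise_sd,
                        seed = seed + i - 1L,
                        label = sprintf("%.2f_mg_ml", mg[i])))
}

# Zero-truncated normal draws by inverse CDF (deterministic under seed).
rtnorm0 <- function(n, loc, scale) {
  if (scale == 0) return(rep(loc, n))
  lo <- stats::pnorm(0, loc, scale)
  stats::qnorm(stats::runif(n, lo, 1), loc, scale)
}

#' Mean of a zero-truncated normal distribution
#'
#' The generators parameterise absorbance by location/scale of the parent
#' normal; truncation at zero shifts the realised mean upward. This helper
#' gives the analytic truncated mean for calibration checks.
#'
#' @param loc,scale parent normal location and scale.
#' @return the mean of the distribution truncated to [0, Inf).
#' @export
truncated_normal_mean <- function(loc, scale) {
  if (scale == 0) return(loc)
  a <- (0 - loc) / scale
  loc + scale * stats::dnorm(a) / (1 - stats::pnorm(a))
}

#' Generate a synthetic ELISA absorbance plate
#'
#' Samples x antigens A450 matrix drawn from zero-truncated normal
#' distributions with per-group location/scale. The defaults mimic the
#' reported contrast between LNA-modified antigens (wide spread: location
#' 0.44, scale 0.46) and unmodified DNA antigens (tighter, higher: location
#' 0.67, scale 0.24); note these are parent-normal parameters, not realised
#' moments.
#'
#' @param config list: \code{n_samples} (default 30), \code{seed} (1),
#'   \code{group_params} named list of \code{c(loc, scale)} per group,
#'   \code{antigens} named character vector antigen -> group.
#' @return a \code{plate_data}.
#' @export
gen_elisa_plate <- function(config = list()) {
  n <- config[["n_samples"]] %||% 30L
  seed <- config[["seed"]] %||% 1L
  gp <- config[["group_params"]] %||% list(LNA = c(0.44, 0.46),
                                      DNA = c(0.67, 0.24),
                                      control = c(0.67, 0.24))
  antigens <- config[["antigens"]] %||% c(SEQ1 = "LNA", SEQ2 = "LNA", SEQ3 = "LNA",
                                     SEQ4 = "LNA", SEQ5 = "DNA", SEQ6 = "DNA",
                                     SEQ7 = "DNA", SEQ8 = "control",
                                     CTD = "control")
  set.seed(seed)
  ab <- sapply(names(antigens), function(ag) {
    p <- gp[[antigens[[ag]]]]
    rtnorm0(n, p[1], p[2])
  })
  ab <- matrix(ab, nrow = n,
               dimnames = list(sprintf("P%02d", seq_len(n)), names(antigens)))
  plate_data(ab, group_of_antigen = antigens)
}
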