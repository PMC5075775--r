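# Interface metrics on antibody-oligonucleotide coordinate frames:
# Shrake-Rupley SASA, buried contact area, switched-cutoff nonbonded
# energies with trajectory averaging, and H-bond / pi-stack detection.

COULOMB_KCAL <- 332.0636  # kcal A / (mol e^2)

#' Read coordinate frames from (multi-model) PDB
#'
#' Parses a PDB file or text via bio3d and merges a per-atom parameter
#' side-table keyed by (residue name, atom name). MODEL/ENDMDL blocks give
#' one frame each; single-model files yield one frame.
#'
#' @param pdb path to a PDB file, or PDB text (single string or character
#'   vector of lines).
#' @param param_table data.frame with columns \code{resid}, \code{elety},
#'   \code{charge}, \code{rmin_half}, \code{epsilon}, \code{vdw_radius}.
#' @return list of frames; each frame is a data.frame (class
#'   \code{oligo_frame}) with atom fields, coordinates and parameters, and a
#'   \code{frame_index} attribute.
#' @export
read_frames <- function(pdb, param_table) {
  path <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    pdb
  } else {
    tf <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb) == 1L) strsplit(pdb, "\n")[[1]] else pdb, tf)
    tf
  }
  raw <- readLines(path)
  if (!any(grepl("^(ATOM|HETATM)", raw)))
    stop("no ATOM records in PDB input")
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- p$atom
  nmod <- nrow(p$xyz)
  needed <- c("resid", "elety", "charge", "rmin_half", "epsilon", "vdw_radius")
  if (!all(needed %in% names(param_table)))
    stop("param_table must have columns: ", paste(needed, collapse = ", "))
  key <- paste(at$resid, at$elety)
  pkey <- paste(param_table$resid, param_table$elety)
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("no parameters for atom ", at$elety[miss], " of residue ",
         at$resid[miss], " ", at$resno[miss])
  }
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(p$xyz[m, ], ncol = 3L, byrow = TRUE)
    fr <- data.frame(serial = at$eleno, elety = at$elety, resid = at$resid,
                     resno = at$resno, chain = at$chain,
                     element = at$elesy,
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     charge = param_table$charge[idx],
                     rmin_half = param_table$rmin_half[idx],
                     epsilon = param_table$epsilon[idx],
                     vdw_radius = param_table$vdw_radius[idx],
                     stringsAsFactors = FALSE)
    if (anyDuplicated(fr$serial)) stop("duplicate atom serials in frame ", m)
    if (any(fr$vdw_radius <= 0)) stop("vdw_radius must be positive")
    attr(fr, "frame_index") <- m
    class(fr) <- c("oligo_frame", "data.frame")
    fr
  })
}

#' Atom selection specification
#'
#' @param chain,resno,elety,resid optional filters (vectors; \code{NULL}
#'   matches everything).
#' @param label one of \code{"protein"}, \code{"nucleic_acid"},
#'   \code{"subset"}.
#' @return object of class \code{atom_selection}.
#' @export
atom_selection <- function(chain = NULL, resno = NULL, elety = NULL,
                           resid = NULL, label = "subset") {
  structure(list(chain = chain, resno = resno, elety = elety, resid = resid,
                 label = label),
            class = "atom_selection")
}

resolve_selection <- function(frame, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  stopifnot(inherits(sel, "atom_selection"))
  keep <- rep(TRUE, nrow(frame))
  if (!is.null(sel$chain)) keep <- keep & frame$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & frame$resno %in% sel$resno
  if (!is.null(sel$elety)) keep <- keep & frame$elety %in% sel$elety
  if (!is.null(sel$resid)) keep <- keep & frame$resid %in% sel$resid
  which(keep)
}

# Deterministic near-uniform unit-sphere points (Fibonacci spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe over the selected atoms: each atom's sphere of radius
#' (vdW + probe) is sampled at \code{n_sphere_points} near-uniform points and
#' points buried inside any other selected atom's expanded sphere are
#' excluded. Only atoms in the selection form the occluding context, so the
#' selection is measured in isolation.
#'
#' @param frame an \code{oligo_frame}.
#' @param selection \code{atom_selection} or integer row indices.
#' @param probe_radius probe radius in Angstrom (default 1.4, water).
#' @param n_sphere_points test points per atom (default 960).
#' @return total accessible area in Angstrom^2.
#' @export
sasa <- function(frame, selection, probe_radius = 1.4, n_sphere_points = 960L) {
  idx <- resolve_selection(frame, selection)
  if (!length(idx)) stop("empty selection")
  xyz <- as.matrix(frame[idx, c("x", "y", "z")])
  rad <- frame$vdw_radius[idx] + probe_radius
  pts <- sphere_points(n_sphere_points)
  n <- length(idx)
  total <- 0
  for (i in seq_len(n)) {
    pi_xyz <- sweep(pts * rad[i], 2L, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- sum((xyz[i, ] - xyz[j, ])^2)
      if (d2 >= (rad[i] + rad[j])^2) next
      dj2 <- (pi_xyz[, 1] - xyz[j, 1])^2 + (pi_xyz[, 2] - xyz[j, 2])^2 +
        (pi_xyz[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 > rad[j]^2
      if (!any(exposed)) break
    }
    total <- total + 4 * pi * rad[i]^2 * sum(exposed) / n_sphere_points
  }
  total
}

#' Buried contact area between two selections
#'
#' The interface buried between two binding partners: the accessible areas of
#' each selection in isolation minus the accessible area of their union,
#' S = S_a + S_b - S_complex. Zero for separated bodies, symmetric in its two
#' selections.
#'
#' @inheritParams sasa
#' @param sel_protein,sel_nucleic disjoint selections.
#' @return list (class \code{contact_area_result}) with \code{s_protein},
#'   \code{s_nucleic_acid}, \code{s_complex}, \code{s_contact}.
#' @export
contact_area <- function(frame, sel_protein, sel_nucleic,
                         probe_radius = 1.4, n_sphere_points = 960L) {
  ia <- resolve_selection(frame, sel_protein)
  ib <- resolve_selection(frame, sel_nucleic)
  if (!length(ia) || !length(ib)) stop("empty selection")
  if (length(intersect(ia, ib))) stop("selections overlap")
  s_a <- sasa(frame, ia, probe_radius, n_sphere_points)
  s_b <- sasa(frame, ib, probe_radius, n_sphere_points)
  s_ab <- sasa(frame, c(ia, ib), probe_radius, n_sphere_points)
  res <- list(s_protein = s_a, s_nucleic_acid = s_b, s_complex = s_ab,
              s_contact = s_a + s_b - s_ab)
  stopifnot(abs(res$s_contact - (s_a + s_b - s_ab)) < 1e-9)
  structure(res, class = "contact_area_result")
}

# CHARMM-style C1-continuous switching function on [switch_start, cutoff].
switch_factor <- function(r, switch_start, cutoff) {
  s <- ifelse(r <= switch_start, 1,
              ifelse(r >= cutoff, 0,
                     (cutoff^2 - r^2)^2 * (cutoff^2 + 2 * r^2 - 3 * switch_start^2) /
                       (cutoff^2 - switch_start^2)^3))
  s
}

#' Switched-cutoff nonbonded interaction energy between two selections
#'
#' Sum over cross pairs of Coulomb (332.0636 q_i q_j / r) and Lennard-Jones
#' terms (Rmin by arithmetic combination of half-Rmins, epsilon geometric),
#' each multiplied by a C1-continuous switching function equal to 1 below
#' \code{switch_start} and exactly 0 at and beyond \code{cutoff}.
#'
#' @inheritParams contact_area
#' @param sel_a,sel_b disjoint selections.
#' @param cutoff outer cutoff, Angstrom (default 12).
#' @param switch_start switching onset, Angstrom (default 10).
#' @return energy in kcal/mol.
#' @export
nonbonded_energy <- function(frame, sel_a, sel_b, cutoff = 12, switch_start = 10) {
  ia <- resolve_selection(frame, sel_a)
  ib <- resolve_selection(frame, sel_b)
  if (!length(ia) || !length(ib)) stop("empty selection")
  if (length(intersect(ia, ib))) stop("selections overlap")
  need <- c("charge", "rmin_half", "epsilon")
  if (anyNA(frame[c(ia, ib), need]))
    stop("missing nonbonded parameters in selection")
  xa <- as.matrix(frame[ia, c("x", "y", "z")])
  xb <- as.matrix(frame[ib, c("x", "y", "z")])
  qa <- frame$charge[ia]; qb <- frame$charge[ib]
  ra <- frame$rmin_half[ia]; rb <- frame$rmin_half[ib]
  ea <- frame$epsilon[ia]; eb <- frame$epsilon[ib]
  e <- 0
  for (i in seq_along(ia)) {
    d <- sqrt((xb[, 1] - xa[i, 1])^2 + (xb[, 2] - xa[i, 2])^2 +
                (xb[, 3] - xa[i, 3])^2)
    inside <- d < cutoff
    if (!any(inside)) next
    d <- d[inside]
    sw <- switch_factor(d, switch_start, cutoff)
    e_coul <- COULOMB_KCAL * qa[i] * qb[inside] / d
    rmin <- ra[i] + rb[inside]
    eps <- sqrt(ea[i] * eb[inside])
    sr6 <- (rmin / d)^6
    e_lj <- eps * (sr6^2 - 2 * sr6)
    e <- e + sum(sw * (e_coul + e_lj))
  }
  e
}

#' Per-frame binding energy averaged over a trajectory
#'
#' Evaluates \code{\link{nonbonded_energy}} frame by frame (optionally
#' strided) and reports mean, sample standard deviation and the number of
#' frames averaged.
#'
#' @param trajectory list of \code{oligo_frame}.
#' @param sel_a,sel_b disjoint selections.
#' @param frame_stride keep every \code{frame_stride}-th frame.
#' @param ... passed to \code{\link{nonbonded_energy}}.
#' @return list (class \code{energy_stats}) with \code{mean}, \code{sd},
#'   \code{n}, \code{energies}.
#' @export
binding_energy_stats <- function(trajectory, sel_a, sel_b, frame_stride = 1L, ...) {
  if (!length(trajectory)) stop("empty trajectory")
  keep <- seq(1L, length(trajectory), by = frame_stride)
  if (!length(keep)) stop("no frames left after striding")
  e <- vapply(trajectory[keep], nonbonded_energy, 0, sel_a = sel_a,
              sel_b = sel_b, ...)
  structure(list(mean = mean(e),
                 sd = if (length(e) > 1L) stats::sd(e) else 0,
                 n = length(e), energies = e),
            class = "energy_stats")
}

frame_xyz <- function(frame, serial) {
  i <- match(serial, frame$serial)
  if (anyNA(i)) stop("unknown atom serial ", serial[which(is.na(i))[1]])
  as.matrix(frame[i, c("x", "y", "z"), drop = FALSE])
}

angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Candidate donor-acceptor pair table for H-bond detection
#' @param donors data.frame with \code{donor_serial} and optional
#'   \code{h_serial} (\code{NA} for heavy-atom-only donors).
#' @param acceptors vector of acceptor serials.
#' @return pair table with an \code{id} column, one row per combination.
#' @export
hbond_pairs <- function(donors, acceptors) {
  if (is.null(donors$h_serial)) donors$h_serial <- NA_integer_
  g <- expand.grid(di = seq_len(nrow(donors)), acceptor_serial = acceptors)
  out <- data.frame(donor_serial = donors$donor_serial[g$di],
                    h_serial = donors$h_serial[g$di],
                    acceptor_serial = g$acceptor_serial)
  out$id <- sprintf("%d-%d", out$donor_serial, out$acceptor_serial)
  out
}

#' Geometric hydrogen-bond detection on one frame
#'
#' A candidate pair scores a hit when the donor-acceptor distance is at most
#' \code{d_max} and, when a hydrogen is given, the donor-H-acceptor angle
#' deviates from linear (180 degrees) by at most \code{angle_max}. Pairs with
#' \code{h_serial = NA} are evaluated heavy-atom-only (distance criterion
#' alone).
#'
#' @param frame an \code{oligo_frame}.
#' @param donor_acceptor_table pair table as from \code{\link{hbond_pairs}}.
#' @param d_max donor-acceptor distance threshold, Angstrom (default 3.5).
#' @param angle_max maximum deviation from linearity, degrees (default 30).
#' @return data.frame of hits with geometry and \code{frame_index}.
#' @export
detect_hbonds <- function(frame, donor_acceptor_table, d_max = 3.5,
                          angle_max = 30) {
  tab <- donor_acceptor_table
  if (is.null(tab$id)) tab$id <- sprintf("%d-%d", tab$donor_serial, tab$acceptor_serial)
  hits <- list()
  for (r in seq_len(nrow(tab))) {
    d_xyz <- frame_xyz(frame, tab$donor_serial[r])[1, ]
    a_xyz <- frame_xyz(frame, tab$acceptor_serial[r])[1, ]
    dist <- sqrt(sum((d_xyz - a_xyz)^2))
    if (dist > d_max) next
    dev <- NA_real_
    if (!is.na(tab$h_serial[r])) {
      h_xyz <- frame_xyz(frame, tab$h_serial[r])[1, ]
      dev <- 180 - angle_deg(d_xyz, h_xyz, a_xyz)
      if (dev > angle_max) next
    }
    hits[[length(hits) + 1L]] <-
      data.frame(kind = "hbond", id = tab$id[r],
                 donor_serial = tab$donor_serial[r],
                 acceptor_serial = tab$acceptor_serial[r],
                 distance = dist, angle_dev = dev,
                 frame_index = attr(frame, "frame_index") %||% 1L)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(kind = character(0), id = character(0),
               donor_serial = integer(0), acceptor_serial = integer(0),
               distance = numeric(0), angle_dev = numeric(0),
               frame_index = integer(0))
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Fraction of frames in which the identified donor-acceptor contact is
#' detected; quantifies how stable an interaction is over the run.
#'
#' @param trajectory list of \code{oligo_frame}.
#' @param donor_acceptor_table pair table with an \code{id} column.
#' @param bond_id which pair to track.
#' @param ... passed to \code{\link{detect_hbonds}}.
#' @return fraction in [0, 1].
#' @export
hbond_occupancy <- function(trajectory, donor_acceptor_table, bond_id, ...) {
  if (!length(trajectory)) stop("empty trajectory")
  if (is.null(donor_acceptor_table$id))
    donor_acceptor_table$id <- sprintf("%d-%d", donor_acceptor_table$donor_serial,
                                       donor_acceptor_table$acceptor_serial)
  if (!bond_id %in% donor_acceptor_table$id)
    stop("unknown bond id: ", bond_id)
  tab <- donor_acceptor_table[donor_acceptor_table$id == bond_id, , drop = FALSE]
  present <- vapply(trajectory, function(fr)
    nrow(detect_hbonds(fr, tab, ...)) > 0L, NA)
  mean(present)
}

ring_geometry <- function(frame, serials) {
  if (length(serials) < 3L) stop("ring must have at least 3 atoms")
  xyz <- frame_xyz(frame, serials)
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2L, centroid)
  ev <- eigen(crossprod(centered), symmetric = TRUE)
  list(centroid = centroid, normal = ev$vectors[, 3L])
}

#' Geometric pi-stacking detection on one frame
#'
#' Ring pairs with centroid distance at most \code{centroid_max} are
#' classified by interplanar angle: near-parallel (face-to-face stacking) or
#' near-perpendicular (T-shaped / edge-to-face).
#'
#' @param frame an \code{oligo_frame}.
#' @param ring_definitions named list of atom-serial vectors, one per ring
#'   (at least 3 atoms each).
#' @param centroid_max centroid-centroid threshold, Angstrom (default 5.5).
#' @param parallel_max maximum interplanar angle for parallel stacking,
#'   degrees (default 30).
#' @param tshaped_range interplanar-angle band for T-shaped contacts,
#'   degrees (default 60-90).
#' @return data.frame of hits (\code{kind}, ring labels, geometry).
#' @export
detect_pi_stacks <- function(frame, ring_definitions, centroid_max = 5.5,
                             parallel_max = 30, tshaped_range = c(60, 90)) {
  rings <- lapply(ring_definitions, ring_geometry, frame = frame)
  labs <- names(ring_definitions) %||% as.character(seq_along(ring_definitions))
  hits <- list()
  nr <- length(rings)
  if (nr >= 2L) for (i in 1:(nr - 1L)) for (j in (i + 1L):nr) {
    d <- sqrt(sum((rings[[i]]$centroid - rings[[j]]$centroid)^2))
    if (d > centroid_max) next
    cosang <- abs(sum(rings[[i]]$normal * rings[[j]]$normal))
    ang <- acos(pmin(1, cosang)) * 180 / pi   # folded to [0, 90]
    kind <- if (ang <= parallel_max) "pi_parallel"
    else if (ang >= tshaped_range[1] && ang <= tshaped_range[2]) "pi_tshaped"
    else next
    hits[[length(hits) + 1L]] <-
      data.frame(kind = kind, ring_a = labs[i], ring_b = labs[j],
                 distance = d, angle = ang,
                 frame_index = attr(frame, "frame_index") %||% 1L)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(kind = character(0), ring_a = character(0),
               ring_b = character(0), distance = numeric(0),
               angle = numeric(0), frame_index = integer(0))
}
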