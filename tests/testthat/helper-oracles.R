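# Independent oracle implementations used across the suite. These stay
# deliberately naive (closed forms, exhaustive enumeration, dense grids,
# direct ODE integration) and never call the code paths they check.

WC <- c(A = "T", C = "G", G = "C", T = "A")

rand_strand <- function(n) {
  annotated_strand(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   lna_flags = integer(0))
}

# Longest antiparallel self-complementary run by direct O(n^3) enumeration
# over all (i, j, L) windows.
oracle_self_dimer_run <- function(bases) {
  n <- length(bases)
  best <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    L <- 0L
    while (i + L <= n && j - L >= 1 &&
           WC[bases[i + L]] == bases[j - L]) L <- L + 1L
    best <- max(best, L)
  }
  best
}

# All valid hairpin stem triples (i, j, k) by brute force; returns a
# data.frame of every (not only maximal) stem satisfying the thresholds.
oracle_hairpin_triples <- function(bases, min_stem, min_loop) {
  n <- length(bases)
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j - i - 2L * k + 1L < min_loop || k < min_stem) next
    if (i + k - 1L > n || j > n) next
    ok <- TRUE
    for (t in 0:(k - 1L))
      if (WC[bases[i + t]] != bases[j - t]) { ok <- FALSE; break }
    if (ok) out[[length(out) + 1L]] <- c(i = i, j = j, k = k)
  }
  if (length(out)) as.data.frame(do.call(rbind, out)) else
    data.frame(i = integer(0), j = integer(0), k = integer(0))
}

# Accessible area of sphere 1 (radius r1) partially buried by one sphere
# (radius r2) at centre distance d: closed-form spherical cap.
oracle_sasa_two_spheres <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d + r1 <= r2) return(0)
  cos_theta <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
  4 * pi * r1^2 - 2 * pi * r1^2 * (1 - cos_theta)
}

# Dense latitude-longitude numerical SASA (independent grid construction
# with sin(theta) area weights); xyz is an n x 3 matrix, radii the expanded
# atom radii (vdW + probe).
oracle_sasa_grid <- function(xyz, radii, n_theta = 320L, n_phi = 640L) {
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  dthe <- pi / n_theta; dphi <- 2 * pi / n_phi
  grid <- cbind(rep(sin(theta), each = n_phi) * cos(phi),
                rep(sin(theta), each = n_phi) * sin(phi),
                rep(cos(theta), each = n_phi))
  w <- rep(sin(theta), each = n_phi) * dthe * dphi
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    pts <- sweep(grid * radii[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, nrow(pts))
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > radii[j]^2
    }
    total <- total + radii[i]^2 * sum(w[exposed])
  }
  total
}

# Direct numerical integration of dR/dt = ka C(t) (Rmax - R) - kd R with a
# square-pulse injection, via deSolve.
oracle_ode_sensorgram <- function(ka, kd, rmax, conc, times, t_assoc_end) {
  f <- function(t, y, p) {
    C <- if (t <= t_assoc_end) conc else 0
    list(ka * C * (rmax - y[1]) - kd * y[1])
  }
  assoc_t <- unique(c(times[times <= t_assoc_end], t_assoc_end))
  dis_t <- unique(c(t_assoc_end, times[times > t_assoc_end]))
  o1 <- deSolve::ode(c(R = 0), assoc_t, f, NULL, method = "lsoda",
                     rtol = 1e-12, atol = 1e-12)
  r_end <- unname(o1[nrow(o1), "R"])
  f2 <- function(t, y, p) list(-kd * y[1])
  o2 <- deSolve::ode(c(R = r_end), dis_t, f2, NULL, method = "lsoda",
                     rtol = 1e-12, atol = 1e-12)
  resp <- c(o1[o1[, "time"] %in% times, "R"],
            o2[o2[, "time"] %in% times & o2[, "time"] > t_assoc_end, "R"])
  unname(resp)
}

# Welch statistics straight from the textbook formulas.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_anova <- function(groups) {
  v <- unlist(groups); N <- length(v); k <- length(groups)
  grand <- mean(v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  se <- sqrt(sum(res^2) / (length(x) - 2) / sxx)
  list(slope = slope, intercept = intercept,
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
       p_slope = 2 * pt(-abs(slope / se), length(x) - 2))
}

# One-atom-per-selection frame builder for energy/SASA unit tests.
toy_frame <- function(xyz, charge, rmin_half = 0, epsilon = 0,
                      vdw = 1.7, chain = NULL) {
  n <- nrow(xyz)
  fr <- data.frame(serial = seq_len(n), elety = paste0("X", seq_len(n)),
                   resid = "TST", resno = seq_len(n),
                   chain = chain %||% rep("A", n), element = "C",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   charge = charge, rmin_half = rmin_half,
                   epsilon = epsilon, vdw_radius = vdw)
  attr(fr, "frame_index") <- 1L
  class(fr) <- c("oligo_frame", "data.frame")
  fr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
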