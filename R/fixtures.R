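#' Synthetic structure and dataset generators
#'
#' Deterministic fixtures used throughout the test-suite and examples: ideal
#' alpha-helices, extended zig-zag chains, chains built exactly at the force
#' field's ideal internal geometry, exactly-sampled double-well umbrella
#' datasets (with their analytic free-energy profile attached), and small
#' perturbed memory libraries. All structure generators write standard PDB
#' files so fixtures pass through the same readers as real data.
#'
#' @name fixtures
NULL

# place the carbonyl-O bead given two consecutive Calpha positions so that
# |CA_i - O| = a and |O - CA_{i+1}| = b exactly (triangle construction)
.place_o <- function(ca_i, ca_next, a, b, perp_hint) {
  u <- ca_next - ca_i
  d <- sqrt(sum(u^2))
  u <- u / d
  x <- (d^2 + a^2 - b^2) / (2 * d)
  h2 <- a^2 - x^2
  if (h2 < 0) stop("O-bead triangle construction infeasible for this geometry")
  w <- perp_hint - sum(perp_hint * u) * u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-8) {                       # hint parallel to the bond; pick any
    w <- c(-u[2], u[1], 0)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-8) { w <- c(0, -u[3], u[2]); nw <- sqrt(sum(w^2)) }
  }
  ca_i + x * u + sqrt(h2) * (w / nw)
}

# chiral Cbeta placement from the local Calpha frame: along the bisector of
# the two backbone bonds with an out-of-plane component, as in L-amino acids
.place_cb <- function(ca, i, bond, fallback) {
  n <- nrow(ca)
  if (i <= 1 || i >= n) return(ca[i, ] + bond * fallback)
  u1 <- ca[i - 1, ] - ca[i, ]; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- ca[i + 1, ] - ca[i, ]; u2 <- u2 / sqrt(sum(u2^2))
  bis <- -(u1 + u2)
  nb <- sqrt(sum(bis^2))
  if (nb < 1e-8) return(ca[i, ] + bond * fallback)
  bis <- bis / nb
  nrm <- c(u1[2] * u2[3] - u1[3] * u2[2], u1[3] * u2[1] - u1[1] * u2[3],
           u1[1] * u2[2] - u1[2] * u2[1])
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-8) return(ca[i, ] + bond * fallback)
  dir <- 0.6 * bis + 0.8 * nrm / nn
  ca[i, ] + bond * dir / sqrt(sum(dir^2))
}

.expand_sequence <- function(sequence, n) {
  if (is.null(sequence)) return(rep("A", n))
  s <- strsplit(sequence, "")[[1]]
  if (length(s) == 1) s <- rep(s, n)
  if (length(s) != n) stop("sequence length must equal n")
  s
}

.write_fixture_pdb <- function(file, seq1, ca, cb, o) {
  n <- length(seq1)
  xyz <- c(); elety <- c(); resno <- c(); resid <- c()
  for (i in seq_len(n)) {
    beads <- list(CA = ca[i, ], O = o[i, ])
    if (seq1[i] != "G") beads <- list(CA = ca[i, ], CB = cb[i, ], O = o[i, ])
    for (nm in names(beads)) {
      xyz <- c(xyz, beads[[nm]])
      elety <- c(elety, nm)
      resno <- c(resno, i)
      resid <- c(resid, bio3d::aa123(seq1[i]))
    }
  }
  bio3d::write.pdb(file = file, xyz = round(xyz, 3), resno = resno,
                   resid = resid, elety = elety, chain = rep("A", length(elety)),
                   eleno = seq_along(elety), o = rep(1, length(elety)),
                   b = rep(0, length(elety)))
  invisible(file)
}

#' Generate an ideal alpha-helix as a PDB file
#'
#' Calpha beads lie on a helix with 2.3 A radius, 1.5 A rise and 100 degree
#' twist per residue (consecutive Calpha-Calpha close to 3.8 A); Cbeta beads
#' point radially outward at the ideal bond length and carbonyl-O beads sit at
#' the ideal bond distances between consecutive Calpha positions.
#'
#' @param n number of residues (at least 4)
#' @param sequence one-letter amino-acid sequence (single letter recycled;
#'   default poly-alanine)
#' @param file output PDB path
#' @return the PDB file path, invisibly
#' @export
make_ideal_helix <- function(n, sequence = NULL,
                             file = tempfile(fileext = ".pdb")) {
  if (n < 4) stop("an ideal helix fixture needs n >= 4 residues")
  seq1 <- .expand_sequence(sequence, n)
  radius <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  ang <- (0:n) * twist
  ca_all <- cbind(radius * cos(ang), radius * sin(ang), (0:n) * rise)
  ca <- ca_all[1:n, , drop = FALSE]
  radial <- cbind(cos(ang[1:n]), sin(ang[1:n]), 0)
  cb <- t(vapply(seq_len(n), function(i) .place_cb(ca, i, 1.54, radial[i, ]),
                 numeric(3)))
  o <- t(vapply(seq_len(n), function(i) {
    .place_o(ca_all[i, ], ca_all[i + 1, ], 2.44, 2.83, radial[i, ])
  }, numeric(3)))
  .write_fixture_pdb(file, seq1, ca, cb, o)
}

#' Generate an extended (zig-zag) chain as a PDB file
#'
#' @inheritParams make_ideal_helix
#' @return the PDB file path, invisibly
#' @export
make_extended_chain <- function(n, sequence = NULL,
                                file = tempfile(fileext = ".pdb")) {
  if (n < 3) stop("need n >= 3 residues")
  seq1 <- .expand_sequence(sequence, n)
  idx <- 0:n
  ca_all <- cbind(idx * 3.4, 0.85 * (-1)^idx, 0)
  ca <- ca_all[1:n, , drop = FALSE]
  cb <- t(vapply(seq_len(n), function(i) .place_cb(ca, i, 1.54, c(0, 0, -1)),
                 numeric(3)))
  o <- t(vapply(seq_len(n), function(i) {
    .place_o(ca_all[i, ], ca_all[i + 1, ], 2.44, 2.83, c(0, 0, 1))
  }, numeric(3)))
  .write_fixture_pdb(file, seq1, ca, cb, o)
}

#' Generate a chain at the force field's exact ideal internal geometry
#'
#' Planar Calpha trace with every bond length and every bond angle at the
#' backbone term's ideal values, so the connectivity and chain-angle energies
#' vanish identically. Used to probe the harmonic minima of the backbone terms.
#'
#' @inheritParams make_ideal_helix
#' @param forcefield a [default_forcefield()] object supplying the ideal
#'   geometry
#' @return the PDB file path, invisibly
#' @export
make_ideal_geometry_chain <- function(n, forcefield = default_forcefield(),
                                      sequence = NULL,
                                      file = tempfile(fileext = ".pdb")) {
  if (n < 3) stop("need n >= 3 residues")
  seq1 <- .expand_sequence(sequence, n)
  bb <- forcefield$params$backbone
  b <- bb$r_ca_ca
  theta0 <- bb$theta0_deg * pi / 180
  turn <- (pi - theta0) / 2
  ca_all <- matrix(0, n + 1, 3)
  for (i in seq_len(n)) {
    phi <- turn * (-1)^i
    ca_all[i + 1, ] <- ca_all[i, ] + b * c(cos(phi), sin(phi), 0)
  }
  ca <- ca_all[1:n, , drop = FALSE]
  cb <- t(vapply(seq_len(n), function(i) {
    .place_cb(ca, i, bb$r_ca_cb, c(0, 0, -1))
  }, numeric(3)))
  o <- t(vapply(seq_len(n), function(i) {
    .place_o(ca_all[i, ], ca_all[i + 1, ], bb$r_ca_o, bb$r_o_ca, c(0, 0, 1))
  }, numeric(3)))
  .write_fixture_pdb(file, seq1, ca, cb, o)
}

#' Exactly-sampled double-well umbrella dataset with analytic ground truth
#'
#' Draws per-window samples from the Boltzmann distribution of a quartic
#' double-well potential plus each window's harmonic bias by inverse-CDF
#' sampling on a fine grid, and attaches the analytic unbiased free-energy
#' profile. The analytic profile is the oracle against which the MBAR/WHAM
#' estimators are validated.
#'
#' @param well_sep distance between the two minima (A)
#' @param barrier barrier height at the midpoint (kcal/mol)
#' @param temperature simulation temperature (K)
#' @param windows a [make_windows()] grid supplying bias centers and k
#' @param n_per_window samples drawn per window
#' @param seed RNG seed (same seed, same dataset)
#' @param center midpoint between the wells (A)
#' @param n_grid grid resolution for the inverse-CDF draw
#' @return list with `samples` (window, rg0, k, rg), `potential`,
#'   `analytic_pmf(centers)` in kBT units (minimum zero),
#'   `analytic_gamma(cutoff)`, and `temperature`
#' @export
make_double_well_samples <- function(well_sep = 6, barrier = 3,
                                     temperature = 300,
                                     windows = make_windows(),
                                     n_per_window = 200, seed = 1,
                                     center = 19.5, n_grid = 4001) {
  if (temperature <= 0) stop("temperature must be positive")
  if (n_per_window < 1) stop("n_per_window must be positive")
  kBT <- .kB * temperature
  d <- well_sep / 2
  U <- function(x) barrier * ((x - center)^2 - d^2)^2 / d^4
  lo <- min(windows$rg0) - 1.5
  hi <- max(windows$rg0) + 1.5
  xs <- seq(lo, hi, length.out = n_grid)
  u0 <- U(xs)
  set.seed(seed)
  out <- vector("list", nrow(windows))
  ranges <- matrix(0, nrow(windows), 2)
  for (w in seq_len(nrow(windows))) {
    lp <- -(u0 + 0.5 * windows$k[w] * (xs - windows$rg0[w])^2) / kBT
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    x <- sample(xs, n_per_window, replace = TRUE, prob = p)
    cdf <- cumsum(p)
    ranges[w, ] <- c(xs[max(1, findInterval(0.005, cdf))],
                     xs[min(n_grid, findInterval(0.995, cdf) + 1)])
    out[[w]] <- data.frame(window = w, rg0 = windows$rg0[w],
                           k = windows$k[w], rg = x)
  }
  ord <- order(windows$rg0)
  for (a in seq_len(length(ord) - 1)) {
    i <- ord[a]; j <- ord[a + 1]
    if (ranges[j, 1] >= ranges[i, 2]) {
      stop(sprintf(
        "zero-overlap configuration: windows at rg0 = %.2f and %.2f do not overlap",
        windows$rg0[i], windows$rg0[j]))
    }
  }
  analytic_pmf <- function(centers, bin_width = NULL) {
    if (is.null(bin_width)) bin_width <- diff(centers[1:2])
    fe <- vapply(centers, function(cc) {
      g <- seq(cc - bin_width / 2, cc + bin_width / 2, length.out = 101)
      -log(mean(exp(-U(g) / kBT)) * bin_width)
    }, numeric(1))
    fe - min(fe)
  }
  analytic_gamma <- function(cutoff = 18.5) {
    g <- seq(lo, hi, length.out = 20001)
    p <- exp(-U(g) / kBT)
    sum(p[g < cutoff]) / sum(p[g >= cutoff])
  }
  list(samples = do.call(rbind, out), potential = U,
       analytic_pmf = analytic_pmf, analytic_gamma = analytic_gamma,
       temperature = temperature)
}

#' Perturbed copies of a base structure as a toy memory set
#'
#' Emulates, at toy scale, a memory library's spread of compactness: each copy
#' is isotropically rescaled about its center of mass and jittered with
#' Gaussian noise.
#'
#' @param base a `cg_chain`
#' @param n_memories number of copies
#' @param noise per-coordinate Gaussian noise (A); 0 gives exact copies
#' @param scale_spread half-width of the isotropic scaling range; copies are
#'   scaled by factors in `1 +/- scale_spread`
#' @param seed RNG seed
#' @return list of `cg_chain` objects
#' @export
make_mini_memory_set <- function(base, n_memories = 5, noise = 0.25,
                                 scale_spread = 0, seed = 1) {
  stopifnot(inherits(base, "cg_chain"))
  set.seed(seed)
  scales <- if (n_memories == 1) 1 else
    seq(1 - scale_spread, 1 + scale_spread, length.out = n_memories)
  lapply(seq_len(n_memories), function(m) {
    ch <- base
    com <- colMeans(ch$coords)
    ch$coords <- sweep(sweep(ch$coords, 2, com), 1, rep(scales[m], nrow(ch$coords)), `*`)
    ch$coords <- sweep(ch$coords, 2, -com)
    if (noise > 0) {
      ch$coords <- ch$coords + matrix(rnorm(length(ch$coords), sd = noise),
                                      ncol = 3)
    }
    ch$id <- sprintf("mem%02d", m)
    ch
  })
}
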