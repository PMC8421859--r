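# Shared helpers: quick chains, a synthetic calmodulin-like scaffold, and a
# central-finite-difference force checker.

helix_chain <- function(n = 12, sequence = NULL) {
  build_cg_from_pdb(make_ideal_helix(n, sequence = sequence))
}

extended_chain <- function(n = 12, sequence = NULL) {
  build_cg_from_pdb(make_extended_chain(n, sequence = sequence))
}

# 148-residue scaffold whose four EF-hand loops carry the calcium-loop
# sequences at their reference positions; everything else is alanine. A
# synthetic stand-in for a full-length structure: the loop chemistry is what
# the calcium charge model consumes.
cam_scaffold_sequence <- function() {
  s <- rep("A", 148)
  loops <- utils::read.table(
    system.file("extdata", "cam_loops.tsv", package = "cgcam"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  for (l in seq_len(nrow(loops))) {
    s[loops$start[l]:loops$end[l]] <- strsplit(loops$sequence[l], "")[[1]]
  }
  paste(s, collapse = "")
}

cam_scaffold_chain <- function() {
  assign_default_charges(
    build_cg_from_pdb(make_extended_chain(148, cam_scaffold_sequence())))
}

# maximum-norm relative error between analytic forces and central finite
# differences of the energy
force_fd_error <- function(energy_fn, coords, h = 1e-5) {
  r <- energy_fn(coords)
  fn <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) {
    for (q in 1:3) {
      xp <- coords; xp[i, q] <- xp[i, q] + h
      xm <- coords; xm[i, q] <- xm[i, q] - h
      fn[i, q] <- -(energy_fn(xp)$energy - energy_fn(xm)$energy) / (2 * h)
    }
  }
  max(abs(r$forces - fn)) / max(max(abs(r$forces)), 1e-8)
}

random_rigid_transform <- function(coords, seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- rnorm(3, sd = 5)
  sweep(coords %*% R, 2, -tr)
}

two_bead_chain <- function(r = 4, mass = 100) {
  structure(list(
    sequence = c("A", "A"), n_res = 2,
    coords = rbind(c(0, 0, 0), c(r, 0, 0)),
    bead_res = 1:2, bead_type = c("CA", "CA"), ca_idx = 1:2,
    cb_idx = c(NA_integer_, NA_integer_), o_idx = c(NA_integer_, NA_integer_),
    masses = c(mass, mass), charges = c(0, 0), default_charges = NULL,
    resno = 1:2, mass_mode = "uniform", applied_loops = integer(0),
    restraints = list()), class = "cg_chain")
}

harmonic_pair_ff <- function(k = 20, r0 = 4) {
  function(x) {
    d <- x[2, ] - x[1, ]
    r <- sqrt(sum(d^2))
    u <- d / r
    g <- k * (r - r0)
    f <- rbind(g * u, -g * u)
    list(energy = 0.5 * k * (r - r0)^2, forces = f)
  }
}
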