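ff <- default_forcefield()

test_that("a chain at the ideal internal geometry has vanishing connectivity and angle energy", {
  ch <- build_cg_from_pdb(make_ideal_geometry_chain(10, ff))
  e <- v_backbone(ch, ff)
  # PDB coordinates are rounded to 0.001 A, so "zero" means < 1e-3 kcal/mol
  expect_lt(e$terms[["v_con"]], 1e-3)
  expect_lt(e$terms[["v_chain"]], 1e-3)
})

test_that("overlapping beads are repelled and separated beads are not", {
  ch <- helix_chain(6)
  x <- ch$coords
  x[ch$ca_idx[5], ] <- x[ch$ca_idx[1], ]       # residues 1 and 5 collide
  e <- ff_energy(ch, ff, terms = "excl", coords = x)
  expect_gt(e$energy, 0)
  xfar <- ch$coords * 20                       # everything beyond any cutoff
  efar <- ff_energy(ch, ff, terms = c("excl", "contact"), coords = xfar)
  expect_equal(efar$terms[["v_contact"]], 0, tolerance = 1e-10)
  expect_equal(efar$terms[["v_excl"]], 0)
})

test_that("backbone energy rejects chains shorter than three residues", {
  expect_error(v_backbone(two_bead_chain(), ff), "at least 3")
})

test_that("analytic forces match central finite differences for every term", {
  set.seed(42)
  seqs <- c("ADKLGEMRFVQW", "DDEEKKRRGGSS")
  terms <- c("con", "chain", "chi", "rama", "excl", "contact", "burial",
             "beta", "pap", "helical", "dh")
  ffp <- default_forcefield("physical")   # large DH cutoff so charges interact
  for (s in seqs) {
    ch <- assign_default_charges(build_cg_from_pdb(make_ideal_helix(12, s)))
    x0 <- ch$coords + matrix(rnorm(length(ch$coords), sd = 0.3), ncol = 3)
    for (tm in terms) {
      err <- force_fd_error(function(x) ff_energy(ch, ffp, terms = tm,
                                                  coords = x), x0)
      expect_lt(err, 1e-5, label = paste("force error for", tm, "on", s))
    }
  }
})

test_that("every term is invariant under rigid rotation and translation", {
  set.seed(7)
  ch <- assign_default_charges(
    build_cg_from_pdb(make_ideal_helix(14, "ADKLGEMRFVQWDE")))
  ffp <- default_forcefield("physical")
  e0 <- ff_energy(ch, ffp)
  for (seed in 1:3) {
    xr <- random_rigid_transform(ch$coords, seed)
    er <- ff_energy(ch, ffp, coords = xr)
    for (nm in names(e0$terms)) {
      expect_equal(er$terms[[nm]], e0$terms[[nm]], tolerance = 1e-8,
                   label = paste("isometry of", nm))
    }
  }
})

test_that("the screened Coulomb energy matches the closed form", {
  ch <- build_cg_from_pdb(make_extended_chain(3, "DAK"))
  ch <- assign_default_charges(ch)
  # move the two charged beads to exactly 5 A apart, far from others
  x <- ch$coords
  i <- ch$cb_idx[1]; j <- ch$cb_idx[3]
  x[i, ] <- c(0, 50, 0); x[j, ] <- c(5, 50, 0)
  cfg <- electrostatics_config(epsr = 80, l_D = 78.74, cutoff = Inf,
                               shift = FALSE)
  e <- v_debye_huckel(ch, cfg, coords = x)
  oracle <- 332.24 * (-1) / (80 * 5) * exp(-5 / 78.74)
  expect_equal(e$energy, oracle, tolerance = 1e-12)
})

test_that("like charges repel and the interaction decays with distance", {
  ch <- assign_default_charges(build_cg_from_pdb(make_extended_chain(3, "DAD")))
  cfg <- electrostatics_config(cutoff = Inf, shift = FALSE)
  e1 <- v_debye_huckel(ch, cfg)
  expect_gt(e1$energy, 0)
  x2 <- ch$coords * 2
  e2 <- v_debye_huckel(ch, cfg, coords = x2)
  expect_lt(abs(e2$energy), abs(e1$energy))
})

test_that("V_DH scales linearly in K_Elec and charges, inversely in eps_r", {
  ch <- assign_default_charges(
    build_cg_from_pdb(make_extended_chain(6, "DKDKEK")))
  base <- electrostatics_config(cutoff = Inf, shift = FALSE)
  e0 <- v_debye_huckel(ch, base)$energy
  e2k <- v_debye_huckel(ch, electrostatics_config(cutoff = Inf, shift = FALSE,
                                                  kelec = 2 * 332.24))$energy
  expect_equal(e2k, 2 * e0, tolerance = 1e-12)
  ehalf <- v_debye_huckel(ch, electrostatics_config(epsr = 40, cutoff = Inf,
                                                    shift = FALSE))$energy
  expect_equal(ehalf, 2 * e0, tolerance = 1e-12)
  chq <- ch; chq$charges <- 2 * ch$charges
  e4 <- v_debye_huckel(chq, base)$energy
  expect_equal(e4, 4 * e0, tolerance = 1e-12)
})

test_that("invalid electrostatics parameters are rejected", {
  expect_error(electrostatics_config(epsr = 0), "dielectric")
  expect_error(electrostatics_config(l_D = -1), "Debye length")
  expect_error(electrostatics_config(cutoff = 0), "cutoff")
})

test_that("energies are continuous when a pair crosses the cutoff", {
  ch <- assign_default_charges(build_cg_from_pdb(make_extended_chain(3, "DAK")))
  cfg <- electrostatics_config(cutoff = 10, shift = TRUE)
  x <- ch$coords
  i <- ch$cb_idx[1]; j <- ch$cb_idx[3]
  x[i, ] <- c(0, 30, 0)
  # straddle the cutoff tightly so the smooth slope contributes ~1e-10 and
  # any discontinuity would dominate
  xa <- x; xa[j, ] <- c(10 + 1e-9, 30, 0)
  xb <- x; xb[j, ] <- c(10 - 1e-9, 30, 0)
  ea <- v_debye_huckel(ch, cfg, coords = xa)$energy
  eb <- v_debye_huckel(ch, cfg, coords = xb)$energy
  expect_lt(abs(ea - eb), 1e-8)
  # without the shift the crossing is a genuine jump
  cfg2 <- electrostatics_config(cutoff = 10, shift = FALSE)
  ea2 <- v_debye_huckel(ch, cfg2, coords = xa)$energy
  eb2 <- v_debye_huckel(ch, cfg2, coords = xb)$energy
  expect_gt(abs(ea2 - eb2), 1e-8)
})

test_that("the helical term favors the ideal helix over the extended chain", {
  hel <- helix_chain(12)
  ext <- extended_chain(12)
  eh <- ff_energy(hel, ff, terms = "helical")$terms[["v_helical"]]
  ee <- ff_energy(ext, ff, terms = "helical")$terms[["v_helical"]]
  expect_lt(eh, ee)
})

test_that("glycine contributes no chirality term and no Cbeta interactions", {
  chg <- build_cg_from_pdb(make_ideal_helix(8, "AAAGAAAA"))
  cha <- build_cg_from_pdb(make_ideal_helix(8, "AAAAAAAA"))
  sg <- cgcam:::ff_spec(chg, ff)
  sa <- cgcam:::ff_spec(cha, ff)
  expect_equal(length(sg$chis$a), length(sa$chis$a) - 1)
  expect_false(chg$ca_idx[4] %in% sg$chis$b)
  # glycine's contact site falls back to its Calpha
  expect_equal(sg$contact$site[4], chg$ca_idx[4])
})

test_that("the total energy is the component sum and the forces add", {
  set.seed(13)
  ch <- assign_default_charges(
    build_cg_from_pdb(make_ideal_helix(12, "ADKLGEMRFVQW")))
  x <- ch$coords + matrix(rnorm(length(ch$coords), sd = 0.2), ncol = 3)
  tot <- total_energy(ch, ff, coords = x)
  expect_equal(tot$v_total, sum(tot$terms), tolerance = 1e-10)
  fsum <- 0
  esum <- 0
  for (tm in ff$terms) {
    r <- ff_energy(ch, ff, terms = tm, coords = x)
    fsum <- fsum + r$forces
    esum <- esum + r$energy
  }
  expect_equal(esum, tot$v_total, tolerance = 1e-10)
  expect_equal(fsum, tot$forces, tolerance = 1e-8)
})

test_that("disabling all terms but an uncharged DH gives zero energy", {
  ch <- helix_chain(6)   # no charges assigned: all zero
  ch$default_charges <- ch$charges
  ffd <- default_forcefield(terms = "dh")
  e <- total_energy(ch, ffd)
  expect_identical(e$v_total, 0)
})

test_that("the ionic-strength route reproduces the aqueous Debye length", {
  # 150 mM 1:1 salt in water at 300 K screens over roughly 8 A
  cfg <- electrostatics_config(ionic_strength = 0.15, temperature = 300)
  expect_equal(1 / cfg$kappa, 7.9, tolerance = 0.1)
})
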