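test_that("radius of gyration handles the elementary cases", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  # symmetric dumbbell: two unit masses 2 A apart
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  expect_error(radius_of_gyration(matrix(numeric(0), 0, 3)), "empty")
  expect_error(radius_of_gyration(rbind(c(0, 0, 0)), masses = -1), "positive")
  # mass weighting: all mass on one particle collapses Rg to that particle
  rg <- radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)),
                           masses = c(1e9, 1))
  expect_lt(rg, 1e-3)
})

test_that("Rg is isometry-invariant and scales linearly with coordinates", {
  ch <- helix_chain(15)
  rg0 <- rg_chain(ch)
  for (seed in 1:3) {
    xr <- random_rigid_transform(ch$coords, seed)
    expect_equal(rg_chain(ch, coords = xr), rg0, tolerance = 1e-10)
  }
  expect_equal(rg_chain(ch, coords = ch$coords * 2.5), 2.5 * rg0,
               tolerance = 1e-10)
})

test_that("all-atom PDB Rg agrees with an independent mass-weighted computation", {
  f <- make_ideal_helix(20, "ADKLGEMRFVQWADKLGEMR")
  pdb <- bio3d::read.pdb(f, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  # independent mass assignment: beads here are only C and O atoms
  m <- ifelse(bio3d::atom2ele(at$elety) == "O", 15.9994, 12.0107)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  com <- colSums(xyz * m) / sum(m)
  oracle <- sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  expect_equal(rg_pdb(f), oracle, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(rg_pdb(f), rg_pdb(f, mode = "calpha"))))
})

test_that("Qw of a structure against itself is exactly 1", {
  for (n in c(10, 20, 37)) {
    ch <- helix_chain(n)
    expect_identical(qw(ch, ch), 1)
  }
  # strict-as-printed pair set over-counts and exceeds 1 on self-comparison
  ch <- helix_chain(20)
  expect_gt(qw(ch, ch, strict = TRUE), 1)
})

test_that("Qw decays to zero for grossly perturbed structures and is isometric", {
  ch <- helix_chain(16)
  ext <- extended_chain(16)
  q <- qw(ext, ch)
  expect_gt(q, 0)
  expect_lt(q, 1)
  # perturb all pairwise distances by ~100 sigma: similarity vanishes
  far <- ch$coords[ch$ca_idx, ] * 60
  expect_lt(qw(far, ch), 1e-6)
  for (seed in 4:6) {
    xr <- random_rigid_transform(ext$coords, seed)
    expect_equal(qw(ext$coords[ext$ca_idx, , drop = FALSE],
                    ch)[1],
                 qw(xr[ext$ca_idx, , drop = FALSE], ch), tolerance = 1e-10)
  }
  expect_error(qw(helix_chain(10), helix_chain(12)), "differ in length")
})

test_that("the collapsed/extended classification uses a strict 18.5 A threshold", {
  expect_identical(classify_conformation(15), "collapsed")
  expect_identical(classify_conformation(18.5), "extended")
  expect_identical(classify_conformation(22), "extended")
  expect_identical(classify_conformation(c(14, 18.49, 18.5, 30)),
                   c("collapsed", "collapsed", "extended", "extended"))
  expect_error(classify_conformation(NaN), "finite")
})

test_that("statistical inefficiency is 1 for white noise and > 1 for correlated series", {
  set.seed(61)
  expect_lt(statistical_inefficiency(rnorm(5000)), 1.3)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 5000))
  g <- statistical_inefficiency(ar)
  expect_gt(g, 5)    # theory: (1+rho)/(1-rho) = 19
  expect_lt(g, 40)
})

test_that("a single unrestrained window reduces to the histogram estimate", {
  set.seed(71)
  x <- rnorm(4000, mean = 20, sd = 1)
  s <- data.frame(window = 0, rg0 = 20, k = 0, rg = x)
  pm <- estimate_pmf(s, temperature = 300, bin_width = 0.25, n_boot = 10)
  h <- hist(x, breaks = seq(min(pm$table$bin) - 0.125,
                            max(pm$table$bin) + 0.125, by = 0.25),
            plot = FALSE)
  fh <- -log(h$counts / sum(h$counts))
  fh <- fh - min(fh[is.finite(fh)])
  ok <- is.finite(pm$table$f) & is.finite(fh)
  expect_equal(pm$table$f[ok], fh[ok], tolerance = 1e-6)
})

test_that("disjoint neighboring windows raise an error naming the gap", {
  set.seed(81)
  s <- rbind(
    data.frame(window = 0, rg0 = 10, k = 100, rg = rnorm(200, 10, 0.05)),
    data.frame(window = 1, rg0 = 20, k = 100, rg = rnorm(200, 20, 0.05)))
  expect_error(estimate_pmf(s), "disjoint.*10\\.00.*20\\.00")
  s$rg[s$rg < 15] <- NA
  expect_error(estimate_pmf(s), "non-finite")
})

test_that("MBAR recovers an analytic double-well profile within 2 SE", {
  dw <- make_double_well_samples(well_sep = 5, barrier = 2, temperature = 300,
                                 windows = make_windows(15, 24, 0.5, k = 20),
                                 n_per_window = 400, seed = 101)
  pm <- estimate_pmf(dw$samples, temperature = 300, bin_width = 0.5,
                     n_boot = 30)
  fa <- dw$analytic_pmf(pm$table$bin, 0.5)
  ok <- is.finite(pm$table$f)
  z <- abs(pm$table$f[ok] - fa[ok]) / pmax(pm$table$se[ok], 1e-3)
  expect_lt(max(z), 2)
  # the recovered ratio matches the analytic Boltzmann ratio
  ga <- dw$analytic_gamma(18.5)
  expect_lt(abs(pm$gamma_ce - ga), 2 * pmax(pm$gamma_se, 0.05))
})

test_that("doubling the sample count shrinks the mean standard error", {
  w <- make_windows(15, 24, 0.5, k = 20)
  dw1 <- make_double_well_samples(windows = w, n_per_window = 150, seed = 5)
  dw2 <- make_double_well_samples(windows = w, n_per_window = 600, seed = 5)
  p1 <- estimate_pmf(dw1$samples, n_boot = 25, bin_width = 0.5)
  p2 <- estimate_pmf(dw2$samples, n_boot = 25, bin_width = 0.5)
  expect_lt(mean(p2$table$se, na.rm = TRUE), mean(p1$table$se, na.rm = TRUE))
})

test_that("MBAR and WHAM agree within their joint uncertainties", {
  dw <- make_double_well_samples(well_sep = 5, barrier = 2, temperature = 300,
                                 windows = make_windows(15, 24, 0.5, k = 20),
                                 n_per_window = 400, seed = 102)
  pm <- estimate_pmf(dw$samples, n_boot = 25, bin_width = 0.5)
  pw <- estimate_pmf(dw$samples, n_boot = 25, bin_width = 0.5,
                     estimator = "wham")
  sh <- is.finite(pm$table$f) & is.finite(pw$table$f)
  z <- abs(pm$table$f[sh] - pw$table$f[sh]) /
    sqrt(pm$table$se[sh]^2 + pw$table$se[sh]^2 + 1e-4)
  expect_lt(max(z), 2)
})

test_that("PMF observables agree with direct weighted histograms on unbiased samples", {
  set.seed(91)
  x <- sample(c(rnorm(3000, 16, 0.8), rnorm(6000, 21, 0.8)))
  s <- data.frame(window = 0, rg0 = 0, k = 0, rg = x)
  pm <- estimate_pmf(s, n_boot = 10)
  direct_gamma <- sum(x < 18.5) / sum(x >= 18.5)
  expect_equal(pm$gamma_ce, direct_gamma, tolerance = 0.05)
  expect_equal(pm$rg_mean, mean(x), tolerance = 0.05)
})

test_that("ensemble observables follow from the bin probabilities", {
  tab <- data.frame(bin = c(15, 22), p = c(0.5, 0.5))
  ob <- ensemble_observables(tab)
  expect_equal(ob$rg_mean, 18.5)
  expect_equal(ob$gamma_ce, 1)

  tab2 <- data.frame(bin = c(15, 21.5), p = c(0.1, 0.9))
  ob2 <- ensemble_observables(tab2)
  expect_equal(ob2$gamma_ce, 1 / 9, tolerance = 1e-12)
  expect_equal(ob2$rg_mean, 20.85)

  # all mass extended: ratio 0; all mass collapsed: flagged Inf
  expect_equal(ensemble_observables(data.frame(bin = 22, p = 1))$gamma_ce, 0)
  obinf <- ensemble_observables(data.frame(bin = 15, p = 1))
  expect_identical(obinf$gamma_ce, Inf)
  expect_identical(attr(obinf, "flag"), "zero-extended-population")
})

test_that("classification plus ratio reproduces exact counts on hand-built frames", {
  rg <- c(14, 15, 18.4, 18.5, 19, 22, 25)
  cls <- classify_conformation(rg)
  expect_equal(sum(cls == "collapsed"), 3)
  expect_equal(sum(cls == "extended"), 4)
  expect_equal(sum(cls == "collapsed") / sum(cls == "extended"), 0.75)
})

test_that("PMF files are written with their summary", {
  dw <- make_double_well_samples(windows = make_windows(17, 22, 1, k = 10),
                                 n_per_window = 100, seed = 3)
  pm <- estimate_pmf(dw$samples, n_boot = 5, bin_width = 1)
  pre <- tempfile()
  out <- write_pmf(pm, pre)
  expect_true(all(file.exists(out)))
  tab <- utils::read.table(out[1], header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(pm$table))
  js <- jsonlite::read_json(out[2])
  expect_equal(js$rg_mean, pm$rg_mean, tolerance = 1e-10)
})
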