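#' Mass-weighted radius of gyration
#'
#' `Rg = sqrt( sum_i m_i |r_i - r_com|^2 / sum_i m_i )`. Unit masses are
#' used when `masses` is `NULL`.
#'
#' @param coords n x 3 coordinate matrix (A)
#' @param masses particle masses (positive); default unit masses
#' @return Rg (A)
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- rbind(coords)
  if (nrow(coords) == 0) stop("empty coordinate set")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (length(masses) != nrow(coords)) stop("one mass per particle required")
  if (any(masses <= 0)) stop("masses must be positive")
  com <- colSums(coords * masses) / sum(masses)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Coarse-grained radius of gyration of a chain
#'
#' Uses the Calpha beads only, with their masses.
#'
#' @param chain a `cg_chain`
#' @param coords optional coordinates overriding `chain$coords`
#' @return Rg (A)
#' @export
rg_chain <- function(chain, coords = NULL) {
  stopifnot(inherits(chain, "cg_chain"))
  if (is.null(coords)) coords <- chain$coords
  radius_of_gyration(coords[chain$ca_idx, , drop = FALSE],
                     chain$masses[chain$ca_idx])
}

#' All-atom radius of gyration of a PDB structure
#'
#' Protein atoms only (waters and ions excluded), weighted by standard
#' atomic masses; hydrogens are included when the file resolves them.
#'
#' @param pdb path to a PDB file or a `bio3d` pdb object
#' @param mode `"all-atom"` or `"calpha"`
#' @return Rg (A)
#' @export
rg_pdb <- function(pdb, mode = c("all-atom", "calpha")) {
  mode <- match.arg(mode)
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  sel <- if (mode == "all-atom") bio3d::atom.select(pdb, "protein") else
    bio3d::atom.select(pdb, "calpha")
  at <- pdb$atom[sel$atom, , drop = FALSE]
  if (nrow(at) == 0) stop("no protein atoms found")
  ele <- bio3d::atom2ele(at$elety, rescue = TRUE)
  tabenv <- new.env()
  utils::data("elements", package = "bio3d", envir = tabenv)
  masses <- tabenv$elements$mass[match(ele, tabenv$elements$symb)]
  if (anyNA(masses)) stop("unknown element(s): ",
                          paste(unique(ele[is.na(masses)]), collapse = ", "))
  radius_of_gyration(as.matrix(at[, c("x", "y", "z")]), masses)
}

.ca_coords <- function(x) {
  if (inherits(x, "cg_chain")) x$coords[x$ca_idx, , drop = FALSE] else
    as.matrix(x)
}

#' Qw pairwise structural similarity
#'
#' `Qw = 2/((N-2)(N-3)) * sum_pairs exp(-(r_ij - r_ij^ref)^2 /
#' (2 sigma_ij^2))` over Calpha pair distances, with
#' `sigma_ij = (1 + |i-j|)^0.15`. Under the default pair convention
#' (sequence separation >= 3) the normalization is exact and a structure
#' compared against itself gives exactly 1. `strict = TRUE` uses the
#' separation >= 2 pair set with the same prefactor (self-comparison then
#' exceeds 1).
#'
#' @param x a `cg_chain` or Calpha coordinate matrix
#' @param reference reference `cg_chain` or Calpha coordinate matrix of the
#'   same length
#' @param strict use the separation >= 2 pair set
#' @return Qw (dimensionless, in (0, 1] under the default convention)
#' @export
qw <- function(x, reference, strict = FALSE) {
  a <- .ca_coords(x); b <- .ca_coords(reference)
  n <- nrow(a)
  if (nrow(b) != n) stop("structures differ in length: ", n, " vs ", nrow(b))
  if (n < 4) stop("Qw needs at least 4 residues")
  min_sep <- if (strict) 2L else 3L
  da <- as.matrix(stats::dist(a))
  db <- as.matrix(stats::dist(b))
  idx <- which(upper.tri(da), arr.ind = TRUE)
  sep <- idx[, 2] - idx[, 1]
  keep <- sep >= min_sep
  sig <- (1 + sep[keep])^0.15
  g <- exp(-(da[idx][keep] - db[idx][keep])^2 / (2 * sig^2))
  2 * sum(g) / ((n - 2) * (n - 3))
}

#' Classify a conformation as collapsed or extended
#'
#' Strict threshold: collapsed when `Rg < cutoff` (default 18.5 A),
#' extended otherwise (the boundary value is extended).
#'
#' @param rg radius of gyration (A), vectorized
#' @param cutoff classification threshold (A)
#' @return character vector of `"collapsed"` / `"extended"`
#' @export
classify_conformation <- function(rg, cutoff = 18.5) {
  if (any(!is.finite(rg))) stop("Rg must be finite")
  ifelse(rg < cutoff, "collapsed", "extended")
}

#' Statistical inefficiency of a time series
#'
#' `g = 1 + 2 sum_t (1 - t/N) C(t)` with the normalized autocorrelation
#' summed until it first becomes non-positive. Every `g`-th sample is
#' approximately independent.
#'
#' @param x numeric series
#' @return g (>= 1)
#' @export
statistical_inefficiency <- function(x) {
  n <- length(x)
  if (n < 3 || stats::var(x) == 0) return(1)
  lag_max <- min(n - 1, 1000)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  s <- 0
  for (t in seq_along(rho)) {
    if (rho[t] <= 0) break
    s <- s + (1 - t / n) * rho[t]
  }
  max(1, 1 + 2 * s)
}

# MBAR estimating equations. u: n x K reduced bias matrix, Nk: samples per
# state. A few self-consistent sweeps for stability, then Newton-Raphson on
# the MBAR objective (the self-consistent map alone converges far too slowly
# for many stiff windows). Returns dimensionless free energies f (f[1] = 0)
# and the unbiased sample weights.
.mbar_solve <- function(u, Nk, f0 = NULL, tol = 1e-10, max_iter = 200) {
  K <- ncol(u)
  E <- exp(-u)                      # constant across iterations
  f <- if (is.null(f0)) numeric(K) else f0
  kappa <- function(f) {
    sum(log(as.vector(E %*% (Nk * exp(f))))) - sum(Nk * f)
  }
  for (it in 1:5) {                 # self-consistent warm-up
    denom <- as.vector(E %*% (Nk * exp(f)))
    f <- -log(as.vector(crossprod(E, 1 / denom)))
    f <- f - f[1]
  }
  obj <- kappa(f)
  for (it in seq_len(max_iter)) {
    ef <- exp(f)
    num <- sweep(E, 2, Nk * ef, `*`)          # N_k exp(f_k - u_nk)
    denom <- rowSums(num)
    P <- num / denom                          # n x K responsibilities
    cs <- colSums(P)
    g <- cs - Nk
    H <- diag(cs, K) - crossprod(P)
    # f[1] is pinned; solve the reduced system
    idx <- 2:K
    step <- numeric(K)
    sol <- tryCatch(solve(H[idx, idx, drop = FALSE], -g[idx]),
                    error = function(e) NULL)
    if (is.null(sol)) {                       # fall back to one SC sweep
      denom <- as.vector(E %*% (Nk * exp(f)))
      fnew <- -log(as.vector(crossprod(E, 1 / denom)))
      fnew <- fnew - fnew[1]
      if (max(abs(fnew - f)) < tol) { f <- fnew; break }
      f <- fnew
      next
    }
    step[idx] <- sol
    alpha <- 1
    repeat {
      fnew <- f + alpha * step
      onew <- kappa(fnew)
      if (is.finite(onew) && onew <= obj + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-6) { fnew <- f; onew <- obj; break }
    }
    delta <- max(abs(fnew - f))
    f <- fnew; obj <- onew
    if (delta < tol) break
  }
  denom <- as.vector(E %*% (Nk * exp(f)))
  w <- (1 / denom)
  list(f = f, w = w / sum(w))
}

.bin_centers <- function(x, bin_width) {
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (length(breaks) < 2) breaks <- c(lo, lo + bin_width)
  breaks
}

# Binned WHAM on the same data; independent of the MBAR route. Stiff
# restraints make the bias vary by several kBT across one reporting bin, so
# the self-consistent equations are solved on a refined internal grid (each
# reporting bin split `refine`-fold, with the bias factor additionally
# averaged within each fine bin) and the probabilities are aggregated back
# to the reporting bins at the end.
.wham_solve <- function(x, win, Nk, kk, rg0, breaks, kBT, tol = 1e-8,
                        max_iter = 50000, f0 = NULL, refine = 5L) {
  h <- diff(breaks[1:2])
  nb0 <- length(breaks) - 1
  fine <- seq(breaks[1], breaks[length(breaks)], by = h / refine)
  fc <- (fine[-1] + fine[-length(fine)]) / 2
  nf <- length(fc)
  K <- length(Nk)
  hist_f <- tabulate(findInterval(x, fine, all.inside = TRUE), nbins = nf)
  hf <- h / refine
  sub <- seq(-hf / 2 + hf / 6, hf / 2 - hf / 6, length.out = 3)
  C <- matrix(0, nf, K)
  for (k in seq_len(K)) {
    acc <- 0
    for (s in sub) acc <- acc + exp(-0.5 * kk[k] * (fc + s - rg0[k])^2 / kBT)
    C[, k] <- acc / length(sub)
  }
  fk <- if (is.null(f0)) numeric(K) else f0
  for (it in seq_len(max_iter)) {
    denom <- as.vector(C %*% (Nk * exp(fk)))
    p <- ifelse(denom > 0, hist_f / denom, 0)
    fnew <- -log(as.vector(crossprod(C, p)))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - fk)) < tol) { fk <- fnew; break }
    fk <- fnew
  }
  denom <- as.vector(C %*% (Nk * exp(fk)))
  p <- ifelse(denom > 0, hist_f / denom, 0)
  agg <- rep(seq_len(nb0), each = refine)[seq_len(nf)]
  pc <- as.vector(tapply(p, agg, sum))
  pc <- pc / sum(pc)
  list(centers = (breaks[-1] + breaks[-length(breaks)]) / 2, p = pc, f0 = fk)
}

.pmf_from_weights <- function(x, w, breaks) {
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin <- findInterval(x, breaks, all.inside = TRUE)
  p <- vapply(seq_along(centers), function(b) sum(w[bin == b]), numeric(1))
  p <- p / sum(p)
  f <- ifelse(p > 0, -log(p), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  list(centers = centers, p = p, f = f)
}

.observables_from_p <- function(centers, p, cutoff) {
  rg_mean <- sum(p * centers)
  pc <- sum(p[centers < cutoff])
  pe <- sum(p[centers >= cutoff])
  gamma <- if (pe <= 0) Inf else pc / pe
  list(rg_mean = rg_mean, gamma = gamma)
}

#' Estimate the free-energy profile from umbrella-sampling data
#'
#' Unbiases the pooled windows with the multistate Bennett acceptance ratio
#' (self-consistent MBAR) or binned WHAM. Samples are decorrelated per
#' window by statistical-inefficiency subsampling before estimation;
#' neighboring windows whose sampled ranges do not overlap raise an error
#' naming the gap. Per-bin standard errors (and errors on the derived
#' observables) come from a bootstrap over the decorrelated samples.
#'
#' @param samples a `cgcam_umbrella` object or data.frame with columns
#'   `window`, `rg0`, `k`, `rg`
#' @param temperature temperature (K) of the sampling
#' @param bin_width reporting bin width (A; default the window spacing 0.25)
#' @param estimator `"mbar"` (default) or `"wham"`
#' @param n_boot bootstrap replicates for the standard errors
#' @param cutoff collapsed/extended threshold (A)
#' @param decorrelate subsample by statistical inefficiency first
#' @return a `cgcam_pmf`: `table` (bin, f in kBT with the minimum at 0, se,
#'   p, p_se), `rg_mean`, `gamma_ce` (collapsed:extended ratio; `Inf` with a
#'   flag when the extended population is empty), overlap diagnostics and
#'   per-window inefficiencies
#' @export
estimate_pmf <- function(samples, temperature = 300, bin_width = 0.25,
                         estimator = c("mbar", "wham"), n_boot = 40,
                         cutoff = 18.5, decorrelate = TRUE) {
  estimator <- match.arg(estimator)
  if (inherits(samples, "cgcam_umbrella")) samples <- samples$samples
  stopifnot(all(c("window", "rg0", "k", "rg") %in% names(samples)))
  if (any(!is.finite(samples$rg))) stop("non-finite values in the Rg series")
  kBT <- .kB * temperature

  wins <- unique(samples[, c("window", "rg0", "k")])
  wins <- wins[order(wins$rg0), ]
  K <- nrow(wins)
  xs <- list(); g <- numeric(K)
  for (k in seq_len(K)) {
    xk <- samples$rg[samples$window == wins$window[k]]
    g[k] <- statistical_inefficiency(xk)
    if (decorrelate && g[k] > 1)
      xk <- xk[seq(1, length(xk), by = max(1L, round(g[k])))]
    xs[[k]] <- xk
  }
  overlap <- NULL
  if (K >= 2) {
    rng <- t(vapply(xs, range, numeric(2)))
    ov <- pmin(rng[-1, 2], rng[-K, 2]) - pmax(rng[-1, 1], rng[-K, 1])
    overlap <- data.frame(left = wins$rg0[-K], right = wins$rg0[-1],
                          overlap = ov)
    if (any(ov <= 0)) {
      i <- which(ov <= 0)[1]
      stop(sprintf(
        "disjoint neighboring windows: no Rg overlap between rg0 = %.2f and rg0 = %.2f",
        wins$rg0[i], wins$rg0[i + 1]))
    }
  }

  x <- unlist(xs)
  Nk <- lengths(xs)
  breaks <- .bin_centers(x, bin_width)
  bias_u <- function(xv) {
    u <- matrix(0, length(xv), K)
    for (k in seq_len(K)) u[, k] <- 0.5 * wins$k[k] * (xv - wins$rg0[k])^2 / kBT
    u
  }

  point <- function(xv, Nkv, f0 = NULL) {
    if (estimator == "mbar") {
      sol <- .mbar_solve(bias_u(xv), Nkv, f0 = f0)
      pm <- .pmf_from_weights(xv, sol$w, breaks)
      pm$f0 <- sol$f
      pm
    } else {
      win_id <- rep(seq_len(K), Nkv)
      sol <- .wham_solve(xv, win_id, Nkv, wins$k, wins$rg0, breaks, kBT,
                         f0 = f0)
      f <- ifelse(sol$p > 0, -log(sol$p), NA_real_)
      list(centers = sol$centers, p = sol$p, f = f - min(f, na.rm = TRUE),
           f0 = sol$f0)
    }
  }

  est <- point(x, Nk)
  obs <- .observables_from_p(est$centers, est$p, cutoff)

  nb <- length(est$centers)
  boot_f <- matrix(NA_real_, n_boot, nb)
  boot_p <- matrix(NA_real_, n_boot, nb)
  boot_rg <- numeric(n_boot); boot_gm <- numeric(n_boot)
  starts <- c(0, cumsum(Nk))
  for (b in seq_len(n_boot)) {
    xb <- unlist(lapply(seq_len(K), function(k) {
      xk <- xs[[k]]
      xk[sample.int(length(xk), replace = TRUE)]
    }))
    eb <- point(xb, Nk, f0 = est$f0)
    boot_f[b, ] <- eb$f
    boot_p[b, ] <- eb$p
    ob <- .observables_from_p(eb$centers, eb$p, cutoff)
    boot_rg[b] <- ob$rg_mean
    boot_gm[b] <- if (is.finite(ob$gamma)) ob$gamma else NA_real_
  }
  se <- apply(boot_f, 2, stats::sd, na.rm = TRUE)
  p_se <- apply(boot_p, 2, stats::sd, na.rm = TRUE)

  gamma <- obs$gamma
  res <- structure(list(
    table = data.frame(bin = est$centers, f = est$f, se = se, p = est$p,
                       p_se = p_se),
    rg_mean = obs$rg_mean, rg_mean_se = stats::sd(boot_rg, na.rm = TRUE),
    gamma_ce = gamma, gamma_se = stats::sd(boot_gm, na.rm = TRUE),
    cutoff = cutoff, temperature = temperature, estimator = estimator,
    bin_width = bin_width, overlap = overlap, inefficiency = g,
    n_samples = Nk), class = "cgcam_pmf")
  if (!is.finite(gamma)) attr(res, "flag") <- "zero-extended-population"
  res
}

#' Ensemble observables from a free-energy profile
#'
#' `Rg_mean = sum_b p_b Rg_b` and the collapsed:extended population ratio
#' `gamma_ce = P(Rg < cutoff) / P(Rg >= cutoff)`. A zero extended
#' population yields `Inf` with a `flag` attribute.
#'
#' @param pmf a `cgcam_pmf`, or a data.frame with columns `bin` and `p`
#' @param cutoff classification threshold (A)
#' @return list with `rg_mean` and `gamma_ce`
#' @export
ensemble_observables <- function(pmf, cutoff = 18.5) {
  if (inherits(pmf, "cgcam_pmf")) {
    tab <- pmf$table
    if (missing(cutoff)) cutoff <- pmf$cutoff
  } else tab <- pmf
  stopifnot(all(c("bin", "p") %in% names(tab)))
  p <- tab$p / sum(tab$p)
  ob <- .observables_from_p(tab$bin, p, cutoff)
  out <- list(rg_mean = ob$rg_mean, gamma_ce = ob$gamma)
  if (!is.finite(ob$gamma)) attr(out, "flag") <- "zero-extended-population"
  out
}

#' @export
print.cgcam_pmf <- function(x, ...) {
  cat(sprintf(
    "cgcam_pmf (%s): %d bins of %.2f A, T = %g K\n",
    x$estimator, nrow(x$table), x$bin_width, x$temperature))
  cat(sprintf("  Rg_mean = %.2f A,  gamma_c:e = %s (cutoff %.1f A)\n",
              x$rg_mean,
              if (is.finite(x$gamma_ce)) sprintf("%.3f", x$gamma_ce) else
                "Inf (no extended population)", x$cutoff))
  invisible(x)
}

#' Plot a free-energy profile
#'
#' Two panels: the free energy (kBT, with bootstrap error bars) and the
#' normalized probability as functions of Rg; the collapse cutoff is marked.
#'
#' @param x a `cgcam_pmf`
#' @param ... unused
#' @export
plot.cgcam_pmf <- function(x, ...) {
  tab <- x$table
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  ok <- is.finite(tab$f)
  graphics::plot(tab$bin[ok], tab$f[ok], type = "b", pch = 16, cex = 0.6,
                 xlab = "Rg (A)", ylab = "F (kBT)")
  graphics::arrows(tab$bin[ok], tab$f[ok] - tab$se[ok], tab$bin[ok],
                   tab$f[ok] + tab$se[ok], angle = 90, code = 3,
                   length = 0.02, col = "grey40")
  graphics::abline(v = x$cutoff, lty = 2, col = "red3")
  graphics::plot(tab$bin, tab$p, type = "h", lwd = 3, col = "steelblue",
                 xlab = "Rg (A)", ylab = "p")
  graphics::abline(v = x$cutoff, lty = 2, col = "red3")
  invisible(x)
}

#' Write a free-energy profile and its summary to disk
#'
#' Emits `<prefix>_pmf.tsv` (bin, free energy, stderr, probability) and
#' `<prefix>_summary.json` (Rg_mean, gamma_ce, cutoff, estimator settings);
#' both are written atomically.
#'
#' @param pmf a `cgcam_pmf`
#' @param prefix output path prefix
#' @return the two file paths, invisibly
#' @export
write_pmf <- function(pmf, prefix) {
  stopifnot(inherits(pmf, "cgcam_pmf"))
  tsv <- paste0(prefix, "_pmf.tsv")
  js <- paste0(prefix, "_summary.json")
  .atomic_write(tsv, function(f) {
    utils::write.table(pmf$table, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  })
  .atomic_write(js, function(f) {
    writeLines(jsonlite::toJSON(list(
      rg_mean = pmf$rg_mean, rg_mean_se = pmf$rg_mean_se,
      gamma_ce = if (is.finite(pmf$gamma_ce)) pmf$gamma_ce else "Inf",
      gamma_se = pmf$gamma_se, cutoff = pmf$cutoff,
      temperature = pmf$temperature, estimator = pmf$estimator,
      bin_width = pmf$bin_width, n_samples = pmf$n_samples),
      auto_unbox = TRUE, digits = NA), f)
  })
  invisible(c(tsv, js))
}
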