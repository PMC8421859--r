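#' Electrostatics configuration for the Debye-Hueckel term
#'
#' The screened Coulomb interaction between charged sidechain beads,
#' `V_DH = K_Elec sum_{i<j} q_i q_j / (eps_r r_ij) exp(-r_ij / l_D)`,
#' with `K_Elec = 332.24 kcal mol^-1 e^-2 A`. The screening can be given as
#' the inverse Debye length `kappa` (default 0.0127 A^-1), as the Debye
#' length `l_D`, or derived from an ionic strength and temperature.
#'
#' @param epsr relative dielectric constant (> 0)
#' @param kappa inverse Debye length (1/A)
#' @param l_D Debye length (A); overrides `kappa`
#' @param cutoff nonbonded cutoff (A); the literal protocol value is 3.5 A,
#'   `Inf` disables the cutoff
#' @param shift subtract the value at the cutoff so the energy is continuous
#' @param kelec Coulomb constant (kcal mol^-1 e^-2 A)
#' @param ionic_strength molar ionic strength of a 1:1 salt; used with
#'   `temperature` to derive `l_D` when neither `kappa` nor `l_D` is given
#' @param temperature temperature (K) for the ionic-strength derivation
#' @return an `electrostatics_config`
#' @export
electrostatics_config <- function(epsr = 80, kappa = 0.0127, l_D = NULL,
                                  cutoff = 3.5, shift = TRUE, kelec = 332.24,
                                  ionic_strength = NULL, temperature = 300) {
  if (epsr <= 0) stop("relative dielectric constant must be positive")
  if (!is.null(ionic_strength)) {
    # kappa^2 = 8 pi lambda_B n, lambda_B = K_Elec/(epsr kB T),
    # n = number density of a 1:1 salt at the given molarity
    lambda_b <- kelec / (epsr * .kB * temperature)
    n_dens <- ionic_strength * 6.02214076e-4  # ions per A^3 per mol/L
    kappa <- sqrt(8 * pi * lambda_b * n_dens)
  }
  if (!is.null(l_D)) {
    if (l_D <= 0) stop("Debye length must be positive")
    kappa <- 1 / l_D
  }
  if (kappa < 0) stop("inverse Debye length must be non-negative")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(kelec = kelec, epsr = epsr, kappa = kappa,
                 cutoff = cutoff, shift = shift),
            class = "electrostatics_config")
}

.load_ff_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  kd <- unlist(p$hydrophobicity_kd)[.aa1]
  h <- (kd + 4.5) / 9
  g0 <- p$contact$gamma_g0; g1 <- p$contact$gamma_g1
  gamma <- outer(h, h, function(a, b) g0 + g1 * (a + b) / 2)
  dimnames(gamma) <- list(.aa1, .aa1)
  beta <- cbind(p$burial$beta_scale * (1 - h),
                rep(p$burial$beta_middle, 20),
                p$burial$beta_scale * h)
  rownames(beta) <- .aa1
  p$contact_gamma <- gamma
  p$burial_beta <- beta
  p
}

#' Construct the coarse-grained force field
#'
#' Bundles the backbone, many-body and hydrogen-bond parameter tables with an
#' electrostatics configuration and the periodic-box settings. Two profiles
#' are provided: `"as-printed"` reproduces the protocol constants literally
#' (electrostatic cutoff 3.5 A), `"physical"` extends the cutoff to several
#' Debye lengths (capped at half the box edge, as the minimum-image
#' convention requires).
#'
#' @param profile `"as-printed"` or `"physical"`
#' @param elec an [electrostatics_config()]; built from the profile if `NULL`
#' @param terms character vector of enabled terms, a subset of
#'   `c("con","chain","chi","rama","excl","contact","burial","beta","pap",
#'   "helical","dh","fm")`
#' @param box cubic box edge (A)
#' @param periodic apply the minimum-image convention to nonbonded pairs
#' @param params_file bundled parameter file (JSON)
#' @return a `cg_forcefield`
#' @export
default_forcefield <- function(profile = c("as-printed", "physical"),
                               elec = NULL, terms = NULL, box = 400,
                               periodic = TRUE,
                               params_file = cgcam_file("forcefield",
                                                        "params.json")) {
  profile <- match.arg(profile)
  params <- .load_ff_params(params_file)
  if (is.null(elec)) {
    cutoff <- if (profile == "as-printed") 3.5 else min(4 / 0.0127, box / 2)
    elec <- electrostatics_config(cutoff = cutoff)
  }
  all_terms <- c("con", "chain", "chi", "rama", "excl", "contact", "burial",
                 "beta", "pap", "helical", "dh", "fm")
  if (is.null(terms)) terms <- all_terms
  if (!all(terms %in% all_terms))
    stop("unknown term(s): ", paste(setdiff(terms, all_terms), collapse = ", "))
  structure(list(params = params, elec = elec, box = box, periodic = periodic,
                 terms = terms, fm = NULL, profile = profile),
            class = "cg_forcefield")
}

#' Attach a fragment-memory library and weights to a force field
#'
#' @param ff a `cg_forcefield`
#' @param library a [build_memory_library()] result
#' @param weights a [memory_weights()] or [preset_weights()] object
#' @return the force field with the memory bias attached
#' @export
set_fragment_memory <- function(ff, library, weights) {
  stopifnot(inherits(ff, "cg_forcefield"))
  .check_weights(library, weights)
  ff$fm <- list(library = library, weights = weights)
  if (!"fm" %in% ff$terms) ff$terms <- c(ff$terms, "fm")
  ff
}

# map user-facing term names to compiled-spec keys
.term_key <- c(con = "bonds", chain = "angles", chi = "chis", rama = "ramas",
               excl = "excl", contact = "contact", burial = "burial",
               beta = "beta", pap = "pap", helical = "helical", dh = "dh",
               fm = "fm")

# Assemble the compiled evaluation spec for a chain under a force field.
# Built once per run; the C++ kernels consume it directly.
ff_spec <- function(chain, ff, terms = ff$terms) {
  stopifnot(inherits(chain, "cg_chain"), inherits(ff, "cg_forcefield"))
  p <- ff$params
  bb <- p$backbone
  n <- chain$n_res
  ca <- chain$ca_idx; cb <- chain$cb_idx; o <- chain$o_idx
  spec <- list(box = ff$box, periodic = isTRUE(ff$periodic))

  if ("con" %in% terms) {
    bi <- c(ca[-n], o[-n], ca, ca[!is.na(cb)])
    bj <- c(ca[-1], ca[-1], o, cb[!is.na(cb)])
    r0 <- c(rep(bb$r_ca_ca, n - 1), rep(bb$r_o_ca, n - 1),
            rep(bb$r_ca_o, n), rep(bb$r_ca_cb, sum(!is.na(cb))))
    spec$bonds <- list(i = as.integer(bi), j = as.integer(bj), r0 = r0,
                       k = rep(bb$k_con, length(bi)))
  }
  if ("chain" %in% terms && n >= 3) {
    id <- 2:(n - 1)
    spec$angles <- list(a = as.integer(ca[id - 1]), b = as.integer(ca[id]),
                        c = as.integer(ca[id + 1]), k = bb$k_chain,
                        cos0 = cos(bb$theta0_deg * pi / 180))
  }
  if ("chi" %in% terms) {
    id <- which(!is.na(cb))
    id <- id[id >= 2 & id <= n - 1]
    if (length(id) > 0) {
      spec$chis <- list(a = as.integer(ca[id - 1]), b = as.integer(ca[id]),
                        c = as.integer(ca[id + 1]), d = as.integer(cb[id]),
                        k = bb$k_chi, chi0 = bb$chi0)
    }
  }
  if ("rama" %in% terms && n >= 4) {
    id <- 2:(n - 2)
    spec$ramas <- list(a = as.integer(ca[id - 1]), b = as.integer(ca[id]),
                       c = as.integer(ca[id + 1]), d = as.integer(ca[id + 2]),
                       A = bb$rama$A, phi0 = bb$rama$phi0_deg * pi / 180,
                       kappa = bb$rama$kappa)
  }
  if ("excl" %in% terms) {
    beads <- c(ca, cb[!is.na(cb)])
    res <- c(seq_len(n), which(!is.na(cb)))
    sig <- c(rep(bb$sig_ca, n), rep(bb$sig_cb, sum(!is.na(cb))))
    spec$excl <- list(beads = as.integer(beads), res = as.integer(res),
                      sig = sig, k = bb$k_excl,
                      min_sep = as.integer(bb$excl_min_sep))
  }
  site <- ifelse(is.na(cb), ca, cb)   # Cbeta, Calpha for glycine
  rtype <- as.integer(.aa_index(chain$sequence) - 1L)
  if ("contact" %in% terms) {
    spec$contact <- list(site = as.integer(site), rtype = rtype,
                         gamma = p$contact_gamma, eta = p$contact$eta,
                         rd1 = p$contact$r_direct[1], rd2 = p$contact$r_direct[2],
                         rw1 = p$contact$r_water[1], rw2 = p$contact$r_water[2],
                         wfrac = p$contact$water_fraction,
                         min_sep = as.integer(p$contact$min_sep))
  }
  if ("burial" %in% terms) {
    spec$burial <- list(site = as.integer(site), rtype = rtype,
                        beta = p$burial_beta, lo = p$burial$wells_lo,
                        hi = p$burial$wells_hi, eta_d = p$burial$eta_density,
                        r_d = p$burial$r_density, eta_b = p$burial$eta_burial,
                        min_sep = as.integer(p$burial$min_sep))
  }
  if ("helical" %in% terms && n >= 5) {
    id <- 1:(n - 4)
    spec$helical <- list(i = as.integer(ca[id]), j = as.integer(ca[id + 4]),
                         gamma = p$hbond$helical$gamma, r0 = p$hbond$helical$r0,
                         sigma = p$hbond$helical$sigma)
  }
  if ("beta" %in% terms) {
    spec$beta <- list(ca = as.integer(ca), gamma = p$hbond$beta$gamma,
                      r0 = p$hbond$beta$r0, sigma = p$hbond$beta$sigma,
                      min_sep = as.integer(p$hbond$beta$min_sep))
  }
  if ("pap" %in% terms) {
    spec$pap <- list(ca = as.integer(ca), gamma = p$hbond$pap$gamma,
                     r1 = p$hbond$pap$r1, r2 = p$hbond$pap$r2,
                     eta = p$hbond$pap$eta,
                     min_sep = as.integer(p$hbond$pap$min_sep))
  }
  if ("dh" %in% terms) {
    qi <- which(chain$charges != 0)
    spec$dh <- list(beads = as.integer(qi), q = chain$charges[qi],
                    kelec = ff$elec$kelec, epsr = ff$elec$epsr,
                    kappa = ff$elec$kappa, cutoff = ff$elec$cutoff,
                    shift = isTRUE(ff$elec$shift))
  }
  if ("fm" %in% terms && !is.null(ff$fm)) {
    spec$fm <- .fm_spec(chain, ff$fm$library, ff$fm$weights)
  }
  spec
}

#' Evaluate selected force-field terms
#'
#' @param chain a `cg_chain`
#' @param ff a `cg_forcefield`
#' @param terms terms to evaluate (default: all enabled in `ff`)
#' @param coords optional coordinate matrix overriding `chain$coords`
#' @return list with `terms` (named energies, kcal/mol), `energy` (their sum)
#'   and `forces` (n_beads x 3, kcal/mol/A)
#' @export
ff_energy <- function(chain, ff, terms = ff$terms, coords = NULL) {
  spec <- ff_spec(chain, ff, terms)
  if (is.null(coords)) coords <- chain$coords
  ff_eval_cpp(coords, spec)
}

#' Backbone energy and forces
#'
#' The five backbone sub-terms: connectivity (`v_con`), chain angles
#' (`v_chain`), chirality (`v_chi`, skipped for glycine), Ramachandran bias
#' (`v_rama`) and excluded volume (`v_excl`).
#'
#' @inheritParams ff_energy
#' @return list with the five sub-term energies, their sum and the forces
#' @export
v_backbone <- function(chain, ff = default_forcefield(), coords = NULL) {
  if (chain$n_res < 3) stop("backbone energy needs at least 3 residues")
  ff_energy(chain, ff, terms = c("con", "chain", "chi", "rama", "excl"),
            coords = coords)
}

#' Many-body potential-of-mean-force terms
#'
#' Contact (direct + water-mediated wells), burial (residue-type propensity
#' by local density) and hydrogen-bond (`v_beta`, `v_pap`, `v_helical`)
#' contributions; each is individually toggleable through `terms`.
#'
#' @inheritParams ff_energy
#' @export
v_pmf <- function(chain, ff = default_forcefield(),
                  terms = c("contact", "burial", "beta", "pap", "helical"),
                  coords = NULL) {
  ff_energy(chain, ff, terms = terms, coords = coords)
}

#' Debye-Hueckel electrostatic energy and forces
#'
#' Screened Coulomb sum over distinct charged bead pairs within the cutoff,
#' under the minimum-image convention.
#'
#' @param chain a `cg_chain` with charges assigned
#' @param elec an [electrostatics_config()]
#' @param box cubic box edge (A)
#' @param periodic minimum-image convention
#' @param coords optional coordinates
#' @export
v_debye_huckel <- function(chain, elec = electrostatics_config(), box = 400,
                           periodic = TRUE, coords = NULL) {
  stopifnot(inherits(elec, "electrostatics_config"))
  if (is.null(chain$default_charges))
    stop("assign charges before evaluating electrostatics")
  ff <- structure(list(params = NULL, elec = elec, box = box,
                       periodic = periodic, terms = "dh", fm = NULL),
                  class = "cg_forcefield")
  qi <- which(chain$charges != 0)
  spec <- list(box = box, periodic = isTRUE(periodic),
               dh = list(beads = as.integer(qi), q = chain$charges[qi],
                         kelec = elec$kelec, epsr = elec$epsr,
                         kappa = elec$kappa, cutoff = elec$cutoff,
                         shift = isTRUE(elec$shift)))
  if (is.null(coords)) coords <- chain$coords
  ff_eval_cpp(coords, spec)
}

#' Total energy breakdown
#'
#' Evaluates every enabled term; the total equals the component sum and the
#' per-bead forces are the sum of the component forces.
#'
#' @inheritParams ff_energy
#' @return a `cgcam_energy` list: per-term energies, `v_total`, and `forces`
#' @export
total_energy <- function(chain, ff = default_forcefield(), coords = NULL) {
  r <- ff_energy(chain, ff, coords = coords)
  structure(list(terms = r$terms, v_total = r$energy, forces = r$forces),
            class = "cgcam_energy")
}

#' @export
print.cgcam_energy <- function(x, ...) {
  cat("Energy breakdown (kcal/mol):\n")
  for (nm in names(x$terms)) cat(sprintf("  %-10s %12.4f\n", nm, x$terms[nm]))
  cat(sprintf("  %-10s %12.4f\n", "v_total", x$v_total))
  invisible(x)
}
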