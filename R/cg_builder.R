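#' Build a three-bead coarse-grained chain from a PDB structure
#'
#' Each residue is represented by its Calpha, Cbeta and carbonyl-O atoms
#' (glycine lacks Cbeta). Waters, ions and hetero atoms are excluded; only
#' `ATOM` records of the selected chain are used. Charges are all zero until
#' [assign_default_charges()] is called.
#'
#' @param pdb path to a PDB file, or a `bio3d` pdb object
#' @param chain_id chain identifier; default: the first protein chain
#' @param mass_mode `"ca-residue"` (default): the Calpha bead carries the full
#'   residue mass (the coarse-grained radius of gyration uses Calpha beads
#'   only) and Cbeta/O beads get nominal masses for the dynamics;
#'   `"uniform"`: the residue mass is split evenly over its beads
#' @param validate check chain geometry (consecutive Calpha-Calpha distances
#'   within 2-5 A)
#' @return a `cg_chain` object
#' @export
build_cg_from_pdb <- function(pdb, chain_id = NULL,
                              mass_mode = c("ca-residue", "uniform"),
                              validate = TRUE) {
  mass_mode <- match.arg(mass_mode)
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records found in structure")
  if (is.null(chain_id)) chain_id <- at$chain[1]
  at <- at[at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0) stop("empty chain: no atoms for chain ", chain_id)

  key <- paste(at$resno, at$insert)
  resno <- at$resno[!duplicated(key)]
  resid <- at$resid[!duplicated(key)]
  n <- length(resno)
  if (n < 3) stop("chain must contain at least 3 residues, found ", n)

  seq1 <- bio3d::aa321(resid)
  if (any(seq1 == "X")) {
    stop("non-standard residue(s): ",
         paste(unique(resid[seq1 == "X"]), collapse = ", "))
  }

  coords <- matrix(NA_real_, 0, 3)
  bead_res <- integer(0); bead_type <- character(0)
  ca_idx <- cb_idx <- o_idx <- rep(NA_integer_, n)
  ukey <- unique(key)
  for (i in seq_len(n)) {
    ri <- at[key == ukey[i], , drop = FALSE]
    pick <- function(name) {
      j <- which(ri$elety == name)
      if (length(j) == 0) return(NULL)
      as.numeric(ri[j[1], c("x", "y", "z")])
    }
    ca <- pick("CA"); o <- pick("O"); cb <- pick("CB")
    lab <- sprintf("%s%d", resid[i], resno[i])
    if (is.null(ca)) stop("residue ", lab, " is missing backbone atom CA")
    if (is.null(o)) stop("residue ", lab, " is missing backbone atom O")
    if (is.null(cb) && seq1[i] != "G")
      stop("residue ", lab, " is missing atom CB")
    add <- function(x, type) {
      coords <<- rbind(coords, x)
      bead_res <<- c(bead_res, i)
      bead_type <<- c(bead_type, type)
      nrow(coords)
    }
    ca_idx[i] <- add(ca, "CA")
    if (!is.null(cb) && seq1[i] != "G") cb_idx[i] <- add(cb, "CB")
    o_idx[i] <- add(o, "O")
  }
  dimnames(coords) <- NULL

  nbead <- nrow(coords)
  masses <- numeric(nbead)
  resm <- .res_mass[seq1]
  if (mass_mode == "ca-residue") {
    masses[ca_idx] <- resm
    masses[o_idx] <- 16
    masses[stats::na.omit(cb_idx)] <- 10
  } else {
    nb_per <- ifelse(seq1 == "G", 2, 3)
    for (i in seq_len(n)) {
      b <- c(ca_idx[i], cb_idx[i], o_idx[i])
      masses[stats::na.omit(b)] <- resm[i] / nb_per[i]
    }
  }

  chain <- structure(list(
    sequence = seq1, n_res = n, coords = coords,
    bead_res = bead_res, bead_type = bead_type,
    ca_idx = ca_idx, cb_idx = cb_idx, o_idx = o_idx,
    masses = masses, charges = numeric(nbead),
    default_charges = NULL, resno = resno, mass_mode = mass_mode,
    applied_loops = integer(0), restraints = list()
  ), class = "cg_chain")
  if (validate) validate_cg_chain(chain)
  chain
}

#' Validate a coarse-grained chain
#'
#' @param chain a `cg_chain`
#' @return the chain, invisibly; errors on violation
#' @export
validate_cg_chain <- function(chain) {
  stopifnot(inherits(chain, "cg_chain"))
  if (chain$n_res < 3) stop("chain must have at least 3 residues")
  ca <- chain$coords[chain$ca_idx, , drop = FALSE]
  d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
  bad <- which(d < 2 | d > 5)
  if (length(bad) > 0) {
    stop("consecutive Calpha-Calpha distance out of [2, 5] A at residue(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  gly <- chain$sequence == "G"
  if (any(!is.na(chain$cb_idx[gly]))) stop("glycine residue carries a Cbeta bead")
  if (any(is.na(chain$cb_idx[!gly]))) stop("non-glycine residue lacks a Cbeta bead")
  invisible(chain)
}

#' @export
print.cg_chain <- function(x, ...) {
  cat(sprintf("cg_chain: %d residues, %d beads, total charge %+.3f e\n",
              x$n_res, nrow(x$coords), total_charge(x)))
  cat(" sequence:", paste(x$sequence, collapse = ""), "\n")
  invisible(x)
}

#' Total charge of a chain
#' @param chain a `cg_chain`
#' @return sum of per-bead charges (e)
#' @export
total_charge <- function(chain) sum(chain$charges)

#' Assign default sidechain charges
#'
#' Aspartate and glutamate Cbeta beads carry -1 e, lysine and arginine +1 e;
#' every other bead is neutral (histidine neutral, no terminal charges).
#'
#' @param chain a `cg_chain`
#' @return the chain with charges assigned and the defaults stored
#' @export
assign_default_charges <- function(chain) {
  stopifnot(inherits(chain, "cg_chain"))
  q <- numeric(nrow(chain$coords))
  neg <- which(chain$sequence %in% c("D", "E"))
  pos <- which(chain$sequence %in% c("K", "R"))
  q[chain$cb_idx[neg]] <- -1
  q[chain$cb_idx[pos]] <- +1
  chain$charges <- q
  chain$default_charges <- q
  chain$applied_loops <- integer(0)
  chain
}

#' EF-hand calcium-binding loop definitions
#'
#' Construct a set of 12-residue EF-hand loops. Coordinating residues are the
#' acidic (D/E) residues at the canonical coordination positions 1, 3, 5, 7,
#' 9 and 12 of each loop.
#'
#' @param starts,ends first/last residue of each loop (reference numbering)
#' @param sequences one-letter sequence of each 12-residue loop
#' @param occupied logical, is a calcium ion bound in each loop
#' @return a `calcium_loop_set`
#' @export
calcium_loop_set <- function(starts, ends, sequences,
                             occupied = rep(TRUE, length(starts))) {
  stopifnot(length(starts) == length(ends),
            length(starts) == length(sequences),
            length(starts) == length(occupied))
  nl <- length(starts)
  if (any(ends - starts + 1 != 12)) stop("every loop must be 12 residues long")
  ord <- order(starts)
  s <- starts[ord]; e <- ends[ord]
  if (nl > 1 && any(s[-1] <= e[-nl])) stop("loops must not overlap")
  canon <- c(1, 3, 5, 7, 9, 12)
  coordinators <- lapply(seq_len(nl), function(l) {
    aa <- strsplit(sequences[l], "")[[1]]
    if (length(aa) != 12) stop("loop sequence must have 12 residues")
    pos <- canon[aa[canon] %in% c("D", "E")]
    starts[l] + pos - 1
  })
  structure(list(
    loops = data.frame(loop = seq_len(nl), start = starts, end = ends,
                       sequence = sequences, occupied = occupied),
    coordinators = coordinators
  ), class = "calcium_loop_set")
}

#' Calmodulin's four calcium-binding loops
#'
#' The bundled loop table (CaM numbering 20-31, 56-67, 93-104, 129-140) with
#' coordinating acidic residues derived from the canonical EF-hand positions;
#' loops 1, 2 and 4 have four coordinators, loop 3 has three.
#'
#' @param occupied calcium occupancy per loop
#' @return a `calcium_loop_set`
#' @export
cam_loops <- function(occupied = rep(TRUE, 4)) {
  tab <- utils::read.table(cgcam_file("cam_loops.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  calcium_loop_set(tab$start, tab$end, tab$sequence, occupied)
}

#' Implicit-calcium charge scheme
#'
#' @param approach `"III"` (default): split the +2 e calcium charge evenly
#'   over the loop's coordinating acidic residues; `"I"`: split over the
#'   negatively charged residues near the loop; `"II"`: as III plus a stiff
#'   harmonic restraint on the radius of gyration of the coordinating
#'   sidechain beads
#' @param k restraint force constant for approach II (kcal/mol/A^2)
#' @param spread for approach I: `"loop"` splits over the D/E residues inside
#'   the 12-residue loop, `"protein"` over every D/E residue in the chain
#' @return a `charge_scheme`
#' @export
charge_scheme <- function(approach = c("III", "I", "II"), k = 30,
                          spread = c("loop", "protein")) {
  approach <- match.arg(approach)
  spread <- match.arg(spread)
  if (approach == "II" && (!is.finite(k) || k <= 0))
    stop("approach II needs a positive, finite force constant")
  structure(list(approach = approach, k = k, spread = spread),
            class = "charge_scheme")
}

#' Apply an implicit-calcium charge model to occupied loops
#'
#' For each occupied loop the +2 e calcium charge is distributed on top of the
#' default -1 e acidic charges. Approach III gives each of the n coordinating
#' acidic residues a charge of -1 + 2/n e (exact rationals are stored);
#' acidic residues that do not coordinate keep -1 e. Approach I spreads the
#' +2 e over the loop's (or the whole chain's) acidic residues. Approach II
#' equals III plus a harmonic restraint on the sidechain radius of gyration of
#' the coordinating beads, with the equilibrium value taken from the reference
#' structure. Every occupied loop changes the total charge by exactly +2 e.
#' Re-application to an already-modified loop is an error;
#' [remove_calcium_model()] restores the default charges bit-exactly.
#'
#' @param chain a `cg_chain` with default charges assigned
#' @param loops a `calcium_loop_set`
#' @param scheme a [charge_scheme()]
#' @param reference chain supplying approach II equilibrium values (default:
#'   `chain` itself)
#' @return the chain with adjusted charges; for approach II the restraint
#'   specs are stored in `$restraints`
#' @export
apply_calcium_model <- function(chain, loops, scheme = charge_scheme(),
                                reference = chain) {
  stopifnot(inherits(chain, "cg_chain"), inherits(loops, "calcium_loop_set"),
            inherits(scheme, "charge_scheme"))
  if (is.null(chain$default_charges))
    stop("assign default charges before applying a calcium model")
  for (l in seq_len(nrow(loops$loops))) {
    row <- loops$loops[l, ]
    if (!row$occupied) next
    if (l %in% chain$applied_loops)
      stop("calcium model already applied to loop ", l,
           "; remove it before re-applying")
    res <- match(row$start:row$end, chain$resno)
    if (anyNA(res)) stop("loop ", l, " residues ", row$start, "-", row$end,
                         " are not all present in the chain")
    aa <- chain$sequence[res]
    acidic <- res[aa %in% c("D", "E")]
    if (length(acidic) == 0)
      stop("occupied loop ", l, " contains no acidic residues")
    if (scheme$approach == "I") {
      targets <- if (scheme$spread == "loop") acidic else
        which(chain$sequence %in% c("D", "E"))
      chain$charges[chain$cb_idx[targets]] <-
        chain$charges[chain$cb_idx[targets]] + 2 / length(targets)
    } else {
      coord <- match(loops$coordinators[[l]], chain$resno)
      if (anyNA(coord)) stop("coordinating residues of loop ", l, " missing")
      if (!all(chain$sequence[coord] %in% c("D", "E")))
        stop("coordinating residues of loop ", l, " must be acidic")
      chain$charges[chain$cb_idx[coord]] <- -1 + 2 / length(coord)
      if (scheme$approach == "II") {
        beads <- chain$cb_idx[coord]
        refxyz <- reference$coords[beads, , drop = FALSE]
        rg0 <- radius_of_gyration(refxyz)
        if (!is.finite(rg0) || rg0 <= 0)
          stop("approach II equilibrium sidechain Rg must be positive")
        chain$restraints[[length(chain$restraints) + 1]] <-
          list(type = "rg", loop = l, bead_idx = beads,
               masses = rep(1, length(beads)), k = scheme$k, rg0 = rg0)
      }
    }
    chain$applied_loops <- c(chain$applied_loops, l)
  }
  chain
}

#' Remove an applied calcium model
#'
#' @param chain a `cg_chain`
#' @return the chain with default charges restored bit-exactly
#' @export
remove_calcium_model <- function(chain) {
  stopifnot(inherits(chain, "cg_chain"))
  if (is.null(chain$default_charges)) return(chain)
  chain$charges <- chain$default_charges
  chain$applied_loops <- integer(0)
  chain$restraints <- list()
  chain
}

#' Write a coarse-grained chain as a PDB file
#'
#' Beads are written as CA/CB/O atom records so the file round-trips through
#' [build_cg_from_pdb()] at PDB coordinate precision (0.001 A).
#'
#' @param chain a `cg_chain`
#' @param file output path
#' @return the file path, invisibly
#' @export
write_cg_pdb <- function(chain, file = tempfile(fileext = ".pdb")) {
  stopifnot(inherits(chain, "cg_chain"))
  nb <- nrow(chain$coords)
  bio3d::write.pdb(
    file = file, xyz = round(as.vector(t(chain$coords)), 3),
    resno = chain$resno[chain$bead_res],
    resid = bio3d::aa123(chain$sequence[chain$bead_res]),
    elety = chain$bead_type, chain = rep("A", nb), eleno = seq_len(nb),
    o = rep(1, nb), b = rep(0, nb))
  invisible(file)
}

#' Serialize a chain's topology to JSON
#'
#' @param chain a `cg_chain`
#' @param file output path (`NULL` returns the JSON string)
#' @return file path or JSON string, invisibly
#' @export
write_cg_topology <- function(chain, file = NULL) {
  stopifnot(inherits(chain, "cg_chain"))
  obj <- list(sequence = paste(chain$sequence, collapse = ""),
              n_res = chain$n_res, resno = chain$resno,
              bead_res = chain$bead_res, bead_type = chain$bead_type,
              masses = chain$masses, charges = chain$charges,
              coords = chain$coords)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(file)) return(invisible(js))
  writeLines(js, file)
  invisible(file)
}
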