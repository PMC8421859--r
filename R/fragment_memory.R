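#' Segment definition for the fragment-memory bias
#'
#' The chain is divided into independent memory channels; pairs spanning a
#' segment boundary receive no bias, which is what lets the central linker
#' stay flexible. The default ranges are calmodulin's: N-domain 5-76, central
#' linker 77-81, C-domain 82-147 (reference numbering).
#'
#' @param ranges list of `c(start, end)` residue ranges, ordered and
#'   non-overlapping
#' @return a `cgcam_segments` object
#' @export
segment_def <- function(ranges = list(c(5, 76), c(77, 81), c(82, 147))) {
  s <- vapply(ranges, `[`, numeric(1), 1)
  e <- vapply(ranges, `[`, numeric(1), 2)
  if (any(e < s)) stop("segment end before start")
  if (length(s) > 1 && any(s[-1] <= e[-length(e)]))
    stop("segments must be ordered and non-overlapping")
  structure(list(start = s, end = e, n = length(s)), class = "cgcam_segments")
}

#' Wrap a coarse-grained chain as a memory structure
#'
#' Only the wrapped chain's own coordinates contribute; for complexes, build
#' the chain from the calmodulin chain only. The alignment map sends target
#' residue numbers to memory residue indices (monotone; `NA` where the memory
#' does not resolve the residue).
#'
#' @param chain a `cg_chain`
#' @param id source identifier (e.g. a PDB ID)
#' @param map integer vector over target residue numbers; default matches the
#'   memory's own residue numbering
#' @return a `memory_structure`
#' @export
memory_structure <- function(chain, id = "memory", map = NULL) {
  stopifnot(inherits(chain, "cg_chain"))
  structure(list(chain = chain, id = id, map = map,
                 rg = rg_chain(chain)), class = "memory_structure")
}

# resolve a target residue number to the memory's internal residue index
.mem_index <- function(mem, target_resno) {
  if (is.null(mem$map)) return(match(target_resno, mem$chain$resno))
  mem$map[match(target_resno, seq_along(mem$map))]
}

#' Build the segmented fragment-memory library
#'
#' Stores, for every memory and segment, the distances `r_ij^m` of all
#' Calpha/Cbeta bead pairs whose residues fall inside one segment with
#' sequence separation between 3 and 9. Pairs spanning segment boundaries are
#' excluded; pairs whose residues a memory does not resolve are skipped for
#' that memory; glycine contributes only its Calpha. The widths are
#' `sigma_ij = |i-j|^0.15`.
#'
#' @param memories list of [memory_structure()] objects (bare `cg_chain`s are
#'   wrapped automatically)
#' @param segments a [segment_def()]
#' @param target the target `cg_chain` (supplies sequence and numbering)
#' @param gamma residue-pair interaction strengths: a single number (default
#'   1) or a 20 x 20 matrix with rows/columns in one-letter order
#' @param min_sep,max_sep sequence-separation bounds (default 3 and 9)
#' @return a `memory_library`
#' @export
build_memory_library <- function(memories, segments = segment_def(), target,
                                 gamma = 1, min_sep = 3, max_sep = 9) {
  stopifnot(inherits(segments, "cgcam_segments"), inherits(target, "cg_chain"))
  memories <- lapply(seq_along(memories), function(m) {
    x <- memories[[m]]
    if (inherits(x, "cg_chain"))
      x <- memory_structure(x, id = sprintf("mem%02d", m))
    stopifnot(inherits(x, "memory_structure"))
    x
  })
  gmat <- if (is.matrix(gamma)) gamma else
    matrix(gamma, 20, 20, dimnames = list(.aa1, .aa1))
  entries <- vector("list", length(memories))
  kept <- logical(length(memories))
  for (m in seq_along(memories)) {
    mem <- memories[[m]]
    rows <- list()
    for (n in seq_len(segments$n)) {
      lo <- max(segments$start[n], min(target$resno))
      hi <- min(segments$end[n], max(target$resno))
      if (hi < lo) next
      tres <- lo:hi
      tidx <- match(tres, target$resno)
      midx <- .mem_index(mem, tres)
      ok <- !is.na(tidx) & !is.na(midx)
      tres <- tres[ok]; tidx <- tidx[ok]; midx <- midx[ok]
      if (length(tres) < 2) next
      for (a in seq_len(length(tres) - 1)) {
        for (b in (a + 1):length(tres)) {
          sep <- tres[b] - tres[a]
          if (sep < min_sep || sep > max_sep) next
          for (ta in c("CA", "CB")) {
            for (tb in c("CA", "CB")) {
              bi_t <- if (ta == "CA") target$ca_idx[tidx[a]] else
                target$cb_idx[tidx[a]]
              bj_t <- if (tb == "CA") target$ca_idx[tidx[b]] else
                target$cb_idx[tidx[b]]
              bi_m <- if (ta == "CA") mem$chain$ca_idx[midx[a]] else
                mem$chain$cb_idx[midx[a]]
              bj_m <- if (tb == "CA") mem$chain$ca_idx[midx[b]] else
                mem$chain$cb_idx[midx[b]]
              if (is.na(bi_t) || is.na(bj_t) || is.na(bi_m) || is.na(bj_m))
                next
              r0 <- sqrt(sum((mem$chain$coords[bj_m, ] -
                              mem$chain$coords[bi_m, ])^2))
              g <- gmat[target$sequence[tidx[a]], target$sequence[tidx[b]]]
              rows[[length(rows) + 1]] <- data.frame(
                m = m, n = n, i = tres[a], j = tres[b], ti = ta, tj = tb,
                r0 = r0, sigma = sep^0.15, gamma = g,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    if (length(rows) == 0) {
      warning("memory ", mem$id,
              " has no aligned residues in any segment; excluded")
      next
    }
    entries[[m]] <- do.call(rbind, rows)
    kept[m] <- TRUE
  }
  if (!any(kept)) stop("no memory contributed any pair")
  tab <- do.call(rbind, entries[kept])
  # renumber memories over the kept set, preserving order
  tab$m <- match(tab$m, which(kept))
  structure(list(entries = tab, n_mem = sum(kept),
                 ids = vapply(memories[kept], `[[`, character(1), "id"),
                 segments = segments, target_n = target$n_res),
            class = "memory_library")
}

#' @export
print.memory_library <- function(x, ...) {
  cat(sprintf("memory_library: %d memories, %d segments, %d stored pairs\n",
              x$n_mem, x$segments$n, nrow(x$entries)))
  invisible(x)
}

#' Number of stored pairs per segment
#'
#' @param library a `memory_library`
#' @param m memory index (default 1)
#' @return named integer vector of pair counts per segment
#' @export
fm_pair_count <- function(library, m = 1) {
  e <- library$entries[library$entries$m == m, ]
  counts <- integer(library$segments$n)
  tt <- table(e$n)
  counts[as.integer(names(tt))] <- as.integer(tt)
  stats::setNames(counts, paste0("segment", seq_len(library$segments$n)))
}

#' Fragment-memory weights
#'
#' @param lambda_fm global scale (non-negative)
#' @param W per-memory, per-segment weight matrix (n_mem x n_segments,
#'   non-negative)
#' @return a `memory_weights`
#' @export
memory_weights <- function(lambda_fm, W) {
  if (lambda_fm < 0) stop("lambda_fm must be non-negative")
  W <- as.matrix(W)
  if (any(W < 0)) stop("memory weights must be non-negative")
  structure(list(lambda_fm = lambda_fm, W = W), class = "memory_weights")
}

# Table of named weight presets: lambda, W for the 59 generic memories, and
# the three per-segment weights of the special (extended crystal) memory.
.preset_table <- local({
  rows <- list(
    I.1 = c(1, 1, 1, 1, 1), I.2 = c(0.1, 1, 1, 1, 1),
    I.3 = c(0.01, 1, 1, 1, 1))
  for (k in 2:9) rows[[paste0("II.", k)]] <- c(0.1, 1, k, k, k)
  for (k in c(1:4, 6:9)) rows[[paste0("III.", k)]] <- c(0.1, 1, 5, k, 5)
  do.call(rbind, rows)
})

#' Named weight presets
#'
#' The model grid explored for calmodulin: family I varies the global scale
#' `lambda_FM` (1, 0.1, 0.01) with all local weights 1; family II raises the
#' weight of the extended crystal-structure memory uniformly over the three
#' segments; family III holds the two domains at weight 5 and varies the
#' central-linker weight. For example `"III.8"` is
#' `lambda_FM = 0.1, W_others = 1, W = (5, 8, 5)` on the special memory.
#'
#' @param model preset id, e.g. `"I.1"`, `"II.9"`, `"III.8"`
#' @param n_mem number of memories in the library (default 60)
#' @param m_special index of the weighted reference memory within the library
#'   (default 60, the extended crystal structure's position in the bundled
#'   manifest)
#' @return a `memory_weights`
#' @export
preset_weights <- function(model, n_mem = 60, m_special = 60) {
  if (!model %in% rownames(.preset_table))
    stop("unknown model id '", model, "'; available: ",
         paste(rownames(.preset_table), collapse = ", "))
  p <- .preset_table[model, ]
  W <- matrix(p[2], n_mem, 3)
  W[m_special, ] <- p[3:5]
  w <- memory_weights(p[1], W)
  w$model <- model
  w
}

.check_weights <- function(library, weights) {
  stopifnot(inherits(library, "memory_library"),
            inherits(weights, "memory_weights"))
  if (nrow(weights$W) != library$n_mem ||
      ncol(weights$W) != library$segments$n)
    stop("weight table is ", nrow(weights$W), " x ", ncol(weights$W),
         " but the library has ", library$n_mem, " memories and ",
         library$segments$n, " segments")
  invisible(TRUE)
}

# compiled-spec block for the fragment-memory term
.fm_spec <- function(chain, library, weights) {
  .check_weights(library, weights)
  e <- library$entries
  ri <- match(e$i, chain$resno)
  rj <- match(e$j, chain$resno)
  if (anyNA(ri) || anyNA(rj))
    stop("memory library references residues absent from the chain")
  bi <- ifelse(e$ti == "CA", chain$ca_idx[ri], chain$cb_idx[ri])
  bj <- ifelse(e$tj == "CA", chain$ca_idx[rj], chain$cb_idx[rj])
  keep <- !is.na(bi) & !is.na(bj)
  w <- weights$W[cbind(e$m, e$n)] * e$gamma
  list(i = as.integer(bi[keep]), j = as.integer(bj[keep]), r0 = e$r0[keep],
       sigma = e$sigma[keep], w = w[keep], lambda = weights$lambda_fm)
}

#' Fragment-memory energy and forces
#'
#' `V_FM = -lambda_FM sum_m sum_n W_n^m sum_pairs gamma_ij
#' exp(-(r_ij - r_ij^m)^2 / (2 sigma_ij^2))`: a non-positive sum of
#' Gaussians, each at its extremum when the instantaneous pair distance
#' matches the stored memory distance; linear in `lambda_FM` and in every
#' `W_n^m`.
#'
#' @param chain a `cg_chain` matching the library's target
#' @param library a [build_memory_library()] result
#' @param weights a [memory_weights()]
#' @param coords optional coordinates overriding `chain$coords`
#' @return list with `energy` (kcal/mol) and `forces`
#' @export
v_fm <- function(chain, library, weights, coords = NULL) {
  spec <- list(box = 0, periodic = FALSE,
               fm = .fm_spec(chain, library, weights))
  if (is.null(coords)) coords <- chain$coords
  r <- ff_eval_cpp(coords, spec)
  list(energy = r$energy, forces = r$forces)
}

#' Bundled memory-structure manifest
#'
#' The 60-structure memory manifest (PDB IDs and their reported radii of
#' gyration). Structures are not bundled; use
#' `inst/scripts/fetch_memories.R` to download them when network access is
#' available. Nothing in the package's tests requires the downloads.
#'
#' @return data.frame with columns `m`, `pdb_id`, `rg`
#' @export
cam_memory_manifest <- function() {
  utils::read.table(cgcam_file("memory_structures.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
}
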