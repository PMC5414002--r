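#' Sequence-based residue pairing
#'
#' Global Needleman-Wunsch alignment of two one-letter sequences (BLOSUM62,
#' affine gaps, open 11 / extend 1 by convention) yielding colinear residue
#' correspondences: pair indices are strictly increasing in both columns.
#'
#' @param seq_a,seq_b one-letter amino-acid strings (typically from
#'   [ca_sequence()]).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return An object of class `residue_pairing`: list with `pairs` (two-column
#'   integer matrix of 1-based positions in `seq_a`/`seq_b`) and
#'   `alignment_score`.
#' @export
pair_residues <- function(seq_a, seq_b, gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be nonempty")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sm <- get("BLOSUM62", envir = environment())
  # map residues missing from the matrix (e.g. "X") onto its wildcard row
  clean <- function(s) {
    ch <- setdiff(unique(strsplit(s, "")[[1]]), colnames(sm))
    if (length(ch)) chartr(paste(ch, collapse = ""), strrep("*", length(ch)), s) else s
  }
  aln <- Biostrings::pairwiseAlignment(clean(seq_a), clean(seq_b),
                                       substitutionMatrix = sm,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend,
                                       type = "global")
  ga <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(ga != "-")
  ib <- cumsum(gb != "-")
  both <- ga != "-" & gb != "-"
  pairs <- cbind(a = ia[both], b = ib[both])
  structure(list(pairs = pairs, alignment_score = Biostrings::score(aln)),
            class = "residue_pairing")
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' (optionally weighted) RMSD of `R a + t` onto `b`. Reflections are
#' corrected so the returned transform is always a proper rotation.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates, n >= 3,
#'   not all collinear.
#' @param weights optional non-negative weights, length n.
#' @return An object of class `superposition`: `transform`
#'   ([rigid_transform()]), `rmsd` (angstrom, over all pairs),
#'   `n_input_pairs`, `n_retained_pairs`, `cycles_run`.
#' @export
kabsch <- function(coords_a, coords_b, weights = NULL) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3L) stop("coordinate sets must be equal n x 3 matrices")
  n <- nrow(A)
  if (n < 3L) stop("at least 3 point pairs are required")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) stop("invalid weights")
  w <- w / sum(w)
  ca <- colSums(A * w); cb <- colSums(B * w)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv_a <- svd(Ac * sqrt(w))$d
  if (sv_a[2] < 1e-9 * max(sv_a[1], 1)) stop("degenerate geometry: points are (nearly) collinear")
  H <- crossprod(Ac * w, Bc)         # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cb - R %*% ca)
  tf <- rigid_transform(R, tr)
  fitted <- A %*% t(R)
  dev2 <- rowSums((sweep(fitted, 2, tr, "+") - B)^2)
  structure(list(transform = tf,
                 rmsd = sqrt(sum(w * dev2)),
                 deviations = sqrt(dev2),
                 n_input_pairs = n, n_retained_pairs = n, cycles_run = 0L),
            class = "superposition")
}

#' Superpose two structures with iterative outlier rejection
#'
#' Calpha atoms are paired by sequence ([pair_residues()]); a Kabsch fit is
#' refined for up to `cycles` cycles, after each of which pairs whose
#' deviation exceeds `cutoff` times the current root-mean-square deviation
#' are rejected (the semantics of the usual "align" tools). With
#' `cycles = 0` all sequence-matched pairs are used.
#'
#' @param struct_a,struct_b [fts_structure()] objects. The returned transform
#'   maps `struct_a` onto `struct_b`.
#' @param chain_a,chain_b chain selections (default: all chains).
#' @param residues_a,residues_b optional residue intervals applied before
#'   pairing.
#' @param cycles maximum rejection cycles (default 5).
#' @param cutoff rejection multiplier on the per-cycle RMS deviation
#'   (default 2.0).
#' @return A `superposition` object; `rmsd` is over retained pairs,
#'   `pairs_res` records the retained author residue numbers.
#' @export
superpose <- function(struct_a, struct_b, chain_a = NULL, chain_b = NULL,
                      residues_a = NULL, residues_b = NULL,
                      cycles = 5, cutoff = 2.0) {
  sa <- select_atoms(struct_a, chain = chain_a, residues = residues_a,
                     atom_names = "CA", hetero = FALSE)
  sb <- select_atoms(struct_b, chain = chain_b, residues = residues_b,
                     atom_names = "CA", hetero = FALSE)
  ca <- sa$atoms; cb <- sb$atoms
  if (nrow(ca) < 3L || nrow(cb) < 3L) stop("fewer than 3 Calpha atoms selected")
  pr <- pair_residues(paste(bio3d::aa321(ca$res_name), collapse = ""),
                      paste(bio3d::aa321(cb$res_name), collapse = ""))
  ia <- pr$pairs[, 1]; ib <- pr$pairs[, 2]
  if (length(ia) < 3L) stop("fewer than 3 sequence-matched Calpha pairs")
  A <- as.matrix(ca[ia, c("x", "y", "z")])
  B <- as.matrix(cb[ib, c("x", "y", "z")])
  retained <- rep(TRUE, nrow(A))
  fit <- kabsch(A, B)
  ncyc <- 0L
  for (cyc in seq_len(cycles)) {
    dev <- fit$deviations
    rms <- sqrt(mean(dev[retained]^2))
    if (rms < 1e-6) break  # already at numerical zero; nothing left to reject
    drop <- retained & (dev > cutoff * rms)
    if (!any(drop)) break
    retained[drop] <- FALSE
    if (sum(retained) < 3L) stop("outlier rejection left fewer than 3 pairs")
    ncyc <- cyc
    sub <- kabsch(A[retained, , drop = FALSE], B[retained, , drop = FALSE])
    # deviations of ALL input pairs under the refined transform
    fitted <- A %*% t(sub$transform$rotation)
    fitted <- sweep(fitted, 2, sub$transform$translation, "+")
    fit <- sub
    fit$deviations <- sqrt(rowSums((fitted - B)^2))
  }
  structure(list(transform = fit$transform,
                 rmsd = sqrt(mean(fit$deviations[retained]^2)),
                 deviations = fit$deviations,
                 retained = retained,
                 pairs_res = cbind(a = ca$res_seq[ia], b = cb$res_seq[ib]),
                 n_input_pairs = nrow(A),
                 n_retained_pairs = sum(retained),
                 cycles_run = ncyc),
            class = "superposition")
}

#' All-versus-all Calpha RMSD matrix
#'
#' Entry (i, j) is the superposition RMSD of structure i onto structure j
#' with the stated number of outlier-rejection cycles (0 by default, i.e.
#' all sequence-matched residues contribute). The diagonal is 0; pairs that
#' fail to superpose yield `NA` with a warning.
#'
#' @param structures named list of [fts_structure()] objects (>= 2).
#' @param chain,residues selection applied to every structure.
#' @param cycles rejection cycles (default 0).
#' @param cutoff rejection multiplier, used when `cycles > 0`.
#' @return Square numeric matrix (angstrom) with structure ids as dimnames.
#' @export
rmsd_matrix <- function(structures, chain = NULL, residues = NULL,
                        cycles = 0, cutoff = 2.0) {
  n <- length(structures)
  if (n < 2L) stop("need at least 2 structures")
  ids <- names(structures)
  if (is.null(ids)) ids <- vapply(structures, function(s) s$id, character(1))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- tryCatch(
      superpose(structures[[i]], structures[[j]], chain_a = chain, chain_b = chain,
                residues_a = residues, residues_b = residues,
                cycles = cycles, cutoff = cutoff)$rmsd,
      error = function(e) {
        warning(sprintf("superposition %s vs %s failed: %s", ids[i], ids[j],
                        conditionMessage(e)), call. = FALSE)
        NA_real_
      })
    m[i, j] <- m[j, i] <- r
  }
  m
}

#' Write an RMSD matrix as CSV
#'
#' Structure ids form the header row and column.
#' @param m matrix from [rmsd_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmsd_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.3f A over %d/%d pairs (%d rejection cycle(s))\n",
              x$rmsd, x$n_retained_pairs, x$n_input_pairs, x$cycles_run))
  invisible(x)
}

#' @export
print.residue_pairing <- function(x, ...) {
  cat(sprintf("Residue pairing: %d pairs, alignment score %.1f\n",
              nrow(x$pairs), x$alignment_score))
  invisible(x)
}
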