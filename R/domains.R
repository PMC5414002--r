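#' Two-domain partition of an FtsZ chain
#'
#' FtsZ consists of an N-terminal GTP-binding domain (NTD) and a C-terminal
#' GTPase-activation domain (CTD) joined by the central helix H-7. Intervals
#' use author residue numbering, inclusive at both ends, and must not
#' overlap. Landmarks are named (res_seq, atom_name) entries used by
#' [landmark_displacement()].
#'
#' @param ntd inclusive NTD residue interval, default `c(12, 165)`.
#' @param ctd inclusive CTD residue interval, default `c(196, 316)`.
#' @param h7 inclusive H-7 interval, default `c(169, 195)`.
#' @param landmarks named list of `list(res_seq =, atom_name =)` entries.
#' @return An object of class `domain_definition`.
#' @export
domain_definition <- function(ntd = c(12, 165), ctd = c(196, 316),
                              h7 = c(169, 195), landmarks = ftsz_landmarks()) {
  iv <- function(x, nm) {
    if (length(x) != 2L || x[1] > x[2]) stop("'", nm, "' must be an interval c(lo, hi)")
    as.integer(x)
  }
  ntd <- iv(ntd, "ntd"); ctd <- iv(ctd, "ctd"); h7 <- iv(h7, "h7")
  ranges <- list(ntd = ntd, ctd = ctd, h7 = h7)
  for (i in 1:2) for (j in (i + 1):3) {
    a <- ranges[[i]]; b <- ranges[[j]]
    if (a[1] <= b[2] && b[1] <= a[2]) {
      stop("domain intervals overlap: ", names(ranges)[i], " and ", names(ranges)[j])
    }
  }
  structure(list(ntd = ntd, ctd = ctd, h7 = h7, landmarks = landmarks),
            class = "domain_definition")
}

#' Shipped FtsZ domain presets
#'
#' Three presets are shipped because published analyses of SaFtsZ used
#' slightly different NTD windows: `"standard"` (NTD 12-165, the default,
#' consistent with both alternatives), `"narrow"` (NTD 13-165, as used for
#' whole-census superposition figures) and `"extended"` (NTD 12-176, as used
#' for all-versus-all RMSD matrices, i.e. NTD plus H-7 start).
#'
#' @param preset one of `"standard"`, `"narrow"`, `"extended"`.
#' @return A [domain_definition()].
#' @export
ftsz_domains <- function(preset = c("standard", "narrow", "extended")) {
  preset <- match.arg(preset)
  switch(preset,
    standard = domain_definition(ntd = c(12, 165)),
    narrow   = domain_definition(ntd = c(13, 165)),
    extended = domain_definition(ntd = c(12, 176), h7 = c(177, 195))
  )
}

#' Landmark atoms used to quantify the FtsZ switch
#'
#' Residues whose rearrangement tracks the open/closed transition:
#' the R29 guanidinium carbon (slots between H-7 and the NTD in the open
#' state), the R191 Calpha on H-7 (moves with the helix shift), and the two
#' polymerization-interface mutation sites F138 and T66. Residue numbers
#' only; author numbering of the S. aureus chain.
#'
#' @return Named list of landmark descriptors.
#' @export
ftsz_landmarks <- function() {
  list(
    R29_CZ  = list(res_seq = 29L,  atom_name = "CZ"),
    R191_CA = list(res_seq = 191L, atom_name = "CA"),
    F138_CA = list(res_seq = 138L, atom_name = "CA"),
    T66_CA  = list(res_seq = 66L,  atom_name = "CA")
  )
}

#' Resolve a landmark against a structure
#'
#' @param structure an [fts_structure()].
#' @param landmark `list(res_seq =, atom_name =, chain = NULL)`.
#' @return length-3 coordinate vector; errors naming the residue/atom when
#'   the landmark is missing.
#' @export
resolve_landmark <- function(structure, landmark) {
  a <- structure$atoms
  keep <- a$res_seq == landmark$res_seq & a$atom_name == landmark$atom_name
  if (!is.null(landmark$chain)) keep <- keep & a$chain == landmark$chain
  hit <- a[keep, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop(sprintf("landmark atom %s of residue %d not found in '%s'",
                 landmark$atom_name, landmark$res_seq, structure$id))
  }
  as.numeric(hit[1, c("x", "y", "z")])
}

#' @export
print.domain_definition <- function(x, ...) {
  cat(sprintf("FtsZ domains: NTD %d-%d | H7 %d-%d | CTD %d-%d | %d landmark(s)\n",
              x$ntd[1], x$ntd[2], x$h7[1], x$h7[2], x$ctd[1], x$ctd[2],
              length(x$landmarks)))
  invisible(x)
}
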