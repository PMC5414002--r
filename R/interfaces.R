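#' Buried surface area of a subunit pair
#'
#' PISA-style interface burial: the SASA lost on complex formation,
#' `bsa_total = sasa_a + sasa_b - sasa_complex`. The `"half_sum"` convention
#' (PISA's "interface area") reports half of that; `"total"` reports the
#' full sum. Both values are carried in the report since published ~700 and
#' ~1200 A^2 interface figures do not state the convention. Contact residues
#' are those losing more than 0.1 A^2.
#'
#' @param subunit_a,subunit_b [fts_structure()] objects, non-empty.
#' @param convention `"half_sum"` (default) or `"total"`.
#' @param probe,n_points,radii,default_radius,uniform_radius passed to
#'   [sasa()].
#' @return An object of class `interface_report`: `sasa_a`, `sasa_b`,
#'   `sasa_complex`, `bsa` (under `convention`), `bsa_half`, `bsa_total`,
#'   `convention`, `n_contact_residues`, `contact_residues` (data.frame).
#' @export
interface_bsa <- function(subunit_a, subunit_b,
                          convention = c("half_sum", "total"),
                          probe = 1.4, n_points = 960, radii = NULL,
                          default_radius = 1.8, uniform_radius = NULL) {
  convention <- match.arg(convention)
  if (nrow(subunit_a$atoms) == 0L || nrow(subunit_b$atoms) == 0L) {
    stop("both subunits must be non-empty")
  }
  args <- list(probe = probe, n_points = n_points, radii = radii,
               default_radius = default_radius, uniform_radius = uniform_radius)
  ra <- do.call(residue_sasa, c(list(subunit_a), args))
  rb <- do.call(residue_sasa, c(list(subunit_b), args))
  cplx <- merge_structures(subunit_a, subunit_b, chains = c("A", "B"),
                           id = paste0(subunit_a$id, "+", subunit_b$id))
  rc <- do.call(residue_sasa, c(list(cplx), args))
  sa <- sum(ra$area); sb <- sum(rb$area); sc <- sum(rc$area)
  bsa_total <- max(0, sa + sb - sc)
  # per-residue loss (complex chains are relabelled A/B in subunit order)
  rca <- rc[rc$chain == "A", ]; rcb <- rc[rc$chain == "B", ]
  loss_a <- ra$area - rca$area[match(paste(ra$res_seq, ra$ins),
                                     paste(rca$res_seq, rca$ins))]
  loss_b <- rb$area - rcb$area[match(paste(rb$res_seq, rb$ins),
                                     paste(rcb$res_seq, rcb$ins))]
  contact <- rbind(
    data.frame(subunit = "a", chain = ra$chain, res_seq = ra$res_seq,
               buried = loss_a, stringsAsFactors = FALSE),
    data.frame(subunit = "b", chain = rb$chain, res_seq = rb$res_seq,
               buried = loss_b, stringsAsFactors = FALSE))
  contact <- contact[!is.na(contact$buried) & contact$buried > 0.1, , drop = FALSE]
  rownames(contact) <- NULL
  structure(list(sasa_a = sa, sasa_b = sb, sasa_complex = sc,
                 bsa = if (convention == "half_sum") bsa_total / 2 else bsa_total,
                 bsa_half = bsa_total / 2, bsa_total = bsa_total,
                 convention = convention,
                 n_contact_residues = nrow(contact),
                 contact_residues = contact),
            class = "interface_report")
}

#' Axial repeat between two filament subunits
#'
#' Superposes subunit `a` onto subunit `b` (the two must be
#' sequence-identical copies of one chain in different lattice positions)
#' and reports the translation component along the screw axis of the
#' resulting transform. For a near-pure translation this is simply the
#' translation length.
#'
#' @param subunit_a,subunit_b [fts_structure()] objects.
#' @return List with `repeat_length` (angstrom), `transform`
#'   ([rigid_transform()]) and `axis` (unit 3-vector).
#' @export
filament_repeat <- function(subunit_a, subunit_b) {
  sa <- ca_records(subunit_a); sb <- ca_records(subunit_b)
  seq_a <- paste(bio3d::aa321(sa$res_name), collapse = "")
  seq_b <- paste(bio3d::aa321(sb$res_name), collapse = "")
  if (!identical(seq_a, seq_b) || nrow(sa) != nrow(sb)) {
    stop("subunits are not sequence-matched copies of one chain")
  }
  fit <- kabsch(as.matrix(sa[, c("x", "y", "z")]), as.matrix(sb[, c("x", "y", "z")]))
  R <- fit$transform$rotation
  tr <- fit$transform$translation
  ang <- rotation_angle(R)
  if (ang < 0.1) {
    rep_len <- sqrt(sum(tr^2))
    axis <- if (rep_len > 1e-9) tr / rep_len else c(0, 0, 1)
  } else {
    axis <- rotation_axis(R)
    rep_len <- abs(sum(axis * tr))
    if (sum(axis * tr) < 0) axis <- -axis
  }
  list(repeat_length = rep_len, transform = fit$transform, axis = axis,
       fit_rmsd = fit$rmsd)
}

#' Build a filament from a subunit and a lattice operator
#'
#' Places `n` copies of the subunit at `operator^k`, k = 0..n-1 — the way
#' protofilaments are reconstituted from one chain plus a crystallographic
#' symmetry operator. Full space-group expansion is deliberately not
#' implemented; supply the one operator that generates the protofilament.
#'
#' @param subunit an [fts_structure()].
#' @param operator a [rigid_transform()].
#' @param n number of subunits (>= 2).
#' @return An object of class `filament_model`: `subunits` (list of
#'   structures, chains relabelled sequentially), `repeat_length`, `axis`,
#'   `operator`.
#' @export
build_filament <- function(subunit, operator, n) {
  stopifnot(inherits(subunit, "fts_structure"), n >= 2, n == round(n))
  if (!inherits(operator, "rigid_transform")) stop("'operator' must be a rigid_transform")
  chain_ids <- make_chain_ids(n)
  subunits <- vector("list", n)
  for (k in seq_len(n)) {
    s <- apply_transform(subunit, transform_power(operator, k - 1L))
    s$atoms$chain <- chain_ids[k]
    s$id <- paste0(subunit$id, "_", chain_ids[k])
    subunits[[k]] <- s
  }
  rep1 <- filament_repeat(subunits[[1]], subunits[[2]])
  # adjacent transforms must agree on the repeat (same operator throughout)
  for (k in seq_len(n - 1)) {
    rk <- filament_repeat(subunits[[k]], subunits[[k + 1]])
    if (abs(rk$repeat_length - rep1$repeat_length) > 0.1) {
      stop("inconsistent adjacent-subunit repeat along the filament")
    }
  }
  structure(list(subunits = subunits, repeat_length = rep1$repeat_length,
                 axis = rep1$axis, operator = operator),
            class = "filament_model")
}

make_chain_ids <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n <= length(pool)) return(pool[seq_len(n)])
  paste0(rep(LETTERS, length.out = n), seq_len(n))
}

#' Flatten a filament model into one multi-chain structure
#'
#' @param filament a `filament_model`.
#' @param id label.
#' @return An [fts_structure()].
#' @export
filament_as_structure <- function(filament, id = "filament") {
  stopifnot(inherits(filament, "filament_model"))
  merge_structures(filament$subunits, id = id)
}

#' Write an interface report as JSON (+ optional contact TSV)
#'
#' @param report an `interface_report`.
#' @param path JSON output path.
#' @param contacts_path optional TSV path for the contact-residue table.
#' @return `path`, invisibly.
#' @export
write_interface_json <- function(report, path, contacts_path = NULL) {
  x <- report[c("sasa_a", "sasa_b", "sasa_complex", "bsa", "bsa_half",
                "bsa_total", "convention", "n_contact_residues")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(contacts_path)) {
    utils::write.table(report$contact_residues, contacts_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("Interface: BSA %.1f A^2 (%s; total %.1f, half %.1f), %d contact residue(s)\n",
              x$bsa, x$convention, x$bsa_total, x$bsa_half, x$n_contact_residues))
  invisible(x)
}

#' @export
print.filament_model <- function(x, ...) {
  cat(sprintf("Filament: %d subunits, repeat %.3f A along (%.3f, %.3f, %.3f)\n",
              length(x$subunits), x$repeat_length, x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}
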