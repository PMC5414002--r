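# Shared fixtures, all generated in code (no stored binary data).

# a compact random Calpha cloud as a structure
random_ca_structure <- function(n = 60, seed = 1, sd = 8, chain = "A", id = "cloud") {
  set.seed(seed)
  xyz <- matrix(rnorm(3 * n, sd = sd), n, 3)
  fts_structure(data.frame(chain = chain, res_seq = seq_len(n), res_name = "ALA",
                           atom_name = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                id = id)
}

# the default synthetic two-domain parent + its domain definition, cached
# per seed so repeated tests do not regenerate
synth_parent <- local({
  cache <- list()
  function(seed = 3) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- make_two_domain_structure(synth_spec(seed = seed))
    }
    cache[[key]]
  }
})

# a two-residue hand-written PDB (format-forced coordinate check)
two_residue_pdb <- function(path) {
  writeLines(c(
    "CRYST1   50.000   60.000   70.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   ALA A  12      11.104  13.207   9.500  1.00 20.00           N",
    "ATOM      2  CA  ALA A  12      12.560  13.400   9.278  1.00 20.00           C",
    "ATOM      3  CA  GLY A  13      14.851  16.033  10.002  0.50 21.00           C",
    "TER",
    "END"), path)
  path
}

# minimal mmCIF writer for cross-format comparisons (atom_site category)
write_minimal_cif <- function(structure, path) {
  a <- structure$atoms
  hdr <- c("data_fixture", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "label_atom_id", "label_alt_id", "label_comp_id",
                                   "label_asym_id", "label_entity_id", "label_seq_id",
                                   "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                                   "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                                   "auth_seq_id", "auth_comp_id", "auth_asym_id",
                                   "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
                  ifelse(a$is_hetero, "HETATM", "ATOM"), seq_len(nrow(a)), a$element,
                  a$atom_name, a$res_name, a$chain, a$res_seq,
                  a$x, a$y, a$z, a$occupancy, a$b, a$res_seq, a$res_name, a$chain,
                  a$atom_name)
  writeLines(c(hdr, rows), path)
  path
}

# directory that may hold user-fetched deposited coordinate files
# (<id>.pdb or <id>.cif, lower case). Real-structure validations need them.
reference_structure_dir <- function() {
  getOption("ftszswitch.pdb_dir",
            file.path(system.file(package = "ftszswitch"), "extdata", "pdb"))
}

find_reference_structure <- function(id) {
  dir <- reference_structure_dir()
  for (ext in c(".pdb", ".cif")) {
    p <- file.path(dir, paste0(tolower(id), ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

missing_reference_message <- function(ids) {
  paste0("deposited coordinate set(s) ", paste(ids, collapse = ", "),
         " not available offline; place the files under ",
         reference_structure_dir(),
         " (or set options(ftszswitch.pdb_dir=...)) to run this validation")
}
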