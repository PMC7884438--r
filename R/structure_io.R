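# Coordinate file input/output and the structure_model container.
#
# A structure_model is the single source of geometry for every downstream
# computation: a flat atom table in author numbering plus a chain -> subunit
# map. Waters are removed at load and alternate locations are resolved to a
# single conformer so that all distances are deterministic.

WATER_COMP_IDS <- c("HOH", "WAT", "DOD")

#' Canonical subunit vocabulary
#'
#' Subunit names accepted by [apply_subunit_map()]: the PSI core subunits
#' PsaA--PsaO and the antenna proteins Lhca1--Lhca8, plus `"unknown"` for
#' chains that are not mapped.
#'
#' @return Character vector of canonical subunit names.
#' @export
subunit_vocabulary <- function() {
  c(paste0("Psa", LETTERS[1:15]), paste0("Lhca", 1:8), "unknown")
}

new_structure_model <- function(entry_id, atoms, subunit_of = NULL) {
  stopifnot(is.data.frame(atoms))
  chains <- unique(atoms$chain)
  if (is.null(subunit_of)) {
    subunit_of <- stats::setNames(rep("unknown", length(chains)), chains)
  }
  structure(
    list(entry_id = entry_id, atoms = atoms, subunit_of = subunit_of),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "structure_model '%s': %d atoms, %d residues, %d chains\n",
    x$entry_id, nrow(x$atoms), nrow(model_residues(x)),
    length(unique(x$atoms$chain))
  ))
  mapped <- x$subunit_of[x$subunit_of != "unknown"]
  if (length(mapped)) {
    cat("  subunits:", paste(sprintf("%s=%s", names(mapped), mapped),
                             collapse = " "), "\n")
  }
  invisible(x)
}

# Unique residue table of a model, in file order.
model_residues <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$seq_num, a$icode, sep = "\r")
  keep <- !duplicated(key)
  data.frame(
    chain = a$chain[keep], comp_id = a$comp_id[keep],
    seq_num = a$seq_num[keep], icode = a$icode[keep],
    is_hetero = a$is_hetero[keep], stringsAsFactors = FALSE
  )
}

# Atoms of one residue, by author identifiers.
residue_atoms <- function(model, chain, seq_num, icode = "") {
  a <- model$atoms
  a[a$chain == chain & a$seq_num == seq_num & a$icode == icode, , drop = FALSE]
}

# Map a chain id to its canonical subunit name ("unknown" when unmapped).
chain_subunit <- function(model, chain) {
  s <- unname(model$subunit_of[chain])
  ifelse(is.na(s), "unknown", s)
}

# Chain id carrying a canonical subunit, or NA.
subunit_chain <- function(model, subunit) {
  hit <- names(model$subunit_of)[model$subunit_of == subunit]
  if (length(hit)) hit[1] else NA_character_
}

infer_element <- function(name, elesy = NULL) {
  if (!is.null(elesy) && !is.na(elesy) && nzchar(trimws(elesy))) {
    return(toupper(trimws(elesy)))
  }
  # strip digits/primes, keep leading letters; two-letter metals kept intact
  core <- gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", name))
  if (toupper(core) %in% c("MG", "FE", "MN", "ZN", "CU", "CL", "BR", "NA",
                           "CA")) {
    # bare metal atom names; note "NA"/"CA" as *residue atom* names are
    # nitrogen/carbon, so only map when the full name is the metal label
    if (toupper(name) %in% c("MG", "FE", "MN", "ZN", "CU")) {
      return(toupper(name))
    }
  }
  toupper(substr(core, 1, 1))
}

# Resolve alternate locations: per (chain, seq_num, icode, atom_name) keep the
# highest-occupancy record; ties broken by lexicographically smallest altloc.
resolve_altlocs <- function(atoms) {
  if (!any(nzchar(atoms$altloc))) return(atoms)
  key <- paste(atoms$chain, atoms$seq_num, atoms$icode, atoms$atom_name,
               sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

#' Load a coordinate file into a structure model
#'
#' Reads an mmCIF or PDB file (model 1 only) into a flat atom table with
#' author chain identifiers and author residue numbering preserved exactly.
#' Water residues (HOH/WAT/DOD) are excluded. When alternate locations are
#' present, the highest-occupancy alternate is kept (ties broken by
#' lexicographic altloc tag). Hydrogens, if present, are retained in the
#' table but ignored by all distance computations downstream.
#'
#' @param path Path to the coordinate file.
#' @param format One of `"auto"` (by file extension), `"mmcif"`, `"pdb"`.
#' @param entry_id Entry identifier to record; defaults to the file stem.
#' @return A `structure_model`: list with `entry_id`, `atoms` (data frame
#'   with columns chain, comp_id, seq_num, icode, atom_name, element,
#'   x, y, z, occupancy, altloc, is_hetero) and `subunit_of` (named
#'   character vector chain -> canonical subunit, `"unknown"` until
#'   [apply_subunit_map()] is called).
#' @export
load_structure <- function(path, format = c("auto", "mmcif", "pdb"),
                           entry_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (is.null(entry_id)) {
    entry_id <- toupper(tools::file_path_sans_ext(basename(path)))
  }
  pdb <- tryCatch(
    if (format == "mmcif") {
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) {
      stop("could not parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- pdb$atom
  n <- nrow(at)
  if (is.null(n) || n == 0L) stop("no atoms in '", path, "'")
  blank <- function(v) {
    v <- as.character(v)
    v[is.na(v)] <- ""
    trimws(v)
  }
  atoms <- data.frame(
    chain = blank(at$chain),
    comp_id = toupper(blank(at$resid)),
    seq_num = as.integer(at$resno),
    icode = blank(at$insert),
    atom_name = toupper(blank(at$elety)),
    element = NA_character_,
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    altloc = blank(at$alt),
    is_hetero = blank(at$type) == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$element <- mapply(infer_element, atoms$atom_name, blank(at$elesy),
                          USE.NAMES = FALSE)
  atoms <- atoms[!(atoms$comp_id %in% WATER_COMP_IDS), , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("no atoms in '", path, "' after water exclusion")
  }
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates in '", path, "'")
  }
  rownames(atoms) <- NULL
  atoms <- resolve_altlocs(atoms)
  rownames(atoms) <- NULL
  new_structure_model(entry_id, atoms)
}

#' Read a subunit map configuration
#'
#' Plain-text config with one `entry chain subunit` triple per line;
#' `#` starts a comment. Canonical subunit names must come from
#' [subunit_vocabulary()].
#'
#' @param path Path to the config file.
#' @return A `subunit_map` data frame with columns entry, chain, subunit,
#'   and attribute `provenance` (the comment lines).
#' @export
read_subunit_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  prov <- sub("^#\\s*", "", lines[grepl("^\\s*#", lines)])
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    m <- data.frame(entry = character(), chain = character(),
                    subunit = character(), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines, "\\s+")
    bad <- lengths(parts) != 3L
    if (any(bad)) {
      stop("malformed subunit-map line(s): ",
           paste(lines[bad], collapse = "; "))
    }
    m <- data.frame(
      entry = toupper(vapply(parts, `[`, "", 1L)),
      chain = vapply(parts, `[`, "", 2L),
      subunit = vapply(parts, `[`, "", 3L),
      stringsAsFactors = FALSE
    )
  }
  unknown <- setdiff(m$subunit, subunit_vocabulary())
  if (length(unknown)) {
    stop("subunit name(s) outside the canonical vocabulary: ",
         paste(unknown, collapse = ", "))
  }
  attr(m, "provenance") <- paste(prov, collapse = "\n")
  class(m) <- c("subunit_map", class(m))
  m
}

#' Packaged default subunit map for a deposited entry
#'
#' Returns the subunit map shipped with the package for the given entry id,
#' if one exists. Shipped maps follow the conventional chain labelling of
#' these deposits and are checked against the loaded model at
#' [apply_subunit_map()] time: a chain named in the map but absent from the
#' model raises a warning, never silent misassignment.
#'
#' @param entry_id Entry identifier, e.g. `"6L35"`.
#' @return A `subunit_map`, or `NULL` when no map is shipped for the entry.
#' @export
default_subunit_map <- function(entry_id) {
  f <- system.file("extdata",
                   paste0("subunit_map_", toupper(entry_id), ".tsv"),
                   package = "pigmentnet")
  if (!nzchar(f)) return(NULL)
  read_subunit_map(f)
}

#' Apply a subunit map to a structure model
#'
#' Populates `subunit_of` from the config. Chains present in the model but
#' absent from the config map to `"unknown"` with a warning; config rows
#' naming chains absent from the model are ignored with a warning. Two
#' chains mapping to the same canonical subunit is a configuration error.
#'
#' @param model A `structure_model`.
#' @param config A `subunit_map` from [read_subunit_map()], or a named
#'   character vector chain -> subunit.
#' @return The model with `subunit_of` populated.
#' @export
apply_subunit_map <- function(model, config) {
  stopifnot(inherits(model, "structure_model"))
  if (is.character(config) && !is.null(names(config))) {
    config <- data.frame(entry = "*", chain = names(config),
                         subunit = unname(config), stringsAsFactors = FALSE)
  }
  cfg <- config[config$entry %in% c("*", toupper(model$entry_id)), ,
                drop = FALSE]
  chains <- unique(model$atoms$chain)
  missing_chain <- setdiff(cfg$chain, chains)
  if (length(missing_chain)) {
    warning("subunit map names chain(s) not in model '", model$entry_id,
            "': ", paste(missing_chain, collapse = ", "),
            " (entries ignored)")
    cfg <- cfg[!(cfg$chain %in% missing_chain), , drop = FALSE]
  }
  dup <- cfg$subunit[cfg$subunit != "unknown"]
  dup <- unique(dup[duplicated(dup)])
  if (length(dup)) {
    stop("duplicate canonical subunit assignment(s): ",
         paste(dup, collapse = ", "))
  }
  sub_of <- stats::setNames(rep("unknown", length(chains)), chains)
  sub_of[cfg$chain] <- cfg$subunit
  unmapped <- chains[sub_of == "unknown"]
  if (length(unmapped)) {
    warning("chain(s) not covered by subunit map for '", model$entry_id,
            "': ", paste(unmapped, collapse = ", "),
            " (mapped to \"unknown\")")
  }
  model$subunit_of <- sub_of
  model
}

#' Write a structure model to a coordinate file
#'
#' Emits PDB or a minimal mmCIF (`atom_site` loop with author identifiers)
#' that [load_structure()] reads back with residue identity preserved
#' exactly and coordinates at format precision (1e-3 A).
#'
#' @param model A non-empty `structure_model`.
#' @param path Output path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif")) {
  stopifnot(inherits(model, "structure_model"))
  format <- match.arg(format)
  a <- model$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty model")
  if (format == "pdb") {
    if (any(nchar(a$atom_name) > 4L)) {
      stop("atom name(s) longer than the 4-character PDB field: ",
           paste(unique(a$atom_name[nchar(a$atom_name) > 4L]),
                 collapse = ", "))
    }
    if (any(nchar(a$chain) > 1L)) {
      stop("chain id(s) longer than the 1-character PDB field: ",
           paste(unique(a$chain[nchar(a$chain) > 1L]), collapse = ", "))
    }
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      type = ifelse(a$is_hetero, "HETATM", "ATOM"),
      resno = a$seq_num, resid = a$comp_id, chain = a$chain,
      insert = ifelse(nzchar(a$icode), a$icode, NA),
      alt = ifelse(nzchar(a$altloc), a$altloc, NA),
      eleno = seq_len(nrow(a)), elety = a$atom_name,
      o = a$occupancy, b = rep(0, nrow(a)), elesy = a$element
    )
  } else {
    write_mmcif_atom_site(model, path)
  }
  invisible(path)
}

# Minimal mmCIF writer: data block + atom_site loop, author fields mirrored
# into label fields so either convention reads back identically.
write_mmcif_atom_site <- function(model, path) {
  a <- model$atoms
  dot <- function(v) ifelse(nzchar(v), v, ".")
  rows <- sprintf(
    "%s %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
    ifelse(a$is_hetero, "HETATM", "ATOM"), seq_len(nrow(a)), a$element,
    a$atom_name, dot(a$altloc), a$comp_id, a$chain, a$seq_num,
    a$x, a$y, a$z, a$occupancy,
    a$seq_num, a$comp_id, a$chain, a$atom_name
  )
  header <- c(
    paste0("data_", model$entry_id), "#", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
             "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"))
  )
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}
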