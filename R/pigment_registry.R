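# Cofactor classification and pigment extraction.
#
# The registry that maps chemical component ids to pigment/lipid classes,
# and per class the conjugated atom subset used for edge-to-edge distances,
# is data (a packaged TSV), not code: renamed or novel component ids are a
# config change. Classification is purely by component id -- no bond-order
# perception from coordinates.

CHL_CLASSES <- c("CHL_A", "CHL_B")
CAR_CLASSES <- c("CAR_BCR", "CAR_LUT", "CAR_VIO")
LIPID_CLASSES <- c("LIPID_PG", "LIPID_MGDG", "LIPID_DGDG")
PIGMENT_CLASSES <- c(CHL_CLASSES, CAR_CLASSES, LIPID_CLASSES)

#' Read a pigment class registry
#'
#' Tab-separated table with columns class, component-id list, Mg atom name
#' (`.` for none), conjugated atom-name list (`.` for none; the sentinel
#' `ALL_C` selects every carbon atom, used for carotenoid polyenes).
#'
#' @param path Path to a registry TSV; default the packaged registry.
#' @return A `pigment_registry`: named list of class entries, each with
#'   `comp_ids`, `mg_atom` and `conjugated` fields.
#' @export
read_pigment_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pigment_registry.tsv",
                        package = "pigmentnet")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("malformed registry line(s): ",
                     paste(lines[bad], collapse = "; "))
  reg <- lapply(parts, function(p) {
    list(
      class = trimws(p[1]),
      comp_ids = toupper(trimws(strsplit(p[2], ",")[[1]])),
      mg_atom = if (trimws(p[3]) == ".") NA_character_ else
        toupper(trimws(p[3])),
      conjugated = if (trimws(p[4]) == ".") character(0) else
        toupper(trimws(strsplit(p[4], ",")[[1]]))
    )
  })
  names(reg) <- vapply(reg, `[[`, "", "class")
  all_ids <- unlist(lapply(reg, `[[`, "comp_ids"))
  if (anyDuplicated(all_ids)) {
    stop("component id(s) assigned to more than one class: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  for (e in reg) {
    if (e$class %in% CHL_CLASSES &&
        (is.na(e$mg_atom) || !length(e$conjugated))) {
      stop("chlorophyll class ", e$class,
           " must define an Mg atom and a conjugated set")
    }
    if (e$class %in% LIPID_CLASSES && length(e$conjugated)) {
      stop("lipid class ", e$class, " must not define a conjugated set")
    }
  }
  class(reg) <- "pigment_registry"
  reg
}

# Memoised default registry.
the <- new.env(parent = emptyenv())
default_registry <- function() {
  if (is.null(the$registry)) the$registry <- read_pigment_registry()
  the$registry
}

#' Classify a residue by chemical component id
#'
#' Total function: any component id not in the registry (including all
#' protein residues) returns `"OTHER"`.
#'
#' @param comp_id Chemical component identifier (e.g. `"CLA"`, `"BCR"`).
#' @param registry A `pigment_registry`.
#' @return The class name, one of the registry classes or `"OTHER"`.
#' @export
classify_residue <- function(comp_id, registry = default_registry()) {
  comp_id <- toupper(comp_id)
  for (e in registry) if (comp_id %in% e$comp_ids) return(e$class)
  "OTHER"
}

pid_string <- function(subunit, comp_id, seq_num) {
  paste(subunit, comp_id, seq_num, sep = ":")
}

new_pigment <- function(subunit, chain, comp_id, seq_num, klass, atoms,
                        conj_names, mg_atom) {
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  if (identical(conj_names, "ALL_C")) {
    conj <- heavy[heavy$element == "C", , drop = FALSE]
  } else {
    conj <- heavy[heavy$atom_name %in% conj_names, , drop = FALSE]
  }
  conj_xyz <- as.matrix(conj[, c("x", "y", "z")])
  rownames(conj_xyz) <- conj$atom_name
  mg <- NULL
  if (!is.na(mg_atom)) {
    hit <- heavy[heavy$atom_name == mg_atom, , drop = FALSE]
    if (nrow(hit)) mg <- as.numeric(hit[1, c("x", "y", "z")])
  }
  base <- if (nrow(conj_xyz)) conj_xyz else
    as.matrix(heavy[, c("x", "y", "z")])
  centroid <- colMeans(base)
  radius <- if (nrow(conj_xyz)) {
    sqrt(max(rowSums((conj_xyz - rep(centroid, each = nrow(conj_xyz)))^2)))
  } else 0
  structure(
    list(pid = pid_string(subunit, comp_id, seq_num),
         subunit = subunit, chain = chain, comp_id = comp_id,
         seq_num = seq_num, klass = klass, atoms = atoms,
         conj_xyz = conj_xyz, mg = mg,
         centroid = as.numeric(centroid), radius = radius),
    class = "pigment"
  )
}

#' @export
print.pigment <- function(x, ...) {
  cat(sprintf("pigment %s [%s]: %d atoms, %d conjugated, Mg %s\n",
              x$pid, x$klass, nrow(x$atoms), nrow(x$conj_xyz),
              if (is.null(x$mg)) "absent" else "present"))
  invisible(x)
}

#' Extract classified pigments from a structure model
#'
#' One `pigment` per hetero residue whose component id is in the registry.
#' The conjugated subset is the intersection of the registry atom names
#' with the atoms actually present; a chlorophyll lacking its Mg atom is
#' retained with `mg = NULL` and a warning. Hydrogens never enter the
#' conjugated set or the centroid.
#'
#' @param model A `structure_model` (apply the subunit map first so pigment
#'   identifiers carry subunit names).
#' @param registry A `pigment_registry`.
#' @return List of `pigment` objects, in file order.
#' @export
extract_pigments <- function(model, registry = default_registry()) {
  stopifnot(inherits(model, "structure_model"))
  res <- model_residues(model)
  res <- res[res$is_hetero, , drop = FALSE]
  out <- vector("list", nrow(res))
  n <- 0L
  for (i in seq_len(nrow(res))) {
    klass <- classify_residue(res$comp_id[i], registry)
    if (klass == "OTHER") next
    e <- registry[[klass]]
    atoms <- residue_atoms(model, res$chain[i], res$seq_num[i], res$icode[i])
    pg <- new_pigment(
      subunit = chain_subunit(model, res$chain[i]), chain = res$chain[i],
      comp_id = res$comp_id[i], seq_num = res$seq_num[i], klass = klass,
      atoms = atoms,
      conj_names = if (identical(e$conjugated, "ALL_C")) "ALL_C" else
        e$conjugated,
      mg_atom = e$mg_atom
    )
    if (klass %in% CHL_CLASSES && is.null(pg$mg)) {
      warning("chlorophyll ", pg$pid, " lacks its Mg atom (", e$mg_atom,
              "); Mg-based quantities unavailable for it")
    }
    n <- n + 1L
    out[[n]] <- pg
  }
  out <- out[seq_len(n)]
  names(out) <- vapply(out, `[[`, "", "pid")
  out
}

#' Tabulate a pigment inventory
#'
#' Counts pigments per subunit and class.
#'
#' @param pigments List of `pigment` objects.
#' @return A `pigment_inventory`: list with `per_subunit` (subunit x class
#'   integer matrix) and `totals` (named integer vector over classes).
#' @export
build_inventory <- function(pigments) {
  classes <- PIGMENT_CLASSES
  subunits <- sort(unique(vapply(pigments, `[[`, "", "subunit")))
  m <- matrix(0L, nrow = length(subunits), ncol = length(classes),
              dimnames = list(subunits, classes))
  for (p in pigments) m[p$subunit, p$klass] <- m[p$subunit, p$klass] + 1L
  structure(list(per_subunit = m, totals = colSums(m)),
            class = "pigment_inventory")
}

#' @export
print.pigment_inventory <- function(x, ...) {
  tot <- x$totals
  cat(sprintf(
    "pigment_inventory: %d Chl (%d a, %d b), %d Car, %d lipid\n",
    sum(tot[CHL_CLASSES]), tot[["CHL_A"]], tot[["CHL_B"]],
    sum(tot[CAR_CLASSES]), sum(tot[LIPID_CLASSES])
  ))
  print(x$per_subunit[rowSums(x$per_subunit) > 0, , drop = FALSE])
  invisible(x)
}

#' Write an inventory report
#'
#' TSV with subunit rows and class columns plus a totals row, and a JSON
#' sidecar with the same content.
#'
#' @param inventory A `pigment_inventory`.
#' @param path Output TSV path; the JSON goes to the same stem `.json`.
#' @return Invisibly, `path`.
#' @export
write_inventory <- function(inventory, path) {
  df <- as.data.frame(inventory$per_subunit)
  df <- cbind(subunit = rownames(df), df)
  tot <- as.data.frame(t(inventory$totals))
  tot <- cbind(subunit = "TOTAL", tot)
  utils::write.table(rbind(df, tot), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(per_subunit = inventory$per_subunit, totals = inventory$totals),
    sub("\\.tsv$", ".json", path), matrix = "rowmajor"
  )
  invisible(path)
}
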