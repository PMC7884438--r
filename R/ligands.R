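# Axial Mg coordination and red-form chlorophyll dimers.
#
# The central Mg of a protein-bound chlorophyll is usually coordinated by
# one side-chain N or O (His NE2/ND1, Asn OD1, Gln OE1, ...); the ligand
# identity (His vs Asn) at the 603 site modulates how far the 603-609
# red-form dimer shifts the fluorescence emission. A chlorophyll with no
# eligible atom within the cutoff is reported unassigned -- never guessed.

PROTEIN_COMP_IDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
BACKBONE_NO_ATOMS <- c("N", "O", "OXT")

# Eligible coordinating atoms: side-chain N/O of protein residues;
# optionally lipid oxygens (off by default). Waters are excluded at load.
eligible_ligand_atoms <- function(model, include_lipids = FALSE) {
  a <- model$atoms
  keep <- !a$is_hetero & a$comp_id %in% PROTEIN_COMP_IDS &
    a$element %in% c("N", "O") & !(a$atom_name %in% BACKBONE_NO_ATOMS)
  if (include_lipids) {
    lipid_ids <- unlist(lapply(default_registry()[LIPID_CLASSES],
                               `[[`, "comp_ids"))
    keep <- keep | (a$comp_id %in% lipid_ids & a$element == "O")
  }
  a[keep, , drop = FALSE]
}

unassigned_ligand <- function(pid) {
  data.frame(
    pigment = pid, ligand_subunit = NA_character_,
    ligand_comp = NA_character_, ligand_seq = NA_integer_,
    ligand_atom = NA_character_, d_lig = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Detect the axial Mg ligand of a chlorophyll
#'
#' Among side-chain N/O atoms of protein residues within `cutoff` of the
#' chlorophyll's Mg, returns the nearest; when none is within the cutoff
#' the assignment is returned unassigned (all-`NA` ligand fields).
#' Backbone N/O and waters are never eligible.
#'
#' @param chl A chlorophyll `pigment` with an Mg position.
#' @param model The `structure_model` the pigment came from.
#' @param cutoff Detection cutoff, A. Default 3.0: typical Mg--N/O
#'   coordination is 2.0--2.4 A and the margin tolerates model error.
#' @param include_lipids Also consider lipid oxygens (default `FALSE`).
#' @return One-row data frame: pigment, ligand_subunit, ligand_comp,
#'   ligand_seq, ligand_atom, d_lig.
#' @export
detect_mg_ligand <- function(chl, model, cutoff = 3.0,
                             include_lipids = FALSE) {
  if (is.null(chl$mg)) {
    stop("pigment ", chl$pid, " has no Mg position")
  }
  cand <- eligible_ligand_atoms(model, include_lipids)
  if (nrow(cand) == 0L) return(unassigned_ligand(chl$pid))
  d <- sqrt((cand$x - chl$mg[1])^2 + (cand$y - chl$mg[2])^2 +
              (cand$z - chl$mg[3])^2)
  within <- which(d <= cutoff)
  if (!length(within)) return(unassigned_ligand(chl$pid))
  best <- within[order(d[within], cand$atom_name[within])][1]
  data.frame(
    pigment = chl$pid,
    ligand_subunit = chain_subunit(model, cand$chain[best]),
    ligand_comp = cand$comp_id[best],
    ligand_seq = cand$seq_num[best],
    ligand_atom = cand$atom_name[best],
    d_lig = d[best], stringsAsFactors = FALSE
  )
}

#' Ligand assignments for all chlorophylls
#'
#' One row per chlorophyll-class pigment (unassigned rows kept, as in the
#' TSV report contract). Pigments without an Mg atom are skipped with a
#' warning.
#'
#' @inheritParams detect_mg_ligand
#' @param pigments List of `pigment` objects.
#' @return Data frame of [detect_mg_ligand()] rows.
#' @export
ligand_table <- function(pigments, model, cutoff = 3.0,
                         include_lipids = FALSE) {
  chls <- Filter(function(p) p$klass %in% CHL_CLASSES, pigments)
  rows <- lapply(chls, function(p) {
    if (is.null(p$mg)) {
      warning("skipping ", p$pid, ": no Mg position")
      return(NULL)
    }
    detect_mg_ligand(p, model, cutoff, include_lipids)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- unassigned_ligand(character(0))
  rownames(out) <- NULL
  out
}

#' Red-form candidate chlorophyll dimers
#'
#' Pairs of chlorophylls within the same subunit carrying the
#' red-form residue numbers (603/609 in the Lhca nomenclature;
#' configurable) whose Mg--Mg distance is within `dimer_cutoff`. Each
#' pair is annotated with the axial ligand of the 603-position member,
#' whose identity (His vs Asn) tracks the extent of the fluorescence
#' red shift.
#'
#' @param pigments List of `pigment` objects.
#' @param model The source `structure_model`.
#' @param dimer_cutoff Mg--Mg cutoff, A. Default 12 -- generous, since
#'   genuinely stacked dimers are far closer; it only guards against
#'   mislabelled residues.
#' @param number_pair Length-2 integer vector of residue numbers,
#'   default `c(603, 609)`.
#' @param ligand_cutoff Cutoff passed to [detect_mg_ligand()].
#' @return Data frame: a, b (pids), subunit, d_mg, ligand_of_603 (comp id
#'   or `NA`).
#' @export
red_form_pairs <- function(pigments, model, dimer_cutoff = 12,
                           number_pair = c(603L, 609L),
                           ligand_cutoff = 3.0) {
  chls <- Filter(function(p) p$klass %in% CHL_CLASSES, pigments)
  out <- data.frame(
    a = character(), b = character(), subunit = character(),
    d_mg = numeric(), ligand_of_603 = character(),
    stringsAsFactors = FALSE
  )
  subs <- unique(vapply(chls, `[[`, "", "subunit"))
  for (s in subs) {
    in_s <- Filter(function(p) p$subunit == s, chls)
    nums <- vapply(in_s, `[[`, 0L, "seq_num")
    pa <- in_s[nums == number_pair[1]]
    pb <- in_s[nums == number_pair[2]]
    if (!length(pa) || !length(pb)) next
    a <- pa[[1]]; b <- pb[[1]]
    d <- mg_mg(a, b)
    if (is.na(d) || d > dimer_cutoff) next
    lig <- if (is.null(a$mg)) NA_character_ else {
      detect_mg_ligand(a, model, ligand_cutoff)$ligand_comp
    }
    out <- rbind(out, data.frame(
      a = a$pid, b = b$pid, subunit = s, d_mg = d,
      ligand_of_603 = lig, stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Write a ligand report to TSV
#'
#' @param tab Data frame from [ligand_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ligand_table <- function(tab, path) {
  tab$d_lig <- round(tab$d_lig, 2)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "unassigned")
  invisible(path)
}
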