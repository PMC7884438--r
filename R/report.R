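# Orchestration: one-call inventory runs and the consolidated
# reproduction report for the moss PSI-LHCI analysis.
#
# No network access anywhere: reproduction against deposited entries
# requires the user to place the coordinate files locally. Claims whose
# structures are absent are marked "skipped", never silently dropped.

#' Run a full pigment inventory on one structure
#'
#' Load, map subunits, extract pigments, tabulate, and optionally write
#' the TSV/JSON report.
#'
#' @param structure_path Coordinate file (mmCIF or PDB).
#' @param map A `subunit_map`, a named chain->subunit vector, or `NULL`
#'   to use the packaged default for the entry (error if none exists).
#' @param out_dir Optional output directory for `inventory.tsv`/`.json`.
#' @param format Passed to [load_structure()].
#' @return List with `model`, `pigments`, `inventory`.
#' @export
run_inventory <- function(structure_path, map = NULL, out_dir = NULL,
                          format = "auto") {
  model <- load_structure(structure_path, format)
  if (is.null(map)) {
    map <- default_subunit_map(model$entry_id)
    if (is.null(map)) {
      stop("no packaged subunit map for entry '", model$entry_id,
           "'; supply one via `map`")
    }
  }
  model <- apply_subunit_map(model, map)
  pigments <- extract_pigments(model)
  inventory <- build_inventory(pigments)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_inventory(inventory, file.path(out_dir, "inventory.tsv"))
  }
  list(model = model, pigments = pigments, inventory = inventory)
}

find_entry_file <- function(structures_dir, entry_id) {
  if (is.null(structures_dir) || !dir.exists(structures_dir)) {
    return(NULL)
  }
  files <- list.files(structures_dir, full.names = TRUE)
  stems <- tolower(tools::file_path_sans_ext(basename(files)))
  exts <- tolower(tools::file_ext(files))
  hit <- which(stems == tolower(entry_id) &
                 exts %in% c("cif", "mmcif", "pdb", "ent"))
  if (length(hit)) files[hit[1]] else NULL
}

# The printed structural claims for the moss PSI-LHCI entry (6L35) and
# its comparison against the pea entry (4XK8). Distances are the
# published edge-to-edge values in Angstrom, reproduced within +/- 0.5 A
# (the convention-level tolerance: the authors' exact conjugated-atom
# set is unstated). Note the source reports the Lhca1 Chl 616 -- PsaF
# Chl 304 contact as 7.3 A in one section and 7.5 A in another; the 7.5
# figure from the pathway listing is used here and the discrepancy is
# documented rather than force-fit.
repro_distance_claims <- function() {
  d <- rbind(
    c("Lhca1", 603, "PsaB", 841, 7.4),
    c("Lhca1", 609, "PsaB", 822, 13.0),
    c("Lhca1", 607, "PsaG", 201, 5.7),
    c("Lhca1", 616, "PsaF", 304, 7.5),
    c("Lhca5", 601, "PsaF", 305, 7.7),
    c("Lhca2", 609, "PsaF", 305, 11.4),
    c("Lhca2", 603, "PsaJ", 101, 12.0),
    c("Lhca2", 607, "PsaJ", 101, 16.9),
    c("Lhca3", 603, "PsaA", 811, 11.0),
    c("Lhca3", 602, "PsaA", 813, 15.3),
    c("Lhca3", 607, "PsaA", 817, 5.9),
    c("Lhca3", 613, "PsaK", 204, 12.8)
  )
  data.frame(
    sub_a = d[, 1], num_a = as.integer(d[, 2]),
    sub_b = d[, 3], num_b = as.integer(d[, 4]),
    paper_d = as.numeric(d[, 5]), stringsAsFactors = FALSE
  )
}

repro_ligand_claims <- function() {
  data.frame(
    subunit = c("Lhca1", "Lhca5", "Lhca2", "Lhca3"),
    comp = c("HIS", "HIS", "HIS", "ASN"),
    seq = c(93L, 117L, 110L, 148L),
    stringsAsFactors = FALSE
  )
}

claim_row <- function(id, description, computed, expected, tolerance,
                      status) {
  data.frame(claim_id = id, description = description,
             computed = computed, expected = expected,
             tolerance = tolerance, status = status,
             stringsAsFactors = FALSE)
}

#' Consolidated reproduction report against the deposited entries
#'
#' Recomputes every machine-checkable structural claim of the moss
#' PSI-LHCI analysis from locally supplied coordinate files: the pigment
#' census (156 Chl = 144 a + 12 b, 34 Car, 10 lipids; 14 Chl per Lhca;
#' 2/3/3/4 Car across the Lhca belt), the printed edge-to-edge distances
#' (+/- 0.5 A), the Chl 603 axial ligand identities (His in
#' Lhca1/Lhca5/Lhca2, Asn in Lhca3), the four 603-609 red-form dimers,
#' the bridging pathway Chl 305 -> 303 -> 841 -> 301 -> 802 with every
#' hop within the 15 A adjacency rule, and -- when the pea entry 4XK8 is
#' also present -- the antenna-belt shift ranking (second Lhca site
#' first, Lhca1 second) and the Lhca3-site carotenoid occupancy
#' difference after superposition on the PsaA/PsaB core.
#'
#' @param structures_dir Directory holding `6L35.cif`/`.pdb` and
#'   optionally `4XK8.cif`/`.pdb`. Files are never downloaded.
#' @param out_dir Optional directory for `repro_report.tsv`/`.json`.
#' @param d_tol Distance tolerance, A (default 0.5).
#' @param D_max Pathway adjacency threshold, A (default 15).
#' @return A `repro_report` data frame: claim_id, description, computed,
#'   expected, tolerance, status (pass/fail/skipped).
#' @export
run_repro <- function(structures_dir, out_dir = NULL, d_tol = 0.5,
                      D_max = 15) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  skip_all <- function(ids_desc, why) {
    for (i in seq_len(nrow(ids_desc))) {
      add(claim_row(ids_desc$id[i], ids_desc$desc[i], NA_real_,
                    ids_desc$expected[i], ids_desc$tol[i], "skipped"))
    }
  }

  path_ref <- find_entry_file(structures_dir, "6L35")
  census_claims <- data.frame(
    id = c("chl_total", "chl_a", "chl_b", "car_total", "lipid_total",
           paste0("chl_per_", c("Lhca1", "Lhca5", "Lhca2", "Lhca3")),
           paste0("car_per_", c("Lhca1", "Lhca5", "Lhca2", "Lhca3"))),
    desc = c("total chlorophylls", "chlorophyll a", "chlorophyll b",
             "total carotenoids", "total lipids",
             paste("Chl count in", c("Lhca1", "Lhca5", "Lhca2", "Lhca3")),
             paste("Car count in", c("Lhca1", "Lhca5", "Lhca2", "Lhca3"))),
    expected = c(156, 144, 12, 34, 10, 14, 14, 14, 14, 2, 3, 3, 4),
    tol = 0, stringsAsFactors = FALSE
  )
  dist_claims <- repro_distance_claims()
  lig_claims <- repro_ligand_claims()

  if (is.null(path_ref)) {
    skip_all(census_claims, "6L35 absent")
    for (i in seq_len(nrow(dist_claims))) {
      add(claim_row(
        sprintf("d_%s%d_%s%d", dist_claims$sub_a[i], dist_claims$num_a[i],
                dist_claims$sub_b[i], dist_claims$num_b[i]),
        sprintf("edge-to-edge %s Chl %d -- %s Chl %d",
                dist_claims$sub_a[i], dist_claims$num_a[i],
                dist_claims$sub_b[i], dist_claims$num_b[i]),
        NA_real_, dist_claims$paper_d[i], d_tol, "skipped"))
    }
    for (i in seq_len(nrow(lig_claims))) {
      add(claim_row(paste0("ligand_603_", lig_claims$subunit[i]),
                    paste("Chl 603 ligand in", lig_claims$subunit[i]),
                    NA_real_, 1, 0, "skipped"))
    }
    add(claim_row("red_form_pairs", "603-609 red-form dimer count",
                  NA_real_, 4, 0, "skipped"))
    add(claim_row("gap_pathway_max_hop",
                  "max hop on Chl 305->303->841->301->802", NA_real_,
                  D_max, 0, "skipped"))
  } else {
    ref <- run_inventory(path_ref)
    inv <- ref$inventory
    per <- inv$per_subunit
    cnt <- function(sub, classes) {
      if (sub %in% rownames(per)) sum(per[sub, classes]) else 0L
    }
    computed <- c(
      sum(inv$totals[CHL_CLASSES]), inv$totals[["CHL_A"]],
      inv$totals[["CHL_B"]], sum(inv$totals[CAR_CLASSES]),
      sum(inv$totals[LIPID_CLASSES]),
      vapply(c("Lhca1", "Lhca5", "Lhca2", "Lhca3"), cnt, 0,
             classes = CHL_CLASSES),
      vapply(c("Lhca1", "Lhca5", "Lhca2", "Lhca3"), cnt, 0,
             classes = CAR_CLASSES)
    )
    for (i in seq_len(nrow(census_claims))) {
      add(claim_row(census_claims$id[i], census_claims$desc[i],
                    computed[i], census_claims$expected[i], 0,
                    if (computed[i] == census_claims$expected[i]) "pass"
                    else "fail"))
    }

    chls <- Filter(function(p) p$klass %in% CHL_CLASSES, ref$pigments)
    find_pig <- function(sub, num) {
      hit <- Filter(function(p) p$subunit == sub && p$seq_num == num, chls)
      if (length(hit)) hit[[1]] else NULL
    }
    for (i in seq_len(nrow(dist_claims))) {
      a <- find_pig(dist_claims$sub_a[i], dist_claims$num_a[i])
      b <- find_pig(dist_claims$sub_b[i], dist_claims$num_b[i])
      id <- sprintf("d_%s%d_%s%d", dist_claims$sub_a[i],
                    dist_claims$num_a[i], dist_claims$sub_b[i],
                    dist_claims$num_b[i])
      desc <- sprintf("edge-to-edge %s Chl %d -- %s Chl %d",
                      dist_claims$sub_a[i], dist_claims$num_a[i],
                      dist_claims$sub_b[i], dist_claims$num_b[i])
      if (is.null(a) || is.null(b)) {
        add(claim_row(id, desc, NA_real_, dist_claims$paper_d[i], d_tol,
                      "fail"))
      } else {
        dd <- edge_to_edge(a, b)
        add(claim_row(id, desc, dd, dist_claims$paper_d[i], d_tol,
                      if (abs(dd - dist_claims$paper_d[i]) <= d_tol)
                        "pass" else "fail"))
      }
    }

    for (i in seq_len(nrow(lig_claims))) {
      p <- find_pig(lig_claims$subunit[i], 603L)
      id <- paste0("ligand_603_", lig_claims$subunit[i])
      desc <- sprintf("Chl 603 ligand in %s is %s %d",
                      lig_claims$subunit[i], lig_claims$comp[i],
                      lig_claims$seq[i])
      if (is.null(p) || is.null(p$mg)) {
        add(claim_row(id, desc, 0, 1, 0, "fail"))
      } else {
        la <- detect_mg_ligand(p, ref$model)
        ok <- !is.na(la$ligand_comp) &&
          la$ligand_comp == lig_claims$comp[i] &&
          la$ligand_seq == lig_claims$seq[i]
        add(claim_row(id, desc, as.numeric(ok), 1, 0,
                      if (ok) "pass" else "fail"))
      }
    }

    rf <- red_form_pairs(ref$pigments, ref$model)
    add(claim_row("red_form_pairs", "603-609 red-form dimer count",
                  nrow(rf), 4, 0, if (nrow(rf) == 4) "pass" else "fail"))

    chain <- list(c("PsaF", 305L), c("PsaF", 303L), c("PsaA", 841L),
                  c("PsaF", 301L), c("PsaA", 802L))
    hops <- rep(NA_real_, length(chain) - 1L)
    for (i in seq_len(length(chain) - 1L)) {
      a <- find_pig(chain[[i]][1], as.integer(chain[[i]][2]))
      b <- find_pig(chain[[i + 1L]][1], as.integer(chain[[i + 1L]][2]))
      if (!is.null(a) && !is.null(b)) hops[i] <- edge_to_edge(a, b)
    }
    ok <- all(!is.na(hops)) && max(hops) <= D_max
    add(claim_row("gap_pathway_max_hop",
                  "max hop on Chl 305->303->841->301->802",
                  if (all(!is.na(hops))) max(hops) else NA_real_,
                  D_max, 0, if (ok) "pass" else "fail"))
  }

  path_mob <- find_entry_file(structures_dir, "4XK8")
  comp_ids <- data.frame(
    id = c("shift_rank1_is_pos2", "shift_rank2_is_Lhca1",
           "car_diff_Lhca3_site"),
    desc = c("largest belt shift at the second Lhca site",
             "second largest belt shift at Lhca1",
             "Car occupancy excess at the Lhca3 site vs pea"),
    expected = c(1, 1, 1), tol = 0, stringsAsFactors = FALSE
  )
  if (is.null(path_ref) || is.null(path_mob)) {
    skip_all(comp_ids, "4XK8 absent")
  } else {
    mob <- run_inventory(path_mob)
    sp <- superpose(mob$model, ref$model, c("PsaA", "PsaB"))
    mobt <- apply_transform(mob$model, sp)
    mob_pigs <- extract_pigments(mobt)
    matches <- match_pigments(ref$pigments, mob_pigs)
    pairing <- read_pairing_table(
      system.file("extdata", "pairing_6L35_4XK8.tsv",
                  package = "pigmentnet"))
    rank <- subunit_shift_ranking(matches, pairing)
    ok1 <- nrow(rank) >= 1 && rank$subunit[1] == "Lhca5"
    ok2 <- nrow(rank) >= 2 && rank$subunit[2] == "Lhca1"
    add(claim_row("shift_rank1_is_pos2", comp_ids$desc[1],
                  as.numeric(ok1), 1, 0, if (ok1) "pass" else "fail"))
    add(claim_row("shift_rank2_is_Lhca1", comp_ids$desc[2],
                  as.numeric(ok2), 1, 0, if (ok2) "pass" else "fail"))
    od <- site_occupancy_diff(ref$inventory, mob$inventory, pairing)
    car_diff <- sum(od$diff[od$site == "pos4" &
                              od$class %in% CAR_CLASSES])
    ok3 <- car_diff == 1
    add(claim_row("car_diff_Lhca3_site", comp_ids$desc[3], car_diff, 1,
                  0, if (ok3) "pass" else "fail"))
  }

  report <- do.call(rbind, rows)
  class(report) <- c("repro_report", class(report))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(out_dir, "repro_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "repro_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.repro_report <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("pass", "fail", "skipped")))
  cat(sprintf("repro_report: %d pass, %d fail, %d skipped\n",
              tab[["pass"]], tab[["fail"]], tab[["skipped"]]))
  print.data.frame(x, digits = 4)
  invisible(x)
}
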