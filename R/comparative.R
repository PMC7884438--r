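# Cross-structure pigment correspondence and shift analysis.
#
# After superposing two homologous structures on their conserved core,
# pigments are matched geometrically (never by residue numbering, which
# is not shared across species) and per-site displacement statistics
# quantify how far each antenna site has shifted.

#' Geometric one-to-one pigment matching
#'
#' Greedy globally-nearest matching by centroid distance: all cross
#' pairs are sorted by distance (ties by pid strings), and a pair is
#' accepted when both members are still unmatched and the distance is at
#' most `threshold`. Remaining reference pigments are `lost_in_mobile`,
#' remaining mobile pigments `gained_in_mobile`.
#'
#' @param ref Pigment list of the reference structure.
#' @param mob_transformed Pigment list of the mobile structure, already
#'   transformed into the reference frame (extract pigments from the
#'   model returned by [apply_transform()]).
#' @param threshold Acceptance threshold, A. Default 3.5: tolerant of
#'   genuine site shifts but well below the ~8--10 A spacing of adjacent
#'   chlorophyll sites, so a match never bridges two different sites.
#' @return Data frame: ref_pid, mob_pid, ref_subunit, mob_subunit,
#'   displacement (A), status.
#' @export
match_pigments <- function(ref, mob_transformed, threshold = 3.5) {
  mob <- mob_transformed
  nr <- length(ref)
  nm <- length(mob)
  ref_pid <- vapply(ref, `[[`, "", "pid")
  mob_pid <- vapply(mob, `[[`, "", "pid")
  rows <- list()
  if (nr && nm) {
    rc <- t(vapply(ref, `[[`, numeric(3), "centroid"))
    mc <- t(vapply(mob, `[[`, numeric(3), "centroid"))
    d <- sqrt(cross_dist2(rc, mc))
    cand <- which(d <= threshold, arr.ind = TRUE)
    ord <- order(d[cand], ref_pid[cand[, 1]], mob_pid[cand[, 2]])
    cand <- cand[ord, , drop = FALSE]
    used_r <- logical(nr)
    used_m <- logical(nm)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_r[i] || used_m[j]) next
      used_r[i] <- TRUE
      used_m[j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        ref_pid = ref_pid[i], mob_pid = mob_pid[j],
        ref_subunit = ref[[i]]$subunit, mob_subunit = mob[[j]]$subunit,
        displacement = d[i, j], status = "matched",
        stringsAsFactors = FALSE
      )
    }
  } else {
    used_r <- logical(nr)
    used_m <- logical(nm)
  }
  for (i in which(!used_r)) {
    rows[[length(rows) + 1L]] <- data.frame(
      ref_pid = ref_pid[i], mob_pid = NA_character_,
      ref_subunit = ref[[i]]$subunit, mob_subunit = NA_character_,
      displacement = NA_real_, status = "lost_in_mobile",
      stringsAsFactors = FALSE
    )
  }
  for (j in which(!used_m)) {
    rows[[length(rows) + 1L]] <- data.frame(
      ref_pid = NA_character_, mob_pid = mob_pid[j],
      ref_subunit = NA_character_, mob_subunit = mob[[j]]$subunit,
      displacement = NA_real_, status = "gained_in_mobile",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ref_pid = character(), mob_pid = character(),
                      ref_subunit = character(), mob_subunit = character(),
                      displacement = numeric(), status = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$status, out$ref_pid, out$mob_pid,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a subunit pairing table
#'
#' Tab-separated columns `site`, `ref_subunit`, `mob_subunit`: the
#' explicit statement of which antenna site in one structure corresponds
#' to which in the other (e.g. the second Lhca position is Lhca5 in one
#' organism and Lhca4 in another). Sites are never paired by name
#' blindly.
#'
#' @param path Path to the TSV (comment lines start with `#`).
#' @return Data frame with columns site, ref_subunit, mob_subunit.
#' @export
read_pairing_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("site", "ref_subunit", "mob_subunit")
  if (!all(need %in% names(df))) {
    stop("pairing table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Per-site pigment displacement statistics
#'
#' Displacement statistics over matched pigments, grouped by reference
#' subunit (optionally relabelled to site names through a pairing
#' table), sorted by decreasing mean displacement.
#'
#' @param matches Data frame from [match_pigments()].
#' @param pairing Optional pairing table ([read_pairing_table()]); when
#'   given, only its `ref_subunit` rows are reported and rows are
#'   labelled by `site`. Naming a subunit absent from the matches is an
#'   error.
#' @return Data frame: site, subunit, n_pigments, mean_disp, median_disp,
#'   max_disp.
#' @export
subunit_shift_ranking <- function(matches, pairing = NULL) {
  m <- matches[matches$status == "matched", , drop = FALSE]
  if (!is.null(pairing)) {
    known <- unique(matches$ref_subunit)
    bad <- setdiff(pairing$ref_subunit, known)
    if (length(bad)) {
      stop("pairing table names unknown subunit(s): ",
           paste(bad, collapse = ", "))
    }
    m <- m[m$ref_subunit %in% pairing$ref_subunit, , drop = FALSE]
    site_of <- stats::setNames(pairing$site, pairing$ref_subunit)
  } else {
    site_of <- NULL
  }
  subs <- sort(unique(m$ref_subunit))
  rows <- lapply(subs, function(s) {
    d <- m$displacement[m$ref_subunit == s]
    data.frame(
      site = if (is.null(site_of)) s else unname(site_of[s]),
      subunit = s, n_pigments = length(d),
      mean_disp = mean(d), median_disp = stats::median(d),
      max_disp = max(d), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(site = character(), subunit = character(),
                      n_pigments = integer(), mean_disp = numeric(),
                      median_disp = numeric(), max_disp = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(-out$mean_disp, out$subunit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-site pigment class occupancy differences
#'
#' Signed count differences (reference minus mobile) per paired site and
#' pigment class, e.g. to show that one structure binds one more
#' carotenoid at a given antenna site.
#'
#' @param ref_inventory,mob_inventory `pigment_inventory` objects.
#' @param pairing Pairing table ([read_pairing_table()]).
#' @return Data frame: site, ref_subunit, mob_subunit, class, ref_count,
#'   mob_count, diff.
#' @export
site_occupancy_diff <- function(ref_inventory, mob_inventory, pairing) {
  get_count <- function(inv, subunit, klass) {
    m <- inv$per_subunit
    if (subunit %in% rownames(m)) m[subunit, klass] else 0L
  }
  rows <- list()
  for (i in seq_len(nrow(pairing))) {
    for (cl in PIGMENT_CLASSES) {
      rc <- get_count(ref_inventory, pairing$ref_subunit[i], cl)
      mc <- get_count(mob_inventory, pairing$mob_subunit[i], cl)
      rows[[length(rows) + 1L]] <- data.frame(
        site = pairing$site[i],
        ref_subunit = pairing$ref_subunit[i],
        mob_subunit = pairing$mob_subunit[i],
        class = cl, ref_count = rc, mob_count = mc, diff = rc - mc,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
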