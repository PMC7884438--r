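# Pigment distance computations and rigid-body superposition.

# Squared-distance matrix between two coordinate matrices (rows = points).
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Edge-to-edge distance between two pigments
#'
#' Minimum Euclidean distance over all pairs of conjugated atoms: the
#' closest approach of the two pi systems, the standard proxy for
#' excitation energy-transfer plausibility. The exact minimum is computed,
#' never an approximation.
#'
#' @param a,b `pigment` objects with non-empty conjugated sets.
#' @return Distance in Angstrom.
#' @export
edge_to_edge <- function(a, b) {
  if (nrow(a$conj_xyz) == 0L) {
    stop("pigment ", a$pid, " has an empty conjugated set")
  }
  if (nrow(b$conj_xyz) == 0L) {
    stop("pigment ", b$pid, " has an empty conjugated set")
  }
  sqrt(min(cross_dist2(a$conj_xyz, b$conj_xyz)))
}

#' Mg--Mg distance between two pigments
#'
#' @param a,b `pigment` objects.
#' @return Distance in Angstrom, or `NA` when either pigment has no Mg.
#' @export
mg_mg <- function(a, b) {
  if (is.null(a$mg) || is.null(b$mg)) return(NA_real_)
  sqrt(sum((a$mg - b$mg)^2))
}

#' All-pairs pigment distance table
#'
#' One record per unordered pigment pair with edge-to-edge, Mg--Mg and
#' centroid--centroid distances, sorted by edge-to-edge distance. With
#' `max_d`, pairs are pre-screened by the centroid bound
#' `d_centroid - r_a - r_b <= max_d` (with `r` the conjugated radius),
#' which can never discard a pair whose true edge-to-edge distance is
#' within `max_d`, and then filtered exactly.
#'
#' @param pigments List of `pigment` objects (at least 2).
#' @param classes Optional class filter (e.g. `c("CHL_A","CHL_B")`).
#' @param max_d Optional cutoff in Angstrom on the edge-to-edge distance.
#' @return Data frame with columns pid_a, pid_b, subunit_a, comp_a, num_a,
#'   subunit_b, comp_b, num_b, d_edge, d_mg, d_centroid.
#' @export
distance_table <- function(pigments, classes = NULL, max_d = NULL) {
  if (!is.null(classes)) {
    pigments <- Filter(function(p) p$klass %in% classes, pigments)
  }
  n <- length(pigments)
  empty <- data.frame(
    pid_a = character(), pid_b = character(),
    subunit_a = character(), comp_a = character(), num_a = integer(),
    subunit_b = character(), comp_b = character(), num_b = integer(),
    d_edge = numeric(), d_mg = numeric(), d_centroid = numeric(),
    stringsAsFactors = FALSE
  )
  if (n < 2L) return(empty)
  cent <- t(vapply(pigments, `[[`, numeric(3), "centroid"))
  rad <- vapply(pigments, `[[`, 0, "radius")
  dc <- sqrt(cross_dist2(cent, cent))
  idx <- which(upper.tri(dc), arr.ind = TRUE)
  if (!is.null(max_d)) {
    ok <- dc[idx] - rad[idx[, 1]] - rad[idx[, 2]] <= max_d
    idx <- idx[ok, , drop = FALSE]
  }
  if (nrow(idx) == 0L) return(empty)
  recs <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    a <- pigments[[i]]; b <- pigments[[j]]
    data.frame(
      pid_a = a$pid, pid_b = b$pid,
      subunit_a = a$subunit, comp_a = a$comp_id, num_a = a$seq_num,
      subunit_b = b$subunit, comp_b = b$comp_id, num_b = b$seq_num,
      d_edge = edge_to_edge(a, b), d_mg = mg_mg(a, b),
      d_centroid = dc[i, j], stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  if (!is.null(max_d)) out <- out[out$d_edge <= max_d, , drop = FALSE]
  out <- out[order(out$d_edge, out$pid_a, out$pid_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a distance table to TSV
#'
#' Distances reported to 0.1 Angstrom, matching how such distances are
#' printed in the structural literature; full precision is available from
#' the in-memory table.
#'
#' @param tab A data frame from [distance_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_table <- function(tab, path) {
  tab$d_edge <- round(tab$d_edge, 1)
  tab$d_mg <- round(tab$d_mg, 1)
  tab$d_centroid <- round(tab$d_centroid, 1)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Correspondence atoms between two models: matching (subunit, seq_num
# [+offset], atom_name) triples restricted to the selection.
superposition_pairs <- function(mobile, reference, subunits,
                                atom_names = "CA", residue_ranges = NULL,
                                offsets = NULL) {
  pick <- function(model, shift) {
    a <- model$atoms
    sub <- chain_subunit(model, a$chain)
    keep <- sub %in% subunits & a$atom_name %in% atom_names
    d <- a[keep, , drop = FALSE]
    d$subunit <- sub[keep]
    d$key_num <- d$seq_num + if (shift && !is.null(offsets)) {
      ifelse(is.na(offsets[d$subunit]), 0L, offsets[d$subunit])
    } else 0L
    if (!is.null(residue_ranges)) {
      ok <- rep(FALSE, nrow(d))
      for (s in names(residue_ranges)) {
        r <- residue_ranges[[s]]
        ok <- ok | (d$subunit == s & d$key_num >= r[1] & d$key_num <= r[2])
      }
      d <- d[ok, , drop = FALSE]
    }
    d$key <- paste(d$subunit, d$key_num, d$atom_name, sep = "\r")
    d[!duplicated(d$key), , drop = FALSE]
  }
  dm <- pick(mobile, shift = TRUE)
  dr <- pick(reference, shift = FALSE)
  common <- intersect(dm$key, dr$key)
  list(
    mobile = as.matrix(dm[match(common, dm$key), c("x", "y", "z")]),
    reference = as.matrix(dr[match(common, dr$key), c("x", "y", "z")]),
    n = length(common)
  )
}

# Kabsch: least-squares rotation (det +1 enforced) + translation mapping
# P (mobile) onto Q (reference).
kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  list(R = R, t = t)
}

#' Rigid-body superposition of one model onto another
#'
#' Least-squares optimal rotation and translation (no scaling; reflections
#' excluded by forcing determinant +1) over a correspondence built from
#' matching (subunit, author residue number, atom name) triples in the
#' selected subunits. Residues present in only one model are dropped. An
#' optional per-subunit residue-number offset table reconciles numbering
#' shifts between homologous entries; no sequence alignment is performed.
#'
#' @param mobile,reference `structure_model`s with subunit maps applied.
#' @param subunits Canonical subunit names to fit on (e.g.
#'   `c("PsaA","PsaB")`).
#' @param atom_names Atom names used for the fit; default CA trace.
#' @param residue_ranges Optional named list of `c(lo, hi)` author-number
#'   windows per subunit (e.g. to restrict to helices).
#' @param offsets Optional named integer vector: added to mobile residue
#'   numbers per subunit before matching.
#' @return A `superposition`: list with `R` (3x3 rotation), `t`
#'   (translation, Angstrom), `rmsd`, `n_atoms`, `selection_desc`.
#' @export
superpose <- function(mobile, reference, subunits, atom_names = "CA",
                      residue_ranges = NULL, offsets = NULL) {
  pr <- superposition_pairs(mobile, reference, subunits, atom_names,
                            residue_ranges, offsets)
  if (pr$n < 3L) {
    stop("superposition needs at least 3 correspondence atom pairs, got ",
         pr$n)
  }
  k <- kabsch(pr$mobile, pr$reference)
  moved <- sweep(pr$mobile %*% t(k$R), 2, k$t, "+")
  rmsd <- sqrt(mean(rowSums((moved - pr$reference)^2)))
  structure(
    list(R = k$R, t = k$t, rmsd = rmsd, n_atoms = pr$n,
         selection_desc = paste0(paste(subunits, collapse = ","), " [",
                                 paste(atom_names, collapse = ","), "]")),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition on %s: %d atoms, rmsd %.3f A\n",
              x$selection_desc, x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to a structure model
#'
#' Maps every atom position x to `R x + t`; all metadata preserved.
#'
#' @param model A `structure_model`.
#' @param sp A `superposition` (or any list with `R` and `t`).
#' @return The transformed model.
#' @export
apply_transform <- function(model, sp) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  moved <- sweep(xyz %*% t(sp$R), 2, sp$t, "+")
  model$atoms$x <- moved[, 1]
  model$atoms$y <- moved[, 2]
  model$atoms$z <- moved[, 3]
  model
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first` and then `second`.
#'
#' @param second,first Lists with `R` and `t`.
#' @return A list with `R` and `t`.
#' @export
compose_transform <- function(second, first) {
  list(R = second$R %*% first$R,
       t = as.numeric(second$R %*% first$t) + second$t)
}

#' Invert a rigid transform
#'
#' @param sp A list with `R` and `t`.
#' @return The inverse transform.
#' @export
invert_transform <- function(sp) {
  list(R = t(sp$R), t = as.numeric(-t(sp$R) %*% sp$t))
}
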