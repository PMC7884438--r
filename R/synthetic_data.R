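# Deterministic synthetic coordinate fixtures with fully known geometry.
#
# Every fixture comes with a ledger of ground-truth quantities (atom
# counts, all pairwise edge-to-edge and Mg--Mg distances, planted ligand
# distances, planted transforms) computed at generation time by direct
# enumeration -- deliberately written as plain loops here, independent of
# the geometry module, so the ledger can serve as an oracle for it.
#
# Templates reuse the real CLA atom naming (MG, NA/NB/NC/ND, C1A..C4A,
# CHA..CHD, ...) so the production registry classifies fixtures without
# special cases. Geometry is idealized, not chemically refined: only the
# distance bookkeeping needs to be exact.

# Brute-force minimum inter-point distance; intentionally loop-based and
# separate from geometry.R's vectorised computation.
brute_min_dist <- function(A, B) {
  m <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < m) m <- d
    }
  }
  m
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Uniform random rotation matrix (Rodrigues on a random axis/angle).
random_rotation <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Idealized planar chlorin macrocycle template
#'
#' Central MG at the origin, four pyrrole nitrogens at radius 2.05 A,
#' twenty conjugated perimeter carbons (sixteen pyrrole-ring carbons at
#' radii 2.9--4.2 A and four methine bridges), and three non-conjugated
#' "phytyl tail" carbons extending 5--10 A out of the macrocycle plane.
#' Conjugated atoms are exactly planar (z = 0) in the template frame.
#'
#' @return List with `atoms` (data frame name/element/x/y/z),
#'   `conjugated_names`, and `diameter` (largest conjugated pairwise
#'   distance, A).
#' @export
macrocycle_template <- function() {
  ring_angles <- c(A = 45, B = 135, C = 225, D = 315) * pi / 180
  bridge_angles <- c(CHA = 0, CHB = 90, CHC = 180, CHD = 270) * pi / 180
  rows <- list(data.frame(name = "MG", element = "MG", x = 0, y = 0, z = 0,
                          stringsAsFactors = FALSE))
  for (k in names(ring_angles)) {
    u <- c(cos(ring_angles[[k]]), sin(ring_angles[[k]]))
    v <- c(-u[2], u[1])
    pos <- rbind(
      2.05 * u,
      2.90 * u + 1.10 * v,
      4.10 * u + 0.68 * v,
      4.10 * u - 0.68 * v,
      2.90 * u - 1.10 * v
    )
    rows[[length(rows) + 1L]] <- data.frame(
      name = c(paste0("N", k), paste0("C", 1:4, k)),
      element = c("N", rep("C", 4)),
      x = pos[, 1], y = pos[, 2], z = 0, stringsAsFactors = FALSE
    )
  }
  for (k in names(bridge_angles)) {
    u <- c(cos(bridge_angles[[k]]), sin(bridge_angles[[k]]))
    rows[[length(rows) + 1L]] <- data.frame(
      name = k, element = "C", x = 3.4 * u[1], y = 3.4 * u[2], z = 0,
      stringsAsFactors = FALSE
    )
  }
  rows[[length(rows) + 1L]] <- data.frame(
    name = c("C1", "C2", "C3"), element = "C",
    x = c(3.0, 3.5, 4.0), y = 0, z = c(5, 7.5, 10),
    stringsAsFactors = FALSE
  )
  atoms <- do.call(rbind, rows)
  conj <- atoms$name[atoms$name != "MG" & !(atoms$name %in%
                                              c("C1", "C2", "C3"))]
  cxyz <- as.matrix(atoms[atoms$name %in% conj, c("x", "y", "z")])
  diam <- 0
  for (i in seq_len(nrow(cxyz))) {
    for (j in seq_len(nrow(cxyz))) {
      d <- sqrt(sum((cxyz[i, ] - cxyz[j, ])^2))
      if (d > diam) diam <- d
    }
  }
  list(atoms = atoms, conjugated_names = conj, diameter = diam)
}

# Transform a template's atoms: x -> R x + t. Returns the atom data frame.
place_template <- function(tpl, R, t) {
  xyz <- as.matrix(tpl$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  out <- tpl$atoms
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}

atoms_df <- function(chain, comp_id, seq_num, placed, is_hetero = TRUE) {
  data.frame(
    chain = chain, comp_id = comp_id, seq_num = as.integer(seq_num),
    icode = "", atom_name = placed$name, element = placed$element,
    x = placed$x, y = placed$y, z = placed$z,
    occupancy = 1, altloc = "", is_hetero = is_hetero,
    stringsAsFactors = FALSE
  )
}

conj_coords <- function(placed, tpl) {
  as.matrix(placed[placed$name %in% tpl$conjugated_names,
                   c("x", "y", "z")])
}

mg_coord <- function(placed) {
  as.numeric(placed[placed$name == "MG", c("x", "y", "z")])
}

# Ledger distance matrices over a list of placed macrocycles.
ledger_distances <- function(placed_list, tpl) {
  n <- length(placed_list)
  de <- matrix(0, n, n)
  dm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      de[i, j] <- brute_min_dist(conj_coords(placed_list[[i]], tpl),
                                 conj_coords(placed_list[[j]], tpl))
      dm[i, j] <- sqrt(sum((mg_coord(placed_list[[i]]) -
                              mg_coord(placed_list[[j]]))^2))
    }
  }
  list(d_edge = de, d_mg = dm)
}

#' Synthetic two-chlorophyll fixture at an exact edge-to-edge distance
#'
#' Two macrocycle copies under seeded random rotations, the second
#' translated along a seeded random direction with the translation
#' magnitude solved (by root finding against the generation-time
#' brute-force distance) so that the true edge-to-edge distance equals
#' `d_edge_target` within 1e-6 A.
#'
#' @param d_edge_target Target edge-to-edge distance, A (> 0).
#' @param seed Integer seed; generation is fully deterministic per seed.
#' @return List with `model` (a `structure_model`, chain A mapped to
#'   Lhca1, residues CLA 601/602) and `ledger` (ground truth: achieved
#'   distances, transforms, atom count).
#' @export
make_pair <- function(d_edge_target, seed = 1L) {
  stopifnot(d_edge_target > 0)
  tpl <- macrocycle_template()
  with_seed(seed, {
    R1 <- random_rotation()
    p1 <- place_template(tpl, R1, c(0, 0, 0))
    c1 <- conj_coords(p1, tpl)
    hi <- d_edge_target + 2 * tpl$diameter + 10
    # draw orientations until the root is bracketed: for small targets a
    # given relative orientation may never approach closer than the
    # target, in which case the orientation is redrawn (deterministic
    # under the seed)
    R2 <- NULL
    for (attempt in 1:50) {
      R2try <- random_rotation()
      utry <- stats::rnorm(3)
      utry <- utry / sqrt(sum(utry^2))
      f <- function(t) {
        p2 <- place_template(tpl, R2try, t * utry)
        brute_min_dist(c1, conj_coords(p2, tpl)) - d_edge_target
      }
      if (f(1e-6) < 0 && f(hi) > 0) {
        R2 <- R2try
        u <- utry
        break
      }
    }
    if (is.null(R2)) {
      stop("could not reach an edge-to-edge distance of ", d_edge_target,
           " A for any sampled orientation; targets well below the ",
           "macrocycle contact distance are geometrically unreachable")
    }
    t_star <- stats::uniroot(f, c(1e-6, hi), tol = 1e-12)$root
    p2 <- place_template(tpl, R2, t_star * u)
    atoms <- rbind(atoms_df("A", "CLA", 601, p1),
                   atoms_df("A", "CLA", 602, p2))
    model <- new_structure_model("SYNPAIR", atoms,
                                 subunit_of = c(A = "Lhca1"))
    led <- ledger_distances(list(p1, p2), tpl)
    list(
      model = model,
      ledger = list(
        seed = seed, entry_id = "SYNPAIR", n_atoms = nrow(atoms),
        pids = c("Lhca1:CLA:601", "Lhca1:CLA:602"),
        d_edge = led$d_edge, d_mg = led$d_mg,
        d_edge_target = d_edge_target,
        d_edge_achieved = led$d_edge[1, 2],
        template_diameter = tpl$diameter,
        transforms = list(list(R = R1, t = c(0, 0, 0)),
                          list(R = R2, t = t_star * u))
      )
    )
  })
}

#' Synthetic chlorophyll grid fixture
#'
#' `n` macrocycles on a line along x at the given spacing, each under a
#' seeded random in-place rotation about its own centre. The ledger
#' carries the full brute-force edge-to-edge and Mg--Mg distance matrices.
#'
#' @param n Number of pigments (>= 1).
#' @param spacing Centre spacing, A; must exceed the template diameter so
#'   neighbours never interpenetrate.
#' @param seed Integer seed.
#' @return List with `model` (chain A -> Lhca1, residues CLA 601..;
#'   entry `SYNGRID`) and `ledger`.
#' @export
make_grid <- function(n, spacing, seed = 1L) {
  stopifnot(n >= 1)
  tpl <- macrocycle_template()
  if (spacing <= tpl$diameter) {
    stop("spacing must exceed the template diameter (",
         round(tpl$diameter, 2), " A)")
  }
  with_seed(seed, {
    placed <- vector("list", n)
    transforms <- vector("list", n)
    for (i in seq_len(n)) {
      R <- random_rotation()
      t <- c((i - 1) * spacing, 0, 0)
      placed[[i]] <- place_template(tpl, R, t)
      transforms[[i]] <- list(R = R, t = t)
    }
    atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
      atoms_df("A", "CLA", 600 + i, placed[[i]])
    }))
    model <- new_structure_model("SYNGRID", atoms,
                                 subunit_of = c(A = "Lhca1"))
    led <- ledger_distances(placed, tpl)
    list(
      model = model,
      ledger = list(
        seed = seed, entry_id = "SYNGRID", n_atoms = nrow(atoms),
        n_pigments = n,
        pids = paste0("Lhca1:CLA:", 600 + seq_len(n)),
        d_edge = led$d_edge, d_mg = led$d_mg,
        template_diameter = tpl$diameter, transforms = transforms
      )
    )
  })
}

# Minimal protein residue with its side-chain coordinating atom at a
# prescribed point and every other N/O atom strictly farther from `mg`.
protein_residue_at <- function(comp, seq_num, chain, target, mg) {
  dir <- target - mg
  dir <- dir / sqrt(sum(dir^2))
  side <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  side <- side - sum(side * dir) * dir
  side <- side / sqrt(sum(side^2))
  coord_atom <- switch(comp, HIS = "NE2", ASN = "OD1",
                       stop("unsupported ligand comp: ", comp))
  # backbone and remaining side-chain atoms pushed outward along dir
  pos <- list()
  pos[[coord_atom]] <- target
  if (comp == "HIS") {
    pos[["CE1"]] <- target + 1.3 * side + 0.4 * dir
    pos[["ND1"]] <- target + 2.1 * side + 1.0 * dir
    pos[["CD2"]] <- target - 0.4 * side + 1.3 * dir
    pos[["CG"]] <- target + 0.9 * side + 2.0 * dir
    pos[["CB"]] <- target + 1.0 * side + 3.4 * dir
  } else {
    pos[["CG"]] <- target + 1.2 * dir
    pos[["ND2"]] <- target + 1.1 * side + 1.6 * dir
    pos[["CB"]] <- target + 0.3 * side + 2.6 * dir
  }
  pos[["CA"]] <- target + 0.8 * side + 4.7 * dir
  pos[["N"]] <- target + 2.0 * side + 5.2 * dir
  pos[["C"]] <- target - 0.6 * side + 5.8 * dir
  pos[["O"]] <- target - 0.8 * side + 6.9 * dir
  nm <- names(pos)
  placed <- data.frame(
    name = nm,
    element = substr(gsub("[0-9]", "", nm), 1, 1),
    x = vapply(pos, `[`, 0, 1), y = vapply(pos, `[`, 0, 2),
    z = vapply(pos, `[`, 0, 3), stringsAsFactors = FALSE
  )
  atoms_df(chain, comp, seq_num, placed, is_hetero = FALSE)
}

#' Synthetic Mg-coordination fixture
#'
#' One macrocycle (CLA 603 in an Lhca1-mapped chain) plus a protein chain
#' holding the named residue with its coordinating atom (His NE2 or Asn
#' OD1) planted at `d_lig` from the Mg on its axial direction, and a decoy
#' residue of the other type at `decoy_d`. All other protein N/O atoms are
#' strictly farther than the decoy.
#'
#' @param ligand_comp `"HIS"` or `"ASN"` -- the planted nearest ligand.
#' @param d_lig Planted Mg--ligand distance, A.
#' @param decoy_d Planted Mg--decoy distance, A (> `d_lig`).
#' @param seed Integer seed.
#' @return List with `model` (entry `SYNLIG`; chains A = Lhca1, B = PsaA)
#'   and `ledger` (planted ligand identity and all Mg--eligible-atom
#'   distances by brute force).
#' @export
make_ligand_fixture <- function(ligand_comp = c("HIS", "ASN"), d_lig = 2.2,
                                decoy_d = 4.0, seed = 1L) {
  ligand_comp <- match.arg(ligand_comp)
  stopifnot(d_lig > 0, d_lig < decoy_d)
  tpl <- macrocycle_template()
  with_seed(seed, {
    R <- random_rotation()
    chl <- place_template(tpl, R, c(0, 0, 0))
    mg <- mg_coord(chl)
    normal <- as.numeric(R %*% c(0, 0, -1))  # axial, away from the tail
    lateral <- as.numeric(R %*% c(1, 0, 0))
    lig_seq <- if (ligand_comp == "HIS") 93L else 148L
    decoy_comp <- if (ligand_comp == "HIS") "ASN" else "HIS"
    decoy_seq <- if (ligand_comp == "HIS") 148L else 93L
    lig <- protein_residue_at(ligand_comp, lig_seq, "B",
                              mg + d_lig * normal, mg)
    dec_dir <- normal * 0.4 + lateral * 0.9163
    dec_dir <- dec_dir / sqrt(sum(dec_dir^2))
    dec <- protein_residue_at(decoy_comp, decoy_seq, "B",
                              mg + decoy_d * dec_dir, mg)
    atoms <- rbind(atoms_df("A", "CLA", 603, chl), lig, dec)
    model <- new_structure_model(
      "SYNLIG", atoms, subunit_of = c(A = "Lhca1", B = "PsaA"))
    prot <- atoms[!atoms$is_hetero & atoms$element %in% c("N", "O"), ,
                  drop = FALSE]
    d_all <- apply(as.matrix(prot[, c("x", "y", "z")]), 1, function(p) {
      sqrt(sum((p - mg)^2))
    })
    list(
      model = model,
      ledger = list(
        seed = seed, entry_id = "SYNLIG", n_atoms = nrow(atoms),
        chl_pid = "Lhca1:CLA:603",
        ligand = list(comp = ligand_comp, seq = lig_seq,
                      atom = if (ligand_comp == "HIS") "NE2" else "OD1",
                      d = d_lig),
        decoy = list(comp = decoy_comp, seq = decoy_seq, d = decoy_d),
        mg = mg,
        eligible_no_distances = data.frame(
          comp = prot$comp_id, seq = prot$seq_num, atom = prot$atom_name,
          d = d_all, stringsAsFactors = FALSE
        )
      )
    )
  })
}

helix_ca_residues <- function(chain, n_res, origin, axis_angle) {
  # straight CA helix: rise 1.5 A, radius 2.3 A, 100 deg/residue, laid
  # along the z axis then rotated about z by axis_angle and shifted
  th <- (seq_len(n_res) - 1) * 100 * pi / 180
  pts <- cbind(2.3 * cos(th), 2.3 * sin(th), (seq_len(n_res) - 1) * 1.5)
  rot <- matrix(c(cos(axis_angle), sin(axis_angle), 0,
                  -sin(axis_angle), cos(axis_angle), 0, 0, 0, 1), 3, 3)
  pts <- sweep(pts %*% t(rot), 2, origin, "+")
  placed <- data.frame(name = "CA", element = "C",
                       x = pts[, 1], y = pts[, 2], z = pts[, 3],
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(n_res), function(i) {
    atoms_df(chain, "ALA", i, placed[i, , drop = FALSE], is_hetero = FALSE)
  }))
}

#' Synthetic two-structure antenna-belt fixture
#'
#' A miniature of a core-based structural comparison: a "core" of two CA
#' helices (PsaA, PsaB) plus a four-site antenna belt (Lhca1, Lhca5,
#' Lhca2, Lhca3; three macrocycles each). The mobile copy is the reference
#' under a seeded random rigid transform, with the pigments of one belt
#' site additionally translated by `site_shift` (planted in the reference
#' frame, radially away from the core) and one pigment deleted.
#'
#' @param seed Integer seed.
#' @param site_shift Planted extra displacement, A, of the shifted site.
#' @param shifted_site Site index 1--4 receiving the shift (default 2,
#'   the Lhca5 position).
#' @param deleted_pid Pigment id (in the mobile copy) to delete; default
#'   one Lhca3 pigment.
#' @return List with `reference`, `mobile` (both `structure_model`s) and
#'   `ledger` (global transform, per-site planted shifts, deleted pid,
#'   reference centroids).
#' @export
make_two_belt_fixture <- function(seed = 1L, site_shift = 3.0,
                                  shifted_site = 2L,
                                  deleted_pid = "Lhca3:CLA:603") {
  tpl <- macrocycle_template()
  sites <- c("Lhca1", "Lhca5", "Lhca2", "Lhca3")
  site_chains <- c("1", "2", "3", "4")
  with_seed(seed, {
    core <- rbind(helix_ca_residues("A", 25, c(0, 0, 0), 0),
                  helix_ca_residues("B", 25, c(8, 0, 0), pi / 3))
    angles <- (seq_along(sites) - 1) * 35 * pi / 180 + pi / 6
    placed_ref <- list()
    belt <- list()
    for (s in seq_along(sites)) {
      u <- c(cos(angles[s]), sin(angles[s]), 0)
      for (k in 1:3) {
        R <- random_rotation()
        centre <- 25 * u + c(0, 0, 6 * (k - 2)) + 4 * k * u
        placed <- place_template(tpl, R, centre)
        pid <- paste0(sites[s], ":CLA:", 600 + k)
        placed_ref[[pid]] <- placed
        belt[[length(belt) + 1L]] <-
          atoms_df(site_chains[s], "CLA", 600 + k, placed)
      }
    }
    sub_map <- c(A = "PsaA", B = "PsaB",
                 stats::setNames(sites, site_chains))
    ref_atoms <- rbind(core, do.call(rbind, belt))
    reference <- new_structure_model("SYNBELTR", ref_atoms, sub_map)

    # plant the site shift in the reference frame, then move everything
    # by one global rigid transform
    Rg <- random_rotation()
    tg <- stats::rnorm(3, sd = 10)
    shift_dir <- c(cos(angles[shifted_site]), sin(angles[shifted_site]), 0)
    mob_atoms <- ref_atoms
    shifted_chain <- site_chains[shifted_site]
    sel <- mob_atoms$chain == shifted_chain
    mob_atoms[sel, c("x", "y", "z")] <-
      sweep(as.matrix(mob_atoms[sel, c("x", "y", "z")]), 2,
            site_shift * shift_dir, "+")
    xyz <- as.matrix(mob_atoms[, c("x", "y", "z")]) %*% t(Rg)
    xyz <- sweep(xyz, 2, tg, "+")
    mob_atoms[, c("x", "y", "z")] <- xyz
    del <- strsplit(deleted_pid, ":")[[1]]
    del_chain <- site_chains[match(del[1], sites)]
    keep <- !(mob_atoms$chain == del_chain &
                mob_atoms$seq_num == as.integer(del[3]))
    mob_atoms <- mob_atoms[keep, , drop = FALSE]
    rownames(mob_atoms) <- NULL
    mobile <- new_structure_model("SYNBELTM", mob_atoms, sub_map)

    shifts <- stats::setNames(rep(0, length(sites)), sites)
    shifts[sites[shifted_site]] <- site_shift
    list(
      reference = reference, mobile = mobile,
      ledger = list(
        seed = seed, entry_id = c("SYNBELTR", "SYNBELTM"),
        global_transform = list(R = Rg, t = tg),
        site_shifts = shifts, deleted_pid = deleted_pid,
        sites = sites,
        ref_centroids = lapply(placed_ref, function(p) {
          colMeans(conj_coords(p, tpl))
        })
      )
    )
  })
}

#' Write a synthetic fixture to disk
#'
#' Emits the coordinate file, the subunit-map config, and the ledger as
#' JSON. Generation is deterministic, so equal seeds give byte-identical
#' files.
#'
#' @param fx A fixture list from one of the `make_*` generators (for
#'   [make_two_belt_fixture()] pass `fx$reference`/`fx$mobile` separately
#'   via `model`).
#' @param dir Output directory (created if needed).
#' @param format Coordinate format, `"pdb"` or `"mmcif"`.
#' @return Invisibly, the coordinate file path.
#' @export
write_fixture <- function(fx, dir, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- fx$model
  ext <- if (format == "pdb") "pdb" else "cif"
  stem <- tolower(model$entry_id)
  cpath <- file.path(dir, paste0(stem, ".", ext))
  write_structure(model, cpath, format)
  map_lines <- c(
    "# synthetic fixture subunit map",
    sprintf("%s %s %s", model$entry_id, names(model$subunit_of),
            unname(model$subunit_of))
  )
  writeLines(map_lines, file.path(dir, paste0(stem, ".map")))
  jsonlite::write_json(fx$ledger, file.path(dir, paste0(stem, ".ledger.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cpath)
}
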