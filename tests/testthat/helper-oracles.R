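# Independent oracles and small constructors used across the suite.
# These deliberately re-derive quantities by direct enumeration, separate
# from both the package implementation and the generator's ledger code.

# plain double-loop minimum inter-point distance
oracle_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# a minimal pigment whose conjugated set is a single point (so pairwise
# edge distances equal point distances) -- for pure graph-logic tests
point_pigment <- function(subunit, seq_num, xyz, klass = "CHL_A",
                          comp_id = "CLA", mg = xyz) {
  xyz <- matrix(as.numeric(xyz), nrow = 1,
                dimnames = list("C1A", c("x", "y", "z")))
  structure(
    list(pid = paste(subunit, comp_id, seq_num, sep = ":"),
         subunit = subunit, chain = "A", comp_id = comp_id,
         seq_num = as.integer(seq_num), klass = klass,
         atoms = data.frame(), conj_xyz = xyz, mg = as.numeric(mg),
         centroid = as.numeric(xyz), radius = 0),
    class = "pigment"
  )
}

random_rigid <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  list(R = diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K),
       t = rnorm(3, sd = 20))
}

transform_pigment <- function(p, tr) {
  p$conj_xyz <- sweep(p$conj_xyz %*% t(tr$R), 2, tr$t, "+")
  if (!is.null(p$mg)) p$mg <- as.numeric(tr$R %*% p$mg) + tr$t
  p$centroid <- as.numeric(tr$R %*% p$centroid) + tr$t
  p
}

# an eet_graph built directly from a symmetric weighted adjacency matrix
graph_from_weights <- function(W, subunits = NULL) {
  n <- nrow(W)
  pids <- sprintf("Lhca1:CLA:%d", 600 + seq_len(n))
  if (is.null(subunits)) subunits <- rep("Lhca1", n)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = pids, subunit = subunits)
  idx <- which(upper.tri(W) & is.finite(W), arr.ind = TRUE)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(pids[idx[, 1]], pids[idx[, 2]]),
                           d_edge = W[idx])
  }
  structure(list(graph = g, edges = NULL, pigments = NULL, D_max = Inf),
            class = "eet_graph")
}

# exhaustive simple-path enumeration under the package's path ordering:
# minimize max edge, then sum, then node count, then node-sequence string
oracle_best_paths <- function(W, pids, source_i, target_is, k) {
  n <- nrow(W)
  found <- list()
  recurse <- function(path, dmax, dsum) {
    head <- path[length(path)]
    if (head %in% target_is && length(path) > 1) {
      found[[length(found) + 1L]] <<- list(
        nodes = pids[path], dmax = dmax, dsum = dsum,
        len = length(path), key = paste(pids[path], collapse = "|"))
    }
    for (nb in seq_len(n)) {
      if (nb %in% path || !is.finite(W[head, nb])) next
      recurse(c(path, nb), max(dmax, W[head, nb]), dsum + W[head, nb])
    }
  }
  recurse(source_i, 0, 0)
  if (!length(found)) return(list())
  ord <- order(
    vapply(found, `[[`, 0, "dmax"), vapply(found, `[[`, 0, "dsum"),
    vapply(found, `[[`, 0L, "len"), vapply(found, `[[`, "", "key"))
  found[ord][seq_len(min(k, length(found)))]
}

# random sparse symmetric weight matrix (Inf = no edge)
random_weight_matrix <- function(n, p_edge = 0.4, wmax = 15) {
  W <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) W[i, j] <- W[j, i] <- runif(1, 1, wmax)
    }
  }
  W
}

# brute-force nearest eligible Mg ligand: scan every protein side-chain
# N/O atom in the model
oracle_nearest_ligand <- function(model, mg, cutoff) {
  a <- model$atoms
  prot <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")
  best <- NULL
  best_d <- Inf
  for (i in seq_len(nrow(a))) {
    if (a$is_hetero[i] || !(a$comp_id[i] %in% prot)) next
    if (!(a$element[i] %in% c("N", "O"))) next
    if (a$atom_name[i] %in% c("N", "O", "OXT")) next
    d <- sqrt((a$x[i] - mg[1])^2 + (a$y[i] - mg[2])^2 + (a$z[i] - mg[3])^2)
    if (d <= cutoff && d < best_d) {
      best_d <- d
      best <- list(comp = a$comp_id[i], seq = a$seq_num[i],
                   atom = a$atom_name[i], d = d)
    }
  }
  best
}

# exhaustive optimal one-to-one assignment (minimum total distance) for
# small point sets
oracle_optimal_assignment <- function(rc, mc, threshold) {
  nr <- nrow(rc); nm <- nrow(mc)
  stopifnot(nr <= 7, nm <= 7)
  d <- sqrt(outer(rowSums(rc^2), rowSums(mc^2), "+") - 2 * tcrossprod(rc, mc))
  k <- min(nr, nm)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  ref_subsets <- utils::combn(nr, k, simplify = FALSE)
  mob_subsets <- utils::combn(nm, k, simplify = FALSE)
  for (rs in ref_subsets) {
    for (ms in mob_subsets) {
      for (pp in perms(ms)) {
        dd <- d[cbind(rs, pp)]
        if (any(dd > threshold)) next
        cost <- sum(dd)
        if (cost < best_cost) {
          best_cost <- cost
          best <- cbind(ref = rs, mob = pp)
        }
      }
    }
  }
  best
}
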