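# Distance-thresholded pigment adjacency graphs and plausible excitation
# energy-transfer (EET) pathways.
#
# The adjacency rule follows the structural-photosynthesis convention
# that EET between chlorophylls is plausible when their edge-to-edge
# distance does not exceed ~15 A; a pathway is an ordered chain of such
# hops. The path objective minimizes the bottleneck (largest hop) first
# -- distance-based plausibility is limited by the longest hop -- with
# total length and hop count as tie-breakers.

#' Build a pigment adjacency graph
#'
#' Nodes are pigments (chlorophyll classes only by default; carotenoids
#' can be included with `classes`), edges exactly the unordered pairs
#' whose edge-to-edge distance is at most `D_max`.
#'
#' @param pigments List of `pigment` objects with conjugated sets.
#' @param D_max Adjacency threshold, A; default 15.
#' @param classes Pigment classes admitted as nodes; default the
#'   chlorophyll classes.
#' @return An `eet_graph`: list with `graph` (igraph, vertices named by
#'   pid with `subunit` attribute, edge attribute `d_edge`), `edges`
#'   (data frame), `pigments` (named list), `D_max`.
#' @export
build_graph <- function(pigments, D_max = 15, classes = CHL_CLASSES) {
  nodes <- Filter(function(p) p$klass %in% classes, pigments)
  tab <- if (length(nodes) >= 2L) {
    distance_table(nodes, max_d = D_max)
  } else {
    distance_table(list())
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(
    g, length(nodes),
    name = vapply(nodes, `[[`, "", "pid"),
    subunit = vapply(nodes, `[[`, "", "subunit")
  )
  if (nrow(tab)) {
    g <- igraph::add_edges(g, rbind(tab$pid_a, tab$pid_b),
                           d_edge = tab$d_edge)
  }
  structure(
    list(graph = g, edges = tab,
         pigments = stats::setNames(nodes,
                                    vapply(nodes, `[[`, "", "pid")),
         D_max = D_max),
    class = "eet_graph"
  )
}

#' @export
print.eet_graph <- function(x, ...) {
  cat(sprintf("eet_graph: %d pigments, %d edges (d_edge <= %g A)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$D_max))
  invisible(x)
}

node_subunits <- function(g) {
  stats::setNames(igraph::V(g$graph)$subunit, igraph::V(g$graph)$name)
}

#' Antenna-core interface report
#'
#' All graph edges crossing from the antenna subunit set to the core
#' subunit set, sorted by edge-to-edge distance, plus a bridging score
#' per pigment: the number of weighted shortest (antenna node, core node)
#' paths that pass through it as an interior vertex, computed exactly on
#' the graph.
#'
#' @param g An `eet_graph`.
#' @param antenna,core Disjoint non-empty canonical subunit name sets.
#' @return An `interface_report`: list with `crossing` (data frame of
#'   crossing edges) and `bridging` (data frame pid/score, sorted by
#'   decreasing score with ties broken by pid order).
#' @export
crossing_edges <- function(g, antenna, core) {
  if (!length(antenna) || !length(core)) {
    stop("antenna and core sets must be non-empty")
  }
  if (length(intersect(antenna, core))) {
    stop("antenna and core sets overlap: ",
         paste(intersect(antenna, core), collapse = ", "))
  }
  subs <- node_subunits(g)
  ant_nodes <- names(subs)[subs %in% antenna]
  core_nodes <- names(subs)[subs %in% core]
  tab <- g$edges
  side <- function(pid) ifelse(pid %in% ant_nodes, "antenna",
                               ifelse(pid %in% core_nodes, "core", "other"))
  crossing <- tab[(side(tab$pid_a) == "antenna" &
                     side(tab$pid_b) == "core") |
                    (side(tab$pid_a) == "core" &
                       side(tab$pid_b) == "antenna"), , drop = FALSE]
  crossing <- crossing[order(crossing$d_edge, crossing$pid_a,
                             crossing$pid_b), , drop = FALSE]
  rownames(crossing) <- NULL

  score <- stats::setNames(rep(0L, length(subs)), names(subs))
  for (a in ant_nodes) {
    sp <- igraph::all_shortest_paths(g$graph, from = a, to = core_nodes,
                                     weights = igraph::E(g$graph)$d_edge)
    for (p in sp$vpaths) {
      nm <- names(p)
      if (length(nm) > 2L) {
        interior <- nm[-c(1L, length(nm))]
        score[interior] <- score[interior] + 1L
      }
    }
  }
  bridging <- data.frame(pid = names(score), score = unname(score),
                         stringsAsFactors = FALSE)
  bridging <- bridging[order(-bridging$score, bridging$pid), , drop = FALSE]
  rownames(bridging) <- NULL
  structure(list(antenna = antenna, core = core, crossing = crossing,
                 bridging = bridging),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface_report: %d crossing edges (%s | %s)\n",
              nrow(x$crossing), paste(x$antenna, collapse = ","),
              paste(x$core, collapse = ",")))
  if (nrow(x$crossing)) {
    print(utils::head(x$crossing[, c("pid_a", "pid_b", "d_edge")], 10))
  }
  invisible(x)
}

path_priority <- function(dmax, dsum, len, key) {
  # lexicographic comparison helpers operate on these fields directly
  list(dmax = dmax, dsum = dsum, len = len, key = key)
}

priority_less <- function(p, q) {
  if (p$dmax != q$dmax) return(p$dmax < q$dmax)
  if (p$dsum != q$dsum) return(p$dsum < q$dsum)
  if (p$len != q$len) return(p$len < q$len)
  p$key < q$key
}

#' Best simple EET pathways from a source pigment
#'
#' The `k` best simple paths from `source` to any pigment in `targets`
#' under the ordering: minimize the maximum hop (bottleneck edge-to-edge
#' distance), then the total edge length, then the node count, with the
#' node-sequence string as a deterministic final tie-break. Implemented
#' as best-first search over simple paths; because every criterion is
#' non-decreasing under path extension, paths are popped in global order
#' and the first `k` arrivals at targets are exactly the `k` best.
#'
#' @param g An `eet_graph`.
#' @param source Pigment id (must be a graph node).
#' @param targets Character vector of pigment ids; unreachable or absent
#'   targets simply contribute nothing.
#' @param k Number of pathways to return.
#' @param max_pop Safety cap on the number of partial paths expanded.
#' @return List of `pathway` objects: list with `nodes`, `edge_dists`,
#'   `max_edge`, `sum_edge`. Empty list when no target is reachable.
#' @export
pathways <- function(g, source, targets, k = 3L, max_pop = 200000L) {
  vnames <- igraph::V(g$graph)$name
  if (!(source %in% vnames)) stop("source pigment not in graph: ", source)
  targets <- intersect(targets, vnames)
  out <- list()
  if (!length(targets)) return(out)

  adj <- lapply(igraph::adjacent_vertices(g$graph, vnames), names)
  names(adj) <- vnames
  wt <- function(a, b) {
    eid <- igraph::get_edge_ids(g$graph, c(a, b))
    igraph::E(g$graph)$d_edge[eid]
  }

  queue <- list(list(nodes = source, dmax = 0, dsum = 0))
  pops <- 0L
  while (length(queue) && length(out) < k && pops < max_pop) {
    # pop the lexicographically best partial path
    best <- 1L
    bp <- path_priority(queue[[1]]$dmax, queue[[1]]$dsum,
                        length(queue[[1]]$nodes),
                        paste(queue[[1]]$nodes, collapse = "|"))
    if (length(queue) > 1L) {
      for (i in 2:length(queue)) {
        pi <- path_priority(queue[[i]]$dmax, queue[[i]]$dsum,
                            length(queue[[i]]$nodes),
                            paste(queue[[i]]$nodes, collapse = "|"))
        if (priority_less(pi, bp)) {
          best <- i
          bp <- pi
        }
      }
    }
    cur <- queue[[best]]
    queue[[best]] <- NULL
    pops <- pops + 1L
    head_node <- cur$nodes[length(cur$nodes)]
    if (head_node %in% targets && length(cur$nodes) > 1L) {
      ed <- vapply(seq_len(length(cur$nodes) - 1L), function(i) {
        wt(cur$nodes[i], cur$nodes[i + 1L])
      }, 0)
      out[[length(out) + 1L]] <- structure(
        list(nodes = cur$nodes, edge_dists = ed,
             max_edge = cur$dmax, sum_edge = cur$dsum),
        class = "pathway"
      )
      if (length(out) >= k) break
      # still expand: a longer continuation may end at another target
    }
    for (nb in adj[[head_node]]) {
      if (nb %in% cur$nodes) next
      w <- wt(head_node, nb)
      queue[[length(queue) + 1L]] <- list(
        nodes = c(cur$nodes, nb),
        dmax = max(cur$dmax, w), dsum = cur$dsum + w
      )
    }
  }
  out
}

#' @export
print.pathway <- function(x, ...) {
  cat(paste(x$nodes, collapse = " -> "), "\n")
  cat(sprintf("  hops: %s  (max %.1f A, sum %.1f A)\n",
              paste(sprintf("%.1f", x$edge_dists), collapse = ", "),
              x$max_edge, x$sum_edge))
  invisible(x)
}

#' Gap-region chlorophylls between antenna and core
#'
#' Pigments assigned to either set that lie between the two sets: their
#' centroid is within `band` of both a nearest antenna pigment and a
#' nearest core pigment (excluding themselves). These are the bridging
#' "gap" pigments that fill the space between the antenna belt and the
#' core.
#'
#' @param g An `eet_graph`.
#' @param antenna,core Canonical subunit name sets.
#' @param band Distance band, A. The gap region has no authoritative
#'   quantitative definition; 10 A is this package's documented choice.
#' @return Character vector of pigment ids.
#' @export
gap_chlorophylls <- function(g, antenna, core, band = 10) {
  if (band <= 0) return(character(0))
  subs <- node_subunits(g)
  pids <- names(subs)
  cent <- t(vapply(g$pigments[pids], `[[`, numeric(3), "centroid"))
  in_ant <- subs %in% antenna
  in_core <- subs %in% core
  out <- character(0)
  for (i in seq_along(pids)) {
    if (!in_ant[i] && !in_core[i]) next
    d <- sqrt(rowSums((cent - rep(cent[i, ], each = nrow(cent)))^2))
    d[i] <- Inf
    d_ant <- if (any(in_ant)) min(d[in_ant]) else Inf
    d_core <- if (any(in_core)) min(d[in_core]) else Inf
    if (d_ant <= band && d_core <= band) out <- c(out, pids[i])
  }
  out
}

#' Write an EET network to JSON
#'
#' Nodes, edges, crossing edges and top-k pathways per antenna subunit in
#' one machine-readable report (full float precision).
#'
#' @param g An `eet_graph`.
#' @param path Output path.
#' @param antenna,core Optional subunit sets; when given, crossing edges
#'   and per-antenna pathways to `targets` are included.
#' @param targets Optional pathway target pids.
#' @param k Pathways per antenna subunit.
#' @return Invisibly, `path`.
#' @export
write_network <- function(g, path, antenna = NULL, core = NULL,
                          targets = NULL, k = 3L) {
  rep <- list(
    D_max = g$D_max,
    nodes = data.frame(pid = igraph::V(g$graph)$name,
                       subunit = igraph::V(g$graph)$subunit,
                       stringsAsFactors = FALSE),
    edges = g$edges[, c("pid_a", "pid_b", "d_edge")]
  )
  if (!is.null(antenna) && !is.null(core)) {
    ir <- crossing_edges(g, antenna, core)
    rep$crossing_edges <- ir$crossing[, c("pid_a", "pid_b", "d_edge")]
    rep$bridging <- ir$bridging
    if (!is.null(targets)) {
      subs <- node_subunits(g)
      rep$pathways <- lapply(stats::setNames(antenna, antenna), function(s) {
        srcs <- names(subs)[subs == s]
        ps <- list()
        for (src in srcs) {
          ps <- c(ps, pathways(g, src, targets, k))
        }
        lapply(ps, function(p) {
          list(nodes = p$nodes, edge_dists = p$edge_dists,
               max_edge = p$max_edge, sum_edge = p$sum_edge)
        })
      })
    }
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
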