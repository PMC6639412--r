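#' Build an area adjacency graph from an edge list
#'
#' @param edges Data frame (or 2-column matrix) with columns `area_a`,
#'   `area_b`: undirected adjacency between cortical areas.
#' @return An `area_graph` list with `edges` (canonical data frame), `areas`
#'   (sorted unique labels) and `graph` (an igraph object).
#' @examples
#' g <- generate_area_graph(data.frame(area_a = c("A", "B"), area_b = c("B", "C")))
#' g$areas
#' @export
generate_area_graph <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) stop("empty edge list: no graph")
  if (ncol(edges) < 2) stop("edges must have two columns (area_a, area_b)")
  names(edges)[1:2] <- c("area_a", "area_b")
  edges$area_a <- as.character(edges$area_a)
  edges$area_b <- as.character(edges$area_b)
  if (any(edges$area_a == edges$area_b)) stop("self-loops are not allowed")
  key <- apply(edges[, 1:2], 1, function(e) paste(sort(e), collapse = "\r"))
  edges <- edges[!duplicated(key), 1:2]
  areas <- sort(unique(c(edges$area_a, edges$area_b)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = areas))
  structure(list(edges = edges, areas = areas, graph = g),
            class = "area_graph")
}

#' @export
print.area_graph <- function(x, ...) {
  cat(sprintf("Area graph: %d areas, %d edges\n",
              length(x$areas), nrow(x$edges)))
  invisible(x)
}

#' Synthetic 48-area visual-cortex adjacency fixture
#'
#' A stand-in adjacency over 48 visual areas (24 per hemisphere, labels
#' prefixed `lh_`/`rh_`) with a retinotopic-atlas-style naming scheme and a
#' plausible neighbor structure rooted at V1 per hemisphere. The true atlas
#' adjacency is not distributed with this package; for analyses of real data
#' the user supplies their own edge list.
#'
#' @return An `area_graph` over 48 areas, connected within each hemisphere.
#' @examples
#' g <- visual_graph_fixture()
#' length(g$areas)  # 48
#' @export
visual_graph_fixture <- function() {
  base <- rbind(
    c("V1", "V2v"), c("V1", "V2d"),
    c("V2v", "V3v"), c("V2d", "V3d"),
    c("V3v", "hV4"), c("V3d", "V3a"), c("V3d", "LO1"),
    c("hV4", "VO1"), c("VO1", "VO2"), c("VO2", "PHC1"), c("PHC1", "PHC2"),
    c("LO1", "LO2"), c("LO2", "TO1"), c("TO1", "TO2"),
    c("V3a", "V3b"), c("V3b", "LO1"),
    c("V3a", "IPS0"), c("IPS0", "IPS1"), c("IPS1", "IPS2"),
    c("IPS2", "IPS3"), c("IPS3", "IPS4"), c("IPS4", "IPS5"),
    c("IPS5", "SPL1"), c("IPS4", "FEF")
  )
  edges <- rbind(
    data.frame(area_a = paste0("lh_", base[, 1]), area_b = paste0("lh_", base[, 2])),
    data.frame(area_a = paste0("rh_", base[, 1]), area_b = paste0("rh_", base[, 2]))
  )
  generate_area_graph(edges)
}

#' Hierarchical level of each area by shortest path to a root
#'
#' Computes the hierarchical level eta of every area in the connected
#' component of `root` as the shortest-path edge count (unit weights,
#' Dijkstra) to the root; `eta(root) = 0` by convention (configurable via
#' `level_offset`).
#'
#' @param graph An `area_graph` or an edge data frame.
#' @param root Root area label (typically V1 of one hemisphere).
#' @param level_offset Integer added to every level (default 0).
#' @return Named integer vector of levels for the areas in the root's
#'   component; errors if any area of that component's label set is
#'   unreachable.
#' @examples
#' g <- generate_area_graph(data.frame(area_a = c("V1", "V2"), area_b = c("V2", "V3")))
#' hierarchical_levels(g, "V1")  # V1=0 V2=1 V3=2
#' @export
hierarchical_levels <- function(graph, root, level_offset = 0L) {
  if (!inherits(graph, "area_graph")) graph <- generate_area_graph(graph)
  if (!root %in% graph$areas) stop("root area not in graph: ", root)
  d <- igraph::distances(graph$graph, v = root, algorithm = "dijkstra")[1, ]
  unreachable <- names(d)[!is.finite(d)]
  if (length(unreachable)) {
    stop("areas unreachable from root ", root, ": ",
         paste(unreachable, collapse = ", "))
  }
  lv <- as.integer(d) + as.integer(level_offset)
  names(lv) <- names(d)
  lv[order(names(lv))]
}

#' Hierarchical levels for a multi-root (per-hemisphere) graph
#'
#' Assigns each area the shortest-path distance to the root of its own
#' connected component. Homologous areas may receive different levels if
#' their hemispheres' adjacency differs; levels are reported per area, never
#' merged.
#'
#' @param graph An `area_graph` or edge data frame.
#' @param roots Character vector of root labels, one per component (e.g.
#'   `c("lh_V1", "rh_V1")`).
#' @param level_offset Integer added to every level.
#' @return Named integer vector of levels covering all areas.
#' @export
hierarchy_levels_multi <- function(graph, roots, level_offset = 0L) {
  if (!inherits(graph, "area_graph")) graph <- generate_area_graph(graph)
  comp <- igraph::components(graph$graph)
  memb <- comp$membership
  root_comp <- memb[roots]
  if (anyNA(root_comp)) stop("root(s) not in graph: ",
                             paste(roots[is.na(root_comp)], collapse = ", "))
  if (anyDuplicated(root_comp)) stop("two roots lie in the same component")
  uncovered <- names(memb)[!memb %in% root_comp]
  if (length(uncovered)) {
    stop("areas unreachable from any root: ", paste(uncovered, collapse = ", "))
  }
  out <- integer(0)
  for (r in roots) {
    sub_areas <- names(memb)[memb == memb[r]]
    sub <- igraph::induced_subgraph(graph$graph, sub_areas)
    sub_edges <- igraph::as_data_frame(sub, what = "edges")
    names(sub_edges) <- c("area_a", "area_b")
    out <- c(out, hierarchical_levels(generate_area_graph(sub_edges), r,
                                      level_offset = level_offset))
  }
  out[order(names(out))]
}

#' Write / read an area edge list as TSV
#' @param graph An `area_graph`.
#' @param path Output TSV path (columns `area_a`, `area_b`).
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  generate_area_graph(utils::read.delim(path, stringsAsFactors = FALSE))
}
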