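#' Read a GMT annotation collection
#'
#' Tab-separated lines: set name, description, then member ids. Set
#' names must be unique and sets non-empty.
#'
#' @param path GMT file path.
#' @param source Source label (e.g. `"GO"`, `"KEGG"`, `"TRRUST"`).
#' @return An `annotation_collection`: named list of character member
#'   vectors, with a `source` attribute.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  annotation_collection(sets, source)
}

#' Build an annotation collection in memory
#'
#' @param sets Named list of character member vectors.
#' @param source Source label.
#' @export
annotation_collection <- function(sets, source = "custom") {
  stopifnot(!anyDuplicated(names(sets)),
            all(vapply(sets, length, integer(1)) > 0))
  structure(sets, source = source, class = "annotation_collection")
}

#' Write a collection to GMT
#'
#' @param collection An `annotation_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, attr(collection, "source"), collection[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric enrichment
#'
#' One-sided hypergeometric tail test `P(X >= overlap)` of a query
#' protein set against every annotation set, after intersecting each set
#' with the universe and filtering to sizes in `[min_size, max_size]`
#' (defaults 10 and 300). P-values are Benjamini-Hochberg corrected
#' across the tested sets, and only sets with `q < q_max` (default 0.01)
#' are reported unless `report_all = TRUE`.
#'
#' @param query Character protein set (must be a subset of `universe`).
#' @param collection An `annotation_collection` (or named list).
#' @param universe Character universe of all model proteins (non-empty).
#' @param min_size,max_size Set-size filter applied after universe
#'   intersection.
#' @param q_max FDR reporting threshold.
#' @param report_all Keep non-significant rows too.
#' @param direction Optional direction tag (e.g. `"UP"`) carried in the
#'   output.
#' @param cluster Optional cluster tag carried in the output.
#' @return data.frame of class `enrichment_result`: `set, set_size,
#'   overlap, p, q, direction, cluster`. An empty query returns an empty
#'   result with a warning.
#' @export
enrich <- function(query, collection, universe, min_size = 10,
                   max_size = 300, q_max = 0.01, report_all = FALSE,
                   direction = NA_character_, cluster = NA_character_) {
  if (length(universe) == 0) stop("enrich: empty universe")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("enrich: query contains proteins outside the universe")
  }
  empty <- data.frame(set = character(), set_size = integer(),
                      overlap = integer(), p = numeric(), q = numeric(),
                      direction = character(), cluster = character(),
                      stringsAsFactors = FALSE)
  if (length(query) == 0) {
    warning("enrich: empty query")
    return(structure(empty, class = c("enrichment_result", "data.frame")))
  }
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  sizes <- vapply(sets, length, integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]; sizes <- sizes[keep]
  if (length(sets) == 0) {
    return(structure(empty, class = c("enrichment_result", "data.frame")))
  }
  N <- length(universe); n <- length(query)
  overlap <- vapply(sets, function(s) length(intersect(s, query)),
                    integer(1))
  p <- stats::phyper(overlap - 1, sizes, N - sizes, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(set = names(sets), set_size = sizes, overlap = overlap,
                    p = p, q = q, direction = direction, cluster = cluster,
                    stringsAsFactors = FALSE)
  if (!report_all) out <- out[out$q < q_max, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Read a two-column edge-list graph
#'
#' @param path TSV with two columns of node ids (no header).
#' @return An undirected [igraph::graph] object.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
}

#' Shortest-path distance table of a protein network
#'
#' Pairwise shortest-path lengths; disconnected pairs are set to
#' `diameter + 1` by default (configurable), so the modified Hausdorff
#' linkage stays finite.
#'
#' @param graph An igraph object.
#' @param disconnected `"diameter_plus_one"` or a numeric value.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
network_distances <- function(graph, disconnected = "diameter_plus_one") {
  d <- igraph::distances(graph)
  if (any(is.infinite(d))) {
    fill <- if (identical(disconnected, "diameter_plus_one")) {
      max(d[is.finite(d)]) + 1
    } else {
      as.numeric(disconnected)
    }
    d[is.infinite(d)] <- fill
  }
  d
}

#' Modified Hausdorff distance between two node sets
#'
#' The Dubuisson-Jain mean-of-minima form:
#' `max(mean_a min_b d(a, b), mean_b min_a d(a, b))`, typically with `d`
#' the shortest-path length on a protein network. The classical max-min
#' Hausdorff is available with `form = "classical"`.
#'
#' @param set_a,set_b Character node sets (members of `dist`).
#' @param dist Symmetric zero-diagonal distance matrix with named
#'   dimensions (e.g. from [network_distances()]).
#' @param form `"mean"` (modified) or `"classical"`.
#' @return Non-negative link value; 0 iff the two sets are equal as node
#'   sets (on finite distances).
#' @export
modified_hausdorff <- function(set_a, set_b, dist,
                               form = c("mean", "classical")) {
  form <- match.arg(form)
  set_a <- unique(set_a); set_b <- unique(set_b)
  missing_n <- setdiff(c(set_a, set_b), rownames(dist))
  if (length(missing_n) > 0) {
    stop("modified_hausdorff: nodes absent from the distance table: ",
         paste(utils::head(missing_n, 5), collapse = ", "))
  }
  d_ab <- dist[set_a, set_b, drop = FALSE]
  mins_a <- apply(d_ab, 1, min)   # min over b for each a
  mins_b <- apply(d_ab, 2, min)
  if (form == "mean") max(mean(mins_a), mean(mins_b))
  else max(max(mins_a), max(mins_b))
}

#' Build and export the enrichment network
#'
#' Nodes are enriched annotation sets (with q, direction and cluster as
#' attributes); edges connect pairs whose modified Hausdorff linkage over
#' the protein network is at or below `link_threshold`, weighted by the
#' linkage value.
#'
#' @param results An `enrichment_result` (rows must be non-empty unless
#'   `allow_empty`).
#' @param collection The `annotation_collection` the results came from.
#' @param graph Protein network (igraph) for shortest-path distances.
#' @param link_threshold Maximum linkage for drawing an edge.
#' @param universe Universe used for the enrichment (set members outside
#'   the graph are dropped from the linkage computation).
#' @return An `enrichment_network`: list `graph` (igraph of sets),
#'   `links` (data.frame `set_a, set_b, link`).
#' @export
build_network <- function(results, collection, graph, link_threshold,
                          universe = NULL) {
  sets <- results$set
  node_df <- data.frame(name = sets, q = results$q,
                        direction = results$direction,
                        cluster = results$cluster, stringsAsFactors = FALSE)
  if (nrow(node_df) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(structure(list(graph = g,
                          links = data.frame(set_a = character(),
                                             set_b = character(),
                                             link = numeric())),
                     class = "enrichment_network"))
  }
  dist <- network_distances(graph)
  members <- lapply(collection[sets], function(s) {
    intersect(intersect(s, rownames(dist)),
              if (is.null(universe)) s else universe)
  })
  links <- list()
  if (length(sets) >= 2) {
    for (i in seq_len(length(sets) - 1)) for (j in (i + 1):length(sets)) {
      if (length(members[[i]]) == 0 || length(members[[j]]) == 0) next
      mhd <- modified_hausdorff(members[[i]], members[[j]], dist)
      if (mhd <= link_threshold) {
        links[[length(links) + 1]] <- data.frame(
          set_a = sets[i], set_b = sets[j], link = mhd,
          stringsAsFactors = FALSE)
      }
    }
  }
  links <- if (length(links) > 0) do.call(rbind, links) else
    data.frame(set_a = character(), set_b = character(), link = numeric())
  g <- igraph::graph_from_data_frame(
    if (nrow(links) > 0) links[, c("set_a", "set_b")] else
      data.frame(from = character(), to = character()),
    directed = FALSE, vertices = node_df)
  if (nrow(links) > 0) igraph::E(g)$weight <- links$link
  structure(list(graph = g, links = links), class = "enrichment_network")
}

#' Export an enrichment network
#'
#' Writes a SIF file (`setA link setB` per edge), a GraphML file
#' (re-readable by [igraph::read_graph()] with nodes, edges and weights
#' intact) and a node-attribute CSV.
#'
#' @param network An `enrichment_network`.
#' @param prefix Output path prefix; writes `<prefix>.sif`,
#'   `<prefix>.graphml`, `<prefix>_nodes.csv`.
#' @return Invisibly, the three paths.
#' @export
write_network <- function(network, prefix) {
  sif <- paste0(prefix, ".sif")
  gml <- paste0(prefix, ".graphml")
  nodes <- paste0(prefix, "_nodes.csv")
  links <- network$links
  writeLines(if (nrow(links) > 0) {
    sprintf("%s\tlink\t%s", links$set_a, links$set_b)
  } else character(0), sif)
  igraph::write_graph(network$graph, gml, format = "graphml")
  vattrs <- igraph::vertex_attr(network$graph)
  utils::write.csv(as.data.frame(vattrs, stringsAsFactors = FALSE), nodes,
                   row.names = FALSE)
  invisible(c(sif = sif, graphml = gml, nodes = nodes))
}
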