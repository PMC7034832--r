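#' Build a node map
#'
#' Maps every atom to exactly one node label. Default granularity is one node
#' per residue (label `RESNAME<resid>`, e.g. `ARG489`); selected residues or
#' atoms can be broken out to atom-level nodes (label `RESNAME<resid>:<name>`,
#' matching networks whose DNA side is resolved to single base atoms), and
#' named atom groups (e.g. the two carboxylate oxygens of a modified base as
#' one node) can be declared explicitly.
#'
#' @param topology a topology.
#' @param atom_level selection (object, expression, or indices) of atoms to
#'   map at atom granularity.
#' @param groups named list: label -> atom indices; each group must lie in a
#'   single residue.
#' @return character vector of node labels, one per atom.
#' @export
make_node_map <- function(topology, atom_level = NULL, groups = NULL) {
  at <- topology$atoms
  labels <- paste0(at$resname, at$resid)
  if (!is.null(atom_level)) {
    idx <- as_indices(topology, atom_level)
    labels[idx] <- paste0(at$resname[idx], at$resid[idx], ":", at$name[idx])
  }
  rkey <- residue_keys(topology)
  for (lab in names(groups)) {
    idx <- groups[[lab]]
    if (length(unique(rkey[idx])) != 1)
      stop_dyadmd("node group '", lab, "' spans more than one residue")
    labels[idx] <- lab
  }
  labels
}

#' Merge per-replica contact series
#'
#' Concatenates the per-frame counts of replica series over the union of
#' pair keys (absent keys contribute zeros). The merged mean interactions
#' per frame is the frame-weighted mean of the replica means.
#'
#' @param series_list list of contact_series sharing one topology.
#' @return a merged contact_series.
#' @export
merge_series <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  if (length(series_list) == 1) return(series_list[[1]])
  names0 <- series_list[[1]]$topology$atoms$name
  for (s in series_list)
    if (!identical(s$topology$atoms$name, names0))
      stop_dyadmd("series have differing topologies")
  keystr <- function(s) paste(s$keys$atom_a, s$keys$atom_b, s$keys$kind, sep = "|")
  all_keys <- sort(unique(unlist(lapply(series_list, keystr))))
  total_frames <- sum(vapply(series_list, function(s) s$n_frames, 1L))
  counts <- matrix(0L, nrow = length(all_keys), ncol = total_frames)
  f0 <- 0L
  for (s in series_list) {
    idx <- match(keystr(s), all_keys)
    if (nrow(s$counts))
      counts[idx, f0 + seq_len(s$n_frames)] <- s$counts
    f0 <- f0 + s$n_frames
  }
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  keys <- data.frame(atom_a = as.integer(vapply(parts, `[`, "", 1)),
                     atom_b = as.integer(vapply(parts, `[`, "", 2)),
                     kind = vapply(parts, `[`, "", 3),
                     stringsAsFactors = FALSE)
  structure(list(keys = keys, counts = counts, n_frames = total_frames,
                 topology = series_list[[1]]$topology),
            class = "contact_series")
}

#' Aggregate a contact series into a weighted interaction network
#'
#' Atom-level per-frame counts are summed into node-level counts (via the
#' node map) before any statistic is computed. Edges whose occupancy is
#' less than or equal to `prune_occupancy` are omitted (strict "<=", so an
#' edge sitting exactly at the threshold is dropped). When
#' `salt_bridge_precedence` is TRUE and a node pair retains both a
#' hydrogen-bond and a salt-bridge edge after pruning, only the salt-bridge
#' edge is emitted. Edge weight is the mean number of interactions per frame
#' at full precision; presentation rounding is left to [format_network()].
#'
#' @param series a contact_series.
#' @param node_map character vector from [make_node_map()].
#' @param prune_occupancy occupancy threshold in `[0, 1)`.
#' @param salt_bridge_precedence see above (default TRUE, the display
#'   convention of the source networks).
#' @return object of class `"interaction_network"`: data.frame of edges
#'   (`node_a`, `node_b`, `kind`, `mean_count`, `occupancy`, `n_frames`)
#'   with the node label set as attribute `"nodes"`.
#' @export
build_network <- function(series, node_map, prune_occupancy = 0.15,
                          salt_bridge_precedence = TRUE) {
  stopifnot(prune_occupancy >= 0, prune_occupancy < 1)
  if (length(node_map) != n_atoms(series$topology))
    stop_dyadmd("node_map length != atom count")
  touched <- unique(c(series$keys$atom_a, series$keys$atom_b))
  if (anyNA(node_map[touched]))
    stop_dyadmd("node_map leaves atoms unmapped: ",
                paste(touched[is.na(node_map[touched])], collapse = ", "))
  la <- node_map[series$keys$atom_a]
  lb <- node_map[series$keys$atom_b]
  keep <- la != lb            # self-edges (same node) are dropped
  edges_empty <- data.frame(node_a = character(0), node_b = character(0),
                            kind = character(0), mean_count = numeric(0),
                            occupancy = numeric(0), n_frames = integer(0))
  if (!any(keep)) {
    return(structure(edges_empty, nodes = sort(unique(node_map)),
                     class = c("interaction_network", "data.frame")))
  }
  a <- pmin(la, lb)[keep]
  b <- pmax(la, lb)[keep]
  grp <- paste(a, b, series$keys$kind[keep], sep = "|")
  summed <- rowsum(series$counts[keep, , drop = FALSE], group = grp)
  ugrp <- rownames(summed)
  occ <- rowMeans(summed >= 1)
  mc <- rowMeans(summed)
  parts <- strsplit(ugrp, "|", fixed = TRUE)
  edges <- data.frame(node_a = vapply(parts, `[`, "", 1),
                      node_b = vapply(parts, `[`, "", 2),
                      kind = vapply(parts, `[`, "", 3),
                      mean_count = unname(mc), occupancy = unname(occ),
                      n_frames = series$n_frames,
                      stringsAsFactors = FALSE)
  edges <- edges[edges$occupancy > prune_occupancy, , drop = FALSE]
  if (salt_bridge_precedence && nrow(edges)) {
    pair <- paste(edges$node_a, edges$node_b, sep = "|")
    has_salt <- pair %in% pair[edges$kind == "saltbridge"]
    edges <- edges[!(edges$kind == "hbond" & has_salt), , drop = FALSE]
  }
  edges <- edges[order(edges$node_a, edges$node_b, edges$kind), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, nodes = sort(unique(node_map)),
            class = c("interaction_network", "data.frame"))
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction network: %d edges over %d frames\n",
              nrow(x), if (nrow(x)) x$n_frames[1] else 0L))
  if (nrow(x)) print(format_network(x))
  invisible(x)
}

#' Presentation table of a network (2-decimal edge weights)
#' @param network an interaction_network
#' @export
format_network <- function(network) {
  data.frame(node_a = network$node_a, node_b = network$node_b,
             kind = network$kind,
             mean_count = sprintf("%.2f", network$mean_count),
             occupancy = sprintf("%.2f", network$occupancy),
             stringsAsFactors = FALSE)
}

#' Edge-wise difference between two networks
#'
#' For every edge in the union of the two edge sets, reports
#' `delta_mean_count = mean_count_b - mean_count_a` and the corresponding
#' occupancy difference; an edge missing from one network contributes
#' weight 0 there.
#'
#' @param a,b interaction networks.
#' @return data.frame with per-edge weights in both networks and deltas.
#' @export
compare_networks <- function(a, b) {
  key <- function(n) paste(n$node_a, n$node_b, n$kind, sep = "|")
  keys <- sort(unique(c(key(a), key(b))))
  ia <- match(keys, key(a))
  ib <- match(keys, key(b))
  pick <- function(n, i, col) ifelse(is.na(i), 0, n[[col]][i])
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(node_a = vapply(parts, `[`, "", 1),
             node_b = vapply(parts, `[`, "", 2),
             kind = vapply(parts, `[`, "", 3),
             mean_count_a = pick(a, ia, "mean_count"),
             mean_count_b = pick(b, ib, "mean_count"),
             delta_mean_count = pick(b, ib, "mean_count") - pick(a, ia, "mean_count"),
             occupancy_a = pick(a, ia, "occupancy"),
             occupancy_b = pick(b, ib, "occupancy"),
             delta_occupancy = pick(b, ib, "occupancy") - pick(a, ia, "occupancy"),
             stringsAsFactors = FALSE)
}

#' Export an interaction network
#'
#' GraphML (lossless: kind, weight, occupancy, n_frames as edge attributes;
#' re-import with [import_network_graphml()] reproduces the network),
#' whitespace edge list, or DOT.
#'
#' @param network an interaction_network.
#' @param file output path.
#' @param format one of `"graphml"`, `"edgelist"`, `"dot"`.
#' @export
export_network <- function(network, file, format = c("graphml", "edgelist", "dot")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- network_to_igraph(network)
    igraph::write_graph(g, file, format = "graphml")
  } else if (format == "edgelist") {
    utils::write.table(as.data.frame(network), file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    lines <- c("graph interactions {")
    if (nrow(network)) {
      style <- ifelse(network$kind == "saltbridge", "color=red", "color=black")
      lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [label=\"%.2f\", %s];",
                                network$node_a, network$node_b,
                                network$mean_count, style))
    }
    lines <- c(lines, "}")
    writeLines(lines, file)
  }
  invisible(file)
}

network_to_igraph <- function(network) {
  nodes <- unique(c(attr(network, "nodes"), network$node_a, network$node_b))
  if (nrow(network)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = network$node_a, to = network$node_b,
                 kind = network$kind, weight = network$mean_count,
                 occupancy = network$occupancy, n_frames = network$n_frames),
      directed = FALSE, vertices = sort(nodes))
  } else {
    g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
    igraph::V(g)$name <- sort(nodes)
  }
  g
}

#' Re-import a GraphML network written by [export_network()]
#' @param file GraphML path
#' @return an interaction_network
#' @export
import_network_graphml <- function(file) {
  g <- igraph::read_graph(file, format = "graphml")
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    edges <- data.frame(node_a = pmin(el[, 1], el[, 2]),
                        node_b = pmax(el[, 1], el[, 2]),
                        kind = igraph::E(g)$kind,
                        mean_count = igraph::E(g)$weight,
                        occupancy = igraph::E(g)$occupancy,
                        n_frames = as.integer(igraph::E(g)$n_frames),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$node_a, edges$node_b, edges$kind), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        kind = character(0), mean_count = numeric(0),
                        occupancy = numeric(0), n_frames = integer(0))
  }
  structure(edges, nodes = sort(igraph::V(g)$name),
            class = c("interaction_network", "data.frame"))
}
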