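# Module detection: maximal bicliques of the bipartite miRNA-pathway
# network, and k-clique percolation communities of the pathway crosstalk
# network.

bipartiteEdges <- function(network) {
  if (is(network, "MirnaPathwayNetwork")) {
    e <- unique(networkEdges(network)[c("mirna_id", "pathway_id")])
  } else {
    e <- as.data.frame(network)[, 1:2]
    names(e) <- c("mirna_id", "pathway_id")
    e <- unique(e)
  }
  if (nrow(e) && length(intersect(e$mirna_id, e$pathway_id)))
    stop("input is not bipartite: ",
         "identifiers occur on both sides", call. = FALSE)
  e
}

#' Enumerate maximal biclique modules of the miRNA-pathway network
#'
#' A biclique module is a complete bipartite subgraph: every miRNA of the
#' module regulates every pathway of the module. Maximality means no
#' further miRNA or pathway can be added while keeping completeness.
#' Enumeration reduces the problem to maximal-clique enumeration on the
#' graph whose two sides are made internally complete: its maximal
#' cliques containing at least one vertex of each side are exactly the
#' maximal bicliques. Modules are sorted lexicographically by member
#' identifiers and given sequential ids.
#'
#' @param network a [MirnaPathwayNetwork-class], or a two-column
#'   data.frame of (miRNA, pathway) edges.
#' @param minMirnas,minPathways size floors, default 1 each (so a single
#'   miRNA regulating several pathways is a representable module).
#' @return list of modules, each a list with elements \code{id},
#'   \code{mirnas}, \code{pathways}.
#' @export
maximalBicliques <- function(network, minMirnas = 1L, minPathways = 1L) {
  e <- bipartiteEdges(network)
  if (!nrow(e)) return(list())
  mirnas <- sort(unique(e$mirna_id))
  pathways <- sort(unique(e$pathway_id))
  aug <- rbind(
    data.frame(from = e$mirna_id, to = e$pathway_id,
               stringsAsFactors = FALSE),
    if (length(mirnas) > 1L) {
      cm <- t(combn(mirnas, 2L))
      data.frame(from = cm[, 1L], to = cm[, 2L], stringsAsFactors = FALSE)
    },
    if (length(pathways) > 1L) {
      cp <- t(combn(pathways, 2L))
      data.frame(from = cp[, 1L], to = cp[, 2L], stringsAsFactors = FALSE)
    })
  g <- graph_from_data_frame(aug, directed = FALSE,
                             vertices = c(mirnas, pathways))
  cl <- max_cliques(g)
  mods <- list()
  for (cc in cl) {
    members <- names(cc)
    u <- sort(intersect(members, mirnas))
    v <- sort(intersect(members, pathways))
    if (length(u) >= minMirnas && length(v) >= minPathways &&
        length(u) > 0L && length(v) > 0L)
      mods[[length(mods) + 1L]] <- list(mirnas = u, pathways = v)
  }
  if (!length(mods)) return(list())
  key <- vapply(mods, function(m)
    paste(c(m$mirnas, "|", m$pathways), collapse = " "), character(1))
  mods <- mods[order(key)]
  for (i in seq_along(mods)) mods[[i]]$id <- sprintf("BM%03d", i)
  mods
}

crosstalkIgraph <- function(network) {
  if (is(network, "CrosstalkNetwork")) {
    e <- networkEdges(network)[c("pathway_i", "pathway_j")]
    v <- networkNodes(network)$pathway_id
  } else {
    e <- as.data.frame(network)[, 1:2]
    v <- unique(c(e[[1L]], e[[2L]]))
  }
  names(e) <- c("from", "to")
  graph_from_data_frame(unique(e), directed = FALSE, vertices = sort(v))
}

#' k-clique percolation communities
#'
#' Enumerates all k-cliques of the (simple, undirected) pathway crosstalk
#' network and chains them: two k-cliques are adjacent when they share
#' k - 1 nodes, and a community is the union of the nodes of a connected
#' component of this clique-overlap graph (the CFinder construction).
#'
#' @param network a [CrosstalkNetwork-class], an igraph graph, or a
#'   two-column edge data.frame.
#' @param k clique size, >= 3 (default 3).
#' @return list of communities, each a sorted character vector of node
#'   identifiers; communities sorted lexicographically.
#' @export
cliquePercolation <- function(network, k = 3L) {
  if (k < 3L) stop("k must be >= 3", call. = FALSE)
  g <- if (inherits(network, "igraph")) network
       else crosstalkIgraph(network)
  cl <- cliques(g, min = k, max = k)
  if (!length(cl)) return(list())
  memb <- vapply(cl, function(cc) {
    m <- logical(vcount(g))
    m[as.integer(cc)] <- TRUE
    m
  }, logical(vcount(g)))
  memb <- t(memb)                       # cliques x vertices
  ov <- tcrossprod(memb * 1)            # shared-node counts
  adj <- ov >= (k - 1)
  nq <- nrow(adj)
  comp <- integer(nq)
  cur <- 0L
  for (s in seq_len(nq)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  out <- lapply(seq_len(cur), function(ci) {
    sort(names(V(g))[colSums(memb[comp == ci, , drop = FALSE]) > 0])
  })
  out[order(vapply(out, paste, character(1), collapse = " "))]
}

#' Extract the core crosstalk module around an anchor pathway
#'
#' Returns the k-clique-percolation community containing the anchor
#' pathway, augmented with the community members' direct neighbors in the
#' crosstalk network (the indirect crosstalk routes through pathways
#' outside the community). An anchor in no community yields just the
#' anchor (plus its direct neighbors).
#'
#' @param network a [CrosstalkNetwork-class].
#' @param anchorPathway pathway identifier; must be a network node.
#' @param k clique size for percolation, default 3.
#' @return list with elements \code{anchor}, \code{core} (community
#'   members), \code{neighbors} (direct neighbors outside the core),
#'   \code{nodes} (core plus neighbors) and \code{edges} (the induced
#'   edge table).
#' @export
extractCoreModule <- function(network, anchorPathway, k = 3L) {
  nodes <- networkNodes(network)$pathway_id
  if (!anchorPathway %in% nodes)
    stop("anchor pathway not in network: ", anchorPathway, call. = FALSE)
  comms <- cliquePercolation(network, k)
  core <- anchorPathway
  for (cm in comms)
    if (anchorPathway %in% cm) { core <- cm; break }
  e <- networkEdges(network)
  nb <- unique(c(e$pathway_j[e$pathway_i %in% core],
                 e$pathway_i[e$pathway_j %in% core]))
  neighbors <- sort(setdiff(nb, core))
  all <- union(core, neighbors)
  induced <- e[e$pathway_i %in% all & e$pathway_j %in% all, ,
               drop = FALSE]
  rownames(induced) <- NULL
  list(anchor = anchorPathway, core = sort(core), neighbors = neighbors,
       nodes = sort(all), edges = induced)
}
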