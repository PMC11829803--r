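# Chu-Liu/Edmonds maximum-weight spanning arborescence.
#
# Internal solver works on integer node ids 1..n and parallel edge vectors
# (from, to, weight); returns indices of the selected edges. Every non-root
# node is assumed reachable from the root (the exported wrapper guarantees
# this by restricting to the root's reachable set).

# pick the best in-edge per node and detect a cycle among the picks
edmonds_best_in <- function(n_nodes, from, to, w, root) {
  best <- rep(NA_integer_, n_nodes)
  for (v in seq_len(n_nodes)) {
    if (v == root) next
    cand <- which(to == v & from != v)
    if (length(cand) == 0L)
      stop("internal: node without in-edge in arborescence solver")
    best[v] <- cand[which.max(w[cand])]
  }
  state <- integer(n_nodes) # 0 new, 1 on path, 2 done
  cycle <- NULL
  for (s in seq_len(n_nodes)) {
    if (state[s] != 0L) next
    path <- integer(0)
    v <- s
    repeat {
      if (v == root || state[v] == 2L) {
        state[path] <- 2L
        break
      }
      if (state[v] == 1L) {
        i0 <- match(v, path)
        cycle <- path[i0:length(path)]
        state[path] <- 2L
        break
      }
      state[v] <- 1L
      path <- c(path, v)
      v <- from[best[v]]
    }
    if (!is.null(cycle)) break
  }
  list(best = best, cycle = cycle)
}

chu_liu_edmonds <- function(n_nodes, from, to, w, root) {
  sel <- edmonds_best_in(n_nodes, from, to, w, root)
  if (is.null(sel$cycle))
    return(as.integer(stats::na.omit(sel$best)))
  cyc <- sel$cycle
  in_cyc <- rep(FALSE, n_nodes)
  in_cyc[cyc] <- TRUE
  new_id <- integer(n_nodes)
  nid <- 0L
  for (v in seq_len(n_nodes)) {
    if (!in_cyc[v]) {
      nid <- nid + 1L
      new_id[v] <- nid
    }
  }
  cnode <- nid + 1L
  new_id[in_cyc] <- cnode
  keep <- which(new_id[from] != new_id[to])
  nf <- new_id[from[keep]]
  nt <- new_id[to[keep]]
  nw <- w[keep]
  enters <- in_cyc[to[keep]]
  nw[enters] <- nw[enters] - w[sel$best[to[keep][enters]]]
  chosen <- chu_liu_edmonds(cnode, nf, nt, nw, new_id[root])
  chosen_orig <- keep[chosen]
  ei <- chosen_orig[nt[match(chosen_orig, keep)] == cnode]
  v0 <- to[ei]
  cycle_edges <- sel$best[cyc]
  c(chosen_orig, setdiff(cycle_edges, sel$best[v0]))
}

# nodes reachable from root along directed edges
reachable_from <- function(root, nodes, from, to) {
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  seen[root] <- TRUE
  frontier <- root
  while (length(frontier)) {
    nxt <- unique(to[from %in% frontier & !seen[to]])
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  nodes[seen]
}

#' Maximum spanning arborescence lineage tree
#'
#' Per weakly-connected component of the entropy-oriented partition graph,
#' extracts the maximum-weight spanning arborescence rooted at the
#' component's highest stable-state entropy partition, using the
#' Chu-Liu/Edmonds algorithm (best in-edge selection with cycle
#' contraction). Nodes a root cannot reach become orphan roots of their own
#' subtrees, with a warning; the result is in general a forest.
#'
#' @param dg A `directed_partition_graph` from [orient_partition_graph()].
#' @return Object of class `lineage_tree`: list with `roots` (partition
#'   ids) and `edges` (data.frame `parent`, `child`, `weight`; every
#'   non-root node has exactly one parent).
#' @export
max_arborescence <- function(dg) {
  stopifnot(inherits(dg, "directed_partition_graph"))
  nodes <- dg$nodes
  sse <- dg$sse
  ed <- dg$edges
  if (nrow(ed) > 0 && any(ed$weight < 0))
    stop("edge weights must be nonnegative")
  # weakly connected components
  und <- igraph::graph_from_data_frame(
    if (nrow(ed)) ed[, c("from", "to")] else data.frame(from = character(0),
                                                        to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = nodes))
  comp <- igraph::components(und)$membership
  roots <- character(0)
  parent <- character(0); child <- character(0); weight <- numeric(0)
  orphans <- character(0)
  for (ci in unique(comp)) {
    remaining <- nodes[comp == ci]
    first <- TRUE
    while (length(remaining)) {
      r <- remaining[order(-sse[remaining], as.numeric(remaining))][1]
      sub <- ed[ed$from %in% remaining & ed$to %in% remaining, , drop = FALSE]
      reach <- reachable_from(r, remaining, sub$from, sub$to)
      if (!first) orphans <- c(orphans, r)
      roots <- c(roots, r)
      sub <- sub[sub$from %in% reach & sub$to %in% reach, , drop = FALSE]
      if (nrow(sub) > 0 && length(reach) > 1) {
        idx_map <- stats::setNames(seq_along(reach), reach)
        sel <- chu_liu_edmonds(length(reach), idx_map[sub$from],
                               idx_map[sub$to], sub$weight, idx_map[r])
        parent <- c(parent, sub$from[sel])
        child <- c(child, sub$to[sel])
        weight <- c(weight, sub$weight[sel])
      }
      remaining <- setdiff(remaining, reach)
      first <- FALSE
    }
  }
  if (length(orphans))
    warning("partition(s) unreachable from their component root became ",
            "orphan roots: ", paste(orphans, collapse = ", "))
  structure(list(roots = roots,
                 edges = data.frame(parent = parent, child = child,
                                    weight = weight,
                                    stringsAsFactors = FALSE)),
            class = "lineage_tree")
}
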