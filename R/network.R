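#' Build the bipartite interaction network from an attempt log
#'
#' Aggregates the successful interactions of a run into a weighted, directed
#' bipartite network: one arc per (host, visitor) pair that completed at
#' least one exchange, weighted by the number of completed exchanges. Arcs
#' point from host to visitor, the direction of the energy flow. Agents with
#' no successful interaction do not appear.
#'
#' @param records Attempt log: a data frame with at least `visitor_id`,
#'   `host_id` and `outcome` columns (e.g. `sim_result$records`); rows whose
#'   `outcome` is not `"success"` are ignored.
#' @return An object of class `interaction_network`: a list with `edges`
#'   (data frame `host_id`, `visitor_id`, `count`), `host_ids` and
#'   `visitor_ids` (sorted), and `n_events` (total successes).
#' @examples
#' recs <- data.frame(visitor_id = c("v1", "v1", "v2"),
#'                    host_id = c("h1", "h1", "h1"),
#'                    outcome = "success")
#' net <- build_network(recs)
#' net$edges
#' @export
build_network <- function(records) {
  succ <- records[records$outcome == "success", , drop = FALSE]
  if (nrow(succ) == 0) {
    edges <- data.frame(host_id = character(0), visitor_id = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
  } else {
    tab <- stats::aggregate(
      list(count = rep(1L, nrow(succ))),
      by = list(host_id = succ$host_id, visitor_id = succ$visitor_id),
      FUN = sum
    )
    tab <- tab[order(tab$host_id, tab$visitor_id), , drop = FALSE]
    rownames(tab) <- NULL
    edges <- tab
  }
  structure(
    list(edges = edges,
         host_ids = sort(unique(edges$host_id)),
         visitor_ids = sort(unique(edges$visitor_id)),
         n_events = sum(edges$count)),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network> %d hosts x %d visitors, %d links, %d events\n",
    length(x$host_ids), length(x$visitor_ids), nrow(x$edges), x$n_events))
  invisible(x)
}

edge_count <- function(net, host_id, visitor_id) {
  hit <- net$edges$host_id == host_id & net$edges$visitor_id == visitor_id
  if (!any(hit)) {
    stop(sprintf("no edge between host '%s' and visitor '%s'",
                 host_id, visitor_id), call. = FALSE)
  }
  net$edges$count[hit]
}

#' Relative strength of one interaction
#'
#' The weight of the (host, visitor) arc relative to all arcs leaving the
#' same host: `count(host, visitor) / sum over visitors of count(host, .)`.
#' Strengths over each host sum to one.
#'
#' @param net An [build_network()] object.
#' @param host_id,visitor_id Endpoints of an existing edge.
#' @return Real in `(0, 1]`.
#' @export
relative_strength <- function(net, host_id, visitor_id) {
  cnt <- edge_count(net, host_id, visitor_id)
  cnt / sum(net$edges$count[net$edges$host_id == host_id])
}

#' Dependence of one species on a partner
#'
#' The fraction of a node's interaction events attributable to one partner:
#' `count(node, partner) / total count over all the node's edges`. Defined in
#' both directions — the dependence of a host on a visitor and of a visitor
#' on a host — and these are in general asymmetric. A value of 1 means the
#' node interacted with no one else.
#'
#' @param net An [build_network()] object.
#' @param node_id A host or visitor present in the network.
#' @param partner_id A partner sharing an edge with `node_id`.
#' @return Real in `(0, 1]`.
#' @export
dependence <- function(net, node_id, partner_id) {
  if (node_id %in% net$host_ids) {
    cnt <- edge_count(net, node_id, partner_id)
    total <- sum(net$edges$count[net$edges$host_id == node_id])
  } else if (node_id %in% net$visitor_ids) {
    cnt <- edge_count(net, partner_id, node_id)
    total <- sum(net$edges$count[net$edges$visitor_id == node_id])
  } else {
    stop(sprintf("node '%s' not present in the network", node_id),
         call. = FALSE)
  }
  cnt / total
}

#' Interaction count matrix
#'
#' The host-by-visitor matrix of interaction counts: entry `(i, j)` is the
#' number of completed exchanges between host `i` and visitor `j` (0 when
#' the pair never interacted). Rows and columns are ordered by decreasing
#' marginal totals (ties broken by id) so the matrix can be overlaid with
#' the isocline of perfect nestedness; all metrics are invariant to this
#' ordering.
#'
#' @param net An [build_network()] object.
#' @return Integer matrix with host ids as rownames and visitor ids as
#'   colnames; `0 x 0` for an empty network.
#' @export
to_matrix <- function(net) {
  m <- matrix(0L, nrow = length(net$host_ids), ncol = length(net$visitor_ids),
              dimnames = list(net$host_ids, net$visitor_ids))
  if (nrow(net$edges) > 0) {
    m[cbind(net$edges$host_id, net$edges$visitor_id)] <- net$edges$count
  }
  if (nrow(m) == 0 || ncol(m) == 0) return(m)
  row_ord <- order(-rowSums(m), rownames(m))
  col_ord <- order(-colSums(m), colnames(m))
  m[row_ord, col_ord, drop = FALSE]
}

#' Convert to an igraph bipartite graph
#'
#' @param net An [build_network()] object.
#' @return An [igraph::graph] with vertex attributes `name` and `type`
#'   (`FALSE` = host, `TRUE` = visitor) and edge attributes `count` and
#'   `strength` (the [relative_strength()]); arcs are directed host to
#'   visitor.
#' @export
as_igraph <- function(net) {
  verts <- data.frame(
    name = c(net$host_ids, net$visitor_ids),
    type = c(rep(FALSE, length(net$host_ids)),
             rep(TRUE, length(net$visitor_ids))),
    stringsAsFactors = FALSE
  )
  host_tot <- tapply(net$edges$count, net$edges$host_id, sum)
  edges <- data.frame(
    from = net$edges$host_id, to = net$edges$visitor_id,
    count = net$edges$count,
    strength = net$edges$count / as.numeric(host_tot[net$edges$host_id]),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Export the network
#'
#' `write_edge_list()` writes a CSV with one row per arc (`host_id`,
#' `visitor_id`, `count`, `relative_strength`); `write_matrix_csv()` writes
#' the interaction count matrix with ids as the header row and first column;
#' `write_graphml()` exports the bipartite graph (with `count` and
#' `strength` edge attributes) in GraphML.
#'
#' @param net An [build_network()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  host_tot <- tapply(net$edges$count, net$edges$host_id, sum)
  out <- net$edges
  out$relative_strength <- if (nrow(out) > 0) {
    out$count / as.numeric(host_tot[out$host_id])
  } else {
    numeric(0)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_matrix_csv <- function(net, path) {
  m <- to_matrix(net)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read an interaction matrix from CSV
#'
#' Reads a host-by-visitor count matrix in the format written by
#' [write_matrix_csv()] (first column = host ids, header = visitor ids) and
#' rebuilds the corresponding `interaction_network`. Counts must be
#' non-negative integers; rows or columns summing to zero are dropped, as
#' species without interactions are not part of the network.
#'
#' @param path CSV file path.
#' @return An `interaction_network`.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) ||
      any(m != round(m))) {
    stop(sprintf(
      "'%s' must contain only non-negative integer counts (%d rows, %d columns read)",
      path, nrow(m), ncol(m)), call. = FALSE)
  }
  network_from_matrix(m)
}

#' Build a network directly from a count matrix
#'
#' @param m Non-negative integer matrix, rows = hosts, columns = visitors;
#'   dimnames are used as ids (defaults `h<i>` / `v<j>` otherwise).
#' @return An `interaction_network`.
#' @export
network_from_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("h", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("v", seq_len(ncol(m)))
  idx <- which(m > 0, arr.ind = TRUE)
  records <- data.frame(
    visitor_id = rep(colnames(m)[idx[, "col"]], m[idx]),
    host_id = rep(rownames(m)[idx[, "row"]], m[idx]),
    outcome = "success", stringsAsFactors = FALSE
  )
  build_network(records)
}
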