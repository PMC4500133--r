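# The 8-node illustrative graph used throughout the centrality
# documentation: a 4-node component {1,2,3,4} in which nodes 1-2-3 form a
# triangle and node 4 hangs off node 2, a 2-node component {5,6}, and two
# isolated nodes 7 and 8.  Node 2 is the only node lying on shortest paths
# between other nodes; all centralities are zero for nodes 7 and 8.

#' The fixed 8-node mock graph
#'
#' @return an object of class `mock_graph`: a list with `nodes` (character
#'   IDs "1".."8"), `edges` (2-column character matrix of unordered pairs)
#'   and `adjacency` (symmetric 0/1 matrix with zero diagonal).
#' @examples
#' g <- mock_graph()
#' degree_centrality(g)   # 2 3 2 1 1 1 0 0
#' @export
mock_graph <- function() {
  nodes <- as.character(1:8)
  edges <- rbind(c("1", "2"), c("1", "3"), c("2", "3"), c("2", "4"),
                 c("5", "6"))
  A <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges[i, 1], edges[i, 2]] <- 1
    A[edges[i, 2], edges[i, 1]] <- 1
  }
  structure(list(nodes = nodes, edges = edges, adjacency = A),
            class = "mock_graph")
}
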