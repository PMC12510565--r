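#' @include hourly-panel.R
NULL

#' Read a city adjacency graph from YAML
#'
#' The YAML maps each city to a list of neighbours. Symmetry is
#' enforced: an edge listed on either side is present in both
#' directions. The diagonal is always zero.
#'
#' @param path YAML file; default the packaged 16-city
#'   Chengdu-Chongqing adjacency derived from shared administrative
#'   borders.
#' @return Symmetric 0/1 integer matrix with city dimnames.
#' @export
readAdjacency <- function(path = system.file("extdata",
                                             "adjacency_chengdu_chongqing.yaml",
                                             package = "hazecast")) {
  adj <- read_yaml(path)
  cityIds <- union(names(adj), unlist(adj, use.names = FALSE))
  A <- matrix(0L, length(cityIds), length(cityIds),
              dimnames = list(cityIds, cityIds))
  for (ci in names(adj)) for (nb in adj[[ci]]) {
    A[ci, nb] <- 1L
    A[nb, ci] <- 1L
  }
  diag(A) <- 0L
  A
}

#' The packaged 16-city adjacency graph
#'
#' @return Symmetric 0/1 matrix over the 16 Chengdu-Chongqing cities.
#' @export
chengduAdjacency <- function() readAdjacency()
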