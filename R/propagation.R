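## Network propagation: each functionally mutated gene of a sample is a heat
## source; heat diffuses over the recurrence network by a random walk with
## restart, F = (1 - r) F0 + r W F, with W the column-degree-normalized
## adjacency. The stationary solution, times a scaling factor, is the
## sample's netProfile; z-scored profiles stack into the netMatrix.

#' Propagation parameters
#'
#' @param restart restart probability r in (0, 1); default 0.5. As r tends
#'   to 0 the profile approaches the seed distribution; as r tends to 1 the
#'   degree-weighted stationary distribution on the seed-reachable component.
#' @param scaling_factor positive multiplier applied to the stationary
#'   scores (default 100000). Any positive value yields the identical
#'   netMatrix after per-sample z-scoring.
#' @param tolerance L1 convergence threshold of the iterative solver
#'   (default 1e-10).
#' @param max_iterations iteration cap; exceeding it is an error reporting
#'   the residual.
#' @return list of propagation parameters.
#' @export
propagation_config <- function(restart = 0.5, scaling_factor = 1e5,
                               tolerance = 1e-10, max_iterations = 1000L) {
  check_fraction(restart, "restart", lo_open = TRUE, hi_open = TRUE)
  if (scaling_factor <= 0) stop_fmt("scaling_factor must be positive")
  if (tolerance <= 0) stop_fmt("tolerance must be positive")
  list(restart = restart, scaling_factor = scaling_factor,
       tolerance = tolerance, max_iterations = as.integer(max_iterations))
}

## Accept a recurrence_network, an igraph, or an edge data.frame.
as_prop_graph <- function(network) {
  if (inherits(network, "recurrence_network")) return(network$graph)
  if (inherits(network, "igraph")) return(network)
  if (is.data.frame(network)) {
    return(igraph::graph_from_data_frame(network[, c("gene1", "gene2")],
                                         directed = FALSE))
  }
  stop_fmt("unsupported network representation: %s", class(network)[1L])
}

## Column-stochastic transition matrix; degree-0 nodes are self-absorbing so
## an isolated seed keeps its restart mass.
transition_matrix <- function(graph) {
  a <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  deg <- Matrix::colSums(a)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  w <- a %*% Matrix::Diagonal(x = inv)
  if (any(deg == 0)) {
    d <- Matrix::Diagonal(n = nrow(a), x = as.numeric(deg == 0))
    w <- w + d
  }
  dimnames(w) <- dimnames(a)
  w
}

## Shared solver: F0 is a genes-by-samples matrix of restart distributions.
solve_rwr <- function(w, f0, config) {
  r <- config$restart
  f <- f0
  for (i in seq_len(config$max_iterations)) {
    f_new <- (1 - r) * f0 + r * as.matrix(w %*% f)
    resid <- max(colSums(abs(f_new - f)))
    f <- f_new
    if (resid < config$tolerance) {
      return(f * config$scaling_factor)
    }
  }
  stop_fmt("propagation failed to converge in %d iterations (residual %.3g)",
           config$max_iterations, resid)
}

#' Propagate a seed gene set into a heating-score profile
#'
#' Places restart mass 1/|seeds| on every seed gene present in the network
#' and solves the random walk with restart to stationarity by fixed-order
#' Jacobi iteration (bit-stable across runs). Seeds missing from the network
#' are dropped with a warning; with no effective seed the profile is all
#' zeros (warned).
#'
#' @param network a `recurrence_network`, `igraph`, or edge `data.frame`.
#' @param seeds character vector of mutated genes.
#' @param config parameters from [propagation_config()].
#' @return named numeric vector of heating scores over the network genes.
#' @export
propagate <- function(network, seeds, config = propagation_config()) {
  propagate_cohort(network, list(sample = seeds), config)[, 1L]
}

#' Propagate founding clones of a cohort into raw netProfiles
#'
#' @param network a `recurrence_network`, `igraph`, or edge `data.frame`.
#' @param clones named list (sample -> seed gene vector), e.g. from
#'   [build_founding_clones()].
#' @param config parameters from [propagation_config()].
#' @return genes-by-samples matrix of heating scores (unnormalized).
#' @export
propagate_cohort <- function(network, clones, config = propagation_config()) {
  graph <- as_prop_graph(network)
  genes <- igraph::V(graph)$name
  w <- transition_matrix(graph)
  f0 <- matrix(0, length(genes), length(clones),
               dimnames = list(genes, names(clones)))
  for (j in seq_along(clones)) {
    eff <- intersect(unique(clones[[j]]), genes)
    dropped <- setdiff(unique(clones[[j]]), genes)
    if (length(dropped)) {
      warn_fmt("sample '%s': %d seed gene(s) not in the network",
               names(clones)[j], length(dropped))
    }
    if (!length(eff)) {
      warn_fmt("sample '%s': no seed genes in the network; all-zero profile",
               names(clones)[j])
    } else {
      f0[eff, j] <- 1 / length(eff)
    }
  }
  solve_rwr(w, f0, config)
}

#' Normalize netProfiles into a netMatrix
#'
#' Per sample (column): subtract the median heating score, then z-score
#' (center to mean 0, scale to standard deviation 1). Each retained column
#' therefore has mean 0 and unit standard deviation, and the result is
#' invariant to any positive propagation scaling factor. Zero-variance
#' profiles (empty seeds) are dropped with a message.
#'
#' @param profiles genes-by-samples matrix from [propagate_cohort()].
#' @return normalized genes-by-samples matrix, possibly with fewer columns.
#' @export
build_netmatrix <- function(profiles) {
  sds <- apply(profiles, 2L, sd)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop)) {
    message(sprintf("build_netmatrix: dropped %d zero-variance profile(s): %s",
                    sum(drop), paste(colnames(profiles)[drop], collapse = ", ")))
    profiles <- profiles[, !drop, drop = FALSE]
  }
  if (!ncol(profiles)) stop_fmt("no sample with nonzero profile variance")
  centered <- sweep(profiles, 2L, apply(profiles, 2L, median))
  centered <- sweep(centered, 2L, colMeans(centered))
  sweep(centered, 2L, apply(centered, 2L, sd), `/`)
}
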