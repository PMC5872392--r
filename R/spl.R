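#' Average shortest path length from a candidate to known targets
#'
#' Validates a candidate target against a herb's known-target set S in a
#' protein-protein interaction (PPI) network: unweighted breadth-first
#' shortest path lengths SPL(t, s) are computed for every s in S, and
#' ASPL(t, S) = mean of the SPLs. Known targets missing from the PPI
#' network are dropped with a warning; target pairs unreachable from the
#' candidate are excluded from the mean and counted.
#'
#' @param ppi a `layer_network` (treated as unweighted, undirected).
#' @param candidate protein id (must be a PPI node).
#' @param known character vector of known target ids.
#' @return An `spl_result` list: `candidate`, `spl` (named vector of finite
#'   SPLs), `aspl`, `n_unreachable`, `frac_below_3` (share of finite SPLs
#'   strictly below 3).
#' @export
aspl <- function(ppi, candidate, known) {
  stopifnot(inherits(ppi, "layer_network"))
  if (!candidate %in% ppi$ids) stop("candidate not in PPI network: ", candidate)
  known <- unique(as.character(known))
  mapped <- intersect(known, ppi$ids)
  if (length(mapped) < length(known)) {
    warning(length(known) - length(mapped),
            " known target(s) not in the PPI network; dropped")
  }
  if (length(mapped) == 0L) stop("no known targets mapped onto the PPI network")
  g <- ppi_graph(ppi)
  d <- igraph::distances(g, v = candidate, to = mapped)[1, ]
  finite <- is.finite(d)
  structure(
    list(candidate = candidate,
         spl = d[finite],
         aspl = if (any(finite)) mean(d[finite]) else NA_real_,
         n_unreachable = sum(!finite),
         frac_below_3 = if (any(finite)) mean(d[finite] < 3) else NA_real_),
    class = "spl_result"
  )
}

#' Random-candidate null for shortest path lengths
#'
#' Draws a uniformly random PPI node per replicate, collects its shortest
#' path lengths to the known-target set, and summarises the pooled SPL
#' distribution and the per-replicate ASPL.
#'
#' @param ppi a `layer_network`.
#' @param known character vector of known target ids.
#' @param n_reps number of random candidates (the reference analysis uses
#'   10000).
#' @param rng_seed RNG seed.
#' @return A list: `spl_histogram` (counts of finite pooled SPLs by length),
#'   `aspl_mean`, `aspl_sd` (NA when `n_reps = 1`), `frac_below_3`,
#'   `n_unreachable`.
#' @export
random_spl_null <- function(ppi, known, n_reps = 10000, rng_seed = NULL) {
  stopifnot(inherits(ppi, "layer_network"), n_reps >= 1)
  known <- unique(as.character(known))
  mapped <- intersect(known, ppi$ids)
  if (length(mapped) == 0L) stop("no known targets mapped onto the PPI network")
  g <- ppi_graph(ppi)
  cands <- with_seed(rng_seed,
                     sample(ppi$ids, n_reps, replace = TRUE))
  D <- igraph::distances(g, v = unique(cands), to = mapped)
  D <- D[match(cands, unique(cands)), , drop = FALSE]
  finite <- is.finite(D)
  pooled <- D[finite]
  aspls <- vapply(seq_len(n_reps), function(r) {
    row <- D[r, ]
    row <- row[is.finite(row)]
    if (length(row)) mean(row) else NA_real_
  }, numeric(1))
  list(
    spl_histogram = table(factor(pooled, levels = 0:max(c(pooled, 0)))),
    aspl_mean = mean(aspls, na.rm = TRUE),
    aspl_sd = if (n_reps > 1) stats::sd(aspls, na.rm = TRUE) else NA_real_,
    frac_below_3 = mean(pooled < 3),
    n_unreachable = sum(!finite)
  )
}

ppi_graph <- function(ppi) {
  igraph::graph_from_adjacency_matrix(
    ppi$W > 0, mode = "undirected", diag = FALSE
  )
}
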