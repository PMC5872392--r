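#' Build a similarity layer network
#'
#' Turns a cosine similarity matrix into an undirected weighted layer: an
#' edge joins every entity pair with positive similarity, weighted by that
#' similarity; the diagonal is dropped. Isolated entities (no positive
#' off-diagonal similarity) stay in the index so node ordering is shared
#' with the other pipeline stages, but [network_stats()] does not count
#' them as layer nodes.
#'
#' @param sim a [cosine_similarity()] result.
#' @return An object of class `layer_network`: list with `ids` and `W`
#'   (sparse symmetric non-negative weights, zero diagonal).
#' @export
build_layer_network <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  W <- sim$S
  Matrix::diag(W) <- 0
  structure(list(ids = sim$ids, W = Matrix::drop0(W)),
            class = "layer_network")
}

#' Construct a layer network from an explicit edge list
#'
#' Used for PPI edge lists (two- or three-column delimited text; the third
#' column, if present, is an edge weight — set `use_weights = FALSE` to treat
#' the network as unweighted, the convention of the shortest-path analysis).
#'
#' @param path path to the edge-list file.
#' @param delimiter field delimiter, default tab.
#' @param use_weights honor a numeric third column as edge weight.
#' @return A `layer_network`.
#' @export
read_edge_list <- function(path, delimiter = "\t", use_weights = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge list: ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("malformed line ", which(nf < 2L)[1L], " in ", path)
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  w <- if (use_weights && all(nf >= 3L)) {
    as.numeric(vapply(fields, `[[`, character(1), 3L))
  } else {
    rep(1, length(a))
  }
  keep <- a != b          # self-loops dropped
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  ids <- sort(unique(c(a, b)))
  W <- Matrix::sparseMatrix(i = match(a, ids), j = match(b, ids), x = w,
                            dims = c(length(ids), length(ids)),
                            dimnames = list(ids, ids),
                            use.last.ij = TRUE)
  W <- pmax_sparse(W, Matrix::t(W))
  structure(list(ids = ids, W = Matrix::drop0(W)), class = "layer_network")
}

# elementwise max of two same-shaped sparse matrices (symmetrization)
pmax_sparse <- function(A, B) {
  D <- A - B
  B + D * (D > 0)
}

#' k-nearest-neighbor pruning of a layer network
#'
#' Keeps edge (i, j) iff j is among i's top-k neighbors by weight or i is
#' among j's top-k (symmetric union), so the pruned network stays undirected.
#' Ties at the k-th weight are all kept, which makes the result independent
#' of neighbor ordering and the operation idempotent.
#'
#' @param net a `layer_network`.
#' @param k number of neighbors retained per node (>= 1).
#' @return A pruned `layer_network` over the same ids.
#' @export
knn_prune <- function(net, k) {
  stopifnot(inherits(net, "layer_network"), k >= 1)
  sm <- Matrix::summary(methods::as(net$W, "TsparseMatrix"))
  if (nrow(sm) == 0L) return(net)
  # per column: threshold at the k-th largest weight, keep ties
  keep <- unlist(lapply(split(seq_len(nrow(sm)), sm$j), function(idx) {
    w <- sm$x[idx]
    if (length(w) <= k) return(idx)
    thr <- sort(w, decreasing = TRUE)[k]
    idx[w >= thr]
  }), use.names = FALSE)
  K <- Matrix::sparseMatrix(i = sm$i[keep], j = sm$j[keep], x = TRUE,
                            dims = dim(net$W))
  K <- K | Matrix::t(K)
  structure(list(ids = net$ids, W = Matrix::drop0(net$W * K)),
            class = "layer_network")
}

#' Assemble the heterogeneous herb-protein network
#'
#' Two node types (herbs, proteins) and three edge types: herb-herb edges
#' from the efficacy-based similarity layer H, protein-protein edges from the
#' pathway-based similarity layer G, and binary herb-target links R from the
#' known association table. The node sets are unions: herbs annotated with
#' efficacies or with targets, proteins annotated with pathways or targeted
#' by a herb; entities present only in the herb-target table enter as
#' layer-isolated nodes reachable through R.
#'
#' @param herb_net herb `layer_network` (efficacy-based).
#' @param prot_net protein `layer_network` (pathway-based).
#' @param ht herb-target [association_table()] (entities = herbs,
#'   attributes = proteins).
#' @return An object of class `hetero_network`: `herb_ids`, `protein_ids`,
#'   `H` (m x m), `G` (n x n), `R` (m x n binary).
#' @export
build_hetero_network <- function(herb_net, prot_net, ht) {
  stopifnot(inherits(herb_net, "layer_network"),
            inherits(prot_net, "layer_network"),
            inherits(ht, "assoc_table"))
  herb_ids <- sort(union(herb_net$ids, ht$entities))
  protein_ids <- sort(union(prot_net$ids, ht$attributes))
  clash <- intersect(herb_ids, protein_ids)
  if (length(clash)) {
    stop("id collision between herb and protein namespaces: ",
         paste(utils::head(clash, 5), collapse = ", "))
  }
  H <- expand_layer(herb_net, herb_ids)
  G <- expand_layer(prot_net, protein_ids)
  R <- Matrix::sparseMatrix(
    i = match(ht$pairs$entity, herb_ids),
    j = match(ht$pairs$attribute, protein_ids),
    x = 1,
    dims = c(length(herb_ids), length(protein_ids)),
    dimnames = list(herb_ids, protein_ids)
  )
  structure(list(herb_ids = herb_ids, protein_ids = protein_ids,
                 H = H, G = G, R = R),
            class = "hetero_network")
}

# pad a layer weight matrix onto a larger id universe
expand_layer <- function(net, ids) {
  sm <- Matrix::summary(methods::as(net$W, "TsparseMatrix"))
  Matrix::sparseMatrix(
    i = match(net$ids[sm$i], ids),
    j = match(net$ids[sm$j], ids),
    x = sm$x,
    dims = c(length(ids), length(ids)),
    dimnames = list(ids, ids)
  )
}

#' Network summary statistics
#'
#' For a layer network: node count excludes isolated nodes; edges are
#' unordered positive-weight pairs; `avg_degree = 2 E / N` and
#' `density = 2 E / (N (N - 1))` (reported as 0 when N < 2). For the
#' heterogeneous network, nodes count every placed herb and protein and
#' edges add over the three edge sets: edges(H) + edges(G) + |R|.
#'
#' @param net a `layer_network` or `hetero_network`.
#' @return A list with `n_nodes`, `n_edges`, `avg_degree`, `density`.
#' @export
network_stats <- function(net) {
  if (inherits(net, "layer_network")) {
    deg <- Matrix::rowSums(net$W > 0)
    n <- sum(deg > 0)
    e <- Matrix::nnzero(net$W) / 2
  } else if (inherits(net, "hetero_network")) {
    n <- length(net$herb_ids) + length(net$protein_ids)
    e <- Matrix::nnzero(net$H) / 2 + Matrix::nnzero(net$G) / 2 +
      Matrix::nnzero(net$R)
  } else {
    stop("expected a layer_network or hetero_network")
  }
  list(
    n_nodes = n,
    n_edges = e,
    avg_degree = if (n > 0) 2 * e / n else 0,
    density = if (n > 1) 2 * e / (n * (n - 1)) else 0
  )
}
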