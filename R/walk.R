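#' Random-walk configuration
#'
#' Parameters of the heterogeneous random walk with restart. `theta` is the
#' restart probability (at each step the walker returns to the initial
#' distribution with probability theta); `phi` is the cross-layer jump
#' probability (given a move, a node with both intra-layer neighbors and
#' cross-layer links sends fraction phi of its outgoing mass across layers);
#' `alpha` and `beta` are the kNN sizes used to prune the herb and protein
#' similarity layers before the walk; `eta` is the share of initial mass
#' placed on the protein layer when seed targets are supplied; `epsilon` is
#' the L1 convergence tolerance and `max_iter` the iteration cap.
#' `exclude_train` controls whether retained training targets are removed
#' from the candidate ranking during evaluation.
#'
#' @param alpha herb-layer kNN size (default 20).
#' @param beta protein-layer kNN size (default 100).
#' @param theta restart probability in (0, 1) (default 0.4).
#' @param phi cross-layer jump probability in (0, 1) (default 0.9).
#' @param epsilon L1 convergence tolerance (default 1e-9).
#' @param eta initial-mass share on seed targets, in [0, 1] (default 0.5).
#' @param max_iter iteration cap (default 10000).
#' @param exclude_train drop retained training targets from rankings.
#' @return A `walk_config` list.
#' @export
walk_config <- function(alpha = 20, beta = 100, theta = 0.4, phi = 0.9,
                        epsilon = 1e-9, eta = 0.5, max_iter = 10000,
                        exclude_train = TRUE) {
  stopifnot(theta > 0, theta <= 1, phi > 0, phi < 1,
            eta >= 0, eta <= 1, epsilon > 0, alpha >= 1, beta >= 1,
            max_iter >= 1)
  structure(list(alpha = alpha, beta = beta, theta = theta, phi = phi,
                 epsilon = epsilon, eta = eta, max_iter = max_iter,
                 exclude_train = exclude_train),
            class = "walk_config")
}

#' Column-stochastic transition operator of the heterogeneous walk
#'
#' For a herb i with herb neighbors (pruned layer H) and known targets (R):
#' outgoing mass phi is distributed over its targets proportionally to the
#' R row and mass (1 - phi) over herb neighbors proportionally to the H
#' column. A node with only one kind of link gives that kind all its mass
#' (the single-kind fallback). The symmetric rule applies to proteins via
#' R columns and the pruned layer G. Dangling nodes (no links of either
#' kind) get a zero column; [propagate()] redirects their mass to the
#' restart vector, which keeps the effective operator stochastic.
#'
#' @param net a [build_hetero_network()] result.
#' @param cfg a [walk_config()].
#' @param prune apply alpha/beta kNN pruning to H and G first (default
#'   TRUE; pass FALSE when the caller pruned already, e.g. inside LOOCV).
#' @return An object of class `transition`: sparse `M` over the m + n nodes
#'   (herbs first), `dangling` logical vector, id vectors and sizes.
#' @export
build_transition <- function(net, cfg = walk_config(), prune = TRUE) {
  stopifnot(inherits(net, "hetero_network"))
  m <- length(net$herb_ids)
  n <- length(net$protein_ids)
  if (m == 0L || n == 0L) stop("empty heterogeneous network")
  H <- net$H
  G <- net$G
  if (prune) {
    H <- knn_prune(structure(list(ids = net$herb_ids, W = H),
                             class = "layer_network"), cfg$alpha)$W
    G <- knn_prune(structure(list(ids = net$protein_ids, W = G),
                             class = "layer_network"), cfg$beta)$W
  }
  R <- net$R
  phi <- cfg$phi

  sh <- Matrix::colSums(H)        # herb i's intra-layer weight
  sr <- Matrix::rowSums(R)        # herb i's number of targets
  sg <- Matrix::colSums(G)        # protein j's intra-layer weight
  sc <- Matrix::colSums(R)        # protein j's number of targeting herbs

  # column weights with single-kind fallback
  w_hh <- ifelse(sh > 0, ifelse(sr > 0, 1 - phi, 1), 0)
  w_ph <- ifelse(sr > 0, ifelse(sh > 0, phi, 1), 0)
  w_pp <- ifelse(sg > 0, ifelse(sc > 0, 1 - phi, 1), 0)
  w_hp <- ifelse(sc > 0, ifelse(sg > 0, phi, 1), 0)

  div <- function(w, s) ifelse(s > 0, w / s, 0)
  M_HH <- H %*% Matrix::Diagonal(x = div(w_hh, sh))
  M_PH <- Matrix::t(R) %*% Matrix::Diagonal(x = div(w_ph, sr))
  M_PP <- G %*% Matrix::Diagonal(x = div(w_pp, sg))
  M_HP <- R %*% Matrix::Diagonal(x = div(w_hp, sc))

  M <- rbind(cbind(M_HH, M_HP), cbind(M_PH, M_PP))
  dimnames(M) <- list(c(net$herb_ids, net$protein_ids),
                      c(net$herb_ids, net$protein_ids))
  structure(
    list(M = M, dangling = c(sh + sr == 0, sg + sc == 0),
         herb_ids = net$herb_ids, protein_ids = net$protein_ids,
         m = m, n = n),
    class = "transition"
  )
}

#' Initial probability of the walk
#'
#' With no seed targets (the NoTarget setting) all mass starts on the query
#' herb. With seed targets (retained training targets in the HalfTarget
#' setting) the herb keeps mass (1 - eta) and mass eta is split uniformly
#' over the seeds.
#'
#' @param net a `hetero_network` (or `transition`; only ids are used).
#' @param query_herb herb id.
#' @param seed_targets character vector of protein ids (may be empty).
#' @param cfg a [walk_config()].
#' @return An object of class `prob_state` with herb-layer vector `u`,
#'   protein-layer vector `v` and `iterations = 0`.
#' @export
initial_state <- function(net, query_herb, seed_targets = character(),
                          cfg = walk_config()) {
  herb_ids <- net$herb_ids
  protein_ids <- net$protein_ids
  if (!query_herb %in% herb_ids) stop("unknown query herb: ", query_herb)
  bad <- setdiff(seed_targets, protein_ids)
  if (length(bad)) stop("unknown seed targets: ", paste(bad, collapse = ", "))
  u <- stats::setNames(numeric(length(herb_ids)), herb_ids)
  v <- stats::setNames(numeric(length(protein_ids)), protein_ids)
  if (length(seed_targets) == 0L || cfg$eta == 0) {
    u[query_herb] <- 1
  } else {
    u[query_herb] <- 1 - cfg$eta
    v[seed_targets] <- cfg$eta / length(seed_targets)
  }
  if (inherits(net, "hetero_network")) {
    linked <- Matrix::colSums(net$H)[query_herb] +
      Matrix::rowSums(net$R)[query_herb]
    if (linked == 0) {
      warning("query herb '", query_herb,
              "' has no links; propagation returns the restart vector")
    }
  }
  structure(list(u = u, v = v, iterations = 0L, converged = TRUE),
            class = "prob_state")
}

#' Propagate to the stationary distribution
#'
#' Iterates p(t) = (1 - theta) M p(t-1) + theta p(0) until the L1 change
#' falls below epsilon (geometric convergence is guaranteed for theta > 0
#' since the update is a contraction with factor 1 - theta). Mass reaching
#' a dangling node is redirected to the restart vector so the total stays 1.
#'
#' @param tr a [build_transition()] result.
#' @param p0 the [initial_state()].
#' @param cfg a [walk_config()].
#' @return A `prob_state` with stationary `u`, `v`, the iteration count and
#'   a `converged` flag (FALSE if `max_iter` was hit).
#' @export
propagate <- function(tr, p0, cfg = walk_config()) {
  stopifnot(inherits(tr, "transition"), inherits(p0, "prob_state"))
  p0vec <- c(p0$u, p0$v)
  stopifnot(abs(sum(p0vec) - 1) < 1e-9)
  theta <- cfg$theta
  p <- p0vec
  it <- 0L
  converged <- FALSE
  while (it < cfg$max_iter) {
    it <- it + 1L
    q <- as.numeric(tr$M %*% p)
    lost <- sum(p[tr$dangling])
    pn <- (1 - theta) * (q + lost * p0vec) + theta * p0vec
    delta <- sum(abs(pn - p))
    p <- pn
    if (delta < cfg$epsilon) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("propagation hit max_iter = ", cfg$max_iter,
            " before reaching epsilon")
  }
  structure(
    list(u = stats::setNames(p[seq_len(tr$m)], tr$herb_ids),
         v = stats::setNames(p[tr$m + seq_len(tr$n)], tr$protein_ids),
         iterations = it, converged = converged),
    class = "prob_state"
  )
}

#' Rank candidate targets
#'
#' Sorts proteins by stationary protein-layer score, descending; ties break
#' lexicographically by id. Proteins in `exclude` (retained training
#' targets) are removed before ranking.
#'
#' @param state a `prob_state`.
#' @param exclude protein ids to drop from the ranking.
#' @return A data frame with columns `rank`, `protein`, `score`.
#' @export
rank_targets <- function(state, exclude = character()) {
  stopifnot(inherits(state, "prob_state"))
  v <- state$v[!names(state$v) %in% exclude]
  ord <- order(-v, names(v))
  data.frame(rank = seq_along(ord),
             protein = names(v)[ord],
             score = unname(v[ord]),
             stringsAsFactors = FALSE)
}

#' End-to-end target prediction for one query herb
#'
#' Convenience wrapper: computes the efficacy- and pathway-based similarity
#' layers, assembles the heterogeneous network, runs the restart walk from
#' the query herb and returns the ranked candidate targets.
#'
#' @param herb_efficacy,protein_pathway,herb_target association tables.
#' @param query_herb herb id.
#' @param seed_targets optional protein ids seeding the protein layer.
#' @param cfg a [walk_config()].
#' @return A list with `ranking` (data frame), `state` and `network`.
#' @export
predict_targets <- function(herb_efficacy, protein_pathway, herb_target,
                            query_herb, seed_targets = character(),
                            cfg = walk_config()) {
  herb_net <- build_layer_network(cosine_similarity(herb_efficacy))
  prot_net <- build_layer_network(cosine_similarity(protein_pathway))
  net <- build_hetero_network(herb_net, prot_net, herb_target)
  tr <- build_transition(net, cfg)
  p0 <- initial_state(net, query_herb, seed_targets, cfg)
  st <- propagate(tr, p0, cfg)
  excl <- if (cfg$exclude_train) seed_targets else character()
  list(ranking = rank_targets(st, exclude = excl), state = st, network = net)
}
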