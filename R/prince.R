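#' PRINCE configuration
#'
#' The baseline is label propagation on a protein-protein interaction (PPI)
#' network: F(t) = alpha_mix W' F(t-1) + (1 - alpha_mix) Y, where W' is the
#' degree-symmetric normalization of the PPI weights and Y a prior built
#' from the query herb's efficacy-similar herbs.
#'
#' @param alpha_mix propagation/prior mixing weight in (0, 1).
#' @param epsilon L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return A `prince_config` list.
#' @export
prince_config <- function(alpha_mix = 0.5, epsilon = 1e-9, max_iter = 10000) {
  stopifnot(alpha_mix > 0, alpha_mix < 1, epsilon > 0, max_iter >= 1)
  structure(list(alpha_mix = alpha_mix, epsilon = epsilon,
                 max_iter = max_iter),
            class = "prince_config")
}

#' Similarity-weighted prior over proteins
#'
#' Each protein's prior score is the best evidence from herbs similar to the
#' query: max over herbs h != query of sim(query, h) for herbs whose known
#' targets include the protein. The vector is normalized to sum 1; if no
#' similar herb contributes, the all-zero prior is returned with attribute
#' `flagged = TRUE` (propagation then has nothing to spread).
#'
#' @param query_herb herb id.
#' @param herb_sim efficacy-based [cosine_similarity()] of herbs.
#' @param ht herb-target [association_table()].
#' @return Named numeric prior over the proteins of `ht`.
#' @export
prince_prior <- function(query_herb, herb_sim, ht) {
  stopifnot(inherits(herb_sim, "similarity_matrix"),
            inherits(ht, "assoc_table"))
  if (!query_herb %in% herb_sim$ids) {
    stop("query herb not in similarity matrix: ", query_herb)
  }
  sims <- herb_sim$S[, query_herb]
  sims[query_herb] <- 0
  prior <- stats::setNames(numeric(length(ht$attributes)), ht$attributes)
  hsim <- sims[match(ht$pairs$entity, herb_sim$ids)]
  hsim[is.na(hsim)] <- 0
  pos <- hsim > 0
  if (any(pos)) {
    agg <- tapply(hsim[pos], ht$pairs$attribute[pos], max)
    prior[names(agg)] <- agg
    prior <- prior / sum(prior)
    attr(prior, "flagged") <- FALSE
  } else {
    attr(prior, "flagged") <- TRUE
  }
  prior
}

#' Propagate a prior over the PPI network
#'
#' Iterates F(t) = alpha_mix W' F(t-1) + (1 - alpha_mix) Y to convergence,
#' with W' = D^{-1/2} W D^{-1/2}. Prior entries for proteins absent from the
#' PPI network are dropped (their information cannot spread); isolated PPI
#' nodes retain their own prior mass.
#'
#' @param ppi a `layer_network` of protein-protein interactions.
#' @param prior named numeric prior (typically from [prince_prior()]).
#' @param cfg a [prince_config()].
#' @return A data frame `rank`, `protein`, `score` (empty, with attribute
#'   `flagged = TRUE`, when the prior carries no mass on the network).
#' @export
prince_propagate <- function(ppi, prior, cfg = prince_config()) {
  stopifnot(inherits(ppi, "layer_network"))
  y <- stats::setNames(numeric(length(ppi$ids)), ppi$ids)
  common <- intersect(names(prior), ppi$ids)
  y[common] <- prior[common]
  if (sum(y) == 0) {
    out <- data.frame(rank = integer(), protein = character(),
                      score = numeric(), stringsAsFactors = FALSE)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  deg <- Matrix::rowSums(ppi$W)
  inv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Wn <- Matrix::Diagonal(x = inv) %*% ppi$W %*% Matrix::Diagonal(x = inv)
  a <- cfg$alpha_mix
  f <- y
  for (it in seq_len(cfg$max_iter)) {
    fn <- a * as.numeric(Wn %*% f) + (1 - a) * y
    delta <- sum(abs(fn - f))
    f <- fn
    if (delta < cfg$epsilon) break
  }
  if (delta >= cfg$epsilon) {
    warning("PRINCE propagation hit max_iter = ", cfg$max_iter)
  }
  names(f) <- ppi$ids
  ord <- order(-f, ppi$ids)
  out <- data.frame(rank = seq_along(ord), protein = ppi$ids[ord],
                    score = unname(f[ord]), stringsAsFactors = FALSE)
  attr(out, "flagged") <- FALSE
  out
}
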