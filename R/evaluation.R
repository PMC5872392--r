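#' Split a herb's known targets into train and test sets
#'
#' `NoTarget` removes every known target (train empty, test all): the walk
#' must recover the targets from the herb layer alone. `HalfTarget` holds
#' out a random half, floor(k/2) targets, as the test set and retains the
#' rest as seeds; it requires at least two targets.
#'
#' @param targets character vector of known target ids.
#' @param mode `"NoTarget"` or `"HalfTarget"`.
#' @param rng_seed optional seed for the HalfTarget draw (caller's RNG
#'   stream is restored afterwards).
#' @return A list with `train` and `test` character vectors.
#' @export
split_targets <- function(targets, mode = c("NoTarget", "HalfTarget"),
                          rng_seed = NULL) {
  mode <- match.arg(mode)
  targets <- unique(as.character(targets))
  if (mode == "NoTarget") {
    if (length(targets) < 1L) stop("NoTarget requires at least one target")
    return(list(train = character(), test = targets))
  }
  if (length(targets) < 2L) {
    stop("HalfTarget requires more than one target; ",
         "single-target herbs are only usable under NoTarget")
  }
  n_test <- length(targets) %/% 2L
  test <- with_seed(rng_seed, sample(targets, n_test))
  list(train = setdiff(targets, test), test = test)
}

#' Score one ranked prediction against held-out targets
#'
#' With k = |test| held-out targets, the top-k ranked candidates are the
#' predictions: TP = |top-k intersect test|, FP = k - TP, FN = |test| - TP,
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean
#' (defined as 0 when TP = 0). Because k = |test|, precision, recall and F1
#' coincide. `hit_at_1` records whether the top-ranked candidate is a
#' held-out target. A ranking shorter than k is padded with misses and
#' flagged.
#'
#' @param ranked data frame from [rank_targets()] or [prince_propagate()].
#' @param test character vector of held-out target ids (non-empty).
#' @return One-row data frame: `n_test`, `n_correct`, `precision`, `recall`,
#'   `f1`, `hit_at_1`, `padded`.
#' @export
score_prediction <- function(ranked, test) {
  test <- unique(as.character(test))
  k <- length(test)
  stopifnot(k >= 1L)
  topk <- utils::head(ranked$protein, k)
  tp <- length(intersect(topk, test))
  precision <- tp / k
  recall <- tp / k
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  data.frame(
    n_test = k,
    n_correct = tp,
    precision = precision,
    recall = recall,
    f1 = f1,
    hit_at_1 = length(ranked$protein) >= 1L && ranked$protein[1L] %in% test,
    padded = length(ranked$protein) < k
  )
}

#' Leave-one-out cross-validation of target prediction
#'
#' For every query herb in the roster, the query's held-out targets are
#' removed from the herb-target table (all of them under NoTarget, a random
#' half under HalfTarget) while every other herb's links stay intact; the
#' chosen algorithm then ranks candidate targets and the ranking is scored
#' against the held-out set. Rosters follow the evaluation protocol:
#' NoTarget uses herbs that have both at least one herb-layer neighbor and
#' at least one known target (otherwise the restart vector carries no
#' spreadable information); HalfTarget uses herbs with more than one known
#' target.
#'
#' @param herb_efficacy,protein_pathway,herb_target association tables.
#' @param mode `"NoTarget"` or `"HalfTarget"`.
#' @param cfg a [walk_config()].
#' @param algorithm `"heNetRW"` (the heterogeneous walk) or `"PRINCE"`.
#' @param ppi PPI `layer_network`, required for PRINCE.
#' @param prince_cfg a [prince_config()] (PRINCE only).
#' @param split_seed seed for the HalfTarget splits (one stream per run).
#' @param repeats number of independent HalfTarget split repetitions
#'   (seeds `split_seed`, `split_seed + 1`, ...); aggregates are averaged.
#' @param roster optional explicit character vector of query herbs.
#' @return A list with `records` (one row per query herb, plus a `repeat.`
#'   column when `repeats > 1`) and `aggregate` (`n_herbs`, `mean_f1`,
#'   `sd_f1`, `hit_at_1_pct`).
#' @export
loocv <- function(herb_efficacy, protein_pathway, herb_target,
                  mode = c("NoTarget", "HalfTarget"),
                  cfg = walk_config(),
                  algorithm = c("heNetRW", "PRINCE"),
                  ppi = NULL, prince_cfg = prince_config(),
                  split_seed = 1L, repeats = 1L, roster = NULL) {
  mode <- match.arg(mode)
  algorithm <- match.arg(algorithm)
  if (algorithm == "PRINCE" && is.null(ppi)) {
    stop("PRINCE requires a PPI network")
  }
  herb_sim <- cosine_similarity(herb_efficacy)
  herb_net <- build_layer_network(herb_sim)
  prot_net <- build_layer_network(cosine_similarity(protein_pathway))
  net <- build_hetero_network(herb_net, prot_net, herb_target)
  # prune the static layers once; per-query networks only change R
  net$H <- knn_prune(structure(list(ids = net$herb_ids, W = net$H),
                               class = "layer_network"), cfg$alpha)$W
  net$G <- knn_prune(structure(list(ids = net$protein_ids, W = net$G),
                               class = "layer_network"), cfg$beta)$W

  targets_by_herb <- split(herb_target$pairs$attribute,
                           herb_target$pairs$entity)
  if (is.null(roster)) {
    has_neighbor <- Matrix::colSums(net$H > 0) > 0
    roster <- switch(mode,
      NoTarget = intersect(names(targets_by_herb),
                           net$herb_ids[has_neighbor]),
      HalfTarget = names(targets_by_herb)[lengths(targets_by_herb) > 1L]
    )
  }
  roster <- sort(roster)
  if (length(roster) == 0L) stop("empty evaluation roster")
  if (mode == "NoTarget") repeats <- 1L

  run_once <- function(seed) {
    recs <- with_seed(if (mode == "HalfTarget") seed else NULL, {
      lapply(roster, function(q) {
        sp <- split_targets(targets_by_herb[[q]], mode)
        rec <- eval_one_query(q, sp, net, herb_sim, herb_target,
                              cfg, algorithm, ppi, prince_cfg)
        rec
      })
    })
    do.call(rbind, recs)
  }

  all_records <- lapply(seq_len(repeats), function(r) {
    recs <- run_once(split_seed + r - 1L)
    if (repeats > 1L) recs$repeat. <- r
    recs
  })
  records <- do.call(rbind, all_records)
  per_rep <- lapply(all_records, function(recs) {
    c(mean_f1 = mean(recs$f1), sd_f1 = stats::sd(recs$f1),
      hit_at_1_pct = 100 * mean(recs$hit_at_1))
  })
  agg <- colMeans(do.call(rbind, per_rep))
  list(
    records = records,
    aggregate = list(n_herbs = length(roster),
                     mean_f1 = unname(agg["mean_f1"]),
                     sd_f1 = unname(agg["sd_f1"]),
                     hit_at_1_pct = unname(agg["hit_at_1_pct"]))
  )
}

# one LOOCV query: remove the held-out links, predict, score
eval_one_query <- function(q, sp, net, herb_sim, herb_target,
                           cfg, algorithm, ppi, prince_cfg) {
  excl <- if (cfg$exclude_train) sp$train else character()
  if (algorithm == "heNetRW") {
    net2 <- net
    net2$R[q, sp$test] <- 0
    net2$R <- Matrix::drop0(net2$R)
    tr <- build_transition(net2, cfg, prune = FALSE)
    p0 <- suppressWarnings(initial_state(net2, q, sp$train, cfg))
    st <- propagate(tr, p0, cfg)
    ranked <- rank_targets(st, exclude = excl)
  } else {
    keep <- !(herb_target$pairs$entity == q &
                herb_target$pairs$attribute %in% sp$test)
    ht2 <- herb_target
    ht2$pairs <- herb_target$pairs[keep, , drop = FALSE]
    prior <- if (q %in% herb_sim$ids) {
      prince_prior(q, herb_sim, ht2)
    } else {
      structure(stats::setNames(numeric(0), character(0)), flagged = TRUE)
    }
    ranked <- prince_propagate(ppi, prior, prince_cfg)
    if (length(excl)) {
      ranked <- ranked[!ranked$protein %in% excl, , drop = FALSE]
      if (nrow(ranked)) ranked$rank <- seq_len(nrow(ranked))
    }
  }
  rec <- score_prediction(ranked, sp$test)
  cbind(data.frame(herb = q, n_train = length(sp$train),
                   stringsAsFactors = FALSE), rec)
}
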