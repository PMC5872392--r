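#' Binned overlap of two similarity measures
#'
#' Checks the guilt-by-association assumption behind the walk: entity pairs
#' that are similar under one annotation (e.g. shared efficacies) should
#' also be similar under another (e.g. shared targets). All unordered pairs
#' are assigned to 10 equal-width bins [0, 0.1), ..., [0.9, 1.0] by their
#' `simA` value and the mean `simB` value per bin is reported.
#'
#' @param simA,simB `similarity_matrix` objects over the same entity roster
#'   (restrict with [subset_similarity()] first if needed).
#' @param n_bins number of equal-width bins over [0, 1].
#' @param min_sim optional lower cutoff: pairs with `simA < min_sim` are
#'   dropped (default keeps all pairs, zero-similarity pairs landing in the
#'   first bin).
#' @return Data frame: `bin_low`, `bin_high`, `n_pairs`, `observed_mean`
#'   (NA for empty bins).
#' @export
binned_overlap <- function(simA, simB, n_bins = 10, min_sim = NULL) {
  stopifnot(inherits(simA, "similarity_matrix"),
            inherits(simB, "similarity_matrix"))
  if (!identical(simA$ids, simB$ids)) {
    stop("simA and simB must cover the same entity roster")
  }
  pv <- pair_values(simA$S, simB$S)
  if (!is.null(min_sim)) pv <- pv[pv$a >= min_sim, , drop = FALSE]
  bins <- assign_bins(pv$a, n_bins)
  agg_bins(bins, pv$b, n_bins)
}

#' Fisher-Yates shuffle null for the binned overlap
#'
#' Keeps the binning similarity (`simA`) fixed and destroys the second
#' annotation: each replicate reassigns every entity a uniformly random
#' attribute set of its original size, drawn (Fisher-Yates) from the full
#' attribute universe of `tableB`, recomputes the cosine similarity and the
#' per-bin means. Bin membership is keyed by the fixed `simA`, so pair
#' counts per bin are identical across replicates.
#'
#' @param tableB the [association_table()] behind the second similarity
#'   (e.g. herb-target links), restricted to the analysis roster but keeping
#'   the full attribute universe (see [subset_table()] `keep_attributes`).
#' @param simA the fixed binning `similarity_matrix` (same roster).
#' @param n_bins number of equal-width bins.
#' @param n_reps number of shuffle replicates.
#' @param rng_seed RNG seed for the replicates.
#' @param min_sim optional lower `simA` cutoff, as in [binned_overlap()].
#' @return Data frame: `bin_low`, `bin_high`, `n_pairs`, `null_mean`,
#'   `null_sd` (sd is NA with a single replicate).
#' @export
shuffle_null <- function(tableB, simA, n_bins = 10, n_reps = 100,
                         rng_seed = NULL, min_sim = NULL) {
  stopifnot(inherits(tableB, "assoc_table"),
            inherits(simA, "similarity_matrix"))
  if (!setequal(tableB$entities, simA$ids)) {
    stop("tableB entities must match the simA roster")
  }
  degrees <- table(tableB$pairs$entity)[simA$ids]
  universe <- tableB$attributes
  a_upper <- as.matrix(simA$S)
  mask <- upper.tri(a_upper)
  avals <- a_upper[mask]
  keep <- if (is.null(min_sim)) rep(TRUE, length(avals)) else avals >= min_sim
  bins <- assign_bins(avals[keep], n_bins)

  per_rep <- with_seed(rng_seed, {
    vapply(seq_len(n_reps), function(rep) {
      ent <- rep(simA$ids, times = degrees)
      att <- unlist(lapply(degrees, function(d) sample(universe, d)),
                    use.names = FALSE)
      simB <- cosine_similarity(association_table(ent, att))
      simB <- subset_similarity(
        structure(list(ids = simB$ids, S = simB$S,
                       zero_annotation = simB$zero_annotation),
                  class = "similarity_matrix"), simA$ids)
      bvals <- as.matrix(simB$S)[mask][keep]
      vapply(seq_len(n_bins), function(bi) {
        v <- bvals[bins == bi]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
    }, numeric(n_bins))
  })
  per_rep <- matrix(per_rep, nrow = n_bins)
  edges <- seq(0, 1, length.out = n_bins + 1)
  data.frame(
    bin_low = edges[-length(edges)],
    bin_high = edges[-1],
    n_pairs = tabulate(bins, nbins = n_bins),
    null_mean = rowMeans(per_rep),
    null_sd = apply(per_rep, 1, stats::sd)
  )
}

#' Observed-versus-null overlap analysis
#'
#' Convenience wrapper: restricts both tables to their common entities
#' (the dual-annotated roster), computes simA from `tableA` and simB from
#' `tableB`, and returns the observed binned means joined with the shuffle
#' null.
#'
#' @param tableA binning association table (e.g. herb-efficacy).
#' @param tableB second association table (e.g. herb-target).
#' @param n_bins,n_reps,rng_seed,min_sim see [binned_overlap()] and
#'   [shuffle_null()].
#' @return Data frame: `bin_low`, `bin_high`, `n_pairs`, `observed_mean`,
#'   `null_mean`, `null_sd`.
#' @export
overlap_analysis <- function(tableA, tableB, n_bins = 10, n_reps = 100,
                             rng_seed = NULL, min_sim = NULL) {
  roster <- intersect(tableA$entities, tableB$entities)
  if (length(roster) < 2L) stop("fewer than two dual-annotated entities")
  tA <- subset_table(tableA, roster)
  tB <- subset_table(tableB, roster, keep_attributes = TRUE)
  simA <- cosine_similarity(tA)
  simB <- cosine_similarity(tB)
  obs <- binned_overlap(simA, simB, n_bins, min_sim)
  nul <- shuffle_null(tB, simA, n_bins, n_reps, rng_seed, min_sim)
  cbind(obs, nul[, c("null_mean", "null_sd")])
}

# unordered pair values of two same-roster symmetric matrices
pair_values <- function(A, B) {
  Am <- as.matrix(A)
  Bm <- as.matrix(B)
  mask <- upper.tri(Am)
  data.frame(a = Am[mask], b = Bm[mask])
}

# equal-width bins over [0,1]; last bin right-closed
assign_bins <- function(x, n_bins) {
  stopifnot(all(x >= 0 & x <= 1 + 1e-12))
  pmin(floor(x * n_bins) + 1L, n_bins)
}

agg_bins <- function(bins, vals, n_bins) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  data.frame(
    bin_low = edges[-length(edges)],
    bin_high = edges[-1],
    n_pairs = tabulate(bins, nbins = n_bins),
    observed_mean = vapply(seq_len(n_bins), function(bi) {
      v <- vals[bins == bi]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  )
}
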