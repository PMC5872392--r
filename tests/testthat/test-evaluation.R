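test_that("target splitting follows the NoTarget/HalfTarget rules", {
  targets <- sprintf("t%02d", 1:64)
  sp <- split_targets(targets, "HalfTarget", rng_seed = 1)
  expect_length(sp$test, 32)
  expect_length(sp$train, 32)
  expect_setequal(c(sp$test, sp$train), targets)

  sp5 <- split_targets(sprintf("t%d", 1:5), "HalfTarget", rng_seed = 2)
  expect_length(sp5$test, 2)   # floor(5/2)
  expect_length(sp5$train, 3)

  spn <- split_targets(targets, "NoTarget")
  expect_length(spn$train, 0)
  expect_setequal(spn$test, targets)

  expect_error(split_targets("t1", "HalfTarget"), "more than one")
})

test_that("scoring reproduces the worked per-herb examples", {
  mk_ranked <- function(k, tp, test) {
    hits <- test[seq_len(tp)]
    fillers <- sprintf("x%03d", seq_len(k - tp))
    data.frame(rank = seq_len(k), protein = c(hits, fillers),
               score = seq(k, 1), stringsAsFactors = FALSE)
  }
  # 35 correct in the top 64
  test64 <- sprintf("t%03d", 1:64)
  rec <- score_prediction(mk_ranked(64, 35, test64), test64)
  expect_equal(round(rec$f1, 4), 0.5469)
  expect_equal(rec$precision, rec$recall)
  expect_equal(rec$precision, rec$f1)
  # 81 correct in the top 152
  test152 <- sprintf("t%03d", 1:152)
  rec2 <- score_prediction(mk_ranked(152, 81, test152), test152)
  expect_equal(round(rec2$f1, 4), 0.5329)
  # no correct prediction: F1 defined as 0
  rec0 <- score_prediction(mk_ranked(10, 0, sprintf("t%d", 1:10)),
                           sprintf("t%d", 1:10))
  expect_equal(rec0$f1, 0)
  expect_false(rec0$hit_at_1)
})

test_that("precision = recall = F1 whenever k = |test| (algebraic identity)", {
  set.seed(42)
  for (i in 1:20) {
    k <- sample(1:30, 1)
    tp <- sample(0:k, 1)
    test <- sprintf("t%03d", seq_len(k))
    ranked <- data.frame(
      rank = seq_len(k),
      protein = c(test[seq_len(tp)],
                  sprintf("x%03d", seq_len(k - tp)))[sample(k)],
      score = seq(k, 1))
    rec <- score_prediction(ranked, test)
    expect_equal(rec$precision, rec$recall)
    expect_equal(rec$precision, rec$f1)
  }
})

test_that("rankings shorter than k are padded and flagged", {
  ranked <- data.frame(rank = 1L, protein = "t1", score = 1)
  rec <- score_prediction(ranked, c("t1", "t2", "t3"))
  expect_true(rec$padded)
  expect_equal(rec$n_correct, 1)
  expect_equal(rec$recall, 1 / 3)
})

test_that("a single-herb roster aggregates to that herb's record", {
  tabs <- generate_tables(synth_config(rng_seed = 5))
  cfg <- walk_config(alpha = 5, beta = 10)
  res <- loocv(tabs$herb_efficacy, tabs$protein_pathway, tabs$herb_target,
               mode = "NoTarget", cfg = cfg, roster = "herb003")
  expect_equal(nrow(res$records), 1)
  expect_equal(res$aggregate$mean_f1, res$records$f1)
  expect_equal(res$aggregate$hit_at_1_pct, 100 * res$records$hit_at_1)
})

test_that("each query is isolated: other roster members do not change it", {
  tabs <- generate_tables(synth_config(rng_seed = 5))
  cfg <- walk_config(alpha = 5, beta = 10)
  solo <- loocv(tabs$herb_efficacy, tabs$protein_pathway, tabs$herb_target,
                mode = "NoTarget", cfg = cfg, roster = "herb007")
  many <- loocv(tabs$herb_efficacy, tabs$protein_pathway, tabs$herb_target,
                mode = "NoTarget", cfg = cfg,
                roster = c("herb001", "herb007", "herb020"))
  expect_equal(many$records[many$records$herb == "herb007",
                            c("f1", "n_correct", "hit_at_1")],
               solo$records[, c("f1", "n_correct", "hit_at_1")],
               ignore_attr = TRUE)
})

test_that("the aggregate is invariant to roster order", {
  tabs <- generate_tables(synth_config(rng_seed = 5))
  cfg <- walk_config(alpha = 5, beta = 10)
  r1 <- loocv(tabs$herb_efficacy, tabs$protein_pathway, tabs$herb_target,
              mode = "NoTarget", cfg = cfg,
              roster = c("herb001", "herb002", "herb003"))
  r2 <- loocv(tabs$herb_efficacy, tabs$protein_pathway, tabs$herb_target,
              mode = "NoTarget", cfg = cfg,
              roster = c("herb003", "herb001", "herb002"))
  expect_equal(r1$aggregate, r2$aggregate)
})

test_that("HalfTarget uses retained targets as seeds and excludes them", {
  tabs <- generate_tables(synth_config(rng_seed = 5))
  cfg <- walk_config(alpha = 5, beta = 10)
  res <- loocv(tabs$herb_efficacy, tabs$protein_pathway, tabs$herb_target,
               mode = "HalfTarget", cfg = cfg, split_seed = 3,
               roster = c("herb001", "herb002"))
  expect_true(all(res$records$n_train >= 1))
  expect_true(all(res$records$n_test >= 1))
  # same split seed reproduces the run exactly
  res2 <- loocv(tabs$herb_efficacy, tabs$protein_pathway, tabs$herb_target,
                mode = "HalfTarget", cfg = cfg, split_seed = 3,
                roster = c("herb001", "herb002"))
  expect_equal(res$records, res2$records)
})
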