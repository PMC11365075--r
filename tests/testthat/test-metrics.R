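# Per-pixel segmentation metrics: hand-computed cases, degenerate-denominator
# conventions, and exact agreement with a brute-force enumeration oracle.

test_that("confusion counts match hand-enumerated cases", {
  m <- matrix(0, 4, 4); m[1:2, 1:3] <- 1; m[3, 1:4] <- 1   # 10 fg, 6 bg
  cc <- confusion_counts(m, m)
  expect_equal(cc[c("tp", "tn", "fp", "fn")], list(tp = 10, tn = 6, fp = 0, fn = 0))

  all_fg <- matrix(1, 4, 4); all_bg <- matrix(0, 4, 4)
  cc2 <- confusion_counts(all_fg, all_bg)
  expect_equal(cc2[c("tp", "fp", "fn", "tn")], list(tp = 0, fp = 16, fn = 0, tn = 0))

  # |pred| = 6, |ref| = 4, |intersection| = 3 on a 4x4 grid
  pred <- matrix(0, 4, 4); pred[1, 1:4] <- 1; pred[2, 1:2] <- 1
  ref <- matrix(0, 4, 4); ref[1, 1:3] <- 1; ref[3, 1] <- 1
  cc3 <- confusion_counts(pred, ref)
  expect_equal(cc3, list(tp = 3, fp = 3, fn = 1, tn = 9))

  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("scores follow the accuracy/overlap/precision/recall/F formulas", {
  m <- matrix(c(1, 1, 0, 0), 2, 2)
  r <- score_masks(m, m)
  expect_equal(unlist(r[c("accuracy", "overlap", "precision", "recall", "f_measure")]),
               c(accuracy = 1, overlap = 1, precision = 1, recall = 1, f_measure = 1))

  pred <- matrix(0, 4, 4); pred[1, 1:4] <- 1; pred[2, 1:2] <- 1
  ref <- matrix(0, 4, 4); ref[1, 1:3] <- 1; ref[3, 1] <- 1
  r2 <- score_masks(pred, ref)
  expect_equal(r2$accuracy, 0.75)
  expect_equal(r2$overlap, 3 / 7)
  expect_equal(r2$precision, 0.5)
  expect_equal(r2$recall, 0.75)
  expect_equal(r2$f_measure, 0.6)

  a <- matrix(0, 3, 3); a[1, 1] <- 1
  b <- matrix(0, 3, 3); b[3, 3] <- 1
  r3 <- score_masks(a, b)
  expect_equal(r3$overlap, 0)
  expect_equal(r3$f_measure, 0)
  expect_equal(r3$accuracy, 7 / 9)
})

test_that("degenerate denominators follow the documented conventions", {
  e <- matrix(0, 3, 3)
  r <- score_masks(e, e)   # identical empty masks score perfect
  expect_equal(unlist(r[c("accuracy", "overlap", "precision", "recall", "f_measure")]),
               c(accuracy = 1, overlap = 1, precision = 1, recall = 1, f_measure = 1))

  full <- matrix(1, 3, 3)
  r2 <- score_masks(e, full)   # total miss scores zero
  expect_equal(r2$precision, 0)
  expect_equal(r2$recall, 0)
  expect_equal(r2$f_measure, 0)
  r3 <- score_masks(full, e)
  expect_equal(r3$precision, 0)
  expect_equal(r3$recall, 0)
})

test_that("score agrees exactly with the enumeration oracle on random masks", {
  for (s in 1:60) {
    pred <- random_mask(8, runif(1), seed = s)
    ref <- random_mask(8, runif(1), seed = s + 1000)
    got <- score_masks(pred, ref)
    exp <- oracle_score(pred, ref)
    for (f in names(exp)) expect_identical(got[[f]] + 0, exp[[f]] + 0)
  }
})

test_that("metric symmetries and bounds hold", {
  for (s in 1:40) {
    a <- random_mask(10, 0.4, seed = s)
    b <- random_mask(10, 0.3, seed = s + 500)
    ra <- score_masks(a, b); rb <- score_masks(b, a)
    expect_equal(ra$accuracy, rb$accuracy)
    expect_equal(ra$overlap, rb$overlap)
    expect_equal(ra$precision, rb$recall)
    cc <- confusion_counts(a, b)
    if (cc$tp + cc$fp > 0 && cc$tp + cc$fn > 0 && cc$tp + cc$fp + cc$fn > 0) {
      expect_lte(ra$overlap, ra$precision)
      expect_lte(ra$overlap, ra$recall)
    }
  }
})

test_that("cohort summaries use min/max/mean/population-sd", {
  one <- score_masks(matrix(1, 2, 2), matrix(1, 2, 2), "a")
  one$f_measure <- 0.9
  s1 <- summarize_metrics(one, "f_measure")
  expect_equal(unlist(s1[c("minimum", "maximum", "mean", "standard_deviation")]),
               c(minimum = 0.9, maximum = 0.9, mean = 0.9, standard_deviation = 0))

  recs <- do.call(rbind, lapply(c(0.8, 0.9, 1.0), function(v) {
    r <- one; r$f_measure <- v; r
  }))
  s3 <- summarize_metrics(recs, "f_measure")
  expect_equal(s3$mean, 0.9)
  expect_equal(s3$minimum, 0.8)
  expect_equal(s3$maximum, 1.0)
  expect_equal(s3$standard_deviation, sqrt(2 * 0.01 / 3), tolerance = 1e-12)
  expect_lte(s3$minimum, s3$mean); expect_lte(s3$mean, s3$maximum)

  expect_error(summarize_metrics(recs[0, ], "f_measure"), "nonempty")
  expect_error(summarize_metrics(recs, "dice"), "unknown metric")
})

test_that("method comparison table matches per-method summaries", {
  set.seed(9)
  refs <- lapply(1:10, function(i) random_mask(8, 0.3, seed = i))
  preds1 <- lapply(1:10, function(i) random_mask(8, 0.3, seed = i + 100))
  ids <- sprintf("im%02d", 1:10)
  r1 <- score_cohort(preds1, refs, pair_ids = ids)
  r_perfect <- score_cohort(refs, refs, pair_ids = ids)
  tab <- compare_methods(list(noisy = r1, perfect = r_perfect, noisy2 = r1))
  expect_equal(nrow(tab), 3)
  expect_equal(tab[tab$method == "noisy", -1], tab[tab$method == "noisy2", -1],
               ignore_attr = TRUE)
  expect_equal(unlist(tab[tab$method == "perfect",
                          c("accuracy_mean", "overlap_mean", "f_mean",
                            "accuracy_sd", "overlap_sd", "f_sd")]),
               c(accuracy_mean = 1, overlap_mean = 1, f_mean = 1,
                 accuracy_sd = 0, overlap_sd = 0, f_sd = 0))
  expect_equal(tab$f_mean[1], summarize_metrics(r1, "f_measure")$mean)

  r_bad <- r1; r_bad$pair_id <- sprintf("other%02d", 1:10)
  expect_error(compare_methods(list(a = r1, b = r_bad)), "same pair_id")
})
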