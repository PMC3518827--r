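test_that("published scale carries the published constants", {
  sc <- am_scale()
  expect_equal(sc$weights["wbc_pre", "F2"], 0.914729)
  expect_equal(sc$thresholds$cutoff, c(-1.4, 1.0, 0.4))
  expect_equal(sc$thresholds$recovery_side, c("above", "below", "below"))
  expect_equal(sc$combination, "majority")
  expect_identical(dim(sc$weights), c(8L, 3L))
})

test_that("scale YAML round-trips", {
  sc <- am_scale()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scale(sc, path)
  back <- read_scale(path)
  expect_equal(back$weights, sc$weights)
  expect_equal(back$ref$means, sc$ref$means)
  expect_equal(back$thresholds, sc$thresholds)
  expect_equal(back$combination, sc$combination)
})

test_that("votes and combination rules follow the published semantics", {
  sc <- am_scale()
  # published case 4: all three factors vote recovery
  p4 <- predict_recovery(scored_from(2.96689, 0.0611059, -1.30167), sc)
  expect_true(all(unlist(p4[c("vote1", "vote2", "vote3")])))
  expect_equal(p4$predicted, "recovery")
  # published case 18 under the factor-1 rule: death
  p18 <- predict_recovery(scored_from(-1.56375, -2.27389, -0.389642), sc,
                          rule = "f1_only")
  expect_equal(p18$predicted, "death")
  # published case 8: majority recovery, factor-1 rule death
  s8 <- scored_from(-2.55507, 0.0101163, -0.12325)
  expect_equal(predict_recovery(s8, sc)$predicted, "recovery")
  expect_equal(predict_recovery(s8, sc, rule = "f1_only")$predicted, "death")
  expect_equal(predict_recovery(s8, sc, rule = "unanimous")$predicted,
               "death")
})

test_that("a score exactly at a cutoff votes non-recovery", {
  sc <- am_scale()
  p <- predict_recovery(scored_from(-1.4, 1.0, 0.4), sc)
  expect_false(any(unlist(p[c("vote1", "vote2", "vote3")])))
  expect_equal(p$predicted, "death")
  expect_equal(predict_recovery(scored_from(-1.4, 1.0, 0.4), sc,
                                rule = "unanimous")$predicted, "death")
})

test_that("majority vote is self-dual and monotone per factor", {
  sc <- am_scale()
  set.seed(31)
  f1 <- rnorm(200, 0, 3); f2 <- rnorm(200, 0, 1.5); f3 <- rnorm(200, 0, 1.5)
  pred <- predict_recovery(scored_from(f1, f2, f3), sc)$predicted
  # reflecting every score across its cutoff flips every vote
  mirror <- scored_from(2 * -1.4 - f1, 2 * 1.0 - f2, 2 * 0.4 - f3)
  pred_m <- predict_recovery(mirror, sc)$predicted
  expect_true(all(pred != pred_m))
  # pushing a score further onto its recovery side never flips to death
  up <- predict_recovery(scored_from(f1 + 2, f2, f3), sc)
  was_rec <- pred == "recovery"
  expect_true(all(up$predicted[was_rec] == "recovery"))
})

test_that("classification of the published cases reproduces the printed labels", {
  cases <- am_cases()
  cls <- classify_cases(cases, rule = "f1_only")
  expect_equal(cls$classification, cases$classification)
  expect_equal(sum(cls$classification %in% c("FP", "FN")), 7)
})

test_that("majority-rule confusion counts match the exhaustive vote count", {
  cases <- am_cases()
  cls <- classify_cases(cases)  # published combination = majority
  cc <- confusion_counts(cls)
  expect_equal(cc$tp, 27)
  expect_equal(cc$fn, 3)
  expect_equal(cc$tn, 9)
  expect_equal(cc$fp, 5)
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 44)
})

test_that("classification is deterministic across repeated runs", {
  cases <- am_cases()
  a <- classify_cases(cases)$classification
  b <- classify_cases(cases)$classification
  expect_identical(a, b)
})

test_that("missing outcomes are a contract error listing the ids", {
  cases <- am_cases()
  cases$outcome[c(2, 5)] <- NA
  expect_error(classify_cases(cases), "2, 5")
  noout <- cases[setdiff(names(cases), "outcome")]
  expect_error(classify_cases(noout), "outcome")
})

test_that("diagnostic power follows the published formulas and display", {
  p1 <- diagnostic_power(structure(list(tp = 26, fn = 4, tn = 11, fp = 3),
                                   class = "am_confusion"))
  expect_equal(p1$snc, 100 * 26 / 30)
  expect_equal(round(p1$snc), 87)
  expect_equal(round(p1$spc), 79)
  p2 <- diagnostic_power(structure(list(tp = 27, fn = 3, tn = 9, fp = 5),
                                   class = "am_confusion"))
  expect_equal(p2$snc, 90)
  expect_equal(p2$spc, 100 * 9 / 14)
  und <- diagnostic_power(structure(list(tp = 0, fn = 0, tn = 3, fp = 1),
                                    class = "am_confusion"))
  expect_true(is.na(und$snc))
  expect_false(is.na(und$spc))
})

test_that("per-factor power reproduces the published coefficients", {
  pf <- per_factor_power(am_cases())
  expect_equal(round(pf$snc), c(87, 87, 73))
  expect_equal(round(pf$spc), c(79, 50, 71))
  expect_equal(pf$snc[2], 100 * 26 / 30)
  expect_equal(pf$spc[2], 50)
  # an oracle factor that equals the outcome scores perfectly
  sc <- am_scale()
  perfect <- scored_from(ifelse(am_cases()$outcome == "recovery", 5, -5),
                         0, 0, outcome = am_cases()$outcome)
  pfp <- per_factor_power(perfect, sc)
  expect_equal(pfp$snc[1], 100)
  expect_equal(pfp$spc[1], 100)
})

test_that("Youden threshold derivation matches the exhaustive search", {
  cases <- am_cases()
  thr <- derive_thresholds(cases, method = "youden")
  # independent oracle: exhaustive midpoint search on factor 1
  s <- cases$f1; rec <- cases$outcome == "recovery"
  u <- sort(unique(s)); mids <- (u[-1] + u[-length(u)]) / 2
  j <- sapply(mids, function(ct)
    mean(s[rec] > ct) + mean(s[!rec] <= ct) - 1)
  expect_equal(thr$cutoff[1], mids[which.max(j)])
  expect_equal(thr$youden[1], max(j))
  # frozen oracle values: midpoint of (-1.56375, -1.4526], J = 24/35
  expect_equal(thr$cutoff[1], -1.508175, tolerance = 1e-6)
  expect_equal(thr$youden[1], 27 / 30 + 11 / 14 - 1, tolerance = 1e-12)
  expect_equal(thr$recovery_side, c("above", "below", "below"))
})

test_that("threshold derivation handles trivial and degenerate inputs", {
  toy <- scored_from(c(0, 1), 0:1, 0:1, outcome = c("death", "recovery"))
  thr <- derive_thresholds(toy, "youden")
  expect_equal(thr$cutoff[1], 0.5)
  expect_equal(thr$recovery_side[1], "above")
  expect_equal(thr$youden[1], 1)
  sep <- scored_from(c(-3, -2, 2, 3), c(3, 2, -2, -3), c(3, 2, -2, -3),
                     outcome = c("death", "death", "recovery", "recovery"))
  expect_equal(derive_thresholds(sep, "youden")$youden, rep(1, 3))
  single <- scored_from(1:3, 1:3, 1:3, outcome = rep("recovery", 3))
  expect_error(derive_thresholds(single, "youden"), "both outcome")
  fx <- derive_thresholds(toy, "fixed", cutoffs = c(-1.4, 1, 0.4),
                          sides = c("above", "below", "below"))
  expect_equal(fx$cutoff, c(-1.4, 1, 0.4))
  expect_identical(attr(fx, "method"), "fixed")
})
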