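# Agreement statistics, sleep metrics, cohort tests, trends.

test_that("confusion matrix counts scored epochs and excludes artifacts", {
  h <- hypnogram
  cm <- confusion(h(c("WAKE", "N3", "ARTIFACT", "REM")),
                  h(c("WAKE", "N1N2", "WAKE", "REM")))
  expect_equal(sum(cm), 3)
  expect_equal(cm["N3", "N1N2"], 3 - sum(diag(cm)))
  expect_equal(sum(diag(cm)), 2)

  ident <- h(sample(SLEEP_STAGES, 50, replace = TRUE))
  cmi <- confusion(ident, ident)
  expect_equal(sum(cmi) - sum(diag(cmi)), 0)

  pct <- confusion_percent(cmi)
  rs <- rowSums(pct)[rowSums(cmi) > 0]
  expect_true(all(abs(rs - 100) < 1e-9))

  expect_error(confusion(h(c("WAKE")), h(c("WAKE", "N3"))), "length")
})

test_that("accuracy and kappa reproduce hand-computed values", {
  mk <- function(m) {
    cm <- matrix(0L, 4, 4, dimnames = list(expert = SLEEP_STAGES,
                                           predicted = SLEEP_STAGES))
    cm[1:nrow(m), 1:ncol(m)] <- m
    structure(cm, class = c("confusion_matrix", "matrix"))
  }
  # perfect agreement
  cm1 <- mk(diag(c(10, 20, 30, 40)))
  expect_equal(accuracy(cm1), 100)
  expect_equal(cohens_kappa(cm1), 1)
  # marginally independent: p_o = p_e = 0.5
  cm2 <- mk(rbind(c(25, 25), c(25, 25)))
  expect_equal(accuracy(cm2), 50)
  expect_equal(cohens_kappa(cm2), 0)
  # textbook case: p_o = 0.7, p_e = 0.5, kappa = 0.4
  cm3 <- mk(rbind(c(40, 10), c(20, 30)))
  expect_equal(accuracy(cm3), 70)
  expect_equal(cohens_kappa(cm3), 0.4)

  expect_error(accuracy(mk(matrix(0, 2, 2))), "empty")
})

test_that("kappa is invariant to class permutation and reconstructs p_o", {
  set.seed(2)
  cm <- matrix(rpois(16, 20), 4, 4,
               dimnames = list(expert = SLEEP_STAGES, predicted = SLEEP_STAGES))
  cm <- structure(cm, class = c("confusion_matrix", "matrix"))
  k <- cohens_kappa(cm)
  perm <- c(3, 1, 4, 2)
  cmp <- structure(cm[perm, perm], class = c("confusion_matrix", "matrix"))
  expect_equal(cohens_kappa(cmp), k)
  # p_o = kappa + p_e (1 - kappa)
  pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
  expect_equal(k + pe * (1 - k), sum(diag(cm)) / sum(cm))
})

test_that("sleep metrics reproduce hand-counted examples", {
  sm <- sleep_metrics(hypnogram(c("WAKE", "WAKE", "N1N2", "N1N2", "N3", "N3",
                                  "REM", "N1N2", "WAKE", "WAKE")))
  expect_equal(sm$tib_min, 5)
  expect_equal(sm$tst_min, 3)
  expect_equal(sm$se_pct, 60)
  expect_equal(sm$sol_min, 1)
  expect_equal(sm$pct_n1n2, 50)
  expect_equal(sm$pct_n3, 100 / 3)
  expect_equal(sm$pct_rem, 100 / 6)

  allw <- sleep_metrics(hypnogram(rep("WAKE", 20)))
  expect_equal(allw$tst_min, 0)
  expect_true(is.na(allw$sol_min))
  expect_true(is.na(allw$pct_n3))
  expect_equal(allw$se_pct, 0)

  # ARTIFACT counts toward TIB but not TST
  art <- sleep_metrics(hypnogram(c("WAKE", "ARTIFACT", "N3")))
  expect_equal(art$tib_min, 1.5)
  expect_equal(art$tst_min, 0.5)

  # PAD epochs are outside the scored window entirely
  pad <- sleep_metrics(hypnogram(c("WAKE", "N3", "PAD", "PAD")))
  expect_equal(pad$tib_min, 1)
})

test_that("paired t-test matches the closed-form computation and flags degeneracy", {
  before <- c(60, 70, 65, 75)
  after <- c(66, 74, 72, 80)
  r <- paired_metric_test(before, after)
  # closed-form oracle
  d <- after - before
  t_hand <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_hand <- 2 * stats::pt(-abs(t_hand), length(d) - 1)
  expect_equal(r$t, t_hand)
  expect_equal(r$p, p_hand)
  expect_false(r$degenerate)

  same <- paired_metric_test(before, before)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  shift <- paired_metric_test(c(60, 65, 70), c(70, 75, 80))
  expect_true(shift$degenerate)
  expect_equal(shift$mean_diff, 10)
})

test_that("variance-consistency test detects reduced spread, ignores shifts", {
  acc_a <- c(60, 70, 80, 90)        # spread +-15, mean 75
  acc_b <- c(73, 74, 76, 77)        # spread +-2, same-ish mean
  r <- variance_consistency_test(acc_a, acc_b)
  expect_lt(r$t, 0)                  # spread decreased
  expect_false(r$degenerate)

  same <- variance_consistency_test(acc_a, acc_a)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  shifted <- variance_consistency_test(acc_a, acc_b + 7)
  expect_equal(r$t, shifted$t)       # mean-centering invariance
  expect_equal(r$p, shifted$p)
})

test_that("trend tables: identity predictions, SEM bookkeeping, label screening", {
  hp <- hypnogram_params()
  records <- list()
  for (p in 1:3) {
    for (lb in c("B1", "I1", "I2")) {
      h <- generate_hypnogram(hp, 6, seed = derive_seed(900, p, match(lb, c("B1", "I1", "I2"))))
      records[[length(records) + 1L]] <- list(
        participant_id = sprintf("P%02d", p), night_label = lb,
        truth = h, prediction = h)
    }
  }
  tr <- longitudinal_trends(records)
  for (src_metric in unique(tr$metric)) {
    sub <- tr[tr$metric == src_metric, ]
    ex <- sub[sub$source == "expert", c("night_label", "mean", "sem")]
    mo <- sub[sub$source == "model", c("night_label", "mean", "sem")]
    expect_equal(ex, mo, ignore_attr = TRUE)
  }
  expect_true(all(tr$n == 3))

  single <- longitudinal_trends(records[1])
  expect_true(all(is.na(single$sem)))
  expect_true(all(single$n == 1))

  expect_message(
    skipped <- longitudinal_trends(c(records[1], list(list(
      participant_id = "P09", night_label = "X9",
      truth = hypnogram(rep("N3", 10)), prediction = NULL)))),
    "unrecognized")
  expect_false("X9" %in% skipped$night_label)
})

test_that("three-class relabeling merges the non-REM stages only", {
  expect_equal(collapse_stages(c("WAKE", "N1N2", "N3", "REM", "ARTIFACT")),
               c("WAKE", "NREM", "NREM", "REM", "ARTIFACT"))
})
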