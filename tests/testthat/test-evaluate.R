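test_that("score combination is exactly linear in alpha", {
  expect_equal(pcsd_score(2.0, 0.25, 0.8), 1.65)
  expect_equal(pcsd_score(2.0, 0.25, 0), 0.25)   # density only
  expect_equal(pcsd_score(2.0, 0.25, 1), 2.0)    # participation only
  expect_error(pcsd_score(1, 1, -0.1), "alpha")
  expect_error(pcsd_score(1, 1, 1.5), "alpha")
})

test_that("ranking is descending with a deterministic identifier tie-break", {
  expect_equal(rank_proteins(c(A = 2, B = 3, C = 1)), c("B", "A", "C"))
  expect_equal(rank_proteins(c(C = 1, A = 1, B = 1)), c("A", "B", "C"))
  s <- c(D = 0.5, A = 0.9, C = 0.5, B = 0.9)
  expect_equal(rank_proteins(s), rank_proteins(s[sample(4)]))
  expect_error(rank_proteins(c(1, 2, 3)), "identifier")
})

test_that("top-percent counts and the jackknife curve are consistent", {
  ranking <- c("e1", "x1", "e2", "x2", "e3", "x3", "x4", "e4", "x5", "x6")
  ess <- c("e1", "e2", "e3", "e4")
  expect_equal(jackknife_curve(ranking, ess),
               c(1, 1, 2, 2, 3, 3, 3, 4, 4, 4))
  expect_equal(count_true_essentials(ranking, ess, 100), 4L)
  expect_equal(jackknife_curve(ranking, character(0)), rep(0, 10))
  # identity: count at p equals the jackknife at the rounded cutoff
  jk <- jackknife_curve(ranking, ess)
  for (p in c(7, 10, 25, 33, 50, 99, 100)) {
    k <- round(length(ranking) * p / 100)
    expect_equal(count_true_essentials(ranking, ess, p),
                 if (k == 0) 0L else jk[[k]])
  }
  # rounding conventions
  expect_equal(count_true_essentials(ranking, ess, 25, "floor"),
               sum(ranking[1:2] %in% ess))
  expect_equal(count_true_essentials(ranking, ess, 26, "ceil"),
               sum(ranking[1:3] %in% ess))
})

test_that("precision-recall follows TP/k and TP/total", {
  expect_equal(pr_curve(c("e", "x"), "e"),
               data.frame(k = 1:2, recall = c(1, 1), precision = c(1, 0.5)))
  perfect <- pr_curve(c("e1", "e2", "x1", "x2"), c("e1", "e2"))
  expect_true(all(perfect$precision[perfect$recall < 1] == 1))
  expect_error(pr_curve(c("x1", "x2"), "e"), "undefined")
  # precision at k is the jackknife value over k
  ranking <- c("e1", "x1", "e2", "x2", "e3")
  ess <- c("e1", "e2", "e3")
  pr <- pr_curve(ranking, ess)
  expect_equal(pr$precision, jackknife_curve(ranking, ess) / (1:5))
})

test_that("ROC/AUC matches the Mann-Whitney pairwise probability", {
  sep <- c(a = 3, b = 2, x = 1, y = 0.5)
  expect_equal(roc_auc(sep, c("a", "b"))$auc, 1)
  flat <- c(a = 1, b = 1, x = 1, y = 1)
  expect_equal(roc_auc(flat, c("a", "b"))$auc, 0.5)
  expect_error(roc_auc(c(a = 1, b = 2), c("a", "b")), "non-essential")

  set.seed(99)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    # duplicated values force the tie convention to matter
    score <- setNames(sample(seq(0, 1, by = 0.1), n, replace = TRUE),
                      paste0("P", seq_len(n)))
    ess <- paste0("P", sample(n, sample(2:(n - 2), 1)))
    got <- roc_auc(score, ess)
    expect_equal(got$auc, oracle_auc(score, ess), tolerance = 1e-9)
    expect_true(all(got$curve$fpr >= 0 & got$curve$fpr <= 1))
    expect_true(all(diff(got$curve$tpr) >= 0))
    expect_equal(got$curve$tpr[1], 0)
    expect_equal(got$curve$tpr[nrow(got$curve)], 1)
  }
})

test_that("the evaluation bundle ties all protocol pieces together", {
  fx <- simulate_ppi_data(n_proteins = 40, seed = 12)
  fit <- suppressMessages(
    pcsd(fx$network, fx$expression, fx$complexes, fx$annotations))
  ev <- evaluate_essentials(fit, fx$essentials)
  expect_s3_class(ev, "pcsd_eval")
  expect_equal(ev$n, 40L)
  expect_true(all(diff(ev$jackknife) %in% c(0L, 1L)))
  expect_equal(ev$jackknife[ev$n], ev$n_essential)
  expect_equal(unname(ev$topk[["top25%"]]),
               ev$jackknife[[round(40 * 25 / 100)]])
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  expect_error(evaluate_essentials(fit, "NOT-A-PROTEIN"), "no gold-standard")
  expect_output(print(ev), "ROC AUC")
})

test_that("the alpha sweep reproduces single evaluations and shifts toward PC", {
  fx <- simulate_ppi_data(n_proteins = 40, seed = 22)
  fit <- suppressMessages(
    pcsd(fx$network, fx$expression, fx$complexes, fx$annotations))
  sweep <- alpha_sweep(fit, fx$essentials, alphas = c(0, 0.8, 1))
  ev <- evaluate_essentials(fit, fx$essentials)
  expect_equal(unlist(sweep[sweep$alpha == 0.8, -1], use.names = FALSE),
               unname(ev$topk))

  # as alpha rises the ranking moves monotonically toward the PC order
  pc_rank <- rank_proteins(setNames(fit$scores$pc, fit$scores$id))
  tau <- vapply(seq(0, 1, by = 0.25), function(a) {
    r <- rank_proteins(pcsd_score(fit$scores$pc, fit$scores$sd, a),
                       fit$scores$id)
    stats::cor(match(fit$scores$id, r), match(fit$scores$id, pc_rank),
               method = "kendall")
  }, numeric(1))
  expect_true(all(diff(tau) >= -1e-12))
})
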