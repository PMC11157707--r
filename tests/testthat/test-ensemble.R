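test_that("AUROC matches the pROC reference on random score sets", {
  skip_if_not_installed("pROC")
  set.seed(101)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.5); y[1] <- 1; y[2] <- 0
    s <- rnorm(40) + y
    expect_equal(aurocScore(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  }
  expect_error(aurocScore(1:3, c(1, 1, 1)), "both classes")
})

test_that("Youden threshold agrees with an exhaustive-search oracle", {
  ## well-separated toy set: midpoint rule gives 0.5 at J = 1
  th <- youdenThreshold(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(as.numeric(th), 0.5)
  expect_equal(attr(th, "youden"), 1)
  ## degenerate: all scores equal -> J = 0
  expect_equal(attr(youdenThreshold(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)),
                    "youden"), 0)
  ## randomized 10-sample sets vs brute force over all candidate cuts
  set.seed(7)
  for (i in 1:20) {
    y <- c(1, 0, rbinom(8, 1, 0.5))
    s <- round(runif(10), 2)
    th <- youdenThreshold(s, y)
    jAt <- function(t) mean(s[y == 1] > t) + mean(s[y == 0] <= t) - 1
    grid <- sort(unique(c(s - 1e-6, s + 1e-6, 0, 1)))
    expect_equal(attr(th, "youden"), max(vapply(grid, jAt, numeric(1))),
                 tolerance = 1e-9)
    expect_equal(jAt(as.numeric(th)), attr(th, "youden"))
  }
})

test_that("rank importance ledger reproduces hand-computed weighted scores", {
  ## two models, weights 2 and 1; A ranks 1st then 26th, B 2nd then 1st
  vars <- paste0("v", 1:30)
  imp1 <- stats::setNames(c(30, 29, 28:1), vars)   # v1 ranks 1st, v2 2nd
  r2 <- c(26, 1, 2:25, 27:30)                      # v1 ranks 26th, v2 1st
  imp2 <- stats::setNames(31 - r2, vars)
  led <- rankImportanceLedger(list(imp1, imp2), weights = c(2, 1))
  a <- led$score[led$feature == "v1"]
  b <- led$score[led$feature == "v2"]
  expect_equal(a, (2 * 25 + 1 * 1) / 3)       # = 17
  expect_equal(b, (2 * 24 + 1 * 25) / 3)      # = 73/3
  expect_equal(led$relative[led$feature == "v1"], 17 / (73 / 3))
  ## exactly one variable attains relative importance 1
  expect_equal(sum(led$relative == 1), 1L)
  ## single model: its top variable is 1.0
  led1 <- rankImportanceLedger(list(imp1), weights = 5)
  expect_equal(led1$relative[led1$feature == "v1"], 1)
  ## a variable beyond rank 25 everywhere gets the floor score 1
  expect_equal(min(led$score), 1)
  expect_equal(min(led1$relative), 1 / 25)
})

test_that("differential profiling matches the exact rank-sum distribution", {
  ## identical groups -> p ~ 1
  x <- matrix(rep(c(1, 2, 3, 4), 2), ncol = 1)
  expect_gt(differentialProfile(x, rep(c(1, 0), each = 4))$p_value, 0.9)
  ## 4 vs 4: enumeration oracle over all C(8,4) rank assignments
  set.seed(33)
  v <- rnorm(8)
  y <- rep(c(1, 0), each = 4)
  p <- differentialProfile(matrix(v, ncol = 1), y)$p_value
  W <- sum(rank(v)[y == 1]) - 4 * 5 / 2
  combs <- utils::combn(8, 4)
  Wall <- apply(combs, 2, function(idx) sum(rank(v)[idx]) - 10)
  pOracle <- mean(abs(Wall - 8) >= abs(W - 8))
  expect_equal(p, pOracle)
  ## strongly shifted groups at n = 20/20
  set.seed(34)
  xm <- cbind(shift = c(rnorm(20, 3), rnorm(20)), null = rnorm(40))
  dp <- differentialProfile(xm, rep(c(1, 0), each = 20))
  expect_lt(dp$p_value[1], 1e-4)
  expect_gt(dp$p_value[2], 0.05)
  expect_error(differentialProfile(xm, rep(c(1, 0), c(2, 38))), "at least 3")
})

test_that("the base layer returns exactly 20 models and rejects bad input", {
  pf <- plantedFeatures(n = 40L, seed = 2L)
  base <- trainBaseLayer(pf$features, pf$labels, nSearch = 2L, seed = 5L)
  expect_length(base$selected, 20L)
  expect_equal(ncol(base$oof), 20L)
  expect_equal(as.integer(table(vapply(base$selected, `[[`, character(1),
                                       "type"))), rep(5L, 4L))
  expect_true(all(base$oof >= 0 & base$oof <= 1))
  expect_error(trainBaseLayer(pf$features, rep(1, 40), nSearch = 2L),
               "both classes")
  ## determinism
  base2 <- trainBaseLayer(pf$features, pf$labels, nSearch = 2L, seed = 5L)
  expect_equal(base$oof, base2$oof)
  expect_equal(vapply(base$selected, `[[`, numeric(1), "cvAuroc"),
               vapply(base2$selected, `[[`, numeric(1), "cvAuroc"))
})

test_that("the stack layer keeps 5 models and exploits an informative column", {
  set.seed(9)
  y <- rep(c(1, 0), each = 30)
  folds <- rep_len(1:5, 60)
  ## one perfectly informative base column among noise
  oof <- matrix(runif(60 * 20), 60, 20)
  oof[, 7] <- y * 0.8 + 0.1
  colnames(oof) <- paste0("b", 1:20)
  st <- trainStackLayer(oof, y, folds, nSearch = 3L, seed = 4L)
  expect_length(st$selected, 5L)
  expect_true(all(vapply(st$selected, `[[`, numeric(1), "cvAuroc") >= 0.99))
  ## all-noise columns: stacked CV AUROC ~ 0.5
  noise <- matrix(runif(60 * 20), 60, 20)
  colnames(noise) <- paste0("b", 1:20)
  stN <- trainStackLayer(noise, y, folds, nSearch = 3L, seed = 4L)
  expect_lt(mean(vapply(stN$selected, `[[`, numeric(1), "cvAuroc")), 0.72)
  expect_error(trainStackLayer(oof[, 1:7], y, folds), "20 base model")
})

test_that("ensemble prediction averages the five stacked outputs", {
  pf <- plantedFeatures(n = 40L, seed = 3L)
  m <- trainEnsemble(pf$features, pf$labels, nSearch = 2L, nSearchStack = 2L,
                     seed = 6L)
  expect_s4_class(m, "CfdnaEnsemble")
  p <- predictEnsemble(m, pf$features)
  baseScores <- vapply(m@baseModels, function(b)
    cfgastro:::.predictModel(b$fit, pf$features[[b$type]]), numeric(40L))
  colnames(baseScores) <- colnames(m@oof)
  stackPred <- vapply(m@stackModels, function(s)
    cfgastro:::.predictModel(s$fit, baseScores), numeric(40L))
  expect_equal(p, rowMeans(stackPred))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predictEnsemble(m, pf$features[c("FSP", "CNV")]),
               "missing feature block")
  ## separable synthetic features: near-perfect cross-validated AUROC
  expect_gt(m@cvAuroc, 0.95)
})

test_that("label permutation keeps base-model mean CV AUROC near chance", {
  pf <- plantedFeatures(n = 60L, seed = 8L)
  set.seed(99)
  yPerm <- sample(pf$labels)
  base <- trainBaseLayer(pf$features, yPerm, nSearch = 2L, seed = 10L)
  expect_gt(mean(vapply(base$selected, `[[`, numeric(1), "cvAuroc")), 0.35)
  expect_lt(mean(vapply(base$selected, `[[`, numeric(1), "cvAuroc")), 0.65)
})

test_that("planted variables surface at the top of the importance ledger", {
  pf <- plantedFeatures(n = 50L, seed = 12L)
  m <- trainEnsemble(pf$features, pf$labels, nSearch = 2L, nSearchStack = 2L,
                     seed = 13L)
  led <- rankImportance(m)
  hits <- 0L
  for (type in names(pf$plantedPerType)) {
    planted <- pf$plantedPerType[[type]]
    sub <- led[led$type == type, ]
    topk <- sub$feature[seq_along(planted)]
    hits <- hits + sum(planted %in% topk)
  }
  expect_gte(hits, 4L)
  ## ledger invariants: relative in (0, 1], one max per type
  expect_true(all(led$relative > 0 & led$relative <= 1))
  expect_equal(as.numeric(tapply(led$relative, led$type, max)), rep(1, 4))
})
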