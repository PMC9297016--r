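test_that("the adult filter is inclusive at the threshold", {
  tab <- makeFakeTable(seed = 1)
  tab$age_months <- rep_len(c(12, 24, 36), nrow(tab))
  kept <- filterAdults(tab)
  expect_setequal(unique(kept$age_months), c(24, 36))
  expect_identical(filterAdults(tab, 0), tab)
  expect_warning(filterAdults(tab, 999), "no rows")
})

test_that("the individual-dataset filter drops small bouts then sparse callers", {
  mk <- function(caller, bouts) {
    do.call(rbind, lapply(seq_along(bouts), function(b)
      data.frame(whoop_id = sprintf("%s_b%d_w%d", caller, b,
                                    seq_len(bouts[b])),
                 bout_id = sprintf("%s_b%d", caller, b),
                 caller_id = caller, stringsAsFactors = FALSE)))
  }
  # caller A: bouts {3,2,5} -> bout of 2 dropped, caller kept with 2 bouts
  # caller B: bouts {3,2}   -> only 1 qualifying bout, caller dropped
  tab <- rbind(mk("A", c(3, 2, 5)), mk("B", c(3, 2)), mk("C", c(4, 4)))
  out <- prepareIndividualDataset(tab)
  expect_setequal(unique(out$caller_id), c("A", "C"))
  expect_equal(sum(out$caller_id == "A"), 8)
  # hand-computed oracle on a 5-caller fixture
  tab5 <- rbind(mk("A", c(3, 3)), mk("B", c(2, 2, 2)), mk("C", c(5, 1)),
                mk("D", c(3, 3, 3)), mk("E", c(4, 2, 3)))
  out5 <- prepareIndividualDataset(tab5)
  # survivors: A (3+3), D (3+3+3), E (4+3); B all bouts < 3; C one bout
  expect_setequal(unique(out5$caller_id), c("A", "D", "E"))
  expect_equal(nrow(out5), 6 + 9 + 7)
  expect_error(prepareIndividualDataset(mk("A", c(3, 3))), "fewer than 2")
})

test_that("type subsetting filters rows as tallied", {
  tab <- makeFakeTable(seed = 2)
  expect_identical(subsetTypes(tab, c("A", "S", "P", "T")), tab)
  expect_error(subsetTypes(tab, character(0)), "at least one")
  out <- subsetTypes(tab, "A")
  expect_equal(nrow(out), sum(tab$whoop_type == "A"))
})

test_that("the clan split holds out exactly one caller per clan", {
  tab <- makeFakeTable(n_clans = 4, callers_per_clan = 3, seed = 3)
  for (s in 1:25) {
    set.seed(s)
    sp <- clanSplit(tab)
    held <- unique(sp$test[c("caller_id", "clan_id")])
    expect_equal(nrow(held), 4L)
    expect_equal(length(unique(held$clan_id)), 4L)
    expect_length(intersect(unique(sp$train$caller_id),
                            unique(sp$test$caller_id)), 0)
    # all of a held-out caller's whoops are in the test set
    expect_equal(nrow(sp$test),
                 sum(tab$caller_id %in% held$caller_id))
  }
  one <- makeFakeTable(n_clans = 1, callers_per_clan = 1, seed = 3)
  expect_error(clanSplit(one), "single caller")
})

test_that("held-out callers are selected uniformly", {
  tab <- makeFakeTable(n_clans = 1, callers_per_clan = 3, seed = 4)
  picks <- character(1000)
  for (s in seq_len(1000)) {
    set.seed(s)
    picks[s] <- unique(clanSplit(tab)$test$caller_id)
  }
  freq <- table(picks) / 1000
  se <- sqrt((1 / 3) * (2 / 3) / 1000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})

test_that("the bout split holds out one bout per caller", {
  tab <- makeFakeTable(n_clans = 1, callers_per_clan = 13, n_bouts = 3,
                       seed = 5)
  set.seed(1)
  sp <- boutSplit(tab)
  expect_equal(length(unique(sp$test$bout_id)), 13L)
  expect_equal(length(unique(sp$test$caller_id)), 13L)
  expect_length(intersect(unique(sp$train$bout_id),
                          unique(sp$test$bout_id)), 0)
  expect_setequal(unique(sp$train$caller_id), unique(sp$test$caller_id))
  # uniformity of the held-out bout for one caller
  picks <- character(600)
  for (s in seq_len(600)) {
    set.seed(s)
    te <- boutSplit(tab)$test
    picks[s] <- unique(te$bout_id[te$caller_id == "i01"])[1]
  }
  freq <- table(picks) / 600
  se <- sqrt((1 / 3) * (2 / 3) / 600)
  expect_true(all(abs(freq - 1 / 3) < 3.5 * se))
  single <- makeFakeTable(n_bouts = 1, seed = 5)
  expect_error(boutSplit(single), "single bout")
})

test_that("forests separate disjoint classes and normalize votes", {
  tab <- makeFakeTable(n_clans = 2, callers_per_clan = 1, n_bouts = 4,
                       whoops_per_bout = 6, effect = 0, bout_effect = 0,
                       seed = 6)
  # two perfectly separated classes on f1
  tab$f1 <- ifelse(tab$caller_id == "i01", rnorm(nrow(tab), -5),
                   rnorm(nrow(tab), 5))
  set.seed(2)
  m <- trainForest(tab, splitSpec(n_trees = 100), "caller_id",
                   features = fakeFeatures())
  v <- voteFractions(m, tab)
  expect_equal(unname(rowSums(v)), rep(1, nrow(tab)))
  tv <- v[cbind(seq_len(nrow(tab)), match(tab$caller_id, colnames(v)))]
  expect_gte(mean(tv), 0.95)
  expect_true(all(tv >= 0.75))
  one <- tab[tab$caller_id == "i01", ]
  expect_error(trainForest(one, splitSpec(), "caller_id",
                           features = fakeFeatures()), "single-class")
})

test_that("weighted expectation follows its closed forms", {
  expect_equal(weightedExpectation(rep(letters[1:4], 25),
                                   rep(letters[1:4], 10)), 0.25)
  expect_equal(weightedExpectation(c(rep("a", 4), rep("b", 6)),
                                   rep("a", 7)), 0.4)
  expect_equal(weightedExpectation(c(rep("a", 9), "b"),
                                   c(rep("a", 9), "b")), 0.82)
  expect_equal(weightedExpectation(letters[1:3], letters[1:3],
                                   mode = "uniform"), 1 / 3)
  expect_error(weightedExpectation(character(0), "a"), "empty")
  expect_error(weightedExpectation(c("a", "b"), c("a", "c")),
               "not all present")
})

test_that("weighted expectation matches a Monte-Carlo guesser", {
  set.seed(31)
  for (case in 1:6) {
    K <- sample(2:8, 1)
    ftr <- as.numeric(rmultinom(1, 200, runif(K) + 0.1)) / 200
    fte <- as.numeric(rmultinom(1, 60, runif(K) + 0.1)) / 60
    train <- rep(letters[1:K], round(ftr * 200))
    test <- rep(letters[1:K], round(fte * 60))
    we <- weightedExpectation(train, test)
    n <- 2e5
    guess <- sample(train, n, replace = TRUE)
    truth <- sample(test, n, replace = TRUE)
    mc <- mean(guess == truth)
    expect_lt(abs(we - mc), 3 * sqrt(we * (1 - we) / n))
  }
})

test_that("repeated CV is deterministic and summarizes correctly", {
  tab <- makeFakeTable(n_clans = 2, callers_per_clan = 3, effect = 2,
                       seed = 7)
  spec <- splitSpec("individual", n_repeats = 4, n_trees = 60, seed = 12)
  a <- runRepeats(tab, spec, features = fakeFeatures())
  b <- runRepeats(tab, spec, features = fakeFeatures())
  expect_identical(cvRepeats(a), cvRepeats(b))
  expect_identical(pooledConfusion(a), pooledConfusion(b))
  expect_equal(meanAccuracy(a), mean(cvRepeats(a)$accuracy))
  # pooled confusion row sums equal total tested whoops per true class
  expect_equal(sum(pooledConfusion(a)), sum(cvRepeats(a)$n_test))
  one <- runRepeats(tab, splitSpec("individual", n_repeats = 1,
                                   n_trees = 60, seed = 3),
                    features = fakeFeatures())
  expect_true(is.na(sdAccuracy(one)))
  expect_equal(meanAccuracy(one), cvRepeats(one)$accuracy[1])
})

test_that("CV results are invariant to row and feature-column order", {
  tab <- makeFakeTable(n_clans = 2, callers_per_clan = 3, effect = 2,
                       seed = 8)
  spec <- splitSpec("individual", n_repeats = 3, n_trees = 60, seed = 5)
  base <- runRepeats(tab, spec, features = fakeFeatures())
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(cvRepeats(runRepeats(shuf, spec,
                                    features = fakeFeatures())),
               cvRepeats(base))
  expect_equal(cvRepeats(runRepeats(tab, spec,
                                    features = rev(fakeFeatures()))),
               cvRepeats(base))
})

test_that("an informative world beats chance; a permuted one does not", {
  tab <- makeFakeTable(n_clans = 2, callers_per_clan = 4, n_bouts = 4,
                       whoops_per_bout = 5, effect = 2.5,
                       bout_effect = 0.3, seed = 9)
  spec <- splitSpec("individual", n_repeats = 25, n_trees = 120, seed = 2)
  cv <- runRepeats(tab, spec, features = fakeFeatures())
  expect_gt(meanAccuracy(cv), meanWE(cv) + 2 * sdAccuracy(cv))
  # type-I null: a fresh label permutation per repeat
  cvp <- runRepeats(tab, splitSpec("individual", n_repeats = 40,
                                   n_trees = 120, seed = 13),
                    features = fakeFeatures(), permute_labels = TRUE)
  se <- sdAccuracy(cvp) / sqrt(nrow(cvRepeats(cvp)))
  expect_lt(abs(meanAccuracy(cvp) - meanWE(cvp)), 3 * se)
  # a single permuted table keeps the grouped design intact:
  # one caller per bout, and every caller keeps its bout count
  perm <- permuteLabels(tab, "individual", seed = 3)
  expect_true(all(tapply(perm$caller_id, perm$bout_id,
                         function(v) length(unique(v))) == 1))
  bouts_per <- function(d) sort(unname(tapply(d$bout_id, d$caller_id,
                                              function(v)
                                                length(unique(v)))))
  expect_equal(bouts_per(perm), bouts_per(tab))
})

test_that("importance flags informative features and ignores noise", {
  tab <- makeFakeTable(n_clans = 2, callers_per_clan = 4, n_bouts = 3,
                       whoops_per_bout = 5, effect = 0, bout_effect = 0,
                       seed = 10)
  # only f1 carries identity; f6 is an appended pure-noise decoy
  mu <- setNames(rnorm(length(unique(tab$caller_id)), sd = 3),
                 unique(tab$caller_id))
  tab$f1 <- mu[tab$caller_id] + rnorm(nrow(tab))
  tab$f6 <- runif(nrow(tab))
  imp <- featureImportance(tab, splitSpec("individual", n_repeats = 12,
                                          n_trees = 120, seed = 4),
                           features = c(fakeFeatures(), "f6"))
  expect_equal(nrow(imp), 6L)
  expect_identical(imp$feature[1], "f1")
  dec <- imp[imp$feature == "f6", ]
  expect_lte(abs(dec$importance), max(2 * dec$se, 1e-8))
})
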