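## Signature testing: leakage-proof random-forest cross-validation with a
## composition-weighted chance expectation.

#' Cross-validation specification
#'
#' @param scheme \code{"clan"} (hold out one caller per clan, so clan
#'   accuracy cannot come from recognizing individuals) or
#'   \code{"individual"} (hold out one bout per caller, so individual
#'   accuracy cannot come from bout-level autocorrelation).
#' @param n_repeats number of repeated splits (default 1000).
#' @param n_trees trees per forest (default 500).
#' @param seed integer seed; each repeat derives its own stream.
#' @return a \code{SplitSpec} (named list, classed).
#' @export
splitSpec <- function(scheme = c("individual", "clan"), n_repeats = 1000,
                      n_trees = 500, seed = 1L) {
  scheme <- match.arg(scheme)
  if (n_repeats < 1 || n_trees < 1)
    stop("splitSpec: n_repeats and n_trees must be >= 1")
  structure(list(scheme = scheme, n_repeats = as.integer(n_repeats),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "SplitSpec")
}

#' Keep only adult callers
#'
#' @param table a FeatureTable.
#' @param min_age_months inclusive age threshold (default 24).
#' @return the filtered table (warns when empty).
#' @export
filterAdults <- function(table, min_age_months = 24) {
  out <- table[table$age_months >= min_age_months, , drop = FALSE]
  if (!nrow(out)) warning("filterAdults: no rows at or above ",
                          min_age_months, " months")
  out
}

#' Reduce to callers suitable for the individual-signature test
#'
#' Keeps bouts with at least \code{min_whoops_per_bout} whoops, then
#' callers with at least \code{min_bouts} surviving bouts.
#'
#' @param table a FeatureTable.
#' @param min_bouts minimum qualifying bouts per caller (default 2).
#' @param min_whoops_per_bout minimum whoops per bout (default 3).
#' @return the filtered table; errors if fewer than 2 callers survive.
#' @export
prepareIndividualDataset <- function(table, min_bouts = 2,
                                     min_whoops_per_bout = 3) {
  bout_sizes <- table(table$bout_id)
  keep_bouts <- names(bout_sizes)[bout_sizes >= min_whoops_per_bout]
  out <- table[table$bout_id %in% keep_bouts, , drop = FALSE]
  bouts_per_caller <- tapply(out$bout_id, out$caller_id,
                             function(v) length(unique(v)))
  keep_callers <- names(bouts_per_caller)[bouts_per_caller >= min_bouts]
  out <- out[out$caller_id %in% keep_callers, , drop = FALSE]
  if (length(unique(out$caller_id)) < 2L)
    stop("prepareIndividualDataset: fewer than 2 surviving callers; ",
         "classification undefined")
  out
}

#' Restrict to a set of whoop types
#'
#' @param table a FeatureTable.
#' @param keep character vector of types to keep (default A and S).
#' @return the filtered table.
#' @export
subsetTypes <- function(table, keep = c("A", "S")) {
  if (!length(keep)) stop("subsetTypes: keep must name at least one type")
  table[table$whoop_type %in% keep, , drop = FALSE]
}

#' Clan-scheme split: hold out one caller per clan
#'
#' The test set is all whoops of one randomly selected caller from each
#' clan; no caller appears in both sets, so clan accuracy can only come
#' from features that generalize across clan members.
#'
#' @param table a FeatureTable.
#' @return list \code{train}, \code{test}.
#' @export
clanSplit <- function(table) {
  u <- unique(table[c("caller_id", "clan_id")])
  u <- u[order(u$clan_id, u$caller_id), ]
  held <- vapply(split(u, u$clan_id), function(d) {
    if (nrow(d) < 2L)
      stop("clanSplit: clan ", d$clan_id[1], " has a single caller")
    d$caller_id[sample.int(nrow(d), 1L)]
  }, character(1))
  test <- table$caller_id %in% held
  split_guard(table[!test, , drop = FALSE], table[test, , drop = FALSE],
              "caller_id")
}

#' Individual-scheme split: hold out one bout per caller
#'
#' The test set is one randomly selected bout from each caller; no bout
#' spans both sets, so individual accuracy cannot come from within-bout
#' autocorrelation.
#'
#' @param table a FeatureTable (pass through
#'   \code{\link{prepareIndividualDataset}} first).
#' @return list \code{train}, \code{test}.
#' @export
boutSplit <- function(table) {
  u <- unique(table[c("bout_id", "caller_id")])
  u <- u[order(u$caller_id, u$bout_id), ]
  held <- vapply(split(u, u$caller_id), function(d) {
    if (nrow(d) < 2L)
      stop("boutSplit: caller ", d$caller_id[1],
           " has a single bout (filter first)")
    d$bout_id[sample.int(nrow(d), 1L)]
  }, character(1))
  test <- table$bout_id %in% held
  split_guard(table[!test, , drop = FALSE], table[test, , drop = FALSE],
              "bout_id")
}

## hard leakage guard: the grouping unit must not span train and test.
## Rows are put in canonical (whoop_id) order so results are invariant to
## the input row order under a fixed seed.
split_guard <- function(train, test, unit) {
  if (length(intersect(unique(train[[unit]]), unique(test[[unit]]))))
    stop("leakage guard violated: ", unit, " present in both sets")
  if (!is.null(train$whoop_id)) {
    train <- train[order(train$whoop_id), , drop = FALSE]
    test <- test[order(test$whoop_id), , drop = FALSE]
  }
  list(train = train, test = test)
}

#' Train a random forest on a feature table
#'
#' An ensemble of \code{n_trees} CART trees over the sixteen acoustic
#' features (standard random-forest contract: bootstrap resampling and
#' feature subsampling at each split), with the maximum number of terminal
#' nodes set to the training-set size. Exposes majority-vote predictions
#' and per-class tree-vote fractions.
#'
#' @param train training FeatureTable.
#' @param spec a \code{\link{splitSpec}} (uses \code{n_trees}).
#' @param target label column, \code{"clan_id"} or \code{"caller_id"}.
#' @param features feature columns (default the 16 acoustic features).
#' @return a \code{WhoopForest}: list with the fitted
#'   \code{randomForest}, \code{classes}, \code{target}, \code{features}.
#' @export
trainForest <- function(train, spec = splitSpec(), target = "caller_id",
                        features = whoopFeatureNames()) {
  y <- factor(train[[target]])
  if (nlevels(y) < 2L) stop("trainForest: single-class training set")
  features <- sort(features)   # canonical order: column-order invariance
  X <- train[, features, drop = FALSE]
  if (all(vapply(X, function(col) length(unique(col)) == 1L, logical(1))))
    stop("trainForest: all features are constant; nothing to split on")
  fit <- randomForest::randomForest(
    x = X, y = y, ntree = spec$n_trees, maxnodes = nrow(X))
  structure(list(forest = fit, classes = levels(y), target = target,
                 features = features), class = "WhoopForest")
}

#' Per-class tree-vote fractions
#'
#' @param model a \code{WhoopForest} from \code{\link{trainForest}}.
#' @param newdata FeatureTable rows to score.
#' @return matrix (rows x classes) of vote fractions; each row sums to 1.
#' @export
voteFractions <- function(model, newdata) {
  v <- predict(model$forest, newdata[, model$features, drop = FALSE],
               type = "vote", norm.votes = TRUE)
  rownames(v) <- NULL
  v
}

#' Majority-vote class predictions
#'
#' @inheritParams voteFractions
#' @return factor of predicted classes.
#' @export
predictClass <- function(model, newdata) {
  predict(model$forest, newdata[, model$features, drop = FALSE],
          type = "response")
}

#' Weighted expectation: composition-weighted chance accuracy
#'
#' The expected proportion correct of a guesser that draws labels from the
#' training-class distribution, evaluated on the test composition:
#' \code{sum_c f_train(c) * f_test(c)}. \code{mode = "uniform"} gives the
#' plain 1/K alternative.
#'
#' @param train_labels training labels.
#' @param test_labels test labels (classes must appear in training).
#' @param mode \code{"weighted"} (default) or \code{"uniform"}.
#' @return chance-level accuracy in [0, 1].
#' @export
weightedExpectation <- function(train_labels, test_labels,
                                mode = c("weighted", "uniform")) {
  mode <- match.arg(mode)
  if (!length(train_labels) || !length(test_labels))
    stop("weightedExpectation: empty label set")
  if (length(setdiff(unique(test_labels), unique(train_labels))))
    stop("weightedExpectation: test classes not all present in training")
  if (mode == "uniform") return(1 / length(unique(train_labels)))
  ftr <- table(train_labels) / length(train_labels)
  fte <- table(factor(test_labels, levels = names(ftr))) /
    length(test_labels)
  sum(as.numeric(ftr) * as.numeric(fte))
}

#' Permute identity labels at the design's grouping unit
#'
#' Breaks the link between acoustic features and identity while keeping
#' the grouped cross-validation design intact, for type-I-error checks of
#' the whole harness. For the individual scheme, caller identities are
#' permuted among bouts (every bout keeps one caller; every caller keeps
#' its bout count; clan follows the caller). For the clan scheme, clan
#' labels are permuted among callers.
#'
#' @param table a FeatureTable.
#' @param scheme \code{"individual"} (permute callers among bouts) or
#'   \code{"clan"} (permute clans among callers).
#' @param seed integer seed.
#' @return the permuted table.
#' @export
permuteLabels <- function(table, scheme = c("individual", "clan"),
                          seed = 1L) {
  scheme <- match.arg(scheme)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(deriveSeed(seed, 99L))
  if (scheme == "individual") {
    u <- unique(table[c("bout_id", "caller_id", "clan_id")])
    u <- u[order(u$bout_id), ]
    perm <- sample.int(nrow(u))
    new_caller <- setNames(u$caller_id[perm], u$bout_id)
    new_clan <- setNames(u$clan_id[perm], u$bout_id)
    table$caller_id <- unname(new_caller[table$bout_id])
    table$clan_id <- unname(new_clan[table$bout_id])
  } else {
    u <- unique(table[c("caller_id", "clan_id")])
    u <- u[order(u$caller_id), ]
    new_clan <- setNames(u$clan_id[sample.int(nrow(u))], u$caller_id)
    table$clan_id <- unname(new_clan[table$caller_id])
  }
  table
}

dropUnusableRows <- function(table, features) {
  usable <- !table$failed &
    complete.cases(table[, features, drop = FALSE])
  n_bad <- sum(!usable)
  if (n_bad) message("excluding ", n_bad,
                     " row(s) with failed or incomplete features")
  table[usable, , drop = FALSE]
}

## one split-train-test repeat; returns accuracy, WE, confusion, and
## (optionally) per-test-row vote fractions with bout bookkeeping
cvOneRepeat <- function(table, spec, target, features, collect_votes,
                        permute_labels = FALSE) {
  if (permute_labels)
    table <- permuteLabels(table, spec$scheme,
                           seed = sample.int(2147483646L, 1L))
  sp <- if (spec$scheme == "clan") clanSplit(table) else boutSplit(table)
  model <- trainForest(sp$train, spec, target, features)
  pred <- predictClass(model, sp$test)
  truth <- factor(sp$test[[target]], levels = model$classes)
  acc <- mean(as.character(pred) == as.character(truth))
  we <- weightedExpectation(sp$train[[target]], sp$test[[target]])
  conf <- table(truth, factor(pred, levels = model$classes))
  votes <- NULL
  if (collect_votes) {
    v <- voteFractions(model, sp$test)
    votes <- list(bout_id = sp$test$bout_id,
                  position = sp$test$position_in_bout,
                  true = as.character(truth), votes = v)
  }
  list(accuracy = acc, we = we, confusion = conf, n_test = nrow(sp$test),
       votes = votes)
}

#' Repeated leakage-proof cross-validation
#'
#' Runs \code{n_repeats} independent split-train-test cycles of the
#' chosen scheme, each against its own weighted expectation, and
#' summarizes accuracy (mean, s.d.), mean WE, the pooled confusion matrix
#' and per-class accuracies. Fully reproducible from
#' \code{(table, spec)}.
#'
#' @param table a FeatureTable (failed/incomplete rows are excluded up
#'   front, with a message).
#' @param spec a \code{\link{splitSpec}}.
#' @param target label column; defaults to \code{"clan_id"} for the clan
#'   scheme and \code{"caller_id"} for the individual scheme.
#' @param features feature columns used by the forest.
#' @param collect_votes keep per-repeat test vote fractions (needed for
#'   the redundancy analysis).
#' @param permute_labels draw a fresh identity-label permutation (at the
#'   scheme's grouping unit, see \code{\link{permuteLabels}}) for every
#'   repeat — the type-I null of the whole harness. Averaging over fresh
#'   permutations is essential: a single fixed permutation has its own
#'   asymptotic accuracy that need not equal the weighted expectation.
#' @return a \linkS4class{CVSummary}; when \code{collect_votes = TRUE} the
#'   per-repeat vote records are attached as
#'   \code{attr(x, "votes")}.
#' @export
runRepeats <- function(table, spec = splitSpec(), target = NULL,
                       features = whoopFeatureNames(),
                       collect_votes = FALSE, permute_labels = FALSE) {
  if (is.null(target))
    target <- if (spec$scheme == "clan") "clan_id" else "caller_id"
  table <- dropUnusableRows(table, features)
  classes <- sort(unique(table[[target]]))
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(classes, classes))
  reps <- vector("list", spec$n_repeats)
  votes <- if (collect_votes) vector("list", spec$n_repeats)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  for (r in seq_len(spec$n_repeats)) {
    set.seed(deriveSeed(spec$seed, 10000L + r))
    one <- cvOneRepeat(table, spec, target, features, collect_votes,
                       permute_labels)
    reps[[r]] <- data.frame(repeat_index = r, accuracy = one$accuracy,
                            we = one$we, n_test = one$n_test)
    conf[rownames(one$confusion), colnames(one$confusion)] <-
      conf[rownames(one$confusion), colnames(one$confusion)] +
      as.matrix(one$confusion)
    if (collect_votes) votes[[r]] <- one$votes
  }
  reps <- do.call(rbind, reps)
  per_class <- data.frame(
    class = classes,
    accuracy = vapply(classes, function(cl) {
      row <- conf[cl, ]
      if (sum(row) == 0) NA_real_ else row[cl] / sum(row)
    }, numeric(1)))
  out <- new("CVSummary", scheme = spec$scheme,
             meanAccuracy = mean(reps$accuracy),
             sdAccuracy = if (nrow(reps) > 1) sd(reps$accuracy)
             else NA_real_,
             meanWE = mean(reps$we), repeats = reps, confusion = conf,
             perClass = per_class)
  if (collect_votes) attr(out, "votes") <- votes
  out
}

#' Permutation feature importance
#'
#' Mean decrease in held-out accuracy when each feature's information is
#' destroyed: per repeat (individual scheme), the baseline test accuracy
#' is compared with the accuracy after permuting that feature's values
#' within the test set. \code{mode = "retrain"} refits the forest without
#' the feature instead (slower cross-check).
#'
#' @param table a FeatureTable (individual-scheme preconditions apply).
#' @param spec a \code{\link{splitSpec}} with \code{scheme =
#'   "individual"}; \code{n_repeats} controls the averaging.
#' @param features feature columns scored.
#' @param mode \code{"permute"} (default) or \code{"retrain"}.
#' @return data.frame: \code{feature}, \code{importance} (mean accuracy
#'   decrease), \code{se} (standard error across repeats), \code{rank}.
#' @export
featureImportance <- function(table, spec = splitSpec(),
                              features = whoopFeatureNames(),
                              mode = c("permute", "retrain")) {
  mode <- match.arg(mode)
  target <- "caller_id"
  table <- dropUnusableRows(table, features)
  drops <- matrix(NA_real_, spec$n_repeats, length(features),
                  dimnames = list(NULL, features))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  for (r in seq_len(spec$n_repeats)) {
    set.seed(deriveSeed(spec$seed, 20000L + r))
    sp <- boutSplit(table)
    model <- trainForest(sp$train, spec, target, features)
    truth <- as.character(sp$test[[target]])
    base <- mean(as.character(predictClass(model, sp$test)) == truth)
    for (f in features) {
      if (mode == "permute") {
        tst <- sp$test
        tst[[f]] <- tst[[f]][sample.int(nrow(tst))]
        accf <- mean(as.character(predictClass(model, tst)) == truth)
      } else {
        feats2 <- setdiff(features, f)
        m2 <- trainForest(sp$train, spec, target, feats2)
        accf <- mean(as.character(predictClass(m2, sp$test)) == truth)
      }
      drops[r, f] <- base - accf
    }
  }
  imp <- colMeans(drops)
  se <- apply(drops, 2, sd) / sqrt(nrow(drops))
  out <- data.frame(feature = features, importance = unname(imp),
                    se = unname(se))
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
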