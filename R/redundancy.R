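## Serial redundancy: evidence accumulation over the whoops of a bout.

#' Prefix-aggregated class probabilities for one bout
#'
#' For each prefix length k, the aggregated probability vector is the
#' running mean of the per-whoop tree-vote fraction vectors (equivalent to
#' pooling tree votes across the first k whoops). Rows sum to 1.
#'
#' @param votes matrix of per-whoop vote fractions (whoops in natural
#'   bout order x classes), or a \code{WhoopForest} model (then
#'   \code{bout_rows} must hold the bout's feature rows in order).
#' @param bout_rows FeatureTable rows of one bout, natural order (only
#'   when \code{votes} is a model).
#' @return matrix (prefix length k x classes) of aggregated
#'   probabilities.
#' @export
boutPrefixProbabilities <- function(votes, bout_rows = NULL) {
  if (inherits(votes, "WhoopForest")) {
    if (is.null(bout_rows) || !nrow(bout_rows))
      stop("boutPrefixProbabilities: empty bout")
    votes <- voteFractions(votes, bout_rows)
  }
  votes <- as.matrix(votes)
  if (!nrow(votes)) stop("boutPrefixProbabilities: empty bout")
  out <- apply(votes, 2, cumsum) / seq_len(nrow(votes))
  if (nrow(votes) == 1L) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL,
                                                       colnames(votes)))
  out
}

## plurality credit of the true class given an aggregated probability row:
## 1/|argmax set| if the true class is among the maxima, else 0
pluralityCredit <- function(prob_row, true_class) {
  mx <- max(prob_row)
  tied <- which(prob_row >= mx - 1e-12)
  if (true_class %in% names(prob_row)[tied]) 1 / length(tied) else 0
}

#' Equal-informativeness baseline curve
#'
#' Expected probability of a correct plurality decision after k
#' independent, equally informative whoops: each whoop is classified
#' correctly with probability p and to each specific wrong class with
#' probability (1-p)/(K-1); the decision after k whoops is the plurality
#' class (the Bayesian MAP class under this symmetric likelihood), with
#' ties awarded fractional credit 1/|tied set|. Exact mode enumerates
#' vote-count compositions; Monte-Carlo mode simulates (seeded).
#'
#' @param p per-whoop accuracy, in [1/K, 1].
#' @param K number of classes, >= 2.
#' @param k_max curve length.
#' @param method \code{"exact"} (practical for k up to ~10) or
#'   \code{"monte_carlo"}.
#' @param n_sim Monte-Carlo sample size.
#' @param seed Monte-Carlo seed.
#' @return numeric vector \code{curve[1..k_max]};
#'   \code{curve[1] == p} and \code{curve[2] == p} analytically.
#' @export
equalInformativeBaseline <- function(p, K, k_max,
                                     method = c("exact", "monte_carlo"),
                                     n_sim = 20000, seed = 1L) {
  method <- match.arg(method)
  if (K < 2) stop("equalInformativeBaseline: K must be >= 2")
  if (p < 1 / K - 1e-12 || p > 1 + 1e-12)
    stop("equalInformativeBaseline: p must lie in [1/K, 1]")
  if (method == "exact")
    vapply(seq_len(k_max), exactPluralityCorrect, numeric(1), p = p, K = K)
  else
    mcPluralityCorrect(p, K, k_max, n_sim, seed)
}

## integer partitions of w into parts of any size (non-increasing order)
intPartitions <- function(w, max_part = w) {
  if (w == 0) return(list(integer(0)))
  out <- list()
  for (first in seq_len(min(w, max_part))) {
    for (rest in intPartitions(w - first, first))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

## P(plurality decision correct) for k iid symmetric classifications
exactPluralityCorrect <- function(k, p, K) {
  total <- 0
  for (c_votes in 0:k) {
    w <- k - c_votes
    pb <- stats::dbinom(c_votes, k, p)
    if (pb == 0) next
    if (w == 0) {
      credit <- if (c_votes > 0) 1 else 0
      total <- total + pb * credit
      next
    }
    ecredit <- 0
    for (part in intPartitions(w)) {
      s <- length(part)
      if (s > K - 1) next
      tab <- table(part)
      n_assign <- exp(lfactorial(K - 1) - lfactorial(K - 1 - s) -
                        sum(lfactorial(tab)))
      p_comp <- exp(lfactorial(w) - sum(lfactorial(part))) *
        (1 / (K - 1))^w * n_assign
      M <- max(part)
      credit <- if (c_votes > M) 1
      else if (c_votes == M && c_votes > 0)
        1 / (1 + sum(part == c_votes))
      else 0
      ecredit <- ecredit + p_comp * credit
    }
    total <- total + pb * ecredit
  }
  total
}

mcPluralityCorrect <- function(p, K, k_max, n_sim, seed) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(deriveSeed(seed, 7L))
  correct <- matrix(runif(n_sim * k_max) < p, n_sim, k_max)
  wrong_class <- matrix(sample.int(K - 1, n_sim * k_max, replace = TRUE),
                        n_sim, k_max)
  curve <- numeric(k_max)
  counts <- matrix(0L, n_sim, K)   # class 1 = true class
  for (k in seq_len(k_max)) {
    cls <- ifelse(correct[, k], 1L, 1L + wrong_class[, k])
    counts[cbind(seq_len(n_sim), cls)] <-
      counts[cbind(seq_len(n_sim), cls)] + 1L
    mx <- do.call(pmax, as.data.frame(counts))
    ties <- rowSums(counts == mx)
    curve[k] <- mean(ifelse(counts[, 1] == mx, 1 / ties, 0))
  }
  curve
}

#' Flat chance baseline
#'
#' The uninformative-whoop null: a constant curve at the weighted
#' expectation.
#'
#' @param we chance accuracy in [0, 1].
#' @param k_max curve length.
#' @return numeric vector of length \code{k_max}, all equal to \code{we}.
#' @export
chanceBaseline <- function(we, k_max) {
  if (we < 0 || we > 1) stop("chanceBaseline: we must lie in [0, 1]")
  rep(we, k_max)
}

#' Bout-prefix accuracy curve with baselines
#'
#' Runs repeated individual-scheme cross-validation collecting tree-vote
#' fractions, aggregates votes over bout prefixes in natural order, and
#' averages over all (repeat, bout) pairs with bouts of length >= k. Two
#' empirical summaries are reported per k: \code{mean_prob}, the mean
#' aggregated probability mass on the true caller, and \code{accuracy},
#' the mean fractional-plurality credit of the true caller (the
#' decision-level quantity comparable to the baselines). Following the
#' original design, the analysis refuses to run when mean single-whoop
#' accuracy does not exceed the mean weighted expectation.
#'
#' @param table a FeatureTable (typically A/S whoops only, filtered for
#'   the individual scheme).
#' @param spec a \code{\link{splitSpec}} with \code{scheme =
#'   "individual"}.
#' @param features feature columns for the forest.
#' @param baseline_method method for
#'   \code{\link{equalInformativeBaseline}}.
#' @return a \linkS4class{PrefixCurve}.
#' @export
prefixAccuracyCurve <- function(table, spec = splitSpec(),
                                features = whoopFeatureNames(),
                                baseline_method = "exact") {
  cv <- runRepeats(table, spec, target = "caller_id",
                   features = features, collect_votes = TRUE)
  if (!(meanAccuracy(cv) > meanWE(cv)))
    stop("prefixAccuracyCurve: mean accuracy (", round(meanAccuracy(cv), 3),
         ") does not exceed chance (", round(meanWE(cv), 3),
         "); redundancy analysis not conducted")
  votes <- attr(cv, "votes")
  k_max <- 0L
  acc_prob <- list(); acc_hard <- list()
  for (rep_votes in votes) {
    ord <- order(rep_votes$bout_id, rep_votes$position)
    v <- rep_votes$votes[ord, , drop = FALSE]
    bouts <- rep_votes$bout_id[ord]
    true <- rep_votes$true[ord]
    for (b in unique(bouts)) {
      rows <- which(bouts == b)
      agg <- boutPrefixProbabilities(v[rows, , drop = FALSE])
      tc <- true[rows[1]]
      len <- length(rows)
      k_max <- max(k_max, len)
      for (k in seq_len(len)) {
        row <- agg[k, ]
        acc_prob[[length(acc_prob) + 1L]] <-
          c(k = k, val = unname(row[tc]))
        acc_hard[[length(acc_hard) + 1L]] <-
          c(k = k, val = pluralityCredit(row, tc))
      }
    }
  }
  dp <- do.call(rbind, acc_prob)
  dh <- do.call(rbind, acc_hard)
  ks <- seq_len(k_max)
  curve <- data.frame(
    k = ks,
    mean_prob = vapply(ks, function(k) mean(dp[dp[, "k"] == k, "val"]),
                       numeric(1)),
    accuracy = vapply(ks, function(k) mean(dh[dh[, "k"] == k, "val"]),
                      numeric(1)),
    n_bouts = vapply(ks, function(k) sum(dp[, "k"] == k), numeric(1)))
  K <- length(unique(table$caller_id[!table$failed]))
  p <- min(max(meanAccuracy(cv), 1 / K), 1)
  eib <- equalInformativeBaseline(p, K, k_max, method = baseline_method,
                                  seed = spec$seed)
  new("PrefixCurve", curve = curve, chance = meanWE(cv),
      equalInformative = eib, p = p, nClasses = as.numeric(K))
}
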