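# Random-forest classification of cells from per-cell features and exact
# extrapolation of N-cell majority-vote accuracy.

#' Classifier configuration
#'
#' Defaults mirror the published analysis: a random forest of 500 trees
#' with maximum depth 4, plain random (unstratified) 80/20 train/test
#' splits, and the run-averaged accuracy over many splits.
#'
#' @param nTrees number of trees.
#' @param maxDepth maximum tree depth.
#' @param trainFraction fraction of cells used for training.
#' @param nRuns number of independent train/evaluation splits.
#' @param seed RNG seed for the split/forest stream.
#' @param stratified use per-class stratified splits instead of plain
#'   random ones.
#' @return list configuration.
#' @export
classifierConfig <- function(nTrees = 500, maxDepth = 4,
                             trainFraction = 0.8, nRuns = 1000, seed = 1,
                             stratified = FALSE) {
  stopifnot(trainFraction > 0, trainFraction < 1, nRuns >= 1)
  list(nTrees = nTrees, maxDepth = maxDepth,
       trainFraction = trainFraction, nRuns = nRuns, seed = seed,
       stratified = stratified)
}

#' Train/evaluate a random-forest cell classifier over repeated splits
#'
#' Repeats random train/test splits, fits a random forest per run
#' (\pkg{ranger}), accumulates held-out confusion counts and returns the
#' run-averaged accuracy together with the row-normalized single-cell
#' classification probability matrix P[true, predicted]. Splits that lose a
#' class entirely from the training set are resampled.
#'
#' @param features data.frame (or matrix) of per-cell numeric features.
#' @param labels factor (or coercible) of true classes.
#' @param cfg a [classifierConfig()].
#' @return list with \code{accuracy} (mean over runs), \code{P} (confusion
#'   probability matrix), \code{counts} (raw confusion counts),
#'   \code{runAccuracy}.
#' @export
trainEval <- function(features, labels, cfg = classifierConfig()) {
  labels <- factor(labels)
  K <- nlevels(labels)
  stopifnot(K >= 2, all(table(labels) >= 2))
  df <- as.data.frame(features)
  stopifnot(nrow(df) == length(labels))
  n <- nrow(df)
  nTrain <- floor(cfg$trainFraction * n)
  stopifnot(nTrain >= K, nTrain < n)
  rs <- .localSeed(cfg$seed); on.exit(.restoreSeed(rs))
  conf <- matrix(0, K, K, dimnames = list(levels(labels), levels(labels)))
  runAcc <- numeric(cfg$nRuns)
  df$.y <- labels
  for (run in seq_len(cfg$nRuns)) {
    repeat {
      tr <- if (cfg$stratified) {
        unlist(lapply(levels(labels), function(l) {
          i <- which(labels == l)
          sample(i, max(1, round(cfg$trainFraction * length(i))))
        }))
      } else sample.int(n, nTrain)
      if (nlevels(droplevels(labels[tr])) == K && length(tr) < n) break
    }
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df[tr, , drop = FALSE],
      num.trees = cfg$nTrees, max.depth = cfg$maxDepth,
      num.threads = 1, verbose = FALSE,
      seed = .childSeed(cfg$seed, run))
    pred <- stats::predict(fit, df[-tr, , drop = FALSE],
                           num.threads = 1)$predictions
    tb <- table(factor(labels[-tr], levels(labels)),
                factor(pred, levels(labels)))
    conf <- conf + tb
    runAcc[run] <- sum(diag(tb)) / sum(tb)
  }
  P <- conf / rowSums(conf)
  list(accuracy = mean(runAcc), P = as.matrix(P), counts = conf,
       runAccuracy = runAcc)
}

#' Exact majority-vote accuracy for N cells of one class
#'
#' Given single-cell classification probabilities P[true, predicted], the
#' probability that, among N cells truly of one class, the correct class
#' receives strictly more votes than either incorrect alternative. Computed
#' by exact multinomial enumeration over all vote triples; ties count as
#' failures. Classes are assumed equally likely a priori, so the average
#' accuracy is the unweighted mean over true classes.
#'
#' @param P square (3x3) row-stochastic probability matrix.
#' @param N number of cells voting.
#' @return list with \code{perClass} accuracies and the \code{average}.
#' @examples
#' voteAccuracy(diag(3), 5)$average           # 1
#' voteAccuracy(matrix(1/3, 3, 3), 1)$average # 1/3
#' @export
voteAccuracy <- function(P, N) {
  stopifnot(nrow(P) == 3, ncol(P) == 3, N >= 1)
  if (max(abs(rowSums(P) - 1)) > 1e-9) stop("rows of P must sum to 1")
  votes <- expand.grid(a = 0:N, b = 0:N)
  votes <- votes[votes$a + votes$b <= N, ]
  votes$c <- N - votes$a - votes$b
  lfN <- lgamma(N + 1)
  perClass <- vapply(1:3, function(t) {
    win <- votes[votes[, t] > pmax(votes[, setdiff(1:3, t)[1]],
                                   votes[, setdiff(1:3, t)[2]]), ,
                 drop = FALSE]
    if (!nrow(win)) return(0)
    p <- pmax(P[t, ], 1e-300)
    lp <- lfN - lgamma(win$a + 1) - lgamma(win$b + 1) - lgamma(win$c + 1) +
      win$a * log(p[1]) + win$b * log(p[2]) + win$c * log(p[3])
    sum(exp(lp))
  }, numeric(1))
  names(perClass) <- if (!is.null(rownames(P))) rownames(P) else
    paste0("class", 1:3)
  list(perClass = perClass, average = mean(perClass))
}

#' Majority-vote accuracy as a function of group size
#'
#' @param P 3x3 probability matrix.
#' @param Ns vector of group sizes.
#' @return data.frame with columns N, average, and one per class.
#' @export
voteAccuracyTable <- function(P, Ns = 1:200) {
  rows <- lapply(Ns, function(N) {
    va <- voteAccuracy(P, N)
    cbind(data.frame(N = N, average = va$average),
          as.data.frame(as.list(va$perClass)))
  })
  do.call(rbind, rows)
}
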