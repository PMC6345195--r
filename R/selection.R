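#' ReliefF feature ranking for a binary cohort
#'
#' Standard binary ReliefF with every sample used as an anchor (no
#' stochastic subsampling, so the ranking is deterministic): features are
#' range-normalized internally, each anchor's `nNeighbors` nearest hits
#' (same class) and misses (other class) are found under Manhattan
#' distance, and each feature weight accumulates
#' `diff(f, anchor, miss)/(M*k) - diff(f, anchor, hit)/(M*k)` with the
#' per-feature difference normalized by the feature range. Constant
#' (zero-range) features receive weight exactly 0. Distance ties are broken
#' by sample index; `seed` is accepted for interface stability but the
#' procedure involves no randomness.
#'
#' @param fm a [SpiralFeatures-class] with binary ET/CONTROL labels.
#' @param nNeighbors neighbors per class (default 10).
#' @param seed unused by the deterministic procedure; kept for provenance.
#' @return a [FeatureRanking-class].
#' @examples
#' m <- cbind(sig = rep(c(0, 1), each = 12) + rnorm(24, 0, .05),
#'            noise = rnorm(24))
#' sf <- SpiralFeatures(m, labels = rep(c("CONTROL", "ET"), each = 12))
#' relieffRank(sf, nNeighbors = 5)
#' @export
relieffRank <- function(fm, nNeighbors = 10L, seed = 1L) {
  stopifnot(is(fm, "SpiralFeatures"))
  X <- featureMatrix(fm)
  y <- sampleLabels(fm)
  classes <- unique(y)
  if (length(classes) != 2)
    stop("ReliefF here requires exactly two classes, got: ",
         paste(classes, collapse = ", "))
  nNeighbors <- as.integer(nNeighbors)
  counts <- table(y)
  if (any(counts < nNeighbors + 1))
    stop(sprintf("each class needs more than nNeighbors = %d members (have %s); use a smaller neighbor count",
                 nNeighbors, paste(counts, collapse = "/")))
  M <- nrow(X)
  p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  ok <- rng > 0
  Z <- X
  Z[, ok] <- sweep(sweep(X[, ok, drop = FALSE], 2,
                         apply(X[, ok, drop = FALSE], 2, min)), 2,
                   rng[ok], "/")
  Z[, !ok] <- 0

  w <- numeric(p)
  for (i in seq_len(M)) {
    d <- rowSums(abs(sweep(Z, 2, Z[i, ])))
    d[i] <- Inf
    for (cls in classes) {
      idx <- which(y == cls & seq_len(M) != i)
      nb <- idx[order(d[idx], idx)][seq_len(nNeighbors)]
      diffs <- colSums(abs(sweep(Z[nb, , drop = FALSE], 2, Z[i, ])))
      if (cls == y[i]) w <- w - diffs / (M * nNeighbors)
      else w <- w + diffs / (M * nNeighbors)
    }
  }
  w[!ok] <- 0
  ord <- order(-w, seq_len(p))
  new("FeatureRanking", featureNames = colnames(X), weights = w,
      order = as.integer(ord))
}

#' Top-n features of a ranking
#'
#' @param rank a [FeatureRanking-class].
#' @param n how many features to keep (default 5).
#' @param names return feature names (default) rather than indices.
#' @return the first `n` entries of the ranking, best first.
#' @export
selectTop <- function(rank, n = 5L, names = TRUE) {
  stopifnot(is(rank, "FeatureRanking"))
  n <- as.integer(n)
  if (n < 1 || n > length(rank@order))
    stop("n must be between 1 and the number of features")
  idx <- rank@order[seq_len(n)]
  if (names) rank@featureNames[idx] else idx
}

#' Reference top-5 feature subsets for tremor spirals
#'
#' The ranked five-feature subsets identified by ReliefF on the BIODARWO
#' clinical cohort for the two sequence constructions: for the residue
#' method MNF, WAMP, MAV, MFL, FD; for the radius method MFL, FD, MYO,
#' MAV, STD. Classifiers can be evaluated on exactly these named subsets
#' without re-running the ranking.
#'
#' @param method `"residue"` or `"radius"`.
#' @return character vector of 5 feature names, most relevant first.
#' @export
referenceTopFeatures <- function(method = c("residue", "radius")) {
  switch(match.arg(method),
         residue = c("MNF", "WAMP", "MAV", "MFL", "FD"),
         radius = c("MFL", "FD", "MYO", "MAV", "STD"))
}

#' Write a feature ranking as CSV
#'
#' @param rank a [FeatureRanking-class].
#' @param path output path; columns rank, feature_name, weight.
#' @return `path`, invisibly.
#' @export
writeRankingCsv <- function(rank, path) {
  df <- data.frame(rank = seq_along(rank@order),
                   feature_name = rank@featureNames[rank@order],
                   weight = rank@weights[rank@order])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
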