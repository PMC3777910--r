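# Independent oracles and fixture builders. Every oracle here is written
# against the definition (explicit sums, recursion over the alignment
# graph, exact tail enumeration), not against the package's code paths.

# 1 - PCC dissimilarity by the explicit covariance formula, double loop,
# pairwise-complete genes; NA when < minCommon common genes or a vector
# has zero variance.
oracleDissimMatrix <- function(X, minCommon = 3L) {
  nr <- ncol(X)
  D <- matrix(NA_real_, nr, nr, dimnames = list(colnames(X), colnames(X)))
  diag(D) <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nr)) {
      if (i == j) next
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      n <- sum(ok)
      if (n < minCommon) next
      x <- X[ok, i]; y <- X[ok, j]
      sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
      if (sxx == 0 || syy == 0) next
      sxy <- sum((x - mean(x)) * (y - mean(y)))
      D[i, j] <- 1 - sxy / sqrt(sxx * syy)
    }
  }
  D
}

oracleCurveMean <- function(X, minCommon = 3L) {
  D <- oracleDissimMatrix(X, minCommon)
  mean(D[upper.tri(D)], na.rm = TRUE)
}

# Needleman-Wunsch score by top-down recursion over the alignment graph
# (memoized exhaustive maximum over all global alignments).
oracleNWScore <- function(a, b, sub, gap = 8) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  memo <- matrix(NA_real_, n + 1L, m + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (i == 0L && j == 0L) 0 else {
      cand <- c()
      if (i > 0L && j > 0L) cand <- c(cand, rec(i - 1L, j - 1L) + sub[A[i], B[j]])
      if (i > 0L) cand <- c(cand, rec(i - 1L, j) - gap)
      if (j > 0L) cand <- c(cand, rec(i, j - 1L) - gap)
      max(cand)
    }
    memo[i + 1L, j + 1L] <<- v
    v
  }
  rec(n, m)
}

# score of one explicit alignment (two equal-length gapped strings)
alignmentScore <- function(ga, gb, sub, gap = 8) {
  A <- strsplit(ga, "")[[1]]; B <- strsplit(gb, "")[[1]]
  stopifnot(length(A) == length(B))
  s <- 0
  for (k in seq_along(A)) {
    s <- s + if (A[k] == "-" || B[k] == "-") -gap else sub[A[k], B[k]]
  }
  s
}

# random global alignment of two sequences (monotone lattice path)
randomAlignment <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  i <- 0L; j <- 0L; ga <- c(); gb <- c()
  while (i < length(A) || j < length(B)) {
    moves <- c(if (i < length(A) && j < length(B)) "d",
               if (i < length(A)) "u", if (j < length(B)) "l")
    mv <- sample(moves, 1L)
    if (mv == "d") { i <- i + 1L; j <- j + 1L; ga <- c(ga, A[i]); gb <- c(gb, B[j]) }
    else if (mv == "u") { i <- i + 1L; ga <- c(ga, A[i]); gb <- c(gb, "-") }
    else { j <- j + 1L; ga <- c(ga, "-"); gb <- c(gb, B[j]) }
  }
  c(paste(ga, collapse = ""), paste(gb, collapse = ""))
}

# exact upper-tail hypergeometric probability by term-wise enumeration
oracleHyperTail <- function(N, K, n, o) {
  js <- o:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg by hand: sort, scale by n/rank, cummin from the back
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# adjusted Rand index between two labelings
ariScore <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nC2 <- choose(sum(tab), 2)
  expected <- ai * bj / nC2
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

# uniform random dataset (optionally with missing cells)
randomDataset <- function(nG, nR, nT, seed = 1L, missFrac = 0) {
  set.seed(seed)
  arr <- array(runif(nG * nR * nT, 0, 2), dim = c(nG, nR, nT),
               dimnames = list(sprintf("g%02d", seq_len(nG)),
                               sprintf("r%02d", seq_len(nR)),
                               sprintf("t%d", seq_len(nT))))
  if (missFrac > 0) {
    idx <- sample(length(arr), round(missFrac * length(arr)))
    arr[idx] <- NA_real_
  }
  ExpressionDataset(arr)
}

datasetFromSlices <- function(slices) {
  # slices: named list (timepoint -> gene x region matrix, same dimnames)
  g <- rownames(slices[[1]]); r <- colnames(slices[[1]])
  arr <- array(NA_real_, dim = c(length(g), length(r), length(slices)),
               dimnames = list(g, r, names(slices)))
  for (tp in names(slices)) arr[, , tp] <- slices[[tp]]
  ExpressionDataset(arr)
}

writeTempTsv <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

blosum50Matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM50", package = "Biostrings", envir = e)
  e$BLOSUM50
}

randomPeptide <- function(len) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}
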