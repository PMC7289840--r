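# Fixtures built in code and independent brute-force oracles.

tinyCounts <- function() {
  matrix(c(5, 0, 3,
           2, 7, 1,
           0, 4, 9,
           6, 2, 8),
         nrow = 4, byrow = TRUE,
         dimnames = list(paste0("F", 1:4), paste0("S", 1:3)))
}

tinyTable <- function() otuTable(tinyCounts(), rank = "family")

# Independent scalar oracles ------------------------------------------------

oracleInvSimpson <- function(v) {
  p <- v / sum(v)
  1 / sum(p * p)
}

oracleMorisitaHorn <- function(x, y) {
  X <- sum(x); Y <- sum(y)
  1 - 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

# Exact Mann-Whitney permutation distribution by full enumeration.
oracleMwuExact <- function(values, groups) {
  groups <- as.factor(groups)
  n1 <- sum(groups == levels(groups)[1])
  N <- length(values)
  r <- rank(values)
  uObs <- sum(r[groups == levels(groups)[1]]) - n1 * (n1 + 1) / 2
  uAll <- utils::combn(N, n1, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  list(u = uObs,
       p = min(1, 2 * min(mean(uAll <= uObs), mean(uAll >= uObs))),
       dist = uAll)
}

# Naive O(n^3) agglomerative clustering: returns merge heights in order.
# Independent of stats::hclust (direct set-based linkage evaluation).
oracleLinkageHeights <- function(D, method = c("complete", "single")) {
  method <- match.arg(method)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  linkage <- function(a, b) {
    vals <- D[a, b, drop = FALSE]
    if (method == "complete") max(vals) else min(vals)
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestH <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- linkage(clusters[[i]], clusters[[j]])
      if (h < bestH) { bestH <- h; best <- c(j, i) }
    }
    heights <- c(heights, bestH)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Deterministic prevalence table: counts given exactly, no sampling.
deterministicPrevalence <- function(spec, total, rank = "family") {
  # spec: named list subsite -> named integer vector of detected counts
  rows <- lapply(names(spec), function(s)
    data.frame(subsite = s, taxon = names(spec[[s]]),
               detected = unname(spec[[s]]), total = total,
               stringsAsFactors = FALSE))
  prevalenceTable(do.call(rbind, rows), rank = rank)
}

randomDissimilarity <- function(n, seed, metric = "morisita_horn") {
  set.seed(seed)
  v <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  dimnames(v) <- list(paste0("x", seq_len(n)), paste0("x", seq_len(n)))
  dissimilarityMatrix(v, metric = metric)
}

detectedTaxa <- function(tab) rownames(tab)[rowSums(otuCounts(tab)) > 0]
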