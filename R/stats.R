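#' Covariance PCA of an abundance matrix
#'
#' Principal component analysis on mean-centred, unscaled columns
#' (covariance form, the convention for relative-abundance fingerprint
#' matrices where the common scale is meaningful). Components are ordered by
#' decreasing eigenvalue; the sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param x Numeric matrix, samples in rows (>= 2 rows and columns).
#' @return List with `scores` (samples x components), `loadings`,
#'   `varianceExplained` (fractions summing to 1, or all zero for a
#'   constant matrix) and `sdev`.
#' @export
covariancePCA <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least a 2 x 2 matrix")
  centered <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) {
    k <- min(dim(x))
    return(list(scores = matrix(0, nrow(x), k,
                                dimnames = list(rownames(x), paste0("PC", seq_len(k)))),
                loadings = matrix(0, ncol(x), k),
                varianceExplained = rep(0, k), sdev = rep(0, k)))
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, loadings = loadings, varianceExplained = ve,
       sdev = p$sdev)
}

#' Euclidean distances between PC scores
#'
#' @param scores Score matrix from [covariancePCA()].
#' @param nComponents Number of leading components to use (default 2, the
#'   plotted and tested axes; use `ncol(scores)` for the full isometric
#'   embedding).
#' @return A square symmetric distance matrix with zero diagonal.
#' @export
euclideanPCDistances <- function(scores, nComponents = 2) {
  if (nComponents > ncol(scores))
    stop("nComponents exceeds available components")
  as.matrix(stats::dist(scores[, seq_len(nComponents), drop = FALSE]))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(a, b) = 1 - 2 * sum(min(a, b)) / (sum(a) + sum(b))`, in `[0, 1]`.
#' A pair of all-zero rows is defined as distance 0 (with a warning) rather
#' than NaN.
#'
#' @param x Non-negative abundance matrix, samples in rows.
#' @return Square symmetric dissimilarity matrix.
#' @examples
#' brayCurtisMatrix(rbind(a = c(0.7, 0.3), b = c(0.3, 0.7)))  # 0.4
#' @export
brayCurtisMatrix <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  rs <- rowSums(x)
  warned <- FALSE
  for (i in seq_len(n)) for (j in seq_len(i)) {
    denom <- rs[i] + rs[j]
    if (denom == 0) {
      if (!warned) {
        warning("all-zero row pair: Bray-Curtis defined as 0")
        warned <- TRUE
      }
      d[i, j] <- d[j, i] <- 0
    } else {
      d[i, j] <- d[j, i] <- 1 - 2 * sum(pmin(x[i, ], x[j, ])) / denom
    }
  }
  d
}

#' Mantel permutation test
#'
#' Pearson correlation `r` of the lower triangles of two distance matrices;
#' significance by jointly permuting the row/column labels of the second
#' matrix. One-sided p-value with the add-one convention:
#' `p = (#{permuted r >= observed r} + 1) / (nPerm + 1)`, hence bounded
#' below by `1 / (nPerm + 1)`.
#'
#' @param d1,d2 Square symmetric distance matrices of equal dimension (and
#'   matching labels, when both are labelled).
#' @param nPerm Number of permutations (default 10000, the protocol's
#'   randomisation count).
#' @param seed Optional integer seed for reproducible permutations.
#' @return List with `r`, `p`, `nPerm`.
#' @export
mantelTest <- function(d1, d2, nPerm = 10000, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) stop("distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("distance matrix labels differ: ",
         paste(setdiff(union(rownames(d1), rownames(d2)),
                       intersect(rownames(d1), rownames(d2))),
               collapse = ", "))
  }
  if (nPerm < 1) stop("nPerm must be >= 1")
  n <- nrow(d1)
  lower <- lower.tri(d1)
  v1 <- d1[lower]
  v2 <- d2[lower]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero variance in a distance triangle: Mantel r undefined")
  r <- stats::cor(v1, v2)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (k in seq_len(nPerm)) {
    perm <- sample.int(n)
    rp <- stats::cor(v1, d2[perm, perm][lower])
    if (rp >= r) exceed <- exceed + 1L
  }
  list(r = r, p = (exceed + 1) / (nPerm + 1), nPerm = as.integer(nPerm))
}

#' Margalef's richness index
#'
#' `(S - 1) / ln(N)` where `S` is the number of taxa present and `N` the
#' total count of individuals. For fluorescence fingerprints `N` has no
#' natural unit; the convention here is total retained peak area rounded to
#' the nearest integer, which makes the index sensitive to the overall
#' fluorescence yield — interpret across samples run at comparable yield.
#'
#' @param counts Non-negative vector of per-taxon quantities; `S` counts
#'   entries > 0.
#' @param total Total `N`; defaults to `sum(counts)` rounded. Must exceed 1.
#' @return The index (0 when a single taxon is present).
#' @examples
#' margalefIndex(c(10, 5, 0, 2), total = 1000)
#' @export
margalefIndex <- function(counts, total = round(sum(counts))) {
  if (total <= 1) stop("total N must exceed 1")
  s <- sum(counts > 0)
  if (s < 1) stop("at least one taxon must be present")
  (s - 1) / log(total)
}

#' Simpson's diversity index
#'
#' Default Gini-Simpson form `1 - sum(p^2)` (larger = more even, 0 for a
#' single taxon); the inverse form `1 / sum(p^2)` is available via
#' `variant`.
#'
#' @param proportions Non-negative proportions summing to 1.
#' @param variant `"gini"` (default) or `"inverse"`.
#' @return The index.
#' @examples
#' simpsonIndex(rep(0.25, 4))  # 0.75
#' @export
simpsonIndex <- function(proportions, variant = c("gini", "inverse")) {
  variant <- match.arg(variant)
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("proportions must sum to 1")
  ss <- sum(proportions^2)
  if (variant == "gini") 1 - ss else 1 / ss
}

#' Ordinary least-squares regression of observed on predicted indices
#'
#' @param x Predictor (predicted indices), `n >= 3`, non-constant.
#' @param y Response (observed indices), same length.
#' @return List with `slope`, `intercept`, `r_squared`, `f_statistic`,
#'   `df` (numerator, denominator), `p`.
#' @export
linearRegression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("zero variance in x: slope undefined")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  fstat <- s$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       f_statistic = unname(fstat[1]),
       df = c(unname(fstat[2]), unname(fstat[3])),
       p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                            lower.tail = FALSE)))
}
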