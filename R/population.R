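#' Construct a WellPopulation
#'
#' @param wells data.frame with at least a `volume_nL` column; optionally
#'   `half_depth_area_um2`, centroids, `true_label`, `cluster`.
#' @param metadata optional named list.
#' @return a [WellPopulation-class].
#' @export
WellPopulation <- function(wells, metadata = list()) {
  new("WellPopulation", wells = as.data.frame(wells), metadata = metadata)
}

.volumesOf <- function(x) {
  if (is(x, "WellPopulation")) x@wells$volume_nL
  else if (is.numeric(x)) x
  else stop("expected a WellPopulation or a numeric volume vector")
}

#' Population summary: mean, sd and coefficient of variation
#'
#' Sample mean, sample standard deviation (n-1 denominator) and the
#' coefficient of variation `CoV = 100 * sd / mean` in percent. For
#' reporting, the CoV is additionally rounded to two significant figures
#' (`cov_report`), the convention used in well-array uniformity tables.
#'
#' @param x a [WellPopulation-class] or numeric vector of volumes (nL).
#' @return list with `mean`, `sd`, `cov_pct`, `cov_report`, `n`.
#' @examples
#' v <- c(0.0867, 0.0880, 0.0893)
#' summarizeWells(v)
#' @export
summarizeWells <- function(x) {
  v <- .volumesOf(x)
  n <- length(v)
  if (n < 2L) stop("standard deviation undefined for fewer than 2 wells")
  m <- mean(v)
  s <- stats::sd(v)
  cov <- 100 * s / m
  list(mean = m, sd = s, cov_pct = cov, cov_report = signif(cov, 2),
       n = n)
}

#' Moment-based Gaussian fit of a volume distribution
#'
#' Fits a normal distribution by its first two moments, builds a
#' Freedman-Diaconis histogram for plotting, and reports a Shapiro-Wilk
#' normality diagnostic (on a fixed-seed subsample of at most 5000 wells
#' for large populations). The diagnostic is informational: a population
#' is summarized either way.
#'
#' @param x a [WellPopulation-class] or numeric vector of volumes (>= 10).
#' @return list with `mean`, `sd`, `histogram` (a [graphics::hist()]
#'   object, not plotted), `shapiro_p`, `normal` (`TRUE` when
#'   `shapiro_p > 0.01`).
#' @export
fitGaussianVolumes <- function(x) {
  v <- .volumesOf(x)
  if (length(v) < 10L) stop("Gaussian fit requires at least 10 wells")
  h <- graphics::hist(v, breaks = "FD", plot = FALSE)
  sub <- if (length(v) > 5000L)
    withr::with_seed(0L, sample(v, 5000L)) else v
  sw <- stats::shapiro.test(sub)
  list(mean = mean(v), sd = stats::sd(v), histogram = h,
       shapiro_p = sw$p.value, normal = sw$p.value > 0.01)
}

## k-means++ seeding on a feature matrix
.kmeansPP <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1, ] <- x[i, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    tot <- sum(d2)
    i <- if (tot > 0) sample.int(n, 1L, prob = d2 / tot)
         else sample.int(n, 1L)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' K-means typing of well sub-groups
#'
#' Clusters wells on z-score-standardized features (volume and, when
#' present, half-depth area; the two differ by orders of magnitude, so
#' standardization keeps both informative) using Lloyd's algorithm with
#' k-means++ initialization, keeping the best of `n_restarts` runs by
#' within-cluster sum of squares. Deterministic under `seed`.
#'
#' @param wells a [WellPopulation-class], or a numeric matrix/data.frame of
#'   features (one row per well).
#' @param k number of clusters (>= 1; `k = 1` labels everything 1).
#' @param seed integer seed.
#' @param n_restarts number of k-means++ restarts (default 10).
#' @param features feature columns to use when `wells` is a
#'   WellPopulation; defaults to volume plus half-depth area when
#'   available.
#' @return for a WellPopulation input, the population with a `cluster`
#'   column added (metadata records seed, k and the winning WCSS);
#'   otherwise an integer label vector with attributes `wcss` and
#'   `centers`.
#' @export
kmeansClassify <- function(wells, k, seed = 1, n_restarts = 10,
                           features = NULL) {
  if (is(wells, "WellPopulation")) {
    if (is.null(features))
      features <- intersect(c("volume_nL", "half_depth_area_um2"),
                            names(wells@wells))
    x <- as.matrix(wells@wells[, features, drop = FALSE])
  } else {
    x <- as.matrix(wells)
  }
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (k < 1) stop("k must be at least 1")
  if (n < k) stop("need at least k wells to form k clusters")
  # z-score each feature; constant features carry no information
  xs <- apply(x, 2, function(col) {
    s <- stats::sd(col)
    if (s > 0) (col - mean(col)) / s else col * 0
  })
  xs <- matrix(xs, n)
  n_distinct <- nrow(unique(xs))
  if (n_distinct < k) {
    warning("only ", n_distinct, " distinct feature points; reducing k")
    k <- n_distinct
  }
  if (k == 1L) {
    # Lloyd with one centre is just the mean; no restarts needed
    ctr <- colMeans(xs)
    wcss <- sum(sweep(xs, 2, ctr)^2)
    labels <- rep(1L, n)
    if (is(wells, "WellPopulation")) {
      wells@wells$cluster <- labels
      wells@metadata$kmeans <- list(k = 1L, seed = as.integer(seed),
                                    n_restarts = n_restarts,
                                    features = features, wcss = wcss)
      return(wells)
    }
    return(structure(labels, wcss = wcss,
                     centers = matrix(ctr, 1)))
  }
  res <- withr::with_seed(as.integer(seed), {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      ctr <- .kmeansPP(xs, k)
      km <- tryCatch(
        stats::kmeans(xs, centers = ctr, iter.max = 100L,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(stats::kmeans(xs, centers = ctr,
                                         iter.max = 100L,
                                         algorithm = "Lloyd"))
        })
      if (!is.null(km) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
    best
  })
  if (is.null(res)) stop("k-means failed on all restarts")
  labels <- as.integer(res$cluster)
  if (is(wells, "WellPopulation")) {
    wells@wells$cluster <- labels
    wells@metadata$kmeans <- list(k = k, seed = as.integer(seed),
                                  n_restarts = n_restarts,
                                  features = features,
                                  wcss = res$tot.withinss)
    wells
  } else {
    structure(labels, wcss = res$tot.withinss, centers = res$centers)
  }
}

## all permutations of 1..k (k small)
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in .permutations(k - 1L))
    for (pos in 0:(k - 1L))
      out[[length(out) + 1L]] <- append(p, k, after = pos)
  out
}

#' Count misclassified wells under the optimal cluster-to-type mapping
#'
#' Cluster labels are arbitrary, so clusters are first mapped to designed
#' types by the permutation of the confusion matrix that minimizes total
#' disagreement (optimal assignment; both label sets must have the same
#' cardinality, at most 8 for the exhaustive search). The count of wells
#' whose mapped cluster differs from their true type is returned; it is
#' invariant to any wholesale relabeling of either argument.
#'
#' @param labels cluster labels.
#' @param true_labels designed type labels, same length.
#' @return integer count of misclassified wells, with attribute `mapping`
#'   (named vector: cluster level -> true level).
#' @examples
#' misclassificationCount(c(2, 2, 1, 1), c(1, 1, 2, 2))  # 0: permutation
#' @export
misclassificationCount <- function(labels, true_labels) {
  if (length(labels) != length(true_labels))
    stop("labels and true_labels have different lengths")
  lu <- sort(unique(labels))
  tu <- sort(unique(true_labels))
  if (length(lu) != length(tu))
    stop("label sets have different cardinalities (", length(lu), " vs ",
         length(tu), ")")
  k <- length(lu)
  if (k > 8L) stop("exhaustive assignment supported up to 8 classes")
  conf <- table(factor(labels, levels = lu),
                factor(true_labels, levels = tu))
  best <- Inf
  best_p <- NULL
  for (p in .permutations(k)) {
    agree <- sum(conf[cbind(seq_len(k), p)])
    if (length(labels) - agree < best) {
      best <- length(labels) - agree
      best_p <- p
    }
  }
  structure(as.integer(best),
            mapping = stats::setNames(tu[best_p], as.character(lu)))
}

#' Flag outlier wells by z-score
#'
#' Flags wells whose volume deviates from the population mean by more than
#' `z` standard deviations; when cluster labels exist the criterion is
#' applied within each cluster (each well type has its own distribution).
#' A zero standard deviation yields no flags, with a warning.
#'
#' @param wells a [WellPopulation-class] (>= 10 wells).
#' @param z z-score threshold (default 3).
#' @return integer vector of flagged row indices into `wellTable(wells)`.
#' @export
flagOutliers <- function(wells, z = 3) {
  stopifnot(is(wells, "WellPopulation"))
  df <- wells@wells
  if (nrow(df) < 10L) stop("outlier flagging requires at least 10 wells")
  groups <- if (!is.null(df$cluster)) df$cluster else rep(1L, nrow(df))
  flagged <- integer(0)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    v <- df$volume_nL[idx]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("group ", g, " has zero volume sd; nothing flagged")
      next
    }
    flagged <- c(flagged, idx[abs(v - mean(v)) / s > z])
  }
  sort(flagged)
}

#' Write/read the per-well table as CSV
#' @param wells a [WellPopulation-class].
#' @param path CSV path.
#' @return population (read) or `path` invisibly (write).
#' @export
writeWells <- function(wells, path) {
  utils::write.csv(wells@wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWells
#' @export
readWells <- function(path) {
  WellPopulation(utils::read.csv(path))
}
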