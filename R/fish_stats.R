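# Pairwise 3D DNA FISH distance statistics: distance-class tables,
# exact condition comparisons, and empirical CDFs.

#' Euclidean distance between 3D points
#'
#' @param a,b Numeric length-3 vectors, or n x 3 matrices for row-wise
#'   distances (nm).
#' @return Euclidean distance(s) in nm.
#' @export
pairwise_distance <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) == nrow(b),
            all(is.finite(a)), all(is.finite(b)))
  d <- sqrt(rowSums((a - b)^2))
  if (length(d) == 1) unname(d) else d
}

#' A sample of inter-probe distances for one condition
#'
#' @param distances Non-negative distances (nm), one per nucleus.
#' @param condition Condition label.
#' @return Object of class `"DistanceSample"`.
#' @export
distance_sample <- function(distances, condition = "sample") {
  if (length(distances) < 1) stop("at least one distance is required")
  if (any(!is.finite(distances)) || any(distances < 0))
    stop("distances must be finite and non-negative")
  structure(list(condition = condition, distances = distances,
                 n = length(distances)),
            class = "DistanceSample")
}

#' Tabulate distances into proximity classes
#'
#' Counts distances into classes delimited by the given thresholds, upper
#' boundaries included in the lower class (the conventional classes are
#' `[0, 100]`, `(100, 200]` and `> 200` nm; distances at or below 200 nm are
#' the regime detectable as 5C contacts).
#'
#' @param sample A [distance_sample()] or numeric vector of distances (nm).
#' @param thresholds Strictly increasing class boundaries (nm); default
#'   `c(100, 200)`.
#' @return Object of class `"DistanceClassTable"`: named `counts` and
#'   `proportions` ordered from the nearest class to the farthest, plus `n`,
#'   `thresholds` and the `condition` label.
#' @export
classify_distances <- function(sample, thresholds = c(100, 200)) {
  if (is.numeric(sample)) sample <- distance_sample(sample)
  stopifnot(inherits(sample, "DistanceSample"))
  if (any(diff(thresholds) <= 0) || length(thresholds) < 1)
    stop("thresholds must be strictly increasing")
  breaks <- c(-Inf, thresholds, Inf)
  labs <- c(sprintf("<=%g", thresholds[1]),
            if (length(thresholds) > 1)
              sprintf("(%g,%g]", thresholds[-length(thresholds)],
                      thresholds[-1]),
            sprintf(">%g", thresholds[length(thresholds)]))
  cls <- cut(sample$distances, breaks = breaks, labels = labs, right = TRUE)
  counts <- as.vector(table(cls))
  names(counts) <- labs
  structure(list(counts = counts, proportions = counts / sample$n,
                 n = sample$n, thresholds = thresholds,
                 condition = sample$condition),
            class = "DistanceClassTable")
}

# star annotation convention for p-values
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Compare two conditions by exact test
#'
#' Fisher's exact test between two distance-class tables.  By default the
#' classes are collapsed at `collapse_at` nm into a 2 x 2 table
#' (close vs far, condition a vs b); `method = "full"` instead tests the
#' complete class table (2 x k).  Two-sided p-values sum the probabilities
#' of all tables, with the observed margins, at most as probable as the
#' observed one.
#'
#' @param table_a,table_b [classify_distances()] outputs with identical
#'   thresholds.
#' @param collapse_at Threshold (nm) used for the 2 x 2 collapse; must be
#'   one of the tables' thresholds.  Default 200.
#' @param method `"collapsed"` (2 x 2, default) or `"full"` (2 x k).
#' @return List with `p_value`, `stars`, the tested `table` and `flags`
#'   (degenerate margins give p = 1 with a flag).
#' @export
compare_conditions <- function(table_a, table_b, collapse_at = 200,
                               method = c("collapsed", "full")) {
  method <- match.arg(method)
  stopifnot(inherits(table_a, "DistanceClassTable"),
            inherits(table_b, "DistanceClassTable"))
  if (!identical(table_a$thresholds, table_b$thresholds))
    stop("tables were built with different thresholds")
  if (method == "collapsed") {
    k <- match(collapse_at, table_a$thresholds)
    if (is.na(k)) stop("collapse_at must be one of the class thresholds")
    close_a <- sum(table_a$counts[seq_len(k)])
    close_b <- sum(table_b$counts[seq_len(k)])
    tab <- matrix(c(close_a, table_a$n - close_a,
                    close_b, table_b$n - close_b),
                  nrow = 2,
                  dimnames = list(class = c("close", "far"),
                                  condition = c(table_a$condition,
                                                table_b$condition)))
  } else {
    tab <- cbind(table_a$counts, table_b$counts)
    dimnames(tab) <- list(class = names(table_a$counts),
                          condition = c(table_a$condition,
                                        table_b$condition))
  }
  flags <- character(0)
  if (any(rowSums(tab) == 0)) {
    flags <- "degenerate margin: all observations in one class in both conditions"
    p <- 1
  } else {
    p <- stats::fisher.test(tab)$p.value
  }
  list(p_value = min(p, 1), stars = significance_stars(p), table = tab,
       flags = flags)
}

#' Empirical cumulative distribution of distances
#'
#' @param sample A [distance_sample()] or numeric vector (nm).
#' @return `data.frame` with the sorted unique `distance` values and the
#'   right-continuous `cumulative_fraction` at each (the last is 1).
#' @export
distance_ecdf <- function(sample) {
  if (is.numeric(sample)) sample <- distance_sample(sample)
  stopifnot(inherits(sample, "DistanceSample"))
  x <- sort(unique(sample$distances))
  F <- stats::ecdf(sample$distances)
  data.frame(distance = x, cumulative_fraction = F(x))
}
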