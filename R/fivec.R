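# Post-alignment 5C contact-matrix processing.
#
# Stage order follows the assay's processing convention:
# noise removal (primer z-score filter) -> read scaling -> overlapping
# binning -> Sinkhorn-Knopp/ICE balancing, then expected-by-distance and
# anchored-window quantification on the processed matrix.

#' Construct a contact matrix
#'
#' @param counts Square numeric matrix of interaction counts; must be
#'   symmetric and non-negative.
#' @param intervals `data.frame` with columns `chr`, `start`, `end`
#'   (0-based half-open), one row per matrix row/column.
#' @param mask Logical validity vector per row/column; masked entries are
#'   excluded from all statistics.  Defaults to all valid.
#' @param status Processing state, one of `"raw"`, `"filtered"`, `"scaled"`,
#'   `"binned"`, `"balanced"`.
#' @param history Character vector of applied operations.
#' @return Object of class `"ContactMatrix"`.
#' @export
contact_matrix <- function(counts, intervals, mask = NULL, status = "raw",
                           history = character(0)) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) stop("counts must be square")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  asym <- abs(counts - t(counts))
  tol <- 1e-8 * max(1, max(abs(counts)))
  if (any(asym > tol)) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("matrix is not symmetric: cell (%d, %d) = %g but (%d, %d) = %g",
                 ij[1], ij[2], counts[ij[1], ij[2]],
                 ij[2], ij[1], counts[ij[2], ij[1]]))
  }
  stopifnot(is.data.frame(intervals),
            all(c("chr", "start", "end") %in% names(intervals)),
            nrow(intervals) == n)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(is.logical(mask), length(mask) == n)
  structure(list(counts = counts, intervals = intervals, mask = mask,
                 status = status, history = history),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d x %d [%s], %d masked, total %.4g\n",
              nrow(x$counts), ncol(x$counts), x$status, sum(!x$mask),
              unmasked_total(x)))
  invisible(x)
}

#' @export
dim.ContactMatrix <- function(x) dim(x$counts)

# total counts over valid rows/columns
unmasked_total <- function(mat) {
  v <- mat$mask
  sum(mat$counts[v, v, drop = FALSE])
}

#' Filter outlier primers by cis/trans z-score
#'
#' Primers with very low or excessive interaction totals are masked.  Per
#' primer, the cis (same-chromosome) and trans (different-chromosome)
#' interaction totals are computed over currently valid primers,
#' log1p-transformed (raw totals are heavy-tailed), and z-scored across
#' primers; a primer is masked when |z_cis| > `cis_z` or |z_trans| >
#' `trans_z`.  When the matrix contains a single chromosome the trans filter
#' is skipped with a message.
#'
#' @param mat A `"ContactMatrix"` with raw counts.
#' @param cis_z,trans_z Two-sided z-score thresholds (defaults 6 and 12).
#' @return The matrix with an updated mask and status `"filtered"`.
#' @export
filter_primers <- function(mat, cis_z = 6, trans_z = 12) {
  stopifnot(inherits(mat, "ContactMatrix"))
  v <- mat$mask
  if (sum(v) < 3) stop("fewer than 3 valid primers: cannot compute z-scores")
  chr <- mat$intervals$chr
  same_chr <- outer(chr, chr, "==")
  A <- mat$counts
  A[!v, ] <- 0; A[, !v] <- 0
  cis_tot <- rowSums(A * same_chr)
  zs <- function(x) {
    lx <- log1p(x[v])
    s <- stats::sd(lx)
    z <- rep(0, length(x))
    if (s > 0) z[v] <- (log1p(x[v]) - mean(lx)) / s
    z
  }
  drop <- abs(zs(cis_tot)) > cis_z
  if (any(!same_chr[v, v])) {
    trans_tot <- rowSums(A * !same_chr)
    drop <- drop | abs(zs(trans_tot)) > trans_z
  } else {
    message("single-chromosome matrix: trans z-score filter skipped")
  }
  mat$mask <- v & !drop
  mat$status <- "filtered"
  mat$history <- c(mat$history, sprintf("filter_primers(cis_z=%g, trans_z=%g): %d masked",
                                        cis_z, trans_z, sum(v & drop)))
  mat
}

#' Scale a matrix to a target read total
#'
#' Read-normalization across samples: every entry is multiplied by
#' `target_total / current unmasked total`, so samples scaled to the same
#' target have equal unmasked sums.
#'
#' @param mat A `"ContactMatrix"`.
#' @param target_total Desired total over valid entries (> 0).
#' @return The rescaled matrix, status `"scaled"`.
#' @export
scale_reads <- function(mat, target_total) {
  stopifnot(inherits(mat, "ContactMatrix"), target_total > 0)
  tot <- unmasked_total(mat)
  if (tot <= 0) stop("unmasked total is zero: nothing to scale")
  mat$counts <- mat$counts * (target_total / tot)
  mat$status <- "scaled"
  mat$history <- c(mat$history, sprintf("scale_reads(target_total=%g)", target_total))
  mat
}

#' Binning configuration
#'
#' Sliding bins of width `bin_width` advanced by `bin_width /
#' steps_per_bin`, so consecutive bins overlap by
#' `bin_width * (1 - 1/steps_per_bin)`; the conventional 15-kb bins with 8
#' steps give 1.875-kb steps and 13.125-kb overlaps.
#'
#' @param bin_width Bin width (bp), > 0.  Default 15000.
#' @param steps_per_bin Number of steps per bin width, >= 1.  Default 8.
#' @param aggregation `"sum"` (default; conserves totals under disjoint
#'   tiling) or `"mean"`.
#' @return Object of class `"BinningConfig"` with derived `step` and
#'   `overlap` (bp).
#' @export
binning_config <- function(bin_width = 15000, steps_per_bin = 8,
                           aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (steps_per_bin < 1) stop("steps_per_bin must be >= 1")
  step <- bin_width / steps_per_bin
  structure(list(bin_width = bin_width, steps_per_bin = as.integer(steps_per_bin),
                 step = step, overlap = bin_width - step,
                 aggregation = aggregation),
            class = "BinningConfig")
}

#' Bin a fragment-level matrix into overlapping genomic bins
#'
#' Bins of width `config$bin_width` start every `config$step` bp from the
#' leftmost fragment start.  A fragment belongs to every bin containing its
#' midpoint, and the binned entry (I, J) aggregates the counts of all valid
#' fragment pairs assigned to bins I and J.
#'
#' @param mat A fragment-level `"ContactMatrix"` (single chromosome).
#' @param config A [binning_config()].
#' @return A binned `"ContactMatrix"`; bins containing no valid fragment are
#'   masked.  The step size is recorded in attribute `"step"`.
#' @export
bin_matrix <- function(mat, config = binning_config()) {
  stopifnot(inherits(mat, "ContactMatrix"), inherits(config, "BinningConfig"))
  iv <- mat$intervals
  if (length(unique(iv$chr)) != 1)
    stop("bin_matrix expects a single-chromosome matrix")
  frag_len <- max(iv$end - iv$start)
  if (config$bin_width < frag_len)
    warning("bin_width is smaller than the largest fragment")
  region_start <- min(iv$start); region_end <- max(iv$end)
  nb <- ceiling((region_end - region_start) / config$step)
  starts <- region_start + config$step * (seq_len(nb) - 1)
  starts <- starts[starts < region_end]
  ends <- pmin(starts + config$bin_width, region_end)
  mid <- (iv$start + iv$end) / 2
  # membership: fragment f in bin b iff its midpoint lies in [start_b, end_b)
  memb <- outer(starts, mid, "<=") & outer(ends, mid, ">")
  v <- mat$mask
  memb_v <- memb & rep(v, each = length(starts))
  Mm <- memb_v * 1
  A <- mat$counts
  A[!v, ] <- 0; A[, !v] <- 0
  binned <- Mm %*% A %*% t(Mm)
  if (config$aggregation == "mean") {
    npairs <- Mm %*% matrix(1, nrow(A), ncol(A)) %*% t(Mm)
    binned <- ifelse(npairs > 0, binned / npairs, 0)
  }
  bin_mask <- rowSums(Mm) > 0
  out <- contact_matrix(binned,
                        data.frame(chr = iv$chr[1], start = starts, end = ends),
                        mask = bin_mask, status = "binned",
                        history = c(mat$history,
                                    sprintf("bin_matrix(width=%g, steps=%d, step=%g, overlap=%g, %s)",
                                            config$bin_width, config$steps_per_bin,
                                            config$step, config$overlap,
                                            config$aggregation)))
  attr(out, "step") <- config$step
  out
}

#' Balance a matrix with the Sinkhorn-Knopp / ICE iteration
#'
#' Iteratively divides every row and column by (its sum / mean of valid
#' sums) until all valid row sums agree to within `tol` relative, removing
#' multiplicative per-locus biases: after convergence the total interaction
#' count per locus is the same.  Symmetry is preserved exactly (rows and
#' columns are corrected by the same factors).
#'
#' @param mat A `"ContactMatrix"` (typically binned).
#' @param tol Convergence tolerance on the maximum relative deviation of
#'   valid row sums from their mean.  Default 1e-5.
#' @param max_iter Maximum iterations (default 200); non-convergence is
#'   flagged in the history and as attribute `"converged"`.
#' @return The balanced matrix (status `"balanced"`) with attributes
#'   `"ice_bias"` (the accumulated per-row correction factors, proportional
#'   to the multiplicative biases removed), `"converged"` and
#'   `"iterations"`.  All-zero valid rows are masked with a message.
#' @export
ice_balance <- function(mat, tol = 1e-5, max_iter = 200) {
  stopifnot(inherits(mat, "ContactMatrix"))
  v <- mat$mask
  A <- mat$counts
  zero_rows <- v & (rowSums(A[, v, drop = FALSE]) == 0)
  if (any(zero_rows)) {
    message(sprintf("%d all-zero rows masked before balancing", sum(zero_rows)))
    v <- v & !zero_rows
  }
  if (sum(v) < 2) stop("fewer than 2 valid rows: cannot balance")
  W <- A[v, v, drop = FALSE]
  bias <- rep(1, sum(v))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    s <- rowSums(W)
    m <- mean(s)
    if (max(abs(s / m - 1)) < tol) { converged <- TRUE; break }
    f <- s / m
    W <- W / outer(f, f)
    bias <- bias * f
  }
  A[v, v] <- W
  out_bias <- rep(NA_real_, length(v))
  out_bias[v] <- bias
  mat$counts <- A
  mat$mask <- v
  mat$status <- "balanced"
  mat$history <- c(mat$history,
                   sprintf("ice_balance(tol=%g): %s in %d iterations",
                           tol, if (converged) "converged" else "NOT converged", it))
  if (!converged) warning("ICE balancing did not converge within max_iter")
  attr(mat, "ice_bias") <- out_bias
  attr(mat, "converged") <- converged
  attr(mat, "iterations") <- it
  mat
}

#' Expected interaction by genomic distance
#'
#' Estimates the expected interaction count as a smooth function of genomic
#' separation by locally weighted regression (LOWESS) of log mean count on
#' log separation, over the per-distance means of valid off-diagonal pairs.
#'
#' @param mat A binned/balanced `"ContactMatrix"`.
#' @param lowess_frac LOWESS smoother span (default 0.3).
#' @return Object of class `"ExpectedModel"`: a `data.frame` `fit` with
#'   columns `distance` (bp) and `expected`, plus an interpolating
#'   `predict()` method.  Requires >= 10 distinct separations.
#' @export
expected_by_distance <- function(mat, lowess_frac = 0.3) {
  stopifnot(inherits(mat, "ContactMatrix"))
  v <- mat$mask
  iv <- mat$intervals
  mid <- (iv$start + iv$end) / 2
  idx <- which(v)
  pairs <- which(upper.tri(mat$counts), arr.ind = TRUE)
  pairs <- pairs[v[pairs[, 1]] & v[pairs[, 2]], , drop = FALSE]
  d <- abs(mid[pairs[, 1]] - mid[pairs[, 2]])
  val <- mat$counts[pairs]
  mu <- tapply(val, d, mean)
  dd <- as.numeric(names(mu))
  keep <- mu > 0 & dd > 0
  if (sum(keep) < 10)
    stop("fewer than 10 distinct separations with positive mean counts")
  fit <- stats::lowess(log(dd[keep]), log(mu[keep]), f = lowess_frac)
  out <- data.frame(distance = exp(fit$x), expected = exp(fit$y))
  structure(list(fit = out, lowess_frac = lowess_frac), class = "ExpectedModel")
}

#' Predict expected counts at given separations
#'
#' @param object An `"ExpectedModel"`.
#' @param distance Genomic separations (bp).
#' @param ... Unused.
#' @return Expected interaction values (log-log interpolation, constant
#'   extrapolation beyond the fitted range).
#' @export
predict.ExpectedModel <- function(object, distance, ...) {
  exp(stats::approx(log(object$fit$distance), log(object$fit$expected),
                    xout = log(distance), rule = 2)$y)
}

#' Observed-over-expected matrix
#'
#' @param mat A `"ContactMatrix"`.
#' @param model An `"ExpectedModel"` (defaults to one fitted from `mat`).
#' @return A `"ContactMatrix"` whose valid off-diagonal entries are divided
#'   by the expected value at their separation.
#' @export
observed_over_expected <- function(mat, model = expected_by_distance(mat)) {
  iv <- mat$intervals
  mid <- (iv$start + iv$end) / 2
  D <- abs(outer(mid, mid, "-"))
  E <- matrix(1, nrow(D), ncol(D))
  off <- D > 0
  E[off] <- predict(model, D[off])
  mat$counts <- mat$counts / E
  diag(mat$counts) <- 0
  mat$history <- c(mat$history, "observed_over_expected")
  mat
}

#' Mean interaction count versus genomic separation
#'
#' The distance-decay curve: for each bin offset, the mean count over valid
#' pairs at that offset.
#'
#' @param mat A binned `"ContactMatrix"`.
#' @return `data.frame` with `offset` (bins), `separation` (bp, median
#'   midpoint separation at that offset) and `mean_count`.
#' @export
counts_vs_distance <- function(mat) {
  stopifnot(inherits(mat, "ContactMatrix"))
  v <- mat$mask
  mid <- (mat$intervals$start + mat$intervals$end) / 2
  n <- nrow(mat$counts)
  res <- lapply(seq_len(n - 1), function(k) {
    i <- seq_len(n - k); j <- i + k
    ok <- v[i] & v[j]
    if (!any(ok)) return(NULL)
    data.frame(offset = k,
               separation = stats::median(abs(mid[j[ok]] - mid[i[ok]])),
               mean_count = mean(mat$counts[cbind(i[ok], j[ok])]))
  })
  do.call(rbind, res)
}

#' Define an anchored window
#'
#' @param name Anchor label (e.g. an ERBS or a TSS).
#' @param summit Anchor position (bp).
#' @param half_width Window half-width (bp); the window is
#'   `[summit - half_width, summit + half_width)`.  Default 10000.
#' @return Object of class `"AnchorWindow"`.
#' @export
anchor_window <- function(name, summit, half_width = 10000) {
  if (half_width <= 0) stop("half_width must be > 0")
  structure(list(name = name, summit = summit, half_width = half_width),
            class = "AnchorWindow")
}

#' Quantify interactions between two anchored windows
#'
#' Collects every valid matrix entry (i, j) whose bin i intersects window
#' `a` and bin j intersects window `b`; these per-cell values feed violin
#' plots, and their mean is the window interaction score.  Symmetric in the
#' two windows.
#'
#' @param mat A `"ContactMatrix"`.
#' @param a,b [anchor_window()] objects.
#' @return List with `values`, `mean`, `n_cells` and `flags`.
#' @export
window_interaction <- function(mat, a, b) {
  stopifnot(inherits(mat, "ContactMatrix"),
            inherits(a, "AnchorWindow"), inherits(b, "AnchorWindow"))
  iv <- mat$intervals
  hit <- function(w) {
    ws <- w$summit - w$half_width; we <- w$summit + w$half_width
    if (we <= min(iv$start) || ws >= max(iv$end))
      stop(sprintf("window '%s' [%g, %g) lies outside the matrix extent",
                   w$name, ws, we))
    which(iv$start < we & iv$end > ws)
  }
  ia <- hit(a); ib <- hit(b)
  v <- mat$mask
  ia <- ia[v[ia]]; ib <- ib[v[ib]]
  flags <- character(0)
  if (!length(ia) || !length(ib)) {
    flags <- "all bins in one window are masked"
    return(list(values = numeric(0), mean = NA_real_, n_cells = 0L,
                flags = flags))
  }
  vals <- as.vector(mat$counts[ia, ib, drop = FALSE])
  list(values = vals, mean = mean(vals), n_cells = length(vals),
       flags = flags)
}

#' Run the full 5C processing chain
#'
#' Applies the stages in the fixed order filter -> scale -> bin -> balance,
#' recording each operation and its parameters in the matrix history.
#'
#' @param mat A raw `"ContactMatrix"`.
#' @param cis_z,trans_z Primer-filter thresholds (defaults 6, 12).
#' @param target_total Read-scaling target; `NULL` keeps the current total.
#' @param config A [binning_config()].
#' @param tol,max_iter ICE parameters.
#' @return The processed `"ContactMatrix"` (status `"balanced"`).
#' @export
process_fivec <- function(mat, cis_z = 6, trans_z = 12, target_total = NULL,
                          config = binning_config(), tol = 1e-5,
                          max_iter = 200) {
  stopifnot(inherits(mat, "ContactMatrix"))
  if (mat$status != "raw")
    stop("process_fivec expects a raw matrix (got status '", mat$status, "')")
  m <- filter_primers(mat, cis_z = cis_z, trans_z = trans_z)
  if (is.null(target_total)) target_total <- unmasked_total(m)
  m <- scale_reads(m, target_total)
  m <- bin_matrix(m, config)
  ice_balance(m, tol = tol, max_iter = max_iter)
}
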