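# Three-loci survival-zone triangulation.
#
# Three loci (labelled R, G, B after their fluorophores) are assumed to move,
# across the cell population, within coplanar disks ("survival zones").  The
# population min/max of each pairwise distance then determines the three disk
# radii in closed form, and the midranges determine the triangle of disk
# centers and the angle at G.

#' Build a triplet distance set
#'
#' Container for per-nucleus triplets of pairwise 3D distances among three
#' loci R, G and B, as measured by three-colour DNA FISH.
#'
#' @param d_RG,d_GB,d_RB Numeric vectors of equal length: one pairwise
#'   distance (nm) per nucleus.
#' @param nucleus_id Optional identifiers; defaults to `1:n`.
#' @param tol Relative tolerance for the triangle-inequality check.  Triplets
#'   violating the triangle inequality beyond `tol` are flagged in the
#'   `"violations"` attribute but kept (measurement noise can produce them);
#'   use `strict = TRUE` to drop them.
#' @param strict Drop flagged triplets instead of keeping them.
#' @return A `data.frame` of class `"TripletDistanceSet"` with columns
#'   `nucleus_id`, `d_RG`, `d_GB`, `d_RB` and attribute `violations`
#'   (integer row indices).
#' @export
triplet_distance_set <- function(d_RG, d_GB, d_RB, nucleus_id = NULL,
                                 tol = 1e-6, strict = FALSE) {
  n <- length(d_RG)
  if (n < 1L) stop("at least one triplet is required")
  if (length(d_GB) != n || length(d_RB) != n)
    stop("d_RG, d_GB and d_RB must have equal length")
  if (any(!is.finite(c(d_RG, d_GB, d_RB))) ||
      any(c(d_RG, d_GB, d_RB) < 0))
    stop("distances must be finite and non-negative")
  if (is.null(nucleus_id)) nucleus_id <- seq_len(n)
  # triangle inequality among the three pairwise distances of one nucleus
  scale <- pmax(d_RG, d_GB, d_RB, 1)
  bad <- which(d_RB > d_RG + d_GB + tol * scale |
               d_RG > d_RB + d_GB + tol * scale |
               d_GB > d_RG + d_RB + tol * scale)
  out <- data.frame(nucleus_id = nucleus_id,
                    d_RG = d_RG, d_GB = d_GB, d_RB = d_RB)
  if (strict && length(bad)) {
    out <- out[-bad, , drop = FALSE]
    if (nrow(out) == 0L) stop("all triplets violate the triangle inequality")
    bad <- integer(0)
  }
  structure(out, violations = bad,
            class = c("TripletDistanceSet", "data.frame"))
}

#' Summarize pairwise distance ranges
#'
#' Reduces a set of per-nucleus distance triplets to the per-pair minimum and
#' maximum (or, optionally, robust quantiles).  With the default quantiles
#' `(0, 1)` these are the exact sample min/max, which under the survival-zone
#' model converge (for large n) to the geometric extremes
#' `center_distance - r_a - r_b` and `center_distance + r_a + r_b`.
#'
#' @param triplets A [triplet_distance_set()].
#' @param lower_q,upper_q Quantiles used as "min" and "max"; defaults
#'   `(0, 1)` give the exact extremes.  A robust choice such as
#'   `(0.01, 0.99)` tempers sensitivity to outliers.
#' @return An object of class `"PairRanges"`: a list with elements
#'   `drgmin`, `drgmax`, `dgbmin`, `dgbmax`, `drbmin`, `drbmax` (nm) and `n`.
#' @export
summarize_ranges <- function(triplets, lower_q = 0, upper_q = 1) {
  stopifnot(is.data.frame(triplets), nrow(triplets) >= 1L)
  if (!(lower_q >= 0 && lower_q < upper_q && upper_q <= 1))
    stop("quantiles must satisfy 0 <= lower_q < upper_q <= 1")
  rng <- function(x) {
    if (lower_q == 0 && upper_q == 1) range(x)
    else unname(stats::quantile(x, c(lower_q, upper_q), type = 7))
  }
  rg <- rng(triplets$d_RG); gb <- rng(triplets$d_GB); rb <- rng(triplets$d_RB)
  pair_ranges(rg[1], rg[2], gb[1], gb[2], rb[1], rb[2], n = nrow(triplets))
}

#' Construct pairwise distance ranges directly
#'
#' @param drgmin,drgmax,dgbmin,dgbmax,drbmin,drbmax Extremes of the R-G, G-B
#'   and R-B distance distributions (nm).
#' @param n Optional number of observations the ranges summarize.
#' @return An object of class `"PairRanges"`.
#' @export
pair_ranges <- function(drgmin, drgmax, dgbmin, dgbmax, drbmin, drbmax,
                        n = NA_integer_) {
  v <- c(drgmin, drgmax, dgbmin, dgbmax, drbmin, drbmax)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all range bounds must be finite and non-negative")
  if (drgmax < drgmin || dgbmax < dgbmin || drbmax < drbmin)
    stop("each max must be >= the corresponding min")
  structure(list(drgmin = drgmin, drgmax = drgmax,
                 dgbmin = dgbmin, dgbmax = dgbmax,
                 drbmin = drbmin, drbmax = drbmax, n = n),
            class = "PairRanges")
}

#' Solve survival-zone radii from distance ranges
#'
#' The survival-zone model relates the population extremes of each pairwise
#' distance to the two disk radii involved: `drgmax = 2(Rr + Rg) + drgmin`,
#' and cyclically for the other pairs.  Solving the three linear relations
#' gives each radius as a signed quarter-sum of the six extremes, e.g.
#' `Rg = (drgmax + dgbmax - drbmax - drgmin - dgbmin + drbmin) / 4`.
#'
#' Raw radii can come out negative when the coplanar-disk model is violated
#' or n is small; such values are clamped to 0 and flagged, with the raw
#' values kept for diagnostics.
#'
#' @param ranges A [pair_ranges()] object.
#' @return List with `radius_R`, `radius_G`, `radius_B` (clamped, nm),
#'   `raw_radii` (named, pre-clamp) and `flags` (character).
#' @export
solve_radii <- function(ranges) {
  stopifnot(inherits(ranges, "PairRanges"))
  with(ranges, {
    Rg <- (drgmax + dgbmax - drbmax - drgmin - dgbmin + drbmin) / 4
    Rb <- (-drgmax + dgbmax + drbmax + drgmin - dgbmin - drbmin) / 4
    Rr <- (drgmax - dgbmax + drbmax - drgmin + dgbmin - drbmin) / 4
    raw <- c(radius_R = Rr, radius_G = Rg, radius_B = Rb)
    flags <- character(0)
    if (any(raw < 0))
      flags <- paste0("negative raw radius clamped to 0: ",
                      paste(names(raw)[raw < 0], collapse = ", "))
    list(radius_R = max(Rr, 0), radius_G = max(Rg, 0), radius_B = max(Rb, 0),
         raw_radii = raw, flags = flags)
  })
}

#' Solve center-triangle geometry from distance ranges
#'
#' The midrange of each pairwise distance estimates the distance between the
#' corresponding zone centers: `A` (R-B), `B` (G-B), `C` (R-G).  The angle
#' at G between the R-G and G-B axes follows from the law of cosines,
#' `cos(theta) = (C^2 + B^2 - A^2) / (2 C B)`.
#'
#' @param ranges A [pair_ranges()] object.
#' @return List with `midrange_A`, `midrange_B`, `midrange_C` (nm),
#'   `angle_theta` (degrees), `cos_theta`, and `flags`.  When `B` or `C` is
#'   zero the angle is undefined (`NA`) and flagged; a cosine outside
#'   `[-1, 1]` (possible under model violations) is clamped and flagged.
#' @export
solve_geometry <- function(ranges) {
  stopifnot(inherits(ranges, "PairRanges"))
  A <- (ranges$drbmax + ranges$drbmin) / 2
  B <- (ranges$dgbmax + ranges$dgbmin) / 2
  C <- (ranges$drgmax + ranges$drgmin) / 2
  flags <- character(0)
  if (B == 0 || C == 0) {
    flags <- "degenerate geometry: B or C is zero, angle undefined"
    return(list(midrange_A = A, midrange_B = B, midrange_C = C,
                angle_theta = NA_real_, cos_theta = NA_real_, flags = flags))
  }
  ct <- (C^2 + B^2 - A^2) / (2 * C * B)
  if (ct < -1 || ct > 1) {
    flags <- sprintf("cos(theta) = %.6g outside [-1, 1], clamped", ct)
    ct <- min(max(ct, -1), 1)
  }
  list(midrange_A = A, midrange_B = B, midrange_C = C,
       angle_theta = acos(ct) * 180 / pi, cos_theta = ct, flags = flags)
}

#' Full survival-zone solution
#'
#' Convenience wrapper combining [solve_radii()] and [solve_geometry()].
#'
#' @param x A `"PairRanges"` object or a `"TripletDistanceSet"` (in which
#'   case ranges are first summarized with the given quantiles).
#' @param lower_q,upper_q Passed to [summarize_ranges()] when `x` is a
#'   triplet set.
#' @return Object of class `"SurvivalZoneSolution"`: radii, raw radii,
#'   midranges, angle (degrees) and accumulated flags.
#' @export
solve_survival_zones <- function(x, lower_q = 0, upper_q = 1) {
  ranges <- if (inherits(x, "TripletDistanceSet"))
    summarize_ranges(x, lower_q, upper_q) else x
  stopifnot(inherits(ranges, "PairRanges"))
  rad <- solve_radii(ranges)
  geo <- solve_geometry(ranges)
  structure(c(rad[c("radius_R", "radius_G", "radius_B", "raw_radii")],
              geo[c("midrange_A", "midrange_B", "midrange_C",
                    "angle_theta", "cos_theta")],
              list(flags = c(rad$flags, geo$flags), ranges = ranges)),
            class = "SurvivalZoneSolution")
}

#' @export
print.SurvivalZoneSolution <- function(x, ...) {
  cat("Survival-zone solution\n")
  cat(sprintf("  radii (nm):     R = %.2f  G = %.2f  B = %.2f\n",
              x$radius_R, x$radius_G, x$radius_B))
  cat(sprintf("  midranges (nm): A(R-B) = %.2f  B(G-B) = %.2f  C(R-G) = %.2f\n",
              x$midrange_A, x$midrange_B, x$midrange_C))
  cat(sprintf("  angle at G:     %.2f degrees\n", x$angle_theta))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# Canonical 2D frame for the three zone centers: G at the origin, R on the
# positive x-axis at distance C, B at angle theta from the G->R axis at
# distance B.  The frame fixes the translation/rotation gauge freedom of the
# reconstruction.
zone_centers <- function(solution) {
  th <- solution$angle_theta * pi / 180
  rbind(R = c(solution$midrange_C, 0),
        G = c(0, 0),
        B = c(solution$midrange_B * cos(th), solution$midrange_B * sin(th)))
}

#' Build polar grids over the three survival disks
#'
#' Discretizes each survival disk as its center plus `n_radial` rings
#' (ring i at radius `r * i / n_radial`) times `n_angular` polar angles
#' (`2 * pi * j / n_angular`).  Grid points are enumerated center first,
#' then by increasing (radial, angular) index; this ordering is the
#' deterministic tie-break used by [reconstruct_positions()].
#'
#' @param solution A `"SurvivalZoneSolution"`.
#' @param n_radial,n_angular Number of radial rings N and polar angles M.
#' @return Named list (`R`, `G`, `B`) of `"ZoneGrid"` objects, each holding
#'   the disk `center`, `radius`, a `points` matrix (columns x, y; nm) and
#'   the `(i, j)` indices of each point (center is `(0, 0)`).
#' @export
build_zone_grids <- function(solution, n_radial = 20, n_angular = 36) {
  stopifnot(inherits(solution, "SurvivalZoneSolution"),
            n_radial >= 1, n_angular >= 1)
  centers <- zone_centers(solution)
  radii <- c(R = solution$radius_R, G = solution$radius_G,
             B = solution$radius_B)
  out <- lapply(c("R", "G", "B"), function(locus) {
    ctr <- centers[locus, ]
    r <- radii[[locus]]
    if (r == 0) {
      pts <- matrix(ctr, nrow = 1, dimnames = list(NULL, c("x", "y")))
      idx <- cbind(i = 0L, j = 0L)
    } else {
      ii <- rep(seq_len(n_radial), each = n_angular)
      jj <- rep(seq_len(n_angular), times = n_radial)
      ri <- r * ii / n_radial
      aj <- 2 * pi * jj / n_angular
      pts <- rbind(ctr,
                   cbind(ctr[1] + ri * cos(aj), ctr[2] + ri * sin(aj)))
      dimnames(pts) <- list(NULL, c("x", "y"))
      idx <- rbind(c(0L, 0L), cbind(i = ii, j = jj))
    }
    structure(list(center = ctr, radius = r, points = pts, index = idx),
              class = "ZoneGrid")
  })
  names(out) <- c("R", "G", "B")
  out
}

#' Reconstruct per-nucleus locus positions
#'
#' Exhaustive search over the three zone grids for the point combination
#' whose pairwise distances best match one observed distance triplet, in the
#' root-mean-square sense.  The three in-disk constraints are enforced by
#' construction (grid points never leave their disk).  Ties are broken by the
#' lowest grid-point index of the R locus, then G, then B, making the result
#' deterministic.
#'
#' @param triplet Numeric length-3: observed `(d_RG, d_GB, d_RB)` in nm.
#' @param grids Output of [build_zone_grids()].
#' @param infeasible_tol Residual (nm) above which the triplet is flagged as
#'   inconsistent with any in-zone configuration.
#' @return Object of class `"PositionSolution"`: `positions` (3 x 2 matrix,
#'   rows R, G, B), `residual` (RMS distance mismatch, nm), `indices` (chosen
#'   grid-point index per locus) and `flags`.
#' @export
reconstruct_positions <- function(triplet, grids, infeasible_tol = 1e-6) {
  stopifnot(length(triplet) == 3, all(is.finite(triplet)),
            is.list(grids), all(c("R", "G", "B") %in% names(grids)))
  PR <- grids$R$points; PG <- grids$G$points; PB <- grids$B$points
  if (nrow(PR) == 0L || nrow(PG) == 0L || nrow(PB) == 0L)
    stop("empty zone grid")
  t1 <- triplet[1]; t2 <- triplet[2]; t3 <- triplet[3]
  cross_dist <- function(P, Q) {
    # |P_i - Q_j| for all rows; small grids, so outer products are fine
    sqrt(outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q))
  }
  DRG <- cross_dist(PR, PG)   # nR x nG
  DGB <- cross_dist(PG, PB)   # nG x nB
  E3 <- (cross_dist(PR, PB) - t3)^2  # nR x nB
  best <- Inf; best_idx <- c(NA_integer_, NA_integer_, NA_integer_)
  nB <- nrow(PB)
  for (g in seq_len(nrow(PG))) {
    a <- (DRG[, g] - t1)^2
    b <- (DGB[g, ] - t2)^2
    cost <- outer(a, b, "+") + E3          # nR x nB
    k <- which.min(t(cost))                # ties -> lowest R index, then B
    r <- (k - 1L) %/% nB + 1L
    bb <- (k - 1L) %% nB + 1L
    cmin <- cost[r, bb]
    if (cmin < best ||
        (cmin == best && (r < best_idx[1] ||
          (r == best_idx[1] && g < best_idx[2]) ||
          (r == best_idx[1] && g == best_idx[2] && bb < best_idx[3])))) {
      best <- cmin
      best_idx <- c(r, g, bb)
    }
  }
  residual <- sqrt(best / 3)
  flags <- if (residual > infeasible_tol)
    sprintf("no in-zone configuration reproduces the triplet (residual %.3g nm)",
            residual) else character(0)
  pos <- rbind(R = PR[best_idx[1], ], G = PG[best_idx[2], ],
               B = PB[best_idx[3], ])
  colnames(pos) <- c("x", "y")
  structure(list(positions = pos, residual = residual,
                 indices = c(R = best_idx[1], G = best_idx[2],
                             B = best_idx[3]),
                 flags = flags),
            class = "PositionSolution")
}
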