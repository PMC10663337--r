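# Contact-arch and distance analysis of 3D bead-chain model ensembles.

#' Construct a model ensemble
#'
#' @param coords Numeric array of dimension `(n_particles, 3, n_models)`:
#'   xyz coordinates (nm) of every particle in every model.
#' @param bp_per_particle DNA content per particle (bp); default 5000.
#' @param bead_diameter Particle diameter (nm); default 50.
#' @param origin_chr,origin_start Genomic anchor of particle 1: particle k
#'   spans `[origin_start + (k-1)*bp, origin_start + k*bp)` on `origin_chr`.
#' @return Object of class `"ModelEnsemble"`.
#' @export
model_ensemble <- function(coords, bp_per_particle = 5000, bead_diameter = 50,
                           origin_chr = "chrS", origin_start = 0) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  structure(list(coords = coords,
                 n_particles = dim(coords)[1],
                 n_models = dim(coords)[3],
                 bp_per_particle = bp_per_particle,
                 bead_diameter = bead_diameter,
                 origin_chr = origin_chr, origin_start = origin_start),
            class = "ModelEnsemble")
}

#' @export
print.ModelEnsemble <- function(x, ...) {
  cat(sprintf("ModelEnsemble: %d models x %d particles (%g bp, %g nm per bead), %s:%d\n",
              x$n_models, x$n_particles, x$bp_per_particle, x$bead_diameter,
              x$origin_chr, x$origin_start))
  invisible(x)
}

# distances between particles i and j across all models
.pair_distances <- function(ensemble, i, j) {
  di <- ensemble$coords[i, , , drop = FALSE] - ensemble$coords[j, , , drop = FALSE]
  sqrt(colSums(matrix(di, nrow = 3)^2))
}

#' Fraction of models in which two particles are in contact
#'
#' @param ensemble A `"ModelEnsemble"`.
#' @param i,j Particle indices.
#' @param threshold Contact distance threshold (nm); default 200.
#' @return Fraction of models with `d(i, j) < threshold`, in `[0, 1]`.
#'   `i == j` returns 1 with a warning (a particle is trivially in contact
#'   with itself).
#' @export
contact_fraction <- function(ensemble, i, j, threshold = 200) {
  stopifnot(inherits(ensemble, "ModelEnsemble"),
            i >= 1, i <= ensemble$n_particles,
            j >= 1, j <= ensemble$n_particles, threshold >= 0)
  if (i == j) {
    warning("i == j: contact fraction of a particle with itself is 1")
    return(1)
  }
  mean(.pair_distances(ensemble, i, j) < threshold)
}

# full particle x particle contact-fraction matrix
contact_fraction_matrix <- function(ensemble, threshold = 200) {
  P <- ensemble$n_particles
  acc <- matrix(0, P, P)
  for (m in seq_len(ensemble$n_models)) {
    dm <- as.matrix(stats::dist(ensemble$coords[, , m]))
    acc <- acc + (dm < threshold)
  }
  fr <- acc / ensemble$n_models
  diag(fr) <- 1
  fr
}

#' Call contact arches in an ensemble
#'
#' A contact arch links two particles whose distance is below
#' `distance_threshold` in at least `min_model_fraction` of the models.
#' Chain-adjacent pairs (within `exclude_within` beads) are excluded: they
#' are always in contact by construction.
#'
#' @param ensemble A `"ModelEnsemble"`.
#' @param distance_threshold Contact distance (nm); default 200.
#' @param min_model_fraction Minimum model fraction; default 0.5.
#' @param exclude_within Exclude pairs with `|i - j| <= exclude_within`;
#'   default 1.
#' @return `data.frame` with particle indices `i < j`, the contact
#'   `fraction`, and the genomic coordinates of both particles
#'   (`chr`, `start_a`, `end_a`, `start_b`, `end_b`).
#' @export
call_arches <- function(ensemble, distance_threshold = 200,
                        min_model_fraction = 0.5, exclude_within = 1) {
  stopifnot(inherits(ensemble, "ModelEnsemble"), distance_threshold > 0,
            min_model_fraction >= 0, min_model_fraction <= 1)
  if (ensemble$n_models < 1) stop("ensemble has no models")
  fr <- contact_fraction_matrix(ensemble, distance_threshold)
  P <- ensemble$n_particles
  pr <- which(upper.tri(fr), arr.ind = TRUE)
  pr <- pr[pr[, 2] - pr[, 1] > exclude_within, , drop = FALSE]
  keep <- fr[pr] >= min_model_fraction
  pr <- pr[keep, , drop = FALSE]
  bp <- ensemble$bp_per_particle
  data.frame(i = pr[, 1], j = pr[, 2], fraction = fr[pr],
             chr = ensemble$origin_chr,
             start_a = ensemble$origin_start + (pr[, 1] - 1) * bp,
             end_a = ensemble$origin_start + pr[, 1] * bp,
             start_b = ensemble$origin_start + (pr[, 2] - 1) * bp,
             end_b = ensemble$origin_start + pr[, 2] * bp)
}

#' Differential arches between two conditions
#'
#' Per particle pair, the change in contact fraction from ensemble `a` to
#' ensemble `b` is `delta = fraction_b - fraction_a`; pairs with
#' `delta >= differential_delta` are labelled `"increased"`, those with
#' `delta <= -differential_delta` `"decreased"`, the rest `"unchanged"`
#' (the conventional delta is an absolute change of 0.20 in model
#' fraction).
#'
#' @param ensemble_a,ensemble_b `"ModelEnsemble"` objects with identical
#'   particle counts (e.g. hormone-starved vs treated).
#' @param distance_threshold Contact distance (nm); default 200.
#' @param differential_delta Minimum absolute change in model fraction;
#'   default 0.20.
#' @param exclude_within Exclude chain-adjacent pairs as in [call_arches()].
#' @return `data.frame` with `i`, `j`, `fraction_a`, `fraction_b`, `delta`
#'   and `label`.
#' @export
differential_arches <- function(ensemble_a, ensemble_b,
                                distance_threshold = 200,
                                differential_delta = 0.20,
                                exclude_within = 1) {
  stopifnot(inherits(ensemble_a, "ModelEnsemble"),
            inherits(ensemble_b, "ModelEnsemble"))
  if (ensemble_a$n_particles != ensemble_b$n_particles)
    stop("ensembles have different particle counts")
  fa <- contact_fraction_matrix(ensemble_a, distance_threshold)
  fb <- contact_fraction_matrix(ensemble_b, distance_threshold)
  pr <- which(upper.tri(fa), arr.ind = TRUE)
  pr <- pr[pr[, 2] - pr[, 1] > exclude_within, , drop = FALSE]
  delta <- fb[pr] - fa[pr]
  # fractions are ratios of small integers; compare with a float guard so a
  # change of exactly delta (e.g. 14/20 - 10/20 vs 0.20) counts as reaching it
  eps <- 1e-9
  label <- ifelse(delta >= differential_delta - eps, "increased",
                  ifelse(delta <= -(differential_delta - eps), "decreased",
                         "unchanged"))
  data.frame(i = pr[, 1], j = pr[, 2],
             fraction_a = fa[pr], fraction_b = fb[pr],
             delta = delta, label = label)
}

#' Map a genomic interval to ensemble particles
#'
#' @param ensemble A `"ModelEnsemble"`.
#' @param chr,start,end Genomic interval (0-based half-open).
#' @param name Fosmid/probe name.
#' @return Object of class `"FosmidMapping"`: the interval and the indices
#'   of all particles whose genomic span overlaps it.
#' @export
map_interval_to_particles <- function(ensemble, chr, start, end,
                                      name = "fosmid") {
  stopifnot(inherits(ensemble, "ModelEnsemble"), end > start)
  bp <- ensemble$bp_per_particle
  p_start <- ensemble$origin_start + (seq_len(ensemble$n_particles) - 1) * bp
  p_end <- p_start + bp
  hit <- which(chr == ensemble$origin_chr & p_start < end & p_end > start)
  if (!length(hit))
    stop(sprintf("interval %s:%g-%g does not overlap the modeled region",
                 chr, start, end))
  structure(list(name = name, chr = chr, start = start, end = end,
                 particles = hit),
            class = "FosmidMapping")
}

#' Inter-fosmid distance distribution over an ensemble
#'
#' Per model, the Euclidean distance between the two fosmids' positions; a
#' fosmid spanning several particles is located at the unweighted center of
#' mass of its particles.
#'
#' @param ensemble A `"ModelEnsemble"`.
#' @param a,b `"FosmidMapping"` objects (see [map_interval_to_particles()]).
#' @return List with `distances` (nm, one per model) and `summary`
#'   (box-plot five-number statistics plus the mean).
#' @export
fosmid_distance <- function(ensemble, a, b) {
  stopifnot(inherits(ensemble, "ModelEnsemble"),
            inherits(a, "FosmidMapping"), inherits(b, "FosmidMapping"))
  if (!length(a$particles) || !length(b$particles))
    stop("empty particle list in fosmid mapping")
  com <- function(idx) {
    # (3 x n_models) center of mass of the fosmid's particles per model
    apply(ensemble$coords[idx, , , drop = FALSE], c(2, 3), mean)
  }
  d <- sqrt(colSums((com(a$particles) - com(b$particles))^2))
  fv <- stats::fivenum(d)
  list(distances = d,
       summary = c(min = fv[1], lower_hinge = fv[2], median = fv[3],
                   upper_hinge = fv[4], max = fv[5], mean = mean(d)))
}
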