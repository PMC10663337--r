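# Synthetic-data generators.
#
# Every input the analysis stages consume can be generated here with the
# statistical structure those stages assume: coplanar disk-confined loci for
# the three-loci method, power-law distance-decay contact matrices with TAD
# blocks, loops and multiplicative primer biases, two-condition bead-chain
# ensembles with planted folded pairs, and coverage tracks with a
# promoter-proximal peak.

#' Define a three-loci scenario
#'
#' Ground truth for the survival-zone model: three disk centers placed in a
#' plane (G at the origin, R at `center_RG_distance` on the x-axis, B at
#' `center_angle_at_G` degrees from the G->R axis at `center_GB_distance`),
#' each locus confined to a disk of the given radius.
#'
#' @param center_RG_distance,center_GB_distance Center separations (nm).
#' @param center_angle_at_G Angle at G between the G->R and G->B axes
#'   (degrees).
#' @param radius_R,radius_G,radius_B Survival-zone radii (nm), all >= 0.
#' @param n_nuclei Number of nuclei (independent draws), >= 1.
#' @param localization_noise_sd Isotropic Gaussian noise sd (nm) added to
#'   each coordinate before distances are computed; 0 disables noise.
#' @param seed Integer seed for reproducible draws.
#' @param enforce_separation Require every pair of disks to be disjoint along
#'   the inter-center segment (center distance > sum of the two radii); the
#'   closed-form inversion assumes this.
#' @param sampling `"disk"` (coplanar, the model's geometry) or `"sphere"`
#'   (3D balls, for robustness studies).
#' @return Object of class `"TriLociScenario"`.
#' @export
tri_loci_scenario <- function(center_RG_distance, center_GB_distance,
                              center_angle_at_G,
                              radius_R, radius_G, radius_B,
                              n_nuclei, localization_noise_sd = 0,
                              seed = NULL, enforce_separation = TRUE,
                              sampling = c("disk", "sphere")) {
  sampling <- match.arg(sampling)
  radii <- c(R = radius_R, G = radius_G, B = radius_B)
  if (any(radii < 0)) stop("radii must be >= 0")
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  if (localization_noise_sd < 0) stop("noise sd must be >= 0")
  th <- center_angle_at_G * pi / 180
  centers <- rbind(R = c(center_RG_distance, 0),
                   G = c(0, 0),
                   B = center_GB_distance * c(cos(th), sin(th)))
  if (enforce_separation) {
    pairs <- list(c("R", "G"), c("G", "B"), c("R", "B"))
    for (p in pairs) {
      d <- sqrt(sum((centers[p[1], ] - centers[p[2], ])^2))
      if (d <= radii[p[1]] + radii[p[2]])
        stop(sprintf(
          "survival zones %s and %s overlap: center distance %.1f nm <= %.1f nm (sum of radii); shrink the radii or move the centers apart",
          p[1], p[2], d, radii[p[1]] + radii[p[2]]))
    }
  }
  structure(list(centers = centers, radii = radii,
                 center_angle_at_G = center_angle_at_G,
                 n_nuclei = as.integer(n_nuclei),
                 localization_noise_sd = localization_noise_sd,
                 seed = seed, sampling = sampling),
            class = "TriLociScenario")
}

# one uniform draw per disk (or ball), n rows of coordinates
.sample_zone <- function(center, radius, n, sampling) {
  if (sampling == "disk") {
    r <- radius * sqrt(stats::runif(n))
    a <- stats::runif(n) * 2 * pi
    cbind(center[1] + r * cos(a), center[2] + r * sin(a), 0)
  } else {
    r <- radius * stats::runif(n)^(1 / 3)
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    cbind(center[1] + r * v[, 1], center[2] + r * v[, 2], r * v[, 3])
  }
}

#' Generate per-nucleus distance triplets
#'
#' Forward model of the three-loci inverse problem: each locus is drawn
#' uniformly from its survival disk independently per nucleus, optional
#' localization noise is added to every coordinate, and the three pairwise
#' distances are recorded.
#'
#' @param scenario A [tri_loci_scenario()].
#' @return A `"TripletDistanceSet"` with `n_nuclei` rows.
#' @export
generate_triplets <- function(scenario) {
  stopifnot(inherits(scenario, "TriLociScenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n_nuclei
  P <- lapply(c("R", "G", "B"), function(l)
    .sample_zone(scenario$centers[l, ], scenario$radii[[l]], n,
                 scenario$sampling))
  names(P) <- c("R", "G", "B")
  if (scenario$localization_noise_sd > 0)
    P <- lapply(P, function(m)
      m + matrix(stats::rnorm(length(m), sd = scenario$localization_noise_sd),
                 nrow = n))
  d <- function(a, b) sqrt(rowSums((a - b)^2))
  triplet_distance_set(d_RG = d(P$R, P$G), d_GB = d(P$G, P$B),
                       d_RB = d(P$R, P$B))
}

#' Specify a synthetic contact matrix
#'
#' Describes a 5C-like symmetric count matrix: expected counts decay with
#' fragment separation as a power law, optionally enriched inside TAD blocks
#' and at anchored loops, modulated by multiplicative per-primer biases, and
#' Poisson-sampled.
#'
#' @param n_fragments Number of restriction fragments (matrix dimension).
#' @param fragment_size Fragment length (bp); fragments tile `chrS` from 0.
#' @param decay_exponent Power-law exponent of distance decay (> 0).
#' @param depth Expected count at separation 1, before enrichment and bias.
#' @param tad_blocks List of `c(start_idx, end_idx, enrichment)` triples;
#'   pairs with both fragments inside a block are multiplied by `enrichment`.
#' @param loops List of `c(idx_a, idx_b, enrichment)` triples.
#' @param bias_log_sd Standard deviation of log-normal per-primer biases
#'   (geometric mean normalized to 1); 0 disables biases.
#' @param overdispersion If > 0, counts are negative-binomial with this
#'   dispersion (`size = 1/overdispersion`) instead of Poisson.
#' @param seed Integer seed.
#' @return Object of class `"SyntheticMatrixSpec"`.
#' @export
synthetic_matrix_spec <- function(n_fragments, fragment_size = 4000,
                                  decay_exponent = 1, depth = 100,
                                  tad_blocks = list(), loops = list(),
                                  bias_log_sd = 0, overdispersion = 0,
                                  seed = NULL) {
  if (n_fragments < 1) stop("n_fragments must be >= 1")
  if (decay_exponent <= 0) stop("decay_exponent must be > 0")
  if (depth <= 0) stop("depth must be > 0")
  chk_idx <- function(i) all(i >= 1 & i <= n_fragments)
  for (b in tad_blocks) {
    if (length(b) != 3 || !chk_idx(b[1:2]) || b[3] <= 0)
      stop("each tad_block is c(start_idx, end_idx, enrichment > 0) within range")
  }
  for (l in loops) {
    if (length(l) != 3 || !chk_idx(l[1:2]) || l[3] <= 0)
      stop("each loop is c(idx_a, idx_b, enrichment > 0) within range")
  }
  structure(list(n_fragments = as.integer(n_fragments),
                 fragment_size = fragment_size,
                 decay_exponent = decay_exponent, depth = depth,
                 tad_blocks = tad_blocks, loops = loops,
                 bias_log_sd = bias_log_sd,
                 overdispersion = overdispersion, seed = seed),
            class = "SyntheticMatrixSpec")
}

#' Generate a synthetic contact matrix
#'
#' Expected count for a fragment pair (i, j), i != j, is
#' `depth * |i - j|^(-decay_exponent)` times any TAD-block or loop
#' enrichment, times `bias_i * bias_j`.  The diagonal is zero (5C does not
#' report self-ligation informatively).  Counts are Poisson (or
#' negative-binomial) draws on the upper triangle, mirrored to keep the
#' matrix exactly symmetric.
#'
#' @param spec A [synthetic_matrix_spec()].
#' @param sample If `FALSE`, return the noise-free expected matrix instead
#'   of count draws (useful for studying estimators in the large-depth
#'   limit).
#' @return A `"ContactMatrix"` (see [contact_matrix()]) with status
#'   `"raw"`.  The true bias vector is attached as attribute `"bias"`.
#' @export
generate_contact_matrix <- function(spec, sample = TRUE) {
  stopifnot(inherits(spec, "SyntheticMatrixSpec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_fragments
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  lambda <- spec$depth * ifelse(sep == 0, 0, sep^(-spec$decay_exponent))
  for (b in spec$tad_blocks) {
    idx <- seq(b[1], b[2])
    lambda[idx, idx] <- lambda[idx, idx] * b[3]
  }
  for (l in spec$loops) {
    lambda[l[1], l[2]] <- lambda[l[1], l[2]] * l[3]
    lambda[l[2], l[1]] <- lambda[l[2], l[1]] * l[3]
  }
  bias <- rep(1, n)
  if (spec$bias_log_sd > 0) {
    bias <- exp(stats::rnorm(n, 0, spec$bias_log_sd))
    bias <- bias / exp(mean(log(bias)))
  }
  lambda <- lambda * outer(bias, bias)
  counts <- lambda
  if (sample && n > 1) {
    up <- upper.tri(lambda)
    mu <- lambda[up]
    counts[up] <- if (spec$overdispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / spec$overdispersion)
    else stats::rpois(length(mu), mu)
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  }
  intervals <- data.frame(
    chr = "chrS",
    start = (seq_len(n) - 1L) * spec$fragment_size,
    end = seq_len(n) * spec$fragment_size)
  out <- contact_matrix(counts, intervals)
  attr(out, "bias") <- bias
  out
}

#' Specify a synthetic model ensemble
#'
#' Bead-chain ensembles mimicking restraint-based 3D models: freely jointed
#' random walks with a fixed step equal to the bead diameter, with selected
#' bead pairs "folded" to a target distance in a stated fraction of models.
#'
#' @param n_models,n_particles Ensemble dimensions.
#' @param bp_per_particle DNA content per bead (bp); default 5000.
#' @param bead_diameter Bead diameter and chain step length (nm); default 50.
#' @param folded_pairs List of `c(idx_a, idx_b, target_distance_nm,
#'   fraction_of_models)`.  Entries naming the same pair claim disjoint,
#'   consecutive model subsets, so complementary fractions can pin the same
#'   pair near in one subset and far in the rest.
#' @param origin_chr,origin_start Genomic anchor of particle 1.
#' @param seed Integer seed.
#' @return Object of class `"SyntheticEnsembleSpec"`.
#' @export
synthetic_ensemble_spec <- function(n_models, n_particles,
                                    bp_per_particle = 5000,
                                    bead_diameter = 50,
                                    folded_pairs = list(),
                                    origin_chr = "chrS", origin_start = 0,
                                    seed = NULL) {
  if (n_models < 1 || n_particles < 1) stop("n_models and n_particles >= 1")
  for (fp in folded_pairs) {
    if (length(fp) != 4) stop("each folded pair is c(idx_a, idx_b, target_nm, fraction)")
    if (any(fp[1:2] < 1) || any(fp[1:2] > n_particles) || fp[1] == fp[2])
      stop("folded pair indices must be distinct and within range")
    if (fp[3] < 0) stop("target distance must be >= 0")
    if (fp[4] < 0 || fp[4] > 1) stop("fraction must be in [0, 1]")
  }
  structure(list(n_models = as.integer(n_models),
                 n_particles = as.integer(n_particles),
                 bp_per_particle = bp_per_particle,
                 bead_diameter = bead_diameter,
                 folded_pairs = folded_pairs,
                 origin_chr = origin_chr, origin_start = origin_start,
                 seed = seed),
            class = "SyntheticEnsembleSpec")
}

#' Generate a synthetic model ensemble
#'
#' Each model is a freely jointed chain (uniform random step directions,
#' fixed step length `bead_diameter`).  For every folded pair the stated
#' fraction of models (rounded to the nearest integer, with a message when
#' rounding occurs) has the second bead rigidly repositioned at exactly the
#' target distance from the first, in a random direction.
#'
#' @param spec A [synthetic_ensemble_spec()].
#' @return A `"ModelEnsemble"` (see [model_ensemble()]).
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "SyntheticEnsembleSpec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  M <- spec$n_models; P <- spec$n_particles
  coords <- array(0, dim = c(P, 3, M))
  for (m in seq_len(M)) {
    v <- matrix(stats::rnorm(3 * (P - 1)), ncol = 3)
    if (P > 1) {
      v <- v / sqrt(rowSums(v^2)) * spec$bead_diameter
      coords[, , m] <- rbind(c(0, 0, 0), apply(v, 2, cumsum))
    }
  }
  used <- new.env()  # per-pair counter of already-claimed models
  for (fp in spec$folded_pairs) {
    key <- paste(fp[1], fp[2], sep = "_")
    offset <- if (is.null(used[[key]])) 0L else used[[key]]
    k_exact <- fp[4] * M
    k <- as.integer(round(k_exact))
    if (abs(k_exact - k) > 1e-9)
      message(sprintf("folded pair (%d, %d): fraction %.3f of %d models is not integral, using %d models",
                      fp[1], fp[2], fp[4], M, k))
    models <- seq_len(M)[seq_len(M) > offset][seq_len(k)]
    used[[key]] <- offset + k
    if (offset + k > M)
      stop("folded-pair fractions for one pair exceed 1 in total")
    for (m in models) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      coords[fp[2], , m] <- coords[fp[1], , m] + fp[3] * u
    }
  }
  model_ensemble(coords, bp_per_particle = spec$bp_per_particle,
                 bead_diameter = spec$bead_diameter,
                 origin_chr = spec$origin_chr,
                 origin_start = spec$origin_start)
}

#' Generate a piecewise-constant polymerase coverage track
#'
#' Emulates a promoter-proximally paused RNA Pol II profile: constant
#' `proximal_density` over the promoter-proximal window `[tss - 30,
#' tss + 300)` and constant `body_density` over the gene body
#' `[tss + 300, tes)`.
#'
#' @param tss,tes Transcription start and end sites (bp, 0-based); the gene
#'   body must be longer than 300 bp.
#' @param proximal_density,body_density Signal per base in each segment.
#' @param chrom Chromosome name.
#' @return A `"CoverageTrack"` over `[tss - 30, tes)`.
#' @export
generate_coverage <- function(tss, tes, proximal_density, body_density,
                              chrom = "chrS") {
  if (tes - tss <= 300)
    stop("gene must be longer than 300 bp (no gene body beyond TSS + 300)")
  if (proximal_density < 0 || body_density < 0)
    stop("densities must be >= 0")
  start <- tss - 30
  signal <- c(rep(proximal_density, 330), rep(body_density, tes - tss - 300))
  coverage_track(chrom, start, tes, signal)
}
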