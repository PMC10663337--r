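# Readers and writers for the formats the pipeline exchanges, plus the
# umbrella pipeline runner.  All genomic arithmetic is 0-based half-open
# internally; BED and bedGraph are read through rtracklayer and converted.

# parse "chr:start-end" labels into an interval data.frame
.parse_interval_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.+):([0-9]+)-([0-9]+)$", labels))
  bad <- which(vapply(m, length, 1L) != 4L)
  if (length(bad))
    stop("malformed interval label '", labels[bad[1]],
         "' (expected chr:start-end)")
  data.frame(chr = vapply(m, `[`, "", 2),
             start = as.numeric(vapply(m, `[`, "", 3)),
             end = as.numeric(vapply(m, `[`, "", 4)))
}

#' Read a contact matrix from a tab-delimited file
#'
#' Expects a square matrix with identical row and column headers of the
#' form `chr:start-end` (0-based half-open), as written by
#' [write_contact_matrix()].  Symmetry is validated on read.
#'
#' @param path File path.
#' @return A `"ContactMatrix"`.
#' @export
read_contact_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  if (nrow(tab) != ncol(tab))
    stop(sprintf("matrix is not square: %d rows but %d columns (header/body mismatch)",
                 nrow(tab), ncol(tab)))
  if (!identical(rownames(tab), colnames(tab)))
    stop("row and column headers differ")
  counts <- as.matrix(tab)
  intervals <- .parse_interval_labels(rownames(tab))
  if (any(intervals$end <= intervals$start))
    stop("interval with end <= start: input may be 1-based; labels must be 0-based half-open")
  contact_matrix(counts, intervals)
}

#' Write a contact matrix to a tab-delimited file
#'
#' @param mat A `"ContactMatrix"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "ContactMatrix"))
  labels <- sprintf("%s:%d-%d", mat$intervals$chr,
                    as.integer(mat$intervals$start),
                    as.integer(mat$intervals$end))
  tab <- mat$counts
  dimnames(tab) <- list(labels, labels)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' @param path BED3-BED6 file (0-based half-open).
#' @return `data.frame` with `chr`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chr = as.character(GenomeInfoDb::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr))
  mc <- as.data.frame(gr)
  for (col in intersect(c("name", "score"), names(mc))) out[[col]] <- mc[[col]]
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Read a coverage track from a bedGraph file
#'
#' Builds one per-base `"CoverageTrack"` spanning the given chromosome's
#' covered range; positions not covered by any bedGraph interval are treated
#' as 0 signal (a message reports the gap total).
#'
#' @param path bedGraph file (0-based half-open).
#' @param chrom Chromosome to extract; default: the only chromosome present.
#' @return A `"CoverageTrack"`.
#' @export
read_bedgraph <- function(path, chrom = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chr = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   score = gr$score)
  if (is.null(chrom)) {
    chrom <- unique(df$chr)
    if (length(chrom) != 1)
      stop("bedGraph covers several chromosomes; pass `chrom`")
  }
  df <- df[df$chr == chrom, , drop = FALSE]
  if (!nrow(df)) stop("no intervals on chromosome ", chrom)
  lo <- min(df$start); hi <- max(df$end)
  signal <- numeric(hi - lo)
  for (k in seq_len(nrow(df)))
    signal[(df$start[k] - lo + 1):(df$end[k] - lo)] <- df$score[k]
  covered <- sum(df$end - df$start)
  if (covered < hi - lo)
    message(sprintf("%d uncovered bases treated as 0 signal", hi - lo - covered))
  coverage_track(chrom, lo, hi, signal)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal signal are merged into single intervals.
#'
#' @param track A `"CoverageTrack"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "CoverageTrack"))
  r <- rle(track$signal)
  ends <- track$start + cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  utils::write.table(
    data.frame(track$chrom, starts, ends, r$values)[keep, , drop = FALSE],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a multi-model XYZ ensemble
#'
#' The dialect is one `MODEL k` line per model followed by one
#' `idx x y z` line per particle (nm).  All models must have the same
#' particle count.
#'
#' @param path File path.
#' @param ... Metadata passed to [model_ensemble()] (`bp_per_particle`,
#'   `bead_diameter`, `origin_chr`, `origin_start`).
#' @return A `"ModelEnsemble"`.
#' @export
read_xyz_ensemble <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^MODEL\\b", lines)
  if (!length(starts)) stop("no MODEL records found")
  bounds <- c(starts, length(lines) + 1L)
  models <- lapply(seq_along(starts), function(k) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    vals <- utils::read.table(text = block,
                              col.names = c("idx", "x", "y", "z"))
    as.matrix(vals[order(vals$idx), c("x", "y", "z")])
  })
  np <- vapply(models, nrow, 1L)
  if (length(unique(np)) != 1)
    stop("models have unequal particle counts: ",
         paste(unique(np), collapse = ", "))
  coords <- array(vapply(models, identity, matrix(0, np[1], 3)),
                  dim = c(np[1], 3, length(models)))
  model_ensemble(coords, ...)
}

#' Write a multi-model XYZ ensemble
#'
#' @param ensemble A `"ModelEnsemble"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ModelEnsemble"))
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(ensemble$n_models)) {
    writeLines(paste("MODEL", m), con)
    writeLines(sprintf("%d %.6g %.6g %.6g", seq_len(ensemble$n_particles),
                       ensemble$coords[, 1, m], ensemble$coords[, 2, m],
                       ensemble$coords[, 3, m]), con)
  }
  invisible(path)
}

#' Write / read per-nucleus distance triplets as CSV
#'
#' Columns: `nucleus_id`, `d_RG`, `d_GB`, `d_RB` (nm).
#'
#' @param triplets A `"TripletDistanceSet"`.
#' @param path File path.
#' @return `write_triplets`: `path`, invisibly; `read_triplets`: a
#'   `"TripletDistanceSet"`.
#' @export
write_triplets <- function(triplets, path) {
  stopifnot(inherits(triplets, "TripletDistanceSet"))
  utils::write.csv(as.data.frame(triplets), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_triplets
#' @export
read_triplets <- function(path) {
  df <- utils::read.csv(path)
  need <- c("nucleus_id", "d_RG", "d_GB", "d_RB")
  if (!all(need %in% names(df)))
    stop("triplet CSV must have columns ", paste(need, collapse = ", "))
  triplet_distance_set(df$d_RG, df$d_GB, df$d_RB, nucleus_id = df$nucleus_id)
}

#' Run the synthetic-to-processed pipeline from a configuration
#'
#' Executes, in fixed order, the stages requested by the configuration:
#' synthetic matrix generation, primer filtering, read scaling, binning and
#' ICE balancing, followed by optional expected-by-distance and
#' anchored-window quantification.  The configuration is a named list (or a
#' YAML file path) with blocks `synthetic` (arguments of
#' [synthetic_matrix_spec()]; alternatively `matrix_path` to read an
#' existing matrix), `fivec` (arguments of [process_fivec()]'s thresholds
#' and [binning_config()]), optional `windows` (list of two
#' [anchor_window()] argument lists), and `out_dir`.  Unknown keys are
#' rejected.
#'
#' @param config Named list or path to a YAML file.
#' @return A report list (echoed parameters, stage summaries, output file
#'   paths and their MD5 hashes), also written as `report.json` in
#'   `out_dir` when one is given.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("synthetic", "matrix_path", "fivec", "windows", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  report <- list(parameters = config, stages = list())

  if (!is.null(config$synthetic)) {
    spec <- do.call(synthetic_matrix_spec, config$synthetic)
    mat <- generate_contact_matrix(spec)
    report$stages$synthetic <- list(n_fragments = spec$n_fragments,
                                    seed = spec$seed,
                                    total_counts = sum(mat$counts) / 2)
  } else if (!is.null(config$matrix_path)) {
    mat <- read_contact_matrix(config$matrix_path)
    report$stages$input <- list(path = config$matrix_path,
                                n_fragments = nrow(mat$counts))
  } else stop("config must provide either `synthetic` or `matrix_path`")

  fv <- config$fivec
  if (!is.null(fv)) {
    cfg <- binning_config(bin_width = fv$bin_width %||% 15000,
                          steps_per_bin = fv$steps_per_bin %||% 8)
    mat <- process_fivec(mat,
                         cis_z = fv$cis_z %||% 6,
                         trans_z = fv$trans_z %||% 12,
                         target_total = fv$target_total,
                         config = cfg,
                         tol = fv$tol %||% 1e-5,
                         max_iter = fv$max_iter %||% 200)
    report$stages$fivec <- list(history = mat$history,
                                n_bins = nrow(mat$counts),
                                n_masked = sum(!mat$mask),
                                converged = attr(mat, "converged"))
  }

  if (!is.null(config$windows)) {
    wa <- do.call(anchor_window, config$windows[[1]])
    wb <- do.call(anchor_window, config$windows[[2]])
    wi <- window_interaction(mat, wa, wb)
    report$stages$windows <- list(a = wa$name, b = wb$name,
                                  mean = wi$mean, n_cells = wi$n_cells)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    mpath <- file.path(config$out_dir, "processed_matrix.tsv")
    write_contact_matrix(mat, mpath)
    report$outputs <- list(processed_matrix = mpath,
                           md5 = unname(tools::md5sum(mpath)))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
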