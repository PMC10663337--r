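# Coverage-track metrics: region densities and the RNA Pol II pausing index.

#' Construct a coverage track
#'
#' @param chrom Chromosome name.
#' @param start,end Interval covered (bp, 0-based half-open).
#' @param signal Per-base signal vector of length `end - start`, >= 0.
#' @return Object of class `"CoverageTrack"`.
#' @export
coverage_track <- function(chrom, start, end, signal) {
  if (end <= start) stop("end must be > start")
  if (length(signal) != end - start)
    stop("signal length must equal end - start")
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("signal must be finite and non-negative")
  structure(list(chrom = chrom, start = start, end = end, signal = signal),
            class = "CoverageTrack")
}

#' Mean per-base signal over a region
#'
#' @param track A `"CoverageTrack"`.
#' @param start,end Region (bp, 0-based half-open), within the track.
#' @return Mean signal per base over `[start, end)`.
#' @export
region_density <- function(track, start, end) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (end <= start) stop("end must be > start")
  if (start < track$start || end > track$end)
    stop(sprintf("region [%g, %g) outside track [%g, %g)",
                 start, end, track$start, track$end))
  idx <- seq(start - track$start + 1, end - track$start)
  mean(track$signal[idx])
}

#' Define a gene annotation
#'
#' @param chr Chromosome.
#' @param tss,tes Transcription start and end sites (bp).  For `+` strand
#'   genes `tes > tss`; for `-` strand genes the TSS is the larger
#'   coordinate (`tss > tes`).
#' @param strand `"+"` or `"-"`.
#' @return Object of class `"GeneAnnotation"`.
#' @export
gene_annotation <- function(chr, tss, tes, strand = "+") {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (strand == "+" && tes <= tss)
    stop("on the + strand, tes must be > tss")
  if (strand == "-" && tes >= tss)
    stop("on the - strand, tss must be > tes")
  structure(list(chr = chr, tss = tss, tes = tes, strand = strand),
            class = "GeneAnnotation")
}

#' RNA Pol II pausing index
#'
#' Ratio of polymerase density in the promoter-proximal window
#' `[TSS - 30, TSS + 300)` to the density over the transcribed region
#' `[TSS + 300, TES)` (windows reflected for minus-strand genes).  The index
#' is scale-invariant: normalizing the track does not change it.
#'
#' @param track A `"CoverageTrack"` covering both windows.
#' @param gene A [gene_annotation()]; the gene body must be longer than
#'   300 bp.
#' @return List with `index` (dimensionless; `Inf` with a flag when the
#'   body density is 0 and the proximal density is positive, `NaN` when
#'   both are 0), `proximal_density`, `body_density` and `flags`.
#' @export
pausing_index <- function(track, gene) {
  stopifnot(inherits(track, "CoverageTrack"), inherits(gene, "GeneAnnotation"))
  len <- abs(gene$tes - gene$tss)
  if (len <= 300)
    stop("gene shorter than 300 bp: no transcribed region beyond TSS + 300")
  if (gene$strand == "+") {
    prox <- c(gene$tss - 30, gene$tss + 300)
    body <- c(gene$tss + 300, gene$tes)
  } else {
    prox <- c(gene$tss - 300, gene$tss + 30)
    body <- c(gene$tes, gene$tss - 300)
  }
  pd <- region_density(track, prox[1], prox[2])
  bd <- region_density(track, body[1], body[2])
  flags <- character(0)
  if (bd == 0)
    flags <- "gene-body density is zero: pausing index undefined"
  list(index = pd / bd, proximal_density = pd, body_density = bd,
       flags = flags)
}
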