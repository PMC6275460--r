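#' Whole-track summary metrics
#'
#' Computes the chromosome length `G`, the depth of coverage (mean and
#' median of the per-base coverage), the population standard deviation
#' `sigma` (divide-by-N, descriptive), the coefficient of variation
#' `cv = sigma / doc_mean` and the breadth of coverage `boc` (fraction of
#' bases covered by at least one read). `centralness` and `W_used` are
#' filled in by the pipeline once z-scores exist.
#'
#' @param track A [coverage_track()].
#' @return A `SummaryStats` list.
#' @export
summary_stats <- function(track) {
  x <- as_coverage_vector(track)
  if (length(x) == 0L) stop("empty track")
  m <- mean(x)
  sigma <- sqrt(mean((x - m)^2))
  structure(list(
    G = length(x),
    doc_mean = m,
    doc_median = median(x),
    sigma = sigma,
    cv = if (m > 0) sigma / m else NA_real_,
    boc = mean(x >= 1),
    centralness = NA_real_,
    W_used = NA_integer_),
    class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat(sprintf("Coverage summary over %d bases\n", x$G))
  cat(sprintf("  DOC %.2fX (median %g), sigma %.2f, CV %.3f, BOC %.4f\n",
              x$doc_mean, x$doc_median, x$sigma, x$cv, x$boc))
  if (!is.na(x$centralness))
    cat(sprintf("  centralness %.4f (W = %d)\n", x$centralness, x$W_used))
  invisible(x)
}

#' GC content vs coverage 2-D histogram
#'
#' Per-base GC fraction is computed over a centred window of `gc_window`
#' bases (truncated at chromosome ends); ambiguous IUPAC bases are excluded
#' from both numerator and denominator, and a base whose window holds no
#' unambiguous base has undefined GC. The joint histogram of (GC%, coverage)
#' summarises compositional bias: regions of unusual GC often coincide with
#' depleted coverage.
#'
#' @param track A [coverage_track()].
#' @param reference Reference sequence for the same chromosome: a character
#'   string, a `Biostrings::DNAString`/`DNAStringSet`, or a FASTA file path
#'   (the record matching the track's chromosome name is used, else the
#'   first).
#' @param gc_window Odd window length for the GC fraction (default 101).
#' @param gc_breaks Breaks for the GC% axis (default 2% bins).
#' @param cov_breaks Breaks for the coverage axis (default 50 equal bins).
#' @return List with `counts` (matrix GC-bins x coverage-bins), `gc_breaks`,
#'   `cov_breaks` and `gc_percent` (the per-base GC vector, NA where
#'   undefined).
#' @export
gc_coverage_histogram <- function(track, reference, gc_window = 101L,
                                  gc_breaks = seq(0, 100, by = 2),
                                  cov_breaks = NULL) {
  seq_chars <- reference_as_chars(reference, track$chrom)
  n <- length(track$coverage)
  if (length(seq_chars) != n)
    stop("reference length (", length(seq_chars),
         ") does not match track length (", n, ")")
  gc_window <- as.integer(gc_window)
  if (gc_window < 1L || gc_window %% 2L == 0L)
    stop("gc_window must be a positive odd integer")
  is_gc <- as.numeric(seq_chars %in% c("G", "C", "g", "c", "S", "s"))
  is_acgt <- as.numeric(seq_chars %in%
                          c("A", "C", "G", "T", "a", "c", "g", "t"))
  is_gc[is_acgt == 0] <- 0   # ambiguous bases count in neither term
  V <- (gc_window - 1L) %/% 2L
  lo <- pmax(seq_len(n) - V, 1L); hi <- pmin(seq_len(n) + V, n)
  cs_gc <- c(0, cumsum(is_gc)); cs_ok <- c(0, cumsum(is_acgt))
  num <- cs_gc[hi + 1L] - cs_gc[lo]
  den <- cs_ok[hi + 1L] - cs_ok[lo]
  gc_pct <- ifelse(den > 0, 100 * num / den, NA_real_)

  defined <- !is.na(gc_pct)
  cov <- track$coverage[defined]
  if (is.null(cov_breaks))
    cov_breaks <- seq(0, max(cov, 1), length.out = 51L)
  gi <- cut(gc_pct[defined], breaks = gc_breaks, include.lowest = TRUE)
  ci <- cut(cov, breaks = cov_breaks, include.lowest = TRUE)
  list(counts = table(gc = gi, coverage = ci),
       gc_breaks = gc_breaks, cov_breaks = cov_breaks, gc_percent = gc_pct)
}

reference_as_chars <- function(reference, chrom) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA requires the Biostrings package")
    ss <- Biostrings::readDNAStringSet(reference)
    nm <- sub("\\s.*$", "", names(ss))
    i <- match(chrom, nm)
    if (is.na(i)) i <- 1L
    reference <- as.character(ss[[i]])
  } else if (methods::is(reference, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(reference))
    i <- match(chrom, nm)
    if (is.na(i)) i <- 1L
    reference <- as.character(reference[[i]])
  } else if (methods::is(reference, "DNAString")) {
    reference <- as.character(reference)
  }
  if (!is.character(reference) || length(reference) != 1L)
    stop("reference must be a sequence string, DNAString(Set) or FASTA path")
  strsplit(reference, "", fixed = TRUE)[[1L]]
}
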