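#' Build high/low-confidence zones from padded exome capture intervals
#'
#' Capture BED files are typically distributed with a flanking buffer already
#' added to each target (assumed 50 bp per side). Calls well inside the
#' target — within the unpadded capture region extended by `margin` bp — are
#' high confidence; the remaining `assumed_buffer - margin` bp at each end of
#' every padded interval are low confidence. At the defaults (buffer 50,
#' margin 10) each padded interval `[s, e)` yields a high zone
#' `[s + 40, e - 40)` and two 40 bp low flanks. Intervals too short to hold a
#' high zone (length <= `2 * (assumed_buffer - margin)`) are entirely low
#' confidence, with a warning.
#'
#' @param capture An [interval_set()] of padded capture intervals.
#' @param assumed_buffer Buffer (bp) assumed already present on each end of
#'   every distributed interval.
#' @param margin Extension (bp) past the unpadded capture region still
#'   considered high confidence.
#' @return A `confidence_zones` object with `high` and `low` interval sets
#'   partitioning the padded capture space.
#' @export
build_zones <- function(capture, assumed_buffer = 50L, margin = 10L) {
  stopifnot(assumed_buffer >= 0, margin >= 0, margin <= assumed_buffer)
  trim <- assumed_buffer - margin
  d <- as.data.frame(capture)  # merged, so zones cannot overlap across rows
  hi <- list(chrom = character(), start = numeric(), end = numeric())
  lo <- list(chrom = character(), start = numeric(), end = numeric())
  n_short <- 0L
  add <- function(zone, chrom, start, end) {
    if (end > start) {
      zone$chrom <- c(zone$chrom, chrom)
      zone$start <- c(zone$start, start)
      zone$end <- c(zone$end, end)
    }
    zone
  }
  for (i in seq_len(nrow(d))) {
    s <- d$start[i]; e <- d$end[i]
    if ((e - s) <= 2 * trim) {
      n_short <- n_short + 1L
      lo <- add(lo, d$chrom[i], s, e)
    } else {
      hi <- add(hi, d$chrom[i], s + trim, e - trim)
      lo <- add(lo, d$chrom[i], s, s + trim)
      lo <- add(lo, d$chrom[i], e - trim, e)
    }
  }
  if (n_short > 0) {
    warning(sprintf(
      "%d capture interval(s) shorter than %d bp are entirely low confidence",
      n_short, 2 * trim + 1))
  }
  structure(list(
    high = interval_set(hi$chrom, hi$start, hi$end),
    low = interval_set(lo$chrom, lo$start, lo$end),
    assumed_buffer = assumed_buffer, margin = margin),
    class = "confidence_zones")
}

#' @export
print.confidence_zones <- function(x, ...) {
  cat(sprintf("<confidence_zones: buffer %d bp, margin %d bp; high %g bp, low %g bp>\n",
              x$assumed_buffer, x$margin,
              interval_total_width(x$high), interval_total_width(x$low)))
  invisible(x)
}

#' Label DNVs by capture confidence zone
#'
#' Each DNV's 1-based position is point-queried against the zones:
#' `high` and `low` inside the padded capture space, `off_target` outside it.
#'
#' @param dnvs Candidate-DNV table (needs `chrom`, `pos`).
#' @param zones A `confidence_zones` object from [build_zones()].
#' @return `dnvs` with the `confidence` column filled.
#' @export
classify_dnvs <- function(dnvs, zones) {
  stopifnot(inherits(zones, "confidence_zones"))
  if (nrow(dnvs) == 0) {
    dnvs$confidence <- character(0)
    return(dnvs)
  }
  p0 <- dnvs$pos - 1  # 1-based VCF position -> 0-based point
  hi <- interval_overlaps(zones$high, dnvs$chrom, p0)
  lo <- interval_overlaps(zones$low, dnvs$chrom, p0)
  dnvs$confidence <- ifelse(hi, "high", ifelse(lo, "low", "off_target"))
  dnvs
}

#' Pileup rescue test for high-confidence exome DNVs
#'
#' A high-confidence DNV enters the final high-confidence callset only if,
#' in mpileup evidence taken at any base quality, the alternate allele never
#' appears in either parent and appears at least once in the child. DNVs
#' labelled `low` or `off_target` keep their label and are not subjected to
#' the test. Missing pileup evidence for any trio member drops the DNV with
#' the distinct audit code `no_pileup`.
#'
#' @param dnvs Candidate-DNV table with a `confidence` column
#'   ([classify_dnvs()]).
#' @param pileup Pileup counts (from [parse_mpileup()] or
#'   [read_pileup_tsv()]) covering the DNV sites for `child`, `father` and
#'   `mother`.
#' @return `dnvs` with the `rescue` column set for high-confidence rows:
#'   `retain`, `drop`, or `no_pileup`.
#' @export
pileup_rescue <- function(dnvs, pileup) {
  if (nrow(dnvs) == 0) {
    dnvs$rescue <- character(0)
    return(dnvs)
  }
  dnvs$rescue <- NA_character_
  idx <- which(!is.na(dnvs$confidence) & dnvs$confidence == "high")
  for (i in idx) {
    at <- pileup[pileup$chrom == dnvs$chrom[i] & pileup$pos == dnvs$pos[i], ]
    get <- function(role) at[at$sample == role, , drop = FALSE]
    ch <- get("child"); fa <- get("father"); mo <- get("mother")
    if (nrow(ch) == 0 || nrow(fa) == 0 || nrow(mo) == 0) {
      dnvs$rescue[i] <- "no_pileup"
    } else if (fa$alt_count[1] == 0 && mo$alt_count[1] == 0 &&
               ch$alt_count[1] >= 1) {
      dnvs$rescue[i] <- "retain"
    } else {
      dnvs$rescue[i] <- "drop"
    }
  }
  dnvs
}
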