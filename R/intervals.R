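#' Construct an interval set
#'
#' An `interval_set` is a per-contig collection of 0-based, half-open
#' `[start, end)` genomic intervals, stored sorted and merged (overlapping or
#' book-ended intervals are unioned). It backs the region blacklist and the
#' exome capture / confidence zones, and supports point and span overlap
#' queries.
#'
#' @param chrom,start,end Parallel vectors; `start`/`end` 0-based half-open.
#' @return An object of class `interval_set`.
#' @export
interval_set <- function(chrom = character(), start = integer(), end = integer()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  start <- as.numeric(start)
  end <- as.numeric(end)
  keep <- end > start
  chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  per <- list()
  for (ctg in unique(chrom)) {
    i <- chrom == ctg
    # IRanges is 1-based closed; shift and merge, then shift back
    ir <- IRanges::reduce(IRanges::IRanges(start[i] + 1, end[i]))
    per[[ctg]] <- data.frame(start = IRanges::start(ir) - 1,
                             end = IRanges::end(ir))
  }
  structure(list(intervals = per), class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  n <- sum(vapply(x$intervals, nrow, integer(1)))
  cat(sprintf("<interval_set: %d merged intervals on %d contig(s), %g bp>\n",
              n, length(x$intervals), interval_total_width(x)))
  invisible(x)
}

#' Total width of an interval set in bases
#' @param x An `interval_set`.
#' @return Numeric total width.
#' @export
interval_total_width <- function(x) {
  sum(vapply(x$intervals, function(d) sum(d$end - d$start), numeric(1)))
}

#' Flatten an interval set to a data.frame
#' @param x An `interval_set`.
#' @param ... Unused.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
as.data.frame.interval_set <- function(x, ...) {
  if (length(x$intervals) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  do.call(rbind, lapply(names(x$intervals), function(ctg) {
    cbind(chrom = ctg, x$intervals[[ctg]])
  }))
}

#' Test whether genomic spans overlap an interval set
#'
#' @param x An `interval_set`.
#' @param chrom Contig names.
#' @param start,end 0-based half-open query spans (for a point at 0-based
#'   position p use `start = p, end = p + 1`).
#' @return Logical vector: does each span overlap any stored interval?
#' @export
interval_overlaps <- function(x, chrom, start, end = start + 1) {
  n <- length(chrom)
  out <- logical(n)
  for (ctg in unique(chrom)) {
    d <- x$intervals[[ctg]]
    i <- which(chrom == ctg)
    if (is.null(d) || nrow(d) == 0) next
    subj <- IRanges::IRanges(d$start + 1, d$end)
    qry <- IRanges::IRanges(start[i] + 1, end[i])
    out[i] <- IRanges::overlapsAny(qry, subj)
  }
  out
}

#' Read a BED3+ file into an interval_set
#'
#' Standard 0-based half-open BED; columns beyond the third are ignored.
#' Zero-length intervals are dropped with a warning; `start > end` is fatal.
#'
#' @param path Path to a BED file.
#' @return An `interval_set` (merged).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) return(interval_set())
  parts <- strsplit(lines, "\t| +")
  bad_ncol <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad_ncol)) {
    stop(sprintf("BED line %d of %s has fewer than 3 columns", bad_ncol[1], path))
  }
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  end <- as.numeric(vapply(parts, `[[`, character(1), 3L))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric start/end in BED file ", path)
  }
  rev_int <- which(start > end)
  if (length(rev_int)) {
    stop(sprintf("BED line %d of %s has start > end", rev_int[1], path))
  }
  zero <- start == end
  if (any(zero)) {
    warning(sprintf("dropping %d zero-length interval(s) in %s", sum(zero), path))
  }
  interval_set(chrom, start, end)
}

#' Write an interval_set as BED3
#' @param x An `interval_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  d <- as.data.frame(x)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Union of several interval sets
#' @param ... `interval_set` objects.
#' @return The merged `interval_set`.
#' @export
interval_union <- function(...) {
  ds <- lapply(list(...), as.data.frame)
  d <- do.call(rbind, ds)
  interval_set(d$chrom, d$start, d$end)
}
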