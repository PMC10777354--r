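is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}

is_transition <- function(ref, alt) {
  paste0(ref, alt) %in% c("AG", "GA", "CT", "TC")
}

#' Transition/transversion ratio of a callset
#'
#' Transitions are A<->G and C<->T; all other single-base substitutions are
#' transversions. Indels and other non-SNVs are excluded from both numerator
#' and denominator. With zero transversions the ratio is undefined and `NA`
#' is returned.
#'
#' @param dnvs data.frame with `ref` and `alt` columns.
#' @return Ti/Tv ratio, or `NA`.
#' @export
titv_ratio <- function(dnvs) {
  snv <- is_snv(dnvs$ref, dnvs$alt)
  ti <- sum(snv & is_transition(dnvs$ref, dnvs$alt))
  tv <- sum(snv) - ti
  if (tv == 0) NA_real_ else ti / tv
}

#' Fraction of SNVs at CpG sites
#'
#' A SNV sits at a CpG site when its reference base is a C immediately
#' followed by G, or a G immediately preceded by C (the dinucleotide on
#' either strand). Contig-edge positions lacking the neighbouring base are
#' never CpG. Non-SNVs are excluded from the numerator, and by default from
#' the denominator too.
#'
#' @param dnvs data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param reference Named `DNAStringSet` from [load_reference()].
#' @param denominator `"snv"` (default) or `"all"` — whether indels count in
#'   the denominator.
#' @return Fraction in `[0, 1]`, or `NA` for an empty denominator.
#' @export
cpg_fraction <- function(dnvs, reference, denominator = c("snv", "all")) {
  denominator <- match.arg(denominator)
  snv <- is_snv(dnvs$ref, dnvs$alt)
  denom <- if (denominator == "snv") sum(snv) else nrow(dnvs)
  if (denom == 0) return(NA_real_)
  cpg <- rep(FALSE, nrow(dnvs))
  idx <- which(snv)
  if (length(idx)) {
    clen <- Biostrings::width(reference)[match(dnvs$chrom[idx], names(reference))]
    ref_b <- dnvs$ref[idx]
    nxt <- rep(NA_character_, length(idx))
    prv <- rep(NA_character_, length(idx))
    has_next <- dnvs$pos[idx] + 1 <= clen
    has_prev <- dnvs$pos[idx] - 1 >= 1
    if (any(has_next)) {
      nxt[has_next] <- ref_bases(reference, dnvs$chrom[idx][has_next],
                                 dnvs$pos[idx][has_next] + 1L)
    }
    if (any(has_prev)) {
      prv[has_prev] <- ref_bases(reference, dnvs$chrom[idx][has_prev],
                                 dnvs$pos[idx][has_prev] - 1L)
    }
    cpg[idx] <- (ref_b == "C" & !is.na(nxt) & nxt == "G") |
      (ref_b == "G" & !is.na(prv) & prv == "C")
  }
  sum(cpg) / denom
}

#' Per-child DNV callset summary across trios
#'
#' One row per child with DNV count, CpG fraction (percent) and Ti/Tv, plus
#' a cohort row carrying the mean and standard deviation of the counts.
#'
#' @param dnv_tables Named list of candidate-DNV tables (final calls), one
#'   per child.
#' @param reference Named `DNAStringSet`.
#' @return data.frame with columns `child`, `n_dnv`, `pct_cpg`, `titv`,
#'   and attributes-free cohort row (`child = "cohort"`) with `mean_n` and
#'   `sd_n` columns populated.
#' @export
per_sample_summary <- function(dnv_tables, reference) {
  stopifnot(length(dnv_tables) >= 1)
  rows <- lapply(names(dnv_tables), function(id) {
    d <- dnv_tables[[id]]
    data.frame(child = id, n_dnv = nrow(d),
               pct_cpg = 100 * cpg_fraction(d, reference),
               titv = titv_ratio(d),
               mean_n = NA_real_, sd_n = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cohort <- data.frame(
    child = "cohort", n_dnv = NA_integer_, pct_cpg = NA_real_, titv = NA_real_,
    mean_n = mean(out$n_dnv),
    sd_n = if (nrow(out) > 1) stats::sd(out$n_dnv) else NA_real_,
    stringsAsFactors = FALSE)
  rbind(out, cohort)
}

#' Overlap accounting between named variant callsets
#'
#' For every non-empty subset of callset names, counts the variant keys
#' whose membership pattern is exactly that subset (the numbers behind an
#' upset plot). Counts over all patterns sum to the size of the union.
#'
#' @param callsets Named list (2-8 entries) of character vectors of
#'   normalized variant keys (see [variant_key()]).
#' @return data.frame with `pattern` (ampersand-joined callset names),
#'   `degree` (number of callsets in the pattern) and `count`, ordered by
#'   descending count then pattern name.
#' @export
compare_callsets <- function(callsets) {
  stopifnot(is.list(callsets), length(callsets) >= 2, length(callsets) <= 8,
            !is.null(names(callsets)), all(nzchar(names(callsets))))
  sets <- lapply(callsets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plain-text upset-style summary of callset overlaps
#' @param overlap Output of [compare_callsets()].
#' @return Character vector of formatted lines.
#' @export
format_overlap <- function(overlap) {
  c(sprintf("%-40s %8s", "pattern", "count"),
    sprintf("%-40s %8d", overlap$pattern, overlap$count),
    sprintf("%-40s %8d", "union", sum(overlap$count)))
}
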