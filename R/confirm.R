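#' Confirm DNVs against independent high-coverage pileup evidence
#'
#' Re-evaluates called DNVs with pileup counts from an independent (ideally
#' much deeper, e.g. 300x) sequencing run of the same trio. A DNV is
#' `confirmed` when the child's variant allele frequency exceeds
#' `child_min_vaf` (strictly) and both parents' VAFs are below
#' `parent_max_vaf` (strictly); the parent cutoff of 1% reflects the typical
#' Illumina base error rate. VAF is computed over the full pileup depth
#' (all covering reads). Any trio member with zero depth, or a site without
#' pileup evidence, yields `no_data`.
#'
#' Note the asymmetry with the primary filter: the calling filter requires
#' child VAF "at least" 25% (inclusive), while confirmation requires
#' strictly more than 25%.
#'
#' @param dnvs Candidate-DNV table (needs `chrom`, `pos`).
#' @param pileup Pileup counts for `child`, `father`, `mother` at the DNV
#'   sites (deep, independent evidence).
#' @param child_min_vaf Strict lower bound on child VAF (default 0.25).
#' @param parent_max_vaf Strict upper bound on each parent VAF (default 0.01).
#' @return `dnvs` with the `confirmation` column set to `confirmed`,
#'   `not_confirmed` or `no_data`.
#' @export
confirm_dnv <- function(dnvs, pileup, child_min_vaf = 0.25,
                        parent_max_vaf = 0.01) {
  if (nrow(dnvs) == 0) {
    dnvs$confirmation <- character(0)
    return(dnvs)
  }
  dnvs$confirmation <- vapply(seq_len(nrow(dnvs)), function(i) {
    at <- pileup[pileup$chrom == dnvs$chrom[i] & pileup$pos == dnvs$pos[i], ]
    get <- function(role) at[at$sample == role, , drop = FALSE]
    ch <- get("child"); fa <- get("father"); mo <- get("mother")
    if (nrow(ch) == 0 || nrow(fa) == 0 || nrow(mo) == 0) return("no_data")
    if (ch$depth[1] == 0 || fa$depth[1] == 0 || mo$depth[1] == 0) return("no_data")
    vaf <- function(x) x$alt_count[1] / x$depth[1]
    if (vaf(ch) > child_min_vaf && vaf(fa) < parent_max_vaf &&
        vaf(mo) < parent_max_vaf) "confirmed" else "not_confirmed"
  }, character(1))
  dnvs
}

#' Confirmation rate of a DNV callset
#'
#' @param dnvs Candidate-DNV table with a `confirmation` column, or a
#'   character vector of confirmation statuses.
#' @return List with `rate` = confirmed / (confirmed + not_confirmed)
#'   (`NA` when nothing is evaluable), `confirmed`, `not_confirmed` and
#'   `no_data` counts; `no_data` sites are excluded from the denominator.
#' @export
confirmation_rate <- function(dnvs) {
  status <- if (is.data.frame(dnvs)) dnvs$confirmation else dnvs
  conf <- sum(status == "confirmed", na.rm = TRUE)
  not <- sum(status == "not_confirmed", na.rm = TRUE)
  nd <- sum(status == "no_data", na.rm = TRUE)
  list(rate = if (conf + not > 0) conf / (conf + not) else NA_real_,
       confirmed = conf, not_confirmed = not, no_data = nd)
}
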