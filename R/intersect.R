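#' Intersect two callers' trio callsets on exact normalized variant identity
#'
#' A variant pairs iff its normalized (chrom, pos, ref, alt) key appears in
#' both callsets; genotype concordance between callers is not required.
#' Duplicate keys within one callset collapse to the first occurrence with a
#' warning. The result is sorted by (contig, pos, ref, alt) and is symmetric
#' up to the a/b labelling.
#'
#' @param records_a,records_b Trio record tables from [read_trio_vcf()]
#'   (already normalized and decomposed).
#' @param keep_private If `TRUE`, records present in only one callset are
#'   retained with the other caller's evidence columns set to `NA`; the
#'   `in_both` column distinguishes them. Used to audit what the
#'   intersection rule removes.
#' @return data.frame of paired records: shared key columns, evidence
#'   columns suffixed `_a`/`_b`, and logicals `in_a`, `in_b`, `in_both`.
#' @export
intersect_callsets <- function(records_a, records_b, keep_private = FALSE) {
  dedup <- function(d, label) {
    if (nrow(d) == 0) return(d)
    key <- variant_key(d$chrom, d$pos, d$ref, d$alt)
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sprintf("%d duplicate key(s) in callset %s; keeping first occurrence",
                      sum(dup), label))
      d <- d[!dup, , drop = FALSE]
    }
    d
  }
  a <- dedup(records_a, "a")
  b <- dedup(records_b, "b")
  evid_cols <- setdiff(names(empty_trio_table()),
                       c("chrom", "pos", "ref", "alt", "caller"))
  rename_ev <- function(d, sfx) {
    keep <- intersect(c("caller", evid_cols), names(d))
    out <- d[c("chrom", "pos", "ref", "alt", keep)]
    names(out)[names(out) %in% keep] <- paste0(keep, "_", sfx)
    out$key <- variant_key(d$chrom, d$pos, d$ref, d$alt)
    out
  }
  aa <- rename_ev(a, "a")
  bb <- rename_ev(b, "b")
  m <- merge(aa, bb, by = c("key", "chrom", "pos", "ref", "alt"),
             all = keep_private, sort = FALSE)
  m$in_a <- if (nrow(m)) !is.na(m$caller_a) else logical(0)
  m$in_b <- if (nrow(m)) !is.na(m$caller_b) else logical(0)
  m$in_both <- m$in_a & m$in_b
  m$key <- NULL
  # contig order: order of first appearance in callset a, then b
  ctg_order <- unique(c(a$chrom, b$chrom))
  m <- m[order(match(m$chrom, ctg_order), m$pos, m$ref, m$alt), , drop = FALSE]
  rownames(m) <- NULL
  m
}
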