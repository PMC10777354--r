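#' Normalize a variant to its minimal, left-aligned representation
#'
#' Reduces a (chrom, pos, ref, alt) description of a sequence change to the
#' unique canonical spelling used as the cross-caller matching key:
#' shared suffix bases are trimmed, indels are shifted left through repeat
#' tracts by extending with the preceding reference base, and the shared
#' prefix is trimmed except for the single anchor base an indel must keep.
#' The operation is idempotent: a normalized variant maps to itself.
#'
#' @param chrom Contig name (scalar).
#' @param pos 1-based position of the first reference base (scalar).
#' @param ref,alt Allele strings over A/C/G/T/N; must differ and be non-empty.
#' @param reference A named `DNAStringSet`; used for reference-consistency
#'   checking and left extension of indels.
#' @return A one-row data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chrT = "GGCAAAAT"))
#' normalize_variant("chrT", 7, "CAA", "CA", ref)  # -> chrT:3 CA>C
#' @export
normalize_variant <- function(chrom, pos, ref, alt, reference) {
  pos <- as.integer(pos)
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt)) {
    stop(sprintf("empty allele at %s:%d", chrom, pos))
  }
  if (grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt)) {
    stop(sprintf("allele with characters outside A/C/G/T/N at %s:%d", chrom, pos))
  }
  if (ref == alt) {
    stop(sprintf("ref and alt are identical at %s:%d (not a variant)", chrom, pos))
  }
  seen <- ref_bases(reference, chrom, pos, nchar(ref))
  if (seen != ref) {
    stop(sprintf(
      "reference mismatch at %s:%d: VCF ref '%s' but reference sequence has '%s'",
      chrom, pos, ref, seen))
  }
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  repeat {
    # trim shared suffix; if an allele would empty, left-extend from reference
    while (length(r) > 0 && length(a) > 0 && r[length(r)] == a[length(a)]) {
      if (length(r) == 1L || length(a) == 1L) {
        if (pos == 1L) break  # cannot extend past the contig start
        pos <- pos - 1L
        b <- ref_bases(reference, chrom, pos, 1L)
        r <- c(b, r[-length(r)])
        a <- c(b, a[-length(a)])
      } else {
        r <- r[-length(r)]
        a <- a[-length(a)]
      }
    }
    break
  }
  # trim shared prefix, keeping the indel anchor base
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  data.frame(chrom = chrom, pos = pos,
             ref = paste(r, collapse = ""), alt = paste(a, collapse = ""),
             stringsAsFactors = FALSE)
}

#' Canonical matching key for normalized variants
#'
#' @param chrom,pos,ref,alt Parallel vectors describing normalized variants.
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Canonicalize one genotype string in k-allele space down to the {0, alt_index}
# biallelic space: alleles equal to alt_index become 1, everything else called
# becomes 0, missing stays ".". Phase separators are normalized to "/" and
# diploid genotypes sorted so 1/0 == 0/1. Haploid calls are kept as-is.
recode_genotype <- function(gt, alt_index) {
  vapply(gt, function(g) {
    if (is.na(g) || g == "." || g == "./." || g == ".|.") return("./.")
    al <- strsplit(g, "[/|]")[[1]]
    al <- vapply(al, function(x) {
      if (x == ".") return(".")
      if (as.integer(x) == alt_index) "1" else "0"
    }, character(1))
    if (length(al) > 1L) {
      miss <- al == "."
      al <- c(sort(al[!miss]), al[miss])
    }
    paste(al, collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

# Split the comma-separated AD string into ref count and the count for alt k.
ad_collapse <- function(ad, alt_index) {
  out <- matrix(NA_integer_, nrow = length(ad), ncol = 2L,
                dimnames = list(NULL, c("ref", "alt")))
  for (i in seq_along(ad)) {
    if (is.na(ad[i]) || ad[i] == ".") next
    v <- suppressWarnings(as.integer(strsplit(ad[i], ",")[[1]]))
    if (length(v) >= alt_index + 1L) {
      out[i, ] <- c(v[1], v[alt_index + 1L])
    }
  }
  out
}

#' Decompose a raw multi-sample record into biallelic trio records
#'
#' One output row per alternate allele. Genotypes are recoded into the
#' \{0, 1\} space of that allele (other alternate alleles are treated as
#' reference, missing stays missing), AD is collapsed to
#' (ref count, this-alt count), and rows originating from a multi-allelic
#' site carry `multiallelic = TRUE`. Alleles are then normalized with
#' [normalize_variant()].
#'
#' @param chrom,pos,ref 1-based raw record coordinates and reference allele.
#' @param alts Character vector of alternate alleles (length >= 1).
#' @param calls A named list with elements `child`, `father`, `mother`, each a
#'   list with `gt` (string), `dp` (int), `gq` (int), `ad` (comma string).
#' @param reference Named `DNAStringSet` for normalization.
#' @param caller Callset label recorded on every output row.
#' @param filter_input Original VCF FILTER value (kept for the audit trail).
#' @return A data.frame of trio records, one row per alternate allele.
#' @export
split_multiallelic <- function(chrom, pos, ref, alts, calls, reference,
                               caller = "caller", filter_input = ".") {
  stopifnot(length(alts) >= 1L)
  rows <- vector("list", length(alts))
  for (k in seq_along(alts)) {
    nv <- normalize_variant(chrom, pos, ref, alts[k], reference)
    row <- data.frame(
      chrom = nv$chrom, pos = nv$pos, ref = nv$ref, alt = nv$alt,
      caller = caller, multiallelic = length(alts) > 1L,
      filter_input = filter_input, stringsAsFactors = FALSE)
    for (role in c("child", "father", "mother")) {
      cc <- calls[[role]]
      ad <- ad_collapse(if (is.null(cc$ad)) NA_character_ else cc$ad, k)
      row[[paste0(role, "_gt")]] <- recode_genotype(
        if (is.null(cc$gt)) NA_character_ else cc$gt, k)
      row[[paste0(role, "_dp")]] <- if (is.null(cc$dp)) NA_integer_ else as.integer(cc$dp)
      row[[paste0(role, "_gq")]] <- if (is.null(cc$gq)) NA_integer_ else as.integer(cc$gq)
      row[[paste0(role, "_ad_ref")]] <- ad[1, "ref"]
      row[[paste0(role, "_ad_alt")]] <- ad[1, "alt"]
    }
    rows[[k]] <- row
  }
  do.call(rbind, rows)
}
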