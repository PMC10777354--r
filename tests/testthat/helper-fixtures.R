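# Shared fixture builders. Everything is constructed in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

ref_from_strings <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

# Independent oracle: apply a (pos, ref, alt) edit to a reference string and
# return the altered haplotype. Two variant spellings are equivalent iff they
# produce the same haplotype from the same reference.
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# Brute-force enumeration of every reference-consistent (pos, ref, alt)
# spelling (ref length <= max_len) equivalent to a given haplotype edit.
# Complete: any equivalent spelling leaves the sequence before pos intact,
# so its alt is forced to be the matching substring of the target haplotype
# and its length is fixed by the overall length change.
equivalent_spellings <- function(seq, target_hap, max_len = 6L) {
  delta <- nchar(target_hap) - nchar(seq)
  out <- list()
  for (pos in seq_len(nchar(seq))) {
    for (rl in 1:max_len) {
      if (pos + rl - 1L > nchar(seq)) next
      ref <- substr(seq, pos, pos + rl - 1L)
      al <- rl + delta
      if (al < 1L || pos + al - 1L > nchar(target_hap)) next
      alt <- substr(target_hap, pos, pos + al - 1L)
      if (ref == alt) next
      if (apply_variant(seq, pos, ref, alt) == target_hap) {
        out[[length(out) + 1L]] <- list(pos = pos, ref = ref, alt = alt)
      }
    }
  }
  out
}

# A one-row paired-record table (both callers) with clean, all-rules-passing
# evidence; individual fields overridable.
mk_paired <- function(chrom = "chr1", pos = 500L, ref = "A", alt = "G", ...) {
  row <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  for (sfx in c("a", "b")) {
    row[[paste0("caller_", sfx)]] <- toupper(sfx)
    row[[paste0("multiallelic_", sfx)]] <- FALSE
    row[[paste0("filter_input_", sfx)]] <- "PASS"
    row[[paste0("child_gt_", sfx)]] <- "0/1"
    row[[paste0("child_dp_", sfx)]] <- 30L
    row[[paste0("child_gq_", sfx)]] <- 60L
    row[[paste0("child_ad_ref_", sfx)]] <- 15L
    row[[paste0("child_ad_alt_", sfx)]] <- 15L
    for (p in c("father", "mother")) {
      row[[paste0(p, "_gt_", sfx)]] <- "0/0"
      row[[paste0(p, "_dp_", sfx)]] <- 30L
      row[[paste0(p, "_gq_", sfx)]] <- 60L
      row[[paste0(p, "_ad_ref_", sfx)]] <- 30L
      row[[paste0(p, "_ad_alt_", sfx)]] <- 0L
    }
  }
  row$in_a <- TRUE
  row$in_b <- TRUE
  row$in_both <- TRUE
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# Write a small multi-sample VCF from a record list; each record is
# list(chrom, pos, ref, alt (comma string), calls = named list by sample of
# "GT:DP:GQ:AD" strings).
write_test_vcf <- function(path, samples, records, contigs) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", "GT:DP:GQ:AD",
            unlist(r$calls[samples])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# A trio record table row (single caller), for intersection tests.
mk_trio_record <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                           caller = "X") {
  d <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  caller = caller, multiallelic = FALSE, filter_input = "PASS",
                  stringsAsFactors = FALSE)
  for (role in c("child", "father", "mother")) {
    d[[paste0(role, "_gt")]] <- "0/1"
    d[[paste0(role, "_dp")]] <- 30L
    d[[paste0(role, "_gq")]] <- 60L
    d[[paste0(role, "_ad_ref")]] <- 15L
    d[[paste0(role, "_ad_alt")]] <- 15L
  }
  d
}

# Random trio record table over a small key universe (for oracle tests).
random_callset <- function(n, caller, universe) {
  pick <- universe[sample.int(nrow(universe), n), , drop = FALSE]
  do.call(rbind, lapply(seq_len(n), function(i) {
    mk_trio_record(pick$chrom[i], pick$pos[i], pick$ref[i], pick$alt[i],
                   caller = caller)
  }))
}

# Key universe of distinct random SNVs.
key_universe <- function(n_keys, n_contigs = 2) {
  pos <- sample(seq(10L, 100000L, by = 7L), n_keys)
  ref <- sample(c("A", "C", "G", "T"), n_keys, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  data.frame(chrom = paste0("chr", sample(n_contigs, n_keys, replace = TRUE)),
             pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "triodnv-default-sim")
      cache <<- simulate_trio(simulation_config(seed = 20231L), dir)
    }
    cache
  }
})
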