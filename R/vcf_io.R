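#' Define a trio pedigree
#'
#' @param child_id,father_id,mother_id Sample identifiers exactly as they
#'   appear in the VCF header. Must be three distinct non-empty strings.
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(child_id, father_id, mother_id) {
  ids <- c(child = child_id, father = father_id, mother = mother_id)
  if (any(!nzchar(ids)) || anyNA(ids)) stop("pedigree sample IDs must be non-empty")
  if (anyDuplicated(ids)) stop("pedigree sample IDs must be distinct")
  structure(as.list(ids), class = "pedigree")
}

# Pull one FORMAT element for one sample out of vcfR's gt matrix; NA when the
# field is absent from the record's FORMAT.
extract_fmt <- function(gt_matrix, format_col, sample, field) {
  keys <- strsplit(format_col, ":")
  vals <- strsplit(gt_matrix[, sample], ":")
  vapply(seq_along(keys), function(i) {
    k <- match(field, keys[[i]])
    if (is.na(k) || k > length(vals[[i]])) return(NA_character_)
    v <- vals[[i]][k]
    if (identical(v, ".")) NA_character_ else v
  }, character(1))
}

#' Read a joint-genotyped trio VCF into a table of biallelic records
#'
#' Parses a multi-sample VCF, maps samples to roles by pedigree ID (column
#' order is irrelevant), decomposes multi-allelic records into biallelic
#' rows, and normalizes every allele pair against the reference. GT is
#' required; DP/GQ/AD are read when present and recorded as missing
#' otherwise. Input order is preserved.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param ped A [pedigree()].
#' @param reference Named `DNAStringSet` from [load_reference()].
#' @param caller Label identifying the upstream caller of this callset.
#' @return data.frame of trio records (one row per alternate allele) with
#'   per-role `gt`, `dp`, `gq`, `ad_ref`, `ad_alt` columns.
#' @export
read_trio_vcf <- function(path, ped, reference, caller = "caller") {
  stopifnot(inherits(ped, "pedigree"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF has no sample columns: ", path)
  samples <- colnames(gt)[-1]
  missing_ids <- setdiff(unlist(ped), samples)
  if (length(missing_ids)) {
    stop(sprintf("pedigree sample(s) %s not in VCF header of %s (samples: %s)",
                 paste(missing_ids, collapse = ", "), path,
                 paste(samples, collapse = ", ")))
  }
  fix <- v@fix
  if (nrow(fix) == 0) return(empty_trio_table(caller))
  fmt <- gt[, "FORMAT"]
  if (any(!grepl("(^|:)GT(:|$)", fmt))) {
    stop("record(s) without GT in FORMAT in ", path)
  }
  fields <- list()
  for (role in c("child", "father", "mother")) {
    sm <- ped[[role]]
    fields[[role]] <- list(
      gt = extract_fmt(gt, fmt, sm, "GT"),
      dp = extract_fmt(gt, fmt, sm, "DP"),
      gq = extract_fmt(gt, fmt, sm, "GQ"),
      ad = extract_fmt(gt, fmt, sm, "AD"))
  }
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",")[[1]]
    calls <- lapply(fields, function(f) {
      list(gt = f$gt[i],
           dp = suppressWarnings(as.integer(f$dp[i])),
           gq = suppressWarnings(as.integer(f$gq[i])),
           ad = f$ad[i])
    })
    filt <- fix[i, "FILTER"]
    out[[i]] <- split_multiallelic(
      fix[i, "CHROM"], as.integer(fix[i, "POS"]), fix[i, "REF"], alts,
      calls, reference, caller = caller,
      filter_input = if (is.na(filt)) "." else filt)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_trio_table <- function(caller = "caller") {
  d <- data.frame(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), caller = character(),
                  multiallelic = logical(), filter_input = character(),
                  stringsAsFactors = FALSE)
  for (role in c("child", "father", "mother")) {
    d[[paste0(role, "_gt")]] <- character()
    d[[paste0(role, "_dp")]] <- integer()
    d[[paste0(role, "_gq")]] <- integer()
    d[[paste0(role, "_ad_ref")]] <- integer()
    d[[paste0(role, "_ad_alt")]] <- integer()
  }
  d
}

#' Write a DNV callset as a minimal VCF 4.2
#'
#' One record per candidate DNV with an INFO tag per audit rule, plus the
#' final verdict, confidence zone label and confirmation status when present.
#' Output is byte-identical for identical input (no timestamps).
#'
#' @param dnvs A candidate-DNV table from [call_dnvs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dnv_vcf <- function(dnvs, path) {
  rules <- grep("^rule_", names(dnvs), value = TRUE)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=triodnv-%s", as.character(utils::packageVersion("triodnv"))),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Audit outcome for filter rule %s">',
            toupper(rules), sub("^rule_", "", rules)),
    '##INFO=<ID=FINAL,Number=0,Type=Flag,Description="Passed every evaluated DNV filter rule">',
    '##INFO=<ID=CONFIDENCE,Number=1,Type=String,Description="WES capture-zone confidence label">',
    '##INFO=<ID=CONFIRMATION,Number=1,Type=String,Description="High-coverage confirmation status">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(dnvs) > 0) {
    info <- vapply(seq_len(nrow(dnvs)), function(i) {
      tags <- sprintf("%s=%s", toupper(rules), unlist(dnvs[i, rules]))
      if (isTRUE(dnvs$final[i])) tags <- c(tags, "FINAL")
      if (!is.null(dnvs$confidence) && !is.na(dnvs$confidence[i])) {
        tags <- c(tags, sprintf("CONFIDENCE=%s", dnvs$confidence[i]))
      }
      if (!is.null(dnvs$confirmation) && !is.na(dnvs$confirmation[i])) {
        tags <- c(tags, sprintf("CONFIRMATION=%s", dnvs$confirmation[i]))
      }
      paste(tags, collapse = ";")
    }, character(1))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                    dnvs$chrom, dnvs$pos, dnvs$ref, dnvs$alt, info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
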