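# Parse one mpileup base string into counts for a specific query allele.
#
# Token rules (samtools mpileup text dialect):
#   "." / ","            read matches the reference base (counts as ref)
#   A/C/G/T/N (any case) read shows a substituted base (alt when it matches
#                        an SNV query)
#   "^X"                 read start; the following character is a mapping
#                        quality and is skipped
#   "$"                  read end marker, skipped
#   "*"                  placeholder for a base deleted by an upstream
#                        deletion; counts toward depth only
#   "+N<seq>" / "-N<seq>" insertion/deletion attached to the preceding base;
#                        consumed, and counted as alt support when the
#                        inserted/deleted sequence matches an indel query.
#
# Base qualities are deliberately ignored: every read at any quality level
# is counted. For SNV queries an indel suffix attached to a ref-matching
# base leaves that base a ref match, never alt support.
parse_base_string <- function(bases, query_type, query_seq) {
  chars <- strsplit(bases, "")[[1]]
  depth <- 0L; ref_count <- 0L; alt_count <- 0L
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      if (i + 1L > n) stop("dangling '^' at end of pileup base string")
      i <- i + 2L
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "*") {
      depth <- depth + 1L
      i <- i + 1L
    } else if (ch == "." || ch == ",") {
      depth <- depth + 1L
      ref_count <- ref_count + 1L
      i <- i + 1L
      # possible indel suffix attached to this read
      if (i <= n && (chars[i] == "+" || chars[i] == "-")) {
        parsed <- consume_indel(chars, i)
        if (query_type == "ins" && chars[i] == "+" &&
            toupper(parsed$seq) == query_seq) {
          alt_count <- alt_count + 1L
          ref_count <- ref_count - 1L
        } else if (query_type == "del" && chars[i] == "-" &&
                   toupper(parsed$seq) == query_seq) {
          alt_count <- alt_count + 1L
          ref_count <- ref_count - 1L
        }
        i <- parsed$next_i
      }
    } else if (grepl("[ACGTNacgtn]", ch)) {
      depth <- depth + 1L
      if (query_type == "snv" && toupper(ch) == query_seq) {
        alt_count <- alt_count + 1L
      }
      i <- i + 1L
      if (i <= n && (chars[i] == "+" || chars[i] == "-")) {
        i <- consume_indel(chars, i)$next_i
      }
    } else if (ch == "+" || ch == "-") {
      # indel with no preceding base in this string (malformed for samtools,
      # but unambiguous): consume without counting
      i <- consume_indel(chars, i)$next_i
    } else {
      stop(sprintf("unsupported character '%s' at column %d of pileup base string",
                   ch, i))
    }
  }
  c(depth = depth, ref_count = ref_count, alt_count = alt_count)
}

# Consume "+N<seq>" or "-N<seq>" starting at chars[i] (the sign).
consume_indel <- function(chars, i) {
  n <- length(chars)
  j <- i + 1L
  digits <- character(0)
  while (j <= n && grepl("[0-9]", chars[j])) {
    digits <- c(digits, chars[j])
    j <- j + 1L
  }
  if (length(digits) == 0) stop(sprintf("indel marker at column %d lacks a length", i))
  len <- as.integer(paste(digits, collapse = ""))
  if (j + len - 1L > n) stop(sprintf("truncated indel sequence at column %d", i))
  list(seq = paste(chars[j:(j + len - 1L)], collapse = ""), next_i = j + len)
}

# Classify a normalized ref/alt pair into the pileup query it implies.
pileup_query <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    list(type = "snv", seq = toupper(alt))
  } else if (nchar(ref) == 1L && nchar(alt) > 1L && substr(alt, 1, 1) == ref) {
    list(type = "ins", seq = toupper(substr(alt, 2, nchar(alt))))
  } else if (nchar(alt) == 1L && nchar(ref) > 1L && substr(ref, 1, 1) == alt) {
    list(type = "del", seq = toupper(substr(ref, 2, nchar(ref))))
  } else {
    list(type = "complex", seq = toupper(alt))
  }
}

#' Count reference and alternate support in samtools mpileup text
#'
#' Parses the base-string columns of `samtools mpileup` output and counts,
#' per sample column, how many reads support the query alternate allele.
#' Every read is counted regardless of base quality. For SNV queries only a
#' substituted base matching the alt counts; for indel queries only a
#' matching `+N<seq>`/`-N<seq>` token counts.
#'
#' @param lines Character vector of mpileup lines, or a file path.
#' @param ref_allele,alt_allele Normalized query alleles (e.g. `"A"`/`"G"`
#'   for an SNV, `"A"`/`"AAT"` for an insertion, `"CAA"`/`"C"` for a
#'   deletion).
#' @param samples Role names for the per-sample column triplets, in file
#'   order (default `child`, `father`, `mother`).
#' @return data.frame with one row per (site, sample): `chrom`, `pos`
#'   (1-based), `sample`, `depth`, `ref_count`, `alt_count`.
#' @export
parse_mpileup <- function(lines, ref_allele, alt_allele,
                          samples = c("child", "father", "mother")) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  lines <- lines[nzchar(lines)]
  q <- pileup_query(ref_allele, alt_allele)
  out <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    f <- strsplit(lines[li], "\t")[[1]]
    n_sample_cols <- (length(f) - 3L) %/% 3L
    if (length(f) < 6L || (length(f) - 3L) %% 3L != 0L) {
      stop(sprintf("mpileup line %d has %d fields; expected 3 + 3 per sample",
                   li, length(f)))
    }
    k <- min(n_sample_cols, length(samples))
    rows <- vector("list", k)
    for (s in seq_len(k)) {
      bases <- f[3L + (s - 1L) * 3L + 2L]
      if (bases == "*") bases <- ""  # samtools placeholder for zero coverage
      counts <- tryCatch(
        parse_base_string(bases, q$type, q$seq),
        error = function(e) {
          stop(sprintf("mpileup line %d, sample %s: %s",
                       li, samples[s], conditionMessage(e)))
        })
      rows[[s]] <- data.frame(
        chrom = f[1], pos = as.integer(f[2]), sample = samples[s],
        depth = unname(counts["depth"]),
        ref_count = unname(counts["ref_count"]),
        alt_count = unname(counts["alt_count"]),
        stringsAsFactors = FALSE)
    }
    out[[li]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_pileup_table()
  res
}

empty_pileup_table <- function() {
  data.frame(chrom = character(), pos = integer(), sample = character(),
             depth = integer(), ref_count = integer(), alt_count = integer(),
             stringsAsFactors = FALSE)
}

#' Per-site pileup counts for a table of variants
#'
#' For each variant, finds its line in per-sample mpileup files and parses
#' the base string with that variant's own ref/alt query. Sites without a
#' pileup line are simply absent from the result (downstream tests treat
#' them as missing evidence).
#'
#' @param pileup_paths Named list/vector of mpileup file paths; names are
#'   sample roles (`child`, `father`, `mother`).
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt` (normalized).
#' @return data.frame of pileup counts, one row per (site, sample) found.
#' @export
pileup_for_sites <- function(pileup_paths, sites) {
  per_file <- lapply(pileup_paths, function(p) {
    lines <- readLines(p)
    lines <- lines[nzchar(lines)]
    key <- vapply(strsplit(lines, "\t"), function(f) paste(f[1], f[2], sep = ":"),
                  character(1))
    stats::setNames(lines, key)
  })
  out <- list()
  for (i in seq_len(nrow(sites))) {
    key <- paste(sites$chrom[i], sites$pos[i], sep = ":")
    for (role in names(per_file)) {
      line <- per_file[[role]][key]
      if (is.na(line)) next
      out[[length(out) + 1L]] <- parse_mpileup(
        unname(line), sites$ref[i], sites$alt[i], samples = role)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_pileup_table()
  rownames(res) <- NULL
  res
}

#' Read pileup evidence in either supported format
#'
#' Dispatches on content: a tab-separated file whose header starts with
#' `chrom<TAB>pos<TAB>sample` is read as a pre-counted pileup TSV; anything
#' else is treated as single-sample samtools mpileup text and parsed
#' per-site against `sites`.
#'
#' @param path Path to a pileup TSV or mpileup text file.
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`; required for
#'   mpileup text.
#' @param role Sample role of an mpileup-format file.
#' @return data.frame of pileup counts.
#' @export
read_pileup_any <- function(path, sites = NULL, role = "child") {
  first <- readLines(path, n = 1L)
  if (length(first) && grepl("^chrom\tpos\tsample", first)) {
    return(read_pileup_tsv(path))
  }
  if (is.null(sites)) stop("mpileup text input needs the variant sites to query")
  res <- pileup_for_sites(stats::setNames(list(path), role), sites)
  res
}

#' Read pre-counted pileup evidence from a TSV
#'
#' Alternative to mpileup text: a tab-separated table with columns
#' `chrom`, `pos` (1-based), `sample`, `depth`, `ref_count`, `alt_count`.
#' Both paths produce the same per-site, per-sample count records.
#'
#' @param path Path to the TSV (with header).
#' @return data.frame of pileup counts.
#' @export
read_pileup_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "sample", "depth", "ref_count", "alt_count")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("pileup TSV ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- d$alt_count > d$depth | d$ref_count > d$depth |
    d$alt_count < 0 | d$ref_count < 0 | d$depth < 0
  if (any(bad)) {
    stop(sprintf("inconsistent pileup counts at %s:%d in %s",
                 d$chrom[bad][1], d$pos[bad][1], path))
  }
  d[need]
}

#' Write pileup counts as TSV
#' @param counts data.frame of pileup counts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
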