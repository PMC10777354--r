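#' Load a reference genome from a FASTA file
#'
#' Reads a (small) reference genome into memory as a named
#' [Biostrings::DNAStringSet]. Sequence names are truncated at the first
#' whitespace, matching common FASTA identifier conventions.
#'
#' @param path Path to an uncompressed or gzipped FASTA file.
#' @return A `DNAStringSet` named by contig.
#' @export
load_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Extract reference bases
#'
#' Vectorised 1-based substring lookup on a loaded reference. Queries that
#' fall outside a contig raise an error.
#'
#' @param reference A named `DNAStringSet` from [load_reference()].
#' @param chrom Contig name(s).
#' @param pos 1-based start position(s).
#' @param width Number of bases to extract (recycled).
#' @return Character vector of uppercase base strings.
#' @export
ref_bases <- function(reference, chrom, pos, width = 1L) {
  n <- max(length(chrom), length(pos), length(width))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.integer(pos), n)
  width <- rep_len(as.integer(width), n)
  missing_contig <- !(chrom %in% names(reference))
  if (any(missing_contig)) {
    stop("contig(s) not in reference: ",
         paste(unique(chrom[missing_contig]), collapse = ", "))
  }
  clen <- Biostrings::width(reference)[match(chrom, names(reference))]
  bad <- pos < 1L | (pos + width - 1L) > clen
  if (any(bad)) {
    stop(sprintf("reference lookup out of bounds at %s:%d (width %d)",
                 chrom[bad][1], pos[bad][1], width[bad][1]))
  }
  out <- character(n)
  for (ctg in unique(chrom)) {
    i <- which(chrom == ctg)
    out[i] <- as.character(Biostrings::extractAt(
      reference[[ctg]], IRanges::IRanges(pos[i], width = width[i])))
  }
  toupper(out)
}
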