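# Fixed column order of the DNV TSV; everything downstream (WES
# classification, confirmation, metrics, CLI round-trips) keys on it.
dnv_table_columns <- function() {
  per_caller <- function(sfx) {
    c(sprintf("child_gt_%s", sfx), sprintf("child_dp_%s", sfx),
      sprintf("child_gq_%s", sfx), sprintf("child_vaf_%s", sfx),
      sprintf("child_ad_ref_%s", sfx), sprintf("child_ad_alt_%s", sfx),
      sprintf("father_gt_%s", sfx), sprintf("father_ad_alt_%s", sfx),
      sprintf("mother_gt_%s", sfx), sprintf("mother_ad_alt_%s", sfx))
  }
  c("chrom", "pos", "ref", "alt", "caller_a", "caller_b",
    per_caller("a"), per_caller("b"),
    paste0("rule_", dnv_rule_names()),
    "final", "confidence", "rescue", "confirmation")
}

#' Names of the eight DNV filter rules, in workflow order
#'
#' child genotype 0/1 or 1/1; parents 0/0; presence in both callers'
#' callsets; site depth; child genotype quality; child variant allele
#' fraction; zero parental alt reads; region blacklist.
#'
#' @return Character vector of rule names.
#' @export
dnv_rule_names <- function() {
  c("child_genotype", "parents_homref", "intersection", "depth",
    "child_gq", "child_vaf", "parent_reads", "blacklist")
}

#' Write a candidate-DNV table as TSV
#'
#' Fixed column order; byte-identical output for identical input. Missing
#' values are written as `NA`.
#'
#' @param dnvs Candidate-DNV table ([call_dnvs()] output, possibly annotated
#'   by [classify_dnvs()], [pileup_rescue()] or [confirm_dnv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dnv_table <- function(dnvs, path) {
  cols <- dnv_table_columns()
  for (cl in setdiff(cols, names(dnvs))) dnvs[[cl]] <- rep(NA, nrow(dnvs))
  utils::write.table(dnvs[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a candidate-DNV table written by [write_dnv_table()]
#' @param path Path to the TSV.
#' @return Candidate-DNV data.frame.
#' @export
read_dnv_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  miss <- setdiff(c("chrom", "pos", "ref", "alt"), names(d))
  if (length(miss)) {
    stop("DNV table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  if ("final" %in% names(d)) d$final <- as.logical(d$final)
  for (cl in grep("^rule_|^confidence$|^rescue$|^confirmation$", names(d), value = TRUE)) {
    d[[cl]] <- as.character(d[[cl]])
  }
  d
}
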