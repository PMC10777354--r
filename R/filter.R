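#' Configuration of the DNV filter thresholds
#'
#' Defaults encode the standard short-read trio filter: site depth at least
#' 10x, child genotype quality at least 20, child variant allele fraction at
#' least 25% (inclusive), and zero parental reads carrying the alternate
#' allele.
#'
#' @param min_depth Minimum DP (reads) at the site; inclusive.
#' @param min_gq Minimum child genotype quality (phred); inclusive.
#' @param min_child_vaf Minimum child alt-allele fraction of AD reads;
#'   inclusive.
#' @param max_parent_alt_reads Maximum alt-supporting reads (AD) tolerated
#'   in each parent; default 0 ("no reads with the variant").
#' @param depth_scope `"all_trio"` applies the depth rule to child, father
#'   and mother; `"child_only"` to the child alone.
#' @param numeric_scope `"both_callers"` demands each per-sample rule hold on
#'   both callers' evidence; `"either_caller"` accepts one.
#' @param allow_hemizygous Treat a haploid child genotype `"1"` (e.g. male
#'   chrX/Y) as `1/1` for the child-genotype rule.
#' @param rules_enabled Named logical vector over [dnv_rule_names()];
#'   disabled rules are recorded as `not_evaluated` in the audit and do not
#'   affect the verdict.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 10L, min_gq = 20L, min_child_vaf = 0.25,
                          max_parent_alt_reads = 0L,
                          depth_scope = c("all_trio", "child_only"),
                          numeric_scope = c("both_callers", "either_caller"),
                          allow_hemizygous = TRUE,
                          rules_enabled = NULL) {
  depth_scope <- match.arg(depth_scope)
  numeric_scope <- match.arg(numeric_scope)
  stopifnot(min_depth >= 0, min_gq >= 0,
            min_child_vaf >= 0, min_child_vaf <= 1, max_parent_alt_reads >= 0)
  enabled <- stats::setNames(rep(TRUE, length(dnv_rule_names())), dnv_rule_names())
  if (!is.null(rules_enabled)) {
    unknown <- setdiff(names(rules_enabled), dnv_rule_names())
    if (length(unknown)) stop("unknown rule(s): ", paste(unknown, collapse = ", "))
    enabled[names(rules_enabled)] <- rules_enabled
  }
  structure(list(min_depth = min_depth, min_gq = min_gq,
                 min_child_vaf = min_child_vaf,
                 max_parent_alt_reads = max_parent_alt_reads,
                 depth_scope = depth_scope, numeric_scope = numeric_scope,
                 allow_hemizygous = allow_hemizygous,
                 rules_enabled = enabled),
            class = "filter_config")
}

# --- individual rule predicates (vectorized; NA evidence fails) -----------

#' @rdname dnv_rules
#' @name dnv_rules
#' @title Individual DNV filter rule predicates
#' @description Vectorized predicates for the eight filter rules. Missing
#'   evidence always fails (conservative). These are exposed for auditing
#'   and testing; [call_dnvs()] applies them jointly.
#' @param child_gt,father_gt,mother_gt Canonical genotype strings
#'   (`"0/1"`-style, post-decomposition).
#' @param config A [filter_config()].
#' @return Logical vector (`TRUE` = rule passed).
NULL

#' @rdname dnv_rules
#' @export
rule_child_genotype <- function(child_gt, config = filter_config()) {
  ok <- child_gt %in% c("0/1", "1/1")
  if (config$allow_hemizygous) ok <- ok | child_gt %in% "1"
  ok & !is.na(child_gt)
}

#' @rdname dnv_rules
#' @export
rule_parents_homref <- function(father_gt, mother_gt) {
  ok_one <- function(g) !is.na(g) & g %in% c("0/0", "0")
  ok_one(father_gt) & ok_one(mother_gt)
}

#' @rdname dnv_rules
#' @param child_dp,father_dp,mother_dp Per-sample read depths (DP).
#' @export
rule_depth <- function(child_dp, father_dp, mother_dp, config = filter_config()) {
  ok <- function(dp) !is.na(dp) & dp >= config$min_depth
  if (config$depth_scope == "child_only") {
    ok(child_dp)
  } else {
    ok(child_dp) & ok(father_dp) & ok(mother_dp)
  }
}

#' @rdname dnv_rules
#' @param child_gq Child genotype quality (GQ).
#' @export
rule_child_gq <- function(child_gq, config = filter_config()) {
  !is.na(child_gq) & child_gq >= config$min_gq
}

#' @rdname dnv_rules
#' @param ad_ref,ad_alt Child allele depths for the reference and alternate
#'   allele. The VAF denominator is `ad_ref + ad_alt` (allele-resolved), not
#'   DP; a zero denominator fails.
#' @export
rule_child_vaf <- function(ad_ref, ad_alt, config = filter_config()) {
  denom <- ad_ref + ad_alt
  vaf <- ifelse(!is.na(denom) & denom > 0, ad_alt / denom, NA_real_)
  !is.na(vaf) & vaf >= config$min_child_vaf
}

#' @rdname dnv_rules
#' @param father_ad_alt,mother_ad_alt Parental alt-allele read counts (AD).
#' @export
rule_parent_reads <- function(father_ad_alt, mother_ad_alt,
                              config = filter_config()) {
  ok <- function(x) !is.na(x) & x <= config$max_parent_alt_reads
  ok(father_ad_alt) & ok(mother_ad_alt)
}

#' @rdname dnv_rules
#' @param chrom,pos,ref Variant coordinates; the reference span
#'   `[pos-1, pos-1+nchar(ref))` (0-based half-open) is tested for overlap.
#' @param blacklist An [interval_set()] of excluded regions.
#' @export
rule_blacklist <- function(chrom, pos, ref, blacklist) {
  if (is.null(blacklist)) return(rep(TRUE, length(chrom)))
  !interval_overlaps(blacklist, chrom, pos - 1, pos - 1 + nchar(ref))
}

# Combine per-caller passes under the configured scope. pa/pb are logical
# vectors of per-caller outcomes; avail_* say whether that caller called the
# variant at all.
combine_callers <- function(pa, pb, in_a, in_b, scope) {
  pa[!in_a] <- NA
  pb[!in_b] <- NA
  if (scope == "both_callers") {
    out <- ifelse(is.na(pa), TRUE, pa) & ifelse(is.na(pb), TRUE, pb)
    out[!in_a & !in_b] <- FALSE
  } else {
    out <- ifelse(is.na(pa), FALSE, pa) | ifelse(is.na(pb), FALSE, pb)
  }
  out
}

#' Apply the eight-rule DNV filter with a per-rule audit trail
#'
#' Every paired record receives an audit entry (`pass` / `fail` /
#' `not_evaluated`) for each of the eight rules and a `final` verdict that is
#' `TRUE` exactly when every evaluated rule passed. Per-sample rules are
#' evaluated against each caller's evidence and combined under
#' `config$numeric_scope`. Records whose alleles contain `N` are flagged
#' (`n_allele = TRUE`) and always fail. Bad or missing evidence fails the
#' affected rule; it never raises an error.
#'
#' @param paired Paired records from [intersect_callsets()].
#' @param blacklist An [interval_set()] of excluded regions (repeat,
#'   low-complexity, centromere zones), or `NULL` for none.
#' @param config A [filter_config()].
#' @return Candidate-DNV data.frame: key and evidence columns, per-caller
#'   child VAF, `rule_*` audit columns, `n_allele` and `final`.
#' @export
call_dnvs <- function(paired, blacklist = NULL, config = filter_config()) {
  d <- paired
  n <- nrow(d)
  if (is.null(d$in_a)) d$in_a <- rep(TRUE, n)
  if (is.null(d$in_b)) d$in_b <- rep(TRUE, n)
  if (is.null(d$in_both)) d$in_both <- d$in_a & d$in_b

  vaf_of <- function(r, a) ifelse(!is.na(r + a) & (r + a) > 0, a / (r + a), NA_real_)
  d$child_vaf_a <- vaf_of(d$child_ad_ref_a, d$child_ad_alt_a)
  d$child_vaf_b <- vaf_of(d$child_ad_ref_b, d$child_ad_alt_b)

  per_caller <- function(f) {
    list(a = f("a"), b = f("b"))
  }
  scope <- config$numeric_scope
  comb <- function(p) combine_callers(p$a, p$b, d$in_a, d$in_b, scope)

  raw <- list(
    child_genotype = comb(per_caller(function(s)
      rule_child_genotype(d[[paste0("child_gt_", s)]], config))),
    parents_homref = comb(per_caller(function(s)
      rule_parents_homref(d[[paste0("father_gt_", s)]],
                          d[[paste0("mother_gt_", s)]]))),
    intersection = d$in_both,
    depth = comb(per_caller(function(s)
      rule_depth(d[[paste0("child_dp_", s)]], d[[paste0("father_dp_", s)]],
                 d[[paste0("mother_dp_", s)]], config))),
    child_gq = comb(per_caller(function(s)
      rule_child_gq(d[[paste0("child_gq_", s)]], config))),
    child_vaf = comb(per_caller(function(s)
      rule_child_vaf(d[[paste0("child_ad_ref_", s)]],
                     d[[paste0("child_ad_alt_", s)]], config))),
    parent_reads = comb(per_caller(function(s)
      rule_parent_reads(d[[paste0("father_ad_alt_", s)]],
                        d[[paste0("mother_ad_alt_", s)]], config))),
    blacklist = rule_blacklist(d$chrom, d$pos, d$ref, blacklist)
  )

  final <- rep(TRUE, n)
  for (rn in dnv_rule_names()) {
    col <- paste0("rule_", rn)
    if (!config$rules_enabled[[rn]]) {
      d[[col]] <- rep("not_evaluated", n)
    } else {
      d[[col]] <- ifelse(raw[[rn]], "pass", "fail")
      final <- final & raw[[rn]]
    }
  }
  d$n_allele <- grepl("N", d$ref, fixed = TRUE) | grepl("N", d$alt, fixed = TRUE)
  d$final <- final & !d$n_allele
  d$confidence <- rep(NA_character_, n)
  d$rescue <- rep(NA_character_, n)
  d$confirmation <- rep(NA_character_, n)
  rownames(d) <- NULL
  d
}

#' Per-rule failure counts of a filtered callset
#'
#' @param dnvs Output of [call_dnvs()].
#' @return Named integer vector: records failing each rule (a record can
#'   fail several), plus `final` (passing) and `total`.
#' @export
filter_summary <- function(dnvs) {
  fails <- vapply(dnv_rule_names(), function(rn) {
    sum(dnvs[[paste0("rule_", rn)]] == "fail")
  }, integer(1))
  c(total = nrow(dnvs), final = sum(dnvs$final), fails)
}
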