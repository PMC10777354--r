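cfg <- filter_config()

test_that("genotype rules accept only de novo configurations", {
  expect_true(rule_child_genotype("0/1", cfg))
  expect_true(rule_child_genotype("1/1", cfg))
  expect_false(rule_child_genotype("0/0", cfg))
  expect_false(rule_child_genotype("./.", cfg))
  expect_false(rule_child_genotype(NA_character_, cfg))
  expect_true(rule_child_genotype("1", cfg))  # hemizygous as 1/1
  expect_false(rule_child_genotype("1", filter_config(allow_hemizygous = FALSE)))

  expect_true(rule_parents_homref("0/0", "0/0"))
  expect_false(rule_parents_homref("0/1", "0/0"))
  expect_false(rule_parents_homref("./.", "0/0"))  # conservative on missing
})

test_that("numeric rules are inclusive at their thresholds", {
  # depth: "at least 10x" is >= 10
  expect_true(rule_depth(10L, 30L, 30L, cfg))
  expect_false(rule_depth(9L, 30L, 30L, cfg))
  expect_false(rule_depth(30L, 30L, 9L, cfg))  # all_trio scope
  expect_true(rule_depth(30L, 30L, 9L, filter_config(depth_scope = "child_only")))
  expect_false(rule_depth(NA_integer_, 30L, 30L, cfg))

  # GQ: "at least 20" is >= 20
  expect_true(rule_child_gq(20L, cfg))
  expect_false(rule_child_gq(19L, cfg))
  expect_false(rule_child_gq(NA_integer_, cfg))

  # VAF: "at least 25%" is >= 0.25, denominator ref+alt AD
  expect_true(rule_child_vaf(6L, 2L, cfg))         # exactly 0.25
  expect_false(rule_child_vaf(31L, 10L, cfg))      # 0.2439...
  expect_false(rule_child_vaf(0L, 0L, cfg))        # degenerate
  expect_false(rule_child_vaf(NA_integer_, 5L, cfg))

  # parents: no alt reads at default, configurable tolerance
  expect_true(rule_parent_reads(0L, 0L, cfg))
  expect_false(rule_parent_reads(0L, 1L, cfg))
  expect_true(rule_parent_reads(0L, 1L,
                                filter_config(max_parent_alt_reads = 1L)))
  expect_false(rule_parent_reads(NA_integer_, 0L, cfg))
})

test_that("blacklist overlap uses the variant's full reference span", {
  bl <- interval_set("chr1", 99, 200)
  expect_false(rule_blacklist("chr1", 100L, "A", bl))  # SNV inside
  expect_true(rule_blacklist("chr1", 99L, "A", bl))    # half-open boundary
  # 5 bp deletion starting at 1-based 96 spans into the interval;
  # brute-force per-base check as the oracle
  span_bases <- 96:100
  oracle_hit <- any(vapply(span_bases, function(p)
    interval_overlaps(bl, "chr1", p - 1), logical(1)))
  expect_true(oracle_hit)
  expect_false(rule_blacklist("chr1", 96L, "AAAAA", bl))
  expect_true(rule_blacklist("chr1", 94L, "AAAAA", bl))  # [93,98) vs [99,200)
  expect_true(rule_blacklist("chr1", 100L, "A", NULL))   # no blacklist
})

test_that("call_dnvs audits every rule and applies caller scope", {
  clean <- mk_paired()
  out <- call_dnvs(clean, NULL, cfg)
  expect_true(out$final)
  expect_true(all(unlist(out[paste0("rule_", dnv_rule_names())]) == "pass"))

  # caller B has low VAF: both_callers scope fails, either_caller passes
  lowb <- mk_paired(child_ad_ref_b = 28L, child_ad_alt_b = 2L)
  strict <- call_dnvs(lowb, NULL, cfg)
  expect_false(strict$final)
  expect_equal(strict$rule_child_vaf, "fail")
  expect_true(all(unlist(strict[paste0("rule_",
    setdiff(dnv_rule_names(), "child_vaf"))]) == "pass"))
  lax <- call_dnvs(lowb, NULL, filter_config(numeric_scope = "either_caller"))
  expect_true(lax$final)

  # caller-private record fails the intersection rule only
  priv <- mk_paired(in_b = FALSE, in_both = FALSE)
  ev_b <- setdiff(grep("_b$", names(priv), value = TRUE), "in_b")
  for (cl in ev_b) priv[[cl]] <- NA
  pout <- call_dnvs(priv, NULL, cfg)
  expect_false(pout$final)
  expect_equal(pout$rule_intersection, "fail")
  expect_true(all(unlist(pout[paste0("rule_",
    setdiff(dnv_rule_names(), "intersection"))]) == "pass"))

  # disabling a rule records not_evaluated and removes it from the verdict
  dis <- call_dnvs(priv, NULL,
                   filter_config(rules_enabled = c(intersection = FALSE)))
  expect_true(dis$final)
  expect_equal(dis$rule_intersection, "not_evaluated")

  # N alleles are flagged and never pass
  nn <- call_dnvs(mk_paired(alt = "N"), NULL, cfg)
  expect_true(nn$n_allele)
  expect_false(nn$final)
})

test_that("tightening thresholds never enlarges the final callset", {
  set.seed(123)
  n <- 100
  rand_row <- function(i) {
    mk_paired(pos = 100L + 7L * i,
              child_gt_a = sample(c("0/1", "1/1", "0/0", "./."), 1),
              child_dp_a = sample(5:40, 1), child_dp_b = sample(5:40, 1),
              father_dp_a = sample(5:40, 1), mother_dp_a = sample(5:40, 1),
              child_gq_a = sample(5:90, 1), child_gq_b = sample(5:90, 1),
              child_ad_ref_a = sample(0:30, 1), child_ad_alt_a = sample(0:30, 1),
              father_ad_alt_a = sample(0:2, 1), mother_ad_alt_b = sample(0:2, 1))
  }
  fixtures <- do.call(rbind, lapply(seq_len(n), rand_row))
  base_cfg <- filter_config(min_depth = 10L, min_gq = 20L,
                            min_child_vaf = 0.25, max_parent_alt_reads = 1L)
  base <- call_dnvs(fixtures, NULL, base_cfg)
  tighter <- list(
    filter_config(min_depth = 15L, min_gq = 20L, min_child_vaf = 0.25,
                  max_parent_alt_reads = 1L),
    filter_config(min_depth = 10L, min_gq = 40L, min_child_vaf = 0.25,
                  max_parent_alt_reads = 1L),
    filter_config(min_depth = 10L, min_gq = 20L, min_child_vaf = 0.4,
                  max_parent_alt_reads = 1L),
    filter_config(min_depth = 10L, min_gq = 20L, min_child_vaf = 0.25,
                  max_parent_alt_reads = 0L))
  keys <- function(d) variant_key(d$chrom, d$pos, d$ref, d$alt)[d$final]
  for (tc in tighter) {
    expect_true(all(keys(call_dnvs(fixtures, NULL, tc)) %in% keys(base)))
  }
})

test_that("no inherited variant survives the genotype and parental-read rules", {
  set.seed(321)
  for (i in 1:50) {
    carrier <- sample(c("father", "mother"), 1)
    gt <- sample(c("0/1", "1/1"), 1)
    alt_reads <- sample(5:20, 1)
    args <- list(pos = 1000L + 11L * i)
    for (sfx in c("a", "b")) {
      args[[paste0(carrier, "_gt_", sfx)]] <- gt
      args[[paste0(carrier, "_ad_alt_", sfx)]] <- alt_reads
    }
    row <- do.call(mk_paired, args)
    out <- call_dnvs(row, NULL, cfg)
    expect_false(out$final)
    expect_true(out$rule_parents_homref == "fail" ||
                out$rule_parent_reads == "fail")
  }
})

test_that("audit accounting reconciles totals", {
  set.seed(9)
  rows <- do.call(rbind, lapply(1:40, function(i) {
    mk_paired(pos = 50L + 13L * i,
              child_gq_a = sample(c(10L, 60L), 1),
              child_dp_a = sample(c(8L, 30L), 1))
  }))
  out <- call_dnvs(rows, NULL, cfg)
  failed <- !out$final
  # every failed record lists at least one failed rule
  rule_cols <- paste0("rule_", dnv_rule_names())
  n_failed_rules <- rowSums(out[rule_cols] == "fail")
  expect_true(all(n_failed_rules[failed] >= 1))
  expect_true(all(n_failed_rules[!failed] == 0))
  expect_equal(sum(out$final) + sum(failed), nrow(out))
})
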