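snv_table <- function(ref, alt, chrom = "chr1", pos = NULL) {
  if (is.null(pos)) pos <- seq_along(ref) * 10L
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

test_that("Ti/Tv counts transitions over transversions, SNVs only", {
  expect_equal(titv_ratio(snv_table(c("A", "C", "C"), c("G", "T", "A"))), 2.0)
  expect_true(is.na(titv_ratio(snv_table("A", "G"))))  # no transversions
  # indels excluded from both sides
  d <- snv_table(c("A", "C", "AT"), c("G", "A", "A"))
  expect_equal(titv_ratio(d), 1.0)
  # partition additivity: numerators and denominators add
  set.seed(1)
  u <- key_universe(600)
  part <- sample(1:3, 600, replace = TRUE)
  count_titv <- function(d) {
    snv <- nchar(d$ref) == 1 & nchar(d$alt) == 1
    ti <- sum(snv & paste0(d$ref, d$alt) %in% c("AG", "GA", "CT", "TC"))
    c(ti = ti, tv = sum(snv) - ti)
  }
  whole <- count_titv(u)
  parts <- Reduce(`+`, lapply(1:3, function(k) count_titv(u[part == k, ])))
  expect_equal(parts, whole)
  expect_equal(titv_ratio(u), whole[["ti"]] / whole[["tv"]])
})

test_that("uniform substitutions give Ti/Tv near 4/8 at n = 12000", {
  set.seed(2027)
  bases <- c("A", "C", "G", "T")
  subs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$alt, ]  # the 12 substitution types
  pick <- subs[sample.int(12, 12000, replace = TRUE), ]
  r <- titv_ratio(snv_table(pick$ref, pick$alt))
  # 4 transition types / 8 transversion types = 0.5; 3 SD Monte-Carlo band
  expect_lt(abs(r - 0.5), 0.03)
})

test_that("CpG detection reads the dinucleotide context on both strands", {
  ref <- ref_from_strings(chr1 = "ACGT")
  # C at position 2 followed by G: CpG
  expect_equal(cpg_fraction(snv_table("C", "T", pos = 2L), ref), 1.0)
  # G at position 3 preceded by C: CpG
  expect_equal(cpg_fraction(snv_table("G", "A", pos = 3L), ref), 1.0)
  # A at position 1: not CpG; also covers the no-left-neighbour edge
  expect_equal(cpg_fraction(snv_table("A", "G", pos = 1L), ref), 0.0)
  # contig-edge G with no preceding base
  ref2 <- ref_from_strings(chr1 = "GCGT")
  expect_equal(cpg_fraction(snv_table("G", "A", pos = 1L), ref2), 0.0)
  # order and strand-restatement invariance
  d2 <- snv_table(c("C", "G"), c("T", "A"), pos = c(2L, 3L))
  expect_equal(cpg_fraction(d2, ref), cpg_fraction(d2[2:1, ], ref))
})

test_that("a constructed genome yields the planted CpG proportion exactly", {
  # genome of 100 well-separated C sites: 20 followed by G (CpG), 80 by A
  blocks <- c(rep("TTCGTTTTTT", 20), rep("TTCATTTTTT", 80))
  ref <- ref_from_strings(chrC = paste(blocks, collapse = ""))
  pos <- 10L * (0:99) + 3L   # every site is the C of its block
  d <- snv_table(rep("C", 100), rep("T", 100), chrom = "chrC", pos = pos)
  expect_equal(cpg_fraction(d, ref), 0.20)
  # indels: excluded from the default denominator, included with "all"
  d2 <- rbind(d, data.frame(chrom = "chrC", pos = 501L, ref = "TT", alt = "T"))
  expect_equal(cpg_fraction(d2, ref), 0.20)
  expect_equal(cpg_fraction(d2, ref, denominator = "all"), 20 / 101)
})

test_that("per-sample summaries aggregate counts with cohort mean and SD", {
  ref <- ref_from_strings(chr1 = strrep("ACGT", 300))
  tabs <- list(kid1 = key_universe(70), kid2 = key_universe(80),
               kid3 = key_universe(90))
  tabs <- lapply(tabs, function(d) { d$chrom <- "chr1"; d$pos <- pmin(d$pos, 1100L); d })
  s <- per_sample_summary(tabs, ref)
  expect_equal(s$n_dnv[1:3], c(70L, 80L, 90L))
  cohort <- s[s$child == "cohort", ]
  expect_equal(cohort$mean_n, 80)
  expect_equal(cohort$sd_n, 10)
  # single trio: SD undefined
  s1 <- per_sample_summary(tabs[1], ref)
  expect_true(is.na(s1$sd_n[s1$child == "cohort"]))
  # empty callset row
  s0 <- per_sample_summary(list(none = key_universe(5)[0, ]), ref)
  expect_equal(s0$n_dnv[1], 0L)
  expect_true(is.na(s0$titv[1]))
  expect_true(is.na(s0$pct_cpg[1]))
})

test_that("callset overlap patterns match per-key enumeration", {
  ov <- compare_callsets(list(A = c("v1", "v2"), B = c("v2", "v3")))
  expect_setequal(ov$pattern, c("A", "B", "A&B"))
  expect_true(all(ov$count == 1L))

  same <- compare_callsets(list(A = c("x", "y"), B = c("y", "x")))
  expect_equal(same$pattern, "A&B")
  expect_equal(same$count, 2L)

  set.seed(555)
  universe_keys <- sprintf("k%03d", 1:400)
  sets <- lapply(1:5, function(i) sample(universe_keys, 200))
  names(sets) <- paste0("S", 1:5)
  ov <- compare_callsets(sets)
  # brute-force per-key membership enumeration
  union_keys <- unique(unlist(sets))
  oracle <- table(vapply(union_keys, function(k) {
    paste(names(sets)[vapply(sets, function(s) k %in% s, logical(1))],
          collapse = "&")
  }, character(1)))
  expect_equal(sum(ov$count), length(union_keys))
  for (i in seq_len(nrow(ov))) {
    expect_equal(ov$count[i], unname(as.integer(oracle[ov$pattern[i]])))
  }
  # deterministic ordering: descending count, ties lexicographic
  expect_true(all(diff(ov$count) <= 0))
})
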