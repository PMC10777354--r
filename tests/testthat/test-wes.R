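test_that("zone arithmetic at buffer 50 / margin 10 trims 40 bp flanks", {
  z <- build_zones(interval_set("chr1", 1000, 1200), 50, 10)
  expect_equal(as.data.frame(z$high),
               data.frame(chrom = "chr1", start = 1040, end = 1160))
  expect_equal(as.data.frame(z$low),
               data.frame(chrom = "chr1", start = c(1000, 1160),
                          end = c(1040, 1200)))
  # high and low partition the padded interval
  expect_equal(interval_total_width(z$high) + interval_total_width(z$low), 200)

  # interval of length 80 cannot hold a high zone
  expect_warning(z80 <- build_zones(interval_set("chr1", 0, 80), 50, 10),
                 "entirely low")
  expect_equal(interval_total_width(z80$high), 0)
  expect_equal(interval_total_width(z80$low), 80)

  # margin = buffer: the whole padded interval is high
  zlim <- build_zones(interval_set("chr1", 1000, 1200), 50, 50)
  expect_equal(interval_total_width(zlim$high), 200)
  expect_equal(interval_total_width(zlim$low), 0)
})

test_that("classification boundaries follow the half-open convention", {
  z <- build_zones(interval_set("chr1", 1000, 1200), 50, 10)
  d <- data.frame(chrom = "chr1", pos = c(1041L, 1040L, 1160L, 1161L, 2000L),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  out <- classify_dnvs(d, z)
  # 1-based 1041 -> 0-based 1040 = first high base; 1160 -> 1159 last high
  expect_equal(out$confidence,
               c("high", "low", "high", "low", "off_target"))
})

test_that("zone labels match a per-base brute-force oracle on random intervals", {
  set.seed(2024)
  for (trial in 1:4) {
    n <- 8
    start <- sample(seq(0, 4000, by = 120), n)
    width <- sample(c(60, 90, 150, 300), n, replace = TRUE)
    capture <- interval_set(rep("c", n), start, start + width)
    buffer <- 50L; margin <- 10L; trim <- buffer - margin
    z <- suppressWarnings(build_zones(capture, buffer, margin))
    merged <- as.data.frame(capture)
    # oracle: label every base by direct distance computation on the merged
    # intervals
    oracle <- rep("off_target", 5000)
    for (i in seq_len(nrow(merged))) {
      s <- merged$start[i]; e <- merged$end[i]
      for (p0 in s:(e - 1)) {
        oracle[p0 + 1] <- if ((e - s) > 2 * trim &&
                              p0 >= s + trim && p0 < e - trim) "high" else "low"
      }
    }
    d <- data.frame(chrom = "c", pos = 1:5000, ref = "A", alt = "G",
                    stringsAsFactors = FALSE)  # 1-based pos = p0 + 1
    got <- classify_dnvs(d, z)$confidence
    expect_equal(got, oracle)
    # partition: inside capture every base is exactly one of high/low
    inside <- interval_overlaps(capture, rep("c", 5000), 0:4999)
    expect_true(all(got[inside] %in% c("high", "low")))
    expect_true(all(got[!inside] == "off_target"))
  }
})

test_that("zones are invariant to interval input order and monotone in margin", {
  set.seed(3)
  n <- 10
  start <- sample(seq(0, 3000, by = 130), n)
  width <- sample(c(100, 200, 250), n, replace = TRUE)
  perm <- sample.int(n)
  z1 <- suppressWarnings(build_zones(interval_set(rep("c", n), start, start + width)))
  z2 <- suppressWarnings(build_zones(interval_set(rep("c", n), start[perm],
                                                  (start + width)[perm])))
  expect_equal(as.data.frame(z1$high), as.data.frame(z2$high))
  expect_equal(as.data.frame(z1$low), as.data.frame(z2$low))

  # shrinking margin toward 0 never moves a position from low to high
  capture <- interval_set(rep("c", n), start, start + width)
  pos <- 1:3500
  prev_high <- NULL
  for (m in c(30L, 20L, 10L, 0L)) {
    z <- suppressWarnings(build_zones(capture, 50L, m))
    hi <- interval_overlaps(z$high, rep("c", length(pos)), pos - 1)
    if (!is.null(prev_high)) expect_true(all(hi <= prev_high))
    prev_high <- hi
  }
})

test_that("pileup rescue keeps only child-supported, parent-clean DNVs", {
  d <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                  ref = "A", alt = "G",
                  confidence = c("high", "high", "high", "low", "high"),
                  stringsAsFactors = FALSE)
  pu <- rbind(
    data.frame(chrom = "chr1", pos = 10L, sample = c("child", "father", "mother"),
               depth = 30L, ref_count = c(25L, 30L, 30L), alt_count = c(5L, 0L, 0L)),
    data.frame(chrom = "chr1", pos = 20L, sample = c("child", "father", "mother"),
               depth = 30L, ref_count = c(25L, 29L, 30L), alt_count = c(5L, 1L, 0L)),
    data.frame(chrom = "chr1", pos = 30L, sample = c("child", "father", "mother"),
               depth = 30L, ref_count = c(30L, 30L, 30L), alt_count = c(0L, 0L, 0L)))
  out <- pileup_rescue(d, pu)
  expect_equal(out$rescue,
               c("retain",    # child 5, parents 0/0
                 "drop",      # father carries 1 alt read
                 "drop",      # child has no alt support
                 NA,          # low confidence: not subjected to the test
                 "no_pileup"))# no evidence at pos 50
})
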