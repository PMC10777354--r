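#' Configuration for the synthetic trio simulator
#'
#' Defines the study conditions emulated by [simulate_trio()]: a small random
#' genome, Mendelian-consistent trio genotypes from two simulated callers,
#' planted true DNVs that satisfy every filter rule, one violation class per
#' filter rule, inherited variation, caller discordance, and pileup evidence
#' with controlled allele fractions. The seed fully determines every output.
#'
#' @param seed Integer seed; drives all randomness.
#' @param n_contigs,contig_length Genome shape (default two 100 kb contigs).
#' @param gc GC fraction of the random genome.
#' @param n_inherited Inherited (Mendelian) variants planted; a handful are
#'   emitted as multi-allelic records and a fraction as deliberately
#'   non-minimal spellings, to exercise decomposition and normalization.
#' @param n_true_dnvs True de novo SNVs planted; every one satisfies all
#'   eight filter rules in both callers (unless made caller-private).
#' @param n_violations_per_rule Variants planted per filter rule, each
#'   violating exactly that one rule.
#' @param depth_mean,depth_dispersion Negative-binomial read depth model
#'   (mean and size); clean sites are floored at 12x so depth never
#'   interferes with other rule classes.
#' @param child_vaf_shape Beta(shape, shape) model for the child's true DNV
#'   allele fraction, centred at 0.5; draws are truncated to (0.30, 0.70) so
#'   planted DNVs always clear the 25% VAF rule.
#' @param parent_error Per-read error rate used for parental alt counts in
#'   deep pileup simulation.
#' @param caller_discordance Probability a true DNV is emitted by only one
#'   caller (and is therefore lost to the intersection rule).
#' @param blacklist_fraction Fraction of the genome covered by the
#'   blacklist.
#' @param titv_bias Probability a planted substitution is a transition
#'   (2/3 gives the genome-wide Ti/Tv of about 2 typical of real DNVs).
#' @param cpg_fraction_true Fraction of true DNVs placed at CpG sites (as
#'   C>T / G>A transitions), emulating CpG hypermutability.
#' @param sample_ids Child/father/mother sample names written to the VCFs.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_contigs = 2L, contig_length = 100000L,
                              gc = 0.4, n_inherited = 100L, n_true_dnvs = 50L,
                              n_violations_per_rule = 5L,
                              depth_mean = 30, depth_dispersion = 8,
                              child_vaf_shape = 20, parent_error = 0.001,
                              caller_discordance = 0.2,
                              blacklist_fraction = 0.05,
                              titv_bias = 2 / 3, cpg_fraction_true = 0.2,
                              sample_ids = c(child = "CHILD", father = "FATHER",
                                             mother = "MOTHER")) {
  stopifnot(n_contigs >= 1, contig_length >= 2000, gc > 0, gc < 1,
            n_inherited >= 0, n_true_dnvs >= 0, n_violations_per_rule >= 0,
            caller_discordance >= 0, caller_discordance <= 1,
            blacklist_fraction >= 0, blacklist_fraction < 1,
            parent_error >= 0, parent_error <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

rand_genome <- function(cfg) {
  probs <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
             T = (1 - cfg$gc) / 2)
  seqs <- vapply(seq_len(cfg$n_contigs), function(i) {
    paste(sample(names(probs), cfg$contig_length, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(cfg$n_contigs))
  Biostrings::DNAStringSet(seqs)
}

# Non-overlapping random intervals covering roughly `fraction` of each contig.
rand_intervals <- function(cfg, fraction, width) {
  chrom <- character(); start <- numeric(); end <- numeric()
  n_per <- max(0L, round(fraction * cfg$contig_length / width))
  for (ctg in paste0("chr", seq_len(cfg$n_contigs))) {
    if (n_per == 0) next
    anchors <- sort(sample.int(cfg$contig_length - width - 1L, n_per))
    chrom <- c(chrom, rep(ctg, n_per))
    start <- c(start, anchors)
    end <- c(end, anchors + width)
  }
  interval_set(chrom, start, end)
}

# Tile padded capture intervals (target + 50 bp buffer each side) over the
# first half of each contig, leaving the rest off-target.
capture_intervals <- function(cfg, target_len = 200L, buffer = 50L,
                              spacing = 1000L) {
  width <- target_len + 2L * buffer
  chrom <- character(); start <- numeric()
  for (ctg in paste0("chr", seq_len(cfg$n_contigs))) {
    anchors <- seq(200L, floor(cfg$contig_length / 2), by = spacing)
    chrom <- c(chrom, rep(ctg, length(anchors)))
    start <- c(start, anchors)
  }
  interval_set(chrom, start, start + width)
}

trunc_beta <- function(n, shape, lo = 0.30, hi = 0.70) {
  v <- stats::rbeta(n, shape, shape)
  pmin(pmax(v, lo), hi)
}

clean_depth <- function(n, cfg) {
  pmax(12L, stats::rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_dispersion))
}

alt_base <- function(ref, titv_bias) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  if (stats::runif(1) < titv_bias) {
    transition[[ref]]
  } else {
    sample(setdiff(setdiff(c("A", "C", "G", "T"), ref), transition[[ref]]), 1)
  }
}

# One caller's view of clean child-het evidence with true VAF v: small
# independent jitter that never leaves the all-rules-pass region.
jitter_clean_child <- function(dp, gq, v) {
  dp_c <- max(10L, dp + sample(-2:2, 1))
  alt <- round(dp_c * v)
  alt <- min(max(alt, ceiling(0.28 * dp_c)), floor(0.72 * dp_c))
  gq_c <- max(25L, min(99L, gq + sample(-3:3, 1)))
  list(gt = "0/1", dp = dp_c, gq = gq_c, ad = c(dp_c - alt, alt))
}

jitter_clean_parent <- function(dp, gq) {
  dp_c <- max(10L, dp + sample(-2:2, 1))
  gq_c <- max(25L, min(99L, gq + sample(-3:3, 1)))
  list(gt = "0/0", dp = dp_c, gq = gq_c, ad = c(dp_c, 0L))
}

#' Simulate a complete synthetic trio dataset
#'
#' Writes, under `out_dir`: the reference FASTA; two joint-genotyped trio
#' VCFs (`callerA.vcf`, `callerB.vcf`) with GT/DP/GQ/AD; single-sample
#' samtools-mpileup-format text for child, father and mother covering every
#' emitted site; a region blacklist BED; a padded capture BED; and
#' `truth.tsv` labelling every emitted variant as `true_dnv`, `inherited`,
#' `caller_private` (a true DNV emitted by only one caller) or
#' `violation:<rule>`. Planted true DNVs satisfy every filter rule; each
#' violation class breaks exactly one rule. Outputs are byte-identical for
#' identical configs.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a manifest list: file paths, planted-class counts and
#'   the truth table; also written as `manifest.yaml`.
#' @export
simulate_trio <- function(cfg = simulation_config(), out_dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  genome <- rand_genome(cfg)
  blacklist <- rand_intervals(cfg, cfg$blacklist_fraction, width = 500L)
  capture <- capture_intervals(cfg)

  # --- candidate positions: an 11 bp grid keeps planted variants from
  # colliding even after indel left-alignment
  pool <- list()
  for (ctg in names(genome)) {
    cand <- seq(150L, cfg$contig_length - 150L, by = 11L)
    inside_bl <- interval_overlaps(blacklist, rep(ctg, length(cand)),
                                   cand - 1, cand)
    pool[[ctg]] <- list(clean = cand[!inside_bl], bl = cand[inside_bl])
  }
  pool_df <- function(slot) {
    do.call(rbind, lapply(names(pool), function(ctg) {
      p <- pool[[ctg]][[slot]]
      data.frame(chrom = rep(ctg, length(p)), pos = p,
                 stringsAsFactors = FALSE)
    }))
  }
  clean_pool <- pool_df("clean")
  bl_pool <- pool_df("bl")
  clean_pool <- clean_pool[sample.int(nrow(clean_pool)), , drop = FALSE]
  bl_pool <- bl_pool[sample.int(nrow(bl_pool)), , drop = FALSE]

  nv <- cfg$n_violations_per_rule
  n_ma <- min(5L, cfg$n_inherited %/% 10L)      # multi-allelic inherited sites
  n_bi <- cfg$n_inherited - 2L * n_ma
  n_clean_needed <- cfg$n_true_dnvs + n_bi + n_ma + 7L * nv
  if (nrow(clean_pool) < n_clean_needed) {
    stop(sprintf("genome too small: need %d clean sites, have %d",
                 n_clean_needed, nrow(clean_pool)))
  }
  if (nrow(bl_pool) < nv && nv > 0) {
    stop(sprintf(
      "blacklist fraction %.3f leaves only %d blacklisted site(s); %d needed",
      cfg$blacklist_fraction, nrow(bl_pool), nv))
  }
  take <- function(pool, n) {
    if (n == 0) return(list(rows = pool[0, ], rest = pool))
    list(rows = pool[seq_len(n), , drop = FALSE],
         rest = pool[-seq_len(n), , drop = FALSE])
  }

  base_at <- function(chrom, pos) ref_bases(genome, chrom, pos, 1L)

  # find CpG "C" positions in the clean pool for planted hypermutable DNVs
  is_cpg_c <- function(chrom, pos) {
    base_at(chrom, pos) == "C" & base_at(chrom, pos + 1L) == "G"
  }

  records <- list()   # per emitted VCF record (possibly multi-allelic)
  truth <- list()     # per planted allele
  emit <- function(chrom, pos, ref, alts, calls_a, calls_b, in_a, in_b,
                   classes, truth_keys) {
    records[[length(records) + 1L]] <<- list(
      chrom = chrom, pos = pos, ref = ref, alts = alts,
      calls_a = calls_a, calls_b = calls_b, in_a = in_a, in_b = in_b)
    for (k in seq_along(alts)) {
      truth[[length(truth) + 1L]] <<- data.frame(
        chrom = truth_keys$chrom[k], pos = truth_keys$pos[k],
        ref = truth_keys$ref[k], alt = truth_keys$alt[k],
        class = classes[k], in_a = in_a, in_b = in_b,
        child_vaf = truth_keys$child_vaf[k],
        child_alt_pileup = truth_keys$child_alt[k],
        father_alt_pileup = truth_keys$father_alt[k],
        mother_alt_pileup = truth_keys$mother_alt[k],
        stringsAsFactors = FALSE)
    }
  }
  fmt_call <- function(gt, dp, gq, ad) {
    list(gt = gt, dp = dp, gq = gq, ad = ad)
  }

  ## ---- true DNVs (SNVs; a planted fraction at CpG sites) ----------------
  n_cpg <- round(cfg$cpg_fraction_true * cfg$n_true_dnvs)
  cpg_idx <- which(is_cpg_c(clean_pool$chrom, clean_pool$pos))
  cpg_rows <- clean_pool[cpg_idx[seq_len(min(n_cpg, length(cpg_idx)))], , drop = FALSE]
  clean_pool <- clean_pool[setdiff(seq_len(nrow(clean_pool)),
                                   cpg_idx[seq_len(min(n_cpg, length(cpg_idx)))]), ,
                           drop = FALSE]
  tk <- take(clean_pool, cfg$n_true_dnvs - nrow(cpg_rows))
  clean_pool <- tk$rest
  dnv_sites <- rbind(cpg_rows, tk$rows)
  dnv_is_cpg <- c(rep(TRUE, nrow(cpg_rows)), rep(FALSE, nrow(tk$rows)))

  for (i in seq_len(nrow(dnv_sites))) {
    chrom <- dnv_sites$chrom[i]; pos <- dnv_sites$pos[i]
    ref <- base_at(chrom, pos)
    alt <- if (dnv_is_cpg[i]) "T" else alt_base(ref, cfg$titv_bias)
    v <- trunc_beta(1, cfg$child_vaf_shape)
    dp <- clean_depth(3, cfg); gq <- sample(40:99, 3, replace = TRUE)
    in_a <- TRUE; in_b <- TRUE
    if (stats::runif(1) < cfg$caller_discordance) {
      if (stats::runif(1) < 0.5) in_b <- FALSE else in_a <- FALSE
    }
    mk <- function() list(
      child = do.call(fmt_call, jitter_clean_child(dp[1], gq[1], v)),
      father = do.call(fmt_call, jitter_clean_parent(dp[2], gq[2])),
      mother = do.call(fmt_call, jitter_clean_parent(dp[3], gq[3])))
    ca <- mk(); cb <- mk()
    # pileup evidence mirrors the first caller that emitted the site
    child_alt <- if (in_a) ca$child$ad[2] else cb$child$ad[2]
    emit(chrom, pos, ref, alt, ca, cb, in_a, in_b,
         classes = if (in_a && in_b) "true_dnv" else "caller_private",
         truth_keys = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                                 child_vaf = v, child_alt = child_alt,
                                 father_alt = 0L, mother_alt = 0L))
  }

  ## ---- inherited variants ----------------------------------------------
  tk <- take(clean_pool, n_bi); clean_pool <- tk$rest
  bi_sites <- tk$rows
  for (i in seq_len(nrow(bi_sites))) {
    chrom <- bi_sites$chrom[i]; pos <- bi_sites$pos[i]
    ref <- base_at(chrom, pos)
    kind <- sample(c("snv", "snv_padded", "ins", "del"), 1,
                   prob = c(0.6, 0.2, 0.1, 0.1))
    if (kind %in% c("snv", "snv_padded")) {
      alt <- alt_base(ref, cfg$titv_bias)
      w_pos <- pos; w_ref <- ref; w_alt <- alt
      if (kind == "snv_padded") {  # non-minimal spelling: shared suffix base
        sfx <- base_at(chrom, pos + 1L)
        w_ref <- paste0(ref, sfx); w_alt <- paste0(alt, sfx)
      }
    } else if (kind == "ins") {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
                   collapse = "")
      w_pos <- pos; w_ref <- ref; w_alt <- paste0(ref, ins)
    } else {
      dlen <- sample(1:3, 1)
      w_pos <- pos; w_ref <- ref_bases(genome, chrom, pos, 1L + dlen)
      w_alt <- ref
    }
    nv_key <- normalize_variant(chrom, w_pos, w_ref, w_alt, genome)
    carrier <- sample(c("father", "mother"), 1)
    v <- trunc_beta(2, cfg$child_vaf_shape)
    dp <- clean_depth(3, cfg); gq <- sample(40:99, 3, replace = TRUE)
    het <- function(dpx, gqx, vx) {
      alt_n <- max(1L, round(dpx * vx))
      fmt_call("0/1", dpx, gqx, c(dpx - alt_n, alt_n))
    }
    hom <- function(dpx, gqx) fmt_call("0/0", dpx, gqx, c(dpx, 0L))
    mk <- function() {
      calls <- list(child = het(dp[1], gq[1], v[1]))
      calls$father <- if (carrier == "father") het(dp[2], gq[2], v[2]) else hom(dp[2], gq[2])
      calls$mother <- if (carrier == "mother") het(dp[3], gq[3], v[2]) else hom(dp[3], gq[3])
      calls
    }
    emit(chrom, w_pos, w_ref, w_alt, mk(), mk(), TRUE, TRUE, "inherited",
         truth_keys = data.frame(chrom = nv_key$chrom, pos = nv_key$pos,
                                 ref = nv_key$ref, alt = nv_key$alt,
                                 child_vaf = v[1],
                                 child_alt = max(1L, round(dp[1] * v[1])),
                                 father_alt = if (carrier == "father")
                                   max(1L, round(dp[2] * v[2])) else 0L,
                                 mother_alt = if (carrier == "mother")
                                   max(1L, round(dp[3] * v[2])) else 0L))
  }

  # multi-allelic inherited: child 1/2, father carries alt1, mother alt2
  tk <- take(clean_pool, n_ma); clean_pool <- tk$rest
  ma_sites <- tk$rows
  for (i in seq_len(nrow(ma_sites))) {
    chrom <- ma_sites$chrom[i]; pos <- ma_sites$pos[i]
    ref <- base_at(chrom, pos)
    alts <- sample(setdiff(c("A", "C", "G", "T"), ref), 2)
    dp <- clean_depth(3, cfg); gq <- sample(40:99, 3, replace = TRUE)
    a1 <- round(dp[1] * 0.5); a2 <- dp[1] - a1
    mk <- function() list(
      child = list(gt = "1/2", dp = dp[1], gq = gq[1], ad = c(0L, a1, a2)),
      father = list(gt = "0/1", dp = dp[2], gq = gq[2],
                    ad = c(dp[2] - round(dp[2] / 2), round(dp[2] / 2), 0L)),
      mother = list(gt = "0/2", dp = dp[3], gq = gq[3],
                    ad = c(dp[3] - round(dp[3] / 2), 0L, round(dp[3] / 2))))
    emit(chrom, pos, ref, alts, mk(), mk(), TRUE, TRUE,
         classes = c("inherited", "inherited"),
         truth_keys = data.frame(chrom = chrom, pos = pos, ref = ref,
                                 alt = alts, child_vaf = 0.5,
                                 child_alt = c(a1, a2),
                                 father_alt = c(round(dp[2] / 2), 0L),
                                 mother_alt = c(0L, round(dp[3] / 2))))
  }

  ## ---- per-rule violations ---------------------------------------------
  viol_emit <- function(site, rule, child, father, mother, in_a = TRUE,
                        in_b = TRUE, child_alt = NULL) {
    chrom <- site$chrom; pos <- site$pos
    ref <- base_at(chrom, pos)
    alt <- alt_base(ref, cfg$titv_bias)
    calls <- list(child = child, father = father, mother = mother)
    if (is.null(child_alt)) child_alt <- child$ad[2]
    emit(chrom, pos, ref, alt, calls, calls, in_a, in_b,
         classes = paste0("violation:", rule),
         truth_keys = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                                 child_vaf = child$ad[2] /
                                   max(1L, sum(child$ad)),
                                 child_alt = child_alt,
                                 father_alt = father$ad[2],
                                 mother_alt = mother$ad[2]))
  }
  clean_child <- function() fmt_call("0/1", 30L, 60L, c(15L, 15L))
  clean_parent <- function() fmt_call("0/0", 30L, 60L, c(30L, 0L))
  for (j in seq_len(nv)) {
    tk <- take(clean_pool, 7L); clean_pool <- tk$rest
    s <- tk$rows
    viol_emit(s[1, ], "child_genotype",
              fmt_call("0/0", 30L, 60L, c(15L, 15L)),
              clean_parent(), clean_parent(), child_alt = 15L)
    viol_emit(s[2, ], "parents_homref", clean_child(),
              fmt_call("0/1", 30L, 60L, c(30L, 0L)), clean_parent())
    viol_emit(s[3, ], "intersection", clean_child(), clean_parent(),
              clean_parent(), in_a = (j %% 2 == 1), in_b = (j %% 2 == 0))
    viol_emit(s[4, ], "depth", fmt_call("0/1", 9L, 60L, c(5L, 4L)),
              clean_parent(), clean_parent())
    viol_emit(s[5, ], "child_gq", fmt_call("0/1", 30L, 19L, c(15L, 15L)),
              clean_parent(), clean_parent())
    viol_emit(s[6, ], "child_vaf", fmt_call("0/1", 41L, 60L, c(31L, 10L)),
              clean_parent(), clean_parent())
    viol_emit(s[7, ], "parent_reads", clean_child(), clean_parent(),
              fmt_call("0/0", 30L, 60L, c(24L, 1L)))
    # blacklist: clean evidence at a blacklisted position
    tkb <- take(bl_pool, 1L); bl_pool <- tkb$rest
    viol_emit(tkb$rows[1, ], "blacklist", clean_child(), clean_parent(),
              clean_parent())
  }

  ## ---- write outputs ----------------------------------------------------
  paths <- list(
    reference = file.path(out_dir, "reference.fa"),
    vcf_a = file.path(out_dir, "callerA.vcf"),
    vcf_b = file.path(out_dir, "callerB.vcf"),
    blacklist = file.path(out_dir, "blacklist.bed"),
    capture = file.path(out_dir, "capture.bed"),
    pileup_child = file.path(out_dir, "child.mpileup"),
    pileup_father = file.path(out_dir, "father.mpileup"),
    pileup_mother = file.path(out_dir, "mother.mpileup"),
    truth = file.path(out_dir, "truth.tsv"),
    manifest = file.path(out_dir, "manifest.yaml"))

  Biostrings::writeXStringSet(genome, paths$reference, width = 70L)
  write_bed(blacklist, paths$blacklist)
  write_bed(capture, paths$capture)

  ord <- order(match(vapply(records, `[[`, character(1), "chrom"), names(genome)),
               vapply(records, `[[`, numeric(1), "pos"))
  records <- records[ord]
  write_sim_vcf(records, "a", cfg, genome, paths$vcf_a)
  write_sim_vcf(records, "b", cfg, genome, paths$vcf_b)
  write_sim_mpileup(records, genome, paths)

  truth_df <- do.call(rbind, truth)
  truth_df <- truth_df[order(match(truth_df$chrom, names(genome)),
                             truth_df$pos, truth_df$alt), , drop = FALSE]
  rownames(truth_df) <- NULL
  utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  counts <- as.list(table(truth_df$class))
  manifest <- list(paths = paths,
                   counts = counts,
                   n_records = length(records),
                   seed = cfg$seed,
                   sample_ids = as.list(cfg$sample_ids))
  yaml::write_yaml(manifest, paths$manifest)
  manifest$truth <- truth_df
  invisible(manifest)
}

write_sim_vcf <- function(records, which_caller, cfg, genome, path) {
  present <- vapply(records, function(r)
    if (which_caller == "a") r$in_a else r$in_b, logical(1))
  recs <- records[present]
  ids <- cfg$sample_ids
  hdr <- c("##fileformat=VCFv4.2",
           "##source=triodnv-simulator",
           sprintf("##contig=<ID=%s,length=%d>", names(genome),
                   Biostrings::width(genome)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids[["child"]], ids[["father"]],
                   ids[["mother"]]),
                 collapse = "\t"))
  body <- vapply(recs, function(r) {
    calls <- if (which_caller == "a") r$calls_a else r$calls_b
    fmt <- function(cc) sprintf("%s:%d:%d:%s", cc$gt, cc$dp, cc$gq,
                                paste(cc$ad, collapse = ","))
    paste(c(r$chrom, r$pos, ".", r$ref, paste(r$alts, collapse = ","),
            ".", "PASS", ".", "GT:DP:GQ:AD",
            fmt(calls$child), fmt(calls$father), fmt(calls$mother)),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
}

# Synthesize single-sample mpileup text at every emitted site. Base strings
# carry realistic decoration: read-start (^ + mapping quality), read-end ($),
# strand-cased reference matches, and the planted alt counts embedded as
# substituted bases or +/- indel tokens.
write_sim_mpileup <- function(records, genome, paths) {
  token_for <- function(ref, alt) {
    q <- pileup_query(ref, alt)
    switch(q$type,
           snv = alt,
           ins = sprintf(".+%d%s", nchar(q$seq), q$seq),
           del = sprintf(".-%d%s", nchar(q$seq), q$seq),
           substr(alt, 1, 1))
  }
  mk_bases <- function(depth, alt_counts, tokens) {
    if (depth == 0) return("*")
    reads <- rep(tokens, alt_counts)
    reads <- c(reads, rep(".", max(0, depth - sum(alt_counts))))
    reads <- sample(reads)
    plain <- nchar(reads) == 1L
    low <- stats::runif(length(reads)) < 0.3  # reverse-strand spelling
    flip_ref <- low & plain & reads == "."
    flip_alt <- low & plain & reads != "."
    reads[flip_ref] <- ","
    reads[flip_alt] <- tolower(reads[flip_alt])
    reads[1] <- paste0("^]", reads[1])
    reads[length(reads)] <- paste0(reads[length(reads)], "$")
    paste(reads, collapse = "")
  }
  files <- list(child = character(), father = character(),
                mother = character())
  for (r in records) {
    # pileup counts follow caller A evidence when present, else caller B
    calls <- if (r$in_a) r$calls_a else r$calls_b
    refb <- ref_bases(genome, r$chrom, r$pos, 1L)
    tokens <- vapply(r$alts, function(a) token_for(r$ref, a), character(1))
    for (role in names(files)) {
      cc <- calls[[role]]
      bases <- mk_bases(cc$dp, cc$ad[-1], tokens)
      files[[role]] <- c(files[[role]], paste(
        r$chrom, r$pos, refb, cc$dp, bases,
        paste(rep("I", max(1, cc$dp)), collapse = ""), sep = "\t"))
    }
  }
  writeLines(files$child, paths$pileup_child)
  writeLines(files$father, paths$pileup_father)
  writeLines(files$mother, paths$pileup_mother)
  invisible(paths)
}

#' Simulate deep (e.g. 300x) confirmation pileup evidence
#'
#' Emulates an independent high-coverage sequencing run over called DNV
#' sites: child alt reads are drawn Binomial(depth, planted VAF), parental
#' alt reads Binomial(depth, `parent_error`). Written as a pre-counted
#' pileup TSV consumable by [read_pileup_tsv()].
#'
#' @param truth Truth table (or any data.frame with `chrom`, `pos`,
#'   `child_vaf`).
#' @param path Output TSV path.
#' @param depth Simulated depth per sample.
#' @param parent_error Per-read error rate in the parents.
#' @param seed Integer seed.
#' @return The pileup counts data.frame, invisibly; TSV written to `path`.
#' @export
simulate_deep_pileup <- function(truth, path, depth = 300L,
                                 parent_error = 0.001, seed = 1L) {
  set.seed(seed)
  n <- nrow(truth)
  rows <- vector("list", 3L * n)
  for (i in seq_len(n)) {
    ca <- stats::rbinom(1, depth, truth$child_vaf[i])
    fa <- stats::rbinom(1, depth, parent_error)
    mo <- stats::rbinom(1, depth, parent_error)
    mk <- function(role, alt) data.frame(
      chrom = truth$chrom[i], pos = truth$pos[i], sample = role,
      depth = depth, ref_count = depth - alt, alt_count = alt,
      stringsAsFactors = FALSE)
    rows[[3 * i - 2]] <- mk("child", ca)
    rows[[3 * i - 1]] <- mk("father", fa)
    rows[[3 * i]] <- mk("mother", mo)
  }
  d <- if (n > 0) do.call(rbind, rows) else empty_pileup_table()
  write_pileup_tsv(d, path)
  invisible(d)
}
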