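# independent normalization oracle: build the full alternate haplotype,
# then take the longest-common-prefix/suffix core of (reference, haplotype)
# -- no shifting loop involved
normal_form_oracle <- function(seq, pos, ref, alt) {
  n <- nchar(seq)
  hap <- paste0(substr(seq, 1, pos - 1), alt,
                substr(seq, pos + nchar(ref), n))
  s <- strsplit(seq, "")[[1]]; h <- strsplit(hap, "")[[1]]
  # maximal common suffix first (left alignment), then prefix
  b <- 0
  while (b < min(length(s), length(h)) &&
         s[length(s) - b] == h[length(h) - b]) b <- b + 1
  a <- 0
  while (a < min(length(s), length(h)) - b && s[a + 1] == h[a + 1]) a <- a + 1
  ref_core <- s[seq_len(length(s) - b)][-seq_len(a)]
  alt_core <- h[seq_len(length(h) - b)][-seq_len(a)]
  if (!length(ref_core) || !length(alt_core)) {
    # anchor with the preceding reference base
    list(pos = a, ref = paste(s[a:(length(s) - b)], collapse = ""),
         alt = paste(h[a:(length(h) - b)], collapse = ""))
  } else {
    list(pos = a + 1, ref = paste(ref_core, collapse = ""),
         alt = paste(alt_core, collapse = ""))
  }
}

test_that("variant normalization left-aligns and trims to parsimony", {
  seq <- "GGGCAAAAAATTTT"   # A-run at 5..10
  ref <- Biostrings::DNAStringSet(c(chr1 = seq))
  # deletion of one A written at the right end of the run
  s <- variant_sites("chr1", 9, "AA", "A", 0L, 1L)
  out <- normalize_variants(s, ref)
  o <- normal_form_oracle(seq, 9, "AA", "A")
  expect_equal(out$pos, o$pos)
  expect_equal(out$ref, o$ref)
  expect_equal(out$alt, o$alt)
  expect_equal(out$pos, 4)  # anchored at the C before the run
  # idempotence
  out2 <- normalize_variants(out, ref)
  expect_equal(as.data.frame(out2), as.data.frame(out))
  # reference mismatch is an error naming the site
  bad <- variant_sites("chr1", 2, "T", "A", 0L, 1L)
  expect_error(normalize_variants(bad, ref), "chr1:2")
})

test_that("normalization agrees with the haplotype-core oracle on random indels", {
  set.seed(71)
  for (rep in 1:40) {
    unit <- paste(sample(c("A", "C", "G", "T"), 2), collapse = "")
    seq <- paste0("TCGAT", strrep(unit, 12), "GATCC")
    ref_ss <- Biostrings::DNAStringSet(c(chr1 = seq))
    # random unnormalized indel inside the repeat
    p <- sample(6:20, 1)
    len <- sample(1:4, 1)
    if (runif(1) < 0.5) {
      ref <- substr(seq, p, p + len); alt <- substr(seq, p, p)
    } else {
      ref <- substr(seq, p, p)
      alt <- paste0(ref, strrep(unit, sample(1:2, 1)))
    }
    s <- variant_sites("chr1", p, ref, alt, 0L, 1L)
    out <- normalize_variants(s, ref_ss)
    o <- normal_form_oracle(seq, p, ref, alt)
    if (o$ref == o$alt) next   # degenerate non-variant; skip draw
    expect_equal(out$pos, o$pos)
    expect_equal(out$ref, o$ref)
    expect_equal(out$alt, o$alt)
  }
})

test_that("multi-allelic sites decompose with genotype bookkeeping", {
  seq <- Biostrings::DNAStringSet(c(chr1 = "AACGTACGTA"))
  s <- variant_sites("chr1", 5, "T", "A,C", 1L, 2L)
  out <- normalize_variants(s, seq)
  expect_equal(nrow(out), 2)
  expect_equal(out$alt, c("A", "C"))
  expect_equal(out$a1 + out$a2, c(1L, 1L))  # one copy of each focal allele
})

cmp_fixture <- function() {
  regions <- region_set("chr1", 0, 10000)
  truth_v <- variant_sites(rep("chr1", 4), c(100, 200, 300, 400),
                           c("A", "C", "G", "T"), c("G", "T", "A", "TC"),
                           c(0L, 0L, 1L, 0L), c(1L, 1L, 1L, 1L))
  list(truth = benchmark_set(truth_v, regions), truth_v = truth_v)
}

test_that("comparison of a benchmark against itself is perfect", {
  f <- cmp_fixture()
  out <- compare_benchmark(f$truth_v, f$truth)
  expect_equal(nrow(out$fp), 0)
  expect_equal(nrow(out$fn), 0)
  expect_equal(out$summary$precision, c(1, 1))
  expect_equal(out$summary$recall, c(1, 1))
})

test_that("comparison assigns FP/FN/filtered classes and ignores outside calls", {
  f <- cmp_fixture()
  query <- variant_sites(rep("chr1", 5), c(100, 200, 500, 600, 20000),
                         c("A", "C", "A", "A", "A"),
                         c("G", "T", "T", "T", "T"),
                         c(0L, 0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L, 1L),
                         filter = c("PASS", "PASS", "PASS", "lowq", "PASS"))
  # truth has 4 sites; query hits 2, adds 1 PASS FP, 1 filtered FP inside,
  # and 1 outside the regions (chr1:20000 is outside [0,10000))
  query$chrom[5] <- "chr2"
  out <- compare_benchmark(query, f$truth)
  expect_equal(nrow(out$tp), 2)
  expect_equal(out$fp$pos, 500)
  expect_equal(out$filtered_fp$pos, 600)
  expect_equal(sort(out$fn$pos), c(300, 400))
  # TP + FN equals the number of truth variants in regions
  expect_equal(nrow(out$tp) + nrow(out$fn), 4)
})

test_that("genotype mismatches are FP+FN pairs, or a separate class on request", {
  f <- cmp_fixture()
  query <- f$truth_v
  query$a1[1] <- 1L  # 0/1 -> 1/1 at pos 100
  strict <- compare_benchmark(query, f$truth)
  expect_equal(strict$fp$pos, 100)
  expect_equal(strict$fn$pos, 100)
  flagged <- compare_benchmark(query, f$truth, genotype_error_class = TRUE)
  expect_equal(nrow(flagged$fp), 0)
  expect_equal(nrow(flagged$fn), 0)
  expect_equal(flagged$genotype_error$pos, 100)
})

test_that("removing truth regions never increases FP or FN", {
  f <- cmp_fixture()
  query <- variant_sites(rep("chr1", 3), c(100, 500, 900), "A", "G", 0L, 1L)
  full <- compare_benchmark(query, f$truth)
  shrunk <- benchmark_set(
    f$truth_v[f$truth_v$pos < 250, ],
    region_set("chr1", 0, 250))
  small <- compare_benchmark(query, shrunk)
  expect_lte(nrow(small$fp), nrow(full$fp))
  expect_lte(nrow(small$fn), nrow(full$fn))
})

test_that("stratified counts conserve totals and honour min_truth", {
  f <- cmp_fixture()
  query <- variant_sites(rep("chr1", 3), c(100, 200, 500), c("A", "C", "A"),
                         c("G", "T", "T"), 0L, 1L)
  out <- compare_benchmark(query, f$truth)
  whole <- stratify_comparison(out, list(genome = region_set("chr1", 0, 10000)),
                               min_truth = 1)
  allrow <- whole[whole$type == "all", ]
  expect_equal(allrow$tp, nrow(out$tp))
  expect_equal(allrow$fp, nrow(out$fp))
  expect_equal(allrow$fn, nrow(out$fn))
  # a partition of the genome sums to the unstratified counts
  parts <- list(left = region_set("chr1", 0, 250),
                right = region_set("chr1", 250, 10000))
  st <- stratify_comparison(out, parts, min_truth = 1)
  sums <- aggregate(cbind(tp, fp, fn) ~ type, data = st, sum)
  expect_equal(sums$tp[sums$type == "all"], nrow(out$tp))
  expect_equal(sums$fn[sums$type == "all"], nrow(out$fn))
  # strata below min_truth are dropped
  st2 <- stratify_comparison(out, parts, min_truth = 1000)
  expect_equal(nrow(st2), 0)
})

test_that("gene inclusion fractions match direct intersection", {
  bench <- region_set("chr1", c(0, 5000), c(1000, 5500))
  genes <- data.frame(chrom = "chr1", start = c(100, 4500, 8000),
                      end = c(200, 5500, 9000),
                      name = c("fully", "half", "absent"))
  out <- gene_inclusion(genes, bench)
  expect_equal(out$fraction, c(1, 0.5, 0))
  expect_equal(attr(out, "n_above"), 1)
  expect_error(gene_inclusion(data.frame(chrom = "chr1", start = 5, end = 5,
                                         name = "z"), bench), "length")
})
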