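test_that("normalize merges overlapping and book-ended intervals", {
  rs <- region_set("chr1", c(10, 15), c(20, 30))
  expect_equal(as.data.frame(normalize_regions(rs))[c("start", "end")],
               data.frame(start = 10, end = 30))
  rs <- region_set("chr1", c(10, 20), c(20, 30))
  expect_equal(as.data.frame(normalize_regions(rs))[c("start", "end")],
               data.frame(start = 10, end = 30))
  expect_error(region_set("chr1", 10, 10), "index 1")
  expect_error(region_set("chr1", 20, 10), "index 1")
})

test_that("set operations agree with per-base boolean oracles", {
  set.seed(101)
  genome <- mask_genome(len = 2000)
  for (rep in 1:50) {
    a <- random_rs(genome)
    b <- random_rs(genome)
    ma <- rs_to_mask(a, genome); mb <- rs_to_mask(b, genome)
    expect_same_bases(normalize_regions(a), ma, genome)
    expect_same_bases(union_regions(list(a, b)),
                      mapply(`|`, ma, mb, SIMPLIFY = FALSE), genome)
    expect_same_bases(subtract_regions(a, b),
                      mapply(function(x, y) x & !y, ma, mb, SIMPLIFY = FALSE),
                      genome)
    expect_same_bases(intersect_regions(a, b),
                      mapply(`&`, ma, mb, SIMPLIFY = FALSE), genome)
    expect_same_bases(complement_regions(a, genome), lapply(ma, `!`), genome)
  }
})

test_that("union of empty list and subtract of empty set are identities", {
  a <- region_set("chr1", c(5, 30), c(10, 40))
  expect_equal(nrow(union_regions(list())), 0)
  expect_equal(as.data.frame(union_regions(list(a, region_set()))),
               as.data.frame(normalize_regions(a)))
  expect_equal(as.data.frame(subtract_regions(a, region_set())),
               as.data.frame(normalize_regions(a)))
})

test_that("subtract splits and swallows as expected", {
  a <- region_set("chr1", 0, 100)
  b <- region_set("chr1", 50, 60)
  expect_equal(as.data.frame(subtract_regions(a, b))[c("start", "end")],
               data.frame(start = c(0, 60), end = c(50, 100)))
  expect_equal(nrow(subtract_regions(b, a)), 0)  # a subset vanishes
})

test_that("subtract(a,b) and intersect(a,b) partition a", {
  set.seed(7)
  genome <- mask_genome()
  for (rep in 1:20) {
    a <- random_rs(genome); b <- random_rs(genome)
    left <- subtract_regions(a, b)
    mid <- intersect_regions(a, b)
    expect_equal(region_bp(left) + region_bp(mid), region_bp(a))
    expect_equal(region_bp(union_regions(list(left, mid))), region_bp(a))
  }
})

test_that("complement is an involution and stays in bounds", {
  genome <- genome_file("chr1", 100)
  expect_equal(as.data.frame(complement_regions(region_set(), genome))[c("start", "end")],
               data.frame(start = 0, end = 100))
  a <- region_set("chr1", c(10, 40), c(20, 60), genome = genome)
  cc <- complement_regions(complement_regions(a, genome), genome)
  expect_equal(as.data.frame(cc)[c("start", "end")],
               as.data.frame(normalize_regions(a))[c("start", "end")])
  expect_error(region_set("chr1", 90, 120, genome = genome), "beyond")
})

test_that("slop pct 0.25 grows intervals to 150% and clips at bounds", {
  genome <- genome_file("chr1", 10000)
  out <- slop_regions(region_set("chr1", 1000, 2000), "pct", 0.25, genome)
  expect_equal(as.data.frame(out)[c("start", "end")],
               data.frame(start = 750, end = 2250))
  out <- slop_regions(region_set("chr1", 10, 20), "fixed_bp", 50,
                      genome_file("chr1", 100))
  expect_equal(as.data.frame(out)[c("start", "end")],
               data.frame(start = 0, end = 70))
  expect_warning(slop_regions(region_set("chr1", 10, 20), "pct", 0.25),
                 "not clipped")
})

test_that("slop outputs contain their sources with bounded growth", {
  set.seed(11)
  genome <- mask_genome(len = 5000)
  a <- random_rs(genome, n = 30)
  out <- slop_regions(a, "pct", 0.25, genome)
  # containment: every input base is still covered
  m_in <- rs_to_mask(a, genome); m_out <- rs_to_mask(out, genome)
  expect_true(all(mapply(function(x, y) all(!x | y), m_in, m_out)))
  # pre-merge growth is at most 1.5x each interval (up to clipping)
  len <- a$end - a$start
  expect_true(region_bp(out) <= sum(ceiling(1.5 * len)))
})

test_that("stack depth filter keeps bases covered strictly more than min_depth", {
  six <- region_set(rep("chr1", 6), rep(0, 6), rep(10, 6))
  expect_equal(as.data.frame(stack_depth_filter(six, 5))[c("start", "end")],
               data.frame(start = 0, end = 10))
  five <- region_set(rep("chr1", 5), rep(0, 5), rep(10, 5))
  expect_equal(nrow(stack_depth_filter(five, 5)), 0)
  set.seed(13)
  genome <- mask_genome()
  for (rep in 1:10) {
    a <- random_rs(genome, n = 30)
    d <- depth_mask(a, genome)
    for (k in c(1, 2, 4))
      expect_same_bases(stack_depth_filter(a, k), lapply(d, function(x) x > k),
                        genome)
  }
})

test_that("length filter bounds are strict", {
  a <- region_set("chr1", c(0, 20000), c(10000, 30001))
  out <- filter_by_length(a, min_bp = 10000)
  expect_equal(nrow(out), 1)
  expect_equal(out$end - out$start, 10001)
  contigs <- region_set("chr1", c(0, 500000), c(400000, 1100000))
  kept <- filter_by_length(contigs, max_bp = 500000)
  expect_equal(kept$end - kept$start, 400000)
  expect_error(filter_by_length(a), "at least one")
})

test_that("partially covered repeats are removed wholesale", {
  bench <- region_set("chr1", 0, 100)
  out <- remove_partial_repeats(bench, region_set("chr1", 90, 120))
  expect_equal(as.data.frame(out)[c("start", "end")],
               data.frame(start = 0, end = 90))
  out <- remove_partial_repeats(bench, region_set("chr1", 10, 20))
  expect_equal(as.data.frame(out)[c("start", "end")],
               data.frame(start = 0, end = 100))
})

test_that("remove_partial_repeats is idempotent and leaves no partial repeat", {
  set.seed(17)
  genome <- mask_genome()
  for (rep in 1:20) {
    bench <- random_rs(genome)
    reps <- normalize_regions(random_rs(genome, n = 8, max_len = 60))
    out <- remove_partial_repeats(bench, reps)
    twice <- remove_partial_repeats(out, reps)
    expect_equal(as.data.frame(out), as.data.frame(twice))
    # predicate scan: no base of any not-fully-contained repeat survives
    bm0 <- rs_to_mask(normalize_regions(bench), genome)
    bm <- rs_to_mask(out, genome)
    for (i in seq_len(nrow(reps))) {
      idx <- (reps$start[i] + 1):reps$end[i]
      contained <- all(bm0[[reps$chrom[i]]][idx])
      if (!contained) expect_false(any(bm[[reps$chrom[i]]][idx]))
    }
  }
})

test_that("region stats report totals, fraction and NG50", {
  genome <- genome_file("chr1", 100)
  st <- region_stats(region_set("chr1", 0, 60), genome)
  expect_equal(st$total_bp, 60)
  expect_equal(st$genome_fraction, 0.6)
  expect_equal(st$ng50, 60)
  st <- region_stats(region_set("chr1", c(0, 40), c(30, 70)), genome)
  expect_equal(st$ng50, 30)
  st <- region_stats(region_set(), genome)
  expect_equal(st$total_bp, 0)
  expect_true(is.na(st$ng50))
  # brute-force cumulative scan on random sets
  set.seed(19)
  genome <- mask_genome(len = 3000)
  for (rep in 1:10) {
    a <- normalize_regions(random_rs(genome, n = 15))
    st <- region_stats(a, genome)
    len <- sort(a$end - a$start, decreasing = TRUE)
    ng <- NA_real_
    acc <- 0
    for (l in len) { acc <- acc + l; if (acc >= sum(genome$length) / 2) { ng <- l; break } }
    expect_equal(st$ng50, ng)
  }
})

test_that("BED round-trips and rejects malformed lines", {
  genome <- genome_file(c("chr1", "chr2"), c(1000, 1000))
  set.seed(23)
  a <- normalize_regions(random_rs(genome, n = 15, max_len = 50))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(a, f)
  back <- read_bed(f, genome = genome)
  expect_equal(as.data.frame(back)[c("chrom", "start", "end")],
               as.data.frame(a)[c("chrom", "start", "end")])
  writeLines(c("chr1\t0\t10", "chr1\tx\t20"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\t30\t10"), f)
  expect_error(read_bed(f), "start >= end")
  writeLines(c("chr1\t0\t10\tname\t7"), f)
  extra <- read_bed(f)
  expect_equal(extra$V4, "name")
})
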