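unit_tracks <- function() {
  # give every repeat class a distinct, disjoint interval so membership in
  # a union is readable off the covered bases
  cls <- c("tr_lt51", "tr_51_200", "tr_200_10k", "homopolymer_gt6",
           "imperfect_homopolymer_gt10", "low_mappability",
           "line_l1hs_gt500", "segdup")
  sets <- lapply(seq_along(cls), function(i)
    region_set("chr1", (i - 1) * 100, i * 100 - 50))
  names(sets) <- cls
  do.call(repeat_class_tracks, sets)
}

test_that("technology exclusion profiles follow the repeat-class matrix", {
  tracks <- unit_tracks()
  covered <- function(tech, cls) {
    i <- match(cls, names(tracks))
    region_bp(intersect_regions(
      tech_exclusion(callset_profile("x", tech), tracks),
      region_set("chr1", (i - 1) * 100, i * 100 - 50))) > 0
  }
  # HiFi DeepVariant retains all tandem repeat classes
  expect_false(covered("hifi_deepvariant", "tr_lt51"))
  expect_false(covered("hifi_deepvariant", "tr_51_200"))
  expect_false(covered("hifi_deepvariant", "tr_200_10k"))
  # mate-pair excludes short tandem repeats but retains LINEs
  expect_true(covered("illumina_matepair", "tr_lt51"))
  expect_false(covered("illumina_matepair", "line_l1hs_gt500"))
  # 10x retains segdups and low-mappability, loses homopolymers > 6
  expect_false(covered("tenx", "segdup"))
  expect_false(covered("tenx", "low_mappability"))
  expect_true(covered("tenx", "homopolymer_gt6"))
  expect_error(callset_profile("x", "nanopore"), "unknown technology")
})

test_that("effective callable subtracts the technology exclusions", {
  tracks <- unit_tracks()
  p <- callset_profile("q", "solid", callable = region_set("chr1", 0, 1000))
  eff <- effective_callable(p, tracks)
  # solid is exempt from nothing: all 8 class intervals removed
  expect_equal(region_bp(eff), 1000 - 8 * 50)
  p2 <- callset_profile("q", "solid", callable = region_set("chr1", 2000, 3000))
  expect_equal(region_bp(effective_callable(p2, tracks)), 1000)
  pa <- callset_profile("ion", "ion_exome", annotation_only = TRUE)
  expect_error(effective_callable(pa, tracks), "annotation-only")
})

arb_setup <- function(gts, callables = NULL, annotation = NULL) {
  # gts: named list label -> data.frame(pos, a1, a2) at chrom chr1, A>G SNVs
  labs <- names(gts)
  sites <- lapply(labs, function(l) {
    g <- gts[[l]]
    variant_sites(rep("chr1", nrow(g)), g$pos, "A", "G", g$a1, g$a2,
                  callset = l)
  })
  names(sites) <- labs
  tracks <- repeat_class_tracks()
  profiles <- lapply(labs, function(l) {
    anno <- !is.null(annotation) && isTRUE(annotation[[l]])
    callset_profile(l, if (anno) "ion_exome" else "illumina_pcrfree_gatk",
                    callable = if (anno) NULL else
                      if (is.null(callables)) region_set("chr1", 0, 10000)
                      else callables[[l]],
                    annotation_only = anno)
  })
  names(profiles) <- labs
  list(sites = sites, profiles = profiles, tracks = tracks)
}

test_that("agreeing covered callsets are accepted at min_support", {
  s <- arb_setup(list(a = data.frame(pos = 100, a1 = 0, a2 = 1),
                      b = data.frame(pos = 100, a1 = 0, a2 = 1)))
  out <- arbitrate(s$sites, s$profiles, s$tracks, min_support = 2)
  expect_equal(nrow(out$accepted), 1)
  expect_equal(out$accepted$n_support, 2)
  expect_equal(out$accepted$platforms, "a,b")
  expect_equal(nrow(out$conflict), 0)
  # with min_support 3 the same site fails
  out3 <- arbitrate(s$sites, s$profiles, s$tracks, min_support = 3)
  expect_equal(nrow(out3$accepted), 0)
})

test_that("genotype disagreement between covering callsets becomes conflict", {
  s <- arb_setup(list(a = data.frame(pos = 1000, a1 = 0, a2 = 1),
                      b = data.frame(pos = 1000, a1 = 1, a2 = 1)))
  out <- arbitrate(s$sites, s$profiles, s$tracks, min_support = 2)
  expect_equal(nrow(out$accepted), 0)
  expect_equal(as.data.frame(out$conflict)[c("start", "end")],
               data.frame(start = 949, end = 1050))
})

test_that("a non-covering callset can neither support nor veto", {
  callables <- list(a = region_set("chr1", 0, 10000),
                    b = region_set("chr1", 0, 10000),
                    c = region_set("chr1", 5000, 10000))
  s <- arb_setup(list(a = data.frame(pos = 100, a1 = 0, a2 = 1),
                      b = data.frame(pos = 100, a1 = 0, a2 = 1),
                      c = data.frame(pos = 100, a1 = 1, a2 = 1)),
                 callables = callables)
  out <- arbitrate(s$sites, s$profiles, s$tracks, min_support = 2)
  expect_equal(nrow(out$accepted), 1)   # c's disagreement is outside its callable
  expect_equal(nrow(out$conflict), 0)
})

test_that("annotation-only callsets never support or veto", {
  s <- arb_setup(list(a = data.frame(pos = 100, a1 = 0, a2 = 1),
                      b = data.frame(pos = 100, a1 = 0, a2 = 1),
                      ion = data.frame(pos = 100, a1 = 1, a2 = 1)),
                 annotation = list(ion = TRUE))
  out <- arbitrate(s$sites, s$profiles, s$tracks, min_support = 2)
  expect_equal(nrow(out$accepted), 1)
  expect_equal(out$accepted$platforms, "a,b")
  only_anno <- arb_setup(list(ion = data.frame(pos = 1, a1 = 0, a2 = 1)),
                         annotation = list(ion = TRUE))
  expect_error(arbitrate(only_anno$sites, only_anno$profiles, only_anno$tracks),
               "non-annotation")
})

test_that("benchmark regions require min_support callable callsets and drop excluded variants", {
  tracks <- repeat_class_tracks(homopolymer_gt6 = region_set("chr1", 480, 520))
  profiles <- list(
    a = callset_profile("a", "illumina_pcrfree_gatk",
                        callable = region_set("chr1", 0, 2000)),
    b = callset_profile("b", "hifi_deepvariant",
                        callable = region_set("chr1", 0, 1000)))
  accepted <- variant_sites(rep("chr1", 2), c(100, 700), c("A", "C"),
                            c("G", "T"), 0L, 1L)
  accepted$n_support <- 2L; accepted$platforms <- "a,b"
  excl <- region_set("chr1", 600, 800)
  bench <- build_benchmark(accepted, profiles, tracks, excl, min_support = 2)
  # only [0,1000) is callable twice; [600,800) excluded; homopolymer at
  # [480,520) straddles nothing (fully inside) so it stays
  expect_equal(nrow(bench$variants), 1)
  expect_equal(bench$variants$pos, 100)
  expect_equal(region_bp(intersect_regions(bench$regions,
                                           region_set("chr1", 1000, 2000))), 0)
  expect_equal(region_bp(intersect_regions(bench$regions,
                                           region_set("chr1", 600, 800))), 0)
  # a partially covered homopolymer is removed wholesale
  tracks2 <- repeat_class_tracks(homopolymer_gt6 = region_set("chr1", 580, 620))
  bench2 <- build_benchmark(accepted, profiles, tracks2, excl, min_support = 2)
  expect_equal(region_bp(intersect_regions(bench2$regions,
                                           region_set("chr1", 580, 620))), 0)
})

test_that("shrinking a callset's callable regions never grows the benchmark", {
  set.seed(61)
  tracks <- repeat_class_tracks()
  for (rep in 1:5) {
    pos <- sort(sample(1:900, 12))
    sites <- lapply(list(a = 1, b = 2), function(i)
      variant_sites(rep("chr1", 12), pos, "A", "G", 0L, 1L))
    profiles_full <- list(
      a = callset_profile("a", "illumina_pcrfree_gatk",
                          callable = region_set("chr1", 0, 1000)),
      b = callset_profile("b", "hifi_deepvariant",
                          callable = region_set("chr1", 0, 1000)))
    shrunk <- normalize_regions(random_rs(genome_file("chr1", 1000), n = 5,
                                          max_len = 300))
    profiles_shr <- profiles_full
    profiles_shr$b <- callset_profile("b", "hifi_deepvariant", callable = shrunk)
    run <- function(pr) {
      arb <- arbitrate(sites, pr, tracks, min_support = 2)
      build_benchmark(arb$accepted, pr, tracks, region_set(),
                      conflict = arb$conflict, min_support = 2)
    }
    full <- run(profiles_full); small <- run(profiles_shr)
    expect_equal(region_bp(subtract_regions(small$regions, full$regions)), 0)
    expect_true(all(gt_sort_key(small$variants) %in% gt_sort_key(full$variants)))
  }
})

test_that("benchmark sets enforce their invariants", {
  v <- variant_sites("chr1", 100, "A", "G", 0L, 1L)
  expect_error(benchmark_set(v, region_set("chr1", 500, 600)), "outside")
  v2 <- variant_sites(rep("chr1", 2), c(100, 100), c("A", "A"), c("G", "G"),
                      0L, 1L)
  expect_error(benchmark_set(v2, region_set("chr1", 0, 200)), "duplicate")
})
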