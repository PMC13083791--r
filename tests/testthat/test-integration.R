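genes3 <- data.frame(
  gene = c("geneA", "geneB", "geneC"),
  chrom = c("chr1", "chr1", "chr2"),
  tss = c(10000, 50000, 20000),
  strand = c("+", "-", "+"),
  stringsAsFactors = FALSE
)

test_that("annotate_feature classifies by midpoint with precedence", {
  # midpoint 1.5 kb upstream of geneA's TSS: inside the +/-3 kb promoter
  p_prom <- make_intervals("chr1", 8300, 8700)  # midpoint 8500
  expect_equal(annotate_feature(p_prom, genes3), "promoter")
  # midpoint 10 kb from every TSS, no gene bodies declared: distal
  p_far <- make_intervals("chr1", 29900, 30100)
  expect_equal(annotate_feature(p_far, genes3), "distal_intergenic")

  exons <- data.frame(gene = c("geneB", "geneB"), chrom = "chr1",
                      start = c(40000, 48000), end = c(40500, 50000))
  # midpoint inside geneB's body, between exons, outside promoters: intron
  p_intron <- make_intervals("chr1", 44000, 45000)
  expect_equal(annotate_feature(p_intron, genes3, exons = exons), "intron")
  # midpoint inside an exon
  p_exon <- make_intervals("chr1", 40100, 40300)
  expect_equal(annotate_feature(p_exon, genes3, exons = exons), "exon")
  # promoter wins over exon at the TSS
  p_both <- make_intervals("chr1", 48000, 50000)  # midpoint 49000, in exon
  expect_equal(annotate_feature(p_both, genes3, exons = exons), "promoter")
  expect_error(annotate_feature(p_prom, genes3[0, ]), "empty gene table")
})

test_that("feature_distribution partitions peaks and sums to one", {
  peaks <- make_intervals(rep("chr1", 3), c(8300, 29900, 44000),
                          c(8700, 30100, 45000))
  exons <- data.frame(gene = "geneB", chrom = "chr1", start = 40000,
                      end = 50000)
  fd <- feature_distribution(peaks, genes3, exons = exons)
  expect_equal(sum(fd$count), 3L)
  expect_equal(sum(fd$proportion), 1)
})

test_that("link_peaks_to_genes supports window and nearest modes", {
  # one peak 1 kb from geneA's TSS
  p <- make_intervals("chr1", 11000, 11200)
  expect_equal(link_peaks_to_genes(p, genes3, "window", window = 3000),
               "geneA")
  # nearest mode, peak equidistant between two TSSs links both
  g2 <- data.frame(gene = c("geneA", "geneB"), chrom = "chr1",
                   tss = c(10000, 20000), strand = c("+", "+"))
  mid <- make_intervals("chr1", 14999, 15002)  # spans the midpoint
  expect_setequal(link_peaks_to_genes(mid, g2, "nearest"),
                  c("geneA", "geneB"))
  empty <- make_intervals(character(), numeric(), numeric())
  expect_equal(link_peaks_to_genes(empty, genes3, "window"), character())
})

test_that("gene_set_overlap computes members and hypergeometric p", {
  u <- LETTERS[1:10]
  ov <- gene_set_overlap(c("A", "B", "C"), c("B", "C", "D"), u)
  expect_equal(ov$overlap_size, 2L)
  expect_equal(ov$members, c("B", "C"))
  # the worked case: N=10, K=5, n=4, k=4 -> 5/210
  ov2 <- gene_set_overlap(LETTERS[1:5], LETTERS[2:5], u)
  expect_equal(ov2$overlap_size, 4L)
  expect_equal(ov2$p_enrich, 5 / 210, tolerance = 1e-12)
  # certain overlap
  ov3 <- gene_set_overlap(u, c("A", "B"), u)
  expect_equal(ov3$p_enrich, 1.0)
  # disjoint sets: overlap 0, p = 1
  ov4 <- gene_set_overlap(c("A", "B"), c("C", "D"), u)
  expect_equal(ov4$overlap_size, 0L)
  expect_equal(ov4$p_enrich, 1.0)
  expect_error(gene_set_overlap(c("A", "Z1"), c("B"), u), "subsets")
})

test_that("hypergeometric p agrees with exhaustive enumeration", {
  set.seed(77)
  for (i in 1:25) {
    N <- sample(4:12, 1L)
    K <- sample(1:N, 1L)
    n <- sample(1:N, 1L)
    u <- sprintf("g%02d", 1:N)
    set_a <- u[1:K]
    set_b <- sample(u, n)
    got <- gene_set_overlap(set_a, set_b, u)
    expect_equal(got$p_enrich,
                 oracle_hyper(N, K, n, got$overlap_size),
                 tolerance = 1e-12)
  }
})

test_that("occupancy_by_class computes counts, fractions and the
           normalized metric", {
  po_starts <- seq(0, 19000, 1000)  # 20 regions
  regions <- list(
    PO = make_intervals("chr1", po_starts, po_starts + 500),
    OC = make_intervals("chr2", c(0, 1000), c(500, 1500)),
    CO = make_intervals("chr3", 0, 500))
  # 5 peaks in PO regions, 1 in OC, 1 outside everything
  peaks <- suppressWarnings(
    c(make_intervals("chr1", c(0, 2000, 5000, 12000, 19000),
                     c(0, 2000, 5000, 12000, 19000) + 400),
      make_intervals("chr2", 100, 300),
      make_intervals("chr4", 0, 100)))
  occ <- occupancy_by_class(peaks, regions)
  expect_equal(occ$n_overlapping_peaks, c(5L, 1L, 0L, 1L))
  expect_equal(sum(occ$raw_fraction), 1)
  expect_equal(occ$normalized[1L], 5 / 20)
  expect_equal(occ$normalized[3L], 0)
  expect_true(is.na(occ$normalized[4L]))

  # a peak overlapping two classes goes to the larger overlap,
  # ties to the earlier class
  regions2 <- list(A = make_intervals("chr1", 0, 100),
                   B = make_intervals("chr1", 100, 300))
  straddle <- make_intervals("chr1", 50, 250)  # 50 bases in A, 150 in B
  expect_equal(occupancy_by_class(straddle, regions2)$n_overlapping_peaks,
               c(0L, 1L, 0L))
  tie <- make_intervals("chr1", 50, 150)  # 50 bases in each
  expect_equal(occupancy_by_class(tie, regions2)$n_overlapping_peaks,
               c(1L, 0L, 0L))

  overlapping <- list(A = make_intervals("chr1", 0, 100),
                      B = make_intervals("chr1", 50, 150))
  expect_error(occupancy_by_class(straddle, overlapping), "partition")
})

test_that("doubling every class's region count halves the normalized
           metric with binding held fixed", {
  regions <- list(PO = make_intervals("chr1", c(0, 1000), c(500, 1500)))
  peaks <- make_intervals("chr1", 100, 300)
  base <- occupancy_by_class(peaks, regions)
  doubled <- list(PO = c(regions$PO,
                         make_intervals("chr1", c(5000, 7000),
                                        c(5500, 7500))))
  twice <- occupancy_by_class(peaks, doubled)
  expect_equal(twice$normalized[1L], base$normalized[1L] / 2)
})

test_that("planted binding rates are recovered within binomial CIs", {
  cfg <- default_sim_config(13)
  cfg$modules <- c(PO = 200, OC1 = 40, OC2 = 40, OC3 = 40, OC4 = 40,
                   OC5 = 40, CO1 = 40, CO2 = 40, CO3 = 40, CO4 = 40,
                   CO5 = 40, NE = 0)
  acc <- simulate_accessibility(cfg)
  bind <- simulate_binding(cfg, acc$truth)
  regions <- lapply(split(acc$truth, acc$truth$base), function(d) {
    make_intervals(d$chrom, d$start, d$end)
  })[c("PO", "OC", "CO")]
  occ <- occupancy_by_class(bind$peaks, regions)
  rates <- cfg$binding$rates
  for (cl in names(rates)) {
    row <- occ[occ$atac_class == cl, ]
    ci <- qbinom(c(0.025, 0.975), row$n_regions, rates[[cl]])
    expect_gte(row$n_overlapping_peaks, ci[1L])
    expect_lte(row$n_overlapping_peaks, ci[2L])
  }
  expect_equal(sum(occ$raw_fraction), 1)
})
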