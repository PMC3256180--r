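test_that("the molecular clock reproduces the calibration point and is linear", {
  cal <- clock_calibration()
  expect_identical(date_event(0.82, cal), 41L)
  expect_identical(date_event(0, cal), 0L)
  expect_equal(cal$mya_per_ks, 50)
  # linearity within integer rounding
  set.seed(401)
  for (ks in runif(20, 0, 2.5))
    expect_lte(abs(date_event(2 * ks, cal) - 2 * date_event(ks, cal)), 1)
  expect_error(date_event(NA_real_, cal), "saturated")
  expect_error(date_event(-0.1, cal), "non-negative")
  expect_error(clock_calibration(0, 41), "positive")
})

test_that("printed transposition and cluster ages follow from their Ks values", {
  cal <- clock_calibration()
  # transposition events (single gene vs its progenitor)
  expect_identical(date_event(1.34, cal), 67L)
  expect_identical(date_event(0.94, cal), 47L)
  expect_identical(date_event(1.89, cal), 95L)
  expect_identical(date_event(0.52, cal), 26L)
  # cluster formation (two most diverged members)
  expect_identical(date_event(0.40, cal), 20L)
  expect_identical(date_event(1.21, cal), 61L)
  expect_identical(date_event(0.085, cal), 4L)
})

test_that("progenitor search takes the lowest usable Ks with deterministic ties", {
  kt <- data.frame(
    gene_a = "s1", gene_b = c("p1", "p2", "p3", "p4"),
    aligned_len = 200, identity = 0.8,
    passes_filter = c(TRUE, TRUE, TRUE, FALSE),
    ks = c(1.9, 1.34, 2.2, 0.1), saturated = FALSE,
    stringsAsFactors = FALSE)
  pr <- find_progenitor("s1", kt, c("p1", "p2", "p3", "p4"))
  expect_identical(pr$progenitor, "p2")  # p4 is filtered out
  expect_equal(pr$ks, 1.34)
  # tie broken lexicographically
  kt$ks <- c(1.0, 1.0, 2, NA)
  expect_identical(find_progenitor("s1", kt, kt$gene_b)$progenitor, "p1")
  kt2 <- kt; kt2$ks <- NA_real_
  expect_warning(pr2 <- find_progenitor("s1", kt2, kt$gene_b), "no usable")
  expect_null(pr2)
  expect_error(find_progenitor("s1", kt, character(0)), "no candidate")
})

test_that("cluster formation dates use the maximal within-cluster Ks", {
  clusters <- data.frame(
    cluster_id = c("CL36", "CL15"), chromosome = c("chr05", "chr08"),
    n = c(5L, 2L), span_bp = 1, mean_gap_bp = 1, non_nbs_orfs = 0L,
    members = c("a,b,c", "d,e"), stringsAsFactors = FALSE)
  ks_w <- data.frame(
    gene_a = c("a", "a", "b", "d"), gene_b = c("b", "c", "c", "e"),
    aligned_len = 200, identity = 0.8, passes_filter = TRUE,
    ks = c(0.1, 0.4, 0.40, 0.085), saturated = FALSE,
    stringsAsFactors = FALSE)
  d <- date_cluster_formation(clusters, ks_w)
  expect_identical(d$mya[d$cluster_id == "CL36"], 20L)
  expect_equal(d$ks_max[d$cluster_id == "CL36"], 0.40)
  expect_identical(d$mya[d$cluster_id == "CL15"], 4L)
  # two-gene cluster uses its only Ks
  expect_identical(d$gene_1[d$cluster_id == "CL15"], "d")
})

test_that("colour combinatorics: 10 multisets, 6 compatible with 2 Va + 1 Vc", {
  combos <- enumerate_color_combos()
  expect_identical(length(combos), 10L)
  expect_identical(length(enumerate_color_combos(c("g", "r"))), 4L)
  expect_true(all(nchar(combos) == 3))
  compat <- combos[vapply(combos, is_compatible, logical(1))]
  incompat <- setdiff(combos, compat)
  expect_identical(length(compat), 6L)
  # the four incompatible combinations: 1g 2r, 1y 2r, 3r, 3g
  expect_setequal(incompat, c("grr", "rry", "rrr", "ggg"))
  expect_true(is_compatible(c("g", "g", "r")))
  expect_true(is_compatible("yyy"))
  expect_false(is_compatible("grr"))
  expect_error(is_compatible(c("g", "r", "z")), "invalid colour")
  expect_error(is_compatible(c("g", "r")), "exactly three")
})

mk_assignment <- function(map)
  structure(list(assignment = data.frame(
    chromosome = names(map), genome = unname(map),
    stringsAsFactors = FALSE)), class = "genome_assignment")

test_that("triplet classification colours chromosomes and counts combos", {
  asn <- mk_assignment(c(c1 = "Va", c2 = "Va", c3 = "Vc", c4 = "unassigned",
                         c5 = "Vc"))
  tri <- data.frame(chrom_a = c("c1", "c3"), chrom_b = c("c2", "c5"),
                    chrom_c = c("c3", "c4"), stringsAsFactors = FALSE)
  rep <- classify_triplets(tri, asn)
  expect_identical(rep$triplets$combo, c("ggr", "rry"))
  expect_identical(rep$triplets$compatible, c(TRUE, FALSE))
  expect_identical(rep$n_compatible, 1L)
  expect_error(classify_triplets(
    data.frame(chrom_a = "cX", chrom_b = "c1", chrom_c = "c2"), asn),
    "unknown chromosome")
})

test_that("cross-genome single candidates need a genome-pure clade elsewhere", {
  asn <- mk_assignment(c(c1 = "Va", c2 = "Va", c3 = "Vc", c4 = "Vc",
                         c5 = "unassigned"))
  genes <- data.frame(
    gene_id = c("k1", "k2", "s1", "s2", "s3", "k3"),
    chromosome = c("c1", "c2", "c3", "c1", "c5", "c4"),
    stringsAsFactors = FALSE)
  clusters <- data.frame(
    cluster_id = c("CL1", "CL2"), chromosome = c("c1", "c4"),
    n = 2L, span_bp = 1, mean_gap_bp = 1, non_nbs_orfs = 0L,
    members = c("k1,k2", "k3,k4"), stringsAsFactors = FALSE)
  clade_map <- data.frame(
    gene_id = c("k1", "k2", "s1", "s2", "s3", "k3", "k4"),
    clade = c("A", "A", "A", "A", "A", "B", "B"),
    stringsAsFactors = FALSE)
  # s1 sits on Vc while clade A clusters all sit on Va: candidate Va->Vc
  # s2 sits on Va (intra-genome): no candidate; s3 unassigned: skipped
  cand <- find_cross_genome_singles(asn, clade_map, c("s1", "s2", "s3"),
                                    clusters, genes)
  expect_identical(cand$gene_id, "s1")
  expect_identical(cand$direction, "Va->Vc")
  # clade with clusters in both genomes yields no candidates
  clade_map$clade[clade_map$gene_id == "k3"] <- "A"
  cand2 <- find_cross_genome_singles(asn, clade_map, "s1", clusters, genes)
  expect_identical(nrow(cand2), 0L)
})

test_that("clade purity cross-tabulates clustered genes by genome", {
  asn <- mk_assignment(c(c1 = "Va", c2 = "Va", c3 = "Vc"))
  genes <- data.frame(
    gene_id = c("a", "b", "c", "d", "e", "f"),
    chromosome = c("c1", "c2", "c1", "c3", "c3", "c2"),
    stringsAsFactors = FALSE)
  clusters <- data.frame(
    cluster_id = c("CL1", "CL2"), chromosome = c("c1", "c3"),
    n = 2L, span_bp = 1, mean_gap_bp = 1, non_nbs_orfs = 0L,
    members = c("a,c", "d,e"), stringsAsFactors = FALSE)
  clade_map <- data.frame(
    gene_id = c("a", "c", "b", "d", "e", "f"),
    clade = c("A", "A", "A", "B", "B", "B"),
    stringsAsFactors = FALSE)
  pur <- clade_genome_purity(clade_map, asn, clusters, genes)
  A <- pur[pur$clade == "A", ]
  expect_identical(A$call, "Va")
  expect_equal(A$purity, 1)
  expect_identical(A$n_clustered, 2L)
  # b and f are singles, tabulated separately
  expect_identical(A$singles_va, 1L)
  B <- pur[pur$clade == "B", ]
  expect_identical(B$call, "Vc")
  expect_identical(B$singles_va, 1L)
})
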