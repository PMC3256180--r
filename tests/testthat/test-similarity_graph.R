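test_that("local alignment scores equal an independent DP reference", {
  set.seed(201)
  for (i in 1:20) {
    a <- random_protein(sample(20:60, 1))
    b <- random_protein(sample(20:60, 1))
    expect_equal(align_local(a, b)$score, oracle_local_score(a, b))
  }
})

test_that("gene-pair scoring reports bits, identity and the quality filter", {
  p <- random_protein(200)
  genes <- data.frame(gene_id = c("a", "b"), chromosome = "chr01",
                      start = c(0, 1e6), end = c(600, 1e6 + 600),
                      strand = "+", cds = "", protein = c(p, p),
                      flank3 = "", domains = "NBARC",
                      stringsAsFactors = FALSE)
  sc <- score_gene_pairs(genes, mode = "bit")
  expect_identical(nrow(sc), 1L)
  expect_equal(sc$identity, 1)
  expect_true(sc$passes_filter)
  # bits of the raw self-score via the Karlin-Altschul transform
  raw <- align_local(p, p)$score
  expect_equal(sc$score, (0.267 * raw - log(0.041)) / log(2))
  # unrelated short proteins score low but never below zero bits
  set.seed(202)
  genes$protein <- c(random_protein(50), random_protein(50))
  sc2 <- score_gene_pairs(genes, mode = "bit", min_aln_len = 150)
  expect_gte(sc2$score, 0)
  expect_false(sc2$passes_filter)
})

test_that("between-cluster score is the mean over n x k member pairs", {
  clusters <- data.frame(
    cluster_id = c("CL1", "CL2"), chromosome = c("chr01", "chr02"),
    n = c(2L, 1L), span_bp = 1, mean_gap_bp = 1, non_nbs_orfs = 0L,
    members = c("a1,a2", "b1"), stringsAsFactors = FALSE)
  ps <- data.frame(gene_a = c("a1", "a2", "a1"),
                   gene_b = c("b1", "b1", "a2"),
                   score = c(100, 300, 999), aligned_len = 200,
                   identity = 0.9, passes_filter = TRUE,
                   stringsAsFactors = FALSE)
  m <- between_cluster_scores(ps, clusters)
  expect_equal(m$scores["CL1", "CL2"], 200)
  expect_equal(m$n_pairs, 1)
  # a filtered-out pair contributes zero, not NA
  ps$passes_filter[1] <- FALSE
  expect_equal(between_cluster_scores(ps, clusters)$scores["CL1", "CL2"],
               150)
  # missing member pair is a named error
  expect_error(between_cluster_scores(ps[-1, ], clusters), "a1 b1")
})

test_that("percentile selection matches the sort-based oracle and nests", {
  set.seed(203)
  make_sim <- function(k) {
    m <- matrix(NA_real_, k, k,
                dimnames = list(paste0("CL", 1:k), paste0("CL", 1:k)))
    v <- runif(k * (k - 1) / 2)
    m[upper.tri(m)] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    structure(list(scores = m, n_pairs = k * (k - 1) / 2),
              class = "cluster_similarity")
  }
  for (rep in 1:5) {
    sim <- make_sim(sample(10:20, 1))
    vals <- sim$scores[upper.tri(sim$scores)]
    for (p in c(90, 93, 96)) {
      sel <- percentile_threshold(sim, p)
      expect_identical(nrow(sel$edges), oracle_percentile_selected(vals, p))
      expect_true(all(sel$edges$score >= sel$threshold))
    }
    e90 <- percentile_threshold(sim, 90)$edges
    e93 <- percentile_threshold(sim, 93)$edges
    e96 <- percentile_threshold(sim, 96)$edges
    key <- function(e) paste(e$cluster_a, e$cluster_b)
    expect_true(all(key(e96) %in% key(e93)))
    expect_true(all(key(e93) %in% key(e90)))
  }
  # 105 distinct scores at p = 93: nearest rank 98, so 8 selected
  sim15 <- make_sim(15)
  sim15$scores[upper.tri(sim15$scores)] <-
    sample(seq_len(105))  # distinct integers
  sim15$scores[lower.tri(sim15$scores)] <-
    t(sim15$scores)[lower.tri(sim15$scores)]
  sel <- percentile_threshold(sim15, 93)
  expect_identical(nrow(sel$edges), 8L)
  # tie degeneracy: all scores equal selects everything
  tie <- make_sim(6)
  tie$scores[upper.tri(tie$scores)] <- 1
  tie$scores[lower.tri(tie$scores)] <- 1
  expect_identical(nrow(percentile_threshold(tie, 93)$edges), 15L)
  expect_error(percentile_threshold(tie, 0), "strictly between")
})

test_that("chromosome grouping recovers two planted groups and flags bridges", {
  clusters <- data.frame(
    cluster_id = paste0("CL", 1:7),
    chromosome = c("c1", "c2", "c3", "c4", "c5", "c6", "c6"),
    n = 2L, span_bp = 1, mean_gap_bp = 1, non_nbs_orfs = 0L,
    members = paste0("m", 1:7), stringsAsFactors = FALSE)
  # two disjoint components: {CL1,CL2,CL3} on c1-c3, {CL4,CL5,CL6} on c4-c6
  edges <- data.frame(cluster_a = c("CL1", "CL2", "CL4", "CL5"),
                      cluster_b = c("CL2", "CL3", "CL5", "CL6"),
                      score = c(9, 8, 7, 6), stringsAsFactors = FALSE)
  asn <- assign_genomes(list(edges = edges, threshold = 6), clusters,
                        all_chromosomes = paste0("c", 1:7))
  a <- setNames(asn$assignment$genome, asn$assignment$chromosome)
  expect_setequal(names(a)[a == "Va"], c("c1", "c2", "c3"))
  expect_setequal(names(a)[a == "Vc"], c("c4", "c5", "c6"))
  expect_identical(unname(a["c7"]), "unassigned")
  # invariance to edge order
  asn2 <- assign_genomes(list(edges = edges[sample(4), ], threshold = 6),
                         clusters, all_chromosomes = paste0("c", 1:7))
  expect_identical(asn$assignment, asn2$assignment)
  # a chromosome carrying clusters of both components becomes a conflict
  clusters2 <- rbind(clusters, data.frame(
    cluster_id = c("CL8", "CL9"), chromosome = "cx", n = 2L, span_bp = 1,
    mean_gap_bp = 1, non_nbs_orfs = 0L, members = c("m8", "m9"),
    stringsAsFactors = FALSE))
  edges2 <- rbind(edges, data.frame(cluster_a = c("CL3", "CL6"),
                                    cluster_b = c("CL8", "CL9"),
                                    score = c(5, 5),
                                    stringsAsFactors = FALSE))
  asn3 <- assign_genomes(list(edges = edges2, threshold = 5), clusters2)
  a3 <- setNames(asn3$assignment$genome, asn3$assignment$chromosome)
  expect_identical(unname(a3["cx"]), "conflict")
  expect_setequal(names(a3)[a3 == "Va"], c("c1", "c2", "c3"))
})

test_that("exact recovery holds when every chromosome draws a selected edge", {
  # constructed similarity structure: within-genome scores strictly above
  # between-genome scores, one cluster per chromosome, enough selected
  # edges to cover every chromosome
  set.seed(204)
  for (rep in 1:5) {
    n_va <- 6; n_vc <- 4
    k <- n_va + n_vc
    ids <- paste0("CL", 1:k)
    genome <- rep(c("Va", "Vc"), c(n_va, n_vc))
    clusters <- data.frame(
      cluster_id = ids, chromosome = paste0("chr", 1:k),
      n = 2L, span_bp = 1, mean_gap_bp = 1, non_nbs_orfs = 0L,
      members = paste0("x", 1:k), stringsAsFactors = FALSE)
    m <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      same <- genome[i] == genome[j]
      m[i, j] <- m[j, i] <- if (same) runif(1, 100, 200) else runif(1, 0, 10)
    }
    sim <- structure(list(scores = m, n_pairs = k * (k - 1) / 2),
                     class = "cluster_similarity")
    # percentile low enough that all within-genome pairs are selected
    sel <- list(threshold = 50,
                edges = percentile_threshold(sim, 50)$edges)
    sel$edges <- sel$edges[sel$edges$score >= 50, ]
    asn <- assign_genomes(sel, clusters)
    a <- setNames(asn$assignment$genome, asn$assignment$chromosome)
    expect_identical(unname(a[paste0("chr", 1:n_va)]), rep("Va", n_va))
    expect_identical(unname(a[paste0("chr", (n_va + 1):k)]),
                     rep("Vc", n_vc))
  }
})

test_that("grouping concordance counts per-chromosome agreement", {
  mk <- function(labels)
    structure(list(assignment = data.frame(
      chromosome = paste0("c", seq_along(labels)), genome = labels,
      stringsAsFactors = FALSE)), class = "genome_assignment")
  a <- mk(c("Va", "Va", "Vc", "Vc", "Va"))
  expect_equal(grouping_concordance(a, a)$concordance, 1)
  b <- mk(c("Va", "Va", "Vc", "Vc", "Vc"))
  expect_equal(grouping_concordance(a, b)$concordance, 0.8)
  # unassigned chromosomes are excluded from the fraction
  d <- mk(c("Va", "Va", "Vc", "Vc", "unassigned"))
  expect_equal(grouping_concordance(a, d)$concordance, 1)
})

test_that("bit-score and identity groupings agree on simulated genomes", {
  # the two scoring pipelines are different summaries of the same protein
  # divergence, so their chromosome groupings should largely coincide
  for (seed in 1:3) {
    bit <- get_grouping(seed, "bit")$assignment
    ident <- get_grouping(seed, "identity")$assignment
    cc <- grouping_concordance(bit, ident)
    expect_gte(cc$concordance, 0.8)
  }
})
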