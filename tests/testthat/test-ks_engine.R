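test_that("global alignment scores equal an independent DP reference", {
  expect_equal(align_global("HEAGAWGHEE", "PAWHEAE")$score,
               oracle_global_score("HEAGAWGHEE", "PAWHEAE"))
  set.seed(101)
  for (i in 1:25) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    expect_equal(align_global(a, b)$score, oracle_global_score(a, b))
  }
})

test_that("alignment of identical sequences is gapless with identity 1", {
  p <- random_protein(200)
  a <- align_global(p, p)
  expect_identical(a$aligned_a, p)
  expect_identical(a$aligned_b, p)
  expect_equal(a$identity_fraction, 1)
  expect_identical(a$ungapped_columns, 200L)
})

test_that("alignment score is symmetric and empty input is rejected", {
  set.seed(102)
  for (i in 1:10) {
    a <- random_protein(30); b <- random_protein(40)
    expect_equal(align_global(a, b)$score, align_global(b, a)$score)
    expect_equal(align_local(a, b)$score, align_local(b, a)$score)
  }
  expect_error(align_global("", "PAW"), "empty")
})

test_that("back-translation maps protein columns to codons and gaps to codon gaps", {
  # ungapped: plain codon split
  cds_a <- "ATGGCTGAA"; cds_b <- "ATGGCAGAA"
  aln <- list(aligned_a = "MAE", aligned_b = "MAE")
  ca <- backtranslate(aln, cds_a, cds_b)
  expect_identical(ca$codons_a, c("ATG", "GCT", "GAA"))
  expect_identical(ca$codons_b, c("ATG", "GCA", "GAA"))
  # single gap becomes a codon gap at the matching column
  aln2 <- list(aligned_a = "MA-E", aligned_b = "MAWE")
  ca2 <- backtranslate(aln2, "ATGGCTGAA", "ATGGCATGGGAA")
  expect_identical(ca2$codons_a[3], "---")
  expect_identical(ca2$codons_b[3], "TGG")
  # length mismatch names the offending gene
  expect_error(backtranslate(aln, "ATGGCT", cds_b, "gX", "gY"), "gX")
  # property: translating back-translated columns reproduces the protein
  # alignment, per column
  set.seed(103)
  for (i in 1:10) {
    cds1 <- random_cds(30); cds2 <- random_cds(30)
    p1 <- as.character(Biostrings::translate(Biostrings::DNAString(cds1),
                                             no.init.codon = TRUE))
    p2 <- as.character(Biostrings::translate(Biostrings::DNAString(cds2),
                                             no.init.codon = TRUE))
    a <- align_global(p1, p2)
    cc <- backtranslate(a, cds1, cds2)
    tr <- function(cod) {
      out <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(ifelse(cod == "---", "AAA", cod)),
        no.init.codon = TRUE))
      out[cod == "---"] <- "-"
      out
    }
    expect_identical(paste(tr(cc$codons_a), collapse = ""), a$aligned_a)
    expect_identical(paste(tr(cc$codons_b), collapse = ""), a$aligned_b)
  }
})

test_that("NG86 equals the exhaustive pathway oracle on every sense-codon pair", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  n_zero <- 0L
  for (c1 in sense) {
    for (c2 in sense) {
      want <- oracle_ng86(c1, c2)
      if (want$syn_sites == 0) {
        # pairs of codons with no synonymous degeneracy (Met/Trp): the
        # estimator has nothing to estimate and must say so
        expect_error(compute_ks(list(codons_a = c1, codons_b = c2)),
                     "zero synonymous sites")
        n_zero <- n_zero + 1L
        next
      }
      got <- compute_ks(list(codons_a = c1, codons_b = c2))
      expect_equal(got$ps, want$ps, tolerance = 1e-12,
                   label = paste(c1, c2))
      expect_equal(got$syn_sites, want$syn_sites, tolerance = 1e-12)
      expect_equal(got$syn_diffs, want$syn_diffs, tolerance = 1e-12)
    }
  }
  expect_identical(n_zero, 4L)  # {ATG, TGG} x {ATG, TGG}
})

test_that("NG86 equals the pathway oracle on random short coding sequences", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  set.seed(104)
  for (i in 1:40) {
    n <- sample(3:5, 1)
    ca <- sample(sense, n, replace = TRUE)
    cb <- sample(sense, n, replace = TRUE)
    got <- compute_ks(list(codons_a = ca, codons_b = cb))
    want <- oracle_ng86(ca, cb)
    expect_equal(got$ps, want$ps, tolerance = 1e-12)
    if (!is.na(want$ks)) expect_equal(got$ks, want$ks, tolerance = 1e-12)
    else expect_true(got$saturated)
  }
})

test_that("Ks is zero for identical CDS, symmetric, and flags saturation", {
  set.seed(105)
  cod <- strsplit(random_cds(50), "(?<=...)", perl = TRUE)[[1]]
  r <- compute_ks(list(codons_a = cod, codons_b = cod))
  expect_identical(r$ks, 0)
  expect_false(r$saturated)
  # symmetry
  cod2 <- strsplit(random_cds(50), "(?<=...)", perl = TRUE)[[1]]
  r12 <- compute_ks(list(codons_a = cod, codons_b = cod2))
  r21 <- compute_ks(list(codons_a = cod2, codons_b = cod))
  expect_equal(r12$ps, r21$ps)
  # the single-codon Phe pair saturates (1 synonymous difference over 1/3
  # synonymous site), matching the oracle
  one <- compute_ks(list(codons_a = "TTT", codons_b = "TTC"))
  expect_true(one$saturated)
  expect_equal(one$ps, oracle_ng86("TTT", "TTC")$ps)
  expect_equal(one$syn_sites, 1 / 3)
})

test_that("the Ks table applies the alignment filter and partitions pairs", {
  set.seed(106)
  base <- random_cds(200)
  mut <- function(cds, k) {
    cod <- strsplit(cds, "(?<=...)", perl = TRUE)[[1]]
    tab <- Biostrings::GENETIC_CODE
    sense <- names(tab)[tab != "*"]
    idx <- sample(length(cod), k)
    cod[idx] <- sample(sense, k, replace = TRUE)
    paste(cod, collapse = "")
  }
  cds <- c(g1 = base, g2 = mut(base, 12), g3 = mut(base, 20),
           g4 = random_cds(200))
  genes <- data.frame(
    gene_id = names(cds), chromosome = "chr01",
    start = seq(0, 3e6, by = 1e6)[1:4],
    end = seq(0, 3e6, by = 1e6)[1:4] + 600,
    strand = "+", cds = unname(cds),
    protein = NA, flank3 = "", domains = "NBARC",
    stringsAsFactors = FALSE)
  genes$protein <- vapply(genes$cds, function(x)
    as.character(Biostrings::translate(Biostrings::DNAString(x))), "",
    USE.NAMES = FALSE)
  kt <- compute_ks_table(genes)
  expect_identical(nrow(kt), 6L)
  # unrelated g4 fails the 30% identity filter against the others
  g4rows <- kt$gene_a == "g4" | kt$gene_b == "g4"
  expect_false(any(kt$passes_filter[g4rows]))
  expect_true(all(kt$passes_filter[!g4rows]))
  expect_true(all(!is.na(kt$ks[!g4rows])))
  # partition: cluster {g1,g2,g3} + single g4
  clusters <- data.frame(cluster_id = "CL1", chromosome = "chr01", n = 3L,
                         span_bp = 1, mean_gap_bp = 1, non_nbs_orfs = 0L,
                         members = "g1,g2,g3", stringsAsFactors = FALSE)
  part <- partition_ks(kt, clusters, singles = "g4")
  expect_identical(nrow(part$ks_w), 3L)
  expect_identical(nrow(part$ks_bg), 3L)
  expect_error(partition_ks(kt, clusters, singles = character(0)),
               "neither clustered nor single")
})
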