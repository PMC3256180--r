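# Small in-code fixtures and a lazy cache for expensive simulation-based
# objects shared across test files.

# A hand-built annotation set: three NBS-R genes and two non-NBS ORFs on
# one chromosome, one unanchored gene.
make_tiny_gene_set <- function() {
  cds <- list(
    g1 = "ATGGCTAAAGGTTTCCTG",
    g2 = "ATGGATCGTACCGAATGG",
    g3 = "ATGTGGCATCCGGTTAAA",
    g4 = "ATGCCTGGATTAGCGAAA")
  prot <- vapply(cds, function(x)
    as.character(Biostrings::translate(Biostrings::DNAString(x))),
    character(1))
  genes <- data.frame(
    gene_id = names(cds),
    chromosome = c("chr01", "chr01", "chr01", "unanchored"),
    start = c(1000, 60000, 400000, 0),
    end = c(1018, 60018, 400018, 18),
    strand = c("+", "-", "+", "+"),
    cds = unlist(cds),
    protein = unname(prot),
    flank3 = c("ACGTACGTAC", "TTTTAAAACC", "GGGGCCCCAA", "ACACACACAC"),
    domains = c("CC;NBARC;LRR", "NBARC", "TIR;NBARC", "NBARC;LRR"),
    stringsAsFactors = FALSE)
  orfs <- data.frame(
    gene_id = c("orf1", "orf2"),
    chromosome = "chr01",
    start = c(20000, 30000),
    end = c(21000, 31000),
    stringsAsFactors = FALSE)
  list(genes = nbs_gene_table(genes), orfs = orfs)
}

# Random coding sequence of n codons with no stop codons.
random_cds <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# Lazy per-seed cache of default-condition simulations and derived stages,
# so the acceptance suite and property tests share one computation.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

get_sim <- function(seed) {
  cached(paste0("sim", seed),
         simulate_nbs_genome(simulation_config(seed = seed)))
}

get_called <- function(seed) {
  cached(paste0("called", seed), call_clusters(get_sim(seed)$annotation))
}

get_grouping <- function(seed, mode = "bit") {
  cached(paste0("grp", seed, mode), {
    sim <- get_sim(seed)
    called <- get_called(seed)
    mem <- cluster_membership(called$clusters)
    cl_genes <- sim$genes[sim$genes$gene_id %in% names(mem), , drop = FALSE]
    scores <- score_gene_pairs(cl_genes, mode = mode)
    simmat <- between_cluster_scores(scores, called$clusters)
    sel <- percentile_threshold(simmat, 93)
    asn <- assign_genomes(sel, called$clusters,
                          all_chromosomes = unique(sim$annotation$chromosome))
    list(scores = scores, simmat = simmat, selection = sel,
         assignment = asn)
  })
}

# Ks table restricted to within-cluster pairs plus transposition-event
# pairs (progenitor candidates of each event's clade).
get_ks <- function(seed) {
  cached(paste0("ks", seed), {
    sim <- get_sim(seed)
    called <- get_called(seed)
    mem <- cluster_membership(called$clusters)
    wp <- do.call(rbind, lapply(
      called$clusters$cluster_id, function(cid) {
        mm <- sort(names(mem)[mem == cid])
        cmb <- combn(mm, 2)
        data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                   stringsAsFactors = FALSE)
      }))
    tg <- sim$truth$genes
    ev <- sim$truth$events
    sp <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
      fam <- tg$family[tg$gene_id == ev$single_gene[i]]
      cand <- tg$gene_id[tg$family == fam & tg$role == "clustered"]
      data.frame(gene_a = ev$single_gene[i], gene_b = cand,
                 stringsAsFactors = FALSE)
    }))
    # sampled between pairs for the Ks-w / Ks-bg comparison
    set.seed(seed + 777L)
    ids <- sim$genes$gene_id
    cmb <- combn(sort(ids), 2)
    allp <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                       stringsAsFactors = FALSE)
    key <- function(p) paste(pmin(p$gene_a, p$gene_b),
                             pmax(p$gene_a, p$gene_b))
    bg <- allp[!(key(allp) %in% c(key(wp), key(sp))), , drop = FALSE]
    bg <- bg[sample.int(nrow(bg), min(1500, nrow(bg))), , drop = FALSE]
    pairs <- rbind(wp, sp, bg)
    pairs <- pairs[!duplicated(key(pairs)), , drop = FALSE]
    compute_ks_table(sim$genes, pairs)
  })
}
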