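#' Configuration for the synthetic-genome generator
#'
#' The generator emulates the statistical structure the deconstruction
#' pipeline assumes: chromosomes partitioned into two hidden component
#' genomes (Va, tetraploid-like and larger; Vc, diploid-like) plus
#' genome-unassignable "grey" chromosomes; NBS-R genes organised in
#' tandem-duplication clusters and singletons; clock-like synonymous
#' divergence at \code{1/mya_per_ks} Ks units per million years of
#' separation; post-fusion cross-genome single-gene transpositions, a
#' fraction of which carry a planted helitron footprint in the 3' flank.
#'
#' Component-genome ancestries are unrelated random coding sequences, so
#' between-genome protein similarity is far below within-genome similarity
#' and the planted grouping is recoverable by construction. Within a
#' genome, gene families (used as phylogenetic clades) radiate at
#' \code{family_split_mya} and the cluster founder lineages of a family
#' separate at \code{cluster_split_mya}; both predate the oldest allowed
#' cluster root so the simulated history is time-consistent.
#'
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @param n_chrom_va,n_chrom_vc,n_chrom_grey Chromosome counts (9/5/5).
#' @param fusion_mya Upper bound on cross-genome transposition ages (65).
#' @param mya_per_ks Clock rate, million years per Ks unit (50).
#' @param clusters_per_chrom Inclusive range of clusters per Va/Vc
#'   chromosome (1-4); grey chromosomes carry no clusters.
#' @param cluster_size Inclusive range of genes per cluster (2-15).
#' @param cluster_root_age_mya Range of cluster founding ages (20-138).
#' @param singles_per_chrom Inclusive range of non-transposed single genes
#'   per chromosome (0-3).
#' @param n_transpositions Number of post-fusion cross-genome single-gene
#'   transposition events (8).
#' @param helitron_fraction Fraction of transposed copies receiving a
#'   planted helitron footprint (0.3).
#' @param omega Nonsynonymous/synonymous rate ratio (0.15).
#' @param cds_len_codons Codons per gene (300).
#' @param flank_len 3' flank length in bp (1000).
#' @param non_nbs_orf_per_100kb Density of non-NBS filler ORFs (5).
#' @param n_families_va,n_families_vc Gene families (clades) per genome.
#' @param family_split_mya,cluster_split_mya Radiation ages (160, 140).
#' @return A \code{simulation_config} object.
#' @export
simulation_config <- function(seed,
                              n_chrom_va = 9, n_chrom_vc = 5,
                              n_chrom_grey = 5,
                              fusion_mya = 65, mya_per_ks = 50,
                              clusters_per_chrom = c(1, 4),
                              cluster_size = c(2, 15),
                              cluster_root_age_mya = c(20, 138),
                              singles_per_chrom = c(0, 3),
                              n_transpositions = 8,
                              helitron_fraction = 0.3,
                              omega = 0.15,
                              cds_len_codons = 300,
                              flank_len = 1000,
                              non_nbs_orf_per_100kb = 5,
                              n_families_va = 3, n_families_vc = 2,
                              family_split_mya = 160,
                              cluster_split_mya = 140) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory for reproducibility")
  if (n_chrom_va < 1 || n_chrom_vc < 1)
    stop("each component genome needs at least one chromosome")
  if (cluster_root_age_mya[2] >= cluster_split_mya)
    stop("cluster roots must be younger than cluster_split_mya")
  structure(list(
    seed = as.integer(seed), n_chrom_va = n_chrom_va,
    n_chrom_vc = n_chrom_vc, n_chrom_grey = n_chrom_grey,
    fusion_mya = fusion_mya, mya_per_ks = mya_per_ks,
    clusters_per_chrom = clusters_per_chrom, cluster_size = cluster_size,
    cluster_root_age_mya = cluster_root_age_mya,
    singles_per_chrom = singles_per_chrom,
    n_transpositions = n_transpositions,
    helitron_fraction = helitron_fraction, omega = omega,
    cds_len_codons = cds_len_codons, flank_len = flank_len,
    non_nbs_orf_per_100kb = non_nbs_orf_per_100kb,
    n_families_va = n_families_va, n_families_vc = n_families_vc,
    family_split_mya = family_split_mya,
    cluster_split_mya = cluster_split_mya),
    class = "simulation_config")
}

#' Expected Ks for a planted divergence age
#'
#' The generator's clock is linear: a pair of lineages separated for
#' \code{age} million years accumulates \code{age / mya_per_ks} synonymous
#' substitutions per synonymous site in expectation (41 mya corresponds to
#' Ks 0.82 at the default rate).
#'
#' @param age_mya Divergence age(s), million years.
#' @param config A \code{\link{simulation_config}} (or any list with
#'   \code{mya_per_ks}).
#' @return Expected Ks value(s).
#' @export
expected_ks <- function(age_mya, config) {
  if (any(age_mya < 0)) stop("age must be non-negative")
  age_mya / config$mya_per_ks
}

# --- codon evolution -------------------------------------------------------

.evo_cache <- new.env(parent = emptyenv())

evolution_tables <- function() {
  if (!is.null(.evo_cache$tab)) return(.evo_cache$tab)
  base <- ng86_tables()
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  syn_nb <- list(); non_nb <- list()
  for (cod in base$sense) {
    sn <- character(0); nn <- character(0)
    for (pos in 1:3) {
      for (n in setdiff(nts, substr(cod, pos, pos))) {
        x <- cod; substr(x, pos, pos) <- n
        if (gc[x] == "*") next
        if (gc[x] == gc[cod]) sn <- c(sn, x) else nn <- c(nn, x)
      }
    }
    syn_nb[[cod]] <- sn
    non_nb[[cod]] <- nn
  }
  .evo_cache$tab <- list(sense = base$sense, syn_sites = base$syn_sites,
                         syn_nb = syn_nb, non_nb = non_nb)
  .evo_cache$tab
}

# Evolve a codon vector along one branch of dt million years. The
# per-lineage synonymous rate is 1/(2 * mya_per_ks) per synonymous site per
# million years, so two lineages separated for T my accumulate T/mya_per_ks
# synonymous substitutions per site between them. Substitutions are applied
# as discrete events on randomly chosen codons (synonymous and
# nonsynonymous events drawn as Poisson counts), which approximates a
# Jukes-Cantor-like per-site process including multiple hits.
evolve_codons <- function(cod, dt, omega, mya_per_ks) {
  if (dt <= 0) return(cod)
  tab <- evolution_tables()
  S <- sum(tab$syn_sites[cod])
  N <- 3 * length(cod) - S
  ds <- dt / (2 * mya_per_ks)
  n_syn <- rpois(1, ds * S)
  n_non <- rpois(1, omega * ds * N)
  ev <- sample(rep(c(TRUE, FALSE), c(n_syn, n_non)))
  for (syn in ev) {
    nb <- if (syn) tab$syn_nb else tab$non_nb
    repeat {
      i <- sample.int(length(cod), 1)
      opts <- nb[[cod[i]]]
      if (length(opts) > 0) {
        cod[i] <- opts[[sample.int(length(opts), 1)]]
        break
      }
    }
  }
  cod
}

random_codons <- function(n) {
  sense <- evolution_tables()$sense
  sense[sample.int(length(sense), n, replace = TRUE)]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Uniform integer in an inclusive range (safe for degenerate ranges).
rint <- function(r) {
  if (r[1] >= r[2]) return(r[1])
  r[1] + sample.int(r[2] - r[1] + 1, 1) - 1
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Simulate a tandem-duplication cluster: k leaves descending from a founder
# sequence whose first duplication happened root_age mya; the remaining
# k - 2 duplications occur at uniform times since then, each copying a
# random extant lineage. Returns leaf sequences, per-leaf birth times and
# the pairwise divergence-age matrix.
sim_cluster <- function(founder, k, root_age, omega, mya_per_ks) {
  seqs <- list(founder)
  t_last <- c(root_age)
  birth <- c(root_age)
  div <- matrix(0, k, k)
  times <- if (k >= 2)
    c(root_age, sort(runif(k - 2, 0, root_age), decreasing = TRUE))
  else numeric(0)
  for (td in times) {
    i <- sample.int(length(seqs), 1)
    seqs[[i]] <- evolve_codons(seqs[[i]], t_last[i] - td, omega, mya_per_ks)
    t_last[i] <- td
    j <- length(seqs) + 1
    seqs[[j]] <- seqs[[i]]
    t_last[j] <- td
    birth[j] <- td
    if (j > 1) {
      for (x in seq_len(j - 1)) div[j, x] <- div[x, j] <-
          if (x == i) td else div[i, x]
    }
  }
  for (i in seq_along(seqs)) {
    seqs[[i]] <- evolve_codons(seqs[[i]], t_last[i], omega, mya_per_ks)
    t_last[i] <- 0
  }
  list(seqs = seqs, birth = birth, div = div)
}

# Domain profiles cycled over families; each family's genes share one
# profile, giving family-specific NBS-R classes.
FAMILY_DOMAIN_PROFILES <- list(
  c("TIR", "NBARC", "LRR"), c("CC", "NBARC", "LRR"), c("NBARC"),
  c("CC", "NBARC"), c("NBARC", "LRR"), c("TIR", "NBARC"))

# Planted footprints are perfect inverted repeats (arm >= 10 bp, so the
# stem scores >= 30 under +3/-1) whose total extent respects the scanner's
# 30-bp maxrepeat bound, followed by a CTAG 4-40 nt downstream.
plant_footprint <- function(flank_len, config_scan = helitron_config()) {
  arm <- sample(10:13, 1)
  loop <- rint(c(3, config_scan$max_repeat_len - 2 * arm))
  spacer <- sample(4:40, 1)
  offset <- sample(50:max(51, flank_len - (2 * arm + loop + spacer + 60)), 1)
  left <- random_dna(arm)
  loop_seq <- random_dna(loop)
  motif <- paste0(left, loop_seq, revcomp(left), random_dna(spacer), "CTAG")
  list(offset = offset, arm = arm, loop = loop, spacer = spacer,
       motif = motif,
       stem_left_start = offset,
       stem_right_end = offset + 2 * arm + loop,
       ctag_pos = offset + 2 * arm + loop + spacer)
}

# Random flank guaranteed footprint-free at the given scanner settings.
clean_flank <- function(flank_len, scan_cfg) {
  repeat {
    fl <- random_dna(flank_len)
    if (is.null(detect_footprint(list(gene_id = "tmp", flank3 = fl),
                                 scan_cfg)))
      return(fl)
  }
}

footprint_flank <- function(flank_len, scan_cfg) {
  repeat {
    fp <- plant_footprint(flank_len, scan_cfg)
    fl <- random_dna(flank_len)
    substr(fl, fp$offset + 1, fp$offset + nchar(fp$motif)) <- fp$motif
    det <- detect_footprint(list(gene_id = "tmp", flank3 = fl), scan_cfg)
    if (!is.null(det) &&
        det$stem_left_start == fp$stem_left_start &&
        det$ctag_pos == fp$ctag_pos)
      return(list(flank = fl, fp = fp))
  }
}

#' Simulate a synthetic NBS-R genome with planted ground truth
#'
#' Runs the generative model described in \code{\link{simulation_config}}
#' and returns the gene table, chromosome annotation (including non-NBS
#' filler ORFs) and complete truth tables. Within a chromosome, clusters and
#' singles are separated by 300-600 kb so the planted cluster partition is
#' exactly recoverable under the default calling rule; within-cluster gene
#' gaps are 2-15 kb. All single-gene 3' flanks are guaranteed footprint-free
#' unless a footprint was planted, so scanner specificity is measurable.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param dir Optional output directory; when given, the annotation set
#'   (GFF3 + FASTA + domain TSV) and truth TSVs are written there.
#' @return A list: \code{genes} (validated NBS-R gene table), \code{orfs},
#'   \code{annotation} (input for \code{\link{call_clusters}}),
#'   \code{truth} (list of data.frames: \code{genes}, \code{events},
#'   \code{pairs}, \code{triplets}, \code{genomes}) and \code{config}.
#' @export
simulate_nbs_genome <- function(config, dir = NULL) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  scan_cfg <- helitron_config()
  n_chr <- config$n_chrom_va + config$n_chrom_vc + config$n_chrom_grey
  chroms <- sprintf("chr%02d", seq_len(n_chr))
  perm <- sample(chroms)
  chr_genome <- setNames(
    rep(c("Va", "Vc", "grey"),
        c(config$n_chrom_va, config$n_chrom_vc, config$n_chrom_grey)),
    perm)
  chr_genome <- chr_genome[chroms]

  # Family (clade) ancestries per genome.
  fam_counts <- c(Va = config$n_families_va, Vc = config$n_families_vc)
  fam_tab <- data.frame(family = character(0), genome = character(0),
                        stringsAsFactors = FALSE)
  fam_seq <- list(); fam_dom <- list()
  lab <- 0
  for (g in c("Va", "Vc")) {
    root <- random_codons(config$cds_len_codons)
    stem <- config$family_split_mya - config$cluster_split_mya
    for (f in seq_len(fam_counts[[g]])) {
      lab <- lab + 1
      fam <- LETTERS[lab]
      fam_seq[[fam]] <- evolve_codons(root, stem, config$omega,
                                      config$mya_per_ks)
      fam_dom[[fam]] <-
        FAMILY_DOMAIN_PROFILES[[(lab - 1) %% 6 + 1]]
      fam_tab <- rbind(fam_tab, data.frame(family = fam, genome = g,
                                           stringsAsFactors = FALSE))
    }
  }
  fams_of <- function(g) fam_tab$family[fam_tab$genome == g]

  gene_rows <- list()   # per-gene metadata + sequence
  pair_rows <- list()   # planted pairwise divergence ages
  next_gene <- 0
  next_cluster <- 0
  new_gene_id <- function() {
    next_gene <<- next_gene + 1
    sprintf("g%03d", next_gene)
  }
  add_gene <- function(id, chrom, family, cluster, birth, cod, role) {
    gene_rows[[length(gene_rows) + 1]] <<- list(
      gene_id = id, chromosome = chrom, family = family,
      cluster = cluster, birth_mya = birth, codons = cod, role = role)
  }

  # Clusters and ordinary singles on Va/Vc chromosomes; grey chromosomes
  # receive only singles (poor clustered-gene content keeps them
  # unassignable, as intended).
  for (ch in chroms) {
    g <- chr_genome[[ch]]
    if (g %in% c("Va", "Vc")) {
      n_cl <- sample(seq(config$clusters_per_chrom[1],
                         config$clusters_per_chrom[2]), 1)
      for (ci in seq_len(n_cl)) {
        next_cluster <- next_cluster + 1
        cid <- sprintf("PC%02d", next_cluster)
        fam <- sample(fams_of(g), 1)
        k <- rint(config$cluster_size)
        root_age <- runif(1, config$cluster_root_age_mya[1],
                          config$cluster_root_age_mya[2])
        founder <- evolve_codons(fam_seq[[fam]],
                                 config$cluster_split_mya - root_age,
                                 config$omega, config$mya_per_ks)
        cl <- sim_cluster(founder, k, root_age, config$omega,
                          config$mya_per_ks)
        ids <- vapply(seq_len(k), function(i) new_gene_id(), character(1))
        for (i in seq_len(k))
          add_gene(ids[i], ch, fam, cid, cl$birth[i], cl$seqs[[i]],
                   "clustered")
        if (k >= 2) {
          cmb <- combn(k, 2)
          for (q in seq_len(ncol(cmb))) {
            i <- cmb[1, q]; j <- cmb[2, q]
            pair_rows[[length(pair_rows) + 1]] <- data.frame(
              gene_a = ids[i], gene_b = ids[j],
              age_mya = cl$div[i, j],
              expected_ks = cl$div[i, j] / config$mya_per_ks,
              kind = "within_cluster", stringsAsFactors = FALSE)
          }
        }
      }
    }
    n_s <- rint(config$singles_per_chrom)
    for (si in seq_len(n_s)) {
      fam <- if (g %in% c("Va", "Vc")) sample(fams_of(g), 1) else
        sample(fam_tab$family, 1)
      cod <- evolve_codons(fam_seq[[fam]], config$cluster_split_mya,
                           config$omega, config$mya_per_ks)
      add_gene(new_gene_id(), ch, fam, NA_character_,
               config$cluster_split_mya, cod, "single")
    }
  }

  # Post-fusion cross-genome transpositions: copy a random clustered gene
  # into the other genome as a single. The copy's branch is evolved for
  # twice the event age so that its pairwise divergence from the progenitor
  # equals the event age on the generator's clock.
  clustered_idx <- which(vapply(gene_rows, function(r)
    r$role == "clustered", logical(1)))
  event_rows <- list()
  for (e in seq_len(config$n_transpositions)) {
    pi <- sample(clustered_idx, 1)
    prog <- gene_rows[[pi]]
    donor <- chr_genome[[prog$chromosome]]
    recip <- if (donor == "Va") "Vc" else "Va"
    dest <- sample(names(chr_genome)[chr_genome == recip], 1)
    t_ev <- runif(1, 1, config$fusion_mya)
    cod <- evolve_codons(prog$codons, 2 * t_ev, config$omega,
                         config$mya_per_ks)
    id <- new_gene_id()
    heli <- runif(1) < config$helitron_fraction
    add_gene(id, dest, prog$family, NA_character_, t_ev, cod, "transposed")
    event_rows[[length(event_rows) + 1]] <- data.frame(
      single_gene = id, progenitor = prog$gene_id,
      progenitor_cluster = prog$cluster, time_mya = t_ev,
      expected_ks = t_ev / config$mya_per_ks,
      helitron = heli, direction = paste0(donor, "->", recip),
      stringsAsFactors = FALSE)
    pair_rows[[length(pair_rows) + 1]] <- data.frame(
      gene_a = prog$gene_id, gene_b = id, age_mya = t_ev,
      expected_ks = t_ev / config$mya_per_ks, kind = "transposition",
      stringsAsFactors = FALSE)
  }
  events <- if (length(event_rows) > 0) do.call(rbind, event_rows) else
    data.frame(single_gene = character(0), progenitor = character(0),
               progenitor_cluster = character(0), time_mya = numeric(0),
               expected_ks = numeric(0), helitron = logical(0),
               direction = character(0), stringsAsFactors = FALSE)

  # Flanks: planted footprints for helitron-flagged transposed copies;
  # rejection-sampled footprint-free flanks for every other single-type
  # gene (the population the scanner inspects); plain random flanks for
  # clustered genes.
  fp_cols <- data.frame(single_gene = character(0),
                        stem_left_start = integer(0), arm_len = integer(0),
                        loop_len = integer(0), ctag_pos = integer(0),
                        stringsAsFactors = FALSE)
  heli_of <- setNames(events$helitron, events$single_gene)
  for (i in seq_along(gene_rows)) {
    r <- gene_rows[[i]]
    if (r$role == "clustered") {
      gene_rows[[i]]$flank3 <- random_dna(config$flank_len)
    } else if (isTRUE(heli_of[r$gene_id])) {
      pf <- footprint_flank(config$flank_len, scan_cfg)
      gene_rows[[i]]$flank3 <- pf$flank
      fp_cols <- rbind(fp_cols, data.frame(
        single_gene = r$gene_id,
        stem_left_start = pf$fp$stem_left_start,
        arm_len = pf$fp$arm, loop_len = pf$fp$loop,
        ctag_pos = pf$fp$ctag_pos, stringsAsFactors = FALSE))
    } else {
      gene_rows[[i]]$flank3 <- clean_flank(config$flank_len, scan_cfg)
    }
  }
  events <- merge(events, fp_cols, by = "single_gene", all.x = TRUE,
                  sort = FALSE)

  # Chromosome layout: clusters and singles in random order, 300-600 kb
  # apart; 2-15 kb between cluster members; filler ORFs at the configured
  # density, avoiding gene intervals.
  gene_len <- 3 * config$cds_len_codons
  meta <- data.frame(
    gene_id = vapply(gene_rows, `[[`, character(1), "gene_id"),
    chromosome = vapply(gene_rows, `[[`, character(1), "chromosome"),
    family = vapply(gene_rows, `[[`, character(1), "family"),
    cluster = vapply(gene_rows, function(r)
      ifelse(is.na(r$cluster), NA_character_, r$cluster), character(1)),
    birth_mya = vapply(gene_rows, `[[`, numeric(1), "birth_mya"),
    role = vapply(gene_rows, `[[`, character(1), "role"),
    stringsAsFactors = FALSE)
  start <- setNames(rep(NA_real_, nrow(meta)), meta$gene_id)
  orf_rows <- list()
  for (ch in chroms) {
    rows <- which(meta$chromosome == ch)
    if (length(rows) == 0) next
    units <- split(rows, ifelse(is.na(meta$cluster[rows]),
                                paste0("s_", meta$gene_id[rows]),
                                meta$cluster[rows]))
    units <- units[sample(length(units))]
    pos <- runif(1, 3e4, 6e4)
    for (u in units) {
      u <- u[order(meta$gene_id[u])]
      for (qi in seq_along(u)) {
        start[meta$gene_id[u[qi]]] <- pos
        pos <- pos + gene_len
        if (qi < length(u)) pos <- pos + runif(1, 2e3, 15e3)
      }
      pos <- pos + runif(1, 3e5, 6e5)
    }
    chrom_len <- pos
    n_orf <- rpois(1, chrom_len / 1e5 * config$non_nbs_orf_per_100kb)
    if (n_orf > 0) {
      g_lo <- start[meta$gene_id[rows]]
      g_hi <- g_lo + gene_len
      placed <- 0; attempts <- 0
      while (placed < n_orf && attempts < n_orf * 50) {
        attempts <- attempts + 1
        s <- runif(1, 0, chrom_len - 1000)
        if (!any(s < g_hi & s + 1000 > g_lo)) {
          placed <- placed + 1
          orf_rows[[length(orf_rows) + 1]] <- data.frame(
            gene_id = sprintf("orf_%s_%03d", ch, placed), chromosome = ch,
            start = round(s), end = round(s) + 1000,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  orfs <- if (length(orf_rows) > 0) do.call(rbind, orf_rows) else
    data.frame(gene_id = character(0), chromosome = character(0),
               start = numeric(0), end = numeric(0),
               stringsAsFactors = FALSE)

  cds <- vapply(gene_rows, function(r) paste(r$codons, collapse = ""),
                character(1))
  genes <- data.frame(
    gene_id = meta$gene_id,
    chromosome = meta$chromosome,
    start = round(unname(start[meta$gene_id])),
    end = round(unname(start[meta$gene_id])) + gene_len,
    strand = sample(c("+", "-"), nrow(meta), replace = TRUE),
    cds = cds,
    protein = NA_character_,
    flank3 = vapply(gene_rows, `[[`, character(1), "flank3"),
    domains = vapply(meta$family, function(f)
      paste(fam_dom[[f]], collapse = ";"), character(1),
      USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  genes$protein <- translate_cds(genes$cds)
  genes <- nbs_gene_table(genes)

  # Truth triplets: two Va chromosomes plus one Vc chromosome each.
  va_ch <- sample(names(chr_genome)[chr_genome == "Va"])
  vc_ch <- sample(names(chr_genome)[chr_genome == "Vc"])
  n_tri <- min(floor(length(va_ch) / 2), length(vc_ch))
  triplets <- data.frame(
    chrom_a = va_ch[seq_len(n_tri) * 2 - 1],
    chrom_b = va_ch[seq_len(n_tri) * 2],
    chrom_c = vc_ch[seq_len(n_tri)],
    stringsAsFactors = FALSE)

  pairs <- if (length(pair_rows) > 0) do.call(rbind, pair_rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               age_mya = numeric(0), expected_ks = numeric(0),
               kind = character(0), stringsAsFactors = FALSE)
  truth <- list(
    genes = meta,
    events = events,
    pairs = pairs,
    triplets = triplets,
    genomes = data.frame(chromosome = chroms,
                         genome = unname(chr_genome[chroms]),
                         stringsAsFactors = FALSE))
  out <- list(genes = genes, orfs = orfs,
              annotation = chromosome_annotation(genes, orfs),
              truth = truth, config = config)
  if (!is.null(dir)) {
    write_annotation_set(genes, dir, orfs)
    for (nm in names(truth))
      write.table(truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
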