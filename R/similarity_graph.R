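# Karlin-Altschul constants for gapped BLOSUM62 (gap open 11, extend 1),
# used to express raw Smith-Waterman scores in bits. Any monotone transform
# of the raw score leaves percentile selection unchanged; the constants only
# set the reported units.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Score all gene pairs by protein similarity
#'
#' Two scoring modes mirror the two lines of evidence used for chromosome
#' grouping. \code{"bit"}: optimal local (Smith-Waterman) alignment under
#' BLOSUM62 with affine gaps, converted to bits via
#' \eqn{(\lambda S - \ln K)/\ln 2}; the alignment-quality filter (at least
#' \code{min_aln_len} aligned residues with identity above
#' \code{min_identity}) is evaluated on the local alignment, as a BLAST-style
#' screen would. \code{"identity"}: global (Needleman-Wunsch) alignment
#' identity over ungapped columns, with the filter evaluated on the global
#' alignment.
#'
#' @param genes NBS-R gene table (needs \code{gene_id}, \code{protein}).
#' @param mode \code{"bit"} or \code{"identity"}.
#' @param min_aln_len,min_identity Filter thresholds (150 aa, 0.30).
#' @param gap_open,gap_extend Affine gap parameters.
#' @param pairs Optional data.frame (\code{gene_a}, \code{gene_b});
#'   defaults to all unordered pairs.
#' @return Data.frame: \code{gene_a}, \code{gene_b}, \code{score} (bits or
#'   identity fraction depending on \code{mode}), \code{aligned_len},
#'   \code{identity}, \code{passes_filter}.
#' @export
score_gene_pairs <- function(genes, mode = c("bit", "identity"),
                             min_aln_len = 150, min_identity = 0.30,
                             gap_open = 11, gap_extend = 1, pairs = NULL) {
  mode <- match.arg(mode)
  prot <- setNames(genes$protein, genes$gene_id)
  if (any(!nzchar(prot)))
    stop("empty protein for gene ", names(prot)[!nzchar(prot)][1])
  if (is.null(pairs)) {
    if (length(prot) < 2) stop("need at least two genes")
    cmb <- combn(genes$gene_id, 2)
    pairs <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                        stringsAsFactors = FALSE)
  }
  mat <- resolve_submat("BLOSUM62")
  ia <- match(pairs$gene_a, genes$gene_id)
  ib <- match(pairs$gene_b, genes$gene_id)
  r <- .align_pairs_cpp(genes$protein, ia, ib, mat, gap_open, gap_extend,
                        mode == "bit", FALSE)
  ung <- r$ungapped
  ident <- ifelse(ung > 0, r$nmatch / ung, 0)
  score <- if (mode == "bit")
    (KA_LAMBDA * r$score - log(KA_K)) / log(2)
  else ident
  out <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b, score = score,
    aligned_len = ung, identity = ident,
    passes_filter = ung >= min_aln_len & ident > min_identity,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Average between-cluster similarity matrix
#'
#' The similarity of two clusters with n and k members is the arithmetic
#' mean of the n x k member-pair scores. Pairs failing the alignment-quality
#' filter contribute a score of zero rather than being dropped, so that
#' clusters sharing no alignable genes correctly average low.
#'
#' @param pair_scores Output of \code{\link{score_gene_pairs}}.
#' @param clusters Cluster table from \code{\link{call_clusters}}.
#' @return A \code{cluster_similarity} object: list with \code{scores}
#'   (symmetric matrix, diagonal NA), \code{clusters}, \code{n_pairs}
#'   (number of distinct cluster pairs).
#' @export
between_cluster_scores <- function(pair_scores, clusters) {
  ids <- clusters$cluster_id
  if (length(ids) < 2) stop("need at least two clusters")
  mem <- lapply(strsplit(clusters$members, ",", fixed = TRUE), identity)
  names(mem) <- ids
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  sc <- setNames(ifelse(pair_scores$passes_filter, pair_scores$score, 0),
                 key(pair_scores$gene_a, pair_scores$gene_b))
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      ga <- mem[[i]]; gb <- mem[[j]]
      kk <- key(rep(ga, each = length(gb)), rep(gb, length(ga)))
      v <- sc[kk]
      if (anyNA(v))
        stop("missing score for member pair ", kk[which(is.na(v))[1]])
      m[i, j] <- m[j, i] <- mean(v)
    }
  }
  structure(list(scores = m, clusters = clusters,
                 n_pairs = length(ids) * (length(ids) - 1) / 2),
            class = "cluster_similarity")
}

#' Percentile threshold over between-cluster scores
#'
#' Nearest-rank percentile: the off-diagonal scores are sorted ascending and
#' the threshold is the value at rank \code{ceiling(p/100 * N)}. Cluster
#' pairs scoring at or above the threshold are selected; ties at the
#' threshold can push the selected count above the nominal
#' \code{N * (100 - p)/100}.
#'
#' @param similarity A \code{cluster_similarity} object.
#' @param p Percentile in (0, 100); the grouping analysis conventionally
#'   uses 90, 93 or 96.
#' @return A list: \code{threshold}, \code{p}, \code{edges} (data.frame
#'   \code{cluster_a}, \code{cluster_b}, \code{score}, sorted by
#'   decreasing score).
#' @export
percentile_threshold <- function(similarity, p = 93) {
  if (!is.numeric(p) || p <= 0 || p >= 100)
    stop("percentile must lie strictly between 0 and 100")
  m <- similarity$scores
  ut <- upper.tri(m)
  vals <- m[ut]
  srt <- sort(vals)
  thr <- srt[ceiling(p / 100 * length(srt))]
  idx <- which(ut & m >= thr, arr.ind = TRUE)
  edges <- data.frame(cluster_a = rownames(m)[idx[, 1]],
                      cluster_b = colnames(m)[idx[, 2]],
                      score = m[idx], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$score, edges$cluster_a, edges$cluster_b), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  list(threshold = thr, p = p, edges = edges)
}

#' Group chromosomes into candidate component genomes
#'
#' Builds a graph with clusters as nodes and the selected high-similarity
#' cluster pairs as edges, takes its connected components and projects each
#' component onto the chromosomes its clusters occupy. Components sharing a
#' chromosome are merged, and the two largest resulting chromosome groups
#' become the candidate component genomes, the larger labelled \code{Va}
#' and the smaller \code{Vc}. When merging collapses everything into a
#' single group even though two substantive (multi-chromosome) components
#' existed before merging, the two largest original components are kept as
#' the candidate genomes instead and the chromosomes bridging them -- the
#' ones carrying clusters of both -- are labelled \code{conflict}.
#' Chromosomes carrying no selected cluster remain \code{unassigned}.
#'
#' @param selection Output of \code{\link{percentile_threshold}} (or any
#'   list with an \code{edges} data.frame).
#' @param clusters Cluster table from \code{\link{call_clusters}}.
#' @param all_chromosomes Optional character vector of the full chromosome
#'   universe; chromosomes absent from any group are reported unassigned.
#' @return A \code{genome_assignment} object: list with \code{assignment}
#'   (data.frame \code{chromosome}, \code{genome}), \code{groups} (list of
#'   chromosome sets), \code{edges}, \code{threshold}.
#' @export
assign_genomes <- function(selection, clusters, all_chromosomes = NULL) {
  edges <- selection$edges
  if (nrow(edges) == 0) stop("no selected cluster pairs")
  chrom_of <- setNames(clusters$chromosome, clusters$cluster_id)
  g <- igraph::graph_from_data_frame(
    edges[order(edges$cluster_a, edges$cluster_b),
          c("cluster_a", "cluster_b")], directed = FALSE)
  comp <- igraph::components(g)
  comp_sets <- lapply(seq_len(comp$no), function(i) {
    cls <- names(comp$membership)[comp$membership == i]
    list(clusters = sort(cls),
         chroms = sort(unique(unname(chrom_of[cls]))))
  })
  rank_sets <- function(sets) {
    sizes <- vapply(sets, function(s) length(s$chroms), integer(1))
    ngenes <- vapply(sets, function(s)
      sum(clusters$n[clusters$cluster_id %in% s$clusters]), numeric(1))
    sets[order(-sizes, -ngenes,
               vapply(sets, function(s) s$chroms[1], character(1)))]
  }
  # Transitive merge of components sharing a chromosome.
  groups <- comp_sets
  repeat {
    merged <- FALSE
    n <- length(groups)
    if (n < 2) break
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (length(intersect(groups[[i]]$chroms,
                             groups[[j]]$chroms)) == 0) next
        groups[[i]] <- list(
          clusters = sort(union(groups[[i]]$clusters,
                                groups[[j]]$clusters)),
          chroms = sort(union(groups[[i]]$chroms, groups[[j]]$chroms)))
        groups[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  groups <- rank_sets(groups)
  gsizes <- vapply(groups, function(s) length(s$chroms), integer(1))
  comp_rk <- rank_sets(comp_sets)
  csizes <- vapply(comp_rk, function(s) length(s$chroms), integer(1))
  conflicts <- character(0)
  if (sum(gsizes >= 2) >= 2) {
    multi <- which(gsizes >= 2)
    va <- groups[[multi[1]]]$chroms
    vc <- groups[[multi[2]]]$chroms
  } else if (sum(csizes >= 2) >= 2) {
    # Everything merged into one group through bridge chromosomes: fall
    # back to the two largest original components and flag the bridges.
    multi <- which(csizes >= 2)
    a <- comp_rk[[multi[1]]]$chroms
    b <- comp_rk[[multi[2]]]$chroms
    conflicts <- intersect(a, b)
    va <- setdiff(a, conflicts)
    vc <- setdiff(b, conflicts)
  } else {
    warning("fewer than two multi-chromosome groups; ",
            "all grouped chromosomes labelled Va")
    va <- unique(unlist(lapply(groups, function(s) s$chroms)))
    vc <- character(0)
  }
  comp_sets <- groups
  universe <- sort(unique(c(all_chromosomes, clusters$chromosome,
                            va, vc, conflicts)))
  genome <- rep("unassigned", length(universe))
  genome[universe %in% va] <- "Va"
  genome[universe %in% vc] <- "Vc"
  genome[universe %in% conflicts] <- "conflict"
  structure(list(
    assignment = data.frame(chromosome = universe, genome = genome,
                            stringsAsFactors = FALSE),
    groups = lapply(comp_sets, function(s) s$chroms),
    edges = edges,
    threshold = selection$threshold),
    class = "genome_assignment")
}

#' Concordance between two genome assignments
#'
#' Per-chromosome agreement between assignments derived from two scoring
#' pipelines (e.g. bit scores versus global-alignment identity).
#' Chromosomes unassigned in either are excluded from the overall fraction.
#'
#' @param assign_a,assign_b \code{genome_assignment} objects over the same
#'   chromosome universe.
#' @return A list: \code{table} (per-chromosome labels and agreement) and
#'   \code{concordance} (fraction agreeing).
#' @export
grouping_concordance <- function(assign_a, assign_b) {
  a <- assign_a$assignment
  b <- assign_b$assignment
  chroms <- sort(union(a$chromosome, b$chromosome))
  la <- setNames(a$genome, a$chromosome)[chroms]
  lb <- setNames(b$genome, b$chromosome)[chroms]
  la[is.na(la)] <- "unassigned"
  lb[is.na(lb)] <- "unassigned"
  tab <- data.frame(chromosome = chroms, genome_a = unname(la),
                    genome_b = unname(lb),
                    agree = unname(la == lb), stringsAsFactors = FALSE)
  use <- la != "unassigned" & lb != "unassigned"
  list(table = tab,
       concordance = if (any(use)) mean(la[use] == lb[use]) else NA_real_)
}
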