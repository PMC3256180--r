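#' Cluster-calling rule configuration
#'
#' Two or more NBS-R genes form a cluster when every consecutive pair is
#' separated by at most \code{max_gap_kb} kilobases and by at most
#' \code{max_intervening_orfs} non-NBS open reading frames. The defaults
#' (244 kb, 21 ORFs) follow the Arabidopsis-style rule used for grapevine;
#' the gap is measured from the end of the upstream gene to the start of the
#' downstream gene.
#'
#' @param max_gap_kb Maximum consecutive-pair gap in kilobases.
#' @param max_intervening_orfs Maximum number of non-NBS ORFs lying strictly
#'   between the spans of two consecutive NBS-R genes.
#' @return A \code{cluster_rule} object.
#' @export
cluster_rule <- function(max_gap_kb = 244, max_intervening_orfs = 21) {
  if (max_gap_kb <= 0 || max_intervening_orfs <= 0)
    stop("cluster rule thresholds must be strictly positive")
  structure(list(max_gap_kb = max_gap_kb,
                 max_intervening_orfs = max_intervening_orfs),
            class = "cluster_rule")
}

#' Call NBS-R gene clusters on annotated chromosomes
#'
#' Partitions the anchored NBS-R genes of each chromosome into maximal
#' chains in which every consecutive pair satisfies the distance and
#' intervening-ORF thresholds of \code{rule}. Chains of length one are
#' returned as single genes. The result is deterministic and depends only on
#' gene positions, not on input row order (which must nevertheless be sorted
#' by position; unsorted input is rejected rather than silently reordered).
#'
#' @param annotation Per-chromosome annotation table from
#'   \code{\link{chromosome_annotation}} (NBS-R genes and non-NBS ORFs).
#' @param rule A \code{\link{cluster_rule}}.
#' @param preserve_ids Optional named vector mapping gene_id to an existing
#'   cluster id; when supplied, called clusters take the id of their members
#'   (which must agree), otherwise ids CL1, CL2, ... are assigned in genome
#'   order.
#' @return A list with \code{clusters} (data.frame: \code{cluster_id},
#'   \code{chromosome}, \code{n}, \code{span_bp}, \code{mean_gap_bp},
#'   \code{non_nbs_orfs}, \code{members} comma-joined in position order) and
#'   \code{singles} (character vector of unclustered gene ids).
#' @export
call_clusters <- function(annotation, rule = cluster_rule(),
                          preserve_ids = NULL) {
  if (nrow(annotation) == 0)
    return(list(clusters = empty_cluster_table(), singles = character(0)))
  chroms <- sort(unique(annotation$chromosome))
  out <- list(); singles <- character(0)
  for (ch in chroms) {
    a <- annotation[annotation$chromosome == ch, , drop = FALSE]
    if (is.unsorted(a$start))
      stop("annotation for chromosome ", ch, " is not sorted by start")
    nbs <- a[a$is_nbs, , drop = FALSE]
    orf <- a[!a$is_nbs, , drop = FALSE]
    m <- nrow(nbs)
    if (m == 0) next
    if (m == 1) {
      singles <- c(singles, nbs$gene_id)
      next
    }
    gap <- nbs$start[-1] - nbs$end[-m]
    n_orf <- vapply(seq_len(m - 1), function(i)
      sum(orf$start >= nbs$end[i] & orf$end <= nbs$start[i + 1]),
      integer(1))
    linked <- gap <= rule$max_gap_kb * 1000 &
      n_orf <= rule$max_intervening_orfs
    chain <- cumsum(c(TRUE, !linked))
    for (k in unique(chain)) {
      idx <- which(chain == k)
      if (length(idx) == 1) {
        singles <- c(singles, nbs$gene_id[idx])
      } else {
        g <- nbs[idx, , drop = FALSE]
        gaps <- g$start[-1] - g$end[-nrow(g)]
        span_lo <- min(g$start); span_hi <- max(g$end)
        out[[length(out) + 1]] <- data.frame(
          cluster_id = NA_character_,
          chromosome = ch,
          n = nrow(g),
          span_bp = span_hi - span_lo,
          mean_gap_bp = mean(gaps),
          non_nbs_orfs = sum(orf$start >= span_lo & orf$end <= span_hi),
          members = paste(g$gene_id, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  clusters <- if (length(out) > 0) do.call(rbind, out) else
    empty_cluster_table()
  if (nrow(clusters) > 0) {
    if (!is.null(preserve_ids)) {
      clusters$cluster_id <- vapply(clusters$members, function(mm) {
        ids <- unique(preserve_ids[strsplit(mm, ",")[[1]]])
        ids <- ids[!is.na(ids)]
        if (length(ids) == 1) ids else NA_character_
      }, character(1), USE.NAMES = FALSE)
    }
    need <- is.na(clusters$cluster_id)
    clusters$cluster_id[need] <- paste0("CL", seq_len(sum(need)))
  }
  rownames(clusters) <- NULL
  list(clusters = clusters, singles = singles)
}

empty_cluster_table <- function() {
  data.frame(cluster_id = character(0), chromosome = character(0),
             n = integer(0), span_bp = numeric(0), mean_gap_bp = numeric(0),
             non_nbs_orfs = integer(0), members = character(0),
             stringsAsFactors = FALSE)
}

#' Map cluster members to cluster ids
#'
#' @param clusters Cluster table from \code{\link{call_clusters}}.
#' @return Named character vector: \code{gene_id -> cluster_id}.
#' @export
cluster_membership <- function(clusters) {
  if (nrow(clusters) == 0) return(setNames(character(0), character(0)))
  mem <- strsplit(clusters$members, ",", fixed = TRUE)
  setNames(rep(clusters$cluster_id, lengths(mem)), unlist(mem))
}

#' Summary statistics over a set of called clusters
#'
#' @param clusters Cluster table from \code{\link{call_clusters}}.
#' @return A list with \code{n_clusters}, \code{size_range},
#'   \code{span_range_kb}, \code{mean_gap_kb} (mean over consecutive member
#'   pairs of all clusters, weighted by pair count), and
#'   \code{mean_non_nbs_orfs}.
#' @export
cluster_stats <- function(clusters) {
  if (nrow(clusters) == 0) stop("no clusters to summarise")
  npairs <- clusters$n - 1
  list(n_clusters = nrow(clusters),
       size_range = range(clusters$n),
       span_range_kb = range(clusters$span_bp) / 1000,
       mean_gap_kb = sum(clusters$mean_gap_bp * npairs) / sum(npairs) / 1000,
       mean_non_nbs_orfs = mean(clusters$non_nbs_orfs))
}
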