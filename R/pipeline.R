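#' Run the full genome-deconstruction analysis
#'
#' Orchestrates the stages in dependency order: obtain an annotated gene
#' set (from a simulation or from files), call clusters, score gene pairs,
#' average between-cluster similarities, select high-similarity cluster
#' pairs at a percentile threshold, group chromosomes into candidate
#' component genomes, estimate Ks and partition it into within-cluster and
#' between components, identify and date cross-genome transpositions
#' (including a helitron footprint scan of single genes), date cluster
#' formation, and classify chromosome triplets.
#'
#' Ks for between-cluster pairs is estimated on at most
#' \code{ks_bg_max_pairs} randomly sampled pairs (the between mean is a
#' mean over a large homogeneous set; sampling changes its precision, not
#' its definition). All within-cluster pairs are always used.
#'
#' @param sim_config A \code{\link{simulation_config}}; mutually exclusive
#'   with \code{input}.
#' @param input A list of paths as accepted by
#'   \code{\link{load_annotation_set}}, plus optionally \code{clade_map}
#'   (data.frame or TSV path) and \code{triplets}.
#' @param rule A \code{\link{cluster_rule}}.
#' @param percentile Percentile for cluster-pair selection (93).
#' @param score_mode \code{"bit"} or \code{"identity"} for the primary
#'   grouping.
#' @param compare_modes When TRUE also run the alternative scoring mode and
#'   report grouping concordance.
#' @param scan Helitron scan configuration.
#' @param cal Clock calibration.
#' @param min_aln_len,min_identity Alignment-quality filter thresholds
#'   passed to the scoring and Ks stages (150 aa, 0.30).
#' @param ks_bg_max_pairs Cap on sampled between-pair Ks estimates (2000).
#' @param out_dir Optional directory for stage TSV outputs.
#' @return A report list with elements \code{genes}, \code{clusters},
#'   \code{singles}, \code{cluster_stats}, \code{similarity},
#'   \code{selection}, \code{assignment}, \code{concordance} (or NULL),
#'   \code{ks} (partition), \code{events}, \code{cluster_dates},
#'   \code{triplets} (or NULL), \code{footprints}, \code{summary}.
#' @export
run_full_analysis <- function(sim_config = NULL, input = NULL,
                              rule = cluster_rule(), percentile = 93,
                              score_mode = c("bit", "identity"),
                              compare_modes = FALSE,
                              scan = helitron_config(),
                              cal = clock_calibration(),
                              min_aln_len = 150, min_identity = 0.30,
                              ks_bg_max_pairs = 2000,
                              out_dir = NULL) {
  score_mode <- match.arg(score_mode)
  if (is.null(sim_config) == is.null(input))
    stop("provide exactly one of sim_config or input")
  if (!is.null(sim_config)) {
    sim <- simulate_nbs_genome(sim_config)
    genes <- sim$genes
    annotation <- sim$annotation
    clade_map <- data.frame(gene_id = sim$truth$genes$gene_id,
                            clade = sim$truth$genes$family,
                            stringsAsFactors = FALSE)
    triplets <- sim$truth$triplets
    seed <- sim_config$seed
  } else {
    loaded <- load_annotation_set(input$gff3, input$cds, input$protein,
                                  input$domains, input$flank3)
    genes <- loaded$genes
    annotation <- loaded$annotation
    clade_map <- if (is.character(input$clade_map))
      read.delim(input$clade_map, stringsAsFactors = FALSE) else
        input$clade_map
    triplets <- if (is.character(input$triplets))
      read.delim(input$triplets, stringsAsFactors = FALSE) else
        input$triplets
    seed <- if (is.null(input$seed)) 1L else input$seed
  }
  anchored <- genes[genes$chromosome != "unanchored", , drop = FALSE]

  called <- call_clusters(annotation, rule)
  clusters <- called$clusters
  singles <- called$singles
  stats <- cluster_stats(clusters)

  clustered_ids <- names(cluster_membership(clusters))
  cl_genes <- anchored[anchored$gene_id %in% clustered_ids, , drop = FALSE]
  scores <- score_gene_pairs(cl_genes, mode = score_mode,
                             min_aln_len = min_aln_len,
                             min_identity = min_identity)
  simmat <- between_cluster_scores(scores, clusters)
  selection <- percentile_threshold(simmat, p = percentile)
  assignment <- assign_genomes(selection, clusters,
                               all_chromosomes =
                                 unique(annotation$chromosome))
  concordance <- NULL
  if (compare_modes) {
    alt_mode <- if (score_mode == "bit") "identity" else "bit"
    alt_scores <- score_gene_pairs(cl_genes, mode = alt_mode,
                               min_aln_len = min_aln_len,
                               min_identity = min_identity)
    alt_sel <- percentile_threshold(
      between_cluster_scores(alt_scores, clusters), p = percentile)
    alt_assign <- assign_genomes(alt_sel, clusters,
                                 all_chromosomes =
                                   unique(annotation$chromosome))
    concordance <- grouping_concordance(assignment, alt_assign)
  }

  # Ks: all within-cluster pairs, a sample of between pairs, and all
  # single-vs-clustered pairs needed for progenitor search.
  mem <- cluster_membership(clusters)
  wpairs <- do.call(rbind, lapply(
    clusters$cluster_id[clusters$n >= 2], function(cid) {
      mm <- sort(names(mem)[mem == cid])
      cmb <- combn(mm, 2)
      data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                 stringsAsFactors = FALSE)
    }))
  all_ids <- anchored$gene_id
  cmb <- combn(sort(all_ids), 2)
  allp <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                     stringsAsFactors = FALSE)
  pkey <- function(p) paste(pmin(p$gene_a, p$gene_b),
                            pmax(p$gene_a, p$gene_b))
  is_within <- pkey(allp) %in% pkey(wpairs)
  bgp <- allp[!is_within, , drop = FALSE]
  set.seed(seed + 10007L)
  if (nrow(bgp) > ks_bg_max_pairs)
    bgp <- bgp[sample.int(nrow(bgp), ks_bg_max_pairs), , drop = FALSE]
  spairs <- do.call(rbind, lapply(singles, function(s) {
    cand <- if (!is.null(clade_map)) {
      cl <- clade_map$clade[clade_map$gene_id == s]
      if (length(cl) == 1)
        intersect(clade_map$gene_id[clade_map$clade == cl], clustered_ids)
      else clustered_ids
    } else clustered_ids
    if (length(cand) == 0) return(NULL)
    data.frame(gene_a = s, gene_b = cand, stringsAsFactors = FALSE)
  }))
  kpairs <- rbind(wpairs, bgp, spairs)
  kpairs <- kpairs[!duplicated(pkey(kpairs)), , drop = FALSE]
  ks_table <- compute_ks_table(anchored, kpairs,
                               min_aln_len = min_aln_len,
                               min_identity = min_identity)
  ks_part <- partition_ks(ks_table, clusters, singles)

  # Transposition candidates, helitron scan, progenitors, dating.
  footprints <- scan_flanks(
    anchored[anchored$gene_id %in% singles, , drop = FALSE], scan)
  events <- NULL
  if (!is.null(clade_map)) {
    cand <- find_cross_genome_singles(assignment, clade_map, singles,
                                      clusters, anchored)
    if (nrow(cand) > 0) {
      rows <- lapply(seq_len(nrow(cand)), function(i) {
        s <- cand$gene_id[i]
        cl_cand <- intersect(
          clade_map$gene_id[clade_map$clade == cand$clade[i]],
          clustered_ids)
        pr <- find_progenitor(s, ks_table, cl_cand)
        if (is.null(pr)) return(NULL)
        data.frame(single_gene = s,
                   progenitor = pr$progenitor,
                   progenitor_cluster = unname(mem[pr$progenitor]),
                   direction = cand$direction[i],
                   helitron =
                     footprints$has_footprint[footprints$gene_id == s],
                   ks = pr$ks, mya = date_event(pr$ks, cal),
                   stringsAsFactors = FALSE)
      })
      events <- do.call(rbind, rows)
    }
  }
  cluster_dates <- date_cluster_formation(clusters, ks_part$ks_w, cal)
  triplet_report <- if (!is.null(triplets))
    classify_triplets(triplets, assignment) else NULL

  summary <- list(
    n_genes = nrow(anchored),
    class_counts = table(anchored$nbs_class),
    n_clusters = nrow(clusters),
    n_clustered_genes = length(clustered_ids),
    n_singles = length(singles),
    cluster_stats = stats,
    ks_mean_w = ks_part$mean_w,
    ks_mean_bg = ks_part$mean_bg,
    threshold = selection$threshold,
    n_selected_edges = nrow(selection$edges),
    assignment = assignment$assignment,
    n_footprints = sum(footprints$has_footprint),
    n_events = if (is.null(events)) 0L else nrow(events),
    n_compatible_triplets = if (is.null(triplet_report)) NA_integer_ else
      triplet_report$n_compatible)

  report <- list(genes = anchored, clusters = clusters, singles = singles,
                 cluster_stats = stats, similarity = simmat,
                 selection = selection, assignment = assignment,
                 concordance = concordance, ks = ks_part,
                 ks_table = ks_table, events = events,
                 cluster_dates = cluster_dates,
                 triplets = triplet_report, footprints = footprints,
                 summary = summary)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write the stage outputs of a report bundle as TSV files
#'
#' @param report Output of \code{\link{run_full_analysis}}.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) if (!is.null(x) && nrow(x) > 0)
    write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  w(report$clusters, "clusters.tsv")
  w(data.frame(gene_id = report$singles), "singles.tsv")
  w(report$ks_table, "ks.tsv")
  w(report$selection$edges, "selected_edges.tsv")
  w(report$assignment$assignment, "assignment.tsv")
  w(report$events, "events.tsv")
  w(report$cluster_dates, "cluster_dates.tsv")
  if (!is.null(report$triplets)) w(report$triplets$triplets, "triplets.tsv")
  w(report$footprints, "footprints.tsv")
  invisible(dir)
}
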