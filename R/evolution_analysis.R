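#' Molecular-clock calibration
#'
#' Linear Ks-to-time calibration anchored on the Cleomaceae-Brassicaceae
#' divergence: a Ks of 0.82 corresponds to 41 million years, i.e. 50 mya
#' per Ks unit at the defaults.
#'
#' @param ks_ref Reference Ks (default 0.82).
#' @param mya_ref Reference age in million years (default 41).
#' @return A \code{clock_calibration} object with the implied
#'   \code{mya_per_ks} rate.
#' @export
clock_calibration <- function(ks_ref = 0.82, mya_ref = 41) {
  if (ks_ref <= 0 || mya_ref <= 0)
    stop("calibration constants must be positive")
  structure(list(ks_ref = ks_ref, mya_ref = mya_ref,
                 mya_per_ks = mya_ref / ks_ref),
            class = "clock_calibration")
}

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a Ks value to an integer age in million years
#'
#' \code{mya = round(ks * mya_ref / ks_ref)} with half-away-from-zero
#' rounding, so the calibration point itself converts exactly
#' (0.82 -> 41 mya).
#'
#' @param ks Non-negative Ks value(s); saturated (NA) values are rejected.
#' @param cal A \code{\link{clock_calibration}}.
#' @return Integer million years (vectorised).
#' @export
date_event <- function(ks, cal = clock_calibration()) {
  if (any(is.na(ks)))
    stop("saturated or missing Ks cannot be dated; exclude such pairs")
  if (any(ks < 0)) stop("Ks must be non-negative")
  as.integer(round_half_up(ks * cal$mya_per_ks))
}

#' Identify the most likely progenitor of a single gene
#'
#' Among clustered candidate genes, the progenitor of a putatively
#' transposed single gene is the one with the lowest (non-saturated,
#' filter-passing) Ks to it; ties are broken lexicographically by gene id.
#'
#' @param single_id Gene id of the single gene.
#' @param ks_table Ks table containing pairs between \code{single_id} and
#'   candidates (see \code{\link{compute_ks_table}}).
#' @param candidates Character vector of clustered candidate gene ids.
#' @return A list \code{(progenitor, ks)}, or \code{NULL} (with a warning)
#'   when every candidate pair is saturated or filtered out.
#' @export
find_progenitor <- function(single_id, ks_table, candidates) {
  if (length(candidates) == 0) stop("no candidate progenitors")
  sel <- (ks_table$gene_a == single_id & ks_table$gene_b %in% candidates) |
    (ks_table$gene_b == single_id & ks_table$gene_a %in% candidates)
  t <- ks_table[sel & ks_table$passes_filter & !is.na(ks_table$ks), ,
                drop = FALSE]
  if (nrow(t) == 0) {
    warning("no usable Ks value between ", single_id,
            " and any candidate progenitor")
    return(NULL)
  }
  other <- ifelse(t$gene_a == single_id, t$gene_b, t$gene_a)
  ord <- order(t$ks, other)
  list(progenitor = other[ord[1]], ks = t$ks[ord[1]])
}

#' Candidate cross-genome transposed singles
#'
#' A single gene is a candidate transposition when it lies on a chromosome
#' assigned to one component genome while every clustered gene of its clade
#' lies in the other: the gene's clade anchors it ancestrally to the donor
#' genome, and its position reveals the recipient.
#'
#' @param assignment A \code{genome_assignment}.
#' @param clade_map Data.frame with columns \code{gene_id}, \code{clade}.
#' @param singles Character vector of single gene ids.
#' @param clusters Cluster table.
#' @param genes NBS-R gene table (for chromosome lookup).
#' @return Data.frame of candidates: \code{gene_id}, \code{chromosome},
#'   \code{gene_genome}, \code{clade}, \code{clade_genome},
#'   \code{direction} (e.g. \code{"Va->Vc"}). Singles without a clade are
#'   skipped with a message.
#' @export
find_cross_genome_singles <- function(assignment, clade_map, singles,
                                      clusters, genes) {
  gmap <- setNames(assignment$assignment$genome,
                   assignment$assignment$chromosome)
  chrom_of <- setNames(genes$chromosome, genes$gene_id)
  clade_of <- setNames(clade_map$clade, clade_map$gene_id)
  mem <- cluster_membership(clusters)
  out <- list()
  for (s in singles) {
    cl <- clade_of[s]
    if (is.na(cl)) {
      message("single gene ", s, " has no clade; skipped")
      next
    }
    g_s <- gmap[chrom_of[s]]
    if (is.na(g_s) || !g_s %in% c("Va", "Vc")) next
    clade_clustered <- names(clade_of)[clade_of == cl]
    clade_clustered <- clade_clustered[clade_clustered %in% names(mem)]
    if (length(clade_clustered) == 0) next
    g_c <- unique(unname(gmap[chrom_of[clade_clustered]]))
    g_c <- g_c[!is.na(g_c)]
    if (length(g_c) != 1 || !g_c %in% c("Va", "Vc")) next
    if (g_c == g_s) next
    out[[length(out) + 1]] <- data.frame(
      gene_id = s, chromosome = unname(chrom_of[s]),
      gene_genome = unname(g_s), clade = unname(cl),
      clade_genome = g_c,
      direction = paste0(g_c, "->", g_s),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(0), chromosome = character(0),
                      gene_genome = character(0), clade = character(0),
                      clade_genome = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Date the formation of each cluster
#'
#' A cluster's formation age is taken from its two most diverged members:
#' the maximal within-cluster Ks, converted to million years with the
#' molecular clock.
#'
#' @param clusters Cluster table.
#' @param ks_w Within-cluster Ks table (e.g. \code{partition_ks()$ks_w}).
#' @param cal A \code{\link{clock_calibration}}.
#' @return Data.frame: \code{cluster_id}, \code{n}, \code{gene_1},
#'   \code{gene_2}, \code{ks_max}, \code{mya}. Clusters with no usable Ks
#'   are omitted with a warning.
#' @export
date_cluster_formation <- function(clusters, ks_w,
                                   cal = clock_calibration()) {
  mem <- cluster_membership(clusters)
  usable <- ks_w[ks_w$passes_filter & !is.na(ks_w$ks), , drop = FALSE]
  rows <- list()
  for (cid in clusters$cluster_id) {
    t <- usable[!is.na(mem[usable$gene_a]) & mem[usable$gene_a] == cid, ,
                drop = FALSE]
    if (nrow(t) == 0) {
      warning("cluster ", cid, " has no usable within-cluster Ks; skipped")
      next
    }
    i <- order(-t$ks, t$gene_a, t$gene_b)[1]
    rows[[length(rows) + 1]] <- data.frame(
      cluster_id = cid, n = clusters$n[clusters$cluster_id == cid],
      gene_1 = t$gene_a[i], gene_2 = t$gene_b[i], ks_max = t$ks[i],
      mya = date_event(t$ks[i], cal), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(cluster_id = character(0), n = integer(0),
                      gene_1 = character(0), gene_2 = character(0),
                      ks_max = numeric(0), mya = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Genome colours: g = Va (green), r = Vc (red), y = unassigned (grey).
GENOME_COLORS <- c(Va = "g", Vc = "r", unassigned = "y", conflict = "y")

#' Enumerate the colour combinations of a chromosome triplet
#'
#' All multisets of size three over the colours \code{g} (Va), \code{r}
#' (Vc) and \code{y} (genome-unassigned); there are exactly
#' \code{choose(3 + 3 - 1, 3) = 10}.
#'
#' @param colors Colour alphabet (default \code{c("g", "r", "y")}).
#' @return Character vector of sorted colour triples (e.g. \code{"ggr"}).
#' @export
enumerate_color_combos <- function(colors = c("g", "r", "y")) {
  grid <- expand.grid(rep(list(colors), 3), stringsAsFactors = FALSE)
  combos <- unique(apply(grid, 1, function(r)
    paste(sort(r), collapse = "")))
  sort(combos)
}

#' Is a triplet colour combination compatible with 2 Va + 1 Vc?
#'
#' Under the hypothesis that every chromosome triplet consists of two Va
#' (tetraploid component) and one Vc (diploid component) chromosome, a
#' combination is compatible when its grey (unassigned) slots can be filled
#' to reach exactly two \code{g} and one \code{r}: at most two \code{g} and
#' at most one \code{r} observed.
#'
#' @param combo Three colours, as a character vector of length 3 or a
#'   3-character string over \code{g}, \code{r}, \code{y}.
#' @return Logical.
#' @export
is_compatible <- function(combo) {
  if (length(combo) == 1) combo <- strsplit(combo, "", fixed = TRUE)[[1]]
  if (length(combo) != 3) stop("a triplet has exactly three colours")
  if (!all(combo %in% c("g", "r", "y")))
    stop("invalid colour: ", setdiff(combo, c("g", "r", "y"))[1])
  sum(combo == "g") <= 2 && sum(combo == "r") <= 1
}

#' Classify chromosome triplets against a genome assignment
#'
#' Looks up the colour of each triplet chromosome (Va -> g, Vc -> r,
#' unassigned -> y; conflict chromosomes are treated as y with a warning)
#' and evaluates compatibility with the 2 Va + 1 Vc hypothesis.
#'
#' @param triplets Data.frame with columns \code{chrom_a}, \code{chrom_b},
#'   \code{chrom_c}.
#' @param assignment A \code{genome_assignment}.
#' @return A list: \code{triplets} (input plus \code{combo} and
#'   \code{compatible}), \code{combo_counts} (named table) and
#'   \code{n_compatible}.
#' @export
classify_triplets <- function(triplets, assignment) {
  gmap <- setNames(assignment$assignment$genome,
                   assignment$assignment$chromosome)
  lookup <- function(ch) {
    g <- gmap[ch]
    if (any(is.na(g))) stop("unknown chromosome: ", ch[is.na(g)][1])
    if (any(g == "conflict"))
      warning("conflict chromosome treated as unassigned (y)")
    unname(GENOME_COLORS[g])
  }
  combo <- character(nrow(triplets))
  for (i in seq_len(nrow(triplets))) {
    cols <- lookup(unlist(triplets[i, c("chrom_a", "chrom_b", "chrom_c")]))
    combo[i] <- paste(sort(cols), collapse = "")
  }
  triplets$combo <- combo
  triplets$compatible <- vapply(combo, is_compatible, logical(1),
                                USE.NAMES = FALSE)
  list(triplets = triplets,
       combo_counts = table(combo),
       n_compatible = sum(triplets$compatible))
}

#' Clade-by-genome cross-tabulation and purity
#'
#' For every clade, counts its clustered genes per component genome; the
#' clade's genome call is the majority genome among clustered members and
#' its purity the majority fraction. Single genes are tabulated separately
#' (they are the transposition candidates, not evidence for the clade's
#' ancestral genome).
#'
#' @param clade_map Data.frame with columns \code{gene_id}, \code{clade}.
#' @param assignment A \code{genome_assignment}.
#' @param clusters Cluster table.
#' @param genes NBS-R gene table.
#' @return Data.frame: \code{clade}, \code{n_clustered}, \code{n_va},
#'   \code{n_vc}, \code{n_other}, \code{call}, \code{purity},
#'   \code{singles_va}, \code{singles_vc}.
#' @export
clade_genome_purity <- function(clade_map, assignment, clusters, genes) {
  gmap <- setNames(assignment$assignment$genome,
                   assignment$assignment$chromosome)
  chrom_of <- setNames(genes$chromosome, genes$gene_id)
  mem <- cluster_membership(clusters)
  rows <- lapply(sort(unique(clade_map$clade)), function(cl) {
    ids <- clade_map$gene_id[clade_map$clade == cl]
    ids <- ids[ids %in% names(chrom_of)]
    gen <- unname(gmap[chrom_of[ids]])
    gen[is.na(gen)] <- "unassigned"
    clustered <- ids %in% names(mem)
    gc <- gen[clustered]
    n_va <- sum(gc == "Va"); n_vc <- sum(gc == "Vc")
    n_other <- sum(!gc %in% c("Va", "Vc"))
    tot <- length(gc)
    call <- if (tot == 0) "unassigned" else
      c("Va", "Vc")[which.max(c(n_va, n_vc))]
    if (tot > 0 && n_va == n_vc && n_va > 0) call <- "tie"
    if (tot > 0 && n_va == 0 && n_vc == 0) call <- "unassigned"
    data.frame(clade = cl, n_clustered = tot, n_va = n_va, n_vc = n_vc,
               n_other = n_other, call = call,
               purity = if (tot == 0) NA_real_ else
                 max(n_va, n_vc, n_other) / tot,
               singles_va = sum(gen[!clustered] == "Va"),
               singles_vc = sum(gen[!clustered] == "Vc"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
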