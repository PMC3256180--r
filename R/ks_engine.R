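#' Global protein alignment with affine gaps
#'
#' Needleman-Wunsch global alignment of two protein sequences under a
#' substitution matrix (BLOSUM62 by default) with affine gap costs: a gap of
#' length L costs \code{gap_open + L * gap_extend}, the convention used by
#' BLAST. Identity is computed over ungapped columns only.
#'
#' @param protein_a,protein_b Protein sequences (character).
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (e.g. \code{"BLOSUM62"}) or a numeric matrix.
#' @param gap_open,gap_extend Affine gap parameters.
#' @return A \code{pairwise_alignment} list: \code{aligned_a},
#'   \code{aligned_b} (gapped strings of equal length), \code{score},
#'   \code{aligned_length} (columns), \code{ungapped_columns},
#'   \code{identity_fraction}.
#' @export
align_global <- function(protein_a, protein_b,
                         substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  if (!nzchar(protein_a) || !nzchar(protein_b))
    stop("cannot align an empty sequence")
  mat <- resolve_submat(substitution_matrix)
  r <- .align_pairs_cpp(c(protein_a, protein_b), 1L, 2L, mat,
                        gap_open, gap_extend, FALSE, TRUE)
  new_pairwise_alignment(r$aligned_a[1], r$aligned_b[1], r$score[1])
}

#' Local protein alignment with affine gaps
#'
#' Smith-Waterman optimal local alignment under the same scoring scheme as
#' \code{\link{align_global}}.
#'
#' @inheritParams align_global
#' @return A \code{pairwise_alignment} list (see
#'   \code{\link{align_global}}); coordinates refer to the aligned local
#'   segment only.
#' @export
align_local <- function(protein_a, protein_b,
                        substitution_matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(protein_a) || !nzchar(protein_b))
    stop("cannot align an empty sequence")
  mat <- resolve_submat(substitution_matrix)
  r <- .align_pairs_cpp(c(protein_a, protein_b), 1L, 2L, mat,
                        gap_open, gap_extend, TRUE, TRUE)
  new_pairwise_alignment(r$aligned_a[1], r$aligned_b[1], r$score[1])
}

new_pairwise_alignment <- function(a, b, score) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ung <- ca != "-" & cb != "-"
  structure(list(
    aligned_a = a, aligned_b = b, score = unname(score),
    aligned_length = nchar(a),
    ungapped_columns = sum(ung),
    identity_fraction = if (sum(ung) == 0) NA_real_ else
      sum(ca[ung] == cb[ung]) / sum(ung)),
    class = "pairwise_alignment")
}

resolve_submat <- function(m) {
  if (is.matrix(m)) return(m)
  e <- new.env()
  utils::data(list = m, package = "Biostrings", envir = e)
  get(m, envir = e)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each amino-acid column of a global protein alignment onto the
#' corresponding codon triplets of the two coding sequences; gap columns
#' become codon gaps (\code{"---"}). This protein-guided construction keeps
#' the codon alignment in frame by design.
#'
#' @param alignment A \code{pairwise_alignment} from
#'   \code{\link{align_global}}.
#' @param cds_a,cds_b Coding sequences; each must be exactly three times the
#'   ungapped length of the corresponding aligned protein.
#' @param gene_a,gene_b Optional ids used in error messages.
#' @return A list with \code{codons_a} and \code{codons_b}, character
#'   vectors of equal length holding codons or \code{"---"}.
#' @export
backtranslate <- function(alignment, cds_a, cds_b,
                          gene_a = "gene_a", gene_b = "gene_b") {
  row_codons <- function(aligned, cds, id) {
    ch <- strsplit(aligned, "", fixed = TRUE)[[1]]
    n_res <- sum(ch != "-")
    if (nchar(cds) != 3 * n_res)
      stop("CDS length of ", id, " (", nchar(cds),
           ") does not match 3 x ", n_res, " aligned residues")
    cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    out <- rep("---", length(ch))
    out[ch != "-"] <- cod
    out
  }
  list(codons_a = row_codons(alignment$aligned_a, cds_a, gene_a),
       codons_b = row_codons(alignment$aligned_b, cds_b, gene_b))
}

# ---------------------------------------------------------------------------
# NG86 machinery. Site and pathway counts are precomputed once over the 64
# codons of the standard genetic code and cached in the package namespace.
# Convention: single-nucleotide changes that create a stop codon are excluded
# from both the numerator and the denominator of the per-position synonymous
# site fraction, and mutation pathways passing through a stop codon are
# excluded from pathway averaging (with a fall-back to all pathways, counting
# steps into stops as nonsynonymous, in the rare case every pathway is
# blocked).
# ---------------------------------------------------------------------------

.ng86_cache <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_cache$tab)) return(.ng86_cache$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  sense <- codons[gc != "*"]
  nts <- c("A", "C", "G", "T")
  aa_of <- function(cod) unname(gc[cod])

  syn_sites <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    s <- 0
    for (pos in 1:3) {
      alts <- vapply(setdiff(nts, substr(cod, pos, pos)), function(n) {
        x <- cod; substr(x, pos, pos) <- n; x
      }, character(1))
      alts <- alts[gc[alts] != "*"]
      if (length(alts) > 0)
        s <- s + sum(gc[alts] == gc[cod]) / length(alts)
    }
    syn_sites[cod] <- s
  }

  n <- length(sense)
  sd <- matrix(0, n, n, dimnames = list(sense, sense))
  nd <- matrix(0, n, n, dimnames = list(sense, sense))
  perms2 <- list(1:2, 2:1)
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      c1 <- sense[i]; c2 <- sense[j]
      pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      d <- length(pos)
      perms <- switch(d, list(1L), lapply(perms2, function(p) pos[p]),
                      lapply(perms3, function(p) pos[p]))
      if (d == 1) perms <- list(pos)
      paths <- lapply(perms, function(ord) {
        cur <- c1; steps <- character(0)
        via_stop <- FALSE
        syn <- 0; non <- 0
        for (p in ord) {
          nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
          if (gc[nxt] == "*") via_stop <- TRUE
          if (gc[cur] == gc[nxt] && gc[cur] != "*") syn <- syn + 1
          else non <- non + 1
          cur <- nxt
        }
        list(syn = syn, non = non, via_stop = via_stop)
      })
      ok <- !vapply(paths, `[[`, logical(1), "via_stop")
      use <- if (any(ok)) paths[ok] else paths
      sd[i, j] <- sd[j, i] <- mean(vapply(use, `[[`, numeric(1), "syn"))
      nd[i, j] <- nd[j, i] <- mean(vapply(use, `[[`, numeric(1), "non"))
    }
  }
  .ng86_cache$tab <- list(sense = sense, syn_sites = syn_sites,
                          sd = sd, nd = nd)
  .ng86_cache$tab
}

#' Synonymous and nonsynonymous divergence of a codon alignment (NG86)
#'
#' Nei-Gojobori (1986) estimator: synonymous and nonsynonymous sites are
#' counted per codon (averaged over the two sequences), differences are
#' counted by averaging over all minimal mutation pathways between each
#' codon pair (pathways through stop codons excluded), and the raw
#' proportions are corrected for multiple hits with the Jukes-Cantor
#' formula \eqn{K = -3/4 \log(1 - 4/3 p)}. When the synonymous proportion
#' reaches 3/4 the correction is undefined and the value is flagged as
#' saturated rather than raising an error.
#'
#' @param codon_alignment List with \code{codons_a}, \code{codons_b} as
#'   produced by \code{\link{backtranslate}}.
#' @return A list: \code{ks}, \code{ka} (NA when saturated), \code{ps},
#'   \code{pn} (raw proportions), \code{syn_sites}, \code{nonsyn_sites},
#'   \code{syn_diffs}, \code{nonsyn_diffs}, \code{n_codons} (ungapped,
#'   unambiguous codon columns used), \code{saturated} (logical, refers to
#'   the synonymous component).
#' @export
compute_ks <- function(codon_alignment) {
  tab <- ng86_tables()
  ca <- codon_alignment$codons_a
  cb <- codon_alignment$codons_b
  if (length(ca) != length(cb))
    stop("codon alignment rows differ in length")
  keep <- ca %in% tab$sense & cb %in% tab$sense
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0)
    stop("no ungapped, unambiguous sense-codon columns in alignment")
  ia <- match(ca, tab$sense); ib <- match(cb, tab$sense)
  S <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N <- 3 * length(ca) - S
  if (S <= 0) stop("alignment contains zero synonymous sites")
  Sd <- sum(tab$sd[cbind(ia, ib)])
  Nd <- sum(tab$nd[cbind(ia, ib)])
  ps <- Sd / S
  pn <- Nd / N
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  ks <- jc(ps)
  list(ks = ks, ka = jc(pn), ps = ps, pn = pn,
       syn_sites = S, nonsyn_sites = N,
       syn_diffs = Sd, nonsyn_diffs = Nd,
       n_codons = length(ca), saturated = is.na(ks))
}

#' Pairwise Ks over a set of genes
#'
#' Aligns protein pairs globally (BLOSUM62, affine gaps), applies the
#' alignment quality filter (at least \code{min_aln_len} ungapped aligned
#' amino acids and identity above \code{min_identity}), back-translates
#' passing pairs to codon alignments and estimates Ks with
#' \code{\link{compute_ks}}. Pairs failing the filter are retained in the
#' output with \code{passes_filter = FALSE} and no Ks value.
#'
#' @param genes NBS-R gene table (needs \code{gene_id}, \code{protein},
#'   \code{cds}).
#' @param pairs Optional data.frame with columns \code{gene_a},
#'   \code{gene_b}; defaults to all unordered pairs.
#' @param min_aln_len,min_identity Filter thresholds (150 aa, 0.30).
#' @param gap_open,gap_extend Affine gap parameters.
#' @return Data.frame: \code{gene_a}, \code{gene_b}, \code{aligned_len}
#'   (ungapped columns), \code{identity}, \code{passes_filter}, \code{ks},
#'   \code{saturated}.
#' @export
compute_ks_table <- function(genes, pairs = NULL, min_aln_len = 150,
                             min_identity = 0.30, gap_open = 11,
                             gap_extend = 1) {
  prot <- setNames(genes$protein, genes$gene_id)
  cds <- setNames(genes$cds, genes$gene_id)
  if (is.null(pairs)) {
    if (length(prot) < 2) stop("need at least two genes")
    cmb <- combn(genes$gene_id, 2)
    pairs <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                        stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(prot))
  if (length(unknown) > 0)
    stop("unknown gene in pair list: ", unknown[1])
  mat <- resolve_submat("BLOSUM62")
  ia <- match(pairs$gene_a, genes$gene_id)
  ib <- match(pairs$gene_b, genes$gene_id)
  r <- .align_pairs_cpp(genes$protein, ia, ib, mat, gap_open, gap_extend,
                        FALSE, TRUE)
  ung <- r$ungapped
  ident <- ifelse(ung > 0, r$nmatch / ung, NA_real_)
  passes <- !is.na(ident) & ung >= min_aln_len & ident > min_identity
  ks <- rep(NA_real_, nrow(pairs))
  sat <- rep(NA, nrow(pairs))
  for (i in which(passes)) {
    cal <- backtranslate(
      list(aligned_a = r$aligned_a[i], aligned_b = r$aligned_b[i]),
      cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]],
      pairs$gene_a[i], pairs$gene_b[i])
    kr <- compute_ks(cal)
    ks[i] <- kr$ks
    sat[i] <- kr$saturated
  }
  out <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    aligned_len = ung, identity = ident,
                    passes_filter = passes, ks = ks, saturated = sat,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Partition Ks values into within-cluster and between components
#'
#' A gene pair is within-cluster (Ks-w) when both genes belong to the same
#' called cluster; every other pair (different clusters, or one or both
#' genes single) is between (Ks-bg). Means are computed over filtered,
#' non-saturated values.
#'
#' @param ks_table Output of \code{\link{compute_ks_table}}.
#' @param clusters Cluster table from \code{\link{call_clusters}}.
#' @param singles Character vector of single gene ids.
#' @return A list: \code{ks_w}, \code{ks_bg} (data.frames), \code{mean_w},
#'   \code{mean_bg}, \code{n_saturated}, \code{n_filtered_out}.
#' @export
partition_ks <- function(ks_table, clusters, singles = character(0)) {
  mem <- cluster_membership(clusters)
  known <- c(names(mem), singles)
  unknown <- setdiff(unique(c(ks_table$gene_a, ks_table$gene_b)), known)
  if (length(unknown) > 0)
    stop("gene neither clustered nor single: ", unknown[1])
  cl_a <- unname(mem[ks_table$gene_a])
  cl_b <- unname(mem[ks_table$gene_b])
  within <- !is.na(cl_a) & !is.na(cl_b) & cl_a == cl_b
  ks_table$kind <- ifelse(within, "within", "between")
  usable <- ks_table$passes_filter & !is.na(ks_table$ks)
  mw <- mean(ks_table$ks[within & usable])
  mb <- mean(ks_table$ks[!within & usable])
  list(ks_w = ks_table[within, , drop = FALSE],
       ks_bg = ks_table[!within, , drop = FALSE],
       mean_w = mw, mean_bg = mb,
       n_saturated = sum(ks_table$saturated, na.rm = TRUE),
       n_filtered_out = sum(!ks_table$passes_filter))
}
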