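#' @importFrom stats runif rpois quantile cor setNames
#' @importFrom utils combn read.delim write.table head
#' @importFrom Rcpp evalCpp
#' @useDynLib nbsdecon, .registration = TRUE
NULL

# Valid accessory/core domain symbols for NBS-R proteins.
NBS_DOMAINS <- c("TIR", "CC", "NBARC", "LRR")

# The six recognised NBS-R gene classes.
NBS_CLASSES <- c("CC-NBS-LRR", "CC-NBS", "TIR-NBS-LRR", "TIR-NBS",
                 "NBS-LRR", "NBS-tr")

#' Classify an NBS-R gene from its domain composition
#'
#' NBS-R genes are defined by the presence of the NB-ARC nucleotide-binding
#' domain and fall into six classes depending on which accessory domains
#' (TIR or CC at the N terminus, LRR at the C terminus) accompany it.
#' TIR and CC are structurally alternative N-terminal domains and are never
#' found together in one protein.
#'
#' @param domains Character vector of domain symbols, a subset of
#'   \code{c("TIR", "CC", "NBARC", "LRR")}.
#' @return A single class label, one of \code{"CC-NBS-LRR"}, \code{"CC-NBS"},
#'   \code{"TIR-NBS-LRR"}, \code{"TIR-NBS"}, \code{"NBS-LRR"},
#'   \code{"NBS-tr"}.
#' @examples
#' classify_nbs_gene(c("CC", "NBARC", "LRR"))  # "CC-NBS-LRR"
#' classify_nbs_gene("NBARC")                  # "NBS-tr"
#' @export
classify_nbs_gene <- function(domains) {
  domains <- unique(as.character(domains))
  bad <- setdiff(domains, NBS_DOMAINS)
  if (length(bad) > 0)
    stop("unknown domain symbol(s): ", paste(bad, collapse = ", "))
  if (!"NBARC" %in% domains)
    stop("gene lacks the NB-ARC domain and is not an NBS-R gene")
  if (all(c("TIR", "CC") %in% domains))
    stop("conflicting domains: TIR and CC are mutually exclusive")
  has_lrr <- "LRR" %in% domains
  if ("TIR" %in% domains) {
    if (has_lrr) "TIR-NBS-LRR" else "TIR-NBS"
  } else if ("CC" %in% domains) {
    if (has_lrr) "CC-NBS-LRR" else "CC-NBS"
  } else {
    if (has_lrr) "NBS-LRR" else "NBS-tr"
  }
}

# Parse a "TIR;CC;NBARC;LRR"-style domain string into a character vector.
split_domains <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Construct and validate a table of NBS-R gene records
#'
#' The gene table is the package's central container: one row per NBS-R gene
#' with coordinates (0-based, half-open), strand, coding and protein
#' sequence, 3' genomic flank and domain composition. Validation enforces the
#' structural invariants: end strictly greater than start, CDS length a
#' multiple of three, translation of the CDS equal to the stated protein
#' (terminal stop codons are stripped before comparison), and presence of the
#' NB-ARC domain. The class label is (re)derived from the domain string.
#'
#' @param genes A data.frame with columns \code{gene_id}, \code{chromosome},
#'   \code{start}, \code{end}, \code{strand}, \code{cds}, \code{protein},
#'   \code{flank3}, \code{domains} (semicolon-joined domain symbols).
#'   Unanchored genes use chromosome \code{"unanchored"}.
#' @return The validated data.frame with an \code{nbs_class} column added,
#'   sorted by chromosome then start.
#' @export
nbs_gene_table <- function(genes) {
  req <- c("gene_id", "chromosome", "start", "end", "strand",
           "cds", "protein", "flank3", "domains")
  miss <- setdiff(req, names(genes))
  if (length(miss) > 0)
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(genes$end <= genes$start))
    stop("end must exceed start for gene ",
         genes$gene_id[which(genes$end <= genes$start)[1]])
  badlen <- nchar(genes$cds) %% 3 != 0
  if (any(badlen))
    stop("CDS length not divisible by 3 for gene ",
         genes$gene_id[which(badlen)[1]])
  tr <- translate_cds(genes$cds)
  mism <- tr != genes$protein
  if (any(mism))
    stop("CDS translation does not match protein for gene ",
         genes$gene_id[which(mism)[1]])
  genes$nbs_class <- vapply(genes$domains,
                            function(d) classify_nbs_gene(split_domains(d)),
                            character(1), USE.NAMES = FALSE)
  genes <- genes[order(genes$chromosome, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  genes
}

# Translate a character vector of CDS to proteins, stripping terminal
# stops. Literal codon translation: no initiator-codon special-casing.
translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                           no.init.codon = TRUE,
                                           if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

#' Build per-chromosome gene annotations
#'
#' Combines NBS-R genes and non-NBS open reading frames into one
#' position-ordered table per chromosome, the input expected by
#' \code{\link{call_clusters}}. Intervening non-NBS ORF counts between
#' consecutive NBS-R genes are read off this table.
#'
#' @param genes NBS-R gene table (see \code{\link{nbs_gene_table}});
#'   unanchored genes are dropped.
#' @param orfs Optional data.frame of non-NBS ORFs with columns
#'   \code{gene_id}, \code{chromosome}, \code{start}, \code{end}.
#' @return A data.frame with columns \code{chromosome}, \code{gene_id},
#'   \code{start}, \code{end}, \code{is_nbs}, strictly ordered by
#'   chromosome then start.
#' @export
chromosome_annotation <- function(genes, orfs = NULL) {
  g <- genes[genes$chromosome != "unanchored",
             c("chromosome", "gene_id", "start", "end")]
  g$is_nbs <- TRUE
  if (!is.null(orfs) && nrow(orfs) > 0) {
    o <- orfs[, c("chromosome", "gene_id", "start", "end")]
    o$is_nbs <- FALSE
    g <- rbind(g, o)
  }
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id in annotation: ",
         g$gene_id[duplicated(g$gene_id)][1])
  g <- g[order(g$chromosome, g$start, g$gene_id), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Write an annotation set to disk
#'
#' Emits the on-disk representation of a gene set: a GFF3 file with
#' \code{nbs_gene} and \code{orf} features (1-based inclusive coordinates,
#' converted from the package's internal 0-based half-open convention),
#' FASTA files for CDS, protein and 3' flank sequences, and a TSV domain
#' table with 0/1 flags for TIR, CC, NBARC and LRR.
#'
#' @param genes NBS-R gene table.
#' @param dir Output directory, created if absent.
#' @param orfs Optional non-NBS ORF table (columns \code{gene_id},
#'   \code{chromosome}, \code{start}, \code{end}).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_annotation_set <- function(genes, dir, orfs = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  feat <- genes[, c("chromosome", "gene_id", "start", "end", "strand")]
  feat$type <- "nbs_gene"
  if (!is.null(orfs) && nrow(orfs) > 0) {
    o <- orfs[, c("chromosome", "gene_id", "start", "end")]
    o$strand <- "+"
    o$type <- "orf"
    feat <- rbind(feat, o)
  }
  feat <- feat[order(feat$chromosome, feat$start, feat$gene_id), ,
               drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chromosome,
    ranges = IRanges::IRanges(start = feat$start + 1L, end = feat$end),
    strand = feat$strand)
  gr$type <- feat$type
  gr$ID <- feat$gene_id
  paths <- list(
    gff3 = file.path(dir, "genes.gff3"),
    cds = file.path(dir, "cds.fasta"),
    protein = file.path(dir, "protein.fasta"),
    flank3 = file.path(dir, "flank3.fasta"),
    domains = file.path(dir, "domains.tsv"))
  rtracklayer::export(gr, paths$gff3, format = "gff3")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(genes$cds, genes$gene_id)), paths$cds)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(genes$protein, genes$gene_id)),
    paths$protein)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(genes$flank3, genes$gene_id)),
    paths$flank3)
  dm <- data.frame(gene_id = genes$gene_id)
  for (d in NBS_DOMAINS)
    dm[[d]] <- vapply(genes$domains,
                      function(x) as.integer(d %in% split_domains(x)),
                      integer(1), USE.NAMES = FALSE)
  write.table(dm, paths$domains, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Load an annotation set from disk
#'
#' Reads the files written by \code{\link{write_annotation_set}} (or
#' equivalently structured third-party files) and cross-references them:
#' every \code{nbs_gene} feature must have a CDS, a protein and a domain row,
#' the CDS must translate to the protein, and the NB-ARC domain must be
#' present. GFF3 coordinates are converted to the internal 0-based half-open
#' convention on input.
#'
#' @param gff3_path GFF3 with \code{nbs_gene} and \code{orf} features.
#' @param cds_path,protein_path FASTA files keyed by gene id.
#' @param domains_path TSV with columns \code{gene_id}, \code{TIR},
#'   \code{CC}, \code{NBARC}, \code{LRR} (0/1 flags).
#' @param flank3_path Optional FASTA of 3' flanks; absent flanks are
#'   recorded as empty strings.
#' @return A list with elements \code{genes} (validated NBS-R gene table,
#'   anchored and unanchored) and \code{annotation} (per-chromosome table of
#'   anchored genes plus non-NBS ORFs, see
#'   \code{\link{chromosome_annotation}}).
#' @export
load_annotation_set <- function(gff3_path, cds_path, protein_path,
                                domains_path, flank3_path = NULL) {
  for (p in c(gff3_path, cds_path, protein_path, domains_path))
    if (!file.exists(p)) stop("file not found: ", p)
  gr <- rtracklayer::import(gff3_path)
  feat <- data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    gene_id = as.character(gr$ID),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    stringsAsFactors = FALSE)
  cds <- Biostrings::readDNAStringSet(cds_path)
  prot <- Biostrings::readAAStringSet(protein_path)
  names(cds) <- sub("\\s.*$", "", names(cds))
  names(prot) <- sub("\\s.*$", "", names(prot))
  fl <- if (!is.null(flank3_path) && file.exists(flank3_path)) {
    x <- Biostrings::readDNAStringSet(flank3_path)
    names(x) <- sub("\\s.*$", "", names(x))
    x
  } else NULL
  dm <- read.delim(domains_path, stringsAsFactors = FALSE)
  nbs <- feat[feat$type == "nbs_gene", , drop = FALSE]
  for (id in nbs$gene_id) {
    if (!id %in% names(cds)) stop("no CDS sequence for gene ", id)
    if (!id %in% names(prot)) stop("no protein sequence for gene ", id)
    if (!id %in% dm$gene_id) stop("no domain row for gene ", id)
  }
  dmrow <- dm[match(nbs$gene_id, dm$gene_id), , drop = FALSE]
  domstr <- apply(dmrow[, NBS_DOMAINS, drop = FALSE], 1, function(r)
    paste(NBS_DOMAINS[r == 1], collapse = ";"))
  genes <- data.frame(
    gene_id = nbs$gene_id,
    chromosome = nbs$chromosome,
    start = nbs$start,
    end = nbs$end,
    strand = nbs$strand,
    cds = as.character(cds[nbs$gene_id]),
    protein = as.character(prot[nbs$gene_id]),
    flank3 = if (is.null(fl)) "" else {
      v <- as.character(fl)
      ifelse(nbs$gene_id %in% names(v), unname(v[nbs$gene_id]), "")
    },
    domains = domstr,
    stringsAsFactors = FALSE)
  genes <- nbs_gene_table(genes)
  orfs <- feat[feat$type == "orf",
               c("gene_id", "chromosome", "start", "end"), drop = FALSE]
  list(genes = genes,
       annotation = chromosome_annotation(genes, orfs))
}
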