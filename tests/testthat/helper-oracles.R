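# Independent reference implementations used as oracles. These are written
# from the definitions, not from the package internals, and favour clarity
# over speed.

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# Plain-R Gotoh global alignment score (gap of length L costs go + L*ge,
# end gaps penalised).
oracle_global_score <- function(a, b, go = 11, ge = 1) {
  sub <- blosum62()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(go + ge * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(go + ge * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub[A[i], B[j]]
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                             Y[i, j + 1] - go - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
                             Y[i + 1, j] - ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Plain-R Smith-Waterman local alignment score.
oracle_local_score <- function(a, b, go = 11, ge = 1) {
  sub <- blosum62()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                             Y[i, j + 1] - go - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
                             Y[i + 1, j] - ge)
      M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) +
                               sub[A[i], B[j]])
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# --- NG86 oracle -----------------------------------------------------------
# Exhaustive mutation-pathway implementation of the Nei-Gojobori estimator.
# Conventions (shared with the package, by definition): single-nucleotide
# changes creating a stop codon are excluded from both numerator and
# denominator of the per-position synonymous-site fraction; pathways through
# stop codons are excluded from pathway averaging, with a fall-back to all
# pathways when every one is blocked.

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

oracle_syn_sites <- function(cod) {
  GC <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  tot <- 0
  for (p in 1:3) {
    alts <- vapply(setdiff(nts, substr(cod, p, p)), function(nt) {
      x <- cod; substr(x, p, p) <- nt; x
    }, character(1))
    alts <- alts[GC[alts] != "*"]
    if (length(alts) > 0)
      tot <- tot + sum(GC[alts] == GC[cod]) / length(alts)
  }
  tot
}

oracle_pair_diffs <- function(c1, c2) {
  GC <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(syn = 0, non = 0))
  paths <- lapply(oracle_permutations(pos), function(ord) {
    cur <- c1; syn <- 0; non <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      if (GC[nxt] == "*") blocked <- TRUE
      if (GC[cur] != "*" && GC[cur] == GC[nxt]) syn <- syn + 1
      else non <- non + 1
      cur <- nxt
    }
    list(syn = syn, non = non, blocked = blocked)
  })
  open <- Filter(function(p) !p$blocked, paths)
  if (length(open) == 0) open <- paths
  c(syn = mean(vapply(open, `[[`, numeric(1), "syn")),
    non = mean(vapply(open, `[[`, numeric(1), "non")))
}

oracle_ng86 <- function(codons_a, codons_b) {
  GC <- Biostrings::GENETIC_CODE
  keep <- !is.na(GC[codons_a]) & !is.na(GC[codons_b]) &
    GC[codons_a] != "*" & GC[codons_b] != "*"
  codons_a <- codons_a[keep]; codons_b <- codons_b[keep]
  S <- (sum(vapply(codons_a, oracle_syn_sites, numeric(1))) +
          sum(vapply(codons_b, oracle_syn_sites, numeric(1)))) / 2
  if (S == 0)
    return(list(ks = NA_real_, ps = NA_real_, syn_sites = 0, syn_diffs = 0))
  d <- mapply(function(x, y) oracle_pair_diffs(x, y), codons_a, codons_b)
  Sd <- sum(d["syn", ])
  ps <- Sd / S
  ks <- if (ps >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * ps)
  list(ks = ks, ps = ps, syn_sites = S, syn_diffs = Sd)
}

# --- stem-loop brute-force enumerator --------------------------------------
# TRUE when the sequence contains any arm pairing satisfying the scan
# configuration (score rule), by direct enumeration of every left-arm
# start, arm length and loop length.
oracle_has_stem <- function(seq, config = helitron_config()) {
  ch <- strsplit(toupper(seq), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(ch)
  for (ls in seq_len(n)) {
    for (arm in 1:((config$max_repeat_len - config$min_loop) %/% 2)) {
      for (loop in config$min_loop:min(config$max_loop,
                                       config$max_repeat_len - 2 * arm)) {
        re <- ls + 2 * arm + loop - 1
        if (re > n) next
        sc <- 0
        for (k in 0:(arm - 1)) {
          lnt <- ch[ls + k]
          rnt <- ch[ls + 2 * arm + loop - 1 - k]
          ok <- !is.na(comp[lnt]) && !is.na(rnt) && comp[[lnt]] == rnt
          sc <- sc + if (ok) config$match_score else config$mismatch_score
        }
        if (sc >= config$min_stem_score) return(TRUE)
      }
    }
  }
  FALSE
}

# Nearest-rank percentile selection oracle: how many values lie at or above
# the value at rank ceiling(p/100 * N) of the ascending sort.
oracle_percentile_selected <- function(values, p) {
  srt <- sort(values)
  thr <- srt[ceiling(p / 100 * length(srt))]
  sum(values >= thr)
}

random_protein <- function(n) {
  paste(sample(rownames(blosum62())[1:20], n, replace = TRUE),
        collapse = "")
}
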