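#' Helitron footprint scan configuration
#'
#' Helitron excision leaves two diagnostic marks in the 3' region of a
#' mobilized gene: an inverted repeat able to form a stem-loop, and a CTAG
#' tetranucleotide shortly downstream of it. Stems are scored per paired
#' position (match \code{+3}, mismatch \code{-1}, no gaps) and reported when
#' the arm score reaches \code{min_stem_score}; with the defaults a perfect
#' 10-bp arm (score 30) passes while a 10-bp arm with one mismatch
#' (score 26) does not. \code{max_repeat_len} bounds the total extent of the
#' inverted repeat (left-arm start to right-arm end, the einverted
#' "maxrepeat" convention), so the default scan reports compact, near-perfect
#' hairpins. \code{stem_rule = "length"} instead requires the arm length
#' itself to reach \code{min_stem_score} base pairs (which needs a larger
#' \code{max_repeat_len} to be satisfiable).
#'
#' @param min_stem_score Minimum arm score (or arm length under the length
#'   rule); default 28.
#' @param match_score,mismatch_score Per-position arm scores (+3 / -1).
#' @param max_repeat_len Maximum total stem-loop extent in bp (default 30).
#' @param min_loop,max_loop Loop length bounds in bp.
#' @param max_ctag_distance Maximum distance from the stem-loop to the CTAG
#'   (default 100 bp).
#' @param scan_window How much of the 3' flank to scan (default 1000 bp).
#' @param stem_rule \code{"score"} (default) or \code{"length"}.
#' @return A \code{helitron_config} object.
#' @export
helitron_config <- function(min_stem_score = 28, match_score = 3,
                            mismatch_score = -1, max_repeat_len = 30,
                            min_loop = 3, max_loop = 100,
                            max_ctag_distance = 100, scan_window = 1000,
                            stem_rule = c("score", "length")) {
  if (min_stem_score <= 0) stop("min_stem_score must be positive")
  stem_rule <- match.arg(stem_rule)
  min_arm <- if (stem_rule == "length") min_stem_score else
    ceiling(min_stem_score / match_score)
  if (2 * min_arm + min_loop > max_repeat_len)
    stop("max_repeat_len too small for the minimum achievable stem-loop")
  structure(list(min_stem_score = min_stem_score,
                 match_score = match_score,
                 mismatch_score = mismatch_score,
                 max_repeat_len = max_repeat_len,
                 min_loop = min_loop, max_loop = max_loop,
                 max_ctag_distance = max_ctag_distance,
                 scan_window = scan_window, stem_rule = stem_rule),
            class = "helitron_config")
}

# Encode A/C/G/T as 1..4, anything else (masked) as 0.
encode_nt <- function(seq) {
  v <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T"))
  v[is.na(v)] <- 0L
  v
}

#' Find inverted-repeat stem-loops in a nucleotide sequence
#'
#' Enumerates candidate stem-loops: two arms of equal length separated by a
#' loop of \code{min_loop} to \code{max_loop} bases, with the whole
#' structure spanning at most \code{max_repeat_len} bases, where the right
#' arm is the reverse complement of the left arm up to scored mismatches.
#' For each loop placement the arm is
#' grown outwards from the loop and the best-scoring arm length retained;
#' qualifying hits are then pruned greedily (by score, then leftmost
#' position, then shortest loop) so that reported stem-loops do not overlap.
#' Non-ACGT characters are masked and scored as mismatches, with a warning.
#'
#' @param seq Nucleotide sequence (character scalar).
#' @param config A \code{\link{helitron_config}}.
#' @return Data.frame with 0-based half-open coordinates:
#'   \code{stem_left_start}, \code{stem_left_end}, \code{stem_right_start},
#'   \code{stem_right_end}, \code{arm_len}, \code{loop_len}, \code{score};
#'   one row per retained stem-loop, ordered by decreasing score.
#' @export
find_stem_loops <- function(seq, config = helitron_config()) {
  x <- encode_nt(seq)
  if (any(x == 0L) && nchar(seq) > 0)
    warning("non-ACGT characters masked and scored as mismatches")
  n <- length(x)
  comp <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G
  cx <- ifelse(x == 0L, 0L, comp[pmax(x, 1L)])
  hits <- list()
  min_arm <- if (config$stem_rule == "length") config$min_stem_score else
    max(1L, ceiling(config$min_stem_score / config$match_score))
  max_loop <- min(config$max_loop, config$max_repeat_len - 2 * min_arm)
  if (max_loop < config$min_loop) return(empty_stem_table())
  for (L in seq(config$min_loop, max_loop)) {
    max_arm <- (config$max_repeat_len - L) %/% 2
    # p = 1-based start of the loop; arms grow outwards from the loop.
    p_min <- 2L
    p_max <- n - L
    if (p_max < p_min) break
    p <- seq(p_min, p_max)
    best_score <- rep(-Inf, length(p))
    best_arm <- rep(0L, length(p))
    cum <- rep(0, length(p))
    for (t in seq_len(max_arm)) {
      li <- p - t
      ri <- p + L + t - 1L
      ok <- li >= 1L & ri <= n
      if (!any(ok)) break
      m <- ok & x[pmax(li, 1L)] != 0L &
        x[pmax(li, 1L)] == cx[pmin(ri, n)]
      step <- ifelse(m, config$match_score, config$mismatch_score)
      step[!ok] <- NA
      cum <- cum + step
      if (config$stem_rule == "length") {
        upd <- !is.na(cum) & t >= min_arm & cum > best_score
      } else {
        upd <- !is.na(cum) & cum > best_score
      }
      best_score[upd] <- cum[upd]
      best_arm[upd] <- t
    }
    pass <- if (config$stem_rule == "length")
      best_arm >= min_arm else best_score >= config$min_stem_score
    pass <- pass & is.finite(best_score)
    if (config$stem_rule == "length")
      pass <- pass & is.finite(best_score)
    if (any(pass)) {
      pp <- p[pass]
      aa <- best_arm[pass]
      hits[[length(hits) + 1]] <- data.frame(
        stem_left_start = pp - aa - 1L,
        stem_left_end = pp - 1L,
        stem_right_start = pp + L - 1L,
        stem_right_end = pp + L + aa - 1L,
        arm_len = aa, loop_len = L,
        score = best_score[pass])
    }
  }
  if (length(hits) == 0) return(empty_stem_table())
  h <- do.call(rbind, hits)
  h <- h[order(-h$score, h$stem_left_start, h$loop_len), , drop = FALSE]
  keep <- logical(nrow(h))
  occ_lo <- numeric(0); occ_hi <- numeric(0)
  for (i in seq_len(nrow(h))) {
    lo <- h$stem_left_start[i]; hi <- h$stem_right_end[i]
    if (!any(lo < occ_hi & hi > occ_lo)) {
      keep[i] <- TRUE
      occ_lo <- c(occ_lo, lo); occ_hi <- c(occ_hi, hi)
    }
  }
  h <- h[keep, , drop = FALSE]
  rownames(h) <- NULL
  h
}

empty_stem_table <- function() {
  data.frame(stem_left_start = integer(0), stem_left_end = integer(0),
             stem_right_start = integer(0), stem_right_end = integer(0),
             arm_len = integer(0), loop_len = integer(0), score = numeric(0))
}

#' Locate the CTAG signature downstream of a stem-loop
#'
#' Returns the nearest literal CTAG whose start lies at or downstream of
#' the stem-loop's right arm end, within \code{max_ctag_distance} bases.
#'
#' @param seq Nucleotide sequence (character scalar).
#' @param stem_right_end 0-based position one past the right arm.
#' @param config A \code{\link{helitron_config}}.
#' @return 0-based start of the CTAG, or \code{NA_integer_} if none within
#'   the cutoff.
#' @export
find_ctag <- function(seq, stem_right_end, config = helitron_config()) {
  if (stem_right_end < 0 || stem_right_end > nchar(seq))
    stop("stem interval outside sequence")
  m <- gregexpr("CTAG", toupper(seq), fixed = TRUE)[[1]]
  if (m[1] == -1) return(NA_integer_)
  pos0 <- as.integer(m) - 1L
  pos0 <- pos0[pos0 >= stem_right_end &
                 pos0 - stem_right_end <= config$max_ctag_distance]
  if (length(pos0) == 0) return(NA_integer_)
  pos0[1]
}

#' Detect a helitron footprint in a gene's 3' flank
#'
#' Scans the first \code{scan_window} bases of the 3' flank for stem-loops,
#' and returns the highest-scoring stem-loop that has a CTAG within the
#' distance cutoff downstream; genes whose flank carries no such combined
#' signature yield \code{NULL}.
#'
#' @param gene Either a single-row slice of an NBS-R gene table or a list
#'   with \code{gene_id} and \code{flank3}.
#' @param config A \code{\link{helitron_config}}.
#' @return A \code{helitron_footprint} list (\code{gene_id}, stem
#'   coordinates, \code{arm_len}, \code{loop_len}, \code{stem_score},
#'   \code{ctag_pos}, \code{ctag_to_stem_distance}) or \code{NULL}.
#' @export
detect_footprint <- function(gene, config = helitron_config()) {
  fl <- if (is.data.frame(gene)) gene$flank3[1] else gene$flank3
  id <- if (is.data.frame(gene)) gene$gene_id[1] else gene$gene_id
  if (is.null(fl) || is.na(fl) || !nzchar(fl))
    stop("gene ", id, " has no 3' flank sequence")
  win <- substr(fl, 1, config$scan_window)
  stems <- find_stem_loops(win, config)
  for (i in seq_len(nrow(stems))) {
    ct <- find_ctag(win, stems$stem_right_end[i], config)
    if (!is.na(ct)) {
      return(structure(list(
        gene_id = id,
        stem_left_start = stems$stem_left_start[i],
        stem_left_end = stems$stem_left_end[i],
        stem_right_start = stems$stem_right_start[i],
        stem_right_end = stems$stem_right_end[i],
        arm_len = stems$arm_len[i],
        loop_len = stems$loop_len[i],
        stem_score = stems$score[i],
        ctag_pos = ct,
        ctag_to_stem_distance = ct - stems$stem_right_end[i]),
        class = "helitron_footprint"))
    }
  }
  NULL
}

#' Scan many genes for helitron footprints
#'
#' @param genes NBS-R gene table with non-empty \code{flank3} sequences.
#' @param config A \code{\link{helitron_config}}.
#' @return Data.frame with one row per gene: \code{gene_id},
#'   \code{has_footprint} and, for detected footprints, the stem and CTAG
#'   coordinates (NA otherwise).
#' @export
scan_flanks <- function(genes, config = helitron_config()) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    fp <- detect_footprint(genes[i, ], config)
    if (is.null(fp)) {
      data.frame(gene_id = genes$gene_id[i], has_footprint = FALSE,
                 stem_left_start = NA_integer_, stem_right_end = NA_integer_,
                 arm_len = NA_integer_, loop_len = NA_integer_,
                 stem_score = NA_real_, ctag_pos = NA_integer_,
                 ctag_to_stem_distance = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = fp$gene_id, has_footprint = TRUE,
                 stem_left_start = fp$stem_left_start,
                 stem_right_end = fp$stem_right_end,
                 arm_len = fp$arm_len, loop_len = fp$loop_len,
                 stem_score = fp$stem_score, ctag_pos = fp$ctag_pos,
                 ctag_to_stem_distance = fp$ctag_to_stem_distance,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
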