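# Plant-style miRNA:mRNA complementarity scoring.
#
# The miRNA (5'->3') pairs the transcript site antiparallel: miRNA nt 1
# pairs the 3'-most site base.  Slicing occurs between the transcript bases
# pairing miRNA nt 10 and 11; the cleavage coordinate (C.Site) is the
# transcript base pairing miRNA nt 10, i.e. the 5' nucleotide of the 3'
# cleavage fragment.  All sequences are handled on the DNA alphabet (U -> T).

.CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L, N = 5L)

.encode <- function(seq) {
  x <- .CODE[strsplit(toupper(seq), "", fixed = TRUE)[[1L]]]
  x[is.na(x)] <- 5L
  unname(x)
}

# Pair state between miRNA base (row) and transcript base (col), both DNA
# codes: 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch.  N never pairs.
.PAIR_STATE <- local({
  m <- matrix(2L, 5L, 5L)
  wc <- rbind(c(1L, 4L), c(4L, 1L), c(2L, 3L), c(3L, 2L))
  m[wc] <- 0L
  m[rbind(c(3L, 4L), c(4L, 3L))] <- 1L   # miRNA G : target U ; miRNA U : target G
  m
})

#' Duplex penalty scheme
#'
#' The published analysis states only the gate ("scores up to 7"); the
#' penalties here are the standard plant target-prediction scheme of the
#' CleaveLand lineage: mismatch 1, G:U wobble 0.5, each gapped position 1,
#' all doubled at miRNA positions 2--13.  Every value is configurable.
#'
#' @param mismatch,gu,gap Per-position penalties.
#' @param core_start,core_end 1-based miRNA positions of the doubled core.
#' @param core_mult Multiplier applied inside the core.
#' @return A list of class `duplex_penalties`.
#' @export
duplex_penalties <- function(mismatch = 1, gu = 0.5, gap = 1,
                             core_start = 2L, core_end = 13L, core_mult = 2) {
  stopifnot(mismatch >= 0, gu >= 0, gap >= 0, core_mult >= 1,
            core_start >= 1L, core_end >= core_start)
  structure(list(mismatch = mismatch, gu = gu, gap = gap,
                 core_start = as.integer(core_start),
                 core_end = as.integer(core_end), core_mult = core_mult),
            class = "duplex_penalties")
}

.core_weights <- function(L, pen) {
  ifelse(seq_len(L) >= pen$core_start & seq_len(L) <= pen$core_end,
         pen$core_mult, 1)
}

# Score all antiparallel pairings of mc against tc at 3' window ends `e`,
# with per-position transcript offsets `offs` (transcript index = e - offs).
# `w` carries the core-doubling weights *by original miRNA position* so that
# bulged variants (where mc is a subset) keep the right doubling.
# Returns scores and the length(mc) x length(e) pair-state matrix.
.variant_scores <- function(mc, tc, e, offs, pen, w = .core_weights(length(mc), pen)) {
  L <- length(mc)
  n <- length(e)
  idx <- rep(e, each = L) - offs
  st <- .PAIR_STATE[cbind(rep.int(mc, n), tc[idx])]
  dim(st) <- c(L, n)
  penv <- c(0, pen$gu, pen$mismatch)[st + 1L]
  dim(penv) <- c(L, n)
  score <- as.numeric(w %*% penv)
  list(score = score, st = st)
}

# Whether a single-nt gap attached to miRNA position j (miRNA-side bulge) or
# between j and j+1 (transcript-side bulge) falls in the doubled core.
.gap_penalty <- function(j, side, pen) {
  core <- if (side == "mirna") j >= pen$core_start && j <= pen$core_end
          else j >= pen$core_start && (j + 1L) <= pen$core_end
  pen$gap * if (core) pen$core_mult else 1
}

#' Score a miRNA:target-site duplex
#'
#' Sums per-miRNA-position penalties over a pairing-state vector: Watson-Crick
#' 0, G:U wobble, mismatch and gap as configured, doubled inside the core
#' (miRNA positions 2--13 by default).  The score is a pure, order-independent
#' sum.  When `pairing` is omitted it is derived from the sequences assuming a
#' gap-free antiparallel duplex (`site_seq` given 5'->3' on the transcript,
#' same length as the miRNA).
#'
#' @param mirna_seq miRNA sequence 5'->3' (RNA or DNA alphabet).
#' @param site_seq Transcript site 5'->3'; required when `pairing` is `NULL`.
#' @param pairing Optional character vector of per-miRNA-position states in
#'   `c("WC","GU","MM","GAP")`; must match the miRNA length.
#' @param penalties A [duplex_penalties()].
#' @return Non-negative numeric penalty score.
#' @export
score_duplex <- function(mirna_seq, site_seq = NULL, pairing = NULL,
                         penalties = duplex_penalties()) {
  mc <- .encode(mirna_seq)
  L <- length(mc)
  if (is.null(pairing)) {
    if (is.null(site_seq)) stop("either site_seq or pairing must be given")
    tc <- .encode(site_seq)
    if (length(tc) != L)
      stop("site_seq length (", length(tc),
           ") does not match miRNA length (", L, ") for gap-free pairing")
    st <- .PAIR_STATE[cbind(mc, rev(tc))]
    pairing <- c("WC", "GU", "MM")[st + 1L]
  }
  if (length(pairing) != L)
    stop("pairing vector length (", length(pairing),
         ") does not match miRNA length (", L, ")")
  if (!all(pairing %in% c("WC", "GU", "MM", "GAP")))
    stop("pairing states must be WC, GU, MM or GAP")
  per <- c(WC = 0, GU = penalties$gu, MM = penalties$mismatch,
           GAP = penalties$gap)[pairing]
  sum(per * .core_weights(L, penalties))
}

# Enumerate candidate duplexes of one miRNA against one transcript.
# Variants: gap-free windows; one transcript-side bulge between miRNA
# positions j/j+1 (j != 10: never between the cleavage-flanking bases); one
# miRNA-side bulge at position j in 2..L-1, j not in {10, 11}.
.enumerate_duplexes <- function(mc, tc, pen, gaps = TRUE) {
  L <- length(mc)
  tlen <- length(tc)
  out <- list()
  add <- function(s, e, score, ok, n_gu, c_site, gap_side, gap_pos) {
    out[[length(out) + 1L]] <<- data.frame(
      start = s, end = e, score = score, ok = ok, n_gu = n_gu,
      c_site = c_site, gap_side = gap_side, gap_pos = gap_pos,
      stringsAsFactors = FALSE)
  }
  ok1011 <- function(st, r10, r11) st[r10, ] != 2L & st[r11, ] != 2L

  if (tlen >= L) {
    e <- L:tlen
    v <- .variant_scores(mc, tc, e, offs = 0:(L - 1L), pen)
    add(e - L + 1L, e, v$score, ok1011(v$st, 10L, 11L),
        colSums(v$st == 1L), e - 9L, "none", NA_integer_)
  }
  if (gaps) {
    if (tlen >= L + 1L) {
      e <- (L + 1L):tlen
      for (j in setdiff(seq_len(L - 1L), 10L)) {
        offs <- ifelse(seq_len(L) <= j, seq_len(L) - 1L, seq_len(L))
        v <- .variant_scores(mc, tc, e, offs, pen)
        gp <- .gap_penalty(j, "transcript", pen)
        add(e - L, e, v$score + gp, ok1011(v$st, 10L, 11L),
            colSums(v$st == 1L), if (j >= 11L) e - 9L else e - 10L,
            "transcript", j)
      }
    }
    if (L >= 4L && tlen >= L - 1L) {
      e <- (L - 1L):tlen
      for (j in setdiff(2:(L - 1L), c(10L, 11L))) {
        i <- setdiff(seq_len(L), j)
        offs <- ifelse(i < j, i - 1L, i - 2L)
        v <- .variant_scores(mc[i], tc, e, offs, pen,
                             w = .core_weights(L, pen)[i])
        gp <- .gap_penalty(j, "mirna", pen)
        r10 <- if (j < 10L) 9L else 10L
        r11 <- if (j < 11L) 10L else 11L
        add(e - L + 2L, e, v$score + gp, ok1011(v$st, r10, r11),
            colSums(v$st == 1L), if (j < 10L) e - 8L else e - 9L,
            "mirna", j)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(), score = numeric(),
                      ok = logical(), n_gu = integer(), c_site = integer(),
                      gap_side = character(), gap_pos = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Find candidate miRNA target sites on a transcript
#'
#' Enumerates every gap-free antiparallel window exhaustively, plus variants
#' with at most one single-nucleotide bulge (transcript- or miRNA-side, never
#' between miRNA positions 10 and 11), and returns every site whose best
#' pairing scores at most `max_score` *and* pairs (Watson-Crick or G:U) at
#' miRNA positions 10 and 11 -- the "no mismatch at the cleavage site" rule.
#' For a given window `[start, end]` only the minimum-score pairing is kept
#' (ties broken toward fewer gaps, then fewer G:U pairs); all qualifying
#' windows are returned.
#'
#' @param mirna One-row [mirna_set()] slice, or a single sequence string.
#' @param transcript One-row [transcript_set()] slice, or a sequence string.
#' @param max_score Score gate (default 7).
#' @param penalties A [duplex_penalties()].
#' @param gaps Consider single-bulge variants (default `TRUE`).
#' @return `data.frame` of class `duplex_alignments`: `mirna`, `target`,
#'   `start`, `end`, `score`, `c_site`, `n_gaps`, `n_gu`, `gap_side`,
#'   `gap_pos`, sorted by `start`.
#' @export
find_candidate_sites <- function(mirna, transcript, max_score = 7,
                                 penalties = duplex_penalties(), gaps = TRUE) {
  mid <- if (is.data.frame(mirna)) mirna$id[1L] else NA_character_
  mseq <- if (is.data.frame(mirna)) mirna$seq[1L] else mirna
  tid <- if (is.data.frame(transcript)) transcript$id[1L] else NA_character_
  tseq <- if (is.data.frame(transcript)) transcript$seq[1L] else transcript
  mc <- .encode(mseq)
  tc <- .encode(tseq)
  empty <- data.frame(mirna = character(), target = character(),
                      start = integer(), end = integer(), score = numeric(),
                      c_site = integer(), n_gaps = integer(), n_gu = integer(),
                      gap_side = character(), gap_pos = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("duplex_alignments", "data.frame")
  if (length(tc) < length(mc)) {
    warning("transcript shorter than miRNA; no candidate sites")
    return(empty)
  }
  d <- .enumerate_duplexes(mc, tc, penalties, gaps = gaps)
  d <- d[d$ok & d$score <= max_score, , drop = FALSE]
  if (nrow(d) == 0L) return(empty)
  d$n_gaps <- ifelse(d$gap_side == "none", 0L, 1L)
  # best pairing per window [start, end]
  o <- order(d$start, d$end, d$score, d$n_gaps, d$n_gu, d$gap_pos,
             na.last = FALSE)
  d <- d[o, , drop = FALSE]
  d <- d[!duplicated(d[, c("start", "end")]), , drop = FALSE]
  res <- data.frame(mirna = mid, target = tid, start = d$start, end = d$end,
                    score = d$score, c_site = as.integer(d$c_site),
                    n_gaps = d$n_gaps, n_gu = as.integer(d$n_gu),
                    gap_side = d$gap_side, gap_pos = d$gap_pos,
                    stringsAsFactors = FALSE)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("duplex_alignments", "data.frame")
  res
}

#' Cleavage coordinate of a duplex alignment
#'
#' The transcript coordinate of the 5'-most nucleotide of the 3' cleavage
#' fragment: the base pairing miRNA nt 10.  Equals `end - 9` for gap-free
#' duplexes; bulges 5' of the cleavage point shift it accordingly.
#'
#' @param alignment Row(s) from [find_candidate_sites()].
#' @return Integer vector of 1-based transcript coordinates.
#' @export
cleavage_site <- function(alignment) {
  stopifnot(is.data.frame(alignment), "c_site" %in% names(alignment))
  as.integer(alignment$c_site)
}

# Best candidate score anchored at cleavage coordinates `pos` (vectorised):
# for each position, the minimum score over all duplex variants whose
# cleavage coordinate equals that position, subject to the positions-10/11
# pairing rule and transcript bounds.  `prune_above`: callers that only need
# scores <= prune_above may skip bulge variants when no bulge can beat it.
.anchored_scores <- function(mc, tc, pos, pen, gaps = TRUE,
                             prune_above = Inf) {
  L <- length(mc)
  tlen <- length(tc)
  best <- rep(Inf, length(pos))
  consider <- function(e, offs, r10, r11, extra, sub = seq_len(L)) {
    valid <- which(e - max(offs) >= 1L & e <= tlen)
    if (length(valid) == 0L) return()
    v <- .variant_scores(mc[sub], tc, e[valid], offs, pen,
                         w = .core_weights(L, pen)[sub])
    sc <- v$score + extra
    okp <- v$st[r10, ] != 2L & v$st[r11, ] != 2L
    sc[!okp] <- Inf
    best[valid] <<- pmin(best[valid], sc)
  }
  consider(pos + 9L, 0:(L - 1L), 10L, 11L, 0)
  if (gaps && prune_above >= pen$gap) {   # cheapest bulge costs pen$gap
    for (j in setdiff(seq_len(L - 1L), 10L)) {
      offs <- ifelse(seq_len(L) <= j, seq_len(L) - 1L, seq_len(L))
      e <- if (j >= 11L) pos + 9L else pos + 10L
      consider(e, offs, 10L, 11L, .gap_penalty(j, "transcript", pen))
    }
    if (L >= 4L) {
      for (j in setdiff(2:(L - 1L), c(10L, 11L))) {
        i <- setdiff(seq_len(L), j)
        offs <- ifelse(i < j, i - 1L, i - 2L)
        e <- if (j < 10L) pos + 8L else pos + 9L
        r10 <- if (j < 10L) 9L else 10L
        r11 <- if (j < 11L) 10L else 11L
        consider(e, offs, r10, r11, .gap_penalty(j, "mirna", pen), sub = i)
      }
    }
  }
  best
}
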