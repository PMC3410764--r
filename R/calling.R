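# Classification of cleavage signatures and end-to-end target calling.

#' Category evidence for one transcript profile
#'
#' Summary statistics of a transcript's signature profile used by the
#' category rules: the maximum raw count, the number of positions attaining
#' it, and the median raw count over positions carrying at least one read
#' (zero positions are excluded from the median -- including the overwhelming
#' zeros would make category 2 vacuous on any expressed transcript).
#'
#' @param counts Named integer vector, positions -> raw counts (all >= 1).
#' @return List with `max_count`, `n_max_positions`, `median_count`.
#' @export
category_evidence <- function(counts) {
  if (length(counts) == 0L)
    return(list(max_count = 0L, n_max_positions = 0L, median_count = 0))
  stopifnot(all(counts >= 1L))
  mx <- max(counts)
  list(max_count = mx, n_max_positions = sum(counts == mx),
       median_count = stats::median(counts))
}

#' Classify a cleavage site into categories 0--4
#'
#' CleaveLand-style rules, applied in this order:
#' category 4 if the site carries exactly 1 read ("very low abundance",
#' checked first so a 1-read signature never becomes category 0);
#' category 0 if the site count equals the transcript maximum and that
#' maximum is attained at a single position; category 1 if it equals a
#' maximum attained at more than one position; category 2 if it exceeds the
#' median (of positions with >= 1 read); category 3 otherwise (at or below
#' the median).  Sites with zero reads are not called (`NA` sentinel).
#'
#' @param site_count Raw count at the cleavage coordinate.
#' @param max_count,n_max_positions,median_count Evidence from
#'   [category_evidence()].
#' @return Integer in `0:4`, or `NA_integer_` when `site_count == 0`.
#' @export
classify_category <- function(site_count, max_count, n_max_positions,
                              median_count) {
  if (site_count == 0L) return(NA_integer_)
  stopifnot(site_count <= max_count, n_max_positions >= 1L)
  if (site_count == 1L) return(4L)
  if (site_count == max_count) {
    if (n_max_positions == 1L) return(0L) else return(1L)
  }
  if (site_count > median_count) return(2L)
  3L
}

#' Tags per 100 million mapped reads
#'
#' Library-size-normalised signature abundance:
#' `site_count * 1e8 / total_mapped`, where `total_mapped` is the number of
#' transcriptome-matched reads in the library.
#'
#' @param site_count Raw count at the site (>= 0).
#' @param total_mapped Transcriptome-matched reads in the library (>= 1).
#' @return Non-negative numeric.
#' @export
tp100m <- function(site_count, total_mapped) {
  if (any(total_mapped == 0)) stop("total_mapped must be >= 1")
  site_count * 1e8 / total_mapped
}

#' Locate a cleavage coordinate within the transcript model
#'
#' @param c_site 1-based transcript coordinate.
#' @param cds_start,cds_end 1-based inclusive CDS interval, or `NA` when the
#'   gene model carries no CDS annotation (many computationally predicted
#'   models are deficient at the UTRs; we report `"unknown"` rather than
#'   guess).
#' @return One of `"5'UTR"`, `"CDS"`, `"3'UTR"`, `"unknown"`.
#' @export
locate_region <- function(c_site, cds_start = NA, cds_end = NA) {
  if (is.na(cds_start) || is.na(cds_end)) return("unknown")
  if (c_site < cds_start) return("5'UTR")
  if (c_site <= cds_end) return("CDS")
  "3'UTR"
}

# Composition-preserving mononucleotide shuffle of a sequence string.
.shuffle_seq <- function(seq) {
  paste(sample(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Per-transcript evidence tables for a profile: covered positions, their
# counts and categories. Used by calling and by the shuffle null.
.profile_evidence <- function(profile) {
  split_counts <- split(profile$counts[, c("pos", "count")],
                        profile$counts$transcript)
  lapply(split_counts, function(d) {
    ev <- category_evidence(stats::setNames(d$count, d$pos))
    cat <- vapply(d$count, classify_category, integer(1),
                  max_count = ev$max_count,
                  n_max_positions = ev$n_max_positions,
                  median_count = ev$median_count)
    data.frame(pos = d$pos, count = d$count, category = cat)
  })
}

# Count, over shuffled miRNAs, how many achieve -- anywhere in the transcript
# set -- a candidate alignment with score <= s whose cleavage coordinate
# carries evidence of category <= cat. `shuffles` is a character vector of
# shuffled sequences; evidence is the output of .profile_evidence().
# Returns a matrix [shuffle x call] of logicals for calls given as (s, cat).
.shuffle_hits <- function(shuffles, tcodes, evidence, s_vec, cat_vec, pen,
                          gaps = TRUE) {
  n_calls <- length(s_vec)
  hit <- matrix(FALSE, length(shuffles), n_calls)
  prune <- max(s_vec)
  for (si in seq_along(shuffles)) {
    mc <- .encode(shuffles[[si]])
    remaining <- rep(TRUE, n_calls)
    for (tid in names(evidence)) {
      ev <- evidence[[tid]]
      sc <- .anchored_scores(mc, tcodes[[tid]], ev$pos, pen, gaps = gaps,
                             prune_above = prune)
      for (ci in which(remaining)) {
        if (any(sc <= s_vec[ci] & ev$category <= cat_vec[ci])) {
          hit[si, ci] <- TRUE
          remaining[ci] <- FALSE
        }
      }
      if (!any(remaining)) break
    }
  }
  hit
}

#' Empirical p-value for one target call
#'
#' Composition-preserving mononucleotide shuffles of the miRNA are re-scored
#' against the whole transcript set; `k` counts shuffles that achieve,
#' anywhere, a candidate alignment with score at most the observed score
#' whose cleavage coordinate carries degradome evidence of category at most
#' the observed category.  With the add-one correction,
#' `p = (1 + k) / (1 + n_shuffles)`, so `p >= 1/(n_shuffles + 1)` always.
#'
#' @param mirna One-row [mirna_set()] slice (or sequence string).
#' @param transcripts A [transcript_set()].
#' @param profile A `signature_profile` (see [build_profile()]).
#' @param observed A one-row `data.frame` with columns `score` and
#'   `category` (e.g. a row of [call_targets()] output).
#' @param n_shuffles Number of shuffles, at least 19.
#' @param seed Integer seed; the shuffle stream is fully reproducible.
#' @param penalties A [duplex_penalties()].
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(mirna, transcripts, profile, observed,
                             n_shuffles = 100L, seed,
                             penalties = duplex_penalties()) {
  if (n_shuffles < 19L) stop("n_shuffles must be >= 19")
  mseq <- if (is.data.frame(mirna)) mirna$seq[1L] else mirna
  mseq <- gsub("U", "T", toupper(mseq), fixed = TRUE)
  set.seed(seed)
  shuffles <- vapply(seq_len(n_shuffles), function(i) .shuffle_seq(mseq),
                     character(1))
  tcodes <- lapply(stats::setNames(transcripts$seq, transcripts$id), .encode)
  evidence <- .profile_evidence(profile)
  hit <- .shuffle_hits(shuffles, tcodes, evidence,
                       s_vec = observed$score[1L],
                       cat_vec = observed$category[1L], pen = penalties)
  (1 + sum(hit[, 1L])) / (1 + n_shuffles)
}

#' Call miRNA cleavage targets from signature profiles
#'
#' For each library, miRNA and transcript, candidate cleavage sites are the
#' duplex alignments passing the score gate and the cleavage-site pairing
#' rule whose cleavage coordinate carries at least one degradome read.  Each
#' such site yields one call with its category, TP100M, CDS/UTR location and
#' shuffle-null empirical p-value.  Multiple qualifying sites per transcript
#' are all reported; alignments sharing a cleavage coordinate are collapsed
#' to the best-scoring one.  No multiple-testing correction is applied.
#'
#' The candidate search here is anchored at read-covered positions, which is
#' exactly equivalent to intersecting the exhaustive [find_candidate_sites()]
#' enumeration with the evidence (calls require `site_count >= 1`) and keeps
#' large transcript sets fast.
#'
#' @param profiles A `signature_profile` or list of them (one per library).
#' @param mirnas A [mirna_set()].
#' @param transcripts A [transcript_set()] (CDS attached for locations).
#' @param max_score Duplex score gate (default 7).
#' @param n_shuffles Shuffles for the empirical p-value (default 100).
#' @param seed Integer seed driving the shuffle null.
#' @param penalties A [duplex_penalties()].
#' @param gaps Consider single-bulge duplex variants (default `TRUE`).
#' @return A [target_call_table()] sorted by (library, mirna, target, c_site).
#' @export
call_targets <- function(profiles, mirnas, transcripts, max_score = 7,
                         n_shuffles = 100L, seed = 1L,
                         penalties = duplex_penalties(), gaps = TRUE) {
  if (inherits(profiles, "signature_profile")) profiles <- list(profiles)
  stopifnot(inherits(mirnas, "mirna_set"),
            inherits(transcripts, "transcript_set"))
  if (n_shuffles < 19L) stop("n_shuffles must be >= 19")
  tcodes <- lapply(stats::setNames(transcripts$seq, transcripts$id), .encode)
  tmeta <- transcripts[, c("id", "cds_start", "cds_end")]
  rows <- list()
  for (profile in profiles) {
    if (profile$total_mapped == 0L) next
    evidence <- .profile_evidence(profile)
    evidence <- evidence[names(evidence) %in% transcripts$id]
    for (mi in seq_len(nrow(mirnas))) {
      mc <- .encode(mirnas$seq[mi])
      cand <- list()
      for (tid in names(evidence)) {
        ev <- evidence[[tid]]
        sc <- .anchored_scores(mc, tcodes[[tid]], ev$pos, penalties,
                               gaps = gaps)
        keep <- which(sc <= max_score)
        if (length(keep) == 0L) next
        cand[[tid]] <- data.frame(target = tid, c_site = ev$pos[keep],
                                  site_count = ev$count[keep],
                                  category = ev$category[keep],
                                  score = sc[keep], stringsAsFactors = FALSE)
      }
      if (length(cand) == 0L) next
      cand <- do.call(rbind, cand)
      # one deterministic shuffle stream per (library, miRNA)
      lib_seed <- (seed + 7919L * mi) %% .Machine$integer.max
      set.seed(lib_seed)
      shuffles <- vapply(seq_len(n_shuffles), function(i)
        .shuffle_seq(mirnas$seq[mi]), character(1))
      hit <- .shuffle_hits(shuffles, tcodes, evidence,
                           s_vec = cand$score, cat_vec = cand$category,
                           pen = penalties, gaps = gaps)
      k <- colSums(hit)
      m <- match(cand$target, tmeta$id)
      loc <- mapply(locate_region, cand$c_site,
                    tmeta$cds_start[m], tmeta$cds_end[m])
      rows[[length(rows) + 1L]] <- data.frame(
        library = profile$library, mirna = mirnas$id[mi],
        target = cand$target, c_site = cand$c_site, location = loc,
        category = cand$category,
        tp100m = tp100m(cand$site_count, profile$total_mapped),
        p_value = (1 + k) / (1 + n_shuffles),
        score = cand$score, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(target_call_table(data.frame(
      library = character(), mirna = character(), target = character(),
      c_site = integer(), location = character(), category = integer(),
      tp100m = numeric(), p_value = numeric(), score = numeric(),
      stringsAsFactors = FALSE)))
  target_call_table(do.call(rbind, rows))
}

#' Target-plot data for one transcript
#'
#' The full per-position signature series (every position with >= 1 read, in
#' increasing order) with the candidate cleavage site highlighted --
#' the data behind the published t-plots.
#'
#' @param profile A `signature_profile`.
#' @param transcript Transcript id.
#' @param c_site Candidate cleavage coordinate to highlight.
#' @return `data.frame` of class `tplot` with columns `pos`, `count`,
#'   `highlight`; attribute `zero_evidence` is `TRUE` when the highlighted
#'   site carries no reads.
#' @export
tplot_data <- function(profile, transcript, c_site) {
  stopifnot(inherits(profile, "signature_profile"))
  d <- profile$counts[profile$counts$transcript == transcript,
                      c("pos", "count"), drop = FALSE]
  d <- d[order(d$pos), , drop = FALSE]
  d$highlight <- d$pos == c_site
  rownames(d) <- NULL
  attr(d, "transcript") <- transcript
  attr(d, "c_site") <- as.integer(c_site)
  attr(d, "zero_evidence") <- !any(d$highlight)
  class(d) <- c("tplot", "data.frame")
  d
}

#' Plot a t-plot
#'
#' @param x A [tplot_data()] object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @method plot tplot
#' @export
plot.tplot <- function(x, ...) {
  graphics::plot(x$pos, x$count, type = "h",
                 xlab = "transcript position (nt)",
                 ylab = "signature abundance (raw reads)",
                 main = attr(x, "transcript"), ...)
  hl <- x[x$highlight, , drop = FALSE]
  if (nrow(hl) > 0L)
    graphics::points(hl$pos, hl$count, col = "red", pch = 17)
  else
    graphics::abline(v = attr(x, "c_site"), col = "red", lty = 2)
  invisible(x)
}
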