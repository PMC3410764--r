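# Read filtering and exact-match mapping onto transcripts.
#
# Degradome signatures are the 5' ends of 3' cleavage fragments; only exact
# sense-strand matches of the 20-21 nt tags onto transcript models count as
# evidence. Antisense matches are never cleavage evidence under this model.

#' Length- and quality-filter degradome reads
#'
#' Keeps reads whose length lies in `[min_len, max_len]` and whose mean
#' Phred quality is at least `min_mean_q`.  When a library carries no
#' qualities (FASTA input) the quality filter is skipped with a notice.
#'
#' @param library A [degradome_library()].
#' @param min_len,max_len Accepted read-length window (nt). Degradome
#'   protocols based on MmeI digestion yield 20-21 nt tags.
#' @param min_mean_q Minimum mean Phred score (Phred+33).
#' @return The library with filtered reads; attributes `total_input` and
#'   `total_len_selected` carry the accounting for the library report.
#' @export
filter_reads <- function(library, min_len = 20L, max_len = 21L,
                         min_mean_q = 20) {
  stopifnot(inherits(library, "degradome_library"))
  if (min_len > max_len) stop("min_len must be <= max_len")
  reads <- library$reads
  n_input <- nrow(reads)
  len <- nchar(reads$seq)
  keep <- len >= min_len & len <= max_len
  have_q <- !is.na(reads$qual)
  if (!all(have_q) && n_input > 0L)
    message("quality filter skipped for ", sum(!have_q),
            " read(s) without quality strings")
  mq <- rep(Inf, n_input)
  if (any(have_q))
    mq[have_q] <- vapply(reads$qual[have_q], function(q)
      mean(as.integer(charToRaw(q))) - 33, numeric(1), USE.NAMES = FALSE)
  keep <- keep & mq >= min_mean_q
  library$reads <- reads[keep, , drop = FALSE]
  rownames(library$reads) <- NULL
  attr(library, "total_input") <- n_input
  attr(library, "total_len_selected") <- sum(keep)
  library
}

# Collapse identical read sequences to (sequence, multiplicity). Mapping is
# then done once per distinct sequence and counts multiplied back, which
# reproduces per-position abundances exactly.
.collapse_distinct <- function(seqs) {
  tab <- table(seqs)
  data.frame(seq = names(tab), mult = as.integer(tab), stringsAsFactors = FALSE)
}

#' Build a per-transcript signature profile from filtered reads
#'
#' Every read contributes its multiplicity to `counts[transcript, position]`
#' for *every* transcript and position where it matches exactly on the sense
#' strand (multi-mapping reads count fully at every locus; the published
#' analysis reports all gene-family hits and resolves them downstream).
#' Reads containing `N` never match.  Matching uses a Biostrings
#' [Biostrings::PDict()] per read length; the contract -- every exact
#' sense-strand occurrence is found -- is property-tested against a naive
#' all-substring scan.
#'
#' @param library A filtered [degradome_library()] (see [filter_reads()]).
#' @param transcripts A [transcript_set()].
#' @return A `signature_profile`: list with `library`, `counts` (a
#'   `data.frame` `transcript`, `pos`, `count`), `total_mapped`,
#'   `total_input`, `total_len_selected`.
#' @export
build_profile <- function(library, transcripts) {
  stopifnot(inherits(library, "degradome_library"),
            inherits(transcripts, "transcript_set"))
  seqs <- library$reads$seq
  total_input <- attr(library, "total_input")
  if (is.null(total_input)) total_input <- length(seqs)
  total_sel <- attr(library, "total_len_selected")
  if (is.null(total_sel)) total_sel <- length(seqs)

  tset <- Biostrings::DNAStringSet(stats::setNames(transcripts$seq,
                                                   transcripts$id))
  hits <- list()
  total_mapped <- 0L
  if (length(seqs) > 0L) {
    dist <- .collapse_distinct(seqs)
    dist <- dist[!grepl("N", dist$seq, fixed = TRUE), , drop = FALSE]
    for (w in sort(unique(nchar(dist$seq)))) {
      dw <- dist[nchar(dist$seq) == w, , drop = FALSE]
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(dw$seq))
      matched <- logical(nrow(dw))
      for (j in seq_along(tset)) {
        mi <- Biostrings::matchPDict(pd, tset[[j]])
        st <- Biostrings::startIndex(mi)
        nz <- which(lengths(st) > 0L)
        if (length(nz) == 0L) next
        matched[nz] <- TRUE
        hits[[length(hits) + 1L]] <- data.frame(
          transcript = transcripts$id[j],
          pos = unlist(st[nz], use.names = FALSE),
          count = rep(dw$mult[nz], lengths(st[nz])),
          stringsAsFactors = FALSE)
      }
      total_mapped <- total_mapped + sum(dw$mult[matched])
    }
  }
  if (length(hits) > 0L) {
    h <- do.call(rbind, hits)
    agg <- stats::aggregate(count ~ transcript + pos, data = h, FUN = sum)
    agg <- agg[order(agg$transcript, agg$pos), , drop = FALSE]
    counts <- data.frame(transcript = agg$transcript, pos = as.integer(agg$pos),
                         count = as.integer(agg$count),
                         stringsAsFactors = FALSE)
  } else {
    counts <- data.frame(transcript = character(), pos = integer(),
                         count = integer(), stringsAsFactors = FALSE)
  }
  rownames(counts) <- NULL
  structure(list(library = library$name, tissue = library$tissue,
                 counts = counts,
                 total_mapped = total_mapped,
                 total_input = total_input,
                 total_len_selected = total_sel),
            class = "signature_profile")
}

#' Per-transcript position->count vector from a profile
#'
#' @param profile A `signature_profile`.
#' @param transcript Transcript id.
#' @return Named integer vector (names = 1-based positions), possibly empty.
#' @export
profile_counts <- function(profile, transcript) {
  stopifnot(inherits(profile, "signature_profile"))
  d <- profile$counts[profile$counts$transcript == transcript, , drop = FALSE]
  stats::setNames(d$count, d$pos)
}

#' Library accounting report
#'
#' One row per library in input order: raw reads, length/quality-selected
#' reads, transcriptome-matched reads. (Genome-matched counts are out of
#' scope: the pipeline maps to transcript models only.)
#'
#' @param profiles List of `signature_profile`s.
#' @return `data.frame` with columns `library`, `raw_reads`, `len_selected`,
#'   `transcriptome_matched`.
#' @export
library_report <- function(profiles) {
  if (length(profiles) == 0L) stop("need at least one profile")
  if (inherits(profiles, "signature_profile")) profiles <- list(profiles)
  data.frame(
    library = vapply(profiles, `[[`, "", "library"),
    raw_reads = vapply(profiles, function(p) as.integer(p$total_input),
                       integer(1)),
    len_selected = vapply(profiles, function(p)
      as.integer(p$total_len_selected), integer(1)),
    transcriptome_matched = vapply(profiles, function(p)
      as.integer(p$total_mapped), integer(1)),
    stringsAsFactors = FALSE)
}

#' Dump a signature profile as TSV
#'
#' @param profile A `signature_profile`.
#' @param path Output path; columns `transcript`, `pos`, `count`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "signature_profile"))
  write.table(profile$counts, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.signature_profile <- function(x, ...) {
  cat("signature profile '", x$library, "': ", x$total_mapped, "/",
      x$total_len_selected, "/", x$total_input,
      " mapped/selected/input reads, ", nrow(x$counts),
      " covered positions\n", sep = "")
  invisible(x)
}
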