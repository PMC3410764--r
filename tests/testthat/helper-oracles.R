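# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: character-by-character pairing,
# explicit per-position case analysis, gregexpr-based substring scans.

oracle_pair_state <- function(m, t) {
  # m: miRNA base, t: transcript base, both DNA chars
  wc <- (m == "A" && t == "T") || (m == "T" && t == "A") ||
        (m == "G" && t == "C") || (m == "C" && t == "G")
  if (wc) return("WC")
  if ((m == "G" && t == "T") || (m == "T" && t == "G")) return("GU")
  "MM"
}

# Brute-force scorer over a per-miRNA-position pairing-state vector.
oracle_score_pairing <- function(states) {
  s <- 0
  for (i in seq_along(states)) {
    pen <- switch(states[[i]], WC = 0, GU = 0.5, MM = 1, GAP = 1)
    if (i >= 2 && i <= 13) pen <- pen * 2
    s <- s + pen
  }
  s
}

# Exhaustive gap-free window scorer: every antiparallel window of the
# transcript, with the positions-10/11 pairing rule evaluated explicitly.
oracle_gapfree_sites <- function(mirna_seq, transcript_seq, max_score = 7) {
  mch <- strsplit(chartr("U", "T", toupper(mirna_seq)), "")[[1]]
  tch <- strsplit(toupper(transcript_seq), "")[[1]]
  L <- length(mch)
  rows <- list()
  if (length(tch) < L) return(NULL)
  for (e in L:length(tch)) {
    states <- character(L)
    for (i in 1:L) states[i] <- oracle_pair_state(mch[i], tch[e - i + 1])
    sc <- oracle_score_pairing(states)
    ok <- states[10] != "MM" && states[11] != "MM"
    if (ok && sc <= max_score)
      rows[[length(rows) + 1L]] <- data.frame(start = e - L + 1L, end = e,
                                              score = sc, c_site = e - 9L)
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# Naive all-substring occurrence scan of reads over transcripts.
oracle_occurrences <- function(read_seqs, transcript_ids, transcript_seqs) {
  rows <- list()
  for (r in seq_along(read_seqs)) {
    if (grepl("N", read_seqs[r], fixed = TRUE)) next
    for (j in seq_along(transcript_seqs)) {
      hit <- gregexpr(read_seqs[r], transcript_seqs[j], fixed = TRUE)[[1]]
      # gregexpr misses overlapping occurrences; rescan manually
      tl <- nchar(transcript_seqs[j]); w <- nchar(read_seqs[r])
      pos <- integer(0)
      if (tl >= w)
        for (p in 1:(tl - w + 1))
          if (substr(transcript_seqs[j], p, p + w - 1) == read_seqs[r])
            pos <- c(pos, p)
      if (length(pos) > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          read = r, transcript = transcript_ids[j], pos = pos)
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# Direct evaluation of the category rules on a full counts map.
oracle_category <- function(counts, site) {
  sc <- if (as.character(site) %in% names(counts))
    counts[[as.character(site)]] else 0L
  if (sc == 0L) return(NA_integer_)
  if (sc == 1L) return(4L)
  mx <- max(counts)
  if (sc == mx && sum(counts == mx) == 1L) return(0L)
  if (sc == mx) return(1L)
  if (sc > median(counts)) return(2L)
  3L
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Mutate one base of a sequence at `pos` to a base giving a mismatch against
# `against` (a miRNA base it would pair with).
mismatch_base <- function(mirna_base) {
  # a transcript base that is neither WC nor GU against mirna_base
  switch(mirna_base, A = "C", C = "C", G = "G", T = "T")
}

make_library <- function(seqs, qual = NULL, name = "lib",
                         tissue = "cotyledon") {
  reads <- data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs,
                      stringsAsFactors = FALSE)
  if (!is.null(qual)) reads$qual <- qual
  degradome_library(name, tissue, "test", reads)
}
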