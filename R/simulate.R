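# Seeded generator of degradome libraries with known planted cleavage
# events, plus packaged fixture tables.
#
# The signal model: a planted target embeds the exact reverse complement of
# its miRNA in a random transcript; Poisson(lambda_signal) 20-21 nt reads are
# emitted whose 5' ends sit at the canonical cleavage coordinate (the
# transcript base pairing miRNA nt 10, i.e. between the bases pairing nt 10
# and 11).  Background decay is uniform-position Poisson starts with no 5'
# bias.  Qualities are constant Q40; quality filtering is exercised
# separately with crafted low-quality reads.

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.random_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale degradome library: 10 transcripts of
#' 0.8--2 kb at soybean-transcript-like GC (0.42), three planted targets with
#' a mean of 50 signal reads each over a sparse uniform decay background
#' (0.01 expected background starts per transcript position), read lengths
#' 20/21 nt with equal weight (the protocol yields 20--21 nt tags; their
#' exact ratio is not modelled).
#'
#' @param n_transcripts Number of random transcripts.
#' @param transcript_len Length range `c(min, max)` in nt.
#' @param gc GC content of random transcripts.
#' @param n_planted Planted (miRNA, transcript) cleavage events; each planted
#'   miRNA is assigned its own transcript (the first `n_planted`).
#' @param lambda_signal Poisson mean of signal reads per planted site.
#' @param background_rate Poisson mean of background read starts per
#'   transcript position.
#' @param read_len_weights Named probabilities for read lengths 20 and 21;
#'   must sum to 1.
#' @param n_decoys Additional random miRNAs with no planted site.
#' @param mirna_len Length of generated miRNAs (nt).
#' @param planted Optional explicit plan: `data.frame(mirna, transcript,
#'   lambda_signal)` with optional `seq` column; overrides `n_planted`.
#' @param seed Integer seed; mandatory, the simulation is fully reproducible.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 10L, transcript_len = c(800L, 2000L),
                       gc = 0.42, n_planted = 3L, lambda_signal = 50,
                       background_rate = 0.01,
                       read_len_weights = c("20" = 0.5, "21" = 0.5),
                       n_decoys = 0L, mirna_len = 21L, planted = NULL,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_transcripts >= 1L, length(transcript_len) == 2L,
            transcript_len[1L] <= transcript_len[2L],
            gc > 0, gc < 1, lambda_signal >= 0, background_rate >= 0,
            abs(sum(read_len_weights) - 1) < 1e-9,
            identical(sort(names(read_len_weights)), c("20", "21")),
            n_decoys >= 0L, mirna_len >= 19L)
  structure(list(n_transcripts = as.integer(n_transcripts),
                 transcript_len = as.integer(transcript_len), gc = gc,
                 n_planted = as.integer(n_planted),
                 lambda_signal = lambda_signal,
                 background_rate = background_rate,
                 read_len_weights = read_len_weights,
                 n_decoys = as.integer(n_decoys),
                 mirna_len = as.integer(mirna_len),
                 planted = planted, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a degradome library with known ground truth
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes `reads.fastq`,
#'   `transcripts.fasta`, `mirnas.fasta` (RNA alphabet) and `truth.tsv`.
#' @param name,tissue,stage Library metadata for the returned
#'   [degradome_library()].
#' @return List: `library` (a `degradome_library`), `transcripts`
#'   (a [transcript_set()]), `mirnas` (a [mirna_set()], planted then decoys),
#'   `truth` (`data.frame` `mirna`, `transcript`, `site_start`, `site_end`,
#'   `c_site`, `n_signal_reads`).
#' @export
simulate_library <- function(config, dir = NULL, name = "sim",
                             tissue = "cotyledon", stage = "synthetic") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  max_len <- 21L

  tlen <- sample(config$transcript_len[1L]:config$transcript_len[2L],
                 config$n_transcripts, replace = TRUE)
  tid <- sprintf("tx%03d", seq_len(config$n_transcripts))
  tseq <- vapply(tlen, .random_seq, character(1), gc = config$gc)

  planted <- config$planted
  if (is.null(planted)) {
    n <- config$n_planted
    if (n > config$n_transcripts)
      stop("more planted targets than transcripts")
    planted <- data.frame(mirna = sprintf("sim-miR%02d", seq_len(n)),
                          transcript = tid[seq_len(n)],
                          lambda_signal = rep(config$lambda_signal, n),
                          stringsAsFactors = FALSE)
  }
  if (!"seq" %in% names(planted))
    planted$seq <- vapply(seq_len(nrow(planted)), function(i)
      .random_seq(config$mirna_len, 0.5), character(1))
  planted$seq <- gsub("U", "T", toupper(planted$seq), fixed = TRUE)

  truth <- list()
  reads <- list()
  for (i in seq_len(nrow(planted))) {
    ti <- match(planted$transcript[i], tid)
    if (is.na(ti)) stop("planted transcript not in set: ",
                        planted$transcript[i])
    L <- nchar(planted$seq[i])
    # the site must leave room for a 21-nt read starting at the cleavage
    # coordinate c = e - 9: need e <= tlen - (max_len - 10)
    e_max <- tlen[ti] - (max_len - 10L)
    if (e_max < L)
      stop("transcript ", tid[ti], " too short to plant a site for ",
           planted$mirna[i], " (21-nt reads could not be emitted)")
    e0 <- sample(L:e_max, 1L)
    s0 <- e0 - L + 1L
    site <- .revcomp(planted$seq[i])
    tseq[ti] <- paste0(substr(tseq[ti], 1L, s0 - 1L), site,
                       substr(tseq[ti], e0 + 1L, tlen[ti]))
    c_site <- e0 - 9L
    n_sig <- rpois(1L, planted$lambda_signal[i])
    if (n_sig > 0L) {
      lens <- sample(c(20L, 21L), n_sig, replace = TRUE,
                     prob = config$read_len_weights[c("20", "21")])
      reads[[length(reads) + 1L]] <- data.frame(
        id = sprintf("sig_%s_%d", planted$mirna[i], seq_len(n_sig)),
        seq = substring(tseq[ti], c_site, c_site + lens - 1L),
        stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(mirna = planted$mirna[i], transcript = tid[ti],
                             site_start = s0, site_end = e0, c_site = c_site,
                             n_signal_reads = n_sig, stringsAsFactors = FALSE)
  }
  # uniform decay background, truncated at the transcript 3' end (fragments
  # shorter than the accepted window are removed by the length filter)
  for (ti in seq_len(config$n_transcripts)) {
    n_bg <- rpois(1L, config$background_rate * tlen[ti])
    if (n_bg == 0L) next
    starts <- sample.int(tlen[ti], n_bg, replace = TRUE)
    lens <- sample(c(20L, 21L), n_bg, replace = TRUE,
                   prob = config$read_len_weights[c("20", "21")])
    ends <- pmin(starts + lens - 1L, tlen[ti])
    reads[[length(reads) + 1L]] <- data.frame(
      id = sprintf("bg_%s_%d", tid[ti], seq_len(n_bg)),
      seq = substring(tseq[ti], starts, ends), stringsAsFactors = FALSE)
  }
  reads <- if (length(reads) > 0L) do.call(rbind, reads)
           else data.frame(id = character(), seq = character(),
                           stringsAsFactors = FALSE)
  reads$qual <- strrep("I", nchar(reads$seq))   # constant Q40

  mirna_ids <- planted$mirna
  mirna_seqs <- planted$seq
  if (config$n_decoys > 0L) {
    mirna_ids <- c(mirna_ids,
                   sprintf("decoy-miR%02d", seq_len(config$n_decoys)))
    mirna_seqs <- c(mirna_seqs, vapply(seq_len(config$n_decoys), function(i)
      .random_seq(config$mirna_len, 0.5), character(1)))
  }
  keep <- !duplicated(mirna_ids)
  out <- list(
    library = degradome_library(name, tissue, stage, reads),
    transcripts = transcript_set(tid, tseq),
    mirnas = mirna_set(mirna_ids[keep], mirna_seqs[keep]),
    truth = do.call(rbind, truth))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fq <- file.path(dir, "reads.fastq")
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
               fq)
    writeLines(paste0(">", tid, "\n", tseq), file.path(dir, "transcripts.fasta"))
    writeLines(paste0(">", mirna_ids[keep], "\n",
                      gsub("T", "U", mirna_seqs[keep], fixed = TRUE)),
               file.path(dir, "mirnas.fasta"))
    write.table(out$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Load a packaged fixture table
#'
#' Transcriptions of the published tissue-specific target tables and the
#' annotation-comparison table, shipped as plain-text TSV under `extdata`.
#' `"table3"`/`"table4"` return target-call-shaped records (cotyledon-only
#' and seed-coat-only targets respectively); `"table5"` returns the three
#' annotation lists as `list(williams_only, heinong_only, common)`.
#'
#' @param name One of `"table3"`, `"table4"`, `"table5"`.
#' @return A `data.frame` (table3/table4) or list of character vectors
#'   (table5).
#' @export
load_fixture <- function(name = c("table3", "table4", "table5")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "degradomeR",
                      mustWork = TRUE)
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (name == "table5")
    return(split(d$annotation, factor(d$set, levels = c("williams_only",
                                                        "heinong_only",
                                                        "common")))[
      c("williams_only", "heinong_only", "common")])
  names(d) <- c("mirna", "library", "target", "annotation", "c_site",
                "location", "category", "tp100m", "p_value")
  d$location <- sub("' ", "'", d$location, fixed = TRUE)  # "5' UTR" -> "5'UTR"
  d
}
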