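#' @importFrom stats median rpois
#' @importFrom utils read.delim write.table
NULL

# Canonical call-table column order (the published target-table schema,
# minus the free-text annotation column).
.CALL_COLS <- c("miRNA", "Tissue", "Target", "C.Site", "Location",
                "Category", "TP100M", "P.Value")

.LOCATIONS <- c("5'UTR", "CDS", "3'UTR", "unknown")

#' Read a FASTA file of sequence records
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' package's sequence conventions: records are uppercased, the alphabet is
#' normalized (`U -> T` when reading as DNA, `T -> U` when reading as RNA),
#' and duplicate record ids are a hard error.  Everything downstream of the
#' readers works on the DNA alphabet; mature miRNAs read as RNA are converted
#' at construction time (see [mirna_set()]).
#'
#' @param path Path to a FASTA file. Line wrapping and case are irrelevant.
#' @param alphabet `"dna"` or `"rna"`; controls U/T normalization.
#' @return A `data.frame` with columns `id` and `seq`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- if (alphabet == "dna") gsub("U", "T", seqs, fixed = TRUE)
          else gsub("T", "U", seqs, fixed = TRUE)
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Construct and validate a transcript set
#'
#' @param id Character vector of unique transcript ids.
#' @param seq Character vector of sequences over `A,C,G,T,N` (uppercased and
#'   `U -> T` normalized here).
#' @param cds_start,cds_end Optional 1-based inclusive CDS interval per
#'   transcript (`NA` when unknown).
#' @param annotation Optional free-text annotation per transcript.
#' @return A `data.frame` of class `transcript_set`.
#' @export
transcript_set <- function(id, seq, cds_start = NA_integer_,
                           cds_end = NA_integer_, annotation = NA_character_) {
  if (length(id) == 0L) stop("transcript set must contain at least one record")
  if (anyDuplicated(id)) stop("duplicate transcript id(s): ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  if (any(!nzchar(id))) stop("transcript ids must be nonempty")
  if (any(nchar(seq) < 1L)) stop("transcript sequences must be nonempty")
  if (any(grepl("[^ACGTN]", seq)))
    stop("transcript sequences contain characters outside {A,C,G,T,N}")
  x <- data.frame(id = id, seq = seq,
                  cds_start = as.integer(cds_start),
                  cds_end = as.integer(cds_end),
                  annotation = as.character(annotation),
                  stringsAsFactors = FALSE)
  has_cds <- !is.na(x$cds_start) | !is.na(x$cds_end)
  bad <- has_cds & (is.na(x$cds_start) | is.na(x$cds_end) |
                    x$cds_start < 1L | x$cds_start > x$cds_end |
                    x$cds_end > nchar(x$seq))
  if (any(bad))
    stop("invalid CDS interval for: ", paste(x$id[bad], collapse = ", "))
  class(x) <- c("transcript_set", "data.frame")
  x
}

#' Construct and validate a mature miRNA set
#'
#' Sequences are stored internally on the DNA alphabet (`U -> T`), matching
#' the transcript alphabet so that complementarity checks need a single
#' pairing table.  Lengths outside the typical mature-miRNA range 19--24 nt
#' raise a warning, not an error.
#'
#' @param id Character vector of unique miRNA ids (e.g. `"gma-miR160"`).
#' @param seq Mature sequences 5'->3', RNA or DNA alphabet.
#' @return A `data.frame` of class `mirna_set` with DNA-alphabet `seq`.
#' @export
mirna_set <- function(id, seq) {
  if (length(id) == 0L) stop("miRNA set must contain at least one record")
  if (anyDuplicated(id)) stop("duplicate miRNA id(s): ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  if (any(grepl("[^ACGT]", seq)))
    stop("miRNA sequences contain characters outside {A,C,G,U}")
  n <- nchar(seq)
  if (any(n < 19L | n > 24L))
    warning("miRNA length outside 19-24 nt for: ",
            paste(id[n < 19L | n > 24L], collapse = ", "))
  x <- data.frame(id = id, seq = seq, stringsAsFactors = FALSE)
  class(x) <- c("mirna_set", "data.frame")
  x
}

#' Read per-transcript CDS coordinates
#'
#' Accepts either a headerless 3-column tab-delimited table
#' (`id  start  end`, 1-based inclusive) or a GFF3 file, detected from the
#' `##gff-version` pragma or a `.gff`/`.gff3` extension.  GFF3 `CDS` features
#' are assumed to be in transcript coordinates (seqid = transcript id) and
#' are collapsed per seqid to `[min(start), max(end)]`.
#'
#' @param path Path to the table or GFF3 file.
#' @return A `data.frame` with columns `id`, `start`, `end`.
#' @export
read_cds_table <- function(path) {
  if (!file.exists(path)) stop("CDS file not found: ", path)
  first <- readLines(path, n = 1L)
  is_gff <- grepl("^##gff-version", first) ||
    grepl("\\.gff3?$", path, ignore.case = TRUE)
  if (is_gff) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(f, function(x) length(x) >= 8L && x[3] == "CDS", logical(1))
    f <- f[keep]
    if (length(f) == 0L) stop("no CDS features in GFF3 file: ", path)
    df <- data.frame(id = vapply(f, `[`, "", 1L),
                     start = as.integer(vapply(f, `[`, "", 4L)),
                     end = as.integer(vapply(f, `[`, "", 5L)),
                     stringsAsFactors = FALSE)
    if (anyNA(df$start) || anyNA(df$end))
      stop("non-integer CDS coordinates in: ", path)
    out <- do.call(rbind, lapply(split(df, df$id), function(d)
      data.frame(id = d$id[1L], start = min(d$start), end = max(d$end),
                 stringsAsFactors = FALSE)))
    rownames(out) <- NULL
  } else {
    raw <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "character"))
    if (ncol(raw) < 3L) stop("CDS table needs 3 tab-delimited columns")
    start <- suppressWarnings(as.integer(raw[[2L]]))
    end <- suppressWarnings(as.integer(raw[[3L]]))
    if (anyNA(start) || anyNA(end))
      stop("non-integer CDS coordinates in: ", path)
    out <- data.frame(id = raw[[1L]], start = start, end = end,
                      stringsAsFactors = FALSE)
  }
  bad <- out$start > out$end
  if (any(bad))
    stop("CDS start > end for: ", paste(out$id[bad], collapse = ", "))
  out
}

#' Attach CDS intervals to a transcript set
#'
#' Intervals for ids absent from the transcript set are retained in the CDS
#' table sense but flagged with a warning; transcripts without an interval
#' keep `NA` (their cleavage-site locations become `"unknown"`).
#'
#' @param transcripts A [transcript_set()].
#' @param cds A `data.frame` from [read_cds_table()].
#' @return The transcript set with `cds_start`/`cds_end` filled in.
#' @export
attach_cds <- function(transcripts, cds) {
  stopifnot(inherits(transcripts, "transcript_set"))
  unknown <- setdiff(cds$id, transcripts$id)
  if (length(unknown) > 0L)
    warning("CDS intervals for unknown transcript id(s): ",
            paste(unknown, collapse = ", "))
  m <- match(transcripts$id, cds$id)
  transcripts$cds_start <- cds$start[m]
  transcripts$cds_end <- cds$end[m]
  over <- !is.na(transcripts$cds_end) &
    transcripts$cds_end > nchar(transcripts$seq)
  if (any(over))
    stop("CDS interval exceeds transcript length for: ",
         paste(transcripts$id[over], collapse = ", "))
  transcripts
}

#' Construct a degradome sequencing library
#'
#' Tissue and stage are explicit metadata, never guessed from the library
#' name: the published library names (`Cot25`, `SC100`, ...) encode both but
#' the pipeline treats them as opaque labels.
#'
#' @param name Library name, unique per run.
#' @param tissue `"cotyledon"` or `"seed_coat"`.
#' @param stage Free-text developmental stage (e.g. `"100-200 mg"`).
#' @param reads `data.frame` with columns `id`, `seq` and optionally `qual`
#'   (Phred+33 strings, same lengths as `seq`).
#' @return A list of class `degradome_library`.
#' @export
degradome_library <- function(name, tissue = c("cotyledon", "seed_coat"),
                              stage = "", reads) {
  tissue <- match.arg(tissue)
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  if (!nzchar(name)) stop("library name must be nonempty")
  reads$seq <- gsub("U", "T", toupper(reads$seq), fixed = TRUE)
  if (!"qual" %in% names(reads))
    reads$qual <- rep(NA_character_, nrow(reads))
  bad <- !is.na(reads$qual) & nchar(reads$qual) != nchar(reads$seq)
  if (any(bad)) stop("quality string length mismatch for ",
                     sum(bad), " read(s)")
  structure(list(name = name, tissue = tissue, stage = stage, reads = reads),
            class = "degradome_library")
}

#' Read degradome reads from FASTQ or FASTA into a library
#'
#' @param path FASTQ (Phred+33) or FASTA file; format detected from the first
#'   record character.
#' @inheritParams degradome_library
#' @return A `degradome_library`.
#' @export
read_library <- function(path, name, tissue = c("cotyledon", "seed_coat"),
                         stage = "") {
  if (!file.exists(path)) stop("reads file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "@")) {
    # Biostrings warns about dropping its own metadata columns here; benign
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    reads <- data.frame(id = sub("\\s.*$", "", names(x)),
                        seq = as.character(x),
                        qual = as.character(Biostrings::quality(x)),
                        stringsAsFactors = FALSE)
  } else {
    fa <- read_fasta(path, alphabet = "dna")
    reads <- data.frame(id = fa$id, seq = fa$seq, qual = NA_character_,
                        stringsAsFactors = FALSE)
  }
  rownames(reads) <- NULL
  degradome_library(name, match.arg(tissue), stage, reads)
}

#' Validate a table of target calls
#'
#' @param calls `data.frame` with columns `library`, `mirna`, `target`,
#'   `c_site`, `location`, `category`, `tp100m`, `p_value` and optionally
#'   `score`.
#' @return The validated `data.frame`, class `target_call_table`, sorted by
#'   (library, mirna, target, c_site).
#' @export
target_call_table <- function(calls) {
  need <- c("library", "mirna", "target", "c_site", "location",
            "category", "tp100m", "p_value")
  miss <- setdiff(need, names(calls))
  if (length(miss) > 0L)
    stop("missing call column(s): ", paste(miss, collapse = ", "))
  if (!"score" %in% names(calls)) calls$score <- rep(NA_real_, nrow(calls))
  calls$c_site <- as.integer(calls$c_site)
  calls$category <- as.integer(calls$category)
  if (nrow(calls) > 0L) {
    stopifnot(all(calls$category %in% 0:4),
              all(calls$tp100m >= 0),
              all(calls$p_value > 0 & calls$p_value <= 1),
              all(calls$c_site >= 1L),
              all(calls$location %in% .LOCATIONS))
    o <- order(calls$library, calls$mirna, calls$target, calls$c_site)
    calls <- calls[o, , drop = FALSE]
  }
  rownames(calls) <- NULL
  class(calls) <- c("target_call_table", "data.frame")
  calls
}

#' Write target calls as a TSV in the published table schema
#'
#' Columns, in order: `miRNA`, `Tissue`, `Target`, `C.Site`, `Location`,
#' `Category`, `TP100M`, `P-Value`.  The `Tissue` column carries the library
#' name, as in the published tables.  Rows are sorted by
#' (library, mirna, target, c_site); TP100M is printed with at least four
#' significant digits.
#'
#' @param calls A [target_call_table()] (or coercible `data.frame`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path) {
  calls <- target_call_table(as.data.frame(calls))
  out <- data.frame(calls$mirna, calls$library, calls$target, calls$c_site,
                    calls$location, calls$category,
                    vapply(calls$tp100m, function(x) format(x, digits = 10),
                           character(1)),
                    vapply(calls$p_value, function(x) format(x, digits = 10),
                           character(1)),
                    stringsAsFactors = FALSE)
  names(out) <- c("miRNA", "Tissue", "Target", "C.Site", "Location",
                  "Category", "TP100M", "P-Value")
  if (nrow(out) == 0L)
    out <- out[0L, , drop = FALSE]
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write call table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a target-call TSV written by [write_call_table()]
#'
#' @param path Path to the TSV.
#' @return A `target_call_table`.
#' @export
read_call_table <- function(path) {
  if (!file.exists(path)) stop("call table not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(raw), c("miRNA", "Tissue", "Target", "C.Site",
                               "Location", "Category", "TP100M", "P-Value")))
    stop("unexpected call-table header in ", path)
  target_call_table(data.frame(
    library = as.character(raw$Tissue), mirna = as.character(raw$miRNA),
    target = as.character(raw$Target), c_site = raw[["C.Site"]],
    location = as.character(raw$Location), category = raw$Category,
    tp100m = as.numeric(raw$TP100M), p_value = as.numeric(raw[["P-Value"]]),
    stringsAsFactors = FALSE))
}

#' @export
print.degradome_library <- function(x, ...) {
  cat("degradome library '", x$name, "' (", x$tissue, ", ", x$stage, "): ",
      nrow(x$reads), " reads\n", sep = "")
  invisible(x)
}
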