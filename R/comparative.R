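# Cross-library set logic: tissue partition of called (miRNA, target) pairs
# and annotation-group comparison between two datasets.

#' Partition target calls by tissue
#'
#' Distinct (miRNA, target-transcript) pairs are assigned to one of three
#' disjoint compartments: `shared` (called in at least one cotyledon *and*
#' one seed-coat library), `cotyledon_only`, `seedcoat_only`.  Developmental
#' stages are pooled within a tissue, mirroring the published tissue tables.
#' Targets are compared on full transcript ids (isoform suffix included --
#' the published tables list `.1/.2/.3` isoforms as distinct targets).
#' miRNA-level sets are computed the same way on distinct miRNA ids.
#'
#' @param calls A [target_call_table()] (or data.frame with `library`,
#'   `mirna`, `target`).
#' @param library_meta Named character vector mapping library name ->
#'   `"cotyledon"` or `"seed_coat"`.
#' @return A list of class `tissue_partition`: data.frames `shared`,
#'   `cotyledon_only`, `seedcoat_only` (columns `mirna`, `target`,
#'   `libraries`); character vectors `mirna_shared`, `mirna_cotyledon_only`,
#'   `mirna_seedcoat_only`; and a `counts` summary.
#' @export
partition_by_tissue <- function(calls, library_meta) {
  stopifnot(is.data.frame(calls),
            all(c("library", "mirna", "target") %in% names(calls)))
  unknown <- setdiff(unique(calls$library), names(library_meta))
  if (length(unknown) > 0L)
    stop("library name(s) missing from metadata: ",
         paste(unknown, collapse = ", "))
  if (!all(library_meta %in% c("cotyledon", "seed_coat")))
    stop("tissue must be 'cotyledon' or 'seed_coat'")
  tissue <- unname(library_meta[calls$library])

  pair_key <- paste(calls$mirna, calls$target, sep = "\r")
  pair_df <- function(keys) {
    if (length(keys) == 0L)
      return(data.frame(mirna = character(), target = character(),
                        libraries = character(), stringsAsFactors = FALSE))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    libs <- vapply(keys, function(k)
      paste(sort(unique(calls$library[pair_key == k])), collapse = ","),
      character(1), USE.NAMES = FALSE)
    d <- data.frame(mirna = vapply(parts, `[`, "", 1L),
                    target = vapply(parts, `[`, "", 2L),
                    libraries = libs, stringsAsFactors = FALSE)
    d <- d[order(d$mirna, d$target), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  in_cot <- unique(pair_key[tissue == "cotyledon"])
  in_sc <- unique(pair_key[tissue == "seed_coat"])
  shared_k <- intersect(in_cot, in_sc)
  cot_k <- setdiff(in_cot, in_sc)
  sc_k <- setdiff(in_sc, in_cot)

  mir_cot <- unique(calls$mirna[tissue == "cotyledon"])
  mir_sc <- unique(calls$mirna[tissue == "seed_coat"])
  res <- list(
    shared = pair_df(shared_k),
    cotyledon_only = pair_df(cot_k),
    seedcoat_only = pair_df(sc_k),
    mirna_shared = sort(intersect(mir_cot, mir_sc)),
    mirna_cotyledon_only = sort(setdiff(mir_cot, mir_sc)),
    mirna_seedcoat_only = sort(setdiff(mir_sc, mir_cot)))
  res$counts <- data.frame(
    compartment = c("shared", "cotyledon_only", "seedcoat_only"),
    pairs = c(length(shared_k), length(cot_k), length(sc_k)),
    targets = c(length(unique(res$shared$target)),
                length(unique(res$cotyledon_only$target)),
                length(unique(res$seedcoat_only$target))),
    mirnas = c(length(res$mirna_shared), length(res$mirna_cotyledon_only),
               length(res$mirna_seedcoat_only)),
    stringsAsFactors = FALSE)
  class(res) <- "tissue_partition"
  res
}

#' @export
print.tissue_partition <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

# Annotation strings are free text typed by humans; comparisons are done on a
# normalized form (lowercase, collapsed whitespace, trailing punctuation
# stripped) while original spellings are preserved in the output.
.normalize_annotation <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  sub("[[:punct:]]+$", "", x)
}

#' Compare two sets of target-annotation groups
#'
#' Standard set difference/intersection on normalized annotation strings;
#' the original spelling (first occurrence within each input) is preserved.
#'
#' @param set_a,set_b Character vectors of annotation strings.
#' @return List with character vectors `only_a`, `common`, `only_b` and a
#'   `counts` vector.  `length(only_a) + length(common) == `number of
#'   distinct normalized annotations in `set_a` (and symmetrically for b).
#' @export
compare_annotation_sets <- function(set_a, set_b) {
  na_ <- .normalize_annotation(set_a)
  nb <- .normalize_annotation(set_b)
  first_of <- function(orig, norm) orig[!duplicated(norm)]
  ua <- first_of(set_a, na_); una <- unique(na_)
  ub <- first_of(set_b, nb); unb <- unique(nb)
  common_n <- intersect(una, unb)
  res <- list(only_a = ua[!una %in% unb],
              common = ua[una %in% common_n],
              only_b = ub[!unb %in% una])
  res$counts <- c(only_a = length(res$only_a), common = length(res$common),
                  only_b = length(res$only_b))
  res
}
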