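make_profile <- function(counts_by_tx, total_mapped = NULL, name = "lib") {
  counts <- do.call(rbind, lapply(names(counts_by_tx), function(tx) {
    v <- counts_by_tx[[tx]]
    data.frame(transcript = tx, pos = as.integer(names(v)),
               count = as.integer(v), stringsAsFactors = FALSE)
  }))
  if (is.null(total_mapped)) total_mapped <- sum(counts$count)
  structure(list(library = name, tissue = "cotyledon", counts = counts,
                 total_mapped = total_mapped, total_input = total_mapped,
                 total_len_selected = total_mapped),
            class = "signature_profile")
}

test_that("category rules hit each class, with 1-read overriding a maximum", {
  ev <- function(v) category_evidence(v)
  # unique maximum at the site -> 0
  e <- ev(c(`112` = 50, `300` = 5, `500` = 2))
  expect_equal(classify_category(50, e$max_count, e$n_max_positions,
                                 e$median_count), 0L)
  # tied maximum -> 1
  e <- ev(c(`112` = 50, `300` = 50, `500` = 2))
  expect_equal(classify_category(50, e$max_count, e$n_max_positions,
                                 e$median_count), 1L)
  # above the median but below the maximum -> 2 (median of {10,3,1,1} = 2)
  e <- ev(c(`112` = 3, `300` = 10, `500` = 1, `700` = 1))
  expect_equal(e$median_count, 2)
  expect_equal(classify_category(3, e$max_count, e$n_max_positions,
                                 e$median_count), 2L)
  # at or below the median -> 3
  e <- ev(c(`112` = 2, `300` = 10, `500` = 2, `700` = 2))
  expect_equal(classify_category(2, e$max_count, e$n_max_positions,
                                 e$median_count), 3L)
  # a single read is category 4 even when it is the transcript maximum
  e <- ev(c(`112` = 1))
  expect_equal(classify_category(1, e$max_count, e$n_max_positions,
                                 e$median_count), 4L)
  # zero evidence is a no-call sentinel, not a category
  expect_true(is.na(classify_category(0, 10, 1, 2)))
})

test_that("classifier matches brute-force rule evaluation on 10,000 instances", {
  set.seed(31)
  for (i in 1:10000) {
    n_pos <- sample(1:8, 1)
    counts <- sample(1:12, n_pos, replace = TRUE)
    names(counts) <- sort(sample(1:500, n_pos))
    site <- as.integer(sample(names(counts), 1))
    e <- category_evidence(counts)
    got <- classify_category(counts[[as.character(site)]], e$max_count,
                             e$n_max_positions, e$median_count)
    expect_identical(got, oracle_category(counts, site))
  }
})

test_that("every called state receives exactly one category in 0..4", {
  set.seed(32)
  for (i in 1:500) {
    counts <- sample(1:6, sample(1:6, 1), replace = TRUE)
    names(counts) <- seq_along(counts) * 10L
    e <- category_evidence(counts)
    cats <- vapply(counts, classify_category, integer(1), max_count = e$max_count,
                   n_max_positions = e$n_max_positions,
                   median_count = e$median_count)
    expect_true(all(cats %in% 0:4))
    # category 0 only at a unique maximum
    if (any(cats == 0L)) {
      expect_equal(sum(cats == 0L), 1L)
      expect_equal(sum(counts == max(counts)), 1L)
    }
  }
})

test_that("tp100m arithmetic and linearity", {
  expect_equal(tp100m(5, 1e7), 50)
  expect_equal(tp100m(0, 123), 0)
  expect_equal(tp100m(7, 7), 1e8)
  expect_error(tp100m(1, 0), "total_mapped")
  expect_equal(tp100m(6, 2e7), tp100m(3, 1e7))       # joint doubling invariant
  expect_equal(tp100m(6, 1e7), 2 * tp100m(3, 1e7))   # site-only doubling
})

test_that("locate_region maps coordinates to 5'UTR/CDS/3'UTR/unknown", {
  expect_equal(locate_region(50, 101, 400), "5'UTR")
  expect_equal(locate_region(101, 101, 400), "CDS")
  expect_equal(locate_region(250, 101, 400), "CDS")
  expect_equal(locate_region(400, 101, 400), "CDS")
  expect_equal(locate_region(450, 101, 400), "3'UTR")
  expect_equal(locate_region(250, NA, NA), "unknown")
})

test_that("tplot_data returns the full ordered series with highlight flags", {
  prof <- make_profile(list(t1 = c(`300` = 5, `112` = 50)))
  tp <- tplot_data(prof, "t1", 112L)
  expect_equal(tp$pos, c(112L, 300L))
  expect_equal(tp$count, c(50L, 5L))
  expect_equal(tp$highlight, c(TRUE, FALSE))
  expect_false(attr(tp, "zero_evidence"))
  # site with no reads, transcript covered elsewhere
  tp2 <- tplot_data(prof, "t1", 200L)
  expect_true(attr(tp2, "zero_evidence"))
  # empty profile
  tp3 <- tplot_data(make_profile(list(t1 = c(`5` = 1))), "t2", 10L)
  expect_equal(nrow(tp3), 0L)
  expect_true(attr(tp3, "zero_evidence"))
})

test_that("empirical_pvalue respects the pseudocount bound and preconditions", {
  set.seed(33)
  mdna <- random_dna(21)
  tx <- paste0(random_dna(60), revcomp_chr(mdna), random_dna(60))
  ts <- transcript_set("t1", tx)
  prof <- make_profile(list(t1 = c(`72` = 40, `10` = 2)))  # c_site = 61+21-1-9
  mi <- mirna_set("m1", mdna)
  obs <- data.frame(score = 0, category = 0L)
  p <- empirical_pvalue(mi, ts, prof, obs, n_shuffles = 50, seed = 5)
  expect_gte(p, 1 / 51)
  expect_lte(p, 1)
  expect_error(empirical_pvalue(mi, ts, prof, obs, n_shuffles = 10, seed = 5),
               "19")
  # reproducible given seed
  p2 <- empirical_pvalue(mi, ts, prof, obs, n_shuffles = 50, seed = 5)
  expect_identical(p, p2)
})

test_that("planted perfect target gets p <= 0.1 in >= 95% of seeds", {
  set.seed(34)
  mdna <- random_dna(21)
  tx <- paste0(random_dna(60), revcomp_chr(mdna), random_dna(120))
  ts <- transcript_set("t1", tx)
  prof <- make_profile(list(t1 = stats::setNames(
    c(40, 2, 1), c(61 + 20 - 9, 10, 150))))
  mi <- mirna_set("m1", mdna)
  obs <- data.frame(score = 0, category = 0L)
  ps <- vapply(1:20, function(s)
    empirical_pvalue(mi, ts, prof, obs, n_shuffles = 50, seed = s),
    numeric(1))
  expect_gte(mean(ps <= 0.1), 0.95)
})

test_that("call_targets on a zero-noise planted scenario is forced", {
  cfg <- sim_config(n_transcripts = 4, transcript_len = c(400, 700),
                    n_planted = 1, lambda_signal = 50, background_rate = 0,
                    seed = 35)
  sim <- simulate_library(cfg)
  prof <- build_profile(filter_reads(sim$library), sim$transcripts)
  calls <- call_targets(prof, sim$mirnas, sim$transcripts, n_shuffles = 20,
                        seed = 1)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$category, 0L)
  expect_equal(calls$c_site, sim$truth$c_site)
  expect_equal(calls$score, 0)
  expect_equal(calls$location, "unknown")  # no CDS supplied
  # same scenario, miRNA absent from the input set -> zero calls
  other <- mirna_set("other", random_dna(21))
  expect_equal(nrow(call_targets(prof, other, sim$transcripts,
                                 n_shuffles = 20, seed = 1)), 0L)
})

test_that("two libraries sharing a planted target give identical call keys", {
  cfg <- sim_config(n_transcripts = 3, transcript_len = c(400, 600),
                    n_planted = 1, lambda_signal = 30, background_rate = 0,
                    seed = 36)
  sim <- simulate_library(cfg, name = "A")
  # a second library over the same transcripts: re-emit signal reads
  libB <- sim$library
  libB$name <- "B"
  profs <- list(build_profile(filter_reads(sim$library), sim$transcripts),
                build_profile(filter_reads(libB), sim$transcripts))
  calls <- call_targets(profs, sim$mirnas, sim$transcripts, n_shuffles = 20,
                        seed = 2)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$mirna[1], calls$mirna[2])
  expect_equal(calls$target[1], calls$target[2])
  expect_equal(calls$c_site[1], calls$c_site[2])
  expect_setequal(calls$library, c("A", "B"))
})

test_that("anchored calling equals exhaustive search intersected with evidence", {
  set.seed(37)
  for (rep in 1:3) {
    mdna <- random_dna(21)
    # degenerate planted site (one core mismatch) + noise evidence
    site <- revcomp_chr(mdna)
    substr(site, 17, 17) <- mismatch_base(substr(mdna, 5, 5))
    tx <- paste0(random_dna(50), site, random_dna(100))
    ts <- transcript_set("t1", tx)
    covered <- sort(sample(150, 12))
    cnt <- stats::setNames(sample(1:9, 12, replace = TRUE), covered)
    cs <- 50L + 21L - 9L   # site end 71, c_site 62
    cnt[as.character(cs)] <- 30L
    prof <- make_profile(list(t1 = cnt))
    mi <- mirna_set("m", mdna)
    calls <- call_targets(prof, mi, ts, max_score = 7, n_shuffles = 20,
                          seed = 1, gaps = FALSE)
    full <- find_candidate_sites(mdna, tx, max_score = 7, gaps = FALSE)
    expected_sites <- intersect(unique(full$c_site), as.integer(names(cnt)))
    expect_setequal(calls$c_site, expected_sites)
    if (cs %in% calls$c_site) {
      best <- min(full$score[full$c_site == cs])
      expect_equal(calls$score[calls$c_site == cs], best)
    }
  }
})
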