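mk_reads <- function(...) {
  rows <- list(...)
  do.call(paris_reads, do.call(rbind, lapply(rows, function(r)
    data.frame(read_id = r[[1]], barcode = r[[2]], quality = as.integer(r[[3]]),
               arm1_start = as.integer(r[[4]]), arm1_end = as.integer(r[[5]]),
               arm2_start = as.integer(r[[6]]), arm2_end = as.integer(r[[7]])))))
}

test_that("read filtering enforces the quality floor and transcript bounds", {
  reads <- mk_reads(
    list("r1", "b1", 29, 10, 20, 50, 60),   # below Q30
    list("r2", "b2", 30, 10, 20, 50, 60),   # at the floor: kept
    list("r3", "b3", 35, 10, 20, 50, 120),  # arm2 beyond transcript
    list("r4", "b4", 35, 25, 15, 50, 60))   # malformed interval
  out <- filter_reads(reads, 100, analysis_config())
  expect_equal(out$read_id, "r2")
  rej <- attr(out, "rejected")
  expect_setequal(rej$read_id, c("r1", "r3", "r4"))
  expect_equal(rej$reason[rej$read_id == "r1"], "below quality floor")
  expect_equal(rej$reason[rej$read_id == "r3"], "outside transcript bounds")
  expect_equal(rej$reason[rej$read_id == "r4"], "malformed interval")
})

test_that("arms are swap-normalized so arm1 precedes arm2", {
  r <- mk_reads(list("r1", "b1", 35, 50, 60, 10, 20))
  expect_equal(r$arm1_start, 10L)
  expect_equal(r$arm2_start, 50L)
})

test_that("barcode deduplication keeps one read per (barcode, arms) set", {
  reads <- mk_reads(
    list("r2", "b1", 35, 10, 20, 50, 60),
    list("r1", "b1", 35, 10, 20, 50, 60),   # duplicate; smaller id survives
    list("r3", "b1", 35, 11, 20, 50, 60))   # same barcode, different arms
  out <- dedup_by_barcode(reads)
  expect_setequal(out$read_id, c("r1", "r3"))
  expect_identical(dedup_by_barcode(out), out)  # idempotent
})

test_that("dedup output size equals the number of distinct keys", {
  set.seed(11)
  for (trial in 1:10) {
    n <- 40
    reads <- paris_reads(sprintf("r%02d", sample(n)),
                         sample(c("b1", "b2", "b3"), n, replace = TRUE),
                         35,
                         arm1_start <- sample(1:5, n, replace = TRUE),
                         arm1_start + 10,
                         arm2_start <- sample(30:33, n, replace = TRUE),
                         arm2_start + 10)
    key <- unique(paste(reads$barcode, reads$arm1_start, reads$arm2_start))
    expect_equal(nrow(dedup_by_barcode(reads)), length(key))
  }
})

test_that("compression enforces minimum support and region length", {
  ident <- function(n) do.call(mk_reads, lapply(seq_len(n), function(k)
    list(paste0("r", k), paste0("b", k), 35, 100, 104, 200, 204)))
  g3 <- compress_duplexes(ident(3))
  expect_equal(nrow(g3), 1)
  expect_equal(g3$support, 3L)
  expect_gte(g3$arm1_end - g3$arm1_start + 1, 10)  # expanded from 5 nt
  expect_gte(g3$arm2_end - g3$arm2_start + 1, 10)

  expect_equal(nrow(compress_duplexes(ident(2))), 0)  # support 2: discarded
})

test_that("jittered reads group exactly as the transitive-closure oracle", {
  cfg <- analysis_config()
  for (seed in 1:15) {
    reads <- rand_reads(seed, n_centers = 3, per_center = 5, jitter = 12)
    groups <- compress_duplexes(reads, cfg)
    oracle <- oracle_compress_components(reads, cfg)
    oracle_kept <- Filter(function(ids) length(ids) >= cfg$min_support, oracle)
    got <- sort(vapply(strsplit(groups$read_ids, ","), function(x)
      paste(sort(x), collapse = ","), ""))
    want <- sort(vapply(oracle_kept, function(x)
      paste(sort(x), collapse = ","), ""))
    expect_equal(got, want)
    if (nrow(groups))
      expect_true(all(groups$arm1_end - groups$arm1_start + 1 >= 10))
  }
})

test_that("compression is invariant to input read order", {
  reads <- rand_reads(42, n_centers = 4, per_center = 5, jitter = 10)
  g1 <- compress_duplexes(reads)
  set.seed(1)
  g2 <- compress_duplexes(reads[sample(nrow(reads)), ])
  rownames(g2) <- NULL
  expect_equal(g1, g2)
})

test_that("sum of group supports never exceeds the input read count", {
  for (seed in 1:5) {
    reads <- rand_reads(seed + 50)
    g <- compress_duplexes(reads)
    expect_lte(sum(g$support), nrow(reads))
  }
})

test_that("range classification uses the inner-gap cutoff", {
  cfg <- analysis_config(long_range_min_gap = 80)
  g <- function(a1e, a2s) list(arm1_start = 1L, arm1_end = as.integer(a1e),
                               arm2_start = as.integer(a2s), arm2_end = as.integer(a2s + 10))
  expect_equal(classify_range(g(20, 121), cfg), "long_range")   # gap 100
  expect_equal(classify_range(g(20, 24), cfg), "short_range")   # gap 3
  expect_equal(classify_range(g(20, 100), cfg), "short_range")  # gap 79
  expect_equal(classify_range(g(20, 101), cfg), "long_range")   # gap 80
  expect_error(classify_range(g(20, 15), cfg), "overlap")
})

test_that("groups matching a model helix are consistent, others divergent", {
  m <- rand_small_model(5)
  h <- m$hairpins[[1]]
  st <- list(range(h$pairs[, 1]), range(h$pairs[, 2]))
  exact <- list(arm1_start = st[[1]][1], arm1_end = st[[1]][2],
                arm2_start = st[[2]][1], arm2_end = st[[2]][2])
  res <- match_to_model(exact, m, analysis_config())
  expect_equal(res$model_status, "consistent")
  expect_equal(res$matched_element, h$id)

  # arms in unpaired territory join nothing in the catalog
  unpaired <- which(m$pairing == 0)
  far <- list(arm1_start = unpaired[1], arm1_end = unpaired[1],
              arm2_start = unpaired[length(unpaired)],
              arm2_end = unpaired[length(unpaired)])
  expect_equal(match_to_model(far, m, analysis_config())$model_status, "divergent")
})

test_that("match status equals an exhaustive search over catalog elements", {
  cfg <- analysis_config()
  set.seed(77)
  for (seed in 1:15) {
    m <- rand_small_model(seed + 20)
    L <- nchar(m$sequence)
    for (k in 1:8) {
      s1 <- sample(L - 60, 1); l1 <- sample(6:14, 1)
      s2 <- s1 + l1 + sample(5:40, 1); l2 <- sample(6:14, 1)
      if (s2 + l2 > L) next
      grp <- list(arm1_start = s1, arm1_end = s1 + l1 - 1,
                  arm2_start = s2, arm2_end = s2 + l2 - 1)
      expect_equal(match_to_model(grp, m, cfg)$model_status,
                   oracle_match_status(grp, m, cfg))
    }
  }
})

test_that("pseudoknot status follows the maintained/rearranged/lost rules", {
  m <- rand_small_model(9)
  pk <- m$pseudoknots[[1]]
  mk_group <- function(id, a1, a2, status, matched = NA_character_) {
    data.frame(group_id = id, arm1_start = a1[1], arm1_end = a1[2],
               arm2_start = a2[1], arm2_end = a2[2], support = 3L,
               read_ids = "", range_class = "long_range",
               model_status = status, matched_element = matched,
               stringsAsFactors = FALSE)
  }
  maintained <- pseudoknot_status(
    mk_group("DG1", pk$arm1, pk$arm2, "consistent", pk$id), m)
  expect_equal(maintained$status[maintained$pk_id == pk$id], "maintained")

  # divergent group touching an arm: rearranged
  rearr <- pseudoknot_status(
    mk_group("DG1", pk$arm1, pk$arm1 + 200L, "divergent"), m)
  expect_equal(rearr$status[rearr$pk_id == pk$id], "rearranged")
  expect_equal(rearr$evidence[rearr$pk_id == pk$id], "DG1")

  # divergent group elsewhere (not overlapping either arm): lost
  far1 <- pk$arm2 + 50L
  lost <- pseudoknot_status(
    mk_group("DG1", far1, far1 + 60L, "divergent"), m)
  expect_equal(lost$status[lost$pk_id == pk$id], "lost")
})

test_that("PARIS summary counts equal a recount and partition the groups", {
  p <- sim_params(13, jitter_max = 0, dup_rate = 0, lowq_rate = 0, off_rate = 0)
  m <- gen_model(p)
  tr <- make_truth(m, p)
  reads <- simulate_paris(m, tr, p)
  cfg <- analysis_config()
  kept <- dedup_by_barcode(filter_reads(reads, nchar(m$sequence), cfg))
  groups <- classify_groups(compress_duplexes(kept, cfg), m, cfg)
  s <- summarize_paris(groups, pseudoknot_status(groups, m), m)
  expect_equal(s$n_consistent + s$n_divergent, s$n_groups)
  expect_equal(s$n_divergent_long_range + s$n_divergent_short_range, s$n_divergent)
  expect_equal(s$n_consistent, sum(groups$model_status == "consistent"))
  div <- groups[groups$model_status == "divergent", ]
  implicated <- vapply(m$hairpins, function(h)
    any(div$arm1_start <= h$span[2] & h$span[1] <= div$arm1_end) ||
    any(div$arm2_start <= h$span[2] & h$span[1] <= div$arm2_end), logical(1))
  expect_setequal(s$implicated_hairpins,
                  vapply(m$hairpins, `[[`, "", "id")[implicated])
  expect_error(summarize_paris(groups[0, ], NULL, m), "no duplex groups")
})
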