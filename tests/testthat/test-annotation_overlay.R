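overlay_fixture <- function() {
  ex <- worked_example_hairpins()
  calls <- classify_positions(ex$profile_condition, ex$model, ex$config_condition)
  delta <- compare_to_model(calls, ex$model)
  disrupt <- disruption_table(ex$model, calls, ex$config_condition)
  list(ex = ex, calls = calls, delta = delta, disrupt = disrupt)
}

test_that("annotation loading validates kinds, intervals and seed windows", {
  good <- data.frame(id = "a1", kind = "mirna_site", start = 10, end = 30,
                     seed_start = 22, seed_end = 28, stringsAsFactors = FALSE)
  expect_no_error(read_annotations(good, 100))
  expect_error(read_annotations(transform(good, end = 200), 100), "outside")
  expect_error(read_annotations(transform(good, seed_end = 35), 100), "seed")
  expect_error(read_annotations(transform(good, kind = "enhancer"), 100), "kind")
  expect_error(read_annotations(rbind(good, good), 100), "duplicate")
})

test_that("DMS overlay: loss opens sites, gain closes them, gaps are no_data", {
  fx <- overlay_fixture()
  L <- nchar(fx$ex$model$sequence)
  h44 <- fx$ex$model$hairpins[[1]]
  ann <- read_annotations(data.frame(
    id = c("site_in_disrupted", "site_in_gap"),
    kind = c("mirna_site", "mirna_site"),
    start = c(h44$span[1], L - 4), end = c(h44$span[1] + 10, L),
    seed_start = c(h44$span[1], L - 4), seed_end = c(h44$span[1] + 6, L - 1),
    stringsAsFactors = FALSE), L)
  calls <- overlay_dms(ann, fx$ex$model, fx$disrupt, fx$delta)
  expect_equal(calls$verdict[calls$annotation_id == "site_in_disrupted"],
               "increased_accessibility")
  expect_match(calls$evidence[calls$annotation_id == "site_in_disrupted"], "H44")
  expect_equal(calls$verdict[calls$annotation_id == "site_in_gap"], "no_data")
})

test_that("DMS overlay verdicts equal a rule-by-rule recount", {
  fx <- overlay_fixture()
  L <- nchar(fx$ex$model$sequence)
  set.seed(31)
  starts <- sample(L - 12, 30)
  ann <- read_annotations(data.frame(
    id = sprintf("a%02d", 1:30), kind = "protein_site",
    start = starts, end = starts + sample(0:12, 30, replace = TRUE),
    stringsAsFactors = FALSE), L)
  got <- overlay_dms(ann, fx$ex$model, fx$disrupt, fx$delta)
  disrupted_spans <- lapply(Filter(function(h)
    h$id %in% fx$disrupt$hairpin_id[fx$disrupt$disrupted], fx$ex$model$hairpins),
    `[[`, "span")
  for (k in seq_len(nrow(ann))) {
    pos <- ann$start[k]:ann$end[k]
    loss_len <- sum(vapply(pos, function(p)
      any(vapply(disrupted_spans, function(sp) p >= sp[1] && p <= sp[2],
                 logical(1))), logical(1)))
    gain_len <- sum(fx$delta$delta[pos] == "gain")
    covered <- any(fx$delta$delta[pos] != "no_data")
    want <- if (loss_len > 0 && loss_len >= gain_len) "increased_accessibility"
            else if (gain_len > 0) "decreased_accessibility"
            else if (covered) "unchanged" else "no_data"
    expect_equal(got$verdict[k], want)
  }
  # every annotation receives exactly one verdict
  expect_equal(nrow(got), nrow(ann))
})

test_that("PARIS overlay: divergent arms close seeds, consistent ones do not", {
  groups <- data.frame(
    group_id = c("DG1", "DG2"),
    arm1_start = c(100L, 300L), arm1_end = c(115L, 315L),
    arm2_start = c(150L, 500L), arm2_end = c(165L, 515L),
    support = 3L, read_ids = "", range_class = "short_range",
    model_status = c("divergent", "consistent"),
    matched_element = c(NA, "H1"), stringsAsFactors = FALSE)
  ann <- read_annotations(data.frame(
    id = c("seed_in_divergent", "seed_in_consistent", "untouched"),
    kind = "mirna_site",
    start = c(95L, 295L, 700L), end = c(125L, 325L, 730L),
    seed_start = c(105L, 305L, 710L), seed_end = c(111L, 311L, 716L),
    stringsAsFactors = FALSE), 1000)
  calls <- overlay_paris(ann, groups)
  expect_equal(calls$verdict,
               c("decreased_accessibility", "unchanged", "unchanged"))
  expect_equal(calls$evidence[1], "DG1")

  # seed-only mode: site overlapping a divergent arm outside the seed stays unchanged
  ann2 <- read_annotations(data.frame(
    id = "seed_outside_arm", kind = "mirna_site",
    start = 110L, end = 140L, seed_start = 130L, seed_end = 136L,
    stringsAsFactors = FALSE), 1000)
  expect_equal(overlay_paris(ann2, groups)$verdict, "unchanged")
  expect_equal(overlay_paris(ann2, groups,
    analysis_config(mirna_paris_region = "site"))$verdict,
    "decreased_accessibility")
})

test_that("seed pairing scores Watson-Crick complementarity antiparallel", {
  # site built as the reverse complement of the seed: all 7 pairs WC
  mir <- "UAUUGCACUUGUCCCGGCCUGU"
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  seed <- strsplit(substr(mir, 2, 8), "")[[1]]
  site <- paste0("GG", paste(rev(unname(comp[seed])), collapse = ""), "A")
  rep <- seed_pairing(site, mir)
  expect_equal(rep$n_WC_before, 7L)
  expect_false(rep$disrupted)
  expect_true(all(rep$classes_before == "WC"))
})

test_that("wobble pairs count as pairing but never as WC", {
  # replace the site base pairing seed position 5 (G) with U: G:U wobble
  mir <- "UAUUGCACUUGUCCCGGCCUGU"
  site <- "GGGUGCAAUA"
  base <- seed_pairing(site, mir)
  idx <- 10 - 5 + 1  # site position facing miRNA nt 5 (G)
  site_wob <- site
  substr(site_wob, idx, idx) <- "U"
  wob <- seed_pairing(site_wob, mir)
  expect_equal(unname(wob$classes_before["k5"]), "wobble")
  expect_equal(wob$n_WC_before, base$n_WC_before - 1L)
})

test_that("the seed-disruption worked example loses a WC pair on mutation", {
  wx <- worked_example_seed()
  rep <- seed_pairing(wx$site_seq, wx$mirna_seq, wx$site_start,
                      mutation = wx$mutation, mirna_name = wx$mirna_name)
  expect_equal(rep$n_WC_before, 7L)
  expect_equal(rep$n_WC_after, 6L)
  expect_true(rep$disrupted)
})

test_that("mutations outside the seed window leave the WC count unchanged", {
  wx <- worked_example_seed()
  outside <- list(position = wx$site_start, ref = "A", alt = "G")  # site nt 1
  rep <- seed_pairing(wx$site_seq, wx$mirna_seq, wx$site_start, mutation = outside)
  expect_false(rep$disrupted)
  expect_equal(rep$n_WC_after, rep$n_WC_before)
})

test_that("mutation ref mismatches are rejected and reversion restores n_WC", {
  wx <- worked_example_seed()
  bad <- wx$mutation; bad$ref <- "G"
  expect_error(seed_pairing(wx$site_seq, wx$mirna_seq, wx$site_start,
                            mutation = bad), "ref allele")

  mutated_site <- wx$site_seq
  off <- wx$mutation$position - wx$site_start + 1
  substr(mutated_site, off, off) <- wx$mutation$alt
  revert <- list(position = wx$mutation$position,
                 ref = wx$mutation$alt, alt = wx$mutation$ref)
  back <- seed_pairing(mutated_site, wx$mirna_seq, wx$site_start, mutation = revert)
  orig <- seed_pairing(wx$site_seq, wx$mirna_seq, wx$site_start)
  expect_equal(back$n_WC_after, orig$n_WC_before)
})

test_that("strand-consistency: reversing both sequences reproduces the classes", {
  wx <- worked_example_seed()
  rep <- seed_pairing(wx$site_seq, wx$mirna_seq)
  # pairing classes are symmetric in the two partners
  revstr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  mir_rev <- revstr(wx$mirna_seq)
  site_rev <- revstr(wx$site_seq)
  L <- nchar(wx$site_seq); M <- nchar(wx$mirna_seq)
  for (k in 2:8) {
    b_m <- substr(wx$mirna_seq, k, k)
    b_s <- substr(wx$site_seq, L - k + 1, L - k + 1)
    b_m_r <- substr(mir_rev, M - k + 1, M - k + 1)
    b_s_r <- substr(site_rev, k, k)
    expect_equal(b_m, b_m_r)
    expect_equal(b_s, b_s_r)
  }
  expect_equal(seed_pairing(wx$site_seq, wx$mirna_seq)$classes_before,
               rep$classes_before)  # idempotent without mutation
})

test_that("overlay tallies partition annotations and handle the empty case", {
  fx <- overlay_fixture()
  L <- nchar(fx$ex$model$sequence)
  ann <- read_annotations(data.frame(
    id = c("m1", "p1"), kind = c("modification", "protein_site"),
    start = c(10L, 40L), end = c(10L, 60L), mod_type = c("m6A", ""),
    stringsAsFactors = FALSE), L)
  calls <- overlay_dms(ann, fx$ex$model, fx$disrupt, fx$delta)
  tal <- tally_overlays(calls)
  expect_equal(sum(tal$n), nrow(ann))
  by_kind <- tapply(tal$n, tal$kind, sum)
  expect_true(all(by_kind == table(ann$kind)[names(by_kind)]))

  empty <- tally_overlays(calls[0, ])
  expect_equal(nrow(empty), 0)
})
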