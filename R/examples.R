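#' Worked example: four disrupted hairpins
#'
#' A synthetic stand-in for the published MALAT1 comparison's four
#' illustrative hairpins (H44, H45, H98, H155): a small transcript carrying
#' four stems of 25, 8, 12 and 6 base pairs, together with two count
#' profiles (a high-expression condition read against a 250-read threshold
#' and a reference fibroblast-like condition against a 20-read threshold)
#' whose per-pair call patterns encode the reported loss arithmetic —
#' 13/25, 5/8, 8/12 and 4/6 pairs lost, of which 8, 4, 6 and 2 are novel
#' relative to the reference condition. The per-nucleotide pattern is
#' constructed, not measured: stems place the informative A on the 5'
#' strand (A:U pairs) so each pair is probed through exactly one position.
#'
#' @return List with `model` (catalog ids H44, H45, H98, H155),
#'   `profile_condition`, `profile_reference`, `config_condition`
#'   (threshold 250) and `config_reference` (threshold 20).
#' @export
worked_example_hairpins <- function() {
  stems <- c(H44 = 25L, H45 = 8L, H98 = 12L, H155 = 6L)
  lost_condition <- c(H44 = 13L, H45 = 5L, H98 = 8L, H155 = 4L)
  lost_reference <- c(H44 = 5L, H45 = 1L, H98 = 2L, H155 = 2L)
  loop <- 4L; gap <- 6L
  bases <- character(0); pairing_pairs <- list(); catalog <- list()
  pos <- 0L
  counts_cond <- integer(0); counts_ref <- integer(0); count_pos <- integer(0)
  for (id in names(stems)) {
    s <- stems[[id]]
    bases <- c(bases, rep("G", gap),
               rep("A", s), rep("G", loop), rep("U", s))
    start5 <- pos + gap + 1L
    i <- start5 + seq_len(s) - 1L
    j <- start5 + 2L * s + loop - seq_len(s)
    pairing_pairs[[id]] <- cbind(i = i, j = j)
    # counts at the informative A of each pair: lost pairs read high
    k_lost_cond <- seq_len(lost_condition[[id]])
    k_lost_ref <- seq_len(lost_reference[[id]])
    counts_cond <- c(counts_cond, ifelse(seq_len(s) %in% k_lost_cond, 400L, 50L))
    counts_ref <- c(counts_ref, ifelse(seq_len(s) %in% k_lost_ref, 30L, 5L))
    count_pos <- c(count_pos, i)
    pos <- pos + gap + 2L * s + loop
  }
  bases <- c(bases, rep("G", gap))
  L <- length(bases)
  pairing <- integer(L)
  for (p in pairing_pairs) { pairing[p[, 1]] <- p[, 2]; pairing[p[, 2]] <- p[, 1] }
  catalog <- data.frame(
    id = names(stems), type = "hairpin", derivation = "dms_derived",
    pairs = vapply(pairing_pairs, function(p)
      paste(p[, 1], p[, 2], sep = "-", collapse = ";"), ""),
    stringsAsFactors = FALSE)
  model <- load_catalog(
    structure_model("worked_example", paste(bases, collapse = ""), pairing),
    catalog)
  list(model = model,
       profile_condition = dms_profile("worked_example", count_pos, counts_cond, L),
       profile_reference = dms_profile("worked_example", count_pos, counts_ref, L),
       config_condition = analysis_config(dms_threshold = 250),
       config_reference = analysis_config(dms_threshold = 20))
}

#' Worked example: mutation-driven seed disruption
#'
#' A synthetic binding-site fixture for the A2875U seed-disruption case:
#' a 10-nt site whose 3' portion is perfectly Watson-Crick complementary to
#' the miR-92a-3p seed (miRNA nts 2-8), carrying the transcript coordinate
#' of the A-to-U substitution that breaks one seed pair. The site sequence
#' is constructed to realize full 7/7 seed complementarity, not copied from
#' the transcript.
#'
#' @return List with `site_seq`, `site_start`, `mirna_name`, `mirna_seq`
#'   (mature miR-92a-3p), and `mutation`.
#' @export
worked_example_seed <- function() {
  list(site_seq = "ACGUGCAAUG",
       site_start = 2869L,
       mirna_name = "miR-92a-3p",
       mirna_seq = "UAUUGCACUUGUCCCGGCCUGU",
       mutation = list(position = 2875L, ref = "A", alt = "U"))
}

#' Worked example: threshold calibration anchors
#'
#' The read counts used to calibrate the high-expression threshold: two
#' loop nucleotides known to be unstructured in a verified 3'-end hairpin
#' (314 and 322 reads) and one known-structured modified nucleotide
#' (217 reads). Any threshold in `[217, 313]` separates them under the
#' "no more than the threshold is structured" rule; 250 sits near the
#' middle.
#'
#' @return List with `structured` and `unstructured` count vectors.
#' @export
worked_example_calibration <- function() {
  list(structured = c(217L), unstructured = c(314L, 322L))
}
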