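#' Analysis configuration
#'
#' All tunable thresholds of the pipeline in one record, so that per-dataset
#' choices (notably the DMS read-count threshold, which differs between
#' cell types with different transcript expression levels) are always
#' explicit and never inferred silently from data.
#'
#' @param dms_threshold Read-count threshold for the structured call: an A/C
#'   position with `count <= dms_threshold` is called structured, with
#'   `count > dms_threshold` unstructured. Typical values: 20 for the
#'   low-expression (fibroblast) dataset, 250 for the high-expression (K562)
#'   dataset.
#' @param disruption_cutoff Fraction of base pairs that must be lost for a
#'   hairpin to be called disrupted (default 0.5: "at least half").
#' @param long_range_min_gap Minimum inner gap (nt) between duplex arms for a
#'   long-range classification (default 80).
#' @param compress_max_offset Maximum per-arm start/end offset (nt) for two
#'   PARIS reads to be merged into one duplex group (default 20).
#' @param min_region_len Minimum arm length (nt) of an emitted duplex group;
#'   shorter intersections are expanded symmetrically (default 10).
#' @param min_support Minimum number of supporting reads per duplex group
#'   (default 3).
#' @param min_quality Minimum Phred read quality; reads below it are removed
#'   (default 30).
#' @param compress_rule `"offset"` (default): reads merge when both arms
#'   overlap and their start/end offsets are within `compress_max_offset`.
#'   `"symdiff"`: alternate reading where reads merge when each arm pair's
#'   symmetric-difference length is at most `compress_max_offset`.
#' @param match_min_frac,match_min_nt A duplex arm matches a model strand
#'   when their overlap is at least `min(ceiling(match_min_frac * arm
#'   length), match_min_nt)` nucleotides.
#' @param mirna_dms_region,mirna_paris_region Which part of a miRNA-binding
#'   site must overlap structural change to trigger an accessibility call:
#'   whole `"site"` or `"seed"` sub-interval. Defaults: whole site for
#'   DMS-based loss, seed only for PARIS-based rearrangement.
#' @param exclude_paris_positions When `TRUE`, per-datapoint DMS tallies also
#'   drop positions inside PARIS-derived hairpins (hairpin-level tallies
#'   always drop those hairpins).
#' @return An object of class `AnalysisConfig`.
#' @export
analysis_config <- function(dms_threshold = 250,
                            disruption_cutoff = 0.5,
                            long_range_min_gap = 80,
                            compress_max_offset = 20,
                            min_region_len = 10,
                            min_support = 3,
                            min_quality = 30,
                            compress_rule = c("offset", "symdiff"),
                            match_min_frac = 0.5,
                            match_min_nt = 5,
                            mirna_dms_region = c("site", "seed"),
                            mirna_paris_region = c("seed", "site"),
                            exclude_paris_positions = FALSE) {
  cfg <- list(dms_threshold = as.integer(dms_threshold),
              disruption_cutoff = disruption_cutoff,
              long_range_min_gap = as.integer(long_range_min_gap),
              compress_max_offset = as.integer(compress_max_offset),
              min_region_len = as.integer(min_region_len),
              min_support = as.integer(min_support),
              min_quality = as.integer(min_quality),
              compress_rule = match.arg(compress_rule),
              match_min_frac = match_min_frac,
              match_min_nt = as.integer(match_min_nt),
              mirna_dms_region = match.arg(mirna_dms_region),
              mirna_paris_region = match.arg(mirna_paris_region),
              exclude_paris_positions = isTRUE(exclude_paris_positions))
  with(cfg, stopifnot(
    dms_threshold > 0, disruption_cutoff > 0, disruption_cutoff <= 1,
    long_range_min_gap > 0, compress_max_offset >= 0, min_region_len > 0,
    min_support > 0, min_quality > 0, match_min_frac > 0, match_min_nt > 0))
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Per-nucleotide DMS-Seq read-count profile
#'
#' DMS methylates accessible (unpaired) adenosine and cytidine, so the
#' per-position read count is informative only at A/C positions; positions
#' with no count are coverage gaps (whole missing blocks are common, e.g.
#' when a shorter isoform is the one expressed).
#'
#' @param transcript_id Transcript name; must match the model it is compared
#'   against.
#' @param positions Integer vector of 1-based positions with data.
#' @param counts Non-negative integer read counts, same length as
#'   `positions`.
#' @param transcript_length Total transcript length.
#' @return Object of class `DmsProfile` with a full-length `counts` vector
#'   (`NA` = no data) and the list of covered intervals.
#' @export
dms_profile <- function(transcript_id, positions, counts, transcript_length) {
  positions <- as.integer(positions)
  counts <- as.integer(counts)
  n <- as.integer(transcript_length)
  stopifnot(length(positions) == length(counts))
  if (any(counts < 0, na.rm = TRUE)) stop("negative read count")
  if (length(positions) && (min(positions) < 1 || max(positions) > n))
    stop("read count at out-of-range position ",
         positions[which(positions < 1 | positions > n)[1]])
  if (anyDuplicated(positions))
    stop("duplicate position ", positions[duplicated(positions)][1])
  full <- rep(NA_integer_, n)
  full[positions] <- counts
  covered <- intervals_from_positions(sort(positions))
  structure(list(transcript_id = as.character(transcript_id)[1],
                 counts = full, covered = covered),
            class = "DmsProfile")
}

intervals_from_positions <- function(pos) {
  if (length(pos) == 0) return(matrix(integer(0), ncol = 2,
                                      dimnames = list(NULL, c("start", "end"))))
  breaks <- which(diff(pos) > 1)
  starts <- pos[c(1, breaks + 1)]
  ends <- pos[c(breaks, length(pos))]
  cbind(start = starts, end = ends)
}

#' Read a DMS count table
#'
#' Expects tab-separated columns `position`, `base`, `reads`; `#` lines are
#' comments. Positions are 1-based.
#'
#' @param path TSV file path.
#' @param transcript_id,transcript_length Profile metadata.
#' @return A [dms_profile()].
#' @export
read_dms_counts <- function(path, transcript_id, transcript_length) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("position", "reads")
  if (!all(need %in% names(tab)))
    stop("counts table must have columns position, base, reads")
  dms_profile(transcript_id, tab$position, tab$reads, transcript_length)
}

#' Classify A/C positions as structured or unstructured
#'
#' The central DMS-Seq call: an adenosine or cytidine with no more than
#' `dms_threshold` reads is classified `structured`, one with more reads
#' `unstructured`. A/C positions without data are `no_data`; G/U/N positions
#' are `not_AC` (DMS does not probe them informatively).
#'
#' @param profile A [dms_profile()].
#' @param model The reference [structure_model()]; supplies the sequence.
#' @param config An [analysis_config()]; `dms_threshold` is used.
#' @return Object of class `StructureCallTrack`: per-position calls over
#'   `{structured, unstructured, no_data, not_AC}` plus the counts.
#' @export
classify_positions <- function(profile, model, config = analysis_config()) {
  stopifnot(inherits(profile, "DmsProfile"), inherits(model, "StructureModel"))
  n <- nchar(model$sequence)
  if (profile$transcript_id != model$transcript_id)
    stop("transcript mismatch: profile '", profile$transcript_id,
         "' vs model '", model$transcript_id, "'")
  if (length(profile$counts) != n)
    stop("profile length ", length(profile$counts),
         " does not match model length ", n)
  bases <- transcript_bases(model)
  calls <- rep("not_AC", n)
  ac <- bases %in% c("A", "C")
  calls[ac] <- "no_data"
  has <- ac & !is.na(profile$counts)
  calls[has & profile$counts <= config$dms_threshold] <- "structured"
  calls[has & profile$counts > config$dms_threshold] <- "unstructured"
  structure(list(transcript_id = model$transcript_id,
                 calls = calls, counts = profile$counts),
            class = "StructureCallTrack")
}

#' Calibrate the structured/unstructured read-count threshold
#'
#' Given read counts at positions known to be structured and known to be
#' unstructured (e.g. from well-characterized hairpins such as a 3'-end
#' triple helix), reports the admissible threshold interval under the
#' "count <= threshold is structured" rule and suggests its midpoint. Any
#' threshold in `[max(structured), min(unstructured) - 1]` classifies every
#' anchor correctly; if the two sets overlap there is no admissible
#' threshold and the result is flagged infeasible.
#'
#' @param known_structured_counts,known_unstructured_counts Non-empty
#'   integer vectors of anchor read counts.
#' @return List with `feasible`, `interval` (`c(lo, hi)` or `NULL`), and
#'   `suggested` (floor of the interval midpoint, or `NA`).
#' @export
calibrate_threshold <- function(known_structured_counts, known_unstructured_counts) {
  if (length(known_structured_counts) == 0 || length(known_unstructured_counts) == 0)
    stop("both anchor sets must be non-empty")
  lo <- max(known_structured_counts)
  hi <- min(known_unstructured_counts) - 1L
  if (lo > hi)
    return(list(feasible = FALSE, interval = NULL, suggested = NA_integer_))
  list(feasible = TRUE, interval = c(lo = lo, hi = hi),
       suggested = as.integer(floor((lo + hi) / 2)))
}

#' Compare structure calls to the reference model
#'
#' At each position with a structured/unstructured call: a position paired
#' in the model but called unstructured is a `loss` of structure; unpaired
#' in the model but called structured is a `gain`; otherwise the call
#' `agree`s with the model. Positions without a call propagate `no_data`.
#'
#' @param calls A `StructureCallTrack` from [classify_positions()].
#' @param model The same model the calls were made against.
#' @return Object of class `DeltaTrack`: per-position
#'   `{agree, loss, gain, no_data}`.
#' @export
compare_to_model <- function(calls, model) {
  stopifnot(inherits(calls, "StructureCallTrack"), inherits(model, "StructureModel"))
  if (calls$transcript_id != model$transcript_id)
    stop("transcript mismatch between calls and model")
  n <- nchar(model$sequence)
  paired <- model$pairing > 0
  delta <- rep("no_data", n)
  called <- calls$calls %in% c("structured", "unstructured")
  delta[called] <- "agree"
  delta[called & paired & calls$calls == "unstructured"] <- "loss"
  delta[called & !paired & calls$calls == "structured"] <- "gain"
  structure(list(transcript_id = calls$transcript_id, delta = delta),
            class = "DeltaTrack")
}

hairpin_lost_pairs <- function(hairpin, calls) {
  unstr <- calls$calls[hairpin$pairs[, 1]] == "unstructured" |
           calls$calls[hairpin$pairs[, 2]] == "unstructured"
  unstr
}

hairpin_evaluable_pairs <- function(hairpin, calls) {
  has_call <- function(p) calls$calls[p] %in% c("structured", "unstructured")
  has_call(hairpin$pairs[, 1]) | has_call(hairpin$pairs[, 2])
}

#' Score disruption of one hairpin
#'
#' A base pair is counted lost when at least one of its two nucleotides is
#' called unstructured (the either-partner rule: DMS reports only A and C,
#' and a stem pair generally exposes only one informative base). The
#' denominator is the hairpin's total pair count — pairs with no A/C
#' datapoint can never be counted lost but still dilute the fraction, a
#' deliberately conservative choice. The hairpin is disrupted when the lost
#' fraction reaches `disruption_cutoff`.
#'
#' @param hairpin One hairpin record from the model catalog.
#' @param calls A `StructureCallTrack`.
#' @param config An [analysis_config()].
#' @return One-row data frame: `hairpin_id`, `n_pairs_total`,
#'   `n_pairs_evaluable`, `n_pairs_lost`, `fraction_lost`, `disrupted`.
#' @export
hairpin_disruption <- function(hairpin, calls, config = analysis_config()) {
  if (is.null(hairpin$pairs) || nrow(hairpin$pairs) == 0)
    stop("hairpin ", hairpin$id, " has no base pairs")
  lost <- hairpin_lost_pairs(hairpin, calls)
  evaluable <- hairpin_evaluable_pairs(hairpin, calls)
  n_total <- nrow(hairpin$pairs)
  n_lost <- sum(lost)
  frac <- n_lost / n_total
  data.frame(hairpin_id = hairpin$id,
             n_pairs_total = n_total,
             n_pairs_evaluable = sum(evaluable),
             n_pairs_lost = n_lost,
             fraction_lost = frac,
             disrupted = frac >= config$disruption_cutoff,
             stringsAsFactors = FALSE)
}

#' Score disruption of every hairpin in the model catalog
#'
#' @param model A `StructureModel` with a loaded catalog.
#' @param calls A `StructureCallTrack`.
#' @param config An [analysis_config()].
#' @return Data frame, one row per hairpin, with a `derivation` column.
#' @export
disruption_table <- function(model, calls, config = analysis_config()) {
  if (length(model$hairpins) == 0)
    return(data.frame(hairpin_id = character(0), n_pairs_total = integer(0),
                      n_pairs_evaluable = integer(0), n_pairs_lost = integer(0),
                      fraction_lost = numeric(0), disrupted = logical(0),
                      derivation = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(model$hairpins, hairpin_disruption,
                               calls = calls, config = config))
  out$derivation <- vapply(model$hairpins, `[[`, "", "derivation")
  out
}

#' Count base pairs newly lost relative to a reference condition
#'
#' A pair is a novel loss when it is lost (either partner unstructured)
#' under the test condition but not lost under the reference condition —
#' e.g. pairs lost in a cancer cell line beyond those already lost in the
#' noncancerous data the model was built from.
#'
#' @param calls_condition,calls_reference `StructureCallTrack`s on the same
#'   transcript.
#' @param hairpin Hairpin record to evaluate.
#' @return Integer count of newly lost pairs; the pairs themselves are
#'   attached as attribute `"pairs"`.
#' @export
novel_changes <- function(calls_condition, calls_reference, hairpin) {
  if (calls_condition$transcript_id != calls_reference$transcript_id)
    stop("call tracks are from different transcripts")
  lost_cond <- hairpin_lost_pairs(hairpin, calls_condition)
  lost_ref <- hairpin_lost_pairs(hairpin, calls_reference)
  novel <- lost_cond & !lost_ref
  structure(sum(novel), pairs = hairpin$pairs[novel, , drop = FALSE])
}

#' Round half away from zero
#'
#' All reported percentages use commercial (half-up) rounding to one
#' decimal, not banker's rounding, so 52.05 reports as 52.1.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

pct <- function(k, n) if (n == 0) NA_real_ else round_half_up(100 * k / n, 1)

#' Summarize a DMS comparison run
#'
#' Tallies the structured/unstructured split, the agree/loss/gain split, and
#' the disrupted-hairpin fraction. Hairpins whose pairing was derived from
#' PARIS data are excluded from the disruption tally (they carry no
#' independent DMS support); only hairpins with at least one evaluable pair
#' enter the denominator. Percentages are rounded half-up to one decimal.
#'
#' @param calls A `StructureCallTrack`.
#' @param delta The matching `DeltaTrack`.
#' @param hairpin_results Data frame from [disruption_table()].
#' @param config An [analysis_config()].
#' @return List of counts and one-decimal percentages.
#' @export
summarize_dms <- function(calls, delta, hairpin_results,
                          config = analysis_config()) {
  stopifnot(inherits(calls, "StructureCallTrack"), inherits(delta, "DeltaTrack"))
  called <- calls$calls %in% c("structured", "unstructured")
  if (!any(called)) stop("no called positions to summarize")
  n_called <- sum(called)
  n_unstr <- sum(calls$calls == "unstructured")
  n_str <- sum(calls$calls == "structured")
  d <- delta$delta[called]
  n_agree <- sum(d == "agree"); n_loss <- sum(d == "loss"); n_gain <- sum(d == "gain")

  hp <- hairpin_results[hairpin_results$derivation != "paris_derived" &
                        hairpin_results$n_pairs_evaluable > 0, , drop = FALSE]
  list(
    n_datapoints = n_called,
    n_structured = n_str,
    n_unstructured = n_unstr,
    pct_structured = pct(n_str, n_called),
    pct_unstructured = pct(n_unstr, n_called),
    n_agree = n_agree, n_loss = n_loss, n_gain = n_gain,
    pct_agree = pct(n_agree, n_called),
    pct_loss = pct(n_loss, n_called),
    pct_gain = pct(n_gain, n_called),
    n_hairpins_evaluated = nrow(hp),
    n_hairpins_disrupted = sum(hp$disrupted),
    pct_hairpins_disrupted = pct(sum(hp$disrupted), nrow(hp)))
}

#' Write per-position calls and per-hairpin disruption tables
#'
#' @param calls A `StructureCallTrack`.
#' @param delta Matching `DeltaTrack`.
#' @param model The reference model (for bases).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, delta, model, path) {
  tab <- data.frame(position = seq_along(calls$calls),
                    base = transcript_bases(model),
                    reads = calls$counts,
                    call = calls$calls,
                    delta = delta$delta)
  write_tsv_with_header(tab, path)
}

write_tsv_with_header <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# dmsparis ", as.character(utils::packageVersion("dmsparis"))), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
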