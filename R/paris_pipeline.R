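#' PARIS duplex read table
#'
#' PARIS (psoralen crosslinking) yields chimeric reads whose two arms mark
#' the two strands of an in-cell RNA duplex. Reads are represented as a data
#' frame with columns `read_id`, `barcode`, `quality` (Phred), and 1-based
#' inclusive arm intervals `arm1_start`, `arm1_end`, `arm2_start`,
#' `arm2_end`. On ingest, arms are swap-normalized so that arm1 always
#' precedes arm2 on the transcript (removes orientation ambiguity).
#'
#' @param read_id,barcode Character vectors.
#' @param quality Integer Phred scores.
#' @param arm1_start,arm1_end,arm2_start,arm2_end Integer intervals.
#' @return Data frame of class `c("ParisReads", "data.frame")`.
#' @export
paris_reads <- function(read_id, barcode, quality,
                        arm1_start, arm1_end, arm2_start, arm2_end) {
  df <- data.frame(read_id = as.character(read_id),
                   barcode = as.character(barcode),
                   quality = as.integer(quality),
                   arm1_start = as.integer(arm1_start),
                   arm1_end = as.integer(arm1_end),
                   arm2_start = as.integer(arm2_start),
                   arm2_end = as.integer(arm2_end),
                   stringsAsFactors = FALSE)
  swap <- df$arm2_start < df$arm1_start
  if (any(swap)) {
    tmp <- df[swap, c("arm1_start", "arm1_end")]
    df[swap, c("arm1_start", "arm1_end")] <- df[swap, c("arm2_start", "arm2_end")]
    df[swap, c("arm2_start", "arm2_end")] <- tmp
  }
  class(df) <- c("ParisReads", "data.frame")
  df
}

#' Read a PARIS duplex read table from TSV
#'
#' Columns: `read_id`, `barcode`, `quality`, `arm1_start`, `arm1_end`,
#' `arm2_start`, `arm2_end`. `#` lines are comments.
#'
#' @param path TSV file path.
#' @return A [paris_reads()] table.
#' @export
read_paris_reads <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("read_id", "barcode", "quality",
            "arm1_start", "arm1_end", "arm2_start", "arm2_end")
  if (!all(need %in% names(tab)))
    stop("PARIS read table must have columns: ", paste(need, collapse = ", "))
  do.call(paris_reads, tab[need])
}

#' Filter PARIS reads on quality and transcript bounds
#'
#' Removes reads below the Phred quality floor (quality `>= min_quality` is
#' kept, so Q30 survives a Q30 floor) and reads whose duplex falls outside
#' the transcript coordinates. Records with malformed intervals (start after
#' end) are rejected individually. Rejected records and reasons are attached
#' as attribute `"rejected"`.
#'
#' @param reads A [paris_reads()] table.
#' @param transcript_length Upper transcript bound (lower bound is 1).
#' @param config An [analysis_config()]; `min_quality` is used.
#' @return Filtered `ParisReads` table.
#' @export
filter_reads <- function(reads, transcript_length, config = analysis_config()) {
  n <- as.integer(transcript_length)
  malformed <- reads$arm1_start > reads$arm1_end | reads$arm2_start > reads$arm2_end
  lowq <- !malformed & reads$quality < config$min_quality
  outside <- !malformed & !lowq &
    (reads$arm1_start < 1 | reads$arm2_end > n |
     reads$arm1_end > n | reads$arm2_start < 1)
  reason <- rep(NA_character_, nrow(reads))
  reason[malformed] <- "malformed interval"
  reason[lowq] <- "below quality floor"
  reason[outside] <- "outside transcript bounds"
  keep <- is.na(reason)
  rejected <- data.frame(read_id = reads$read_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Remove PCR duplicates by barcode matching
#'
#' Reads sharing barcode and both arm intervals are PCR duplicates of one
#' molecule; one representative is kept per equivalence set. The keep rule
#' is deterministic: the lexicographically smallest `read_id` survives.
#' Idempotent.
#'
#' @param reads A [paris_reads()] table.
#' @return Deduplicated `ParisReads` table.
#' @export
dedup_by_barcode <- function(reads) {
  if (nrow(reads) == 0) return(reads)
  key <- paste(reads$barcode, reads$arm1_start, reads$arm1_end,
               reads$arm2_start, reads$arm2_end, sep = "\r")
  ord <- order(key, reads$read_id)
  reads <- reads[ord, , drop = FALSE]
  out <- reads[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

arm_overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

reads_link <- function(r, i, j, config) {
  ov1 <- arm_overlap_len(r$arm1_start[i], r$arm1_end[i], r$arm1_start[j], r$arm1_end[j])
  ov2 <- arm_overlap_len(r$arm2_start[i], r$arm2_end[i], r$arm2_start[j], r$arm2_end[j])
  if (ov1 < 1 || ov2 < 1) return(FALSE)
  if (config$compress_rule == "offset") {
    max(abs(r$arm1_start[i] - r$arm1_start[j]),
        abs(r$arm1_end[i] - r$arm1_end[j]),
        abs(r$arm2_start[i] - r$arm2_start[j]),
        abs(r$arm2_end[i] - r$arm2_end[j])) <= config$compress_max_offset
  } else {
    u1 <- max(r$arm1_end[i], r$arm1_end[j]) - min(r$arm1_start[i], r$arm1_start[j]) + 1L
    u2 <- max(r$arm2_end[i], r$arm2_end[j]) - min(r$arm2_start[i], r$arm2_start[j]) + 1L
    (u1 - ov1) <= config$compress_max_offset && (u2 - ov2) <= config$compress_max_offset
  }
}

#' Compress overlapping PARIS reads into duplex groups
#'
#' Single-linkage clustering: two reads join the same group when their
#' corresponding arms overlap by at least 1 nt and (under the default
#' `"offset"` rule) every start/end offset between corresponding arms is at
#' most `compress_max_offset` (default 20 nt). Each group's arms are the
#' intersection of its members' arms, symmetrically expanded to
#' `min_region_len` (default 10 nt) if shorter; groups supported by fewer
#' than `min_support` reads (default 3) are discarded. Input is
#' sort-normalized first so the result is invariant to read order.
#'
#' @param reads Filtered, deduplicated [paris_reads()].
#' @param config An [analysis_config()].
#' @return Data frame of duplex groups: `group_id`, `arm1_start`,
#'   `arm1_end`, `arm2_start`, `arm2_end`, `support`, `read_ids`
#'   (comma-separated).
#' @export
compress_duplexes <- function(reads, config = analysis_config()) {
  empty <- data.frame(group_id = character(0),
                      arm1_start = integer(0), arm1_end = integer(0),
                      arm2_start = integer(0), arm2_end = integer(0),
                      support = integer(0), read_ids = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0) return(empty)
  ord <- order(reads$arm1_start, reads$arm1_end,
               reads$arm2_start, reads$arm2_end, reads$read_id)
  r <- reads[ord, , drop = FALSE]
  n <- nrow(r)
  # union-find over pairwise links
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (reads_link(r, i, j, config)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- lapply(split(seq_len(n), comp), function(idx) {
    if (length(idx) < config$min_support) return(NULL)
    a1 <- intersect_and_expand(r$arm1_start[idx], r$arm1_end[idx], config$min_region_len)
    a2 <- intersect_and_expand(r$arm2_start[idx], r$arm2_end[idx], config$min_region_len)
    data.frame(arm1_start = a1[1], arm1_end = a1[2],
               arm2_start = a2[1], arm2_end = a2[2],
               support = length(idx),
               read_ids = paste(sort(r$read_id[idx]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, groups[!vapply(groups, is.null, TRUE)])
  if (is.null(groups)) return(empty)
  groups <- groups[order(groups$arm1_start, groups$arm2_start), , drop = FALSE]
  groups <- cbind(group_id = sprintf("DG%d", seq_len(nrow(groups))), groups,
                  stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  groups
}

# Intersection of member intervals; if linkage chains leave it empty, fall
# back to the chain's midpoint. Expanded symmetrically to min_len.
intersect_and_expand <- function(starts, ends, min_len) {
  s <- max(starts); e <- min(ends)
  if (s > e) { mid <- (s + e) %/% 2L; s <- mid; e <- mid }
  need <- min_len - (e - s + 1L)
  if (need > 0) {
    s <- s - ceiling(need / 2)
    e <- e + floor(need / 2)
  }
  if (s < 1) { e <- e + (1L - s); s <- 1L }
  c(as.integer(s), as.integer(e))
}

#' Classify a duplex group as short- or long-range
#'
#' The inner gap is the number of nucleotides strictly between the two arms
#' (`arm2_start - arm1_end - 1`). A gap of at least `long_range_min_gap`
#' (default 80 nt) is long-range; anything shorter is a local, short-range
#' duplex. Overlapping arms are not a valid duplex.
#'
#' @param group One duplex-group row (list or one-row data frame).
#' @param config An [analysis_config()].
#' @return `"short_range"` or `"long_range"`.
#' @export
classify_range <- function(group, config = analysis_config()) {
  gap <- group$arm2_start - group$arm1_end - 1L
  if (gap < 0) stop("invalid duplex: arms overlap (gap ", gap, ")")
  if (gap >= config$long_range_min_gap) "long_range" else "short_range"
}

element_strands <- function(el) {
  if (!is.null(el$derivation)) {          # hairpin: 5' and 3' strand position sets
    list(sort(unique(el$pairs[, 1])), sort(unique(el$pairs[, 2])))
  } else {                                # pseudoknot: the two arm intervals
    list(seq.int(el$arm1[1], el$arm1[2]), seq.int(el$arm2[1], el$arm2[2]))
  }
}

arm_matches_strand <- function(arm_start, arm_end, strand, config) {
  arm_len <- arm_end - arm_start + 1L
  # required overlap cannot exceed what the strand can offer: a short helix
  # strand fully contained in the arm is a complete match
  required <- min(ceiling(config$match_min_frac * arm_len),
                  config$match_min_nt, length(strand))
  ov <- sum(strand >= arm_start & strand <= arm_end)
  list(ok = ov >= required, overlap = ov)
}

#' Match a duplex group against the model catalog
#'
#' A group is `consistent` when some hairpin or pseudoknot has two strands
#' that are each overlapped by the corresponding group arm by at least 50%
#' of the arm length or 5 nt, whichever is smaller — capped at the strand's
#' own length, so a short helix strand fully inside the arm always matches
#' (both arm-to-strand assignments are tried); otherwise it is `divergent` —
#' evidence of a structure not in the model. Ties between matching elements
#' are broken by larger total overlap, then by element id.
#'
#' @param group One duplex-group row.
#' @param model A `StructureModel` with a loaded catalog.
#' @param config An [analysis_config()].
#' @return List with `model_status` (`"consistent"`/`"divergent"`) and
#'   `matched_element` (element id or `NA`).
#' @export
match_to_model <- function(group, model, config = analysis_config()) {
  best_id <- NA_character_; best_ov <- -1L
  for (el in c(model$hairpins, model$pseudoknots)) {
    st <- element_strands(el)
    for (assign in list(c(1, 2), c(2, 1))) {
      m1 <- arm_matches_strand(group$arm1_start, group$arm1_end, st[[assign[1]]], config)
      m2 <- arm_matches_strand(group$arm2_start, group$arm2_end, st[[assign[2]]], config)
      if (m1$ok && m2$ok) {
        tot <- m1$overlap + m2$overlap
        if (tot > best_ov || (tot == best_ov && !is.na(best_id) && el$id < best_id)) {
          best_ov <- tot; best_id <- el$id
        }
      }
    }
  }
  if (is.na(best_id)) list(model_status = "divergent", matched_element = NA_character_)
  else list(model_status = "consistent", matched_element = best_id)
}

#' Classify all duplex groups (range + model status)
#'
#' @param groups Data frame from [compress_duplexes()].
#' @param model A `StructureModel` with a catalog.
#' @param config An [analysis_config()].
#' @return `groups` with added columns `range_class`, `model_status`,
#'   `matched_element`.
#' @export
classify_groups <- function(groups, model, config = analysis_config()) {
  if (nrow(groups) == 0) {
    groups$range_class <- character(0)
    groups$model_status <- character(0)
    groups$matched_element <- character(0)
    return(groups)
  }
  res <- lapply(seq_len(nrow(groups)), function(k) {
    g <- groups[k, ]
    m <- match_to_model(g, model, config)
    data.frame(range_class = classify_range(g, config),
               model_status = m$model_status,
               matched_element = m$matched_element,
               stringsAsFactors = FALSE)
  })
  cbind(groups, do.call(rbind, res))
}

interval_overlaps <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

#' Report pseudoknot status from classified duplex groups
#'
#' Per pseudoknot: `maintained` when a consistent group matched it;
#' `rearranged` when no consistent match exists but some divergent group
#' overlaps either arm (the crosslink data place a different structure
#' there); `lost` when no duplex evidence touches it at all.
#'
#' @param groups Classified groups from [classify_groups()].
#' @param model A `StructureModel` with pseudoknots in its catalog.
#' @return Data frame: `pk_id`, `status`, `evidence` (comma-separated group
#'   ids).
#' @export
pseudoknot_status <- function(groups, model) {
  res <- lapply(model$pseudoknots, function(pk) {
    cons <- groups$model_status == "consistent" &
            !is.na(groups$matched_element) & groups$matched_element == pk$id
    div <- groups$model_status == "divergent" &
      (interval_overlaps(groups$arm1_start, groups$arm1_end, pk$arm1[1], pk$arm1[2]) |
       interval_overlaps(groups$arm1_start, groups$arm1_end, pk$arm2[1], pk$arm2[2]) |
       interval_overlaps(groups$arm2_start, groups$arm2_end, pk$arm1[1], pk$arm1[2]) |
       interval_overlaps(groups$arm2_start, groups$arm2_end, pk$arm2[1], pk$arm2[2]))
    status <- if (any(cons)) "maintained" else if (any(div)) "rearranged" else "lost"
    evidence <- if (status == "maintained") groups$group_id[cons]
                else if (status == "rearranged") groups$group_id[div]
                else character(0)
    data.frame(pk_id = pk$id, status = status,
               evidence = paste(evidence, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(res) == 0)
    return(data.frame(pk_id = character(0), status = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Summarize a PARIS comparison run
#'
#' Counts consistent vs divergent groups, splits the divergent groups by
#' range class, and lists hairpins implicated in rearrangement (span
#' overlapped by any divergent group arm). Percentages to one decimal.
#'
#' @param groups Classified groups.
#' @param pk_statuses Output of [pseudoknot_status()].
#' @param model A `StructureModel`.
#' @return List of counts, percentages and implicated hairpin ids.
#' @export
summarize_paris <- function(groups, pk_statuses, model) {
  if (nrow(groups) == 0) stop("no duplex groups to summarize")
  n <- nrow(groups)
  n_cons <- sum(groups$model_status == "consistent")
  n_div <- sum(groups$model_status == "divergent")
  div <- groups[groups$model_status == "divergent", , drop = FALSE]
  n_div_long <- sum(div$range_class == "long_range")
  n_div_short <- sum(div$range_class == "short_range")
  implicated <- vapply(model$hairpins, function(h) {
    any(interval_overlaps(div$arm1_start, div$arm1_end, h$span[1], h$span[2]) |
        interval_overlaps(div$arm2_start, div$arm2_end, h$span[1], h$span[2]))
  }, logical(1))
  list(n_groups = n,
       n_consistent = n_cons, pct_consistent = pct(n_cons, n),
       n_divergent = n_div, pct_divergent = pct(n_div, n),
       n_divergent_long_range = n_div_long,
       pct_divergent_long_range = pct(n_div_long, max(n_div, 1)),
       n_divergent_short_range = n_div_short,
       pct_divergent_short_range = pct(n_div_short, max(n_div, 1)),
       implicated_hairpins = vapply(model$hairpins, `[[`, "", "id")[implicated],
       pk_status_counts = as.list(table(pk_statuses$status)))
}
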