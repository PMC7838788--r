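ANNOTATION_KINDS <- c("mirna_site", "u1_site", "rrna_site", "protein_site",
                      "modification", "snp", "mutation")

#' Read a functional annotation table
#'
#' One row per feature on the transcript: miRNA-binding sites (with their
#' seed sub-interval and miRNA sequence), U1 snRNA/rRNA/protein-binding
#' sites, modification points (m6A, m5C, Am), SNPs, and somatic mutations.
#' Intervals are 1-based inclusive; point features have `start == end`.
#'
#' Required columns: `id`, `kind`, `start`, `end`. Kind-specific payload
#' columns: `mirna_name`, `seed_start`, `seed_end`, `mirna_seq` for
#' `mirna_site`; `mod_type` for `modification`; `ref`, `alt` for
#' `snp`/`mutation`.
#'
#' @param path TSV file path, or a data frame with the same columns.
#' @param transcript_length Transcript bound for validation.
#' @return Validated annotation data frame.
#' @export
read_annotations <- function(path, transcript_length) {
  ann <- if (is.data.frame(path)) path
         else utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "kind", "start", "end")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  bad_kind <- setdiff(unique(ann$kind), ANNOTATION_KINDS)
  if (length(bad_kind)) stop("unknown annotation kind: ", bad_kind[1])
  if (anyDuplicated(ann$id)) stop("duplicate annotation id")
  ann$start <- as.integer(ann$start); ann$end <- as.integer(ann$end)
  n <- as.integer(transcript_length)
  out_of_range <- ann$start < 1 | ann$end > n | ann$start > ann$end
  if (any(out_of_range))
    stop("annotation '", ann$id[out_of_range][1], "' outside transcript (1-", n, ")")
  mir <- ann$kind == "mirna_site"
  if (any(mir)) {
    for (col in c("seed_start", "seed_end"))
      if (!col %in% names(ann)) stop("mirna_site rows require column ", col)
    ss <- as.integer(ann$seed_start[mir]); se <- as.integer(ann$seed_end[mir])
    if (any(is.na(ss) | is.na(se) | ss < ann$start[mir] | se > ann$end[mir] | ss > se))
      stop("miRNA seed sub-interval must lie within its site interval")
  }
  mut <- ann$kind %in% c("snp", "mutation")
  if (any(mut) && !all(c("ref", "alt") %in% names(ann)))
    stop("snp/mutation rows require columns ref, alt")
  ann
}

annotation_region <- function(ann_row, mirna_region) {
  if (ann_row$kind == "mirna_site" && mirna_region == "seed")
    c(as.integer(ann_row$seed_start), as.integer(ann_row$seed_end))
  else c(ann_row$start, ann_row$end)
}

#' Accessibility calls from DMS-based structural loss
#'
#' An annotation overlapping (by at least 1 nt) a disrupted hairpin gains
#' accessibility — the structure occluding it is predicted to open. An
#' annotation overlapping only structure-gain positions loses accessibility.
#' One overlapping covered data but no change is unchanged; one with no
#' covered positions at all is `no_data`. When an annotation overlaps both
#' loss and gain evidence, the verdict with the larger overlapped length
#' wins; ties resolve to increased accessibility (loss dominates).
#'
#' For miRNA sites the overlapped region is the whole site by default
#' (`mirna_dms_region = "site"`); set `"seed"` in the config for the
#' stricter seed-only mode.
#'
#' @param annotations Data frame from [read_annotations()].
#' @param model The reference `StructureModel` (for hairpin spans).
#' @param disruptions Data frame from [disruption_table()].
#' @param delta A `DeltaTrack` from [compare_to_model()].
#' @param config An [analysis_config()].
#' @return Data frame: `annotation_id`, `kind`, `verdict`, `evidence`.
#' @export
overlay_dms <- function(annotations, model, disruptions, delta,
                        config = analysis_config()) {
  disrupted_ids <- disruptions$hairpin_id[disruptions$disrupted]
  spans <- lapply(model$hairpins, function(h)
    if (h$id %in% disrupted_ids) h$span else NULL)
  spans <- spans[!vapply(spans, is.null, TRUE)]
  disrupted_ranges <- if (length(spans))
    IRanges::reduce(IRanges::IRanges(
      start = vapply(spans, `[`, 0, 1), end = vapply(spans, `[`, 0, 2)))
  else IRanges::IRanges()

  res <- lapply(seq_len(nrow(annotations)), function(k) {
    a <- annotations[k, ]
    region <- annotation_region(a, config$mirna_dms_region)
    pos <- seq.int(region[1], region[2])
    loss_len <- sum(IRanges::width(IRanges::pintersect(
      IRanges::findOverlapPairs(IRanges::IRanges(region[1], region[2]),
                                disrupted_ranges))))
    gain_len <- sum(delta$delta[pos] == "gain")
    covered <- any(delta$delta[pos] != "no_data")
    verdict <-
      if (loss_len > 0 && loss_len >= gain_len) "increased_accessibility"
      else if (gain_len > 0) "decreased_accessibility"
      else if (covered) "unchanged"
      else "no_data"
    ev <- character(0)
    if (verdict == "increased_accessibility") {
      ev <- vapply(model$hairpins, function(h)
        if (h$id %in% disrupted_ids &&
            interval_overlaps(region[1], region[2], h$span[1], h$span[2])) h$id
        else NA_character_, "")
      ev <- ev[!is.na(ev)]
    }
    data.frame(annotation_id = a$id, kind = a$kind, verdict = verdict,
               evidence = paste(ev, collapse = ","), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Accessibility calls from PARIS duplex evidence
#'
#' An annotation whose seed (for miRNA sites, by default) or interval
#' (other kinds) overlaps any divergent duplex-group arm is predicted to
#' lose accessibility: a rearranged duplex now occupies the site. Overlap
#' with consistent groups only, or no overlap at all, leaves the annotation
#' unchanged.
#'
#' @param annotations Data frame from [read_annotations()].
#' @param groups Classified groups from [classify_groups()].
#' @param config An [analysis_config()].
#' @return Data frame: `annotation_id`, `kind`, `verdict`, `evidence`.
#' @export
overlay_paris <- function(annotations, groups, config = analysis_config()) {
  res <- lapply(seq_len(nrow(annotations)), function(k) {
    a <- annotations[k, ]
    region <- annotation_region(a, config$mirna_paris_region)
    hits_arm <- interval_overlaps(groups$arm1_start, groups$arm1_end,
                                  region[1], region[2]) |
                interval_overlaps(groups$arm2_start, groups$arm2_end,
                                  region[1], region[2])
    div <- hits_arm & groups$model_status == "divergent"
    verdict <- if (any(div)) "decreased_accessibility" else "unchanged"
    data.frame(annotation_id = a$id, kind = a$kind, verdict = verdict,
               evidence = paste(groups$group_id[div], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

PAIR_WC <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE)
PAIR_WOBBLE <- c(GU = TRUE, UG = TRUE)

pair_class <- function(b1, b2) {
  key <- paste0(b1, b2)
  ifelse(!is.na(PAIR_WC[key]), "WC",
         ifelse(!is.na(PAIR_WOBBLE[key]), "wobble", "none"))
}

#' Seed-region pairing between a miRNA and its binding site
#'
#' Pairs the miRNA antiparallel against the site: miRNA nucleotide k (5'->3')
#' faces site nucleotide `L - k + 1`, so the seed (miRNA nts 2-8) reads
#' against the 3' portion of the site. Pair classes: Watson-Crick (`A:U`,
#' `G:C`), wobble (`G:U`, counted as pairing but not WC), or none. An
#' optional point mutation (transcript coordinates) is applied to the site
#' and the seed WC count recomputed; the site is `disrupted` when the
#' mutation reduces the number of WC pairs in the seed window. Disruption is
#' defined on the WC count only — wobble pairs do not rescue a lost WC pair.
#'
#' @param site_seq RNA sequence of the binding site, 5'->3' on the
#'   transcript; must be at least 8 nt so the seed window is covered.
#' @param mirna_seq miRNA sequence, 5'->3'.
#' @param site_start Transcript coordinate of the first site nucleotide
#'   (used to place `mutation`).
#' @param mutation Optional `list(position =, ref =, alt =)`; `ref` must
#'   match the site sequence at that coordinate (guards against coordinate
#'   drift), and the position must lie within the site.
#' @param mirna_name Label carried into the report.
#' @return List of class `SeedPairingReport`: per-seed-position classes
#'   before (and after, if mutated), `n_WC_before`, `n_WC_after`,
#'   `disrupted`.
#' @export
seed_pairing <- function(site_seq, mirna_seq, site_start = 1L,
                         mutation = NULL, mirna_name = "miRNA") {
  site <- strsplit(toupper(gsub("T", "U", site_seq)), "")[[1]]
  mir <- strsplit(toupper(gsub("T", "U", mirna_seq)), "")[[1]]
  L <- length(site)
  if (L < 8) stop("site must cover the seed-complementary window (>= 8 nt)")
  if (length(mir) < 8) stop("miRNA sequence shorter than the seed (8 nt)")
  seed_k <- 2:8
  site_idx <- L - seed_k + 1L
  classes <- function(s) {
    cl <- pair_class(mir[seed_k], s[site_idx])
    names(cl) <- paste0("k", seed_k)
    cl
  }
  before <- classes(site)
  site_after <- site
  if (!is.null(mutation)) {
    off <- mutation$position - site_start + 1L
    if (off < 1 || off > L)
      stop("mutation position ", mutation$position, " outside the site")
    ref <- toupper(gsub("T", "U", mutation$ref))
    if (site[off] != ref)
      stop("mutation ref allele '", ref, "' does not match site base '",
           site[off], "' at position ", mutation$position)
    site_after[off] <- toupper(gsub("T", "U", mutation$alt))
  }
  after <- classes(site_after)
  n_before <- sum(before == "WC"); n_after <- sum(after == "WC")
  structure(list(mirna = mirna_name,
                 classes_before = before,
                 classes_after = after,
                 n_WC_before = n_before,
                 n_WC_after = n_after,
                 disrupted = n_after < n_before),
            class = "SeedPairingReport")
}

#' @export
print.SeedPairingReport <- function(x, ...) {
  cat("Seed pairing for", x$mirna, "\n")
  cat("  WC pairs in seed:", x$n_WC_before)
  if (!identical(x$classes_before, x$classes_after))
    cat(" -> ", x$n_WC_after, " after mutation", sep = "")
  cat("\n  disrupted:", x$disrupted, "\n")
  invisible(x)
}

#' Tally accessibility calls per annotation kind
#'
#' @param calls Data frame from [overlay_dms()] or [overlay_paris()].
#' @return Data frame with `kind`, `verdict`, `n`, and `pct` (one-decimal
#'   percentage of that kind's annotations); all-zero when `calls` is
#'   empty.
#' @export
tally_overlays <- function(calls) {
  verdicts <- c("increased_accessibility", "decreased_accessibility",
                "unchanged", "no_data")
  if (nrow(calls) == 0)
    return(data.frame(kind = character(0), verdict = character(0),
                      n = integer(0), pct = numeric(0), stringsAsFactors = FALSE))
  res <- expand.grid(kind = unique(calls$kind), verdict = verdicts,
                     stringsAsFactors = FALSE)
  res$n <- mapply(function(k, v) sum(calls$kind == k & calls$verdict == v),
                  res$kind, res$verdict)
  kind_totals <- table(calls$kind)
  res$pct <- mapply(function(k, n) pct(n, kind_totals[[k]]), res$kind, res$n)
  res[order(res$kind, res$verdict), ]
}
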