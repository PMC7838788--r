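#' Simulation parameters
#'
#' Defaults describe the regime the pipeline is meant to operate in: two
#' threshold-separable read-count distributions (structured low, unstructured
#' high, negative-binomial with moderate overdispersion), interior
#' missing-coverage blocks mimicking an expressed shorter isoform and an
#' unprobed central region, and PARIS reads with endpoint jitter, PCR
#' duplicates, sub-Q30 reads and off-transcript decoys.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param transcript_length,n_hairpins,n_pseudoknots Model size.
#' @param frac_paris_derived Fraction of hairpins tagged `paris_derived` in
#'   the catalog (excluded from DMS disruption tallies, as in the reference
#'   model where roughly a fifth of analyzable hairpins were PARIS-derived).
#' @param mu_structured,mu_unstructured Mean read counts of the two count
#'   regimes (defaults 50 and 600, separable by a 250-read threshold).
#' @param dispersion Negative-binomial overdispersion: variance is
#'   `mu + dispersion * mu^2`. `0` is the exact noise-free limit (every
#'   count equals its mean).
#' @param missing_blocks Two-column matrix of 1-based closed intervals with
#'   no DMS coverage; `NULL` uses two default interior blocks scaled to the
#'   transcript (the leading ~15% and a central ~19% block).
#' @param frac_unfolded Fraction of DMS-derived hairpins unfolded in the
#'   simulated condition (their positions draw from the high distribution).
#' @param frac_rearranged Fraction of hairpins whose PARIS reads are
#'   replaced by decoy duplexes at coordinates avoiding the true helices.
#' @param reads_per_helix,jitter_max PARIS reads emitted per surviving helix
#'   and the maximum per-endpoint jitter (nt).
#' @param dup_rate,lowq_rate,off_rate Rates of PCR-duplicate, sub-Q30, and
#'   off-transcript contaminant reads.
#' @return List of class `SimulationParams`.
#' @export
sim_params <- function(seed,
                       transcript_length = 2000,
                       n_hairpins = 20,
                       n_pseudoknots = 2,
                       frac_paris_derived = 0.15,
                       mu_structured = 50,
                       mu_unstructured = 600,
                       dispersion = 0.1,
                       missing_blocks = NULL,
                       frac_unfolded = 0.2,
                       frac_rearranged = 0.1,
                       reads_per_helix = 5,
                       jitter_max = 5,
                       dup_rate = 0.1,
                       lowq_rate = 0.1,
                       off_rate = 0.05) {
  if (is.null(missing_blocks)) {
    L <- transcript_length
    missing_blocks <- rbind(c(1L, as.integer(round(0.152 * L))),
                            c(as.integer(round(0.505 * L)),
                              as.integer(round(0.693 * L))))
  }
  p <- list(seed = as.integer(seed), transcript_length = as.integer(transcript_length),
            n_hairpins = as.integer(n_hairpins),
            n_pseudoknots = as.integer(n_pseudoknots),
            frac_paris_derived = frac_paris_derived,
            mu_structured = mu_structured, mu_unstructured = mu_unstructured,
            dispersion = dispersion, missing_blocks = missing_blocks,
            frac_unfolded = frac_unfolded, frac_rearranged = frac_rearranged,
            reads_per_helix = as.integer(reads_per_helix),
            jitter_max = as.integer(jitter_max),
            dup_rate = dup_rate, lowq_rate = lowq_rate, off_rate = off_rate)
  stopifnot(p$mu_structured > 0, p$mu_unstructured > 0, p$dispersion >= 0,
            p$frac_unfolded >= 0, p$frac_unfolded <= 1,
            p$frac_rearranged >= 0, p$frac_rearranged <= 1,
            p$dup_rate >= 0, p$dup_rate <= 1, p$lowq_rate >= 0, p$lowq_rate <= 1)
  class(p) <- "SimulationParams"
  p
}

COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

#' Generate a random structure model with catalog
#'
#' Places non-overlapping hairpins (stems 4-25 bp, Watson-Crick pairs only,
#' so every pair exposes exactly one informative A or C) separated by
#' unpaired gaps, plus optional pseudoknots pairing two unpaired intervals.
#' Deterministic for a given seed; the result always satisfies the
#' [validate_structure_model()] invariants.
#'
#' @param params A [sim_params()].
#' @return A `StructureModel` with hairpins `H1..Hn` and pseudoknots
#'   `PK1..PKm` in its catalog.
#' @export
gen_model <- function(params) {
  set.seed(params$seed)
  L <- params$transcript_length
  nh <- params$n_hairpins
  stems <- if (nh > 0) sample(4:25, nh, replace = TRUE) else integer(0)
  loops <- if (nh > 0) sample(12:20, nh, replace = TRUE) else integer(0)
  footprints <- 2 * stems + loops
  min_gap <- 8L
  if (nh > 0 && sum(footprints) + (nh + 1) * min_gap > L)
    stop("infeasible packing: ", nh, " hairpins do not fit in ", L, " nt")
  slack <- L - sum(footprints) - (nh + 1) * min_gap
  extra <- if (nh > 0) {
    u <- stats::runif(nh + 1)
    floor(slack * u / sum(u))
  } else slack
  pairing <- integer(L)
  bases <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
  hairpins <- list()
  pos <- 0L
  for (k in seq_len(nh)) {
    pos <- pos + min_gap + extra[k]
    s <- stems[k]; lp <- loops[k]
    i <- pos + seq_len(s)
    j <- pos + 2L * s + lp + 1L - seq_len(s)
    pairing[i] <- j; pairing[j] <- i
    bases[j] <- COMPLEMENT[bases[i]]
    hairpins[[k]] <- list(
      id = paste0("H", k),
      pairs = cbind(i = i, j = j),
      derivation = "dms_derived",
      span = c(min(i), max(j)))
    pos <- pos + 2L * s + lp
  }
  if (nh > 0 && params$frac_paris_derived > 0) {
    n_paris <- round(params$frac_paris_derived * nh)
    if (n_paris > 0) {
      idx <- sample(nh, n_paris)
      for (k in idx) hairpins[[k]]$derivation <- "paris_derived"
    }
  }
  pseudoknots <- list()
  if (params$n_pseudoknots > 0) {
    unpaired <- which(pairing == 0)
    for (q in seq_len(params$n_pseudoknots)) {
      arms <- find_pk_arms(pairing, arm_len = 6L, min_sep = 40L)
      if (is.null(arms)) break
      a1 <- arms[[1]]; a2 <- arms[[2]]
      pairs <- cbind(i = a1, j = rev(a2))
      pairing[pairs[, 1]] <- pairs[, 2]
      pairing[pairs[, 2]] <- pairs[, 1]
      bases[pairs[, 2]] <- COMPLEMENT[bases[pairs[, 1]]]
      pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
      pseudoknots[[length(pseudoknots) + 1]] <- list(
        id = paste0("PK", q), pairs = pairs,
        arm1 = c(min(a1), max(a1)), arm2 = c(min(a2), max(a2)))
    }
  }
  structure_model("synthetic", paste(bases, collapse = ""), pairing,
                  hairpins = hairpins, pseudoknots = pseudoknots)
}

# Two disjoint runs of unpaired positions, arm_len each, >= min_sep apart.
find_pk_arms <- function(pairing, arm_len, min_sep) {
  runs <- intervals_from_positions(which(pairing == 0))
  runs <- runs[runs[, 2] - runs[, 1] + 1 >= arm_len, , drop = FALSE]
  if (nrow(runs) < 2) return(NULL)
  for (attempt in seq_len(50)) {
    k <- sort(sample(nrow(runs), 2))
    a1 <- runs[k[1], 1] + seq_len(arm_len) - 1L
    a2 <- runs[k[2], 2] - arm_len + seq_len(arm_len)
    if (min(a2) - max(a1) >= min_sep) return(list(a1, a2))
  }
  NULL
}

#' Draw ground-truth perturbation labels
#'
#' Selects hairpins to unfold (DMS condition) and hairpins to rearrange
#' (PARIS condition), drawing decoy duplex coordinates for the latter.
#' Decoy arms avoid overlapping any true helix strand by 50% or more, so
#' truth labels stay unambiguous. Unfolding is restricted to DMS-derived
#' hairpins (PARIS-derived ones are excluded from disruption tallies
#' anyway). The per-position true pairing state reflects the unfolding.
#'
#' @param model A generated `StructureModel`.
#' @param params The same [sim_params()].
#' @return List of class `SyntheticTruth`: `unfolded` (hairpin ids),
#'   `rearranged` (data frame of element ids + decoy arm coordinates),
#'   `true_state` (per-position `"paired"`/`"unpaired"`).
#' @export
make_truth <- function(model, params) {
  set.seed(params$seed + 1L)
  L <- nchar(model$sequence)
  dms_ids <- vapply(Filter(function(h) h$derivation == "dms_derived",
                           model$hairpins), `[[`, "", "id")
  n_unfold <- round(params$frac_unfolded * length(dms_ids))
  unfolded <- if (n_unfold > 0) sort(sample(dms_ids, n_unfold)) else character(0)
  all_ids <- vapply(model$hairpins, `[[`, "", "id")
  n_rearr <- round(params$frac_rearranged * length(all_ids))
  rearr_ids <- if (n_rearr > 0) sort(sample(all_ids, n_rearr)) else character(0)
  rearranged <- do.call(rbind, lapply(rearr_ids, function(id) {
    decoy <- draw_decoy(model, L)
    data.frame(element_id = id, arm1_start = decoy[1], arm1_end = decoy[2],
               arm2_start = decoy[3], arm2_end = decoy[4],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rearranged))
    rearranged <- data.frame(element_id = character(0), arm1_start = integer(0),
                             arm1_end = integer(0), arm2_start = integer(0),
                             arm2_end = integer(0), stringsAsFactors = FALSE)
  true_state <- ifelse(model$pairing > 0, "paired", "unpaired")
  for (h in model$hairpins)
    if (h$id %in% unfolded) true_state[c(h$pairs)] <- "unpaired"
  structure(list(unfolded = unfolded, rearranged = rearranged,
                 true_state = true_state),
            class = "SyntheticTruth")
}

# Decoy duplex: two arms of 10-14 nt, neither overlapping any true helix
# strand by >= 50% of the arm, separated by a random gap.
draw_decoy <- function(model, L) {
  strands <- list()
  for (h in model$hairpins) {
    st <- element_strands(h)
    strands <- c(strands, list(range(st[[1]]), range(st[[2]])))
  }
  for (pk in model$pseudoknots) strands <- c(strands, list(pk$arm1, pk$arm2))
  ok_arm <- function(s, e) {
    len <- e - s + 1
    for (st in strands) {
      ov <- arm_overlap_len(s, e, st[1], st[2])
      # must fail the arm-to-strand match criterion against every strand
      if (ov >= min(ceiling(0.5 * len), 5, st[2] - st[1] + 1)) return(FALSE)
    }
    TRUE
  }
  for (attempt in seq_len(500)) {
    l1 <- sample(10:14, 1); l2 <- sample(10:14, 1)
    s1 <- sample(L - l1 - l2 - 30L, 1)
    gap <- sample(c(5:30, 100:300), 1)
    s2 <- s1 + l1 + gap
    if (s2 + l2 - 1 > L) next
    if (ok_arm(s1, s1 + l1 - 1) && ok_arm(s2, s2 + l2 - 1))
      return(c(s1, s1 + l1 - 1L, s2, s2 + l2 - 1L))
  }
  stop("could not place a decoy duplex avoiding the true helices")
}

#' Simulate a DMS-Seq count profile
#'
#' Emits counts only at A/C positions outside the missing blocks. Positions
#' paired in the truth draw from the low-mean (structured) distribution;
#' unpaired or unfolded positions draw from the high-mean (unstructured)
#' distribution. Counts are negative-binomial with variance
#' `mu + dispersion * mu^2`; `dispersion = 0` gives the exact noise-free
#' limit where every count equals its regime mean.
#'
#' @param model,truth,params Model, [make_truth()] labels, [sim_params()].
#' @return A [dms_profile()].
#' @export
simulate_dms <- function(model, truth, params) {
  set.seed(params$seed + 2L)
  L <- nchar(model$sequence)
  bases <- transcript_bases(model)
  covered <- rep(TRUE, L)
  mb <- params$missing_blocks
  for (k in seq_len(nrow(mb))) covered[seq.int(mb[k, 1], min(mb[k, 2], L))] <- FALSE
  idx <- which(bases %in% c("A", "C") & covered)
  mu <- ifelse(truth$true_state[idx] == "paired",
               params$mu_structured, params$mu_unstructured)
  counts <- if (params$dispersion == 0) as.integer(round(mu))
            else stats::rnbinom(length(idx), mu = mu, size = 1 / params$dispersion)
  dms_profile(model$transcript_id, idx, counts, L)
}

#' Simulate PARIS duplex reads
#'
#' Every surviving helix (hairpin or pseudoknot not marked rearranged)
#' emits `reads_per_helix` reads whose arm endpoints are jittered by at most
#' `jitter_max` nt; rearranged elements emit their reads at the decoy
#' coordinates from the truth instead. PCR duplicates (same barcode and
#' arms, new read id) are added at `dup_rate`, sub-Q30 reads at
#' `lowq_rate`, and off-transcript reads at `off_rate`. Deterministic per
#' seed.
#'
#' @param model,truth,params Model, [make_truth()] labels, [sim_params()].
#' @return A [paris_reads()] table.
#' @export
simulate_paris <- function(model, truth, params) {
  set.seed(params$seed + 3L)
  L <- nchar(model$sequence)
  arms_list <- list()
  for (h in model$hairpins) {
    if (h$id %in% truth$rearranged$element_id) {
      d <- truth$rearranged[truth$rearranged$element_id == h$id, ]
      arms_list[[h$id]] <- c(d$arm1_start, d$arm1_end, d$arm2_start, d$arm2_end)
    } else {
      st <- element_strands(h)
      arms_list[[h$id]] <- c(range(st[[1]]), range(st[[2]]))
    }
  }
  for (pk in model$pseudoknots)
    arms_list[[pk$id]] <- c(pk$arm1, pk$arm2)

  jitter <- function(x, lo, hi) {
    if (params$jitter_max == 0) return(x)
    max(lo, min(hi, x + sample(seq.int(-params$jitter_max, params$jitter_max), 1)))
  }
  rows <- list(); rid <- 0L
  emit <- function(a, quality) {
    rid <<- rid + 1L
    s1 <- jitter(a[1], 1L, L); e1 <- jitter(a[2], 1L, L)
    if (s1 > e1) { m <- (s1 + e1) %/% 2L; s1 <- m; e1 <- m }
    s2 <- jitter(a[3], 1L, L); e2 <- jitter(a[4], 1L, L)
    if (s2 > e2) { m <- (s2 + e2) %/% 2L; s2 <- m; e2 <- m }
    data.frame(read_id = sprintf("R%05d", rid),
               barcode = sprintf("BC%05d", rid),
               quality = quality,
               arm1_start = s1, arm1_end = e1, arm2_start = s2, arm2_end = e2,
               stringsAsFactors = FALSE)
  }
  for (id in names(arms_list))
    for (k in seq_len(params$reads_per_helix))
      rows[[length(rows) + 1]] <- emit(arms_list[[id]], sample(31:40, 1))
  base <- do.call(rbind, rows)
  # PCR duplicates: exact copies sharing barcode and arms, fresh read ids
  n_dup <- round(params$dup_rate * nrow(base))
  if (n_dup > 0) {
    src <- base[sample(nrow(base), n_dup, replace = TRUE), , drop = FALSE]
    src$read_id <- sprintf("R%05d", rid + seq_len(n_dup)); rid <- rid + n_dup
    base <- rbind(base, src)
  }
  n_lowq <- round(params$lowq_rate * length(arms_list) * params$reads_per_helix)
  if (n_lowq > 0) {
    ids <- sample(names(arms_list), n_lowq, replace = TRUE)
    lq <- do.call(rbind, lapply(ids, function(id)
      emit(arms_list[[id]], sample(20:29, 1))))
    base <- rbind(base, lq)
  }
  n_off <- round(params$off_rate * length(arms_list) * params$reads_per_helix)
  if (n_off > 0) {
    off <- do.call(rbind, lapply(seq_len(n_off), function(k) {
      rid <<- rid + 1L
      data.frame(read_id = sprintf("R%05d", rid), barcode = sprintf("BC%05d", rid),
                 quality = sample(31:40, 1),
                 arm1_start = L + 10L, arm1_end = L + 25L,
                 arm2_start = L + 60L, arm2_end = L + 75L,
                 stringsAsFactors = FALSE)
    }))
    base <- rbind(base, off)
  }
  do.call(paris_reads, base)
}

#' Score pipeline recovery against the synthetic truth
#'
#' Standard 2x2 tallies. Disrupted-hairpin detection is scored over
#' DMS-derived hairpins whose every pair is evaluable (fully probed), since
#' hairpins inside coverage gaps carry no signal by construction — the same
#' restriction the analysis applies to real data. Divergent-group detection
#' is scored per rearranged element: detected when some divergent group arm
#' overlaps its decoy coordinates; spurious divergent groups count against
#' specificity via the non-rearranged elements' consistent groups.
#'
#' @param disruptions [disruption_table()] output for the simulated DMS run.
#' @param groups [classify_groups()] output for the simulated PARIS run, or
#'   `NULL` for a DMS-only simulation.
#' @param truth The [make_truth()] labels.
#' @return List with `hairpin` (sensitivity, specificity, tp/fp/tn/fn) and
#'   `duplex` (n_rearranged, n_detected, sensitivity, n_false_divergent;
#'   `NULL` when `groups` is `NULL`).
#' @export
score_recovery <- function(disruptions, groups, truth) {
  d <- disruptions[disruptions$derivation == "dms_derived" &
                   disruptions$n_pairs_evaluable == disruptions$n_pairs_total, ,
                   drop = FALSE]
  is_unfolded <- d$hairpin_id %in% truth$unfolded
  tp <- sum(d$disrupted & is_unfolded)
  fn <- sum(!d$disrupted & is_unfolded)
  fp <- sum(d$disrupted & !is_unfolded)
  tn <- sum(!d$disrupted & !is_unfolded)
  hairpin <- list(tp = tp, fp = fp, tn = tn, fn = fn,
                  sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                  specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  if (is.null(groups)) return(list(hairpin = hairpin, duplex = NULL))
  div <- groups[groups$model_status == "divergent", , drop = FALSE]
  detected <- vapply(seq_len(nrow(truth$rearranged)), function(k) {
    r <- truth$rearranged[k, ]
    any(interval_overlaps(div$arm1_start, div$arm1_end, r$arm1_start, r$arm1_end) &
        interval_overlaps(div$arm2_start, div$arm2_end, r$arm2_start, r$arm2_end))
  }, logical(1))
  hits_decoy <- rep(FALSE, nrow(div))
  for (k in seq_len(nrow(truth$rearranged))) {
    r <- truth$rearranged[k, ]
    hits_decoy <- hits_decoy |
      (interval_overlaps(div$arm1_start, div$arm1_end, r$arm1_start, r$arm1_end) &
       interval_overlaps(div$arm2_start, div$arm2_end, r$arm2_start, r$arm2_end))
  }
  duplex <- list(n_rearranged = nrow(truth$rearranged),
                 n_detected = sum(detected),
                 sensitivity = if (nrow(truth$rearranged) > 0)
                   mean(detected) else NA_real_,
                 n_false_divergent = sum(!hits_decoy))
  list(hairpin = hairpin, duplex = duplex)
}

#' Write simulated datasets in the pipeline's input formats
#'
#' Emits the DMS counts TSV, the PARIS reads TSV, the model CT + catalog
#' TSV, and a truth JSON into a directory, so that generated data always
#' round-trips through the same readers real data would use.
#'
#' @param model,truth,profile,reads Simulation outputs.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(model, truth, profile, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- transcript_bases(model)
  pos <- which(!is.na(profile$counts))
  write_tsv_with_header(
    data.frame(position = pos, base = bases[pos], reads = profile$counts[pos]),
    file.path(dir, "dms_counts.tsv"))
  write_tsv_with_header(as.data.frame(reads), file.path(dir, "paris_reads.tsv"))
  writeLines(write_ct(model), file.path(dir, "model.ct"))
  cat_rows <- rbind(
    do.call(rbind, lapply(model$hairpins, function(h)
      data.frame(id = h$id, type = "hairpin", derivation = h$derivation,
                 pairs = paste(h$pairs[, 1], h$pairs[, 2], sep = "-", collapse = ";"),
                 stringsAsFactors = FALSE))),
    do.call(rbind, lapply(model$pseudoknots, function(pk)
      data.frame(id = pk$id, type = "pseudoknot", derivation = "paris_derived",
                 pairs = paste(pk$pairs[, 1], pk$pairs[, 2], sep = "-", collapse = ";"),
                 stringsAsFactors = FALSE))))
  write_tsv_with_header(cat_rows, file.path(dir, "catalog.tsv"))
  jsonlite::write_json(list(unfolded = truth$unfolded,
                            rearranged = truth$rearranged,
                            true_state = truth$true_state),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
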