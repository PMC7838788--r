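# Independent brute-force oracles. These deliberately re-derive each quantity
# by the most literal route available (per-position loops, transitive closure,
# full enumeration) and share no code with the implementation.

# Two-stack (multi-alphabet) dot-bracket re-parse, written independently of
# parse_dotbracket: scans once per bracket alphabet.
oracle_dotbracket_pairs <- function(structure) {
  opens <- c("(", "[", "{", "<", "A", "B")
  closes <- c(")", "]", "}", ">", "a", "b")
  chars <- strsplit(structure, "")[[1]]
  pairs <- NULL
  for (L in seq_along(opens)) {
    stack <- integer(0)
    for (i in seq_along(chars)) {
      if (chars[i] == opens[L]) stack <- c(stack, i)
      else if (chars[i] == closes[L]) {
        pairs <- rbind(pairs, c(stack[length(stack)], i))
        stack <- stack[-length(stack)]
      }
    }
  }
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2))
  pairs[order(pairs[, 1]), , drop = FALSE]
}

pairing_to_set <- function(pairing) {
  i <- which(pairing > seq_along(pairing))
  if (!length(i)) return(character(0))
  sort(paste(i, pairing[i], sep = "-"))
}

# Position-by-position recount of delta categories.
oracle_delta_counts <- function(calls, model) {
  out <- c(agree = 0L, loss = 0L, gain = 0L, no_data = 0L)
  for (p in seq_len(nchar(model$sequence))) {
    cl <- calls$calls[p]
    if (!cl %in% c("structured", "unstructured")) {
      out["no_data"] <- out["no_data"] + 1L
    } else {
      paired <- model$pairing[p] > 0
      if (paired && cl == "unstructured") out["loss"] <- out["loss"] + 1L
      else if (!paired && cl == "structured") out["gain"] <- out["gain"] + 1L
      else out["agree"] <- out["agree"] + 1L
    }
  }
  out
}

# Exhaustive per-pair recount of lost pairs under the either-partner rule.
oracle_lost_count <- function(hairpin, calls) {
  lost <- 0L
  for (k in seq_len(nrow(hairpin$pairs))) {
    i <- hairpin$pairs[k, 1]; j <- hairpin$pairs[k, 2]
    if (calls$calls[i] == "unstructured" || calls$calls[j] == "unstructured")
      lost <- lost + 1L
  }
  lost
}

# Single-linkage transitive closure over an explicit adjacency matrix.
oracle_compress_components <- function(reads, config) {
  n <- nrow(reads)
  link <- function(i, j) {
    ov <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2) + 1)
    o1 <- ov(reads$arm1_start[i], reads$arm1_end[i],
             reads$arm1_start[j], reads$arm1_end[j])
    o2 <- ov(reads$arm2_start[i], reads$arm2_end[i],
             reads$arm2_start[j], reads$arm2_end[j])
    if (o1 < 1 || o2 < 1) return(FALSE)
    offs <- c(abs(reads$arm1_start[i] - reads$arm1_start[j]),
              abs(reads$arm1_end[i] - reads$arm1_end[j]),
              abs(reads$arm2_start[i] - reads$arm2_start[j]),
              abs(reads$arm2_end[i] - reads$arm2_end[j]))
    all(offs <= config$compress_max_offset)
  }
  adj <- diag(n) == 1
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (link(i, j)) adj[i, j] <- adj[j, i] <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comps <- unique(apply(reach, 1, function(r) paste(which(r), collapse = ",")))
  lapply(strsplit(comps, ","), function(x) reads$read_id[as.integer(x)])
}

# Exhaustive search over catalog elements for the duplex-match status.
oracle_match_status <- function(group, model, config) {
  cover <- function(s, e, positions) {
    len <- e - s + 1
    req <- min(ceiling(config$match_min_frac * len), config$match_min_nt,
               length(positions))
    sum(positions >= s & positions <= e) >= req
  }
  for (el in c(model$hairpins, model$pseudoknots)) {
    if (!is.null(el$derivation)) {
      s1 <- el$pairs[, 1]; s2 <- el$pairs[, 2]
    } else {
      s1 <- el$arm1[1]:el$arm1[2]; s2 <- el$arm2[1]:el$arm2[2]
    }
    if ((cover(group$arm1_start, group$arm1_end, s1) &&
         cover(group$arm2_start, group$arm2_end, s2)) ||
        (cover(group$arm1_start, group$arm1_end, s2) &&
         cover(group$arm2_start, group$arm2_end, s1)))
      return("consistent")
  }
  "divergent"
}

# U as a literal pair count: wins of a over b, halves for ties.
oracle_u_paircount <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Exact two-sided permutation p value for the U statistic at small n.
oracle_u_exact_p <- function(a, b) {
  pooled <- c(a, b); n1 <- length(a); N <- length(pooled)
  mu <- n1 * (N - n1) / 2
  obs <- abs(oracle_u_paircount(a, b) - mu)
  sets <- utils::combn(N, n1)
  stat <- apply(sets, 2, function(idx)
    abs(oracle_u_paircount(pooled[idx], pooled[-idx]) - mu))
  mean(stat >= obs - 1e-9)
}

# Small random model for property/oracle tests (always feasible at 200 nt).
rand_small_model <- function(seed) {
  gen_model(sim_params(seed, transcript_length = 200, n_hairpins = 2,
                       n_pseudoknots = 1))
}

# Random call track over a model: each A/C position independently
# structured / unstructured / no_data.
rand_calls <- function(model, seed) {
  set.seed(seed)
  n <- nchar(model$sequence)
  bases <- strsplit(model$sequence, "")[[1]]
  calls <- rep("not_AC", n)
  ac <- which(bases %in% c("A", "C"))
  calls[ac] <- sample(c("structured", "unstructured", "no_data"),
                      length(ac), replace = TRUE, prob = c(0.4, 0.4, 0.2))
  structure(list(transcript_id = model$transcript_id, calls = calls,
                 counts = rep(NA_integer_, n)),
            class = "StructureCallTrack")
}

# Random jittered read cloud around a few true duplexes, plus loners.
rand_reads <- function(seed, n_centers = 3, per_center = 6, jitter = 25) {
  set.seed(seed)
  rows <- list()
  rid <- 0
  for (c in seq_len(n_centers)) {
    a1 <- sort(sample(1:400, 1)) + c(0, sample(8:15, 1))
    a2 <- a1[2] + sample(30:200, 1) + c(0, sample(8:15, 1))
    for (k in seq_len(per_center)) {
      rid <- rid + 1
      j <- function(x) x + sample(seq(-jitter, jitter), 1)
      s1 <- j(a1[1]); e1 <- max(s1, j(a1[2]))
      s2 <- max(e1 + 2, j(a2[1])); e2 <- max(s2, j(a2[2]))
      rows[[rid]] <- data.frame(read_id = sprintf("r%03d", rid),
                                barcode = sprintf("bc%03d", rid),
                                quality = 35,
                                arm1_start = s1, arm1_end = e1,
                                arm2_start = s2, arm2_end = e2)
    }
  }
  do.call(paris_reads, do.call(rbind, rows))
}

toy_hairpin <- function(pairs_mat, id = "H1", derivation = "dms_derived") {
  list(id = id, pairs = pairs_mat, derivation = derivation,
       span = c(min(pairs_mat), max(pairs_mat)))
}
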