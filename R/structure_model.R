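#' Reference secondary-structure model
#'
#' A `StructureModel` bundles a transcript sequence, its base-pairing table,
#' and a catalog of named hairpins and pseudoknots. It is the fixed reference
#' that probing data (DMS-Seq counts, PARIS duplex reads) are compared
#' against; the model itself is never refolded from the data.
#'
#' Coordinates are 1-based and inclusive throughout. The pairing table is a
#' full-length integer vector with `0` marking an unpaired position; it must
#' be symmetric (`pairing[pairing[i]] == i`) and irreflexive. `N` bases are
#' tolerated in the sequence but may not be paired.
#'
#' @param transcript_id Character scalar naming the transcript.
#' @param sequence RNA sequence over `A`, `C`, `G`, `U`, `N` (DNA `T` is
#'   converted to `U` on input).
#' @param pairing Integer vector, one entry per nucleotide; `pairing[i]` is
#'   the partner of position `i`, or `0` if unpaired.
#' @param hairpins List of hairpin records as built by [load_catalog()].
#' @param pseudoknots List of pseudoknot records as built by [load_catalog()].
#' @return An object of class `StructureModel`.
#' @seealso [parse_dotbracket()], [parse_ct()], [load_catalog()]
#' @export
structure_model <- function(transcript_id, sequence, pairing,
                            hairpins = list(), pseudoknots = list()) {
  sequence <- toupper(gsub("T", "U", as.character(sequence)[1], fixed = TRUE))
  pairing <- as.integer(pairing)
  m <- structure(
    list(transcript_id = as.character(transcript_id)[1],
         sequence = sequence,
         pairing = pairing,
         hairpins = hairpins,
         pseudoknots = pseudoknots),
    class = "StructureModel")
  validate_structure_model(m)
  m
}

#' Validate a StructureModel
#'
#' Checks the invariants every model must satisfy: alphabet, pairing symmetry
#' and irreflexivity, no paired `N`, and catalog consistency (every catalog
#' pair present in the pairing table, unique ids, ordered pair endpoints).
#' Called by every constructor and parser; exported so readers of external
#' files can re-assert after manual edits.
#'
#' @param m A `StructureModel`.
#' @return `m`, invisibly; stops with a descriptive error on violation.
#' @export
validate_structure_model <- function(m) {
  stopifnot(inherits(m, "StructureModel"))
  n <- nchar(m$sequence)
  bases <- transcript_bases(m)
  bad <- which(!bases %in% c("A", "C", "G", "U", "N"))
  if (length(bad))
    stop("invalid base '", bases[bad[1]], "' at position ", bad[1])
  if (length(m$pairing) != n)
    stop("pairing table length ", length(m$pairing),
         " does not match sequence length ", n)
  if (any(m$pairing < 0 | m$pairing > n))
    stop("pairing partner out of range")
  paired <- which(m$pairing > 0)
  if (any(m$pairing[paired] == paired))
    stop("self-paired position ", paired[which(m$pairing[paired] == paired)[1]])
  asym <- paired[m$pairing[m$pairing[paired]] != paired]
  if (length(asym))
    stop("pairing table not symmetric at position ", asym[1])
  if (any(bases[paired] == "N"))
    stop("N base cannot be paired (position ",
         paired[which(bases[paired] == "N")[1]], ")")

  ids <- c(vapply(m$hairpins, `[[`, "", "id"),
           vapply(m$pseudoknots, `[[`, "", "id"))
  if (anyDuplicated(ids))
    stop("duplicate catalog id: ", ids[duplicated(ids)][1])
  for (h in m$hairpins) check_catalog_pairs(m, h$id, h$pairs)
  for (pk in m$pseudoknots) {
    check_catalog_pairs(m, pk$id, pk$pairs)
    if (pk$arm1[2] >= pk$arm2[1])
      stop(pk$id, ": arm1 must precede arm2 and arms must be disjoint")
  }
  invisible(m)
}

check_catalog_pairs <- function(m, id, pairs) {
  if (!is.matrix(pairs) || ncol(pairs) != 2 || nrow(pairs) == 0)
    stop(id, ": pair list must be a non-empty two-column matrix")
  if (any(pairs[, 1] >= pairs[, 2]))
    stop(id, ": every pair (i,j) must satisfy i < j")
  missing <- which(m$pairing[pairs[, 1]] != pairs[, 2])
  if (length(missing))
    stop(id, ": pair ", pairs[missing[1], 1], "-", pairs[missing[1], 2],
         " absent from the model pairing table")
  invisible(NULL)
}

transcript_bases <- function(m) strsplit(m$sequence, "", fixed = TRUE)[[1]]

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", x$transcript_id, "\n")
  cat("  length:", nchar(x$sequence), "nt;",
      sum(x$pairing > 0) / 2, "base pairs\n")
  cat("  catalog:", length(x$hairpins), "hairpins,",
      length(x$pseudoknots), "pseudoknots\n")
  invisible(x)
}

# Bracket alphabets for pseudoknot layers, in nesting order.
BRACKET_OPEN  <- c("(", "[", "{", "<", "A", "B")
BRACKET_CLOSE <- c(")", "]", "}", ">", "a", "b")

#' Parse dot-bracket notation with pseudoknot layers
#'
#' Parses layered dot-bracket structure strings into a [structure_model()].
#' Each bracket alphabet — `()`, `[]`, `{}`, `<>`, `Aa`, `Bb` — is an
#' independent nesting layer, so crossing (pseudoknotted) pairings are
#' representable by putting them in different layers. Unpaired positions are
#' `.`; `-`, `:` and `,` are accepted as unpaired synonyms.
#'
#' @param sequence RNA sequence, same length as `structure`.
#' @param structure Dot-bracket string.
#' @param transcript_id Transcript name for the resulting model.
#' @return A `StructureModel` with an empty hairpin/pseudoknot catalog.
#' @examples
#' m <- parse_dotbracket("GGGAAACCC", "(((...)))")
#' m$pairing
#' @export
parse_dotbracket <- function(sequence, structure, transcript_id = "transcript") {
  sequence <- as.character(sequence)[1]
  structure <- as.character(structure)[1]
  if (nchar(sequence) != nchar(structure))
    stop("sequence length (", nchar(sequence),
         ") and structure length (", nchar(structure), ") differ")
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pairing <- integer(n)
  stacks <- rep(list(integer(0)), length(BRACKET_OPEN))
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c(".", "-", ":", ",")) next
    layer <- match(ch, BRACKET_OPEN)
    if (!is.na(layer)) {
      stacks[[layer]] <- c(stacks[[layer]], i)
      next
    }
    layer <- match(ch, BRACKET_CLOSE)
    if (is.na(layer))
      stop("unrecognized structure character '", ch, "' at position ", i)
    if (length(stacks[[layer]]) == 0)
      stop("unbalanced '", ch, "' at position ", i, ": no matching open bracket")
    j <- stacks[[layer]][length(stacks[[layer]])]
    stacks[[layer]] <- stacks[[layer]][-length(stacks[[layer]])]
    pairing[j] <- i
    pairing[i] <- j
  }
  for (layer in seq_along(stacks))
    if (length(stacks[[layer]]))
      stop("unbalanced '", BRACKET_OPEN[layer], "' at position ",
           stacks[[layer]][1], ": never closed")
  structure_model(transcript_id, sequence, pairing)
}

#' Write a model as layered dot-bracket notation
#'
#' Inverse of [parse_dotbracket()] on the pairing set: pairs are assigned
#' greedily to the first bracket layer in which they do not cross any pair
#' already placed there, so nested structures use `()` and pseudoknots spill
#' into `[]`, `{}`, ... as needed.
#'
#' @param m A `StructureModel`.
#' @return Dot-bracket string of the same length as the sequence.
#' @export
write_dotbracket <- function(m) {
  n <- nchar(m$sequence)
  out <- rep(".", n)
  opens <- which(m$pairing > seq_len(n))
  if (length(opens) == 0) return(paste(out, collapse = ""))
  pairs <- cbind(opens, m$pairing[opens])
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  layers <- rep(list(NULL), length(BRACKET_OPEN))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    placed <- FALSE
    for (L in seq_along(layers)) {
      lp <- layers[[L]]
      crossing <- !is.null(lp) &&
        any((lp[, 1] < i & i < lp[, 2] & lp[, 2] < j) |
            (i < lp[, 1] & lp[, 1] < j & j < lp[, 2]))
      if (!crossing) {
        layers[[L]] <- rbind(lp, c(i, j))
        out[i] <- BRACKET_OPEN[L]
        out[j] <- BRACKET_CLOSE[L]
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("pairing too entangled for ", length(layers), " bracket layers")
  }
  paste(out, collapse = "")
}

#' Read and write CT (connectivity table) format
#'
#' `parse_ct()` reads the standard six-column CT layout (index, base,
#' previous index, next index, partner index or 0, renumbering index) with a
#' header line giving the length and a title. `write_ct()` emits it.
#' `parse_ct(write_ct(m))` is the identity on sequence and pairing.
#'
#' @param text Character vector of CT lines, or a single string with
#'   embedded newlines, or a file path (for `parse_ct`).
#' @return `parse_ct`: a `StructureModel` (empty catalog). `write_ct`: a
#'   single string of CT text.
#' @export
parse_ct <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  if (length(text) == 1) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(trimws(text))]
  if (length(text) < 1) stop("empty CT input")
  header <- strsplit(trimws(text[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[1]))
  if (is.na(n)) stop("CT header must begin with the sequence length")
  title <- if (length(header) > 1) paste(header[-1], collapse = " ") else "transcript"
  if (length(text) - 1 != n)
    stop("CT declares ", n, " nucleotides but has ", length(text) - 1, " rows")
  fields <- do.call(rbind, lapply(text[-1], function(l) strsplit(trimws(l), "\\s+")[[1]][1:6]))
  idx <- as.integer(fields[, 1])
  if (!identical(idx, seq_len(n))) stop("CT rows not consecutively numbered from 1")
  partner <- as.integer(fields[, 5])
  if (anyNA(partner)) stop("non-numeric partner column in CT input")
  paired <- which(partner > 0)
  bad <- paired[partner[partner[paired]] != paired]
  if (length(bad))
    stop("asymmetric partner columns at CT row ", bad[1])
  structure_model(title, paste(fields[, 2], collapse = ""), partner)
}

#' @rdname parse_ct
#' @param m A `StructureModel`.
#' @export
write_ct <- function(m) {
  n <- nchar(m$sequence)
  bases <- transcript_bases(m)
  rows <- sprintf("%d %s %d %d %d %d",
                  seq_len(n), bases,
                  seq_len(n) - 1L,
                  c(seq_len(n - 1) + 1L, 0L),
                  m$pairing, seq_len(n))
  paste(c(paste(n, m$transcript_id), rows), collapse = "\n")
}

#' Attach a hairpin/pseudoknot catalog to a model
#'
#' The catalog of named structural elements (H1..Hn hairpins, PK1..PKn
#' pseudoknots) is an input artifact supplied as a table, never recomputed
#' from the pairing: element numbering is authoritative. Each row names one
#' element with its base pairs; every pair must already exist in the model's
#' pairing table.
#'
#' @param m A `StructureModel`.
#' @param catalog Data frame with columns `id`, `type` (`"hairpin"` or
#'   `"pseudoknot"`), `derivation` (`"dms_derived"` or `"paris_derived"`),
#'   and `pairs` (semicolon-separated `"i-j"` pairs), as read by
#'   [read_catalog()].
#' @return `m` with `hairpins` and `pseudoknots` populated.
#' @export
load_catalog <- function(m, catalog) {
  stopifnot(inherits(m, "StructureModel"), is.data.frame(catalog))
  if (nrow(catalog) == 0) return(m)
  need <- c("id", "type", "derivation", "pairs")
  if (!all(need %in% names(catalog)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  hairpins <- list(); pseudoknots <- list()
  for (k in seq_len(nrow(catalog))) {
    row <- catalog[k, ]
    pairs <- parse_pair_list(row$pairs)
    check_catalog_pairs(m, row$id, pairs)
    if (row$type == "hairpin") {
      hairpins[[length(hairpins) + 1]] <- list(
        id = row$id, pairs = pairs,
        derivation = match.arg(row$derivation, c("dms_derived", "paris_derived")),
        span = c(min(pairs), max(pairs)))
    } else if (row$type == "pseudoknot") {
      pseudoknots[[length(pseudoknots) + 1]] <- list(
        id = row$id, pairs = pairs,
        arm1 = c(min(pairs[, 1]), max(pairs[, 1])),
        arm2 = c(min(pairs[, 2]), max(pairs[, 2])))
    } else stop("unknown catalog type '", row$type, "' for ", row$id)
  }
  m$hairpins <- c(m$hairpins, hairpins)
  m$pseudoknots <- c(m$pseudoknots, pseudoknots)
  validate_structure_model(m)
}

parse_pair_list <- function(s) {
  items <- strsplit(trimws(as.character(s)), ";", fixed = TRUE)[[1]]
  items <- items[nzchar(items)]
  if (length(items) == 0) stop("empty pair list")
  mat <- do.call(rbind, lapply(items, function(x) {
    ij <- suppressWarnings(as.integer(strsplit(trimws(x), "-", fixed = TRUE)[[1]]))
    if (length(ij) != 2 || anyNA(ij)) stop("malformed pair '", x, "'")
    sort(ij)
  }))
  colnames(mat) <- c("i", "j")
  mat[order(mat[, 1]), , drop = FALSE]
}

#' Read a catalog TSV
#'
#' Columns: `id`, `type` (hairpin/pseudoknot), `derivation`, `pairs`
#' (semicolon-separated `i-j`). Lines starting with `#` are comments.
#'
#' @param path Path to a tab-separated catalog file.
#' @return Data frame suitable for [load_catalog()].
#' @export
read_catalog <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Dump a model (with catalog) as JSON
#'
#' @param m A `StructureModel`.
#' @param path Optional output file; if `NULL`, the JSON string is returned.
#' @export
write_model_json <- function(m, path = NULL) {
  obj <- list(
    transcript_id = m$transcript_id,
    sequence = m$sequence,
    pairing = m$pairing,
    hairpins = lapply(m$hairpins, function(h)
      list(id = h$id, derivation = h$derivation, span = h$span,
           pairs = apply(h$pairs, 1, function(p) paste(p, collapse = "-")))),
    pseudoknots = lapply(m$pseudoknots, function(pk)
      list(id = pk$id, arm1 = pk$arm1, arm2 = pk$arm2,
           pairs = apply(pk$pairs, 1, function(p) paste(p, collapse = "-")))))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

model_element <- function(m, id) {
  for (h in m$hairpins) if (h$id == id) return(h)
  for (pk in m$pseudoknots) if (pk$id == id) return(pk)
  stop("no catalog element with id '", id, "'")
}
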