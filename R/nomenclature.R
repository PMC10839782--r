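#' Parse a bracket-notation repeat structure
#'
#' Sequence-level STR alleles are written as ordered motif blocks, e.g.
#' `"[TCTA]4[TCTG]6"`, optionally followed by a bare partial repeat unit
#' (`"[AGAT]9 AGA"` is the 9.3 microvariant of a tetranucleotide marker).
#' Whitespace between tokens is ignored.
#'
#' @param text Bracket-notation string.
#' @param period Repeat-unit length of the marker (2-6 bases).
#' @return An object of class `repeat_structure`: a list with `blocks`
#'   (data.frame with columns `motif`, `count`), `partial` (possibly empty
#'   string) and `period`.
#' @examples
#' parse_bracket_notation("[TCTA]4[TCTG]6", period = 4)
#' parse_bracket_notation("[AGAT]9 AGA", period = 4)
#' @export
parse_bracket_notation <- function(text, period) {
  stopifnot(is.character(text), length(text) == 1L)
  period <- as.integer(period)
  if (is.na(period) || period < 2L || period > 6L)
    stop("'period' must be an integer in 2..6")
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s)) stop("empty allele string")

  motifs <- character(0)
  counts <- integer(0)
  while (startsWith(s, "[")) {
    m <- regmatches(s, regexec("^\\[([A-Za-z]*)\\]([0-9]+)", s))[[1]]
    if (length(m) == 0L) {
      tok <- substr(s, 1L, min(nchar(s), 16L))
      stop(sprintf("malformed bracket block at '%s'", tok))
    }
    motif <- toupper(m[2])
    if (!grepl("^[ACGT]{2,6}$", motif))
      stop(sprintf("invalid motif '%s' (need 2-6 bases of ACGT)", m[2]))
    count <- as.integer(m[3])
    if (count < 1L) stop(sprintf("block count must be >= 1 in '%s'", m[1]))
    motifs <- c(motifs, motif)
    counts <- c(counts, count)
    s <- substr(s, nchar(m[1]) + 1L, nchar(s))
  }
  if (length(motifs) == 0L)
    stop(sprintf("no bracket block found in '%s'", text))

  partial <- ""
  if (nzchar(s)) {
    partial <- toupper(s)
    if (!grepl("^[ACGT]+$", partial))
      stop(sprintf("invalid trailing token '%s' (non-ACGT characters)", s))
    if (nchar(partial) >= period)
      stop(sprintf("partial unit '%s' has length >= period %d", partial, period))
  }

  structure(
    list(blocks = data.frame(motif = motifs, count = counts,
                             stringsAsFactors = FALSE),
         partial = partial, period = period),
    class = "repeat_structure")
}

#' Emit the bracket-notation string of a repeat structure
#'
#' Inverse of [parse_bracket_notation()]: blocks in order, single spaces,
#' partial unit appended bare.
#'
#' @param structure A `repeat_structure`.
#' @return A single bracket-notation string.
#' @export
emit_bracket_notation <- function(structure) {
  stopifnot(inherits(structure, "repeat_structure"))
  blocks <- paste0("[", structure$blocks$motif, "]", structure$blocks$count)
  out <- paste(blocks, collapse = "")
  if (nzchar(structure$partial)) out <- paste(out, structure$partial)
  out
}

#' @export
print.repeat_structure <- function(x, ...) {
  cat("STR repeat structure (period", x$period, "):",
      emit_bracket_notation(x), "\n")
  cat("CE designation:", ce_designation(x), "\n")
  invisible(x)
}

#' CE allele designation of a repeat structure
#'
#' The capillary-electrophoresis designation is the total repeat count
#' (sum of block counts), with a `.k` microvariant suffix when `k` extra
#' bases remain beyond full repeat units (e.g. `"9.3"`).
#'
#' @param structure A `repeat_structure` (or a bracket string together with
#'   `period`).
#' @param period Only used when `structure` is a character string.
#' @return Decimal designation string such as `"9"` or `"9.3"`.
#' @examples
#' ce_designation(parse_bracket_notation("[AGAT]9 AGA", 4)) # "9.3"
#' @export
ce_designation <- function(structure, period = NULL) {
  if (is.character(structure))
    structure <- parse_bracket_notation(structure, period)
  stopifnot(inherits(structure, "repeat_structure"))
  total <- sum(structure$blocks$count)
  if (nzchar(structure$partial))
    paste0(total, ".", nchar(structure$partial))
  else
    as.character(total)
}

# TRUE for cells already carrying a plain CE designation ("9", "9.3").
is_ce_label <- function(x) grepl("^[0-9]+(\\.[0-9]+)?$", x)

#' Collapse allele labels to length (CE) resolution
#'
#' Maps each sequence-level (bracket-notation) label to its CE designation;
#' labels already at length level pass through unchanged. Distinct sequence
#' alleles sharing a CE designation become one length allele (many-to-one).
#' Missing values are preserved. Multi-copy cells (comma-joined labels) are
#' collapsed component-wise.
#'
#' @param labels Character vector of allele labels.
#' @param period Repeat-unit length of the marker.
#' @return Character vector of CE designations.
#' @export
collapse_to_length <- function(labels, period) {
  # tables repeat the same few labels thousands of times: collapse each
  # distinct label once and map back
  u <- unique(labels)
  mapped <- vapply(u, function(lab) {
    if (is.na(lab) || !nzchar(lab)) return(NA_character_)
    parts <- strsplit(lab, ",", fixed = TRUE)[[1]]
    parts <- vapply(parts, function(p) {
      p <- trimws(p)
      if (is_ce_label(p)) p else ce_designation(p, period)
    }, character(1))
    paste(parts, collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  mapped[match(labels, u)]
}

#' Distinct-allele inventory of a genotype table
#'
#' Counts, per marker, the distinct alleles observed at least once, either at
#' sequence resolution (labels as stored) or after collapsing to CE length
#' designations. For multi-copy Y markers each component of the cell is an
#' allele. Sequence-level counts can never be below length-level counts.
#'
#' @param tab A `genotype_table`.
#' @param level `"length"` or `"sequence"`.
#' @return A data.frame with columns `marker`, `class`, `n_alleles`, plus a
#'   `"totals"` attribute: named vector with per-class and overall totals.
#' @export
allele_inventory <- function(tab, level = c("sequence", "length")) {
  level <- match.arg(level)
  stopifnot(inherits(tab, "genotype_table"))
  panel <- attr(tab, "panel")
  if (nrow(tab) == 0L) stop("empty genotype table")
  counts <- integer(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    labs <- marker_alleles(tab, panel$marker[i])
    if (level == "length")
      labs <- collapse_to_length(labs, panel$period[i])
    labs <- unlist(strsplit(labs[!is.na(labs)], ",", fixed = TRUE))
    counts[i] <- length(unique(labs))
  }
  out <- data.frame(marker = panel$marker,
                    class = panel$class,
                    n_alleles = counts,
                    stringsAsFactors = FALSE)
  cls <- ifelse(out$class == "autosomal", "autosomal", "y")
  totals <- c(tapply(out$n_alleles, cls, sum), total = sum(out$n_alleles))
  attr(out, "totals") <- totals
  attr(out, "level") <- level
  out
}

#' Added alleles and growth rate from length to sequence resolution
#'
#' For each marker, how many extra alleles sequence resolution reveals over
#' length resolution, and the relative growth in percent. Markers whose
#' allele count more than doubles (growth > 100%) are flagged.
#'
#' @param len_counts,seq_counts Inventories as returned by
#'   [allele_inventory()] at the two levels (or data.frames with columns
#'   `marker`, `n_alleles`), computed from the same table.
#' @return A data.frame with columns `marker`, `n_length`, `n_sequence`,
#'   `added`, `growth_pct`, `doubled`.
#' @export
allele_growth <- function(len_counts, seq_counts) {
  stopifnot(all(c("marker", "n_alleles") %in% names(len_counts)),
            all(c("marker", "n_alleles") %in% names(seq_counts)))
  m <- merge(len_counts[, c("marker", "n_alleles")],
             seq_counts[, c("marker", "n_alleles")],
             by = "marker", suffixes = c(".len", ".seq"))
  if (any(m$n_alleles.len == 0L))
    stop("marker with zero length-level alleles: ",
         paste(m$marker[m$n_alleles.len == 0L], collapse = ", "))
  added <- m$n_alleles.seq - m$n_alleles.len
  if (any(added < 0L))
    stop("sequence-level count below length-level count at: ",
         paste(m$marker[added < 0L], collapse = ", "))
  data.frame(marker = m$marker,
             n_length = m$n_alleles.len,
             n_sequence = m$n_alleles.seq,
             added = added,
             growth_pct = 100 * added / m$n_alleles.len,
             doubled = 100 * added / m$n_alleles.len > 100,
             stringsAsFactors = FALSE)
}
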