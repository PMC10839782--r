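#' Construct a genotype table
#'
#' The canonical container for STR genotype data: a wide data.frame with one
#' row per sample, columns `sample_id`, `sex` (`"M"`/`"F"`), then for each
#' autosomal marker two allele columns `<marker>_1`, `<marker>_2` and for
#' each Y marker one column `<marker>` (multi-copy loci hold comma-joined
#' labels in that single cell). Allele labels are either plain CE
#' designations (`"9"`, `"9.3"`) or bracket-notation repeat strings; missing
#' calls are `NA`. Y columns are `NA` for female samples.
#'
#' @param data A data.frame in the layout above.
#' @param panel A marker panel data.frame with columns `marker`, `class`
#'   (`"autosomal"`, `"y_single"` or `"y_multicopy"`) and `period`.
#' @param level Resolution of the stored labels: `"sequence"`, `"length"` or
#'   `"mixed"`.
#' @return An object of class `genotype_table` (a data.frame with `panel`
#'   and `level` attributes).
#' @export
genotype_table <- function(data, panel, level = c("sequence", "length", "mixed")) {
  level <- match.arg(level)
  panel <- validate_panel(panel)
  stopifnot(is.data.frame(data))
  if (!all(c("sample_id", "sex") %in% names(data)))
    stop("genotype data needs 'sample_id' and 'sex' columns")
  if (!all(data$sex %in% c("M", "F")))
    stop("'sex' must be 'M' or 'F'")
  need <- unlist(lapply(seq_len(nrow(panel)), function(i)
    marker_columns(panel$marker[i], panel$class[i])))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing marker columns: ", paste(missing_cols, collapse = ", "))
  ycols <- panel$marker[panel$class != "autosomal"]
  if (length(ycols)) {
    fem <- data$sex == "F"
    bad <- vapply(ycols, function(m) any(!is.na(data[[m]][fem]) &
                                           nzchar(data[[m]][fem])), logical(1))
    if (any(bad))
      stop("female samples carry Y-marker calls at: ",
           paste(ycols[bad], collapse = ", "))
  }
  structure(data, panel = panel, level = level,
            class = c("genotype_table", "data.frame"))
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  if (!all(c("marker", "class", "period") %in% names(panel)))
    stop("panel needs columns marker, class, period")
  if (anyDuplicated(panel$marker)) stop("duplicate marker names in panel")
  if (!all(panel$class %in% c("autosomal", "y_single", "y_multicopy")))
    stop("panel class must be autosomal, y_single or y_multicopy")
  if (!all(panel$period %in% 2:6)) stop("panel period must be in 2..6")
  panel$marker <- as.character(panel$marker)
  panel$period <- as.integer(panel$period)
  panel
}

marker_columns <- function(marker, class) {
  if (class == "autosomal") paste0(marker, "_", 1:2) else marker
}

panel_row <- function(tab, marker) {
  panel <- attr(tab, "panel")
  i <- match(marker, panel$marker)
  if (is.na(i)) stop(sprintf("marker '%s' not in panel", marker))
  panel[i, ]
}

# All allele copies observed at a marker (2N vector for autosomal, one cell
# per male for Y; multi-copy cells stay comma-joined).
marker_alleles <- function(tab, marker) {
  p <- panel_row(tab, marker)
  if (p$class == "autosomal") {
    c(tab[[paste0(marker, "_1")]], tab[[paste0(marker, "_2")]])
  } else {
    tab[[marker]][tab$sex == "M"]
  }
}

# n x 2 matrix of allele labels for a diploid marker; rows with any missing
# call are all-NA (complete-case per locus).
marker_genotypes <- function(tab, marker) {
  p <- panel_row(tab, marker)
  if (p$class != "autosomal")
    stop(sprintf("'%s' is haploid; use the Y-haplotype functions", marker))
  g <- cbind(tab[[paste0(marker, "_1")]], tab[[paste0(marker, "_2")]])
  g[!nzchar(g) | is.na(g)] <- NA
  g[is.na(g[, 1]) | is.na(g[, 2]), ] <- NA
  g
}

# Haploid calls for a Y marker over male samples; multi-copy cells are
# normalized (components sorted numerically, then lexically).
y_calls <- function(tab, marker) {
  p <- panel_row(tab, marker)
  if (p$class == "autosomal")
    stop(sprintf("'%s' is autosomal; Y functions need Y-class markers", marker))
  x <- tab[[marker]][tab$sex == "M"]
  x[!is.na(x) & !nzchar(x)] <- NA
  vapply(x, function(cell) {
    if (is.na(cell)) return(NA_character_)
    normalize_multicopy(cell)
  }, character(1), USE.NAMES = FALSE)
}

normalize_multicopy <- function(cell) {
  parts <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
  num <- suppressWarnings(as.numeric(parts))
  paste(parts[order(num, parts, na.last = TRUE)], collapse = ",")
}

#' @export
print.genotype_table <- function(x, ...) {
  panel <- attr(x, "panel")
  cat(sprintf("genotype_table: %d samples (%d male, %d female), %s level\n",
              nrow(x), sum(x$sex == "M"), sum(x$sex == "F"),
              attr(x, "level")))
  cat(sprintf("panel: %d autosomal, %d Y (%d multi-copy) markers\n",
              sum(panel$class == "autosomal"),
              sum(panel$class != "autosomal"),
              sum(panel$class == "y_multicopy")))
  invisible(x)
}

#' Collapse a genotype table to length (CE) resolution
#'
#' Applies [collapse_to_length()] to every allele cell, yielding a table
#' whose labels are plain CE designations. Already-collapsed tables pass
#' through unchanged.
#'
#' @param tab A `genotype_table`.
#' @return A `genotype_table` with `level = "length"`.
#' @export
collapse_table <- function(tab) {
  stopifnot(inherits(tab, "genotype_table"))
  if (identical(attr(tab, "level"), "length")) return(tab)
  panel <- attr(tab, "panel")
  out <- as.data.frame(tab)
  for (i in seq_len(nrow(panel))) {
    for (col in marker_columns(panel$marker[i], panel$class[i]))
      out[[col]] <- collapse_to_length(out[[col]], panel$period[i])
  }
  genotype_table(out, panel, level = "length")
}

# Resolve a table to the requested analysis level.
at_level <- function(tab, level = c("sequence", "length")) {
  level <- match.arg(level)
  if (level == "length") collapse_table(tab) else tab
}
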