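#' Read a wide-format genotype table
#'
#' CSV or TSV (by extension) with header `sample_id,sex,...`, two allele
#' columns `<marker>_1,<marker>_2` per autosomal marker and one column per
#' Y marker (multi-copy cells comma-joined). Cells hold plain CE
#' designations, bracket-notation strings, or are empty for missing calls;
#' the two dialects may be mixed within a column. Every cell is validated
#' against the nomenclature rules; violations are reported with their line
#' number.
#'
#' @param path Input file.
#' @param panel Marker panel data.frame (see [read_panel()],
#'   [default_panel()]).
#' @return A `genotype_table`; `level` is `"length"` if every label is a
#'   plain CE designation, `"sequence"` if every label is bracket notation,
#'   else `"mixed"`.
#' @export
read_genotype_table <- function(path, panel) {
  panel <- validate_panel(panel)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = c("", "NA"))
  errors <- character(0)
  any_bracket <- FALSE; any_ce <- FALSE
  for (i in seq_len(nrow(panel))) {
    per <- panel$period[i]
    for (col in marker_columns(panel$marker[i], panel$class[i])) {
      if (!col %in% names(df)) next
      for (r in which(!is.na(df[[col]]))) {
        for (part in trimws(strsplit(df[[col]][r], ",", fixed = TRUE)[[1]])) {
          if (is_ce_label(part)) {
            any_ce <- TRUE
            frac <- sub("^[0-9]+\\.?", "", part)
            if (nzchar(frac) && !(as.integer(frac) %in% seq_len(per - 1)))
              errors <- c(errors, sprintf(
                "line %d, %s: microvariant '%s' incompatible with period %d",
                r + 1L, col, part, per))
          } else {
            any_bracket <- TRUE
            ok <- tryCatch({ parse_bracket_notation(part, per); TRUE },
                           error = function(e) conditionMessage(e))
            if (!isTRUE(ok))
              errors <- c(errors, sprintf("line %d, %s: %s", r + 1L, col, ok))
          }
        }
      }
    }
  }
  if (length(errors))
    stop("invalid allele strings:\n  ", paste(errors, collapse = "\n  "))
  level <- if (any_bracket && any_ce) "mixed"
           else if (any_bracket) "sequence" else "length"
  genotype_table(df, panel, level = level)
}

#' Write a genotype table to CSV
#'
#' @param tab A `genotype_table`.
#' @param path Output file; missing calls become empty cells.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(tab, path) {
  df <- as.data.frame(tab)
  df[is.na(df)] <- ""
  # multi-copy cells are comma-joined, so character fields must be quoted
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write an allele-frequency table to CSV
#'
#' Frequencies are serialized at 6 decimals alongside the raw counts and
#' per-marker gene counts, the usual layout of published population tables.
#'
#' @param ft A `freq_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(ft, path) {
  gc <- attr(ft, "gene_count")
  df <- data.frame(marker = ft$marker, allele = ft$allele, count = ft$count,
                   frequency = formatC(ft$frequency, format = "f",
                                       digits = 6),
                   gene_count = gc[ft$marker],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full forensic STR pipeline
#'
#' Orchestrates every stage on one seeded configuration: simulate (or read)
#' a population, estimate allele frequencies and the forensic-parameter
#' suite with HWE tests at both resolutions, Y-haplotype statistics and kit
#' comparison, divergence simulation with Fst/Rst distance matrices, MDS
#' coordinates and a neighbour-joining tree, plus a machine-readable
#' manifest. Two runs with the same configuration produce byte-identical
#' outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed controlling every random draw.
#' @param input Optional path to a genotype CSV; when `NULL` a population
#'   is simulated with [simulate_str_population()].
#' @param panel Marker panel.
#' @param n_samples,n_males Cohort size when simulating.
#' @param levels Analysis levels to run (`"length"`, `"sequence"`).
#' @param alpha HWE family-wise significance level.
#' @param hwe_permutations Monte-Carlo replicates per HWE test.
#' @param n_pops,f_div Divergence-simulation settings for the distance /
#'   structure stages (set `n_pops = 0` to skip them).
#' @return Named list of output file paths, invisibly.
#' @export
pipeline_run <- function(out_dir, seed = 1, input = NULL,
                         panel = default_panel(),
                         n_samples = 628, n_males = 547,
                         levels = c("length", "sequence"),
                         alpha = 0.05, hwe_permutations = 2000,
                         n_pops = 4, f_div = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  pth <- function(f) file.path(out_dir, f)

  tab <- if (is.null(input)) {
    simulate_str_population(n_samples = n_samples, n_males = n_males,
                            panel = panel, seed = seed)
  } else read_genotype_table(input, panel)
  out$genotypes <- write_genotype_table(tab, pth("genotypes.csv"))

  combined <- list()
  for (lv in levels) {
    out[[paste0("freqs_", lv)]] <-
      write_freq_table(allele_frequencies(tab, level = lv),
                       pth(sprintf("allele_freqs_%s.csv", lv)))
    par <- forensic_params(tab, level = lv)
    pf <- pth(sprintf("forensic_params_%s.csv", lv))
    num <- vapply(par, is.numeric, logical(1)) & names(par) != "n"
    par_out <- par
    par_out[num] <- lapply(par_out[num], formatC, format = "f", digits = 6)
    utils::write.csv(par_out, pf, row.names = FALSE, quote = FALSE)
    out[[paste0("params_", lv)]] <- pf
    cp <- combined_powers(par)
    combined[[lv]] <- list(
      CPE = paste0("1-", format_residual(cp$residual_CPE)),
      CPD = paste0("1-", format_residual(cp$residual_CPD)),
      n_loci = cp$n_loci)
    hw <- hwe_test(tab, level = lv, alpha = alpha,
                   n_permutations = hwe_permutations, seed = seed)
    hf <- pth(sprintf("hwe_%s.csv", lv))
    hw$p_value <- formatC(hw$p_value, format = "f", digits = 6)
    hw$threshold <- formatC(hw$threshold, format = "f", digits = 8)
    utils::write.csv(hw, hf, row.names = FALSE, quote = FALSE)
    out[[paste0("hwe_", lv)]] <- hf
  }
  jsonlite::write_json(combined, pth("combined_powers.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$combined <- pth("combined_powers.json")

  if (sum(tab$sex == "M") >= 2) {
    ystats <- lapply(stats::setNames(levels, levels), function(lv) {
      st <- haplotype_stats(build_haplotypes(tab, level = lv))
      st[c("n_males", "n_haplotypes", "HD", "HMP", "DC", "fraction_unique")]
    })
    jsonlite::write_json(ystats, pth("yhap_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$yhap <- pth("yhap_stats.json")
    kc <- kit_comparison(tab, level = levels[1])
    num <- vapply(kc, is.numeric, logical(1)) &
      !names(kc) %in% c("n_loci", "n_males", "n_haplotypes")
    kc[num] <- lapply(kc[num], formatC, format = "f", digits = 8)
    utils::write.csv(kc, pth("kit_comparison.csv"), row.names = FALSE,
                     quote = FALSE)
    out$kits <- pth("kit_comparison.csv")
  }

  if (n_pops >= 2) {
    div <- simulate_diverged_populations(n_pops = n_pops, f_div = f_div,
                                         panel = panel, seed = seed + 1)
    fst <- pairwise_fst(div$tables)
    rst <- pairwise_rst(div$tables)
    out$fst <- write_dist_matrix(fst, pth("fst.csv"))
    out$rst <- write_dist_matrix(rst, pth("rst.csv"))
    out$heatmap <- write_dist_matrix(rst, pth("rst_heatmap.csv"),
                                     order = "hclust")
    if (n_pops >= 3) {
      out$mds <- write_mds_coords(
        classical_mds(rst, dims = min(2, n_pops - 1)), pth("mds_rst.csv"))
      out$nj <- pth("nj_fst.nwk")
      to_newick(neighbor_joining(fst), out$nj)
    }
  }

  manifest <- list(
    package = "strpopgen",
    version = as.character(utils::packageVersion("strpopgen")),
    seed = seed,
    input = if (is.null(input)) "simulated" else input,
    parameters = list(n_samples = n_samples, n_males = n_males,
                      levels = levels, alpha = alpha,
                      hwe_permutations = hwe_permutations,
                      n_pops = n_pops, f_div = f_div),
    panel_markers = nrow(validate_panel(panel)),
    outputs = c(lapply(out, basename), manifest = "manifest.json"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  out$manifest <- pth("manifest.json")
  invisible(out)
}
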