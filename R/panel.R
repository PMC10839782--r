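#' Default 133-marker forensic STR panel
#'
#' The marker panel emulated by the synthetic-population generator: 52
#' diploid autosomal STRs and 81 Y-chromosomal marker units, four of which
#' are multi-copy (a/b) loci reported as unordered allele pairs. Multi-copy
#' units are named without the slash (e.g. `DYS385ab`). Repeat periods are
#' tri-, tetra- or pentanucleotide as typical for each locus.
#'
#' @return A panel data.frame with columns `marker`, `class`, `period`.
#' @export
default_panel <- function() {
  autosomal <- c(
    "CSF1PO", "D10S1248", "D10S1435", "D11S2368", "D11S4463", "D12ATA63",
    "D12S391", "D13S317", "D13S325", "D14S1434", "D15S659", "D16S539",
    "D17S1290", "D17S1301", "D18S51", "D18S535", "D19S253", "D19S433",
    "D1GATA113", "D1S1656", "D1S1677", "D20S470", "D20S482", "D21S11",
    "D22GATA198B05", "D22S1045", "D2S1338", "D2S441", "D3S1358", "D3S3045",
    "D3S4529", "D4S2366", "D4S2408", "D5S2500", "D5S818", "D6S1017",
    "D6S1043", "D6S474", "D6S477", "D7S1517", "D7S3048", "D7S820",
    "D8S1132", "D8S1179", "D9S1122", "D9S925", "FGA", "Penta-D", "Penta-E",
    "TH01", "TPOX", "vWA")
  y_multi <- c("DYF387S1ab", "DYF404S1ab", "DYS385ab", "DYS527ab")
  y_single <- c(
    "DYS572", "DYS19", "DYS388", "DYS389I", "DYS389II", "DYS390", "DYS391",
    "DYS392", "DYS393", "DYS434", "DYS435", "DYS437", "DYS438", "DYS439",
    "DYS443", "DYS444", "DYS447", "DYS448", "DYS449", "DYS450", "DYS453",
    "DYS454", "DYS455", "DYS456", "DYS458", "DYS460", "DYS472", "DYS476",
    "DYS481", "DYS485", "DYS502", "DYS505", "DYS508", "DYS510", "DYS511",
    "DYS512", "DYS513", "DYS518", "DYS522", "DYS530", "DYS531", "DYS533",
    "DYS538", "DYS541", "DYS549", "DYS552", "DYS556", "DYS557", "DYS565",
    "DYS568", "DYS570", "DYS571", "DYS573", "DYS576", "DYS578", "DYS585",
    "DYS587", "DYS590", "DYS593", "DYS596", "DYS612", "DYS613", "DYS616",
    "DYS617", "DYS622", "DYS626", "DYS627", "DYS630", "DYS635", "DYS638",
    "DYS640", "DYS641", "DYS643", "DYS645", "DYS722", "GATAA10", "GATAH4")
  marker <- c(autosomal, y_multi, y_single)
  class <- c(rep("autosomal", length(autosomal)),
             rep("y_multicopy", length(y_multi)),
             rep("y_single", length(y_single)))
  tri <- c("D12ATA63", "D22S1045", "DYS388", "DYS392", "DYS481")
  penta <- c("Penta-D", "Penta-E")
  period <- ifelse(marker %in% tri, 3L, ifelse(marker %in% penta, 5L, 4L))
  validate_panel(data.frame(marker = marker, class = class, period = period,
                            stringsAsFactors = FALSE))
}

#' Read a marker panel definition file
#'
#' CSV with header `marker,class,period` (class one of `autosomal`,
#' `y_single`, `y_multicopy`; period 2-6).
#'
#' @param path Path to the CSV file.
#' @return A validated panel data.frame.
#' @export
read_panel <- function(path) {
  validate_panel(utils::read.csv(path, stringsAsFactors = FALSE,
                                 check.names = FALSE))
}

#' Built-in Y-STR kit locus lists
#'
#' Locus panels of widely used commercial Y-STR kits, restricted to markers
#' present in [default_panel()], for haplotype-resolution comparison with
#' the full 81-marker panel. Multi-copy loci are included as units.
#'
#' @return Named list of character vectors of marker names.
#' @export
default_kits <- function() {
  list(
    minimal_haplotype = c("DYS19", "DYS385ab", "DYS389I", "DYS389II",
                          "DYS390", "DYS391", "DYS392", "DYS393"),
    powerplex_y = c("DYS19", "DYS385ab", "DYS389I", "DYS389II", "DYS390",
                    "DYS391", "DYS392", "DYS393", "DYS437", "DYS438",
                    "DYS439"),
    yfiler = c("DYS19", "DYS385ab", "DYS389I", "DYS389II", "DYS390",
               "DYS391", "DYS392", "DYS393", "DYS437", "DYS438", "DYS439",
               "DYS448", "DYS456", "DYS458", "DYS635", "GATAH4"),
    yfiler_plus = c("DYS19", "DYS385ab", "DYS389I", "DYS389II", "DYS390",
                    "DYS391", "DYS392", "DYS393", "DYS437", "DYS438",
                    "DYS439", "DYS448", "DYS449", "DYS456", "DYS458",
                    "DYS460", "DYS481", "DYS518", "DYS533", "DYS570",
                    "DYS576", "DYS627", "DYS635", "DYF387S1ab", "GATAH4"),
    full_panel = NULL  # resolved to every Y marker of the table's panel
  )
}

#' Read kit definitions from CSV
#'
#' Long-format CSV with header `kit,marker`; one row per kit-locus pair.
#'
#' @param path Path to the CSV file.
#' @return Named list of character vectors of marker names.
#' @export
read_kit_defs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("kit", "marker") %in% names(df)))
    stop("kit file needs columns kit, marker")
  split(df$marker, df$kit)
}
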