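#' Shipped study fixtures
#'
#' The package ships the published tables of the young-versus-old stromal
#' expression study as plain-text fixtures under `inst/extdata/`:
#'
#' * `table2_de_genes.tsv` — the 227-gene differential expression list
#'   (signed fold change; negative = up-regulated in old patients).
#' * `table1_patients.tsv` — patient / tumour metadata for the 9 young
#'   (< 45 years) and 8 old (>= 80 years) patients.
#' * `table4_gene_sets.gmt` — the four curated gene programmes used for
#'   enrichment analysis (senescence, DNA damage response, SASP, AST).
#' * `external_de_lists_synthetic.tsv` — a *synthetic* stand-in for the
#'   external stromal DE lists used in cross-dataset validation (the original
#'   external lists are not published as tables; this fixture is constructed
#'   so the direction-stratified overlap with the study list reproduces the
#'   published ten overlap genes).
#'
#' @param file fixture filename.
#' @return Full path to the installed fixture.
#' @keywords internal
stromage_extdata <- function(file) {
  path <- system.file("extdata", file, package = "stromage")
  if (!nzchar(path)) stop2("fixture not found in installed package: ", file)
  path
}

#' Load the published differential expression table
#'
#' Returns the study's printed DE gene list: one row per gene with its signed
#' fold change between age groups. Negative values indicate up-regulation in
#' the old patients' stromal samples, positive values up-regulation in the
#' young; every gene passed the |FC| >= 1.5 cut-off.
#'
#' @param path override the shipped fixture (mainly for testing).
#' @return A data.frame with columns `gene_symbol`, `full_name`, `signed_fc`.
#' @examples
#' de <- load_table2_fixture()
#' sum(de$signed_fc < 0)  # genes up-regulated in old stroma
#' @export
load_table2_fixture <- function(path = stromage_extdata("table2_de_genes.tsv")) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE,
                          quote = "", encoding = "UTF-8")
  ok <- identical(names(de), c("gene_symbol", "full_name", "signed_fc")) &&
    nrow(de) > 0 && is.numeric(de$signed_fc) &&
    !anyNA(de$signed_fc) && !any(de$signed_fc == 0) &&
    !any(abs(de$signed_fc) < 1.5) && !anyDuplicated(de$gene_symbol)
  if (!ok) stop2("corrupted DE gene fixture: ", path)
  de
}

#' Load the patient metadata fixture
#'
#' @param path override the shipped fixture.
#' @return A data.frame with columns `patient_id`, `age_years`, `group`
#'   (`young` < 45 years, `old` >= 80 years), `tumour_grade`, `max_size_cm`,
#'   `pT`, `pN`.
#' @export
load_patient_fixture <- function(path = stromage_extdata("table1_patients.tsv")) {
  pts <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(pT = "character", pN = "character"))
  ok <- all(c("patient_id", "age_years", "group") %in% names(pts)) &&
    all(pts$group[pts$age_years < 45] == "young") &&
    all(pts$group[pts$age_years >= 80] == "old") &&
    all(pts$age_years < 45 | pts$age_years >= 80)
  if (!ok) stop2("corrupted patient fixture: ", path)
  pts
}

#' Load the four curated gene programmes
#'
#' The curated sets scored by the enrichment analysis: `senescence` (5 genes),
#' `ddr` (DNA damage response, 3 genes), `sasp` (senescence-associated
#' secretory profile) and `ast` (autophagy-to-senescence transition, 15
#' genes). `CCL3` is carried in the SASP set as a *provisional* member (it is
#' printed parenthesised in the source table, signalling uncertain inclusion)
#' and is excluded from the default membership; set
#' `include_provisional = TRUE` to score with it.
#'
#' @param include_provisional include provisional symbols in the active
#'   membership (`symbols` slot) of each set.
#' @param path override the shipped GMT fixture.
#' @return A [gene_set_collection()] with the four sets.
#' @examples
#' sets <- load_curated_sets()
#' sets$senescence$symbols
#' @export
load_curated_sets <- function(include_provisional = FALSE,
                              path = stromage_extdata("table4_gene_sets.gmt")) {
  sets <- read_gmt(path)
  if (!identical(sort(names(sets)), c("ast", "ddr", "sasp", "senescence")) ||
      length(set_symbols(sets$senescence, TRUE)) != 5 ||
      length(set_symbols(sets$ddr, TRUE)) != 3) {
    stop2("corrupted curated gene-set fixture: ", path)
  }
  gene_set_collection(lapply(sets, function(s) {
    if (include_provisional) {
      # promote provisional members to full membership
      gene_set(s$name, set_symbols(s, include_provisional = TRUE),
               description = s$description)
    } else {
      gene_set(s$name, set_symbols(s, include_provisional = FALSE),
               description = s$description, provisional = s$provisional)
    }
  }))
}
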