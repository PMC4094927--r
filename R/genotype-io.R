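#' Read and write plain delimited dosage matrices
#'
#' The plain dosage format is tab-delimited text: a header row with `id`,
#' `population` and then one column per locus ID; one row per individual with
#' its identifier, population label and 0/1/2 (or fractional) dosages. `NA`
#' marks a missing genotype.
#'
#' @param G a [genotype_matrix].
#' @param path file path.
#' @return `read_dosage()` returns a [genotype_matrix]; `write_dosage()`
#'   returns `path` invisibly.
#' @export
write_dosage <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  tbl <- tibble(id = individual_ids(G),
                population = as.character(populations(G))) |>
    dplyr::bind_cols(as_tibble(G$values))
  readr::write_tsv(tbl, path, na = "NA")
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path) {
  tbl <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                         progress = FALSE)
  stopifnot(all(c("id", "population") %in% names(tbl)[1:2]))
  values <- as.matrix(tbl[, -(1:2)])
  genotype_matrix(values,
                  locus_ids = colnames(values),
                  individual_ids = tbl$id,
                  populations = tbl$population)
}

#' Read a PLINK .raw additive-coded genotype file
#'
#' Parses the whitespace-delimited output of `plink --recode A`: columns
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one dosage column per SNP
#' (counts of the counted allele, `NA` missing). The family ID (`FID`) is
#' used as the population label.
#'
#' @param path path to a `.raw` file.
#' @return A [genotype_matrix].
#' @export
read_plink_raw <- function(path) {
  tbl <- readr::read_table(path, na = c("NA"), show_col_types = FALSE,
                           progress = FALSE)
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(lead %in% names(tbl)[1:6])) {
    abort("not a PLINK .raw file: expected FID IID PAT MAT SEX PHENOTYPE header",
          class = "bcpi_bad_format")
  }
  values <- as.matrix(tbl[, -(1:6)])
  genotype_matrix(values,
                  locus_ids = colnames(values),
                  individual_ids = as.character(tbl$IID),
                  populations = as.character(tbl$FID))
}
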