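## TSV readers/writers for the tabular interchange formats the pipeline
## consumes and emits.  All thin wrappers over read.delim/write.table with
## column validation, so files made by other tools slot in directly.

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Read a FAME table (condition, fatty_acid, wt_percent_cdw)
#' @param path TSV path.
#' @return a `fame_dataset`.
#' @export
read_fame_tsv <- function(path) {
  fame_dataset(read_tsv_checked(path,
                                c("condition", "fatty_acid", "wt_percent_cdw")))
}

#' Read a phenotype-array table
#'
#' Columns: `plate`, `well`, `substrate`, `element_class`, `a590`,
#' `a750`, optional `observed_growth`.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phenotype_tsv <- function(path) {
  read_tsv_checked(path, c("plate", "well", "substrate", "element_class",
                           "a590", "a750"))
}

#' Read a substrate map (substrate, metabolite_id)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_substrate_map_tsv <- function(path) {
  read_tsv_checked(path, c("substrate", "metabolite_id"))
}

#' Read a gene-fitness table (gene, condition, score[, global_essential])
#' @param path TSV path.
#' @return data.frame; `gene` is coerced to character.
#' @export
read_fitness_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene", "condition", "score"))
  df$gene <- as.character(df$gene)
  df
}

#' Read a medium table (exchange_reaction, lower_bound[, upper_bound])
#' @param path TSV path.
#' @return named numeric vector of exchange lower bounds for
#'   [apply_medium()].
#' @export
read_medium_tsv <- function(path) {
  df <- read_tsv_checked(path, c("exchange_reaction", "lower_bound"))
  stats::setNames(df$lower_bound, df$exchange_reaction)
}

#' Read a localization table (gene_id, compartments[, signal_peptide])
#' @param path TSV path.
#' @return data.frame; `compartments` is a comma-separated token list.
#' @export
read_localization_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "compartments"))
  df$gene_id <- as.character(df$gene_id)
  df
}

#' Read a compartment relocation rule table (selector, from, to)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_relocation_rules_tsv <- function(path) {
  read_tsv_checked(path, c("selector", "from", "to"))
}

#' Read a metabolite alias table (keep_id, drop_id[, evidence])
#' @param path TSV path.
#' @return data.frame.
#' @export
read_alias_tsv <- function(path) {
  read_tsv_checked(path, c("keep_id", "drop_id"))
}

#' Write a data.frame as TSV (no quoting, no row names)
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
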