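# Readers and writers for the plain-text interchange formats: drug tables,
# DDI edge lists, SMILES corpora, split assignments and predictions.

.read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

#' Read a drug table (`drug_id,smiles`)
#'
#' @param path CSV or TSV file with header columns `drug_id` and `smiles`.
#' @return Data frame with character columns `drug_id`, `smiles`.
#' @export
read_drug_table <- function(path) {
  df <- .read_delim_auto(path)
  stopifnot(all(c("drug_id", "smiles") %in% names(df)))
  df$drug_id <- as.character(df$drug_id)
  df$smiles <- as.character(df$smiles)
  df
}

#' Read a DDI edge list (`drug_id_1,drug_id_2[,label]`)
#'
#' A missing `label` column means every listed pair is a known interaction.
#'
#' @param path CSV or TSV file.
#' @return Data frame with `drug_id_1`, `drug_id_2`, `label`.
#' @export
read_edge_list <- function(path) {
  df <- .read_delim_auto(path)
  stopifnot(all(c("drug_id_1", "drug_id_2") %in% names(df)))
  if (!("label" %in% names(df))) df$label <- 1L
  df$drug_id_1 <- as.character(df$drug_id_1)
  df$drug_id_2 <- as.character(df$drug_id_2)
  df$label <- as.integer(df$label)
  df
}

#' Read a SMILES corpus (one molecule per line)
#'
#' @param path `.smi` file; anything after the first whitespace on a line is
#'   ignored.
#' @return Character vector of SMILES strings.
#' @export
read_smiles_corpus <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\\s+"), `[[`, character(1), 1L)
}

#' Write a split assignment to TSV
#'
#' Emits `drug_id<TAB>split` for the drug split and, when `pairs` is given,
#' `drug_id_1<TAB>drug_id_2<TAB>label<TAB>split` for the link split.
#'
#' @param split A [scaffold_split()] result.
#' @param path Output TSV path for the drug split.
#' @param network,link_split,pairs_path Optional: the network, its link
#'   splits and an output path for the link-level table.
#' @return `path`, invisibly.
#' @export
write_split_tsv <- function(split, path, network = NULL, link_split = NULL,
                            pairs_path = NULL) {
  utils::write.table(
    data.frame(drug_id = names(split$drug_split), split = split$drug_split),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(network) && !is.null(link_split) && !is.null(pairs_path)) {
    lp <- network$labeled_pairs
    utils::write.table(
      data.frame(drug_id_1 = network$drug_ids[lp$i],
                 drug_id_2 = network$drug_ids[lp$j],
                 label = lp$y, split = link_split),
      pairs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write pair predictions to TSV
#'
#' @param predictions Data frame from [predict_ddi()].
#' @param path Output path (`drug_id_1  drug_id_2  prob_interaction`).
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load an experiment configuration from YAML
#'
#' Any key of [experiment_config()] may appear in the file; unspecified keys
#' keep their defaults.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(experiment_config, raw)
}

#' Write the per-epoch loss log as JSON lines
#'
#' @param loss_log The `loss_log` data frame of a trained `ddi_model`.
#' @param path Output path; one JSON object per epoch.
#' @return `path`, invisibly.
#' @export
write_loss_log <- function(loss_log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(loss_log))) {
    writeLines(jsonlite::toJSON(as.list(loss_log[r, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}
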