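# Delimited-text I/O: Q-matrices, grouped response files, DIF reports.
# Separator is auto-detected (comma vs whitespace) so both CSV and
# TSV/space-delimited files load with the same call.

.read_delim_matrix <- function(path) {
  if (!file.exists(path))
    stop_with("dinadif_invalid", sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  as.matrix(utils::read.table(path, header = FALSE, sep = sep))
}

#' Read a Q-matrix from a delimited text file
#'
#' Header-less J x K table of 0/1, comma- or whitespace-separated.
#'
#' @param path File path.
#' @return A validated numeric Q-matrix.
#' @export
read_qmatrix <- function(path) {
  q <- validate_qmatrix(.read_delim_matrix(path))
  dimnames(q) <- list(NULL, paste0("A", seq_len(ncol(q))))
  q
}

#' Read a grouped response matrix
#'
#' Loads a header-less N x J binary response file plus a one-column
#' group file; group labels "R"/"F" (also "reference"/"focal" or 0/1)
#' map to the reference/focal factor.
#'
#' @param responses_path Path to the response matrix.
#' @param group_path Path to the single-column group label file.
#' @return List with the binary matrix `x` and the `group` factor.
#' @export
read_grouped_responses <- function(responses_path, group_path) {
  x <- validate_binary_matrix(.read_delim_matrix(responses_path), "responses")
  g <- utils::read.table(group_path, header = FALSE,
                         colClasses = "character")[[1L]]
  list(x = x, group = normalize_group(g, nrow(x)))
}

#' Write a response matrix or Q-matrix as delimited text
#'
#' @param x Binary matrix.
#' @param path Output path; `.csv` writes comma-separated, anything
#'   else tab-separated.
#' @export
write_matrix <- function(x, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(x, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a DIF scan report
#'
#' One row per (item, method) with the statistic, degrees of freedom,
#' p-value and flag, in a stable column order; numeric columns keep full
#' precision so the table round-trips losslessly.
#'
#' @param x A `"dina_dif"` object or its `results` data frame.
#' @param path Output CSV path.
#' @export
write_dif_report <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[, c("item", "method", "statistic", "df", "p_value", "flagged")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
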