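#' Conformer weight table
#'
#' Probabilities of the reference configurations (RCs) extracted from the
#' conformational free-energy basins, plus the experimental alpha:beta
#' anomer ratio used for the final spectrum mixing. Printed probability
#' tables typically carry two-digit entries whose sum can drift from 1
#' (rounding); [normalize_weights()] restores exact normalization.
#'
#' @param labels RC labels (e.g. `"A"` ... `"M"`); rotamer class may be
#'   carried in parentheses, e.g. `"A (GT)"`.
#' @param probabilities nonnegative conformer probabilities.
#' @param anomer_ratio length-2 nonnegative vector `(alpha, beta)`; any
#'   scale (e.g. `c(32, 68)`).
#' @return an object of class `conformer_weights`.
#' @export
conformer_weights <- function(labels, probabilities, anomer_ratio = c(1, 1)) {
  if (length(labels) != length(probabilities))
    abort_validation("labels and probabilities differ in length")
  if (any(probabilities < 0) || any(anomer_ratio < 0))
    abort_validation("probabilities and anomer ratio must be nonnegative")
  if (length(anomer_ratio) != 2L)
    abort_validation("anomer_ratio must have exactly 2 entries (alpha, beta)")
  structure(list(
    labels = as.character(labels),
    probabilities = as.numeric(probabilities),
    anomer_ratio = as.numeric(anomer_ratio)
  ), class = "conformer_weights")
}

#' Normalize conformer and anomer weights
#'
#' Divides the conformer probabilities by their sum and the anomer ratio by
#' its sum, so both are proper probability vectors.
#'
#' @param table a `conformer_weights` object.
#' @return the normalized `conformer_weights`.
#' @export
normalize_weights <- function(table) {
  stopifnot(inherits(table, "conformer_weights"))
  s <- sum(table$probabilities)
  if (s <= 0)
    abort_validation("all conformer probabilities are zero")
  table$probabilities <- table$probabilities / s
  sa <- sum(table$anomer_ratio)
  if (sa <= 0)
    abort_validation("anomer ratio sums to zero")
  table$anomer_ratio <- table$anomer_ratio / sa
  table
}

#' @export
print.conformer_weights <- function(x, ...) {
  cat("Conformer weights (", length(x$labels), " RCs):\n", sep = "")
  print(data.frame(label = x$labels, probability = x$probabilities),
        row.names = FALSE)
  cat(sprintf("anomer ratio (alpha:beta): %g:%g\n",
              x$anomer_ratio[1], x$anomer_ratio[2]))
  invisible(x)
}

#' Read a conformer weight table
#'
#' Two-column delimited text (label, probability), `#` comments allowed.
#' The label column may carry the rotamer class in parentheses, e.g.
#' `"A (GT)"`. The anomer ratio comes from the caller (it is experimental
#' input, not part of the RC table).
#'
#' @param path file path.
#' @param anomer_ratio length-2 `(alpha, beta)` ratio, any scale.
#' @return a `conformer_weights` object.
#' @export
read_weight_table <- function(path, anomer_ratio = c(1, 1)) {
  if (!file.exists(path))
    abort_data("weight table not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", strip.white = TRUE,
                          col.names = c("label", "probability"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) == 0)
    abort_validation("weight table is empty: ", path)
  conformer_weights(df$label, df$probability, anomer_ratio)
}

#' Extract the rotamer class carried in weight-table labels
#'
#' Labels of the form `"A (GT)"` yield `"GT"`; labels without a
#' parenthesized class yield `NA`.
#'
#' @param table a `conformer_weights` object.
#' @return character vector of rotamer classes (`"GT"`, `"GG"`, `"TG"` or `NA`).
#' @export
weight_rotamers <- function(table) {
  stopifnot(inherits(table, "conformer_weights"))
  m <- regmatches(table$labels,
                  regexpr("\\((GT|GG|TG)\\)", table$labels))
  out <- rep(NA_character_, length(table$labels))
  has <- lengths(regmatches(table$labels,
                            gregexpr("\\((GT|GG|TG)\\)", table$labels))) > 0
  out[has] <- gsub("[()]", "", m)
  out
}

#' Aggregate conformer probabilities by rotamer class
#'
#' Sums the (raw, un-renormalized) probabilities of a weight table by the
#' rotamer class carried in the labels. With the printed glucose beta
#' column this reproduces the GT:GG = 0.40:0.60 split.
#'
#' @param table a `conformer_weights` object.
#' @return named numeric vector of summed probabilities per rotamer class.
#' @export
rotamer_split <- function(table) {
  rot <- weight_rotamers(table)
  if (anyNA(rot))
    abort_validation("weight table labels do not all carry a rotamer class")
  tapply(table$probabilities, rot, sum)
}
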