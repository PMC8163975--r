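# Shared internal helpers.

# One- and three-letter amino acid tables (20 standard residues).
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")
AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
names(AA3) <- AA1

aa_three_to_one <- function(x) {
  out <- names(AA3)[match(toupper(x), AA3)]
  out[is.na(out)] <- "X"
  out
}

aa_one_to_three <- function(x) {
  out <- unname(AA3[match(toupper(x), names(AA3))])
  out[is.na(out)] <- "UNK"
  out
}

#' @noRd
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("raseffector_config_error",
                                             "raseffector_error")))
}

#' @noRd
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("raseffector_data_error",
                                             "raseffector_error")))
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == round(x)
}

is_scalar_number <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x)
}
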