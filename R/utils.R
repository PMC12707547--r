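#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all reported percentages so that
#' e.g. 8/17 prints as 47.06. Base [round()] uses banker's rounding, which
#' would disagree on exact .5 ties.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return numeric vector rounded half away from zero
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

AA_STANDARD <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# split a sequence string into a character vector of single residues
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(..., class = "serpinscope_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
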