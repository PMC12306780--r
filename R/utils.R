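#' Round half away from zero
#'
#' Display rounding used throughout the printed reports: one decimal,
#' half-up (0.05 -> 0.1), unlike base R's round-half-even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# percentage string with one-decimal half-up rounding, "NA" passthrough
fmt_pct <- function(num, den, digits = 1) {
  ifelse(den > 0,
         sprintf(paste0("%.", digits, "f"), round_half_up(100 * num / den, digits)),
         NA_character_)
}

stop_crms <- function(msg, class) {
  stop(structure(class = c(class, "crms_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind a list of data.frames; NULL when nothing to bind (plain do.call
# with make.row.names on an empty list yields a 1x1 matrix)
rbind_all <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
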