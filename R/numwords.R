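#' Spell a nonnegative integer as English cardinal words
#'
#' Converts a digit string to lowercase cardinal English ("25" -> "twenty
#' five"). Words are space-separated (no hyphens) so the result survives the
#' downstream punctuation filter unchanged. Runs longer than 15 digits are
#' read digit by digit.
#'
#' @param digits A string of ASCII digits.
#' @return A single lowercase string of words.
#' @examples
#' number_to_words("105")
#' @export
number_to_words <- function(digits) {
  stopifnot(is.character(digits), length(digits) == 1L, grepl("^[0-9]+$", digits))
  ones <- c(
    "zero", "one", "two", "three", "four", "five", "six", "seven", "eight",
    "nine", "ten", "eleven", "twelve", "thirteen", "fourteen", "fifteen",
    "sixteen", "seventeen", "eighteen", "nineteen"
  )
  tens <- c(
    "twenty", "thirty", "forty", "fifty", "sixty", "seventy", "eighty",
    "ninety"
  )
  if (nchar(digits) > 15L) {
    return(paste(ones[as.integer(strsplit(digits, "")[[1]]) + 1L], collapse = " "))
  }
  n <- as.numeric(digits)
  if (n == 0) return("zero")

  below_hundred <- function(n) {
    if (n < 20) return(ones[n + 1L])
    t <- n %/% 10L
    r <- n %% 10L
    if (r == 0) tens[t - 1L] else paste(tens[t - 1L], ones[r + 1L])
  }
  below_thousand <- function(n) {
    h <- n %/% 100L
    r <- n %% 100L
    parts <- character(0)
    if (h > 0) parts <- c(parts, ones[h + 1L], "hundred")
    if (r > 0) parts <- c(parts, below_hundred(r))
    paste(parts, collapse = " ")
  }
  scales <- c("", "thousand", "million", "billion", "trillion")
  parts <- character(0)
  i <- 1L
  while (n > 0) {
    chunk <- n %% 1000
    if (chunk > 0) {
      word <- below_thousand(chunk)
      if (nzchar(scales[i])) word <- paste(word, scales[i])
      parts <- c(word, parts)
    }
    n <- n %/% 1000
    i <- i + 1L
  }
  paste(parts, collapse = " ")
}

# Replace every maximal digit run (optionally containing a single internal
# decimal point) in a character vector by its spelled-out form, padded with
# spaces so neighbouring letters are not fused. Decimal digits are read
# digit by digit after "point".
spell_numbers <- function(x) {
  pat <- "[0-9]+(\\.[0-9]+)?"
  m <- gregexpr(pat, x)
  regmatches(x, m) <- lapply(regmatches(x, m), function(runs) {
    if (length(runs) == 0) return(runs)
    vapply(runs, function(r) {
      parts <- strsplit(r, ".", fixed = TRUE)[[1]]
      out <- number_to_words(parts[1])
      if (length(parts) == 2L) {
        frac <- paste(
          c("zero", "one", "two", "three", "four", "five", "six", "seven",
            "eight", "nine")[as.integer(strsplit(parts[2], "")[[1]]) + 1L],
          collapse = " "
        )
        out <- paste(out, "point", frac)
      }
      paste0(" ", out, " ")
    }, character(1))
  })
  x
}
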