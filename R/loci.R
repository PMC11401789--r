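#' Parse a cheek-tooth locus code
#'
#' Locus codes follow the standard dental shorthand for rhinocerotids:
#' `D`/`d` deciduous (milk) molar, `P`/`p` premolar, `M`/`m` molar, followed
#' by the position digit. Capital letters denote upper teeth, lower-case
#' letters lower teeth. Positions are constrained per family: milk molars
#' 1-4, premolars 2-4, molars 1-3.
#'
#' @param code A single character locus code such as `"m1"`, `"P4"`, `"d3"`.
#' @return An object of class `tooth_locus`: a list with fields `code`,
#'   `arcade` (`"upper"`/`"lower"`), `generation` (`"deciduous"`/`"permanent"`),
#'   `family` (`"milk_molar"`/`"premolar"`/`"molar"`), and integer `position`.
#' @examples
#' parse_locus("d3")  # lower third milk molar
#' parse_locus("M2")  # upper second molar
#' @export
parse_locus <- function(code) {
  if (length(code) != 1L || !is.character(code) || is.na(code)) {
    stop("locus code must be a single character string", call. = FALSE)
  }
  if (!grepl("^[dDpPmM][0-9]$", code)) {
    stop(sprintf("malformed locus code '%s': expected a letter in d/D/p/P/m/M followed by one digit", code),
         call. = FALSE)
  }
  letter <- substr(code, 1L, 1L)
  position <- as.integer(substr(code, 2L, 2L))
  arcade <- if (letter %in% c("D", "P", "M")) "upper" else "lower"
  family <- switch(tolower(letter),
    d = "milk_molar",
    p = "premolar",
    m = "molar"
  )
  generation <- if (family == "milk_molar") "deciduous" else "permanent"
  valid <- switch(family,
    milk_molar = 1:4,
    premolar = 2:4,
    molar = 1:3
  )
  if (!position %in% valid) {
    stop(sprintf("locus code '%s': %s positions are %d-%d", code, sub("_", " ", family),
                 min(valid), max(valid)),
         call. = FALSE)
  }
  structure(
    list(code = code, arcade = arcade, generation = generation,
         family = family, position = position),
    class = "tooth_locus"
  )
}

#' @export
format.tooth_locus <- function(x, ...) {
  sprintf("%s %s %s %d [%s]", x$arcade, x$generation,
          sub("_", " ", x$family), x$position, x$code)
}

#' @export
print.tooth_locus <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' All valid cheek-tooth locus codes
#'
#' @return Character vector of the 20 cheek-tooth loci (milk molars 1-4,
#'   premolars 2-4, molars 1-3, upper and lower).
#' @export
all_locus_codes <- function() {
  c(paste0("d", 1:4), paste0("D", 1:4),
    paste0("p", 2:4), paste0("P", 2:4),
    paste0("m", 1:3), paste0("M", 1:3))
}

# Vectorised locus fields for internal data-frame work. Invalid codes become
# NA rows; callers that need hard validation use parse_locus().
locus_fields <- function(codes) {
  ok <- !is.na(codes) & grepl("^[dDpPmM][0-9]$", codes)
  letter <- ifelse(ok, substr(codes, 1L, 1L), NA_character_)
  position <- ifelse(ok, suppressWarnings(as.integer(substr(codes, 2L, 2L))), NA_integer_)
  family <- c(d = "milk_molar", p = "premolar", m = "molar")[tolower(letter)]
  maxpos <- c(milk_molar = 4L, premolar = 4L, molar = 3L)[family]
  minpos <- c(milk_molar = 1L, premolar = 2L, molar = 1L)[family]
  valid <- ok & !is.na(family) & position >= minpos & position <= maxpos
  data.frame(
    code = codes,
    arcade = ifelse(valid, ifelse(letter %in% c("D", "P", "M"), "upper", "lower"), NA),
    generation = ifelse(valid, ifelse(family == "milk_molar", "deciduous", "permanent"), NA),
    family = ifelse(valid, family, NA),
    position = ifelse(valid, position, NA_integer_),
    valid = valid,
    stringsAsFactors = FALSE
  )
}
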