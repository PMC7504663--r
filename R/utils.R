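# Internal helpers shared across modules.

#' The five PHI tag types
#'
#' Single-letter codes used throughout the package: `a` (age), `x` (sex),
#' `t` (time), `h` (hospital), `p` (person).
#'
#' @return A named character vector mapping code to a human-readable name.
#' @export
#' @examples
#' phi_tags()
phi_tags <- function() {
  c(a = "age", x = "sex", t = "time", h = "hospital", p = "person")
}

#' The IOB2 label alphabet
#'
#' `O` plus `B-`/`I-` for each of the five PHI tag types, in a fixed order
#' used by both sequence taggers.
#'
#' @return Character vector of length 11.
#' @export
iob2_labels <- function() {
  types <- names(phi_tags())
  c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards. `seed = NULL` leaves RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Number of Unicode code points in each element of `x`.
nchar_cp <- function(x) nchar(x, type = "chars")

# Empty span table: the canonical shape of a PHI span set.
empty_spans <- function() {
  tibble::tibble(tag_type = character(), begin = integer(), end = integer())
}

#' Construct a PHI span table
#'
#' Spans use 0-based, half-open character (code point) offsets into the raw
#' document text.
#'
#' @param tag_type Character vector of tag codes (see [phi_tags()]).
#' @param begin,end Integer offsets, `begin < end`.
#' @return A tibble with columns `tag_type`, `begin`, `end`, sorted by `begin`.
#' @export
#' @examples
#' phi_spans(c("a", "x"), c(8, 12), c(11, 14))
phi_spans <- function(tag_type = character(), begin = integer(), end = integer()) {
  spans <- tibble::tibble(
    tag_type = as.character(tag_type),
    begin = as.integer(begin),
    end = as.integer(end)
  )
  validate_spans(spans)
  dplyr::arrange(spans, .data$begin, .data$end)
}

# Check structural invariants of a span table; `text_len` additionally bounds
# offsets. Overlap checking is optional because intermediate per-rule span
# sets may overlap before resolution.
validate_spans <- function(spans, text_len = NULL, check_overlap = FALSE) {
  if (!all(spans$tag_type %in% names(phi_tags()))) {
    rlang::abort(paste0(
      "unknown tag type: ",
      paste(setdiff(spans$tag_type, names(phi_tags())), collapse = ", ")
    ))
  }
  if (any(spans$begin >= spans$end)) {
    rlang::abort("span begin must be < end")
  }
  if (any(spans$begin < 0)) rlang::abort("span begin must be >= 0")
  if (!is.null(text_len) && any(spans$end > text_len)) {
    rlang::abort("span end beyond document length")
  }
  if (check_overlap && nrow(spans) > 1) {
    s <- spans[order(spans$begin), ]
    if (any(s$begin[-1] < s$end[-nrow(s)])) {
      rlang::abort("spans overlap")
    }
  }
  invisible(spans)
}

# Format a metric in the conventional presentation: x100, two decimals.
percent2 <- function(x) {
  ifelse(is.na(x), "N/A", sprintf("%.2f", 100 * x))
}
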