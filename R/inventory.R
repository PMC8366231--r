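#' Phoneme inventories and affix specifications
#'
#' A phoneme inventory is the alphabet of single-character phone symbols used
#' in transcriptions, following the DISC convention of one character per
#' phone (so diphthongs such as /aI/ are written with a single symbol, e.g.
#' `"2"`). A reserved boundary symbol (default `"#"`) pads words when they
#' are decomposed into triphones and may never occur word-internally.
#'
#' @param symbols Character vector of unique single-character phone symbols.
#' @param boundary Single reserved character used as the word-boundary
#'   padding symbol; must not occur in `symbols`.
#' @return A character vector of class `phoneme_inventory` with a
#'   `boundary` attribute.
#' @examples
#' inv <- phoneme_inventory(c("k", "{", "t"))
#' boundary_symbol(inv)
#' @export
phoneme_inventory <- function(symbols, boundary = "#") {
  symbols <- as.character(symbols)
  if (length(symbols) == 0L) {
    abort("a phoneme inventory must contain at least one symbol")
  }
  if (any(nchar(symbols) != 1L)) {
    bad <- symbols[nchar(symbols) != 1L]
    abort(paste0("phone symbols must be single characters: ",
                 paste(sQuote(bad), collapse = ", ")))
  }
  if (anyDuplicated(symbols)) {
    abort("phone symbols must be unique")
  }
  if (nchar(boundary) != 1L || boundary %in% symbols) {
    abort("`boundary` must be a single character not present in `symbols`")
  }
  structure(symbols, boundary = boundary, class = "phoneme_inventory")
}

#' @rdname phoneme_inventory
#' @param inventory A `phoneme_inventory`.
#' @export
boundary_symbol <- function(inventory) {
  attr(inventory, "boundary") %||% "#"
}

#' @rdname phoneme_inventory
#' @details `default_inventory()` returns a compact DISC-like alphabet:
#'   plain consonant and vowel letters plus the DISC symbols `"{"` (TRAP),
#'   `"@"` (schwa), `"$"` (THOUGHT), `"I"`, `"S"`, `"Z"`, `"N"`, `"1"`
#'   (FACE) and `"2"` (PRICE).
#' @export
default_inventory <- function() {
  phoneme_inventory(c(
    "p", "b", "t", "d", "k", "g", "m", "n", "N", "f", "v", "s", "z",
    "S", "Z", "h", "r", "l", "w", "j",
    "a", "e", "i", "o", "u", "{", "@", "$", "I", "1", "2"
  ))
}

#' Specify derivational affix categories for the synthetic lexicon
#'
#' Each affix category is a derivational function (a unit of meaning, not of
#' form): it has a label (e.g. `"NESS"`), a phonological exponent
#' (`form`, concatenated to sampled bases as a prefix or suffix), a
#' semantic shift scale controlling the length of its function-lexome
#' vector, and the number of derived word types to generate.
#'
#' @param category Character label, unique within a configuration.
#' @param form Non-empty phone string (one character per phone).
#' @param position `"prefix"` or `"suffix"`.
#' @param shift_scale Positive scale multiplier for the category's
#'   function-lexome vector (relative to the content-vector scale).
#' @param n_types Number of derived types (>= 1) to generate.
#' @return A one-row tibble; bind rows to build a full specification.
#' @examples
#' affix_spec("NESS", "nIs", "suffix", shift_scale = 1, n_types = 10)
#' @export
affix_spec <- function(category, form, position = c("suffix", "prefix"),
                       shift_scale = 1, n_types = 1L) {
  position <- match.arg(position)
  if (!nzchar(form)) abort("`form` must be a non-empty phone string")
  if (n_types < 1L) abort("`n_types` must be >= 1")
  if (shift_scale < 0) abort("`shift_scale` must be >= 0")
  tibble(category = as.character(category), form = as.character(form),
         position = position, shift_scale = as.numeric(shift_scale),
         n_types = as.integer(n_types))
}

#' @rdname affix_spec
#' @param n_types_each Number of derived types per category for the default
#'   five-category specification.
#' @details `default_affixes()` mirrors the five derivational categories of
#'   the study design (DIS as a prefix; NESS, LESS, ATION, IZE as suffixes)
#'   with DISC-like exponents. The shift scales differ markedly across
#'   categories, emulating the strongly separated semantic-transparency
#'   profiles these affix classes show in corpus-trained semantic spaces
#'   (transparent categories such as LESS, DIS, NESS shift their
#'   derivatives coherently; ATION and IZE much less so).
#' @export
default_affixes <- function(n_types_each = 40L) {
  dplyr::bind_rows(
    affix_spec("DIS",   "dIs", "prefix", shift_scale = 1.7, n_types = n_types_each),
    affix_spec("NESS",  "nIs", "suffix", shift_scale = 1.3, n_types = n_types_each),
    affix_spec("LESS",  "lIs", "suffix", shift_scale = 2.1, n_types = n_types_each),
    affix_spec("ATION", "1Sn", "suffix", shift_scale = 0.5, n_types = n_types_each),
    affix_spec("IZE",   "2z",  "suffix", shift_scale = 0.9, n_types = n_types_each)
  )
}

validate_affixes <- function(affixes, inventory) {
  required <- c("category", "form", "position", "shift_scale", "n_types")
  missing <- setdiff(required, names(affixes))
  if (length(missing)) {
    abort(paste0("affix specification lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(affixes$category)) {
    abort("affix category labels must be unique")
  }
  for (f in affixes$form) {
    check_transcription(f, inventory)
  }
  invisible(affixes)
}

check_transcription <- function(transcription, inventory = NULL) {
  if (is.na(transcription) || !nzchar(transcription)) {
    abort("transcriptions must contain at least one phone")
  }
  phones <- strsplit(transcription, "", fixed = TRUE)[[1]]
  if (!is.null(inventory)) {
    bound <- boundary_symbol(inventory)
    if (bound %in% phones) {
      abort(paste0("boundary symbol ", sQuote(bound),
                   " may not occur inside a transcription"))
    }
    bad <- setdiff(phones, as.character(inventory))
    if (length(bad)) {
      abort(paste0("illegal phone symbol(s) in ", sQuote(transcription), ": ",
                   paste(sQuote(unique(bad)), collapse = ", ")))
    }
  }
  invisible(phones)
}
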