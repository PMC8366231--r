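#' Generate a synthetic derivational lexicon
#'
#' Builds a lexicon of monomorphemic base words plus, for each affix
#' category, a set of derived words whose transcription is the affix
#' exponent concatenated to a sampled base (prefixed or suffixed).
#' Base transcriptions are random consonant--vowel alternating strings
#' over the inventory, so that neighbouring words share overlapping
#' triphones the way real lexicons do. Derivatives whose bases are
#' already complex never arise by construction (bases are always
#' monomorphemic), matching the single-affix restriction of the analysis.
#'
#' @param n_bases Number of monomorphemic base words (>= 1).
#' @param affixes Affix specification tibble, see [affix_spec()]. Each
#'   category samples `n_types` distinct bases (so `n_types <= n_bases`).
#' @param inventory A [phoneme_inventory()].
#' @param base_length Integer range (min, max) of base word lengths in
#'   phones.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A tibble of class `ldl_lexicon` with columns `word_id`,
#'   `transcription`, `base_id` (`NA` for monomorphemic words), and
#'   `category` (`NA` for monomorphemic words), with the inventory and the
#'   affix specification stored as attributes.
#' @examples
#' lex <- generate_lexicon(20, default_affixes(5), seed = 1)
#' dplyr::count(lex, category)
#' @export
generate_lexicon <- function(n_bases,
                             affixes = default_affixes(),
                             inventory = default_inventory(),
                             base_length = c(3L, 6L),
                             seed = 1L) {
  if (n_bases < 1L) abort("`n_bases` must be >= 1")
  validate_affixes(affixes, inventory)
  if (any(affixes$n_types > n_bases)) {
    abort("each affix's `n_types` must not exceed `n_bases`")
  }
  set.seed(as.integer(seed))

  symbols <- as.character(inventory)
  vowels <- intersect(symbols, c("a", "e", "i", "o", "u", "{", "@", "$",
                                 "I", "1", "2", "E", "O", "U", "y"))
  consonants <- setdiff(symbols, vowels)
  if (!length(vowels)) vowels <- symbols
  if (!length(consonants)) consonants <- symbols

  make_base <- function() {
    len <- sample(seq(base_length[1], base_length[2]), 1L)
    start_c <- runif(1) < 0.8
    phones <- character(len)
    for (i in seq_len(len)) {
      pool <- if (xor(i %% 2L == 1L, !start_c)) consonants else vowels
      phones[i] <- sample(pool, 1L)
    }
    paste(phones, collapse = "")
  }

  # rejection-sample unique base forms; a too-small alphabet cannot supply
  # n_bases distinct strings and must fail loudly
  bases <- character(0)
  attempts <- 0L
  max_attempts <- 200L * n_bases
  while (length(bases) < n_bases) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(paste0("phone alphabet too small to generate ", n_bases,
                   " unique base forms"))
    }
    cand <- make_base()
    if (!cand %in% bases) bases <- c(bases, cand)
  }

  base_ids <- sprintf("w%03d", seq_len(n_bases))
  lexicon <- tibble(
    word_id = base_ids,
    transcription = bases,
    base_id = NA_character_,
    category = NA_character_
  )

  derived <- purrr::pmap_dfr(affixes, function(category, form, position,
                                               shift_scale, n_types) {
    picked <- sample.int(n_bases, n_types)
    trans <- if (position == "prefix") {
      paste0(form, bases[picked])
    } else {
      paste0(bases[picked], form)
    }
    tibble(
      word_id = paste0(base_ids[picked], "_", category),
      transcription = trans,
      base_id = base_ids[picked],
      category = category
    )
  })

  lexicon <- dplyr::bind_rows(lexicon, derived)
  if (anyDuplicated(lexicon$transcription)) {
    dup <- lexicon$transcription[duplicated(lexicon$transcription)]
    abort(paste0("generated lexicon contains duplicate transcriptions (",
                 paste(unique(dup), collapse = ", "),
                 "); enlarge the inventory or base_length range"))
  }
  new_ldl_lexicon(lexicon, inventory, affixes)
}

new_ldl_lexicon <- function(x, inventory, affixes = NULL) {
  structure(as_tibble(x),
            inventory = inventory,
            affixes = affixes,
            class = c("ldl_lexicon", class(as_tibble(x))))
}

#' @rdname generate_lexicon
#' @param lexicon An `ldl_lexicon`.
#' @export
lexicon_inventory <- function(lexicon) {
  inv <- attr(lexicon, "inventory")
  if (is.null(inv)) abort("lexicon carries no phoneme inventory attribute")
  inv
}

validate_lexicon <- function(lexicon) {
  required <- c("word_id", "transcription", "base_id", "category")
  missing <- setdiff(required, names(lexicon))
  if (length(missing)) {
    abort(paste0("lexicon lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(lexicon$word_id)) {
    abort("duplicate word_id in lexicon")
  }
  derived <- !is.na(lexicon$category)
  if (any(derived & is.na(lexicon$base_id))) {
    abort("derived entries (non-NA category) must name a base_id")
  }
  bad_base <- derived & !(lexicon$base_id %in% lexicon$word_id)
  if (any(bad_base)) {
    abort(paste0("base_id not present in lexicon for: ",
                 paste(lexicon$word_id[bad_base], collapse = ", ")))
  }
  invisible(lexicon)
}

#' Generate a table of mean segment durations
#'
#' One mean duration (ms) per phone in the inventory, drawn from a
#' log-normal distribution so that all means are positive and spread over a
#' plausible range for speech segments (roughly 40--120 ms). This is the
#' synthetic stand-in for corpus-estimated segment means used to compute
#' baseline durations.
#'
#' @param inventory A [phoneme_inventory()].
#' @param meanlog,sdlog Log-normal parameters of the segment means.
#' @param seed Integer seed.
#' @return A tibble with columns `phone` and `mean_duration` (ms).
#' @export
generate_segment_table <- function(inventory = default_inventory(),
                                   meanlog = log(70), sdlog = 0.25,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  tibble(
    phone = as.character(inventory),
    mean_duration = rlnorm(length(inventory), meanlog, sdlog)
  )
}
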