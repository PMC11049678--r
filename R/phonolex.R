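#' Phoneme inventories
#'
#' A phoneme inventory is the closed set of single-character phoneme symbols
#' the model operates over, plus one reserved silence symbol that is not a
#' phoneme. All lexicon and input-schedule machinery validates against an
#' inventory.
#'
#' @param symbols Character vector of unique single-character phoneme codes
#'   (at least 2).
#' @param silence A single character used to denote silence; must not be a
#'   member of `symbols`.
#' @return An object of class `phoneme_inventory` with elements `symbols`
#'   and `silence`.
#' @examples
#' inv <- phoneme_inventory(c("p", "b", "a"))
#' default_inventory()
#' @export
phoneme_inventory <- function(symbols, silence = "-") {
  symbols <- as.character(symbols)
  if (length(symbols) < 2L) {
    stop("inventory must contain at least 2 phoneme symbols", call. = FALSE)
  }
  if (anyDuplicated(symbols)) {
    stop("inventory symbols must be unique", call. = FALSE)
  }
  if (any(nchar(symbols) != 1L)) {
    stop("phoneme symbols must be single characters", call. = FALSE)
  }
  if (!is.character(silence) || length(silence) != 1L || nchar(silence) != 1L) {
    stop("silence must be a single character", call. = FALSE)
  }
  if (silence %in% symbols) {
    stop("silence symbol must not be a phoneme symbol", call. = FALSE)
  }
  structure(list(symbols = symbols, silence = silence),
            class = "phoneme_inventory")
}

#' Default 14-symbol phoneme inventory
#'
#' The bundled default inventory mirrors the classic 14-phoneme set used by
#' small-scale interactive-activation simulations of spoken word
#' recognition: `p b t d k g s S r l a i u ^`, where `S` stands for the
#' postalveolar fricative ("sh") and `^` for the mid-central vowel
#' (schwa-like "uh"). The silence symbol is `-`.
#'
#' @return A [phoneme_inventory()].
#' @export
default_inventory <- function() {
  phoneme_inventory(
    c("p", "b", "t", "d", "k", "g", "s", "S", "r", "l", "a", "i", "u", "^"),
    silence = "-"
  )
}

#' @export
print.phoneme_inventory <- function(x, ...) {
  cat("<phoneme_inventory> ", length(x$symbols), " symbols: ",
      paste(x$symbols, collapse = " "), "  (silence: '", x$silence, "')\n",
      sep = "")
  invisible(x)
}

#' Read / write an inventory as YAML
#'
#' The on-disk format is a YAML mapping with keys `symbols` (list of
#' single-character strings) and `silence`.
#'
#' @param path File path.
#' @return For `load_inventory`, a [phoneme_inventory()].
#' @export
load_inventory <- function(path) {
  y <- yaml::read_yaml(path)
  phoneme_inventory(as.character(y$symbols), silence = y$silence %||% "-")
}

#' @rdname load_inventory
#' @param inventory A [phoneme_inventory()].
#' @export
write_inventory <- function(inventory, path) {
  stopifnot(inherits(inventory, "phoneme_inventory"))
  yaml::write_yaml(list(symbols = as.list(inventory$symbols),
                        silence = inventory$silence), path)
  invisible(path)
}

#' Split a phoneme string into a phoneme vector
#'
#' Phonemes are single characters, so a word like `"pl^g"` splits into
#' `c("p","l","^","g")`. Character vectors of length > 1 are returned
#' unchanged.
#'
#' @param x A single string or a character vector of single-character
#'   phoneme symbols.
#' @return Character vector of phoneme symbols.
#' @export
phonemes <- function(x) {
  if (length(x) == 1L && nchar(x) != 1L) {
    strsplit(x, "", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
}

check_phonemes <- function(phon, inventory, context = "") {
  bad <- setdiff(unique(phon), inventory$symbols)
  if (length(bad)) {
    stop(sprintf("unknown phoneme symbol%s '%s'%s",
                 if (length(bad) > 1) "s" else "",
                 paste(bad, collapse = "', '"), context),
         call. = FALSE)
  }
  invisible(phon)
}

new_lexicon <- function(labels, phoneme_list, inventory) {
  structure(list(labels = labels, phonemes = phoneme_list,
                 inventory = inventory),
            class = "tisk_lexicon")
}

#' Construct a lexicon
#'
#' A lexicon is an ordered set of uniquely-labelled phoneme strings over a
#' fixed inventory; the model's word layer is built from it, one node per
#' entry.
#'
#' @param words Named list or named character vector: names are word labels,
#'   values are phoneme strings (or phoneme character vectors).
#' @param inventory A [phoneme_inventory()].
#' @return An object of class `tisk_lexicon`.
#' @examples
#' lex <- lexicon(c(plug = "pl^g", blush = "bl^S"), default_inventory())
#' @export
lexicon <- function(words, inventory = default_inventory()) {
  stopifnot(inherits(inventory, "phoneme_inventory"))
  labels <- names(words)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("every lexicon entry must have a label", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicate label '%s'", labels[duplicated(labels)][1]),
         call. = FALSE)
  }
  phoneme_list <- lapply(seq_along(words), function(i) {
    ph <- phonemes(words[[i]])
    if (length(ph) < 1L) {
      stop(sprintf("entry '%s' has no phonemes", labels[i]), call. = FALSE)
    }
    check_phonemes(ph, inventory, sprintf(" in entry '%s'", labels[i]))
  })
  new_lexicon(labels, phoneme_list, inventory)
}

#' @export
length.tisk_lexicon <- function(x) length(x$labels)

#' @export
print.tisk_lexicon <- function(x, ...) {
  cat("<tisk_lexicon> ", length(x), " words over ",
      length(x$inventory$symbols), " phonemes\n", sep = "")
  n <- min(length(x), 6L)
  if (n > 0) {
    for (i in seq_len(n)) {
      cat("  ", x$labels[i], "\t/", paste(x$phonemes[[i]], collapse = ""),
          "/\n", sep = "")
    }
    if (length(x) > n) cat("  ... and", length(x) - n, "more\n")
  }
  invisible(x)
}

#' @export
as.data.frame.tisk_lexicon <- function(x, ...) {
  data.frame(label = x$labels,
             phonemes = vapply(x$phonemes, paste, "", collapse = ""),
             length = lengths(x$phonemes),
             stringsAsFactors = FALSE)
}

lexicon_strings <- function(lexicon) {
  vapply(lexicon$phonemes, paste, "", collapse = "")
}

word_index <- function(lexicon, label) {
  i <- match(label, lexicon$labels)
  if (is.na(i)) stop(sprintf("word '%s' not in lexicon", label), call. = FALSE)
  i
}

#' Load a lexicon from a TSV file
#'
#' One entry per line, `label<TAB>phoneme-string`, UTF-8; blank lines and
#' lines starting with `#` are ignored. Every phoneme must belong to the
#' inventory and labels must be unique; violations raise an error naming the
#' offending line and symbol.
#'
#' @param path Path to the TSV file.
#' @param inventory A [phoneme_inventory()].
#' @return A `tisk_lexicon`.
#' @seealso [write_lexicon()], [bundled_lexicon()]
#' @export
load_lexicon <- function(path, inventory = default_inventory()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  labels <- character(0)
  phoneme_list <- list()
  for (ln in keep) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2])) {
      stop(sprintf("line %d: expected 'label<TAB>phonemes', got '%s'",
                   ln, lines[ln]), call. = FALSE)
    }
    lab <- trimws(parts[1])
    ph <- phonemes(trimws(parts[2]))
    if (lab %in% labels) {
      stop(sprintf("line %d: duplicate label '%s'", ln, lab), call. = FALSE)
    }
    bad <- setdiff(unique(ph), inventory$symbols)
    if (length(bad)) {
      stop(sprintf("line %d: unknown phoneme symbol '%s' in entry '%s'",
                   ln, bad[1], lab), call. = FALSE)
    }
    labels <- c(labels, lab)
    phoneme_list <- c(phoneme_list, list(ph))
  }
  new_lexicon(labels, phoneme_list, inventory)
}

#' @rdname load_lexicon
#' @param lexicon A `tisk_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "tisk_lexicon"))
  writeLines(paste(lexicon$labels, lexicon_strings(lexicon), sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Add a word to a lexicon
#'
#' Returns a new lexicon with the entry appended; downstream word-layer
#' sizes reflect the addition when a network is (re)built.
#'
#' @param lexicon A `tisk_lexicon`.
#' @param label Word label (must not already be present).
#' @param word Phoneme string or character vector.
#' @return A new `tisk_lexicon` with one more entry.
#' @examples
#' lex <- lexicon(c(plug = "pl^g"))
#' lex2 <- add_word(lex, "blush", "bl^S")
#' length(lex2)  # 2
#' @export
add_word <- function(lexicon, label, word) {
  stopifnot(inherits(lexicon, "tisk_lexicon"))
  if (label %in% lexicon$labels) {
    stop(sprintf("duplicate label '%s'", label), call. = FALSE)
  }
  ph <- phonemes(word)
  if (length(ph) < 1L) stop("word must have at least one phoneme", call. = FALSE)
  check_phonemes(ph, lexicon$inventory, sprintf(" in entry '%s'", label))
  new_lexicon(c(lexicon$labels, label), c(lexicon$phonemes, list(ph)),
              lexicon$inventory)
}

#' Count lexicon words containing a given ordered open diphone
#'
#' A word contains the ordered diphone (x, y) when some occurrence of x
#' precedes some occurrence of y (adjacent or not). Lexical statistics of
#' this kind drive right-context effects: fewer words sharing a diphone
#' means less feedback-driven competition for it.
#'
#' @param lexicon A `tisk_lexicon`.
#' @param x,y Single phoneme symbols (first and second member).
#' @return Character vector of labels of words containing the diphone.
#' @export
words_with_diphone <- function(lexicon, x, y) {
  stopifnot(inherits(lexicon, "tisk_lexicon"))
  has <- vapply(lexicon$phonemes, function(ph) {
    ix <- which(ph == x)
    iy <- which(ph == y)
    length(ix) > 0 && length(iy) > 0 && min(ix) < max(iy)
  }, logical(1))
  lexicon$labels[has]
}

#' Specification for a synthetic lexicon
#'
#' The synthetic generator emulates the structure of the small lexicons used
#' in classic spoken-word-recognition simulations: a couple hundred words of
#' 2 to 9 phonemes over a ~14-symbol inventory, with controllable densities
#' of onset cohorts, rhymes, and embeddings. Densities are the proportion of
#' words that have at least one competitor of the given class.
#'
#' @param n_words Number of words to generate (>= 1).
#' @param length_range Integer vector `c(min, max)` word length in phonemes
#'   (min >= 2).
#' @param target_cohort_density,target_rhyme_density,target_embedding_density
#'   Target proportions in `[0, 1]` of words with at least one cohort
#'   competitor (shared first two phonemes), same-length rhyme (mismatch only
#'   at the first phoneme), and embedded word (another word occurring as a
#'   contiguous substring), respectively.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_lexicon_spec`.
#' @seealso [generate_synthetic_lexicon()]
#' @export
synthetic_lexicon_spec <- function(n_words,
                                   length_range = c(2L, 9L),
                                   target_cohort_density = 0.5,
                                   target_rhyme_density = 0.3,
                                   target_embedding_density = 0.3,
                                   seed = 1L) {
  stopifnot(is_count(n_words, min = 1L))
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] < 2L ||
      length_range[2] < length_range[1]) {
    stop("length_range must be c(min, max) with min >= 2", call. = FALSE)
  }
  for (d in c(target_cohort_density, target_rhyme_density,
              target_embedding_density)) {
    if (!is_number(d) || d < 0 || d > 1) {
      stop("density targets must be in [0, 1]", call. = FALSE)
    }
  }
  structure(list(n_words = as.integer(n_words),
                 length_range = length_range,
                 target_cohort_density = target_cohort_density,
                 target_rhyme_density = target_rhyme_density,
                 target_embedding_density = target_embedding_density,
                 seed = as.integer(seed)),
            class = "synthetic_lexicon_spec")
}

#' Generate a synthetic lexicon with controllable competitor structure
#'
#' Words are built incrementally. Each new word is derived from an existing
#' one with probability given by the density targets (copying an onset to
#' create a cohort pair, substituting a first phoneme to create a rhyme, or
#' extending a word so that it embeds), otherwise sampled at random.
#' Duplicate phoneme strings and any string in `exclude` are rejected.
#' Achieved class densities are measured exhaustively and attached as the
#' `densities` attribute.
#'
#' @param spec A [synthetic_lexicon_spec()].
#' @param inventory A [phoneme_inventory()].
#' @param exclude Character vector of phoneme strings that must not appear
#'   (e.g. reserved nonwords).
#' @param labels Optional label prefix (default `"w"`; labels are
#'   `w001, w002, ...`).
#' @return A `tisk_lexicon` with attribute `densities` (named numeric:
#'   achieved cohort/rhyme/embedding densities).
#' @examples
#' lex <- generate_synthetic_lexicon(synthetic_lexicon_spec(50, seed = 1))
#' attr(lex, "densities")
#' @export
generate_synthetic_lexicon <- function(spec,
                                       inventory = default_inventory(),
                                       exclude = character(0),
                                       labels = "w") {
  stopifnot(inherits(spec, "synthetic_lexicon_spec"),
            inherits(inventory, "phoneme_inventory"))
  syms <- inventory$symbols
  lmin <- spec$length_range[1]
  lmax <- spec$length_range[2]
  # feasibility: distinct strings available over all admissible lengths
  capacity <- sum(length(syms)^(lmin:lmax))
  if (spec$n_words > capacity - length(exclude)) {
    stop("infeasible spec: n_words exceeds the number of distinct strings",
         call. = FALSE)
  }
  with_seed(spec$seed, {
    words <- list()
    seen <- character(0)
    rand_word <- function() {
      n <- sample(lmin:lmax, 1L)
      sample(syms, n, replace = TRUE)
    }
    propose <- function() {
      k <- length(words)
      if (k == 0L) return(rand_word())
      u <- runif(1)
      # rhyme and embedding moves derive from short bases only: real rhyme
      # neighborhoods and embedding families concentrate on short words,
      # and deriving near-duplicates of long words would create
      # unrealistically dense long-word neighborhoods (real families
      # like cat/bat/scat/cats share a short core)
      short <- which(lengths(words) <= 3L)
      base <- words[[sample.int(k, 1L)]]
      if (u < spec$target_cohort_density) {
        # share the first two phonemes with an existing word
        n <- sample(lmin:lmax, 1L)
        w <- c(base[1:2], if (n > 2) sample(syms, n - 2L, replace = TRUE))
        return(w[seq_len(max(n, 2L))])
      }
      u <- u - spec$target_cohort_density
      if (u < spec$target_rhyme_density && length(short)) {
        # same-length rhyme: substitute the first phoneme of a short base
        base <- words[[short[sample.int(length(short), 1L)]]]
        alt <- setdiff(syms, base[1])
        return(c(sample(alt, 1L), base[-1]))
      }
      u <- u - spec$target_rhyme_density
      if (u < spec$target_embedding_density && length(short)) {
        base <- words[[short[sample.int(length(short), 1L)]]]
        room <- lmax - length(base)
        if (room >= 1L) {
          # embed a short existing word inside a longer one
          extra <- sample.int(room, 1L)
          pre <- sample(0:extra, 1L)
          return(c(if (pre > 0) sample(syms, pre, replace = TRUE),
                   base,
                   if (extra - pre > 0) {
                     sample(syms, extra - pre, replace = TRUE)
                   }))
        }
      }
      rand_word()
    }
    tries <- 0L
    while (length(words) < spec$n_words) {
      w <- propose()
      key <- paste(w, collapse = "")
      # no geminates: adjacent identical phonemes are phonotactically
      # illegal in the emulated lexicons (repeats at a distance are fine)
      geminate <- length(w) > 1L && any(w[-1] == w[-length(w)])
      if (!geminate && !(key %in% seen) && !(key %in% exclude)) {
        words[[length(words) + 1L]] <- w
        seen <- c(seen, key)
        tries <- 0L
      } else {
        tries <- tries + 1L
        if (tries > 10000L) {
          stop("infeasible spec: could not find further distinct strings",
               call. = FALSE)
        }
      }
    }
    labs <- sprintf("%s%03d", labels, seq_along(words))
    lex <- new_lexicon(labs, words, inventory)
    attr(lex, "densities") <- lexicon_densities(lex)
    lex
  })
}

#' Measure competitor-class densities of a lexicon
#'
#' Exhaustive pairwise scan: for each word, does it have at least one cohort
#' competitor (shared first two phonemes), at least one same-length rhyme
#' (mismatch only at the first phoneme), and at least one embedded word
#' (another word as contiguous substring)?
#'
#' @param lexicon A `tisk_lexicon`.
#' @return Named numeric vector with elements `cohort`, `rhyme`, `embedding`
#'   (proportions of words with >= 1 competitor of that class).
#' @export
lexicon_densities <- function(lexicon) {
  n <- length(lexicon)
  if (n < 2L) {
    return(c(cohort = 0, rhyme = 0, embedding = 0))
  }
  ph <- lexicon$phonemes
  strs <- lexicon_strings(lexicon)
  has_cohort <- logical(n)
  has_rhyme <- logical(n)
  has_embed <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- ph[[i]]; b <- ph[[j]]
      if (!has_cohort[i] && length(a) >= 2 && length(b) >= 2 &&
          a[1] == b[1] && a[2] == b[2]) {
        has_cohort[i] <- TRUE
      }
      if (!has_rhyme[i] && length(a) == length(b) && a[1] != b[1] &&
          (length(a) == 1L || identical(a[-1], b[-1]))) {
        has_rhyme[i] <- TRUE
      }
      if (!has_embed[i] && length(b) < length(a) &&
          grepl(strs[j], strs[i], fixed = TRUE)) {
        has_embed[i] <- TRUE
      }
    }
  }
  c(cohort = mean(has_cohort), rhyme = mean(has_rhyme),
    embedding = mean(has_embed))
}

#' The ten Ganong / restoration item words
#'
#' Ten 4-phoneme words used by the Ganong-effect and phoneme-restoration
#' simulations: appeal, box, boost, duty, greet, least, school, shield,
#' screw, and ugly. Transcriptions are over [default_inventory()]; duty is
#' /duti/, the remaining transcriptions are fixed here (the `^` symbol
#' stands for the reduced/mid-central vowel, `S` for "sh").
#'
#' @return Named character vector of 10 four-phoneme strings (names are the
#'   word labels).
#' @seealso [ganong_replacements()], [bundled_lexicon()]
#' @export
ganong_word_fixture <- function() {
  c(appeal = "^pil",
    box    = "baks",
    boost  = "bust",
    duty   = "duti",
    greet  = "grit",
    least  = "list",
    school = "skul",
    shield = "Sild",
    screw  = "skru",
    ugly   = "^gli")
}

#' Replacement phonemes for the Ganong continua
#'
#' For each fixture word and each of its four positions, the phoneme used as
#' the nonword endpoint of the identification continuum. Replacements keep
#' the segment class (consonant for consonant, vowel for vowel) and always
#' produce a nonword relative to the bundled lexicon; for duty they are
#' /buti/, /d^ti/, /duri/ and /dut^/.
#'
#' @return A 10 x 4 character matrix; rows named by word label, columns
#'   `pos1`..`pos4`.
#' @export
ganong_replacements <- function() {
  m <- rbind(
    appeal = c("a", "t", "u", "t"),
    box    = c("d", "u", "t", "t"),
    boost  = c("d", "a", "r", "k"),
    duty   = c("b", "^", "r", "^"),
    greet  = c("b", "l", "u", "p"),
    least  = c("r", "a", "r", "k"),
    school = c("p", "t", "a", "t"),
    shield = c("s", "u", "r", "t"),
    screw  = c("p", "t", "l", "a"),
    ugly   = c("a", "b", "r", "u")
  )
  colnames(m) <- paste0("pos", 1:4)
  m
}

#' The bundled 211-word synthetic lexicon
#'
#' A stand-in for the small historical simulation lexicon: the 10 Ganong
#' fixture words plus plug (/pl^g/) and blush (/bl^S/), filled to 211 words
#' with synthetic entries from [generate_synthetic_lexicon()] under a fixed
#' seed. The strings blug, plush and all Ganong replacement nonwords are
#' excluded, so the critical items of the right-context and Ganong
#' simulations remain nonwords. Stored as a TSV under `extdata` (the
#' filename marks it as synthetic).
#'
#' @return A `tisk_lexicon` of 211 words over [default_inventory()].
#' @export
bundled_lexicon <- function() {
  path <- system.file("extdata", "lexicon_synthetic_211.tsv", package = "tisk")
  if (!nzchar(path)) stop("bundled lexicon not found", call. = FALSE)
  load_lexicon(path, default_inventory())
}
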