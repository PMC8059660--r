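## IPA segmentation, articulatory feature classification, the sound-group
## registry, and the L1 acquisition-order matrix.

# classification-neutral modifier letters that attach to the preceding base
.IPA_MODIFIERS <- c("ː", "ˑ", "ʰ", "ʲ", "ʷ",
                    "ˠ", "ˤ", "ⁿ", "ʼ")
# tie bars joining an affricate's two components
.IPA_TIES <- c("͡", "͜")
# combining diacritics that mark voicelessness (ring below / above)
.IPA_VOICELESS <- c("̥", "̊")

.read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "soundstab")
  if (!nzchar(path)) stop("missing config fixture: ", file)
  x <- read.delim(path, sep = "\t", quote = "", fileEncoding = "UTF-8",
                  stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character", fill = TRUE)
  x[is.na(x)] <- ""
  x
}

.segment_table <- function() {
  if (is.null(.soundstab_cache$segments)) {
    seg <- .read_fixture("segments.tsv")
    feat <- c("major", "place", "manner", "voicing",
              "height", "backness", "rounding")
    missing <- setdiff(feat, names(seg))
    for (m in missing) seg[[m]] <- ""
    rownames(seg) <- seg$token
    .soundstab_cache$segments <- seg
  }
  .soundstab_cache$segments
}

#' Base IPA segment inventory with articulatory feature bundles
#'
#' The shipped segment-to-feature mapping (config fixture
#' \code{extdata/segments.tsv}). Consonants carry place / manner / voicing;
#' vowels carry height / backness / rounding; unused fields are \code{""}.
#' Dental, alveolar and retroflex places are merged as \code{alveolar} and
#' uvulars as \code{velar}; affricates are single stop-class segments;
#' fricatives and approximants are \code{continuant}; trills and taps are
#' \code{vibrant}.
#'
#' @return data.frame with columns token, major, place, manner, voicing,
#'   height, backness, rounding.
#' @export
segmentInventory <- function() {
  seg <- .segment_table()
  rownames(seg) <- NULL
  seg
}

.is_combining <- function(ch) {
  stringi::stri_detect_charclass(ch, "[\\p{Mn}]")
}

#' Tokenize an IPA string into segments
#'
#' Greedy longest-match tokenization against the segment inventory.
#' Combining diacritics and length/secondary-articulation marks attach to
#' the preceding base token; a tie bar joins the two flanking bases into a
#' single affricate token (classed as a stop). A string containing
#' whitespace is treated as pre-segmented and split on it. Input is NFC
#' normalised first.
#'
#' @param text a single IPA string (or a space-delimited pre-segmented one).
#' @return character vector of segment tokens.
#' @examples
#' segmentIPA("kaksi")       # k a k s i
#' segmentIPA("t͡ʃaː")  # t͡ʃ aː
#' @export
segmentIPA <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- stringi::stri_trans_nfc(trimws(text))
  if (!nzchar(text)) stop("empty IPA string")
  if (stringi::stri_detect_regex(text, "\\s"))
    return(stringi::stri_split_regex(text, "\\s+")[[1]])
  inv <- rownames(.segment_table())
  ch <- stringi::stri_sub(text, seq_len(stringi::stri_length(text)),
                          length = 1L)
  n <- length(ch)
  toks <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (L in seq.int(min(3L, n - i + 1L), 1L)) {
      cand <- paste(ch[i:(i + L - 1L)], collapse = "")
      if (cand %in% inv) { matched <- L; break }
    }
    if (matched > 0L) {
      toks <- c(toks, paste(ch[i:(i + matched - 1L)], collapse = ""))
      i <- i + matched
    } else if (ch[i] %in% .IPA_TIES) {
      if (length(toks) == 0L || i == n)
        stop("dangling tie bar at position ", i, " in '", text, "'")
      toks[length(toks)] <- paste0(toks[length(toks)], ch[i], ch[i + 1L])
      i <- i + 2L
    } else if (ch[i] %in% .IPA_MODIFIERS || .is_combining(ch[i])) {
      if (length(toks) == 0L)
        stop("diacritic without base at position ", i, " in '", text, "'")
      toks[length(toks)] <- paste0(toks[length(toks)], ch[i])
      i <- i + 1L
    } else {
      stop("cannot tokenize '", ch[i], "' at position ", i,
           " in '", text, "'")
    }
  }
  toks
}

.strip_marks <- function(token) {
  ch <- stringi::stri_sub(token, seq_len(stringi::stri_length(token)),
                          length = 1L)
  keep <- !(ch %in% .IPA_MODIFIERS) & !.is_combining(ch)
  paste(ch[keep], collapse = "")
}

.classify_one <- function(token, seg) {
  empty <- list(major = NA_character_, place = "", manner = "",
                voicing = "", height = "", backness = "", rounding = "")
  lookup <- function(tok) {
    if (tok %in% rownames(seg)) as.list(seg[tok, -1L]) else NULL
  }
  b <- lookup(token)
  ring <- any(stringi::stri_sub(token,
                                seq_len(stringi::stri_length(token)),
                                length = 1L) %in% .IPA_VOICELESS)
  if (is.null(b)) {
    base <- .strip_marks(token)
    tie <- which(stringi::stri_sub(base,
                                   seq_len(stringi::stri_length(base)),
                                   length = 1L) %in% .IPA_TIES)
    b <- lookup(base)
    if (is.null(b) && length(tie) == 1L) {
      # unknown affricate: stop manner; place/voicing from the fricative
      # component, falling back to the stop component
      parts <- c(stringi::stri_sub(base, 1L, tie - 1L),
                 stringi::stri_sub(base, tie + 1L))
      b2 <- lookup(parts[2L])
      b1 <- lookup(parts[1L])
      src <- if (!is.null(b2)) b2 else b1
      if (is.null(src)) return(NULL)
      b <- src
      b$manner <- "stop"
    }
    if (is.null(b)) return(NULL)
  }
  if (ring && identical(b$major, "consonant")) b$voicing <- "voiceless"
  b
}

#' Classify segment tokens into articulatory feature bundles
#'
#' Deterministic lookup against the shipped inventory. Diacritics are
#' stripped for the lookup (so \code{a} and \code{aː} share a bundle);
#' a voiceless ring overrides voicing; unknown tie-bar clusters are classed
#' as stops via their components.
#'
#' @param tokens character vector of segment tokens (from
#'   \code{\link{segmentIPA}}).
#' @return data.frame with one row per token: token, major, place, manner,
#'   voicing, height, backness, rounding (\code{""} = not applicable).
#' @examples
#' classifySegment(c("p", "u", "r", "n̥"))
#' @export
classifySegment <- function(tokens) {
  stopifnot(is.character(tokens))
  seg <- .segment_table()
  rows <- lapply(tokens, function(tok) {
    b <- .classify_one(tok, seg)
    if (is.null(b))
      stop("unknown segment token: '", tok, "'")
    data.frame(token = tok, major = b$major, place = b$place,
               manner = b$manner, voicing = b$voicing, height = b$height,
               backness = b$backness, rounding = b$rounding,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The default 54-group sound-group registry
#'
#' Consonant groups (32): voiced/voiceless; the five manner groups (nasal,
#' stop, continuant, vibrant, lateral); manner-by-voicing (10); the five
#' place groups (labial, alveolar, palatal, velar, glottal); and
#' place-by-voicing (10). Vowel groups (22): three heights; three
#' backnesses; rounded/unrounded; height-by-backness (9); four
#' backness-by-rounding groups; and low front rounded vowels. Five groups
#' (voiced glottal, voiceless nasal, voiceless lateral, voiceless vibrant,
#' low front rounded vowel) are flagged as excluded from stability
#' estimation for data sparsity.
#'
#' @param file optional path to an alternative registry TSV with the same
#'   columns as \code{extdata/groups.tsv}.
#' @param sparse_excluded character, names of groups to exclude from SSt.
#' @return a \linkS4class{GroupRegistry}.
#' @export
defaultRegistry <- function(file = NULL,
                            sparse_excluded = c("voiced glottal",
                                                "voiceless nasal",
                                                "voiceless lateral",
                                                "voiceless vibrant",
                                                "low front rounded vowel")) {
  g <- if (is.null(file)) .read_fixture("groups.tsv") else {
    x <- read.delim(file, sep = "\t", quote = "", fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE, colClasses = "character",
                    fill = TRUE)
    x[is.na(x)] <- ""
    x
  }
  new("GroupRegistry", groups = g, sparse_excluded = sparse_excluded)
}

#' @rdname accessors
#' @export
setMethod("groupNames", "GroupRegistry", function(x) x@groups$name)

#' @rdname accessors
#' @export
setMethod("sparseExcluded", "GroupRegistry", function(x) x@sparse_excluded)

setMethod("show", "GroupRegistry", function(object) {
  g <- object@groups
  cat("GroupRegistry with", nrow(g), "sound groups (",
      sum(g$major == "consonant"), "consonant,",
      sum(g$major == "vowel"), "vowel );",
      length(object@sparse_excluded), "sparsity-excluded\n")
})

#' Group membership of segment tokens
#'
#' Evaluates every registry group's feature-conjunction predicate on each
#' token's feature bundle.
#'
#' @param tokens character vector of segment tokens.
#' @param registry a \linkS4class{GroupRegistry}.
#' @return logical matrix, tokens x groups.
#' @examples
#' m <- groupMembership("b", defaultRegistry())
#' colnames(m)[m[1, ]]  # voiced, stop, labial, voiced stop, voiced labial
#' @export
groupMembership <- function(tokens, registry = defaultRegistry()) {
  bundle <- classifySegment(tokens)
  g <- registry@groups
  fields <- c("place", "manner", "voicing", "height", "backness", "rounding")
  M <- matrix(FALSE, nrow = length(tokens), ncol = nrow(g),
              dimnames = list(tokens, g$name))
  for (j in seq_len(nrow(g))) {
    ok <- bundle$major == g$major[j]
    for (f in fields) {
      if (nzchar(g[[f]][j])) ok <- ok & (bundle[[f]] == g[[f]][j])
    }
    M[, j] <- ok
  }
  M
}

#' The L1 earlier/later acquisition matrix
#'
#' Relative first-language acquisition order of feature values following
#' the babbling period, over five feature classes: place (labial, alveolar
#' earlier; palatal, velar, glottal later), manner (stop earlier;
#' continuant later), voicing (voiceless earlier; voiced later), openness
#' (low earlier; high, mid later) and backness (back earlier; front,
#' central later).
#'
#' @return data.frame with columns feature_class, feature_value, l1.
#' @export
l1Matrix <- function() .read_fixture("l1_matrix.tsv")

.L1_AXES <- c(place = "place", manner = "manner", voicing = "voicing",
              openness = "height", backness = "backness")

#' Code sound groups as earlier/later in L1 acquisition
#'
#' A group is coded on an axis iff its defining feature conjunction entails
#' a feature value that the L1 matrix codes on that axis, regardless of the
#' group's granularity level (so \code{voiced stop} is \emph{earlier} on
#' the manner axis and \emph{later} on the voicing axis). With
#' \code{axis = NULL} a single label is resolved across all five axes;
#' conflicting entailments yield \code{"none"}.
#'
#' @param registry a \linkS4class{GroupRegistry}.
#' @param axis one of \code{"place"}, \code{"manner"}, \code{"voicing"},
#'   \code{"openness"}, \code{"backness"}, or \code{NULL}.
#' @return named character vector over registry groups with values
#'   \code{"earlier"}, \code{"later"} or \code{"none"}.
#' @examples
#' l1Coding(defaultRegistry(), "manner")[c("stop", "voiced stop", "nasal")]
#' @export
l1Coding <- function(registry = defaultRegistry(), axis = NULL) {
  g <- registry@groups
  l1 <- l1Matrix()
  code_axis <- function(ax) {
    field <- .L1_AXES[[ax]]
    rows <- l1[l1$feature_class == ax, ]
    val <- g[[field]]
    out <- rep("none", nrow(g))
    hit <- match(val, rows$feature_value)
    coded <- nzchar(val) & !is.na(hit)
    out[coded] <- rows$l1[hit[coded]]
    names(out) <- g$name
    out
  }
  if (!is.null(axis)) {
    axis <- match.arg(axis, names(.L1_AXES))
    return(code_axis(axis))
  }
  per <- vapply(names(.L1_AXES), code_axis,
                character(nrow(g)))
  apply(per, 1L, function(v) {
    v <- unique(v[v != "none"])
    if (length(v) == 1L) v else "none"
  })
}
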