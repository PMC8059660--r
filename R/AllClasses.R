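#' @title Core S4 classes
#' @description S4 containers for wordlists, the sound-group registry,
#'   per-language information models, similarity (correspondence) models,
#'   pairwise alignments, and language-pair stability summaries.
#' @name soundstab-classes
NULL

#' Wordlist: long-format lexical data
#'
#' One row per word form: language, concept, the orthographic/IPA form and
#' its segmentation into IPA segment tokens. Synonyms (several forms for
#' one language-concept slot) are allowed and retained.
#'
#' @slot forms data.frame with columns \code{language_id}, \code{concept_id},
#'   \code{form} (character) and \code{segments} (list of character vectors).
#' @exportClass Wordlist
setClass("Wordlist", representation(forms = "data.frame"))

setValidity("Wordlist", function(object) {
  f <- object@forms
  need <- c("language_id", "concept_id", "form", "segments")
  if (!all(need %in% names(f)))
    return(paste("forms must have columns:", paste(need, collapse = ", ")))
  if (nrow(f) == 0L) return(TRUE)
  if (!is.list(f$segments)) return("segments must be a list column")
  if (any(!nzchar(f$language_id)) || any(!nzchar(f$concept_id)))
    return("language_id and concept_id must be non-empty")
  if (any(lengths(f$segments) == 0L))
    return("every form must have a non-empty segmentation")
  if (anyDuplicated(f[, c("language_id", "concept_id", "form")]))
    return("(language_id, concept_id, form) must be unique")
  TRUE
})

#' GroupRegistry: named articulatory sound groups
#'
#' An ordered collection of sound groups, each a conjunction of segment
#' feature values (empty field = unconstrained), plus the names of groups
#' excluded from stability estimation for data sparsity. The default
#' registry (\code{\link{defaultRegistry}}) has 54 groups across the
#' feature classes place, manner, voicing, openness (height), backness and
#' rounding, at several granularity levels.
#'
#' @slot groups data.frame with columns \code{name}, \code{feature_class},
#'   \code{major}, \code{place}, \code{manner}, \code{voicing},
#'   \code{height}, \code{backness}, \code{rounding}.
#' @slot sparse_excluded character, group names left out of SSt estimation.
#' @exportClass GroupRegistry
setClass("GroupRegistry",
         representation(groups = "data.frame", sparse_excluded = "character"))

setValidity("GroupRegistry", function(object) {
  g <- object@groups
  need <- c("name", "feature_class", "major", "place", "manner", "voicing",
            "height", "backness", "rounding")
  if (!all(need %in% names(g)))
    return(paste("groups must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(g$name)) return("group names must be unique")
  if (!all(object@sparse_excluded %in% g$name))
    return("sparse_excluded must be a subset of group names")
  TRUE
})

#' InfoModel: per-language trigram information-content model
#'
#' Symmetric forward/backward trigram counts over one language's segmented
#' forms, padded with two boundary symbols on the relevant side. Surprisal
#' under add-constant smoothing, averaged over the two directions and
#' normalised by the uniform surprisal cap, gives each position an
#' information weight in [0, 1] (see \code{\link{infoContent}}).
#'
#' @slot language_id character scalar.
#' @slot forward,forward_ctx named numeric count tables (trigram, context).
#' @slot backward,backward_ctx the same over reversed forms.
#' @slot inventory_size integer, distinct segment tokens in the language.
#' @slot smoothing numeric add-constant (default 0.5).
#' @exportClass InfoModel
setClass("InfoModel",
         representation(language_id = "character",
                        forward = "numeric", forward_ctx = "numeric",
                        backward = "numeric", backward_ctx = "numeric",
                        inventory_size = "integer", smoothing = "numeric"))

setValidity("InfoModel", function(object) {
  if (object@inventory_size < 1L) return("inventory_size must be >= 1")
  if (any(object@forward < 0) || any(object@backward < 0))
    return("counts must be non-negative")
  if (object@smoothing < 0) return("smoothing must be >= 0")
  TRUE
})

#' SimilarityModel: segment-pair correspondence scores
#'
#' A symmetric score matrix over the segment alphabet plus a linear gap
#' penalty, either feature-based initial scores or PMI scores learned by
#' \code{\link{estimatePMI}}.
#'
#' @slot scores symmetric numeric matrix, dimnames = segment alphabet.
#' @slot gap_penalty negative numeric scalar.
#' @slot iterations_run integer, PMI iterations applied so far.
#' @exportClass SimilarityModel
setClass("SimilarityModel",
         representation(scores = "matrix", gap_penalty = "numeric",
                        iterations_run = "integer"))

setValidity("SimilarityModel", function(object) {
  s <- object@scores
  if (is.null(dimnames(s)) || !identical(rownames(s), colnames(s)))
    return("scores must have identical row and column names")
  if (max(abs(s - t(s))) > 1e-12) return("scores must be symmetric")
  if (object@gap_penalty >= 0) return("gap_penalty must be negative")
  TRUE
})

#' Alignment: a globally aligned pair of word forms
#'
#' Position-wise pairing of two forms' segments. Gaps are \code{NA}; no
#' cell is gap-gap. Each cell carries an information weight in [0, 1]
#' (mean of the two sides' info content; the non-gap side alone for gap
#' cells, 1 when no info models were supplied).
#'
#' @slot left,right character vectors of equal length, \code{NA} = gap.
#' @slot weights numeric, per-cell information weight.
#' @slot score numeric alignment score.
#' @slot left_language,right_language character scalars (may be \code{NA}).
#' @exportClass Alignment
setClass("Alignment",
         representation(left = "character", right = "character",
                        weights = "numeric", score = "numeric",
                        left_language = "character",
                        right_language = "character"))

setValidity("Alignment", function(object) {
  n <- length(object@left)
  if (length(object@right) != n || length(object@weights) != n)
    return("left, right and weights must have equal length")
  if (any(is.na(object@left) & is.na(object@right)))
    return("no cell may be gap on both sides")
  if (any(object@weights < 0 | object@weights > 1, na.rm = TRUE))
    return("weights must lie in [0, 1]")
  TRUE
})

#' PairStability: weighted identity proportion for one language pair
#'
#' @slot language_a,language_b character scalars.
#' @slot s numeric in [0, 1], information-weighted proportion of aligned
#'   both-segment cells whose two segment tokens are identical.
#' @slot n_word_pairs,n_segment_pairs,n_identical integer tallies
#'   (unweighted); \code{n_segment_pairs} counts both-segment cells only.
#' @exportClass PairStability
setClass("PairStability",
         representation(language_a = "character", language_b = "character",
                        s = "numeric", n_word_pairs = "integer",
                        n_segment_pairs = "integer", n_identical = "integer"))

setValidity("PairStability", function(object) {
  if (object@s < 0 || object@s > 1) return("s must lie in [0, 1]")
  if (object@n_identical > object@n_segment_pairs)
    return("n_identical cannot exceed n_segment_pairs")
  TRUE
})

#' SimConfig: configuration of the lexical-evolution simulator
#'
#' See \code{\link{simConfig}} for field semantics and defaults and
#' \code{\link{defaultPresets}} for the named study presets.
#'
#' @slot n_leaves,concept_count integer.
#' @slot branch_length numeric, per-edge duration of the balanced tree.
#' @slot inventory character, segment tokens available to the simulator.
#' @slot word_length integer length-2, min/max proto-word length.
#' @slot suffix_mode logical; \code{suffixes} character, the shared
#'   suffix inventory appended per language after evolution.
#' @slot intensities named numeric, per-class replacement intensity
#'   (consonants by manner: nasal, stop, continuant, vibrant, lateral;
#'   vowels by height: high, mid, low).
#' @slot replacement_kernel named numeric (alpha, beta, delta): within-group
#'   replacement, out-of-group replacement, deletion; sums to 1.
#' @slot insertion_rate numeric, per-unit-branch Poisson insertion rate.
#' @slot iconic_seeds data.frame (concept_id, group, boost).
#' @slot borrowing_rate numeric in [0, 1].
#' @slot seed integer RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
         representation(n_leaves = "integer", branch_length = "numeric",
                        inventory = "character", concept_count = "integer",
                        word_length = "integer", suffix_mode = "logical",
                        suffixes = "character", intensities = "numeric",
                        replacement_kernel = "numeric",
                        insertion_rate = "numeric",
                        iconic_seeds = "data.frame",
                        borrowing_rate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@n_leaves < 2L) return("n_leaves must be >= 2")
  if (object@branch_length <= 0) return("branch_length must be > 0")
  if (object@concept_count < 1L) return("concept_count must be >= 1")
  if (length(object@word_length) != 2L ||
      object@word_length[1] < 1L ||
      object@word_length[2] < object@word_length[1])
    return("word_length must be (min, max) with 1 <= min <= max")
  k <- object@replacement_kernel
  if (!all(c("alpha", "beta", "delta") %in% names(k)))
    return("replacement_kernel needs alpha, beta, delta")
  if (any(k < 0) || abs(sum(k) - 1) > 1e-9)
    return("replacement_kernel must be non-negative and sum to 1")
  need <- c("nasal", "stop", "continuant", "vibrant", "lateral",
            "high", "mid", "low")
  if (!all(need %in% names(object@intensities)))
    return(paste("intensities must name:", paste(need, collapse = ", ")))
  if (any(object@intensities < 0)) return("intensities must be >= 0")
  if (object@insertion_rate < 0) return("insertion_rate must be >= 0")
  if (object@borrowing_rate < 0 || object@borrowing_rate > 1)
    return("borrowing_rate must lie in [0, 1]")
  TRUE
})
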