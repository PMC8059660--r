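#' Accessor generics
#'
#' @param x an object.
#' @return \code{forms}: the underlying data.frame of a
#'   \linkS4class{Wordlist}; \code{languages} / \code{concepts}: sorted
#'   unique ids; \code{nForms}: number of forms; \code{groupNames}: the
#'   registry's group names in registry order; \code{sparseExcluded}: names
#'   of sparsity-excluded groups; \code{simScores} / \code{gapPenalty}: the
#'   score matrix and gap penalty of a \linkS4class{SimilarityModel}.
#' @name accessors
#' @examples
#' wl <- asWordlist(data.frame(language_id = "A", concept_id = "eye",
#'                             form = "kaksi"))
#' languages(wl); concepts(wl); nForms(wl)
NULL

#' @rdname accessors
#' @export
setGeneric("forms", function(x) standardGeneric("forms"))
#' @rdname accessors
#' @export
setGeneric("languages", function(x) standardGeneric("languages"))
#' @rdname accessors
#' @export
setGeneric("concepts", function(x) standardGeneric("concepts"))
#' @rdname accessors
#' @export
setGeneric("nForms", function(x) standardGeneric("nForms"))
#' @rdname accessors
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))
#' @rdname accessors
#' @export
setGeneric("sparseExcluded", function(x) standardGeneric("sparseExcluded"))
#' @rdname accessors
#' @export
setGeneric("simScores", function(x) standardGeneric("simScores"))
#' @rdname accessors
#' @export
setGeneric("gapPenalty", function(x) standardGeneric("gapPenalty"))

#' Replacement rate of a language pair
#'
#' The complement \code{1 - s} of a language pair's information-weighted
#' stability: the overall rate of phonetic replacement between the two
#' languages, used to down-weight aligned segment instances from closely
#' related pairs. A pair with stability 0.791 contributes each aligned
#' instance at only 20.9\% of a full sound pair; identical languages
#' (s = 1) contribute nothing.
#'
#' @param x a \linkS4class{PairStability} or a numeric stability value
#'   in [0, 1].
#' @return numeric in [0, 1].
#' @examples
#' replacementRate(0.791)  # 0.209
#' @export
setGeneric("replacementRate", function(x) standardGeneric("replacementRate"))

#' @rdname replacementRate
setMethod("replacementRate", "numeric", function(x) {
  stopifnot(all(x >= 0 & x <= 1))
  1 - x
})

#' @rdname replacementRate
setMethod("replacementRate", "PairStability", function(x) 1 - x@s)
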