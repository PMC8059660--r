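## Segment-pair similarity learning (iterative PMI), global alignment of
## word pairs, and threshold clustering of each concept's forms into
## homologue sets.

.wordlist_alphabet <- function(wordlist) {
  sort(unique(unlist(wordlist@forms$segments, use.names = FALSE)))
}

#' Feature-based initial similarity scores
#'
#' Bootstrap scores for PMI learning: identical segments +2; same place and
#' manner (consonants) or same height and backness (vowels) +1; same major
#' class 0; consonant against vowel -2. Gap penalty -1.
#'
#' @param wordlist a \linkS4class{Wordlist} supplying the segment alphabet.
#' @param gap_penalty linear gap penalty (negative).
#' @return a \linkS4class{SimilarityModel}.
#' @export
initialScores <- function(wordlist, gap_penalty = -1) {
  alphabet <- .wordlist_alphabet(wordlist)
  b <- classifySegment(alphabet)
  n <- length(alphabet)
  cons <- b$major == "consonant"
  same_major <- outer(b$major, b$major, "==")
  near <- outer(seq_len(n), seq_len(n), function(i, j) {
    ifelse(cons[i],
           b$place[i] == b$place[j] & b$manner[i] == b$manner[j],
           b$height[i] == b$height[j] & b$backness[i] == b$backness[j])
  })
  S <- matrix(-2, n, n, dimnames = list(alphabet, alphabet))
  S[same_major] <- 0
  S[same_major & near] <- 1
  diag(S) <- 2
  new("SimilarityModel", scores = S, gap_penalty = gap_penalty,
      iterations_run = 0L)
}

#' @rdname accessors
#' @export
setMethod("simScores", "SimilarityModel", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("gapPenalty", "SimilarityModel", function(x) x@gap_penalty)

setMethod("show", "SimilarityModel", function(object) {
  cat("SimilarityModel over", nrow(object@scores), "segments; gap penalty",
      object@gap_penalty, "; PMI iterations run:", object@iterations_run,
      "\n")
})

.encode <- function(segments, alphabet) {
  code <- match(segments, alphabet)
  if (anyNA(code))
    stop("segment(s) not in similarity alphabet: ",
         paste(unique(segments[is.na(code)]), collapse = ", "))
  code
}

#' Global alignment of two segmented forms
#'
#' Needleman-Wunsch with a linear gap penalty, maximising the total
#' similarity score. Traceback ties are broken deterministically:
#' match/mismatch first, then a gap on the left side, then a gap on the
#' right. Per-cell information weights are the mean of the two sides'
#' \code{\link{infoContent}} (the non-gap side alone for gap cells); 1
#' when no info models are given.
#'
#' @param left,right character vectors of segment tokens (non-empty).
#' @param sim a \linkS4class{SimilarityModel}.
#' @param info_left,info_right optional \linkS4class{InfoModel}s for the
#'   two forms' languages.
#' @return an \linkS4class{Alignment}.
#' @examples
#' wl <- asWordlist(data.frame(language_id = c("A", "B"),
#'                             concept_id = "eye",
#'                             form = c("kaksi", "kaks")))
#' nwAlign(c("k","a","k","s","i"), c("k","a","k","s"), initialScores(wl))
#' @export
nwAlign <- function(left, right, sim, info_left = NULL, info_right = NULL) {
  stopifnot(length(left) > 0L, length(right) > 0L,
            is(sim, "SimilarityModel"))
  alphabet <- rownames(sim@scores)
  res <- .nw_align_int(.encode(left, alphabet), .encode(right, alphabet),
                       sim@scores, sim@gap_penalty)
  la <- res$la
  ra <- res$ra
  wl <- if (is.null(info_left)) rep(1, length(left)) else
    infoContent(info_left, left)
  wr <- if (is.null(info_right)) rep(1, length(right)) else
    infoContent(info_right, right)
  cl <- ifelse(la > 0L, wl[pmax(la, 1L)], NA_real_)
  cr <- ifelse(ra > 0L, wr[pmax(ra, 1L)], NA_real_)
  w <- rowMeans(cbind(cl, cr), na.rm = TRUE)
  new("Alignment",
      left = ifelse(la > 0L, left[pmax(la, 1L)], NA_character_),
      right = ifelse(ra > 0L, right[pmax(ra, 1L)], NA_character_),
      weights = w, score = res$score,
      left_language = if (is.null(info_left)) NA_character_ else
        info_left@language_id,
      right_language = if (is.null(info_right)) NA_character_ else
        info_right@language_id)
}

setMethod("show", "Alignment", function(object) {
  g <- function(x) ifelse(is.na(x), "-", x)
  cat(paste(g(object@left), collapse = " "), "\n")
  cat(paste(g(object@right), collapse = " "), "\n")
  cat("score:", format(object@score), " mean weight:",
      format(mean(object@weights)), "\n")
})

# All cross-language same-concept form-pair indices (rows of the forms
# data.frame), ordered deterministically.
.concept_pairs <- function(f) {
  idx <- split(seq_len(nrow(f)), f$concept_id)
  out <- lapply(idx, function(rows) {
    if (length(rows) < 2L) return(NULL)
    cmb <- utils::combn(rows, 2L)
    keep <- f$language_id[cmb[1L, ]] != f$language_id[cmb[2L, ]]
    cmb[, keep, drop = FALSE]
  })
  do.call(cbind, out)
}

#' Learn PMI segment-correspondence scores
#'
#' Iteratively: align all cross-language same-concept form pairs with the
#' current scores; keep the best pairs by length-normalised score; recompute
#' each score as the pointwise mutual information
#' \code{log2(p(a,b) / (p(a) p(b)))} of aligned non-gap segment pairs under
#' add-0.1 smoothing, clipped to [-3, 3]. Deterministic given input order.
#'
#' @param wordlist a \linkS4class{Wordlist} with at least 2 languages.
#' @param sim0 initial \linkS4class{SimilarityModel}
#'   (\code{\link{initialScores}} by default).
#' @param iterations number of re-estimation rounds (>= 1).
#' @param keep_fraction proportion of best-scoring pairs kept (0, 1].
#' @return a \linkS4class{SimilarityModel} with updated scores.
#' @export
estimatePMI <- function(wordlist, sim0 = initialScores(wordlist),
                        iterations = 3L, keep_fraction = 0.7) {
  stopifnot(iterations >= 1L, keep_fraction > 0, keep_fraction <= 1)
  if (length(languages(wordlist)) < 2L)
    stop("insufficient data: need >= 2 languages for PMI estimation")
  f <- wordlist@forms
  pairs <- .concept_pairs(f)
  if (is.null(pairs) || ncol(pairs) == 0L)
    stop("insufficient data: no cross-language same-concept pairs")
  alphabet <- rownames(sim0@scores)
  seqs <- lapply(f$segments, .encode, alphabet = alphabet)
  lens <- lengths(seqs)
  allcodes <- unlist(seqs, use.names = FALSE)
  offsets <- cumsum(c(0L, lens))[seq_along(seqs)]
  S <- sim0@scores
  gap <- sim0@gap_penalty
  A <- length(alphabet)
  for (it in seq_len(iterations)) {
    res <- .nw_align_batch(seqs, pairs[1L, ], pairs[2L, ], S, gap)
    norm <- res$score / ((lens[pairs[1L, ]] + lens[pairs[2L, ]]) / 2)
    n_keep <- ceiling(keep_fraction * ncol(pairs))
    kept <- sort(order(norm, decreasing = TRUE)[seq_len(n_keep)])
    use <- res$pair_id %in% kept & res$la > 0L & res$ra > 0L
    # map cell indices back to segment codes via flat offsets
    ai <- allcodes[offsets[pairs[1L, res$pair_id[use]]] + res$la[use]]
    bi <- allcodes[offsets[pairs[2L, res$pair_id[use]]] + res$ra[use]]
    tab <- unclass(table(factor(ai, levels = seq_len(A)),
                         factor(bi, levels = seq_len(A))))
    C <- tab + t(tab)
    Cs <- C + 0.1
    P <- Cs / sum(Cs)
    pa <- rowSums(P)
    S_new <- log2(P / outer(pa, pa))
    S_new <- pmin(pmax(S_new, -3), 3)
    dimnames(S_new) <- list(alphabet, alphabet)
    S <- S_new
  }
  new("SimilarityModel", scores = S, gap_penalty = gap,
      iterations_run = sim0@iterations_run + as.integer(iterations))
}

#' Cluster each concept's forms into homologue sets
#'
#' Pairwise distance between two forms is
#' \code{1 - score(f,g) / mean(score(f,f), score(g,g))}, clipped to [0, 1];
#' average-linkage agglomerative clustering is cut at \code{threshold}.
#' Singleton sets are allowed.
#'
#' @param wordlist a \linkS4class{Wordlist}.
#' @param sim a \linkS4class{SimilarityModel}.
#' @param threshold distance cut in (0, 1).
#' @return data.frame with columns concept_id, set_id, row (index into
#'   \code{forms(wordlist)}), language_id, form.
#' @export
clusterHomologues <- function(wordlist, sim, threshold = 0.45) {
  stopifnot(threshold > 0, threshold < 1)
  f <- wordlist@forms
  alphabet <- rownames(sim@scores)
  seqs <- lapply(f$segments, .encode, alphabet = alphabet)
  self <- vapply(seqs, function(s) sum(diag(sim@scores)[s]), numeric(1))
  gap <- sim@gap_penalty
  out <- lapply(split(seq_len(nrow(f)), f$concept_id), function(rows) {
    m <- length(rows)
    if (m == 1L) {
      cl <- 1L
    } else {
      cmb <- utils::combn(m, 2L)
      res <- .nw_align_batch(seqs[rows], cmb[1L, ], cmb[2L, ],
                             sim@scores, gap)
      denom <- (self[rows[cmb[1L, ]]] + self[rows[cmb[2L, ]]]) / 2
      d <- ifelse(denom > 0, 1 - res$score / denom, 1)
      d <- pmin(pmax(d, 0), 1)
      D <- matrix(0, m, m)
      for (kk in seq_len(ncol(cmb)))
        D[cmb[2L, kk], cmb[1L, kk]] <- d[kk]
      D <- D + t(D)
      cl <- cutree(hclust(as.dist(D), method = "average"), h = threshold)
    }
    data.frame(concept_id = f$concept_id[rows],
               set_id = paste0(f$concept_id[rows], ".", cl),
               row = rows,
               language_id = f$language_id[rows],
               form = f$form[rows],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Homologue sets from simulator ground truth or annotations
#'
#' Convenience constructor: one homologue set per concept containing all
#' its forms (the truth under simulation without borrowing).
#'
#' @param wordlist a \linkS4class{Wordlist}.
#' @return data.frame in the same schema as \code{\link{clusterHomologues}}.
#' @export
trueHomologues <- function(wordlist) {
  f <- wordlist@forms
  data.frame(concept_id = f$concept_id,
             set_id = paste0(f$concept_id, ".1"),
             row = seq_len(nrow(f)),
             language_id = f$language_id,
             form = f$form,
             stringsAsFactors = FALSE)
}

#' B-cubed F-score of a clustering against a reference
#'
#' Standard B-cubed precision/recall averaged over items, comparing two
#' assignments of the same items to clusters.
#'
#' @param predicted,truth vectors of cluster labels, parallel over items.
#' @return list with precision, recall, f.
#' @export
bcubed <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  n <- length(predicted)
  p <- numeric(n)
  r <- numeric(n)
  for (i in seq_len(n)) {
    same_pred <- predicted == predicted[i]
    same_true <- truth == truth[i]
    both <- sum(same_pred & same_true)
    p[i] <- both / sum(same_pred)
    r[i] <- both / sum(same_true)
  }
  P <- mean(p)
  R <- mean(r)
  list(precision = P, recall = R, f = 2 * P * R / (P + R))
}
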