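## Language-pair stability, the replacement-rate and information weighting,
## the four-way outcome decomposition (stable / shift in group / shift out
## of group / loss or gain), and the per-group SSt statistic.

#' Stability of one language pair
#'
#' The information-weighted proportion of aligned both-segment cells whose
#' two segment tokens are identical, over all homologue-pair alignments of
#' one language pair. Gap cells are excluded from this proportion (they
#' enter the group tallies as loss/gain instead). Tallies
#' \code{n_word_pairs}, \code{n_segment_pairs}, \code{n_identical} are
#' unweighted.
#'
#' @param alignments list of \linkS4class{Alignment} objects for one
#'   language pair.
#' @param language_a,language_b optional language ids; taken from the first
#'   alignment when omitted.
#' @return a \linkS4class{PairStability}.
#' @export
pairStability <- function(alignments, language_a = NULL, language_b = NULL) {
  stopifnot(length(alignments) >= 1L)
  num <- 0
  den <- 0
  nseg <- 0L
  nid <- 0L
  for (al in alignments) {
    both <- !is.na(al@left) & !is.na(al@right)
    if (!any(both)) next
    idn <- al@left[both] == al@right[both]
    num <- num + sum(al@weights[both] * idn)
    den <- den + sum(al@weights[both])
    nseg <- nseg + sum(both)
    nid <- nid + sum(idn)
  }
  if (den == 0)
    stop("undefined pair: no aligned both-segment cells")
  a1 <- alignments[[1L]]
  new("PairStability",
      language_a = language_a %||% a1@left_language,
      language_b = language_b %||% a1@right_language,
      s = num / den,
      n_word_pairs = length(alignments),
      n_segment_pairs = nseg, n_identical = nid)
}

setMethod("show", "PairStability", function(object) {
  cat("PairStability ", object@language_a, " ~ ", object@language_b,
      ": s = ", format(object@s, digits = 4),
      " (replacement rate ", format(1 - object@s, digits = 4), "); ",
      object@n_word_pairs, " word pairs, ", object@n_identical, "/",
      object@n_segment_pairs, " identical segment pairs\n", sep = "")
})

.empty_acc <- function(registry) {
  data.frame(group = groupNames(registry),
             w_stable = 0, w_shift_in = 0, w_shift_out = 0, w_indel = 0,
             stringsAsFactors = FALSE)
}

# One-sided outcome accumulation on numeric membership matrices.
# x, o: segment codes of the focal and the other side (0 = gap on the other
# side); w: per-instance weight (info weight x replacement rate).
.accumulate_side <- function(acc, Mnum, x, o, w) {
  if (length(x) == 0L) return(acc)
  st <- o == x
  ind <- o == 0L
  sh <- !st & !ind
  if (any(st)) {
    X <- Mnum[x[st], , drop = FALSE]
    acc$w_stable <- acc$w_stable + as.numeric(crossprod(X, w[st]))
  }
  if (any(ind)) {
    X <- Mnum[x[ind], , drop = FALSE]
    acc$w_indel <- acc$w_indel + as.numeric(crossprod(X, w[ind]))
  }
  if (any(sh)) {
    X <- Mnum[x[sh], , drop = FALSE]
    O <- Mnum[o[sh], , drop = FALSE]
    acc$w_shift_in <- acc$w_shift_in + as.numeric(crossprod(X * O, w[sh]))
    acc$w_shift_out <- acc$w_shift_out +
      as.numeric(crossprod(X * (1 - O), w[sh]))
  }
  acc
}

#' Accumulate four-way outcome weights from one alignment
#'
#' For each cell and each side whose segment exists, and for each group
#' containing that segment, adds \code{info weight x rate} to the group's
#' \emph{stable} (other side identical token), \emph{shift in group} (other
#' side a different segment of the same group), \emph{shift out of group}
#' (other side outside the group) or \emph{loss or gain} (other side a gap)
#' tally. Both sides are counted, so an identical pair registers once per
#' side.
#'
#' @param alignment an \linkS4class{Alignment}.
#' @param rate the language pair's replacement rate in [0, 1].
#' @param registry a \linkS4class{GroupRegistry}.
#' @param acc accumulator data.frame (from a previous call), or \code{NULL}.
#' @return data.frame with columns group, w_stable, w_shift_in,
#'   w_shift_out, w_indel.
#' @export
accumulateOutcomes <- function(alignment, rate, registry = defaultRegistry(),
                               acc = NULL) {
  stopifnot(rate >= 0, rate <= 1, is(alignment, "Alignment"))
  if (is.null(acc)) acc <- .empty_acc(registry)
  toks <- unique(c(alignment@left, alignment@right))
  toks <- toks[!is.na(toks)]
  Mnum <- groupMembership(toks, registry) * 1
  code <- function(x) ifelse(is.na(x), 0L, match(x, toks))
  l <- code(alignment@left)
  r <- code(alignment@right)
  w <- alignment@weights * rate
  acc <- .accumulate_side(acc, Mnum, l[l > 0L], r[l > 0L], w[l > 0L])
  acc <- .accumulate_side(acc, Mnum, r[r > 0L], l[r > 0L], w[r > 0L])
  acc
}

.finish_sst <- function(acc, registry) {
  g <- registry@groups
  total <- acc$w_stable + acc$w_shift_in + acc$w_shift_out + acc$w_indel
  sst <- ifelse(total > 0, (acc$w_stable + acc$w_shift_in) / total, NA_real_)
  sst[acc$group %in% registry@sparse_excluded] <- NA_real_
  data.frame(group = acc$group,
             feature_class = g$feature_class[match(acc$group, g$name)],
             major = g$major[match(acc$group, g$name)],
             w_stable = acc$w_stable, w_shift_in = acc$w_shift_in,
             w_shift_out = acc$w_shift_out, w_indel = acc$w_indel,
             total = total,
             p_stable = ifelse(total > 0, acc$w_stable / total, NA_real_),
             p_shift_in = ifelse(total > 0, acc$w_shift_in / total,
                                 NA_real_),
             p_shift_out = ifelse(total > 0, acc$w_shift_out / total,
                                  NA_real_),
             p_indel = ifelse(total > 0, acc$w_indel / total, NA_real_),
             sst = sst,
             stringsAsFactors = FALSE)
}

#' Per-group sound stability (SSt) and outcome decomposition
#'
#' For every unordered language pair, aligns all cross-language form pairs
#' inside each homologue set, computes the pair's information-weighted
#' stability and its replacement rate, and accumulates the four-way outcome
#' tallies with per-instance weight \code{info content x replacement rate}.
#' SSt is the weighted share of stable plus in-group outcomes. Groups on
#' the registry's sparsity-exclusion list are reported with \code{NA} SSt.
#'
#' A language pair whose forms are all identical has replacement rate 0 and
#' contributes nothing (the weighting annihilates it); if this holds for
#' all pairs every total is 0 and every SSt is \code{NA}.
#'
#' @param wordlist a \linkS4class{Wordlist}.
#' @param homologues homologue-set data.frame
#'   (\code{\link{clusterHomologues}} or \code{\link{trueHomologues}}).
#' @param sim a \linkS4class{SimilarityModel}.
#' @param info named list of \linkS4class{InfoModel}s per language;
#'   fitted from the wordlist when \code{NULL}.
#' @param registry a \linkS4class{GroupRegistry}.
#' @return list with elements \code{sst} (per-group table: weights, total,
#'   four proportions, sst) and \code{pairs} (per language pair: s and
#'   unweighted tallies).
#' @export
computeSST <- function(wordlist, homologues, sim, info = NULL,
                       registry = defaultRegistry()) {
  stopifnot(is(wordlist, "Wordlist"), is(sim, "SimilarityModel"))
  if (is.null(homologues) || nrow(homologues) == 0L)
    stop("empty homologue input")
  f <- wordlist@forms
  if (is.null(info)) info <- fitInfoModels(wordlist)
  wts <- .form_weights(wordlist, info)
  alphabet <- rownames(sim@scores)
  seqs <- lapply(f$segments, .encode, alphabet = alphabet)
  lens <- lengths(seqs)
  allcodes <- unlist(seqs, use.names = FALSE)
  allw <- unlist(wts, use.names = FALSE)
  offsets <- cumsum(c(0L, lens))[seq_along(seqs)]
  Mnum <- groupMembership(alphabet, registry) * 1

  # cross-language form pairs within homologue sets, keyed by language pair
  sets <- split(homologues$row, homologues$set_id)
  plist <- lapply(sets, function(rows) {
    if (length(rows) < 2L) return(NULL)
    cmb <- utils::combn(rows, 2L)
    keep <- f$language_id[cmb[1L, ]] != f$language_id[cmb[2L, ]]
    cmb <- cmb[, keep, drop = FALSE]
    if (ncol(cmb) == 0L) return(NULL)
    swap <- f$language_id[cmb[1L, ]] > f$language_id[cmb[2L, ]]
    cmb[, swap] <- cmb[2:1, swap]
    cmb
  })
  prs <- do.call(cbind, plist)
  if (is.null(prs) || ncol(prs) == 0L)
    stop("no cross-language homologue pairs to align")
  key <- paste(f$language_id[prs[1L, ]], f$language_id[prs[2L, ]],
               sep = "\u001f")

  acc <- .empty_acc(registry)
  pair_rows <- list()
  for (kp in sort(unique(key))) {
    sel <- which(key == kp)
    pi <- prs[1L, sel]
    pj <- prs[2L, sel]
    res <- .nw_align_batch(seqs, pi, pj, sim@scores, sim@gap_penalty)
    gl <- res$la > 0L
    gr <- res$ra > 0L
    nc <- length(res$la)
    xi <- integer(nc)
    yi <- integer(nc)
    wl <- rep(NA_real_, nc)
    wr <- rep(NA_real_, nc)
    il <- offsets[pi[res$pair_id[gl]]] + res$la[gl]
    ir <- offsets[pj[res$pair_id[gr]]] + res$ra[gr]
    xi[gl] <- allcodes[il]
    yi[gr] <- allcodes[ir]
    wl[gl] <- allw[il]
    wr[gr] <- allw[ir]
    cw <- rowMeans(cbind(wl, wr), na.rm = TRUE)
    both <- gl & gr
    if (!any(both) || sum(cw[both]) == 0) next
    idn <- xi[both] == yi[both]
    s <- sum(cw[both] * idn) / sum(cw[both])
    langs <- strsplit(kp, "\u001f", fixed = TRUE)[[1L]]
    pair_rows[[kp]] <- data.frame(
      language_a = langs[1L], language_b = langs[2L], s = s,
      n_word_pairs = length(sel), n_segment_pairs = sum(both),
      n_identical = sum(idn), stringsAsFactors = FALSE)
    rate <- 1 - s
    if (rate == 0) next
    w <- cw * rate
    acc <- .accumulate_side(acc, Mnum, xi[gl], yi[gl], w[gl])
    acc <- .accumulate_side(acc, Mnum, yi[gr], xi[gr], w[gr])
  }
  pairs <- do.call(rbind, pair_rows)
  rownames(pairs) <- NULL
  list(sst = .finish_sst(acc, registry), pairs = pairs)
}
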