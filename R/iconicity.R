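## Per-(concept, group) occurrence coding, Monte-Carlo odds-ratio
## posteriors, ROPE-based noteworthiness, and the iconic-value table.

#' Occurrence counts of sound groups per concept
#'
#' Presence/absence coding per (language, concept) slot: a language counts
#' once per concept regardless of synonym count (any synonym containing a
#' segment of the group makes the slot positive). The baseline counts K
#' (positive slots) and N (all slots) are computed over all concepts,
#' including the focal one.
#'
#' @param wordlist a \linkS4class{Wordlist} with at least 2 concepts.
#' @param registry a \linkS4class{GroupRegistry}.
#' @return data.frame with columns concept_id, group, k (languages whose
#'   form for the concept contains the group), n (languages attesting the
#'   concept), K, N.
#' @export
occurrenceCounts <- function(wordlist, registry = defaultRegistry()) {
  f <- wordlist@forms
  if (length(unique(f$concept_id)) < 2L)
    stop("need >= 2 concepts for occurrence baselines")
  alphabet <- .wordlist_alphabet(wordlist)
  M <- groupMembership(alphabet, registry)
  # per-form presence of each group
  formP <- vapply(f$segments,
                  function(s) colSums(M[match(s, alphabet), , drop = FALSE])
                  > 0,
                  logical(ncol(M)))
  formP <- t(formP)  # forms x groups
  slot <- paste(f$language_id, f$concept_id, sep = "\u001f")
  slotP <- rowsum(formP * 1, slot) > 0  # slots x groups
  slot_concept <- vapply(strsplit(rownames(slotP), "\u001f", fixed = TRUE),
                         `[`, character(1), 2L)
  k <- rowsum(slotP * 1, slot_concept)           # concepts x groups
  n <- as.vector(table(slot_concept)[rownames(k)])
  K <- colSums(slotP)
  N <- nrow(slotP)
  out <- data.frame(
    concept_id = rep(rownames(k), times = ncol(k)),
    group = rep(colnames(k), each = nrow(k)),
    k = as.vector(k),
    n = rep(n, times = ncol(k)),
    K = rep(K, each = nrow(k)),
    N = N,
    stringsAsFactors = FALSE)
  out <- out[order(out$concept_id, match(out$group, groupNames(registry))), ]
  rownames(out) <- NULL
  out
}

#' Monte-Carlo odds-ratio posterior for one (concept, group) cell
#'
#' Beta-Binomial presence/absence model with flat priors: draw
#' \code{p ~ Beta(k+1, n-k+1)} (focal concept) and
#' \code{q ~ Beta(K+1, N-K+1)} (baseline) independently, form the
#' odds-ratio draws \code{odds(p)/odds(q)}, and summarise by the median and
#' the equal-tailed 95\% interval. The centre of the interval is the
#' iconic value. Reproducible given \code{seed}.
#'
#' @param k,n,K,N occurrence counts (see \code{\link{occurrenceCounts}}).
#' @param n_draws number of Monte-Carlo draws (>= 1000).
#' @param seed integer RNG seed.
#' @return list with median, ci_low, ci_high, center.
#' @export
orPosterior <- function(k, n, K, N, n_draws = 4000L, seed = 1L) {
  stopifnot(n >= 1, N >= 1, k >= 0, k <= n, K >= 0, K <= N,
            n_draws >= 1000L)
  set.seed(seed)
  p <- rbeta(n_draws, k + 1, n - k + 1)
  q <- rbeta(n_draws, K + 1, N - K + 1)
  or <- (p / (1 - p)) / (q / (1 - q))
  ci <- unname(quantile(or, c(0.025, 0.975)))
  list(median = median(or), ci_low = ci[1L], ci_high = ci[2L],
       center = (ci[1L] + ci[2L]) / 2)
}

#' Classify a posterior as strong / weak / not noteworthy
#'
#' Strong: iconic value (interval centre) at least 1.25 and the whole 95\%
#' interval above the ROPE. Weak: not strong, centre at least 1.25, the
#' log-OR interval excludes 0 (i.e. \code{ci_low > 1}) and the posterior
#' median lies above the ROPE. Otherwise none. Vectorised.
#'
#' @param median,ci_low,ci_high,center posterior summaries on the OR scale.
#' @param rope length-2 region of practical equivalence around the null OR,
#'   \code{rope[1] < 1 < rope[2]} (default \code{c(1/1.25, 1.25)},
#'   symmetric on the log scale).
#' @return character vector: \code{"strong"}, \code{"weak"} or
#'   \code{"none"}.
#' @export
classifyNoteworthy <- function(median, ci_low, ci_high, center,
                               rope = c(1 / 1.25, 1.25)) {
  if (length(rope) != 2L || !(rope[1] < 1 && 1 < rope[2]))
    stop("configuration error: rope must satisfy rope[1] < 1 < rope[2]")
  strong <- center >= 1.25 & ci_low > rope[2]
  weak <- !strong & center >= 1.25 & ci_low > 1 & median > rope[2]
  ifelse(strong, "strong", ifelse(weak, "weak", "none"))
}

#' Build the iconicity (Ico) table
#'
#' Computes occurrence counts for every (concept, group) cell, the
#' Monte-Carlo odds-ratio posterior of each, the noteworthiness
#' classification, and the iconic value (centre of the 95\% interval).
#' Rows with iconic value below 1 (underrepresentations, mostly redundant
#' mirror images of overrepresentations) are removed when
#' \code{filter = TRUE}; the pre-filter row count is kept as attribute
#' \code{"n_prefilter"}.
#'
#' @inheritParams occurrenceCounts
#' @param n_draws Monte-Carlo draws per cell.
#' @param seed base RNG seed; cell i uses \code{seed + i}.
#' @param rope see \code{\link{classifyNoteworthy}}.
#' @param filter drop rows with iconic value < 1 (default TRUE).
#' @return data.frame with columns concept_id, group, k, n, K, N,
#'   or_median, ci_low, ci_high, center, noteworthy.
#' @export
buildIconicityTable <- function(wordlist, registry = defaultRegistry(),
                                n_draws = 4000L, seed = 1L,
                                rope = c(1 / 1.25, 1.25), filter = TRUE) {
  counts <- occurrenceCounts(wordlist, registry)
  post <- vapply(seq_len(nrow(counts)), function(i) {
    p <- orPosterior(counts$k[i], counts$n[i], counts$K[i], counts$N[i],
                     n_draws = n_draws, seed = seed + i)
    c(p$median, p$ci_low, p$ci_high, p$center)
  }, numeric(4))
  counts$or_median <- post[1L, ]
  counts$ci_low <- post[2L, ]
  counts$ci_high <- post[3L, ]
  counts$center <- post[4L, ]
  counts$noteworthy <- classifyNoteworthy(counts$or_median, counts$ci_low,
                                          counts$ci_high, counts$center,
                                          rope)
  # a group never attested in the focal concept cannot be overrepresented;
  # with k = 0 a large OR is an artefact of the flat prior at n << N
  counts$noteworthy[counts$k == 0L] <- "none"
  n_pre <- nrow(counts)
  if (filter) counts <- counts[counts$center >= 1, , drop = FALSE]
  rownames(counts) <- NULL
  attr(counts, "n_prefilter") <- n_pre
  counts
}
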