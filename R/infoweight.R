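## Per-language information-content models: symmetric forward/backward
## trigram surprisal normalised to [0, 1]. Positions occupied by recurrent
## material (e.g. shared inflectional endings) are predictable in at least
## one direction and receive low weights, so they count less in stability
## estimation.

.BOS <- "⟨"  # start-boundary symbol, outside any IPA inventory
.EOS <- "⟩"  # end-boundary symbol
.SEP <- "\u001f"  # separator that cannot occur inside a segment token

.tri_keys <- function(padded) {
  n <- length(padded) - 2L
  paste(padded[seq_len(n)], padded[seq_len(n) + 1L], padded[seq_len(n) + 2L],
        sep = .SEP)
}

.ctx_keys <- function(padded) {
  n <- length(padded) - 2L
  paste(padded[seq_len(n)], padded[seq_len(n) + 1L], sep = .SEP)
}

.count_table <- function(keys) {
  t <- table(unlist(keys, use.names = FALSE))
  setNames(as.numeric(t), names(t))
}

#' Fit a per-language trigram information model
#'
#' Forward counts are built from all of the language's segmented forms,
#' each padded with two start symbols; backward counts from the reversed
#' forms padded with two end symbols. Deterministic.
#'
#' @param wordlist a \linkS4class{Wordlist}.
#' @param language a language id present in the wordlist.
#' @param smoothing add-constant used at query time (default 0.5, spread
#'   over \code{inventory_size + 1} outcomes).
#' @return an \linkS4class{InfoModel}.
#' @export
fitInfoModel <- function(wordlist, language, smoothing = 0.5) {
  stopifnot(is(wordlist, "Wordlist"))
  f <- wordlist@forms
  segs <- f$segments[f$language_id == language]
  if (length(segs) == 0L)
    stop("lookup error: no forms for language '", language, "'")
  fw_pad <- lapply(segs, function(s) c(.BOS, .BOS, s))
  bw_pad <- lapply(segs, function(s) c(.EOS, .EOS, rev(s)))
  new("InfoModel",
      language_id = language,
      forward = .count_table(lapply(fw_pad, .tri_keys)),
      forward_ctx = .count_table(lapply(fw_pad, .ctx_keys)),
      backward = .count_table(lapply(bw_pad, .tri_keys)),
      backward_ctx = .count_table(lapply(bw_pad, .ctx_keys)),
      inventory_size = length(unique(unlist(segs, use.names = FALSE))),
      smoothing = smoothing)
}

.lookup <- function(tab, keys) {
  v <- tab[keys]
  v[is.na(v)] <- 0
  unname(v)
}

.surprisal <- function(tri, ctx, tri_keys, ctx_keys, k, V) {
  p <- (.lookup(tri, tri_keys) + k) / (.lookup(ctx, ctx_keys) + k * (V + 1))
  -log2(p)
}

#' Information content of positions in a segmented form
#'
#' The mean of the forward and backward smoothed trigram surprisals,
#' divided by the uniform-surprisal cap \code{log2(inventory_size + 1)} and
#' truncated at 1. A segment that deterministically follows its context in
#' both directions approaches weight 0 (in the zero-smoothing limit); a
#' never-observed context yields the capped weight 1.
#'
#' @param model an \linkS4class{InfoModel}.
#' @param segments character vector of segment tokens (one form).
#' @param positions integer positions to evaluate (default: all).
#' @return numeric weights in [0, 1].
#' @export
infoContent <- function(model, segments, positions = seq_along(segments)) {
  stopifnot(is(model, "InfoModel"))
  n <- length(segments)
  if (any(positions < 1L | positions > n))
    stop("position out of range")
  k <- model@smoothing
  V <- model@inventory_size
  cap <- log2(V + 1)
  fw <- c(.BOS, .BOS, segments)
  bw <- c(.EOS, .EOS, rev(segments))
  fw_tri <- .tri_keys(fw)
  fw_ctx <- .ctx_keys(fw)
  bw_tri <- .tri_keys(bw)
  bw_ctx <- .ctx_keys(bw)
  sf <- .surprisal(model@forward, model@forward_ctx,
                   fw_tri[positions], fw_ctx[positions], k, V)
  j <- n + 1L - positions
  sb <- .surprisal(model@backward, model@backward_ctx,
                   bw_tri[j], bw_ctx[j], k, V)
  pmin(1, ((sf + sb) / 2) / cap)
}

setMethod("show", "InfoModel", function(object) {
  cat("InfoModel for language '", object@language_id, "': ",
      length(object@forward), " forward / ", length(object@backward),
      " backward trigrams, inventory size ", object@inventory_size,
      ", smoothing ", object@smoothing, "\n", sep = "")
})

#' Fit information models for every language of a wordlist
#'
#' @inheritParams fitInfoModel
#' @return named list of \linkS4class{InfoModel} objects.
#' @export
fitInfoModels <- function(wordlist, smoothing = 0.5) {
  langs <- languages(wordlist)
  setNames(lapply(langs, function(l) fitInfoModel(wordlist, l, smoothing)),
           langs)
}

# Per-form position weights for all forms of a wordlist, as a list parallel
# to the forms rows. Each form is weighted under its own language's model.
.form_weights <- function(wordlist, models) {
  f <- wordlist@forms
  lapply(seq_len(nrow(f)), function(i) {
    m <- models[[f$language_id[i]]]
    infoContent(m, f$segments[[i]])
  })
}
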