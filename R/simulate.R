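## Lexical-evolution simulator: homologous forms diverging along a balanced
## binary tree with per-class replacement intensities, optional
## inflection-like suffixes, optional borrowing, and seeded iconic
## overrepresentation. Emits a Wordlist plus ground truth so every pipeline
## stage can be validated by parameter recovery.

.default_inventory <- function() {
  c("p", "b", "t", "d", "c", "ɟ", "k", "g", "ʔ", "t͡s", "t͡ʃ",
    "m", "n", "ɲ", "ŋ",
    "f", "v", "s", "z", "ʃ", "ʒ", "x", "ɣ", "h", "j", "w",
    "r", "ɾ", "ʀ",
    "l", "ʎ",
    "i", "y", "ɨ", "u", "ɯ",
    "e", "ø", "ə", "o", "ɤ",
    "a", "æ", "ɐ", "ɑ", "ɒ")
}

#' Simulator configuration
#'
#' @param n_leaves number of leaf languages (balanced binary tree).
#' @param branch_length per-edge duration.
#' @param inventory character vector of segment tokens; must cover every
#'   registry group apart from (optionally) the five sparsity-excluded ones.
#' @param concept_count number of concepts.
#' @param word_length integer (min, max) proto-word length.
#' @param suffix_mode append a per-language inflection-like suffix, drawn
#'   from a shared suffix inventory, to every form after evolution.
#' @param suffixes the shared suffix inventory (IPA strings).
#' @param intensities named per-class replacement intensities (lambda, per
#'   unit branch length): consonants by manner class (nasal, stop,
#'   continuant, vibrant, lateral), vowels by height (high, mid, low).
#' @param replacement_kernel named probabilities (alpha, beta, delta) that a
#'   replacement event is a within-class substitution, an out-of-class
#'   substitution, or a deletion; must sum to 1.
#' @param insertion_rate Poisson insertion intensity per unit branch length.
#' @param iconic_seeds data.frame (concept_id, group, boost): the proto-word
#'   of a seeded concept is forced to contain a segment of the group with
#'   probability \code{boost}.
#' @param borrowing_rate per leaf-concept probability of copying a random
#'   other leaf's form.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(n_leaves = 10L,
                      branch_length = 0.2,
                      inventory = .default_inventory(),
                      concept_count = 50L,
                      word_length = c(3L, 8L),
                      suffix_mode = FALSE,
                      suffixes = c("ta", "na", "si", "ka", "mi", "tu",
                                   "an", "os"),
                      intensities = c(nasal = 0.4, stop = 0.4,
                                      continuant = 0.4, vibrant = 0.4,
                                      lateral = 0.4, high = 0.4, mid = 0.4,
                                      low = 0.4),
                      replacement_kernel = c(alpha = 0.4, beta = 0.5,
                                             delta = 0.1),
                      insertion_rate = 0.05,
                      iconic_seeds = NULL,
                      borrowing_rate = 0,
                      seed = 42L) {
  if (is.null(iconic_seeds))
    iconic_seeds <- data.frame(concept_id = character(0),
                               group = character(0), boost = numeric(0),
                               stringsAsFactors = FALSE)
  new("SimConfig", n_leaves = as.integer(n_leaves),
      branch_length = branch_length, inventory = inventory,
      concept_count = as.integer(concept_count),
      word_length = as.integer(word_length), suffix_mode = suffix_mode,
      suffixes = suffixes, intensities = intensities,
      replacement_kernel = replacement_kernel,
      insertion_rate = insertion_rate, iconic_seeds = iconic_seeds,
      borrowing_rate = borrowing_rate, seed = as.integer(seed))
}

#' Expected per-segment retention under exponential replacement
#'
#' The probability that a segment of a class with intensity \code{lambda}
#' survives unreplaced over a total path length \code{path_length}.
#'
#' @param lambda replacement intensity (>= 0).
#' @param path_length total tree path between two leaves (> 0).
#' @return \code{exp(-lambda * path_length)}.
#' @export
expectedRetention <- function(lambda, path_length) {
  stopifnot(all(lambda >= 0))
  exp(-lambda * path_length)
}

# Balanced binary split of n leaves: returns a nested list; leaves are
# integers 1..n in order. ceiling(n/2) goes left.
.balanced_tree <- function(n, offset = 0L) {
  if (n == 1L) return(offset + 1L)
  nl <- ceiling(n / 2)
  list(.balanced_tree(nl, offset), .balanced_tree(n - nl, offset + nl))
}

# Pairwise leaf-to-leaf path lengths (in units of branch_length): depths via
# binary address strings, path = depth_i + depth_j - 2 * common prefix.
.leaf_addresses <- function(tree, prefix = "") {
  if (!is.list(tree)) return(setNames(prefix, tree))
  c(.leaf_addresses(tree[[1L]], paste0(prefix, "0")),
    .leaf_addresses(tree[[2L]], paste0(prefix, "1")))
}

.path_matrix <- function(tree, branch_length) {
  addr <- .leaf_addresses(tree)
  addr <- addr[order(as.integer(names(addr)))]
  n <- length(addr)
  P <- matrix(0, n, n)
  split_addr <- strsplit(addr, "", fixed = TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- split_addr[[i]]
      b <- split_addr[[j]]
      m <- min(length(a), length(b))
      cp <- 0L
      while (cp < m && a[cp + 1L] == b[cp + 1L]) cp <- cp + 1L
      P[i, j] <- P[j, i] <- (length(a) - cp + length(b) - cp) * branch_length
    }
  }
  P
}

#' Simulate a wordlist with known ground truth
#'
#' Per concept, a proto-word of CV-alternating segments is drawn within
#' \code{word_length}; iconic-seeded concepts are forced to contain a
#' segment of the seeded group with probability \code{boost}. Along each
#' branch of length t, every segment is replaced with probability
#' \code{1 - exp(-lambda_class * t)}; a replacement event is a within-class
#' substitution, an out-of-class substitution (same major class with
#' probability 0.9), or a deletion, per the kernel; insertions are
#' Poisson(\code{insertion_rate * t}) at uniform positions. A deletion that
#' would empty a form is skipped. Suffixing and borrowing are applied at
#' the leaves, in that order. Fully reproducible by \code{seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{wordlist} (a \linkS4class{Wordlist}),
#'   \code{truth}: \code{retention} (per group: mixture intensity
#'   \code{lambda} and expected retention over the tree), \code{homologues}
#'   (the true sets), \code{class_lambda} (per simulator class), and
#'   \code{seeds} (the configured iconic seeds).
#' @export
simulateWordlist <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  inv <- config@inventory
  b <- classifySegment(inv)
  cls <- ifelse(b$major == "consonant", b$manner, b$height)
  lam <- config@intensities[cls]
  if (anyNA(lam))
    stop("configuration error: inventory class without an intensity: ",
         paste(unique(cls[is.na(lam)]), collapse = ", "))
  lam <- unname(lam)
  cons <- which(b$major == "consonant")
  vows <- which(b$major == "vowel")
  if (length(cons) == 0L || length(vows) == 0L)
    stop("inventory must contain consonants and vowels")
  class_members <- split(seq_along(inv), cls)
  kern <- config@replacement_kernel
  bl <- config@branch_length

  concepts <- sprintf("C%03d", seq_len(config@concept_count))
  leaves <- sprintf("L%02d", seq_len(config@n_leaves))

  # proto-words (indices into inv), CV alternating starting with a consonant
  protos <- vector("list", config@concept_count)
  for (ci in seq_len(config@concept_count)) {
    L <- config@word_length[1L] +
      sample.int(config@word_length[2L] - config@word_length[1L] + 1L,
                 1L) - 1L
    pos_major <- rep(c("consonant", "vowel"), length.out = L)
    w <- integer(L)
    w[pos_major == "consonant"] <- sample(cons,
                                          sum(pos_major == "consonant"),
                                          replace = TRUE)
    w[pos_major == "vowel"] <- sample(vows, sum(pos_major == "vowel"),
                                      replace = TRUE)
    protos[[ci]] <- w
  }
  # iconic seeding
  seeds <- config@iconic_seeds
  if (nrow(seeds) > 0L) {
    Minv <- groupMembership(inv, defaultRegistry())
    for (si in seq_len(nrow(seeds))) {
      ci <- match(seeds$concept_id[si], concepts)
      if (is.na(ci)) stop("iconic seed for unknown concept: ",
                          seeds$concept_id[si])
      members <- which(Minv[, seeds$group[si]])
      if (length(members) == 0L)
        stop("iconic seed group not covered by inventory: ",
             seeds$group[si])
      if (runif(1) < seeds$boost[si]) {
        tgt_major <- b$major[members[1L]]
        w <- protos[[ci]]
        slots <- which(b$major[w] == tgt_major)
        if (length(slots) == 0L) slots <- seq_along(w)
        pos <- if (length(slots) == 1L) slots else sample(slots, 1L)
        w[pos] <- if (length(members) == 1L) members else
          sample(members, 1L)
        protos[[ci]] <- w
      }
    }
  }

  evolve_form <- function(w, t) {
    if (length(w) > 0L) {
      p_repl <- 1 - exp(-lam[w] * t)
      hit <- runif(length(w)) < p_repl
      keep <- rep(TRUE, length(w))
      for (i in which(hit)) {
        u <- runif(1)
        if (u < kern[["alpha"]]) {
          mates <- setdiff(class_members[[cls[w[i]]]], w[i])
          if (length(mates) > 0L)
            w[i] <- if (length(mates) == 1L) mates else sample(mates, 1L)
        } else if (u < kern[["alpha"]] + kern[["beta"]]) {
          same_major <- runif(1) < 0.9
          pool <- if (same_major)
            setdiff(if (b$major[w[i]] == "consonant") cons else vows,
                    class_members[[cls[w[i]]]])
          else if (b$major[w[i]] == "consonant") vows else cons
          if (length(pool) > 0L)
            w[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
        } else {
          if (sum(keep) > 1L) keep[i] <- FALSE
        }
      }
      w <- w[keep]
    }
    n_ins <- rpois(1L, config@insertion_rate * t)
    for (dummy in seq_len(n_ins)) {
      at <- sample.int(length(w) + 1L, 1L)
      tok <- sample.int(length(inv), 1L)
      w <- append(w, tok, after = at - 1L)
    }
    if (length(w) == 0L) w <- sample.int(length(inv), 1L)
    w
  }

  # evolve all concepts down the tree; deterministic depth-first order
  tree <- .balanced_tree(config@n_leaves)
  leaf_forms <- vector("list", config@n_leaves)
  walk <- function(node, state) {
    if (!is.list(node)) {
      leaf_forms[[node]] <<- state
      return(invisible(NULL))
    }
    for (child in node) {
      st <- lapply(state, evolve_form, t = bl)
      walk(child, st)
    }
    invisible(NULL)
  }
  walk(tree, protos)

  # per-language suffix, shared suffix inventory
  if (config@suffix_mode) {
    for (li in seq_len(config@n_leaves)) {
      sfx <- .encode(segmentIPA(sample(config@suffixes, 1L)), inv)
      leaf_forms[[li]] <- lapply(leaf_forms[[li]], function(w) c(w, sfx))
    }
  }
  # borrowing: copy a donor leaf's (post-suffix) form
  if (config@borrowing_rate > 0 && config@n_leaves > 1L) {
    for (li in seq_len(config@n_leaves)) {
      for (ci in seq_len(config@concept_count)) {
        if (runif(1) < config@borrowing_rate) {
          others <- setdiff(seq_len(config@n_leaves), li)
          donor <- others[sample.int(length(others), 1L)]
          leaf_forms[[li]][[ci]] <- leaf_forms[[donor]][[ci]]
        }
      }
    }
  }

  df <- data.frame(
    language_id = rep(leaves, each = config@concept_count),
    concept_id = rep(concepts, times = config@n_leaves),
    stringsAsFactors = FALSE)
  segs <- vector("list", nrow(df))
  for (li in seq_len(config@n_leaves))
    for (ci in seq_len(config@concept_count))
      segs[[(li - 1L) * config@concept_count + ci]] <-
        inv[leaf_forms[[li]][[ci]]]
  df$form <- vapply(segs, paste, character(1), collapse = "")
  df$segments <- segs
  # synonym-free by construction, but identical forms can recur; the
  # Wordlist uniqueness invariant is over (language, concept, form)
  wl <- new("Wordlist", forms = df)

  P <- .path_matrix(tree, bl)
  mean_path <- mean(P[upper.tri(P)])
  reg <- defaultRegistry()
  Minv <- groupMembership(inv, reg)
  lam_g <- vapply(groupNames(reg), function(g) {
    m <- Minv[, g]
    if (!any(m)) return(NA_real_)
    mean(lam[m])
  }, numeric(1))
  ret_g <- vapply(lam_g, function(l) {
    if (is.na(l)) return(NA_real_)
    mean(expectedRetention(l, P[upper.tri(P)]))
  }, numeric(1))
  retention <- data.frame(group = groupNames(reg), lambda = unname(lam_g),
                          retention = unname(ret_g),
                          stringsAsFactors = FALSE)
  list(wordlist = wl,
       truth = list(retention = retention,
                    homologues = trueHomologues(wl),
                    class_lambda = config@intensities,
                    mean_path = mean_path,
                    seeds = seeds))
}

#' Closed-form per-group stability of the simulator
#'
#' The quantity that the SSt estimator targets, computed exactly from the
#' simulator's own dynamics with no alignment involved: per edge, a segment
#' survives with probability \code{exp(-lambda_class * branch_length)} or
#' jumps per the replacement kernel, which defines a one-step transition
#' matrix over the inventory plus an absorbing deletion state. For every
#' leaf pair, the two lineages run independent chains from their common
#' ancestor; the probability that the partner of an in-group segment is
#' again in the group (stable or shift in group), against any outcome
#' including deletion, is accumulated over pairs with the same
#' replacement-rate weighting the estimator uses. Insertions and the
#' simulator's empty-form guard are ignored (both are rare).
#'
#' @param config a \linkS4class{SimConfig}.
#' @return data.frame with columns group, true_sst.
#' @export
trueGroupStability <- function(config) {
  stopifnot(is(config, "SimConfig"))
  inv <- config@inventory
  b <- classifySegment(inv)
  cls <- ifelse(b$major == "consonant", b$manner, b$height)
  lam <- unname(config@intensities[cls])
  n <- length(inv)
  cons <- which(b$major == "consonant")
  vows <- which(b$major == "vowel")
  class_members <- split(seq_len(n), cls)
  kern <- config@replacement_kernel
  # one-edge transition matrix over inventory + deletion state (n + 1)
  M <- matrix(0, n + 1L, n + 1L)
  for (i in seq_len(n)) {
    stay <- exp(-lam[i] * config@branch_length)
    move <- 1 - stay
    M[i, i] <- stay
    mates <- setdiff(class_members[[cls[i]]], i)
    if (length(mates) > 0L) {
      M[i, mates] <- M[i, mates] + move * kern[["alpha"]] / length(mates)
    } else {
      M[i, i] <- M[i, i] + move * kern[["alpha"]]
    }
    same <- setdiff(if (b$major[i] == "consonant") cons else vows,
                    class_members[[cls[i]]])
    M[i, same] <- M[i, same] + move * kern[["beta"]] * 0.9 / length(same)
    other <- if (b$major[i] == "consonant") vows else cons
    M[i, other] <- M[i, other] + move * kern[["beta"]] * 0.1 / length(other)
    M[i, n + 1L] <- move * kern[["delta"]]
  }
  M[n + 1L, n + 1L] <- 1
  addr <- .leaf_addresses(.balanced_tree(config@n_leaves))
  addr <- strsplit(addr[order(as.integer(names(addr)))], "", fixed = TRUE)
  maxd <- max(lengths(addr))
  pow <- vector("list", maxd + 1L)
  pow[[1L]] <- diag(n + 1L)
  for (d in seq_len(maxd)) pow[[d + 1L]] <- pow[[d]] %*% M
  # proto occupancy: uniform within each major class, CV alternation
  pi0 <- numeric(n + 1L)
  pi0[cons] <- 0.5 / length(cons)
  pi0[vows] <- 0.5 / length(vows)
  reg <- defaultRegistry()
  Minv <- groupMembership(inv, reg)
  G <- ncol(Minv)
  num <- numeric(G)
  den <- numeric(G)
  nl <- length(addr)
  for (i in seq_len(nl - 1L)) {
    for (j in (i + 1L):nl) {
      a <- addr[[i]]
      bb <- addr[[j]]
      m <- 0L
      lim <- min(length(a), length(bb))
      while (m < lim && a[m + 1L] == bb[m + 1L]) m <- m + 1L
      anc <- as.numeric(pi0 %*% pow[[m + 1L]])
      A <- pow[[length(a) - m + 1L]]
      B <- pow[[length(bb) - m + 1L]]
      seg <- c(rep(1, n), 0)
      Am <- A %*% seg
      Bm <- B %*% seg
      AB <- rowSums(A[, seq_len(n)] * B[, seq_len(n)])
      s_pair <- sum(anc * AB) / sum(anc * Am * Bm)
      rate <- 1 - s_pair
      for (g in seq_len(G)) {
        u <- c(Minv[, g] * 1, 0)
        Au <- A %*% u
        Bu <- B %*% u
        num[g] <- num[g] + rate * 2 * sum(anc * Au * Bu)
        den[g] <- den[g] + rate * sum(anc * (Au + Bu))
      }
    }
  }
  data.frame(group = colnames(Minv),
             true_sst = ifelse(den > 0, num / den, NA_real_),
             stringsAsFactors = FALSE)
}

#' Named simulator presets
#'
#' \describe{
#'   \item{null}{100 well-diverged languages, 50 concepts, uniform moderate
#'     intensities, no iconic seeds: the calibration baseline for the
#'     noteworthiness classifier.}
#'   \item{graded}{32 languages, 100 concepts, suffixing on, intensities
#'     increasing nasal/stop/lateral < continuant < vibrant < vowels (the
#'     coarse stability ordering in which labials, nasals and laterals are
#'     most stable and sonorous vowels least).}
#'   \item{coupled}{graded intensities plus iconic seeds placed in
#'     low-intensity (high-stability) groups: the end-to-end preset under
#'     which iconicity and stability are positively coupled.}
#'   \item{recovery}{20 languages, 300 concepts, intensities spanning
#'     0.2-2.0, fixed seed: the stability parameter-recovery experiment.}
#' }
#'
#' @return named list of \linkS4class{SimConfig} objects.
#' @export
defaultPresets <- function() {
  graded_int <- c(nasal = 0.3, stop = 0.35, lateral = 0.45,
                  continuant = 0.7, vibrant = 0.9,
                  high = 0.9, mid = 1.3, low = 1.7)
  seeds <- data.frame(
    concept_id = sprintf("C%03d", 1:24),
    group = c("nasal", "stop", "voiced nasal", "voiceless stop",
              "labial", "voiced stop", "lateral", "voiced lateral",
              "alveolar", "voiced alveolar", "voiceless alveolar",
              "voiceless labial", "voiced labial", "nasal",
              "high vowel", "high vowel", "high front vowel",
              "high front vowel", "high back vowel", "high back vowel",
              "high central vowel", "high vowel", "high back vowel",
              "high front vowel"),
    boost = 0.85,
    stringsAsFactors = FALSE)
  list(
    null = simConfig(n_leaves = 100L, concept_count = 50L,
                     branch_length = 2.5, word_length = c(5L, 5L),
                     intensities = c(nasal = 1, stop = 1, continuant = 1,
                                     vibrant = 1, lateral = 1, high = 1,
                                     mid = 1, low = 1),
                     replacement_kernel = c(alpha = 0.45, beta = 0.55,
                                            delta = 0),
                     insertion_rate = 0,
                     suffix_mode = FALSE, seed = 42L),
    graded = simConfig(n_leaves = 32L, concept_count = 100L,
                       branch_length = 0.2, intensities = graded_int,
                       suffix_mode = TRUE, seed = 42L),
    coupled = simConfig(n_leaves = 48L, concept_count = 80L,
                        branch_length = 0.15, intensities = graded_int,
                        suffix_mode = FALSE, iconic_seeds = seeds,
                        seed = 42L),
    recovery = simConfig(n_leaves = 20L, concept_count = 300L,
                         branch_length = 0.15,
                         intensities = c(nasal = 0.2, stop = 0.35,
                                         lateral = 0.5, continuant = 0.8,
                                         vibrant = 1.1, high = 1.4,
                                         mid = 1.7, low = 2.0),
                         suffix_mode = FALSE, seed = 20200190L))
}
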