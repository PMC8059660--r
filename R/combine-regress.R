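## Joining iconicity, stability and L1 codings into the combined table, the
## stratified OLS regressions, and the summary tables.

#' Combine iconicity, SSt and L1 codings
#'
#' One row per (concept, group) in the cross product of the iconicity
#' table's concepts with the registry's groups: the iconic value, the
#' group's SSt (NA for sparsity-excluded or unobserved groups), the major
#' class, and the five per-axis L1 codings (\code{"none"} where a group is
#' not coded on an axis).
#'
#' @param ico pre-filter iconicity table
#'   (\code{buildIconicityTable(..., filter = FALSE)}).
#' @param sst per-group SSt table (\code{computeSST(...)$sst}).
#' @param registry a \linkS4class{GroupRegistry}.
#' @return data.frame with columns concept_id, group, ico, noteworthy, sst,
#'   major, l1_place, l1_manner, l1_voicing, l1_openness, l1_backness.
#' @export
combineTables <- function(ico, sst, registry = defaultRegistry()) {
  gnames <- groupNames(registry)
  bad <- setdiff(unique(ico$group), gnames)
  if (length(bad) > 0L)
    stop("join error: group(s) not in registry: ",
         paste(bad, collapse = ", "))
  cids <- sort(unique(ico$concept_id))
  out <- data.frame(
    concept_id = rep(cids, each = length(gnames)),
    group = rep(gnames, times = length(cids)),
    stringsAsFactors = FALSE)
  i <- match(paste(out$concept_id, out$group, sep = "\u001f"),
             paste(ico$concept_id, ico$group, sep = "\u001f"))
  out$ico <- ico$center[i]
  out$noteworthy <- ico$noteworthy[i]
  j <- match(out$group, sst$group)
  out$sst <- sst$sst[j]
  out$major <- registry@groups$major[match(out$group, gnames)]
  for (axis in names(.L1_AXES)) {
    coding <- l1Coding(registry, axis)
    out[[paste0("l1_", axis)]] <- unname(coding[out$group])
  }
  out
}

#' Stratified OLS of iconic value on sound stability
#'
#' Rows are filtered to iconic value >= 1 and defined SSt, optionally to
#' one major class; the response is \code{log(ico)} (the iconic value is
#' ratio-scaled) unless \code{log_response = FALSE}. Reports the slope
#' F-test, degrees of freedom and R-squared; for a simple regression the
#' identity \code{r2 = f / (f + df2)} holds.
#'
#' @param rows combined table from \code{\link{combineTables}}.
#' @param subset \code{"all"}, \code{"consonants"} or \code{"vowels"}.
#' @param log_response logical.
#' @return one-row data.frame: subset, n, f_stat, df1, df2, p, r2, slope,
#'   intercept.
#' @export
fitRegression <- function(rows, subset = c("all", "consonants", "vowels"),
                          log_response = TRUE) {
  subset <- match.arg(subset)
  d <- rows[!is.na(rows$ico) & rows$ico >= 1 & !is.na(rows$sst), ,
            drop = FALSE]
  if (subset == "consonants") d <- d[d$major == "consonant", , drop = FALSE]
  if (subset == "vowels") d <- d[d$major == "vowel", , drop = FALSE]
  if (nrow(d) < 3L)
    stop("insufficient data: need >= 3 usable rows, got ", nrow(d))
  y <- if (log_response) log(d$ico) else d$ico
  fit <- lm(y ~ sst, data = data.frame(y = y, sst = d$sst))
  sm <- summary(fit)
  fs <- sm$fstatistic
  data.frame(subset = subset, n = nrow(d),
             f_stat = unname(fs[1L]), df1 = unname(fs[2L]),
             df2 = unname(fs[3L]),
             p = unname(pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)),
             r2 = sm$r.squared,
             slope = unname(coef(fit)[2L]),
             intercept = unname(coef(fit)[1L]),
             stringsAsFactors = FALSE)
}

#' Stability summary table, most stable group first
#'
#' @param sst per-group SSt table (\code{computeSST(...)$sst}).
#' @return data.frame (group, stable, shift_in, shift_out, indel,
#'   stability_rate) sorted by descending stability rate, NA-rate groups
#'   last and flagged in column \code{excluded}.
#' @export
summarizeStability <- function(sst) {
  out <- data.frame(group = sst$group,
                    stable = sst$p_stable, shift_in = sst$p_shift_in,
                    shift_out = sst$p_shift_out, indel = sst$p_indel,
                    stability_rate = sst$sst,
                    excluded = is.na(sst$sst),
                    stringsAsFactors = FALSE)
  out <- out[order(is.na(out$stability_rate), -out$stability_rate,
                   out$group, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Split the combined table by L1 acquisition order on one axis
#'
#' Rows whose group is not coded on the axis are dropped; the remainder is
#' split into \code{earlier} and \code{later}, with group means of SSt and
#' iconic value per side.
#'
#' @param rows combined table from \code{\link{combineTables}}.
#' @param axis one of place, manner, voicing, openness, backness.
#' @return list with \code{earlier}, \code{later} (data.frames) and
#'   \code{summary} (coding, n, mean_sst, mean_ico).
#' @export
l1Separation <- function(rows, axis = c("place", "manner", "voicing",
                                        "openness", "backness")) {
  axis <- match.arg(axis)
  col <- paste0("l1_", axis)
  sub <- function(lab) rows[rows[[col]] == lab, , drop = FALSE]
  earlier <- sub("earlier")
  later <- sub("later")
  mn <- function(x) if (length(x) == 0L) NA_real_ else mean(x, na.rm = TRUE)
  summary <- data.frame(
    coding = c("earlier", "later"),
    n = c(nrow(earlier), nrow(later)),
    mean_sst = c(mn(earlier$sst), mn(later$sst)),
    mean_ico = c(mn(earlier$ico), mn(later$ico)),
    stringsAsFactors = FALSE)
  list(earlier = earlier, later = later, summary = summary)
}
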