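#' Modified intersection-over-union (annotation recall)
#'
#' The overlap criterion used to judge predicted morphotype regions against
#' expert annotations: `|P n A| / |A|`, i.e. the fraction of the annotated
#' region recovered by the prediction. It is asymmetric by construction —
#' it equals 1 whenever the annotation is fully covered (`A` a subset of
#' `P`), regardless of how much further `P` extends.
#'
#' @param P,A Predicted and annotated regions, either logical matrices of
#'   identical dimension or integer vectors of pixel indices in the same
#'   raster frame.
#' @return Score in \[0, 1\].
#' @export
modified_iou <- function(P, A) {
  sets <- as_pixel_sets(P, A)
  if (length(sets$A) == 0) stop("annotated region A is empty; the score is undefined")
  length(intersect(sets$P, sets$A)) / length(sets$A)
}

as_pixel_sets <- function(P, A) {
  if (is.matrix(P) || is.matrix(A)) {
    if (!is.matrix(P) || !is.matrix(A) || !identical(dim(P), dim(A))) {
      stop("P and A must be matrices of identical dimension (same raster frame)")
    }
    P <- which(P != 0); A <- which(A != 0)
  }
  list(P = unique(as.integer(P)), A = unique(as.integer(A)))
}

#' Training agreement gate over per-morphotype overlap scores
#'
#' The acceptance rule for a trained segmentation model: every category of
#' interest must reach a modified IoU strictly greater than 0.9.
#'
#' @param scores Named numeric vector, one score per morphotype present in
#'   the annotation set.
#' @param threshold Gate threshold, default 0.9 (strict inequality).
#' @return `TRUE` iff all scores exceed the threshold.
#' @export
training_agreement_gate <- function(scores, threshold = 0.9) {
  if (length(scores) == 0) stop("no agreement scores supplied")
  if (any(is.na(scores))) stop("missing agreement score(s)")
  all(scores > threshold)
}

#' Cohen's kappa for paired presence/absence calls
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between two
#' raters' presence calls for one morphotype over the same sections, with
#' expected agreement from the product of the marginals. When both raters
#' are constant (`p_e = 1`) kappa is undefined and flagged.
#'
#' @param calls_a,calls_b Logical vectors of equal length (presence calls on
#'   the same sections).
#' @param morphotype Optional morphotype code recorded in the result.
#' @param rater_a,rater_b Optional rater identifiers.
#' @return List with `kappa` (`NA` when undefined), `p_observed`,
#'   `p_expected`, `n_items`, `undefined` flag and the identifiers.
#' @export
cohen_kappa <- function(calls_a, calls_b, morphotype = NA_character_,
                        rater_a = "A", rater_b = "B") {
  calls_a <- as.logical(calls_a); calls_b <- as.logical(calls_b)
  if (length(calls_a) != length(calls_b)) stop("call vectors differ in length")
  if (any(is.na(calls_a)) || any(is.na(calls_b))) stop("missing calls not allowed")
  n <- length(calls_a)
  if (n == 0) stop("no paired calls")
  p_o <- mean(calls_a == calls_b)
  pa <- mean(calls_a); pb <- mean(calls_b)
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  undefined <- abs(1 - p_e) < .Machine$double.eps^0.5
  kappa <- if (undefined) NA_real_ else (p_o - p_e) / (1 - p_e)
  list(rater_a = rater_a, rater_b = rater_b, morphotype = morphotype,
       kappa = kappa, p_observed = p_o, p_expected = p_e,
       n_items = n, undefined = undefined)
}

#' Pairwise per-morphotype kappa matrix from a rater-call table
#'
#' Computes Cohen's kappa for every rater pair and every morphotype,
#' matching calls by section. Presence/absence is used (not dominance
#' ranks); rank concordance is reported separately by [concordance_rate()].
#'
#' @param calls Rater-call table as read by [read_rater_calls()].
#' @return `data.frame`: `rater_a, rater_b, morphotype, kappa, n_items,
#'   undefined`.
#' @export
kappa_matrix <- function(calls) {
  raters <- sort(unique(calls$rater_id))
  if (length(raters) < 2) stop("need at least two raters")
  sections <- sort(unique(calls$section_id))
  present <- function(rater, morph) {
    sub <- calls[calls$rater_id == rater & calls$morphotype == morph, ]
    sections %in% sub$section_id[sub$present]
  }
  out <- list()
  for (i in seq_len(length(raters) - 1)) for (j in (i + 1):length(raters)) {
    for (m in MORPHOTYPE_CODES) {
      k <- cohen_kappa(present(raters[i], m), present(raters[j], m),
                       morphotype = m, rater_a = raters[i], rater_b = raters[j])
      out[[length(out) + 1]] <- data.frame(
        rater_a = k$rater_a, rater_b = k$rater_b, morphotype = m,
        kappa = k$kappa, n_items = k$n_items, undefined = k$undefined)
    }
  }
  do.call(rbind, out)
}

#' Concordance rate between paired ranked calls
#'
#' Fraction of call slots (e.g. dominant/secondary/tertiary per section)
#' where two assessors named the same morphotype, reported with its
#' numerator and denominator.
#'
#' @param ai_calls,pathologist_calls Equal-length character vectors of
#'   morphotype codes (one per call slot).
#' @return List with `rate`, `n_agree`, `n_total`.
#' @export
concordance_rate <- function(ai_calls, pathologist_calls) {
  if (length(ai_calls) != length(pathologist_calls)) {
    stop("call vectors are unpaired (different lengths)")
  }
  if (length(ai_calls) == 0) stop("no paired call slots")
  agree <- sum(ai_calls == pathologist_calls)
  list(rate = agree / length(ai_calls), n_agree = agree, n_total = length(ai_calls))
}
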