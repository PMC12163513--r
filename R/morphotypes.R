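#' Canonical morphotype vocabulary
#'
#' Six "pure" histological growth patterns of colorectal adenocarcinoma are
#' recognised: complex tubular (CT), solid/trabecular (TB), mucinous (MU),
#' papillary (PP), desmoplastic (DE) and serrated (SE). They map bijectively
#' onto raster label values 1--6 in this fixed order, which is the canonical
#' vector order used everywhere in the package (proportion columns, dominance
#' tie-breaks, output tables). Label value 0 is background / non-tumor.
#'
#' @return Character vector of the six morphotype codes, in canonical order.
#' @examples
#' morphotypes()
#' morphotype_label_value("DE")
#' morphotype_from_label(1:6)
#' @export
morphotypes <- function() MORPHOTYPE_CODES

MORPHOTYPE_CODES <- c("CT", "TB", "MU", "PP", "DE", "SE")

#' Section anatomical roles
#'
#' The four standardised tumor blocks: deepest invasion at the serosa front,
#' deepest invasion at the mesocolon/mesorectum front, the luminal
#' tumor-mucosa transition, and a central block.
#'
#' @return Character vector of the four role names.
#' @export
section_roles <- function() c("serosa", "mesocolon", "luminal", "central")

#' @rdname morphotypes
#' @param code Morphotype code(s), e.g. `"CT"`. The historical alias `"PA"`
#'   for papillary is accepted and mapped to `"PP"`.
#' @export
morphotype_label_value <- function(code) {
  code <- canonical_morphotype(code)
  match(code, MORPHOTYPE_CODES)
}

#' @rdname morphotypes
#' @param value Integer label value(s) in 1..6.
#' @export
morphotype_from_label <- function(value) {
  if (any(!value %in% 1:6)) {
    stop("label value(s) outside 1..6: ",
         paste(setdiff(unique(value), 1:6), collapse = ", "))
  }
  MORPHOTYPE_CODES[value]
}

# Accept the PA alias for papillary; reject anything outside the closed set.
canonical_morphotype <- function(code) {
  code <- as.character(code)
  code[code == "PA"] <- "PP"
  bad <- setdiff(unique(code), MORPHOTYPE_CODES)
  if (length(bad) > 0) {
    stop("unknown morphotype code(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(MORPHOTYPE_CODES, collapse = ", "), " (alias PA -> PP)")
  }
  code
}

# Proportion column names used in all tables, canonical order.
profile_cols <- function() paste0("p_", MORPHOTYPE_CODES)
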