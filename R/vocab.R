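# Controlled substrate vocabularies for the two domain types, plus the
# synonym groups under which a prediction is counted correct.

AT_CODES <- c(
  MC      = "malonyl-CoA",
  MMC     = "methylmalonyl-CoA",
  EMC     = "ethylmalonyl-CoA",
  MOMC    = "methoxymalonyl-CoA",
  PC      = "propionyl-CoA",
  IBuC    = "isobutyryl-CoA",
  `2MBuC` = "2-methylbutyryl-CoA",
  `3MbuC` = "3-methylbutyryl-CoA",
  BzC     = "benzoyl-CoA",
  AC      = "acetyl-CoA",
  CH      = "cyclohexanecarbonyl-CoA",
  CP      = "cyclopropanecarboxyl-CoA"
)

A_CODES <- c(
  ala = "alanine", arg = "arginine", asn = "asparagine", asp = "aspartate",
  cys = "cysteine", gln = "glutamine", glu = "glutamate", gly = "glycine",
  his = "histidine", ile = "isoleucine", leu = "leucine", lys = "lysine",
  met = "methionine", phe = "phenylalanine", pro = "proline", ser = "serine",
  thr = "threonine", trp = "tryptophan", tyr = "tyrosine", val = "valine",
  aad = "2-amino-adipic acid", abu = "2-amino-butyric acid",
  `allo-thr` = "allo-threonine", `b-ala` = "beta-alanine",
  bht = "beta-hydroxy-tyrosine", `b-lys` = "beta-lysine",
  bmt = "(4R)-4[(E)-2-butenyl]-4-methyl-L-threonine",
  dab = "2,4-diamino-butyric acid", dhab = "2,3-dehydroaminobutyric acid",
  dhb = "2,3-dihydroxy-benzoic acid", dhpg = "3,5-dihydroxy-phenyl-glycine",
  dpg = "3,5-dihydroxy-phenyl-glycine (dpg)", dht = "dehydro-threonine",
  `fN5H-orn` = "N5-formyl-N5-hydroxyornithine", horn = "N5-hydroxyornithine",
  hpg = "4-hydroxy-phenyl-glycine",
  hpg2Cl = "3,5-dichloro-4-hydroxy-L-phenylglycine",
  `hyv-d` = "D-hydroxyisovalerate", iva = "isovaline",
  `me-asp` = "methyl-aspartate", `me-pro` = "methyl-proline",
  orn = "ornithine", `phe-ac` = "phenylacetate", pip = "pipecolic acid",
  sal = "salicylic acid", sar = "sarcosine"
)

#' Substrate vocabulary for a domain type
#'
#' Returns the controlled vocabulary of substrate codes for AT (acyl-CoA
#' extender units such as malonyl-CoA) or A (proteinogenic and
#' non-proteinogenic amino acids) domains. Codes are matched
#' case-insensitively on input and canonicalized to these spellings.
#'
#' @param domain_type `"A"` or `"AT"`.
#' @param extra Optional named character vector of additional
#'   `code = "long name"` entries (used e.g. for synthetic benchmark labels).
#' @return An object of class `substrate_vocabulary`: a data.frame with
#'   columns `code` and `name` and a `domain_type` attribute.
#' @examples
#' v <- substrate_vocabulary("AT")
#' canonical_code(v, "mmc")   # "MMC"
#' @export
substrate_vocabulary <- function(domain_type = c("A", "AT"), extra = NULL) {
  domain_type <- match.arg(domain_type)
  codes <- if (domain_type == "AT") AT_CODES else A_CODES
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "")) {
      stopf("extra vocabulary entries must be named (code = long name)")
    }
    codes <- c(codes, extra)
  }
  if (anyDuplicated(tolower(names(codes)))) {
    dup <- names(codes)[duplicated(tolower(names(codes)))][1L]
    stopf("duplicate substrate code after case folding: '%s'", dup)
  }
  structure(
    data.frame(code = names(codes), name = unname(codes),
               stringsAsFactors = FALSE),
    domain_type = domain_type,
    class = c("substrate_vocabulary", "data.frame")
  )
}

#' Canonicalize substrate codes against a vocabulary
#'
#' @param vocabulary A [substrate_vocabulary()].
#' @param codes Character vector of substrate codes (any case).
#' @return Codes in their canonical spelling; unknown codes raise an error.
#' @export
canonical_code <- function(vocabulary, codes) {
  stopifnot(inherits(vocabulary, "substrate_vocabulary"))
  i <- match(tolower(codes), tolower(vocabulary$code))
  if (anyNA(i)) {
    bad <- unique(codes[is.na(i)])
    stopf("unknown substrate code(s) for domain type %s: %s",
          attr(vocabulary, "domain_type"), paste(bad, collapse = ", "))
  }
  vocabulary$code[i]
}

# Synonym groups: a prediction matching any member of the truth label's group
# counts as correct. These follow the label groupings used when reporting
# A-domain classification quality (e.g. "dhb, sal" as one row).
A_SYNONYMS <- list(
  c("dhb", "sal"),
  c("thr", "allo-thr"),
  c("hpg", "hpg2Cl"),
  c("dhab", "dht"),
  c("dhpg", "dpg"),
  c("pro", "me-pro"),
  c("abu", "iva")
)

#' Substrate synonym groups
#'
#' Groups of substrate codes treated as one label when scoring predictions:
#' a predicted code is correct if it falls in the same group as the true
#' code. AT domains have no synonym groups.
#'
#' @param domain_type `"A"` or `"AT"`.
#' @return A list of character vectors (possibly empty).
#' @export
substrate_synonyms <- function(domain_type = c("A", "AT")) {
  domain_type <- match.arg(domain_type)
  if (domain_type == "A") A_SYNONYMS else list()
}

# TRUE where prediction and truth agree directly or via a synonym group.
codes_equivalent <- function(predicted, truth, synonyms) {
  if (length(predicted) != length(truth)) stopf("length mismatch")
  same <- tolower(predicted) == tolower(truth)
  if (length(synonyms)) {
    for (grp in synonyms) {
      g <- tolower(grp)
      same <- same | (tolower(predicted) %in% g & tolower(truth) %in% g)
    }
  }
  same
}
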