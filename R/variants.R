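#' @keywords internal
"_PACKAGE"

# 20-letter standard amino-acid alphabet (no stop symbol)
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3TO1 <- c(Ala = "A", Cys = "C", Asp = "D", Glu = "E", Phe = "F",
            Gly = "G", His = "H", Ile = "I", Lys = "K", Leu = "L",
            Met = "M", Asn = "N", Pro = "P", Gln = "Q", Arg = "R",
            Ser = "S", Thr = "T", Val = "V", Trp = "W", Tyr = "Y")

#' Standard amino-acid alphabet
#'
#' The 20 one-letter codes of the standard amino acids, in alphabetical
#' order. Substitution variants are always drawn from this alphabet; stop
#' codons are not part of a site-saturation substitution library.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() AA20

#' Parse substitution variant notation
#'
#' Parses variant strings in either one-letter ("I91L") or three-letter
#' ("Ile91Leu") notation into a variant table. Mixed notations within one
#' vector are allowed; matching is case-sensitive for one-letter codes and
#' title-case for three-letter codes.
#'
#' @param x Character vector of variant strings.
#' @return A data.frame with columns \code{position} (integer, 1-based),
#'   \code{wt_aa} and \code{alt_aa} (one-letter codes).
#' @examples
#' parse_variants(c("I91L", "Glu242Thr"))
#' @export
parse_variants <- function(x) {
  if (!is.character(x)) stop("variant notation must be a character vector")
  m1 <- regmatches(x, regexec("^([A-Y])([0-9]+)([A-Y])$", x))
  m3 <- regmatches(x, regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", x))
  pos <- integer(length(x)); wt <- alt <- character(length(x))
  for (i in seq_along(x)) {
    if (length(m1[[i]]) == 4L &&
        m1[[i]][2] %in% AA20 && m1[[i]][4] %in% AA20) {
      wt[i] <- m1[[i]][2]; alt[i] <- m1[[i]][4]
      pos[i] <- as.integer(m1[[i]][3])
    } else if (length(m3[[i]]) == 4L &&
               m3[[i]][2] %in% names(AA3TO1) && m3[[i]][4] %in% names(AA3TO1)) {
      wt[i] <- AA3TO1[[m3[[i]][2]]]; alt[i] <- AA3TO1[[m3[[i]][4]]]
      pos[i] <- as.integer(m3[[i]][3])
    } else {
      stop("cannot parse variant string: '", x[i], "'")
    }
  }
  if (any(pos < 1L)) stop("variant positions must be >= 1")
  data.frame(position = pos, wt_aa = wt, alt_aa = alt,
             stringsAsFactors = FALSE)
}

#' Format variants in one-letter notation
#'
#' One-letter notation ("I91L") is the canonical output form.
#'
#' @param variants A data.frame with columns \code{position}, \code{wt_aa},
#'   \code{alt_aa}.
#' @return Character vector of variant strings.
#' @export
format_variants <- function(variants) {
  check_variant_table(variants)
  paste0(variants$wt_aa, variants$position, variants$alt_aa)
}

# Shared validation for variant-keyed tables.
check_variant_table <- function(variants, require_unique = FALSE) {
  needed <- c("position", "wt_aa", "alt_aa")
  if (!all(needed %in% names(variants)))
    stop("variant table must have columns position, wt_aa, alt_aa")
  if (!all(variants$wt_aa %in% AA20) || !all(variants$alt_aa %in% AA20))
    stop("amino-acid codes must be one-letter standard residues")
  if (any(variants$alt_aa == variants$wt_aa))
    stop("substitution must differ from the wild-type residue")
  if (any(variants$position < 1L))
    stop("positions are 1-based and must be >= 1")
  if (require_unique) {
    key <- paste(variants$position, variants$wt_aa, variants$alt_aa)
    if (anyDuplicated(key))
      stop("duplicate variant keys")
  }
  invisible(TRUE)
}

variant_key <- function(variants) {
  paste0(variants$wt_aa, variants$position, variants$alt_aa)
}
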