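#' Encode a sequence under a qualitative (3-group) property
#'
#' Replaces each residue by the index (1, 2 or 3) of the physicochemical
#' group it belongs to under the given partition. Position-wise: the
#' encoding of a concatenation is the concatenation of the encodings.
#'
#' @param residues Residue string over the 20-letter alphabet.
#' @param property Named integer vector mapping each residue to a group in
#'   1..3 (an element of `aa_property_tables()$qualitative`).
#' @return Integer vector of group indices, one per residue.
#' @export
#' @examples
#' tabs <- aa_property_tables()
#' encode_qualitative("KRDE", tabs$qualitative$charge)
encode_qualitative <- function(residues, property) {
  chars <- .residue_chars(residues)
  g <- unname(property[chars])
  if (anyNA(g)) {
    bad <- which(is.na(g))[1]
    stop("residue '", chars[bad], "' at position ", bad,
         " is absent from the property partition", call. = FALSE)
  }
  as.integer(g)
}

#' Encode a sequence under a quantitative (numeric) property scale
#'
#' Replaces each residue by its value under the given per-residue scale.
#' For descriptor extraction the scale should first be normalized to zero
#' mean and unit standard deviation over the 20 residues with
#' [normalize_property_scale()].
#'
#' @param residues Residue string over the 20-letter alphabet.
#' @param scale Named numeric vector of 20 per-residue values.
#' @return Numeric vector, one value per residue.
#' @export
#' @examples
#' h <- normalize_property_scale(aa_property_tables()$quantitative$H)
#' encode_quantitative("GG", h)
encode_quantitative <- function(residues, scale) {
  chars <- .residue_chars(residues)
  v <- unname(scale[chars])
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    stop("residue '", chars[bad], "' at position ", bad,
         " is absent from the property scale", call. = FALSE)
  }
  as.numeric(v)
}

# split a residue string into single characters, with basic validation
.residue_chars <- function(residues) {
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues)) {
    stop("residues must be a non-empty character scalar", call. = FALSE)
  }
  strsplit(residues, "", fixed = TRUE)[[1]]
}
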