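# Shared constants for the 5-element alphabet and the 8 H-containing coupling types.

#' Supported element symbols
#'
#' The element alphabet of the coupling datasets handled by this package:
#' carbon, hydrogen, nitrogen, oxygen and fluorine. Structures containing any
#' other element are rejected rather than coerced.
#'
#' @format Character vector of length 5.
#' @export
GAANN_ELEMENTS <- c("H", "C", "N", "O", "F")

#' Canonical coupling-type strings
#'
#' The eight hydrogen-containing scalar coupling types, written with the H
#' member first (the champs-scalar-coupling dialect): `<N>JH<X>` where `N` is
#' the number of bonds between the coupled nuclei and `X` the partner element.
#'
#' @format Character vector of length 8.
#' @export
GAANN_COUPLING_TYPES <- c("1JHC", "1JHN",
                          "2JHC", "2JHH", "2JHN",
                          "3JHC", "3JHH", "3JHN")

#' Covalent radii used for bond perception
#'
#' Single-bond covalent radii (Cordero-style consensus values, in Angstrom)
#' for the 5-element alphabet.
#'
#' @format Named numeric vector, Angstrom.
#' @export
GAANN_COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57)

# standard valences used by the synthetic generator
.GAANN_VALENCE <- c(C = 4L, N = 3L, O = 2L, H = 1L, F = 1L)

#' Parse a coupling-type string
#'
#' Accepts both element orders (`"1JHC"` and its alias `"1JCH"`) and returns
#' the parsed components with the hydrogen member first.
#'
#' @param type character vector of type strings.
#' @return data.frame with columns `n_bonds` (integer 1-3), `el0` (always
#'   `"H"`), `el1` (partner element) and `type` (canonical string).
#' @export
parse_coupling_type <- function(type) {
  m <- regmatches(type, regexec("^([123])J([CHNOF])([CHNOF])$", type))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("unknown coupling type string(s): ",
         paste(unique(type[bad]), collapse = ", "))
  }
  n  <- as.integer(vapply(m, `[`, "", 2L))
  e0 <- vapply(m, `[`, "", 3L)
  e1 <- vapply(m, `[`, "", 4L)
  swap <- e0 != "H" & e1 == "H"
  tmp <- e0[swap]; e0[swap] <- e1[swap]; e1[swap] <- tmp
  if (any(e0 != "H")) {
    stop("coupling type must involve hydrogen: ",
         paste(unique(type[e0 != "H"]), collapse = ", "))
  }
  canon <- sprintf("%dJ%s%s", n, e0, e1)
  bad2 <- !canon %in% GAANN_COUPLING_TYPES
  if (any(bad2)) {
    stop("coupling type outside the supported set: ",
         paste(unique(type[bad2]), collapse = ", "))
  }
  data.frame(n_bonds = n, el0 = e0, el1 = e1, type = canon,
             swapped = swap, stringsAsFactors = FALSE)
}
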