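#' Restriction enzyme definitions
#'
#' A restriction enzyme is described by its recognition site, the top-strand
#' cut position within the site (`cut_offset`, 0 = before the first site
#' base), and `tag_offset`: the offset within the site at which the RAD tag
#' (the start of read 1) begins once the sequencing adapter has restored the
#' overhang.  All built-in sites are palindromic, so fragments on either
#' side of a cut present the same tag structure.
#'
#' Built-ins: `SbfI` (CCTGCAGG, cut CCTGCA^GG, tags begin "TGCAGG"),
#' `NlaIII` (CATG, cut CATG^, tags begin "CATG") and `Sau3AI`
#' (GATC, cut ^GATC, tags begin "GATC").
#'
#' @param name Enzyme name.
#' @param site Recognition site (palindromic DNA string).
#' @param cut_offset Top-strand cut position within the site, in `[0, nchar(site)]`.
#' @param tag_offset Offset of the first read-1 base within the site.
#' @return An object of class `rad_enzyme`.
#' @examples
#' rad_enzyme("SbfI", "CCTGCAGG", cut_offset = 6, tag_offset = 2)
#' rad_enzymes()$NlaIII
#' @export
rad_enzyme <- function(name, site, cut_offset, tag_offset = 0L) {
  site <- toupper(site)
  stopifnot(nchar(site) >= 2L, grepl("^[ACGT]+$", site))
  if (cut_offset < 0 || cut_offset > nchar(site))
    stop("cut_offset must lie within the recognition site")
  if (site != revcomp(site))
    stop("built-in digest model assumes a palindromic recognition site")
  structure(
    list(name = name, site = site, cut_offset = as.integer(cut_offset),
         tag_offset = as.integer(tag_offset)),
    class = "rad_enzyme")
}

#' @rdname rad_enzyme
#' @export
rad_enzymes <- function() {
  list(
    SbfI   = rad_enzyme("SbfI",   "CCTGCAGG", cut_offset = 6L, tag_offset = 2L),
    NlaIII = rad_enzyme("NlaIII", "CATG",     cut_offset = 4L, tag_offset = 0L),
    Sau3AI = rad_enzyme("Sau3AI", "GATC",     cut_offset = 0L, tag_offset = 0L))
}

#' @export
print.rad_enzyme <- function(x, ...) {
  cat(sprintf("<rad_enzyme> %s  site %s  cut %s^%s\n", x$name, x$site,
              substr(x$site, 1, x$cut_offset),
              substr(x$site, x$cut_offset + 1, nchar(x$site))))
  invisible(x)
}

resolve_enzyme <- function(enzyme) {
  if (inherits(enzyme, "rad_enzyme")) return(enzyme)
  if (is.character(enzyme) && length(enzyme) == 1L) {
    tab <- rad_enzymes()
    hit <- match(tolower(enzyme), tolower(names(tab)))
    if (!is.na(hit)) return(tab[[hit]])
    stop("unknown enzyme: ", enzyme)
  }
  stop("enzyme must be a rad_enzyme or the name of a built-in")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, case preserved).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) revcomp_cpp(as.character(x))
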