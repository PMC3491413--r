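#' Read extracted ion chromatograms from CSV
#'
#' Dialect: header \code{species,rt_min,intensity}, one row per sampled
#' point, rows of one species contiguous or not (they are grouped).
#'
#' @param path CSV path.
#' @return list of \linkS4class{Chromatogram}s, in order of first
#'   appearance.
#' @export
readChromatograms <- function(path) {
  stopIfNot(file.exists(path), "no such file: ", path)
  tb <- utils::read.csv(path, colClasses = c("character", "numeric",
                                             "numeric"))
  stopIfNot(identical(colnames(tb), c("species", "rt_min", "intensity")),
            "expected header: species,rt_min,intensity")
  sp <- unique(tb$species)
  lapply(stats::setNames(sp, sp), function(s) {
    sub <- tb[tb$species == s, ]
    sub <- sub[order(sub$rt_min), ]
    chromatogram(s, sub$rt_min, sub$intensity)
  })
}

#' Write chromatograms as CSV
#' @param chroms list of \linkS4class{Chromatogram}s.
#' @param path output path.
#' @export
writeChromatograms <- function(chroms, path) {
  if (is(chroms, "Chromatogram")) chroms <- list(chroms)
  rows <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(species = ch@species, rt_min = ch@rt,
               intensity = ch@intensity)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a composite b-ion spectrum from CSV
#'
#' Dialect: header \code{site,acetyl_current,propionyl_current}, one row
#' per potentially modified residue.
#'
#' @param path CSV path.
#' @return a \linkS4class{CompositeSpectrum}.
#' @export
readCompositeSpectrum <- function(path) {
  stopIfNot(file.exists(path), "no such file: ", path)
  tb <- utils::read.csv(path, colClasses = c("character", "numeric",
                                             "numeric"))
  stopIfNot(identical(colnames(tb),
                      c("site", "acetyl_current", "propionyl_current")),
            "expected header: site,acetyl_current,propionyl_current")
  compositeSpectrum(tb$site, tb$acetyl_current, tb$propionyl_current)
}

#' Write a composite spectrum as CSV
#' @param spec a \linkS4class{CompositeSpectrum}.
#' @param path output path.
#' @export
writeCompositeSpectrum <- function(spec, path) {
  utils::write.csv(data.frame(site = spec@sites,
                              acetyl_current = spec@acetylCurrent,
                              propionyl_current = spec@propionylCurrent),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
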