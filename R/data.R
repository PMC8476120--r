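#' @include AllClasses.R
NULL

#' Published reference intensity-component tables
#'
#' The archived RJMCMC analysis of S1-GFP kymograph pixel intensities
#' reports, for seven- and nine-component mixture models, the average mean,
#' dispersion and weight of each fluorescence population (background plus
#' one class per number of bound myosins). These tables ship with the
#' package as plain CSV and are the canonical input for mid-point cut-off
#' assignment ([cutoffsFromMeans()], [assignCountsByCutoff()]). The
#' published "variance" column is a dispersion scale in intensity units and
#' is exposed here as `sd`.
#'
#' @param nComponents 9 (default) or 7.
#' @return data.frame with columns binders, mean, sd, weight.
#' @examples
#' tab <- referenceIntensityComponents()
#' cutoffsFromMeans(tab$mean)[1]   # 81.545: background / one-binder cut-off
#' @export
referenceIntensityComponents <- function(nComponents = 9L) {
  nComponents <- as.integer(nComponents)
  if (!nComponents %in% c(7L, 9L)) {
    stop("reference tables exist for 7 or 9 components")
  }
  path <- system.file("extdata",
                      sprintf("intensity_components_%d.csv", nComponents),
                      package = "collapseKinetics", mustWork = TRUE)
  read.csv(path)
}
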