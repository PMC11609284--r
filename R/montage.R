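# Electrode montage handling. The packaged montage is a 64-channel 10-10
# layout with head-centered coordinates in cm (x anterior, y left,
# z superior) on a 9-cm scalp sphere; it contains every ROI label used by
# the analysis (FCz, AFz, CPz and the full FC/C/CP rows).

#' Load a packaged electrode montage
#'
#' @param montageId montage identifier; currently "montage_64_1010".
#' @return data.frame with columns label, x_cm, y_cm, z_cm
#' @export
standardMontage <- function(montageId = "montage_64_1010") {
  path <- system.file("extdata", paste0(montageId, ".tsv"),
                      package = "cardiostop")
  if (!nzchar(path)) stop("unknown montage: ", montageId)
  readMontage(path)
}

#' Read a montage TSV (label, x_cm, y_cm, z_cm)
#' @param path file path.
#' @return data.frame
#' @export
readMontage <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("label", "x_cm", "y_cm", "z_cm")
  if (!all(need %in% names(m)))
    stop("montage file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$label)) stop("duplicate channel labels in montage")
  if (any(!is.finite(as.matrix(m[, need[-1]]))))
    stop("missing coordinate in montage")
  m[, need]
}
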