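#' The 16-channel active montage
#'
#' Ordered channel labels of the 10-20 placement used throughout the package:
#' 16 active recording sites (earlobe references and the ground are not
#' recorded).
#'
#' @return Character vector of 16 channel labels.
#' @export
doc_montage <- function() {
  c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4",
    "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6")
}

#' Left-hemisphere channels of the montage
#' @return Character vector of the 8 left-sided labels.
#' @export
left_channels <- function() c("FP1", "F3", "C3", "P3", "O1", "F7", "T3", "T5")

#' Project 10-20 electrode labels onto the unit head disk
#'
#' Returns deterministic 2-D coordinates (nose up, left hemisphere at
#' negative x) for the requested labels.  Right-side positions are exact
#' mirror images of their homologous left-side electrodes, so homologous
#' pairs are bitwise symmetric in x.
#'
#' @param labels Channel labels, a subset of [doc_montage()].
#' @return A data.frame with columns `label`, `x`, `y`; all points lie
#'   strictly inside the unit disk.
#' @export
project_montage <- function(labels = doc_montage()) {
  ring <- 0.95
  left <- list(
    FP1 = c(cospi(0.6), sinpi(0.6)) * ring,
    F7  = c(cospi(0.8), sinpi(0.8)) * ring,
    T3  = c(-ring, 0),
    T5  = c(cospi(1.2), sinpi(1.2)) * ring,
    O1  = c(cospi(1.4), sinpi(1.4)) * ring,
    F3  = c(-0.38, 0.475),
    C3  = c(-0.50, 0.000),
    P3  = c(-0.38, -0.475))
  homolog <- c(FP1 = "FP2", F7 = "F8", T3 = "T4", T5 = "T6",
               O1 = "O2", F3 = "F4", C3 = "C4", P3 = "P4")
  coords <- left
  for (l in names(homolog))
    coords[[homolog[[l]]]] <- c(-left[[l]][1], left[[l]][2])
  unknown <- setdiff(labels, names(coords))
  if (length(unknown) > 0)
    stop("unknown montage label(s): ", paste(unknown, collapse = ", "))
  xy <- do.call(rbind, coords[labels])
  data.frame(label = labels, x = xy[, 1], y = xy[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}
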